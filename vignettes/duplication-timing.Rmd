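---
title: "Timing gene duplications against the cyclostome-gnathostome split"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timing gene duplications against the cyclostome-gnathostome split}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupetime)
```

## The question and the method

Whether the two rounds of whole-genome duplication at the base of the
vertebrates happened before or after jawless vertebrates (cyclostomes:
lampreys, hagfishes) split from jawed vertebrates (gnathostomes) is hard to
read off single-gene trees: cyclostome sequences are notoriously unstable
in phylogenies.  Rather than trusting one estimated topology, `dupetime`
implements an exhaustive, probability-weighted version of the question for
one gene family at a time:

1. **Constrain** the gnathostome part of the gene tree to a backbone whose
   internal nodes are gene duplications of known identity.  For the
   shaker-related potassium channel (KCNA) family shipped as the default
   (`kcna_backbone()`), the eight gnathostome genes form three paralog
   pairs -- (KCNA1,2), (KCNA3,6), (KCNA5,10) -- created simultaneously by
   one chromosomal duplication of a three-gene cluster, with KCNA4 and
   KCNA7 branching successively outside.  Only the pairing among the three
   pair-clades is left free: all three resolutions are carried as equally
   allowed arrangements.
2. **Enumerate** every rooted topology obtained by attaching the query
   (e.g. a lamprey paralog) to any branch of any arrangement, including
   the branch above the root: 15 branches x 3 arrangements = 45 candidate
   topologies (`enumerate_placements()`).
3. **Score** each topology by maximum likelihood with branch lengths
   optimized under an empirical amino-acid model (JTT or LG, discrete
   gamma rates, optional invariant sites; `optimize_branch_lengths()`),
   and convert total log-likelihoods to normalized weights
   (`topology_weights()`), optionally by RELL bootstrap.
4. **Classify** every topology: the node created by the graft is the
   putative cyclostome-gnathostome speciation, and every duplication event
   on the backbone is timed against it (`classify_placements()`).
5. **Summarize**: weight-average the classifications into scenario
   probabilities and probabilistic duplication counts
   (`summarize_scenarios()`).

Scenario II means the cluster duplication predates the split (the query is
orthologous to genes inside the cluster); scenario I means it postdates it.

## The event-timing rule

Backbone internal nodes are grouped into *events* by a many-to-one map
(`event_model()`): the three pair nodes belong to one focal
cluster-duplication event; the two tandem-duplication nodes inside the
ancestral cluster and the KCNA4- and KCNA7-generating nodes are their own
events.  For a graft point S, an event is

* **before** the split if any of its nodes is a strict ancestor of S,
* **after** if any of its nodes descends from S,
* otherwise **undetermined** -- its nodes sit on "uncle" lineages whose
  duplications cannot be ordered against S.

One propagation step completes the rule: an undetermined event is pulled
to *before* when one of its nodes is ancestral to a node of an event
already classified before (it precedes something that precedes the split).
This is what produces the all-seven-before extreme when the query lands
inside a paralog pair: the pair node makes the single cluster event
"before", and the tandem nodes ancestral to the *other* pairs are dragged
along.  Duplications are *counted per node* but *timed per event*; an
unlinked per-node rule could never time more than the query's direct
ancestors and cannot reach that extreme.

Applied to the full enumeration this rule partitions the 45 topologies
into 21 scenario-I, 18 scenario-II and 6 ambiguous (query next to KCNA4 or
KCNA7) placements:

```{r partition}
placements <- enumerate_placements(kcna_backbone(), "query")
timings <- classify_placements(placements)
scenario_counts(timings)
```

Ambiguous placements donate half their weight to each scenario (the
`ambiguous_prior = 0.5` default), and undetermined node counts split the
same way, so for *any* weight vector P(I) + P(II) = 1 and
N_bef + N_aft = 7, the number of backbone duplication nodes:

```{r conservation}
summarize_scenarios(rep(1 / 45, 45), timings)
```

## Likelihood machinery

Felsenstein pruning runs over the 20-state amino-acid alphabet with the
published JTT and LG exchangeabilities (shipped as plain-text tables under
`extdata`), stationary or empirical (`+F`) frequencies, equal-probability
discrete gamma categories (slice means, Yang-style; slice medians behind a
flag), and an optional invariant class in the standard `+I+G` convention:
variable-category rates are rescaled by 1/(1 - p_inv) so one unit of
branch length stays one expected substitution per site.  Gaps and `X` are
missing data (partial vectors of ones).  Branch lengths are optimized by
cyclic Brent sweeps over branches with cached partial likelihoods (each
sweep costs roughly one tree traversal), bounded in [1e-8, 20], converging
when a sweep gains less than `tol` (default 1e-6) log-units or after
`max_sweeps` (default 50).  Per-site log-likelihoods feed both the RELL
bootstrap and the Kishino-Hasegawa standard errors behind the "within one
sigma of the best topology" candidate set.

Numerical notes, in the package's own defaults:

* Partial likelihoods are not rescaled; with the small trees this tool
  targets (tens of taxa at most) per-site likelihoods stay far above the
  double-precision underflow threshold.
* The two branches meeting at the root are not separately identifiable
  under a reversible model; only their sum is interpretable.
* Each placement starts from the arrangement's ML backbone lengths, so
  the per-placement optimization is a short polish rather than a cold
  start.
* Exact likelihood ties are real, not numerical noise (see below); the
  normalized-weight estimator splits them evenly, and the RELL estimator
  splits tied bootstrap wins evenly.

The topology-probability estimator defaults to normalized likelihood
weights (equal prior over the enumerated topologies) rather than bootstrap
proportions: scenario probabilities must sum to one per gene, which is the
defining property of the normalized estimator; RELL proportions are
provided as the alternative (`method = "rell"`, seeded).

## What the generators emulate -- and what they do not

`simulate_alignment()` evolves sites down a tree under the same models the
scorer uses (root states from the stationary distribution, one gamma
category per site).  `simulate_family()` builds ground-truth placements
for the recovery experiments: scenario II grafts the query on the KCNA1
terminal, scenario I on the cluster-stem branch, basal-ambiguous on the
KCNA4 terminal.  Backbone branch lengths default to 0.4 (terminals) and
0.2 (internals) substitutions per site, with a 0.4 query pendant --
deep-paralog divergences that give the placement problem realistic but not
trivial signal.

One deliberate choice deserves emphasis.  Under a reversible model a query
grafted on the **root branch** yields the same *unrooted* tree as grafts
on the KCNA7 terminal or on the KCNA4-clade stem; the three candidate
topologies tie in likelihood exactly, weights split three ways, and the
best attainable scenario-I probability from a root graft is
1/3 + 1/3 + (1/2)(1/3) = 5/6.  This is an identifiability property of the
model class, not an implementation artifact; a dedicated test asserts the
three-way tie and the 5/6 cap.  The scenario-I recovery experiments
therefore simulate the identifiable basal attachment (cluster stem), and
root grafts remain available via `branch_id = "ROOT"` for studying the
capped behaviour.

`generate_coding_set()` emulates the compositional phenomenon of a genome
whose coding GC at third positions is tunable: amino acids are drawn
i.i.d. from a fixed composition (JTT stationary frequencies by default, so
the package carries one canonical constant set), and within each
synonymous family codons are drawn with a G/C-ending tilt solved
numerically so the expected GC3 equals the target; the tilt never changes
the protein.  An optional per-family preferred-codon weight sharpens bias
beyond the GC effect (at the extreme, one codon per family and ENc near
20).  What these generators do **not** emulate: alignment error, indels,
among-lineage compositional heterogeneity, selection on codon usage linked
to expression, isochore structure.  Passing recovery tests therefore shows
the machinery is correct and well-calibrated under its own model class --
not that real lamprey data are this well behaved.

## Codon-usage statistics and ordination

Codon counts run over the 59 synonymous codons (61 sense codons minus ATG
and TGG); stop codons and N-containing triplets are excluded.  ENc is
Wright's estimator with families at their true degeneracy (Ile 3-fold; the
6-fold Leu/Ser/Arg unsplit): per-family homozygosity
F = (n * sum(p^2) - 1)/(n - 1) for families with n >= 2, averaged within
degeneracy classes, ENc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6 clamped to 61.  A
missing 3-fold class is imputed as (F2 + F4)/2 and any other missing class
by the weighted mean of observed classes (codonW-compatible behaviour);
genes with fewer than two observed classes get NA.  The no-selection
reference curve is ENc(s) = 2 + s + 29/(s^2 + (1 - s)^2) with s = GC3.
Species-level statistics are computed on concatenated coding sequence, the
convention the per-species ENc values follow; a per-gene mean is available
by aggregating the per-gene table.

Correspondence analysis is the standard chi-square SVD; total inertia
equals the Pearson chi-square over the grand total, a property tested on
random fixtures and cross-checked against vegan.  Within-group CA of codon
counts centres each cell on the expectation given the row's family total
and the table-wide within-family codon profile before the same
decomposition, with the original row and column masses retained.  Two
consequences define the method and are enforced by tests: rows with
identical within-family codon proportions produce zero inertia whatever
their amino-acid composition, and a single-family table reduces WCA to
plain CA.  Because the original WCA software's exact mass conventions are
not restated anywhere usable, the implementation documents this
formulation and proves its defining properties by test rather than
claiming numeric identity with ade4.  Axis signs are arbitrary; the first
non-zero column loading is made positive, and correlations with GC3
(`axis_gc_correlation()`) should be read through |r|.  CA of the RSCU
matrix (`ca_rscu()`, unobserved families imputed at the neutral value 1)
is provided as the conventional alternative and gives similar orderings.

## Problem sizes used in validation

The shipped test suite validates the likelihood engine against an
exhaustive state-enumeration oracle on 3-taxon trees, recovers branch
lengths from 10,000 simulated sites on a 4-taxon tree within 10%, and runs
the full placement pipeline on 20 seeded scenario-II and 20 seeded
scenario-I families of 1000 amino-acid sites each, requiring the true
scenario's probability to exceed 0.9 in at least 90% of replicates.  The
compositional track is validated on sweeps of 10 synthetic species (25
genes x 900 nt) with GC3 targets 0.3-0.9: realized GC3 within 0.02 of
target and |Spearman rho| >= 0.9 between the first WCA axis and GC3.
These sizes keep the whole suite in the tens of minutes on a single core
while leaving the statistical margins wide.

## Known limitations

* One query gene at a time; no joint placement of several cyclostome
  paralogs and no duplication-loss reconciliation model.
* No tree search: the backbone is an input, and its within-subgroup
  structure is trusted.
* Amino-acid models only (no codon or nucleotide likelihoods); no
  compositional (non-homogeneous) models, which is material when the
  query lineage's composition deviates as strongly as the lamprey's.
* The AU test and the rest of the CONSEL battery are out of scope; the
  package reports normalized weights, RELL proportions and the KH
  one-sigma set.
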