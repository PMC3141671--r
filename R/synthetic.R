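# Seeded generators: protein alignments evolved along a known tree under
# the package's substitution models, gene families simulated under the
# competing duplication-timing scenarios, and coding-sequence sets with a
# controllable GC3 target and within-family codon preference.

#' Simulate a protein alignment along a tree
#'
#' Root states are drawn from the model's stationary frequencies; states
#' then evolve down the tree with the model's transition matrices.  A
#' discrete gamma rate category is drawn once per site.
#'
#' @param tree `rooted_tree` or `phylo` with branch lengths.
#' @param model a [substitution_model()].
#' @param n_sites number of sites (>= 0).
#' @param seed mandatory integer seed.
#' @return a [protein_alignment()] over the tree's leaves (an empty
#'   0-column alignment when `n_sites = 0`).
#' @export
simulate_alignment <- function(tree, model, n_sites, seed) {
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  phy <- if (inherits(tree, "rooted_tree")) as_phylo(tree) else tree
  phy <- ape::reorder.phylo(phy, "cladewise")
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  root <- ntip + 1L
  state <- matrix(NA_integer_, nnode, n_sites)
  # per-site rate category: with p_inv, a site is invariant with prob p_inv
  K <- length(model$rates)
  cat_of_site <- sample.int(K, n_sites, replace = TRUE)
  if (model$p_inv > 0) {
    invariant <- runif(n_sites) < model$p_inv
  } else invariant <- rep(FALSE, n_sites)
  state[root, ] <- sample.int(20L, n_sites, replace = TRUE,
                              prob = model$freqs)
  if (n_sites > 0) {
    for (e in seq_len(nrow(phy$edge))) {
      p <- phy$edge[e, 1L]
      ch <- phy$edge[e, 2L]
      t <- phy$edge.length[e]
      child <- state[p, ]
      for (k in seq_len(K)) {
        sel <- which(cat_of_site == k & !invariant)
        if (!length(sel)) next
        P <- transition_matrix(model, t, rate = model$rates[k])
        for (a in unique(state[p, sel])) {
          idx <- sel[state[p, sel] == a]
          child[idx] <- sample.int(20L, length(idx), replace = TRUE,
                                   prob = P[a, ])
        }
      }
      state[ch, ] <- child
    }
  }
  seqs <- apply(state[seq_len(ntip), , drop = FALSE], 1L, function(s)
    paste(AA_ORDER[s], collapse = ""))
  if (n_sites == 0L) seqs <- rep("", ntip)
  protein_alignment(setNames(seqs, phy$tip.label))
}

#' Simulate a gene family under a duplication-timing scenario
#'
#' Grafts the query onto the branch that realises the requested scenario
#' (II: inside a paralog-pair clade, i.e. on the `KCNA1` terminal; I: on
#' the cluster-stem branch above node `C1`, the basal scenario-I
#' attachment; basal-ambiguous: on the `KCNA4` terminal), then simulates
#' an alignment on the resulting tree.  The true attachment is returned
#' for recovery tests.
#'
#' The cluster stem, not the root branch, is the scenario-I default
#' because under a reversible substitution model a root graft belongs to
#' an unrooted equivalence class of three rooted placements (root branch,
#' KCNA7 terminal, KCNA4-clade stem) whose likelihoods tie exactly, which
#' caps the recoverable scenario-I probability at 5/6; pass
#' `branch_id = "ROOT"` to study that behaviour deliberately.
#'
#' @param scenario `"II"`, `"I"` or `"basal-ambiguous"`; alternatively set
#'   `branch_id` explicitly.
#' @param n_sites alignment length.
#' @param seed mandatory integer seed.
#' @param spec a [backbone_spec()]; defaults to [kcna_backbone()].
#' @param arrangement arrangement id to simulate on (default: first).
#' @param branch_id overrides the scenario's default attachment branch.
#' @param query query leaf name.
#' @param model simulation model (default JTT with gamma 4, alpha 1).
#' @param pendant query pendant branch length.
#' @return list with `alignment`, `true_tree` (a `rooted_tree`),
#'   `true_branch`, `true_arrangement`, `scenario`.
#' @export
simulate_family <- function(scenario = c("II", "I", "basal-ambiguous"),
                            n_sites = 1000L, seed,
                            spec = kcna_backbone(), arrangement = NULL,
                            branch_id = NULL, query = "query",
                            model = substitution_model("JTT", alpha = 1),
                            pendant = 0.4) {
  if (missing(seed)) stop("a seed is required")
  scenario <- match.arg(scenario)
  if (is.null(arrangement)) arrangement <- names(spec$arrangements)[1]
  if (is.null(branch_id))
    branch_id <- switch(scenario, II = "KCNA1", I = "C1",
                        `basal-ambiguous` = "KCNA4")
  tr <- graft(spec$arrangements[[arrangement]], branch_id, query,
              pendant = pendant)
  aln <- simulate_alignment(tr, model, n_sites, seed = seed)
  list(alignment = aln, true_tree = tr, true_branch = branch_id,
       true_arrangement = arrangement, scenario = scenario)
}

# numeric solve for the GC3 tilt: within each synonymous family codon
# probabilities are base_w * exp(beta * is_gc3); beta is chosen so the
# expected GC3 over all codon draws (including the invariant ATG/TGG
# contribution) matches the target.
solve_gc3_tilt <- function(aa_freq, fam_weights, target) {
  fams <- synonymous_families()
  aa_multi <- names(fams)
  # per-amino-acid expected GC3 as a function of beta
  exp_gc3 <- function(beta) {
    contrib <- vapply(aa_multi, function(a) {
      cods <- fams[[a]]
      w <- fam_weights[[a]] * exp(beta * (substr(cods, 3L, 3L) %in% c("G", "C")))
      sum(w * (substr(cods, 3L, 3L) %in% c("G", "C"))) / sum(w)
    }, numeric(1))
    singles <- c(M = 1, W = 1)               # ATG, TGG end in G
    f <- aa_freq[c(aa_multi, names(singles))]
    sum(f * c(contrib, singles)) / sum(f)
  }
  lo <- exp_gc3(-30)
  hi <- exp_gc3(30)
  if (target <= lo) {
    warning("GC3 target ", target, " unattainable; clamped to ", round(lo, 4))
    return(-30)
  }
  if (target >= hi) {
    warning("GC3 target ", target, " unattainable; clamped to ", round(hi, 4))
    return(30)
  }
  uniroot(function(b) exp_gc3(b) - target, c(-30, 30), tol = 1e-9)$root
}

#' Generate a coding-sequence set with a target GC3
#'
#' Amino acids are drawn i.i.d. from a fixed composition (default: the JTT
#' stationary frequencies); within each synonymous family the codon is
#' drawn with probabilities tilted towards third-position G/C by a weight
#' solved numerically so the expected GC3 equals `gc3_target`.  The tilt
#' acts only on synonymous choice and never changes the protein.  An
#' additional within-family preference of strength `preference_strength`
#' (log-weight for one preferred codon per family, chosen among G/C-ending
#' codons when the target is >= 0.5 and A/T-ending otherwise) sharpens
#' codon bias beyond the GC effect; at extreme strength each family
#' collapses to a single codon and ENc approaches 20.
#'
#' @param n_genes number of genes.
#' @param gene_length gene length in nucleotides (divisible by 3).
#' @param gc3_target expected GC3 in (0, 1).
#' @param preference_strength non-negative log-weight (default 0).
#' @param seed mandatory integer seed.
#' @param aa_freq amino-acid composition (named 20-vector, default JTT).
#' @return a [coding_set()] of genes `g001 ...`.
#' @export
generate_coding_set <- function(n_genes, gene_length, gc3_target,
                                preference_strength = 0, seed,
                                aa_freq = NULL) {
  if (missing(seed)) stop("a seed is required")
  if (gene_length %% 3L != 0L) stop("gene_length must be divisible by 3")
  if (gc3_target <= 0 || gc3_target >= 1)
    stop("gc3_target must be in (0, 1)")
  set.seed(seed)
  if (is.null(aa_freq)) aa_freq <- load_aa_matrix("JTT")$freqs
  stopifnot(abs(sum(aa_freq) - 1) < 1e-6)
  fams <- synonymous_families()
  # per-family base weights carrying the preferred-codon tilt
  fam_weights <- lapply(names(fams), function(a) {
    cods <- fams[[a]]
    w <- rep(1, length(cods))
    if (preference_strength > 0) {
      gc_end <- substr(cods, 3L, 3L) %in% c("G", "C")
      pool <- if (gc3_target >= 0.5 && any(gc_end)) which(gc_end)
              else if (gc3_target < 0.5 && any(!gc_end)) which(!gc_end)
              else seq_along(cods)
      w[pool[1]] <- exp(preference_strength)
    }
    w
  })
  names(fam_weights) <- names(fams)
  beta <- solve_gc3_tilt(aa_freq, fam_weights, gc3_target)
  fam_prob <- lapply(names(fams), function(a) {
    cods <- fams[[a]]
    w <- fam_weights[[a]] *
      exp(beta * (substr(cods, 3L, 3L) %in% c("G", "C")))
    setNames(w / sum(w), cods)
  })
  names(fam_prob) <- names(fams)
  n_cod <- gene_length %/% 3L
  # sample only amino acids that have codons (drop none: all 20 do)
  seqs <- vapply(seq_len(n_genes), function(i) {
    aas <- sample(names(aa_freq), n_cod, replace = TRUE, prob = aa_freq)
    cods <- character(n_cod)
    cods[aas == "M"] <- "ATG"
    cods[aas == "W"] <- "TGG"
    for (a in intersect(unique(aas), names(fam_prob))) {
      idx <- which(aas == a)
      p <- fam_prob[[a]]
      cods[idx] <- sample(names(p), length(idx), replace = TRUE, prob = p)
    }
    paste(cods, collapse = "")
  }, character(1))
  coding_set(setNames(seqs, sprintf("g%03d", seq_len(n_genes))))
}
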