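test_that("alignment simulation is seed-deterministic and length-faithful", {
  m <- substitution_model("JTT", alpha = 1)
  a1 <- simulate_alignment(tree4(), m, 50, seed = 3)
  a2 <- simulate_alignment(tree4(), m, 50, seed = 3)
  expect_identical(a1$seqs, a2$seqs)
  a3 <- simulate_alignment(tree4(), m, 50, seed = 4)
  expect_false(identical(a1$seqs, a3$seqs))
  expect_identical(a1$n_sites, 50L)
  expect_error(simulate_alignment(tree4(), m, 10), "seed")
})

test_that("zero branch lengths reproduce the root state everywhere", {
  tr <- read_newick(text = "((A:0,B:0)ab:0,C:0)r;")
  aln <- simulate_alignment(tr, substitution_model("LG"), 30, seed = 1)
  expect_identical(aln$seqs[1], aln$seqs[2])
  expect_identical(aln$seqs[1], aln$seqs[3])
})

test_that("two-taxon identity proportion matches the transition matrix", {
  m <- substitution_model("JTT")
  t <- 0.5
  tr <- read_newick(text = sprintf("(A:%g,B:0)r;", t))
  n <- 100000
  aln <- simulate_alignment(tr, m, n, seed = 99)
  obs <- mean(strsplit(aln$seqs[1], "")[[1]] ==
              strsplit(aln$seqs[2], "")[[1]])
  P <- transition_matrix(m, t)
  p_ident <- sum(m$freqs * diag(P))
  se <- sqrt(p_ident * (1 - p_ident) / n)
  expect_lt(abs(obs - p_ident), 3 * se)
})

test_that("family simulation labels the true attachment", {
  sim <- simulate_family("II", n_sites = 20, seed = 2)
  expect_identical(sim$true_branch, "KCNA1")
  expect_true("query" %in% tree_leaves(sim$true_tree))
  expect_identical(sim$alignment$n_sites, 20L)
  sim_i <- simulate_family("I", n_sites = 10, seed = 2)
  expect_identical(sim_i$true_branch, "C1")
  sim_a <- simulate_family("basal-ambiguous", n_sites = 10, seed = 2)
  expect_identical(sim_a$true_branch, "KCNA4")
  # same seed -> byte-identical output
  sim2 <- simulate_family("II", n_sites = 20, seed = 2)
  expect_identical(sim$alignment$seqs, sim2$alignment$seqs)
})

test_that("coding-set generation hits its GC3 target", {
  cs <- generate_coding_set(100, 999, 0.85, seed = 1)
  expect_lt(abs(mean(gc3(cs)) - 0.85), 0.02)
  cs2 <- generate_coding_set(50, 999, 0.35, seed = 2)
  expect_lt(abs(mean(gc3(cs2)) - 0.35), 0.02)
  # determinism
  expect_identical(generate_coding_set(3, 300, 0.6, seed = 7)$seqs,
                   generate_coding_set(3, 300, 0.6, seed = 7)$seqs)
  expect_error(generate_coding_set(2, 301, 0.5, seed = 1), "divisible")
  expect_error(generate_coding_set(2, 300, 1.5, seed = 1), "gc3_target")
})

test_that("neutral tilt gives uniform codon usage; extreme preference collapses it", {
  # with beta solved for the family-neutral GC3, RSCU should be ~1
  fams <- dupetime:::synonymous_families()
  neutral <- local({
    # expected GC3 at beta = 0 under the default amino-acid composition
    aaf <- dupetime:::load_aa_matrix("JTT")$freqs
    contrib <- vapply(names(fams), function(a)
      mean(substr(fams[[a]], 3, 3) %in% c("G", "C")), numeric(1))
    f <- aaf[c(names(fams), "M", "W")]
    sum(f * c(contrib, 1, 1)) / sum(f)
  })
  cs <- generate_coding_set(60, 900, neutral, seed = 5)
  tab <- codon_count_table(cs, by = "dataset")
  r <- rscu(tab)
  n_per_fam <- tapply(as.numeric(tab),
                      dupetime:::GENETIC_CODE_STD[colnames(tab)], sum)
  # all RSCU within 3 SE of 1 (multinomial, uniform within family)
  for (a in names(fams)) {
    k <- length(fams[[a]])
    p <- 1 / k
    se <- sqrt(p * (1 - p) / n_per_fam[[a]]) * k   # SE on the RSCU scale
    expect_true(all(abs(r[1, fams[[a]]] - 1) < 3.5 * se))
  }

  # extreme preference: one codon per family, ENc -> 20
  # the extreme preference overrides the GC3 target (clamp warning)
  csx <- suppressWarnings(
    generate_coding_set(10, 900, 0.6, preference_strength = 50, seed = 6))
  expect_lt(enc(codon_count_table(csx, by = "dataset"))[[1]], 21)
})

test_that("unattainable GC3 targets are clamped with a warning", {
  expect_warning(generate_coding_set(2, 300, 1 - 1e-15, seed = 1),
                 "clamped")
  expect_warning(generate_coding_set(2, 300, 1e-15, seed = 1), "clamped")
})

test_that("ENc tracks the no-selection curve across a GC3 sweep", {
  targets <- seq(0.3, 0.9, by = 0.1)
  for (i in seq_along(targets)) {
    cs <- generate_coding_set(20, 900, targets[i], seed = 200 + i)
    tab <- codon_count_table(cs, by = "dataset")
    g3 <- mean(gc3(cs))
    expect_lt(abs(enc(tab)[[1]] - expected_enc(g3)), 5)
  }
})
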