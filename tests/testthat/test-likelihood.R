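test_that("zero-length tree gives the stationary-frequency likelihood", {
  tr <- read_newick(text = "(A:0,B:0)r;")
  m <- substitution_model("JTT")
  aln <- protein_alignment(c(A = "MKR", B = "MKR"))
  res <- pruning_loglik(aln, tr, m)
  expect_equal(res$loglik,
               sum(log(m$freqs[c("M", "K", "R")])),
               tolerance = 1e-10)
})

test_that("pruning equals the exhaustive state-enumeration oracle", {
  m <- substitution_model("JTT", alpha = 0.8, ncat = 4, p_inv = 0.1)
  tr <- tree3()
  aln <- simulate_alignment(tr, m, 5, seed = 42)
  res <- pruning_loglik(aln, tr, m)
  oracle <- brute_loglik3(aln, m, tA = 0.3, tB = 0.5, tU = 0.2, tC = 0.7)
  expect_equal(res$site_loglik, oracle, tolerance = 1e-10)

  # also with missing data in the alignment
  aln2 <- protein_alignment(c(A = "MK-RT", B = "MKRXT", C = "MKRRT"))
  res2 <- pruning_loglik(aln2, tr, m)
  oracle2 <- brute_loglik3(aln2, m, tA = 0.3, tB = 0.5, tU = 0.2, tC = 0.7)
  expect_equal(res2$site_loglik, oracle2, tolerance = 1e-10)
})

test_that("log-likelihood is invariant under re-rooting", {
  # the same unrooted 3-taxon tree (u-A 0.3, u-B 0.5, u-C 0.9) rooted on
  # each of its three branches
  m <- substitution_model("LG", alpha = 1.2, ncat = 4)
  aln <- simulate_alignment(tree3(), m, 40, seed = 11)
  rootings <- c("((A:0.3,B:0.5)u:0.4,C:0.5)r;",
                "((A:0.3,B:0.5)u:0.9,C:0.0)r;",
                "((A:0.3,C:0.9)u:0.2,B:0.3)r;",
                "((B:0.5,C:0.9)u:0.15,A:0.15)r;")
  ll <- vapply(rootings, function(s)
    pruning_loglik(aln, read_newick(text = s), m)$loglik, numeric(1))
  expect_true(all(abs(ll - ll[1]) < 1e-8))
})

test_that("likelihood agrees with phangorn on a fixed tree", {
  skip_if_not_installed("phangorn")
  m <- substitution_model("JTT", alpha = 1, ncat = 4)
  tr <- tree4()
  aln <- simulate_alignment(tr, m, 60, seed = 5)
  mine <- pruning_loglik(aln, tr, m)$loglik
  pd <- phangorn::phyDat(
    setNames(strsplit(aln$seqs, ""), aln$names), type = "AA")
  fit <- phangorn::pml(ape::unroot(as_phylo(tr)), pd, model = "JTT",
                       k = 4, shape = 1)
  expect_equal(mine, fit$logLik, tolerance = 1e-4)
})

test_that("branch lengths are recovered from data simulated on a known tree", {
  tr <- tree4()
  m <- substitution_model("JTT", alpha = 1)
  aln <- simulate_alignment(tr, m, 10000, seed = 3)
  fit <- optimize_branch_lengths(aln, tr, m)
  phy <- fit$tree
  el <- setNames(phy$edge.length,
                 c(phy$tip.label, phy$node.label)[phy$edge[, 2]])
  truth <- c(A = 0.2, B = 0.4, C = 0.3, D = 0.5)
  expect_equal(el[names(truth)], truth, tolerance = 0.1)
  # the two root-adjacent branches are only jointly identifiable
  expect_equal(unname(el["ab"] + el["cd"]), 0.15, tolerance = 0.1)
})

test_that("identical sequences drive branch lengths to the lower bound", {
  aln <- protein_alignment(c(A = "MKRTA", B = "MKRTA", C = "MKRTA"))
  fit <- optimize_branch_lengths(aln, tree3(), substitution_model("JTT"))
  expect_true(all(fit$tree$edge.length < 1e-4))
})

test_that("the optimum is insensitive to perturbed starting lengths", {
  m <- substitution_model("JTT", alpha = 1)
  aln <- simulate_alignment(tree4(), m, 500, seed = 9)
  f1 <- optimize_branch_lengths(aln, tree4(), m, tol = 1e-8)
  tr2 <- as_phylo(tree4())
  tr2$edge.length <- tr2$edge.length * 2
  f2 <- optimize_branch_lengths(aln, tr2, m, tol = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-4)
})

test_that("likelihood is unimodal around the optimum of a single branch", {
  m <- substitution_model("JTT")
  tr <- tree3()
  aln <- simulate_alignment(tr, m, 300, seed = 21)
  fit <- optimize_branch_lengths(aln, tr, m, tol = 1e-8)
  opt <- fit$tree
  idx <- which(c(opt$tip.label, opt$node.label)[opt$edge[, 2]] == "C")
  tC <- opt$edge.length[idx]
  lik_at <- function(t) {
    p <- opt
    p$edge.length[idx] <- t
    pruning_loglik(aln, p, m)$loglik
  }
  grid_left <- vapply(tC * c(0.2, 0.5, 0.9), lik_at, numeric(1))
  grid_right <- vapply(tC * c(1.1, 2, 5), lik_at, numeric(1))
  expect_true(all(diff(grid_left) > 0))     # rising towards the optimum
  expect_true(all(diff(grid_right) < 0))    # falling past it
  expect_true(all(c(grid_left, grid_right) < fit$loglik + 1e-9))
})

test_that("taxa missing from the alignment are reported", {
  aln <- protein_alignment(c(A = "MK", B = "MK"))
  expect_error(pruning_loglik(aln, tree3(), substitution_model("JTT")),
               "missing")
})
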