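test_that("CA reproduces chi-square inertia and hand-computed fixtures", {
  # 2x2 fixture: chi^2 = 2, n = 8 -> total inertia 0.25 on one axis
  X <- matrix(c(3, 1, 1, 3), 2, 2,
              dimnames = list(c("r1", "r2"), c("c1", "c2")))
  r <- ca(X)
  expect_equal(r$total_inertia, 0.25, tolerance = 1e-12)
  expect_length(r$eigenvalues, 1L)
  expect_equal(r$inertia_fraction, 1)

  # chi^2 / n identity on random count fixtures
  set.seed(10)
  for (i in 1:5) {
    Y <- matrix(rpois(48, lambda = 20) + 1, 6, 8)
    dimnames(Y) <- list(paste0("g", 1:6), paste0("c", 1:8))
    chi <- suppressWarnings(chisq.test(Y))$statistic
    expect_equal(ca(Y)$total_inertia, unname(chi) / sum(Y),
                 tolerance = 1e-9)
  }
})

test_that("CA agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(2)
  Y <- matrix(rpois(60, 15) + 1, 6, 10,
              dimnames = list(paste0("r", 1:6), paste0("c", 1:10)))
  mine <- ca(Y)
  ref <- vegan::cca(Y)
  expect_equal(unname(mine$eigenvalues),
               unname(ref$CA$eig[seq_along(mine$eigenvalues)]),
               tolerance = 1e-8)
  # row scores agree up to axis sign
  ref_scores <- vegan::scores(ref, display = "sites", scaling = 1,
                              choices = 1)[, 1]
  ratio <- mine$row_coord[, 1] / ref_scores
  expect_lt(sd(abs(mine$row_coord[, 1]) - abs(ref_scores)), 1e-6)
  expect_true(all(abs(abs(ratio) - abs(ratio[1])) < 1e-6))
})

test_that("degenerate CA inputs behave predictably", {
  # identical row profiles -> zero inertia, zero axes
  X <- rbind(a = c(10, 20, 30), b = c(1, 2, 3), c = c(5, 10, 15))
  colnames(X) <- paste0("c", 1:3)
  r <- ca(X)
  expect_equal(r$total_inertia, 0, tolerance = 1e-12)
  expect_length(r$eigenvalues, 0L)

  # all-zero margins are dropped with a warning
  Y <- rbind(a = c(5, 1, 2), b = c(1, 2, 8), z = c(0, 0, 0))
  colnames(Y) <- paste0("c", 1:3)
  expect_warning(rz <- ca(Y), "all-zero")
  expect_identical(nrow(rz$row_coord), 2L)
  expect_error(ca(matrix(-1, 2, 2)), "non-negative")
})

test_that("exchangeable tables give symmetric coordinates up to sign", {
  X <- matrix(c(5, 2, 1, 2, 5, 2, 1, 2, 5), 3, 3,
              dimnames = list(paste0("r", 1:3), paste0("c", 1:3)))
  r <- ca(X)   # X symmetric: row and column problems coincide
  expect_equal(abs(r$row_coord), abs(r$col_coord), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("WCA removes between-family structure", {
  # rows with very different amino-acid usage but identical within-family
  # codon proportions -> zero within-group inertia
  X <- rbind(a = c(10, 30, 5, 15), b = c(2, 6, 50, 150))
  colnames(X) <- c("AAA", "AAG", "TTT", "TTC")
  g <- setNames(c("K", "K", "F", "F"), colnames(X))
  expect_equal(wca(X, g)$total_inertia, 0, tolerance = 1e-12)

  # single-family table: WCA coincides with plain CA
  Y <- rbind(a = c(5, 10, 2, 3), b = c(1, 8, 9, 2), c = c(4, 4, 4, 4))
  colnames(Y) <- c("CTT", "CTC", "CTA", "CTG")
  gy <- setNames(rep("L", 4), colnames(Y))
  w1 <- wca(Y, gy)
  c1 <- ca(Y)
  expect_equal(w1$eigenvalues, c1$eigenvalues, tolerance = 1e-10)
  expect_equal(w1$row_coord, c1$row_coord, tolerance = 1e-9)

  # two-row GC-ending vs AT-ending fixture: one axis, opposite signs
  Z <- rbind(gc = c(1, 9, 2, 18), at = c(9, 1, 18, 2))
  colnames(Z) <- c("AAA", "AAG", "TTT", "TTC")
  wz <- wca(Z, g)
  expect_length(wz$eigenvalues, 1L)
  expect_equal(wz$inertia_fraction, 1)
  expect_lt(wz$row_coord[1, 1] * wz$row_coord[2, 1], 0)
})

test_that("within-group inertia never exceeds total CA inertia", {
  for (seed in 1:4) {
    cs <- generate_coding_set(5, 600, 0.4 + 0.1 * seed, seed = seed)
    tab <- codon_count_table(cs, by = "gene")
    suppressWarnings(   # sparse fixtures may drop unobserved codons
      expect_lte(wca(tab)$total_inertia, ca(tab)$total_inertia + 1e-12))
  }
})

test_that("axis-GC correlations behave under proportionality and noise", {
  set.seed(31)
  cs <- generate_coding_set(12, 900, 0.6, seed = 8)
  tab <- codon_count_table(cs, by = "gene")
  r <- wca(tab)
  # coordinates exactly proportional to the gc vector -> r^2 = 1
  fake_gc <- 0.2 + 0.05 * r$row_coord[, 1]
  expect_equal(axis_gc_correlation(r, fake_gc)$r_squared, 1,
               tolerance = 1e-12)
  # constant gc -> undefined, flagged
  expect_warning(out <- axis_gc_correlation(r, rep(0.5, 12)), "constant")
  expect_true(is.na(out$r))

  # independent vectors are rarely strongly correlated
  hits <- 0L
  for (i in 1:40) {
    x <- rnorm(100)
    y <- rnorm(100)
    if (abs(cor(x, y)) < 0.3) hits <- hits + 1L
  }
  expect_gte(hits, 38L)
})

test_that("CA of RSCU mirrors the codon-usage ordination", {
  sets <- lapply(1:6, function(i)
    generate_coding_set(10, 600, 0.3 + 0.08 * i, seed = 40 + i))
  names(sets) <- paste0("sp", 1:6)
  concat <- coding_set(setNames(
    vapply(sets, function(s) paste(s$seqs, collapse = ""), character(1)),
    names(sets)))
  tab <- codon_count_table(concat, by = "gene")
  g3 <- gc3(concat)
  rw <- wca(tab)
  rr <- ca_rscu(tab)
  # both orderings track GC3 strongly
  expect_gt(abs(cor(rw$row_coord[, 1], g3)), 0.9)
  expect_gt(abs(cor(rr$row_coord[, 1], g3)), 0.9)
})
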