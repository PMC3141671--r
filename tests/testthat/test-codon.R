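test_that("codon counting covers exactly the 59 synonymous codons", {
  cols <- colnames(codon_count_table(one_codon_per_aa_cds()))
  expect_length(cols, 59L)
  expect_false(any(c("ATG", "TGG", "TAA", "TAG", "TGA") %in% cols))
  # Met/Trp and stop codons never enter the counts
  cs <- suppressWarnings(coding_set(c(g = "ATGTGGTAAAAA")))
  tab <- codon_count_table(cs, by = "gene")
  expect_identical(sum(tab), 1)                 # only AAA counted
  expect_identical(unname(tab[1, "AAA"]), 1)
  # codons containing N are skipped
  cs2 <- coding_set(c(g = "AANAAA"))
  expect_identical(sum(codon_count_table(cs2, by = "gene")), 1)
})

test_that("GC3 and GC are direct positional proportions", {
  cs <- coding_set(c(a = "GGGAAA", b = "GGCGGC", c = "ATGTGG"))
  expect_equal(unname(gc3(cs)), c(0.5, 1.0, 1.0))
  expect_equal(unname(gc_content(cs)["a"]), 0.5)
  # N positions are excluded from the denominator
  csn <- coding_set(c(a = "GGNAAA"))
  expect_equal(unname(gc3(csn)), 0)
})

test_that("ENc spans its theoretical range", {
  # one codon per amino acid -> maximal bias, ENc = 20
  tab <- codon_count_table(one_codon_per_aa_cds(25))
  expect_equal(unname(enc(tab)), 20)

  # equal use of every sense codon -> ENc -> 61
  counts <- setNames(rep(100, 59), colnames(tab))
  expect_equal(unname(enc(counts)), 61, tolerance = 0.5)

  # ENc approximately invariant under scaling counts (large n)
  big <- setNames(round(seq(1000, 3000, length.out = 59)), colnames(tab))
  expect_equal(unname(enc(big)), unname(enc(big * 7L)), tolerance = 0.05)
})

test_that("ENc matches Wright's formula on a two-fold-only gene", {
  fams <- dupetime:::synonymous_families()
  two <- names(fams)[lengths(fams) == 2L]
  expect_length(two, 9L)
  counts <- setNames(numeric(59), colnames(codon_count_table(
    one_codon_per_aa_cds())))
  for (a in two) {
    counts[fams[[a]][1]] <- 80
    counts[fams[[a]][2]] <- 20
  }
  # a single observed degeneracy class is not enough for an estimate
  expect_true(is.na(enc(counts)))

  # add uniform 4-fold Ala usage: two observed classes, the rest imputed
  counts[c("GCT", "GCC", "GCA", "GCG")] <- 25
  f2 <- (100 * (0.8^2 + 0.2^2) - 1) / 99      # hand formula, p = (.8, .2)
  f4 <- (100 * 4 * 0.25^2 - 1) / 99           # uniform 4-fold
  f3 <- (f2 + f4) / 2                          # 3-fold imputation
  f6 <- (9 * f2 + 5 * f4) / 14                 # observed-class mean
  expect_equal(unname(enc(counts)),
               min(61, 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6),
               tolerance = 1e-9)

  # fewer than two observed degeneracy classes alone would be NA
  just_ile <- setNames(numeric(59), names(counts))
  just_ile[c("ATT", "ATC", "ATA")] <- c(5, 3, 2)
  expect_true(is.na(enc(just_ile)))
})

test_that("the no-selection ENc curve evaluates and peaks at GC3 = 0.5", {
  expect_equal(expected_enc(0), 31)
  expect_equal(expected_enc(1), 32)
  expect_equal(expected_enc(0.5), 60.5)
  s <- seq(0, 1, by = 0.01)
  v <- expected_enc(s)
  expect_equal(s[which.max(v)], 0.5)
  expect_true(all(diff(v[s <= 0.5]) > 0))
  expect_true(all(diff(v[s >= 0.5]) < 0))
  expect_error(expected_enc(1.2), "GC3")
})

test_that("RSCU values are count ratios against the family mean", {
  cols <- colnames(codon_count_table(one_codon_per_aa_cds()))
  counts <- setNames(numeric(59), cols)
  counts[c("TTT", "TTC")] <- c(3, 1)                       # Phe 2-fold
  counts[c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG")] <-
    c(6, 0, 0, 0, 0, 0)                                    # Leu 6-fold
  r <- rscu(counts)
  expect_equal(unname(r[1, c("TTT", "TTC")]), c(1.5, 0.5))
  expect_equal(unname(r[1, "TTA"]), 6)
  expect_equal(unname(r[1, "TTG"]), 0)
  expect_true(all(is.na(r[1, c("GGT", "GGC", "GGA", "GGG")])))

  # uniform usage -> RSCU 1 everywhere; family sums equal degeneracy
  u <- setNames(rep(4, 59), cols)
  ru <- rscu(u)
  expect_equal(unname(ru[1, ]), rep(1, 59))
  fams <- dupetime:::synonymous_families()
  r2 <- rscu(counts)
  expect_equal(sum(r2[1, fams$L]), 6)
  expect_equal(sum(r2[1, fams$F]), 2)
})

test_that("amino-acid composition is a permutation-invariant frequency", {
  expect_equal(aa_composition("MKMK"),
               setNames(c(rep(0, 10), 0, 0.5, 0.5, rep(0, 7)),
                        dupetime:::AA_ORDER)[dupetime:::AA_ORDER],
               tolerance = 1e-12)
  a <- aa_composition(c(x = "MKR", y = "TTW"))
  b <- aa_composition(c(y = "TTW", x = "MKR"))
  expect_identical(a, b)
  expect_equal(sum(a), 1)
  # gaps and X are ignored
  expect_equal(aa_composition("M-X")[["M"]], 1)
  expect_error(aa_composition("XX--"), "no canonical")
})

test_that("translation uses the standard code with N -> X", {
  cs <- suppressWarnings(coding_set(c(g = "ATGAAANNNTGA")))
  expect_identical(unname(translate_cds(cs)), "MKX*")
})
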