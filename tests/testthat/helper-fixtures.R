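# Shared fixtures, built in code.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# small rooted 3-taxon tree with lengths and labelled internals
tree3 <- function() read_newick(text = "((A:0.3,B:0.5)ab:0.2,C:0.7)r;")

# 4-taxon balanced tree
tree4 <- function() read_newick(
  text = "((A:0.2,B:0.4)ab:0.15,(C:0.3,D:0.5)cd:0.0)r;")

# brute-force pruning oracle: sum over all internal-state assignments of a
# 3-taxon tree ((A,B)u,C)root with the given branch lengths
brute_loglik3 <- function(aln, model, tA, tB, tU, tC) {
  states <- lapply(strsplit(aln$seqs, ""), function(s) match(s, AA20))
  names(states) <- aln$names
  K <- length(model$rates)
  vapply(seq_len(aln$n_sites), function(s) {
    xa <- states$A[s]; xb <- states$B[s]; xc <- states$C[s]
    tot <- 0
    for (k in seq_len(K)) {
      PU <- transition_matrix(model, tU, model$rates[k])
      PA <- transition_matrix(model, tA, model$rates[k])
      PB <- transition_matrix(model, tB, model$rates[k])
      PC <- transition_matrix(model, tC, model$rates[k])
      acc <- 0
      for (r in 1:20) for (i in 1:20) {
        la <- if (is.na(xa)) 1 else PA[i, xa]
        lb <- if (is.na(xb)) 1 else PB[i, xb]
        lc <- if (is.na(xc)) 1 else PC[r, xc]
        acc <- acc + model$freqs[r] * PU[r, i] * la * lb * lc
      }
      tot <- tot + acc * (1 - model$p_inv) / K
    }
    obs <- c(xa, xb, xc)
    obs <- obs[!is.na(obs)]
    if (model$p_inv > 0 && (length(obs) == 0L || length(unique(obs)) == 1L))
      tot <- tot + model$p_inv *
        (if (length(obs)) model$freqs[obs[1]] else 1)
    log(tot)
  }, numeric(1))
}

# deterministic toy codon set: one codon per amino acid, n copies each
one_codon_per_aa_cds <- function(n = 10L) {
  codons <- c("TTT", "CTT", "ATT", "GTT", "TCT", "CCT", "ACT", "GCT",
              "TAT", "CAT", "AAT", "GAT", "TGT", "CGT", "GGT", "CAA",
              "AAA", "GAA", "ATG", "TGG")
  coding_set(c(gene1 = paste(rep(codons, n), collapse = "")))
}

expect_tsv_columns <- function(path, cols) {
  testthat::expect_true(file.exists(path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  testthat::expect_true(all(cols %in% names(df)))
  invisible(df)
}
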