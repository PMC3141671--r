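# Codon-usage and amino-acid-composition statistics: codon counts over the
# 59 synonymous codons, GC/GC3, Wright's effective number of codons (ENc)
# and its no-selection expectation, and RSCU.

# standard genetic code, indexed by codon string
GENETIC_CODE_STD <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

# the 59 synonymous codons: sense codons minus stops, Met (ATG), Trp (TGG)
synonymous_codons <- function() {
  cod <- names(GENETIC_CODE_STD)
  aa <- GENETIC_CODE_STD
  sort(cod[aa != "*" & !cod %in% c("ATG", "TGG")])
}

# codon -> amino acid partition restricted to the 59 synonymous codons
synonymous_families <- function() {
  cods <- synonymous_codons()
  split(cods, GENETIC_CODE_STD[cods])
}

#' Codon count table
#'
#' Counts of the 59 synonymous codons (61 sense codons minus ATG and TGG)
#' per row.  Rows are genes (`by = "gene"`) or the whole set concatenated
#' into one row (`by = "dataset"`, the convention for species-level codon
#' usage).  Stop codons and codons containing N are excluded; for
#' sequences flagged with internal stops the stop triplets are skipped.
#'
#' @param cds a [coding_set()].
#' @param by `"gene"` or `"dataset"`.
#' @param dataset_name row name used when `by = "dataset"`.
#' @return matrix (rows x 59) of class `codon_count_table`, columns ordered
#'   by codon string.
#' @export
codon_count_table <- function(cds, by = c("gene", "dataset"),
                              dataset_name = "dataset") {
  by <- match.arg(by)
  cols <- synonymous_codons()
  count_one <- function(s) {
    cod <- codon_split(s)
    cod <- cod[!grepl("N", cod, fixed = TRUE)]
    cod <- cod[GENETIC_CODE_STD[cod] != "*"]
    tabulate(match(cod, cols), nbins = length(cols))
  }
  m <- t(vapply(cds$seqs, count_one, numeric(length(cols))))
  dimnames(m) <- list(cds$names, cols)
  if (by == "dataset") {
    m <- matrix(colSums(m), nrow = 1L,
                dimnames = list(dataset_name, cols))
  }
  structure(m, class = c("codon_count_table", class(m)))
}

#' GC and GC3 content of coding sequences
#'
#' `gc3()` is the proportion of G+C at third codon positions (all codons,
#' including ATG and TGG, count; codons containing N are skipped);
#' `gc_content()` is the overall proportion of G+C across all positions.
#'
#' @param cds a [coding_set()].
#' @return named numeric vector, one value per gene (NA when no position
#'   is countable).
#' @export
gc3 <- function(cds) {
  out <- vapply(cds$seqs, function(s) {
    cod <- codon_split(s)
    cod <- cod[!grepl("N", cod, fixed = TRUE)]
    if (length(cod) == 0L) return(NA_real_)
    third <- substr(cod, 3L, 3L)
    mean(third %in% c("G", "C"))
  }, numeric(1))
  setNames(out, cds$names)
}

#' @rdname gc3
#' @export
gc_content <- function(cds) {
  out <- vapply(cds$seqs, function(s) {
    chars <- strsplit(s, "")[[1]]
    chars <- chars[chars != "N"]
    if (length(chars) == 0L) return(NA_real_)
    mean(chars %in% c("G", "C"))
  }, numeric(1))
  setNames(out, cds$names)
}

# Wright's homozygosity estimate for one synonymous family
family_homozygosity <- function(counts) {
  n <- sum(counts)
  if (n < 2L) return(NA_real_)
  p <- counts / n
  (n * sum(p^2) - 1) / (n - 1)
}

#' Wright's effective number of codons (ENc)
#'
#' For each amino acid with k synonymous codons and at least two counted
#' codons, the codon homozygosity F is estimated; F values are averaged
#' within the degeneracy classes k = 2 (9 amino acids), 3 (Ile),
#' 4 (5 amino acids) and 6 (Leu, Ser, Arg), and
#' `ENc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, clamped to at most 61.
#' If the 3-fold class is unobserved its average is imputed as
#' `(F2 + F4)/2`; any other unobserved class is imputed with the weighted
#' mean homozygosity of the observed classes (so sparse genes still get an
#' estimate, in the spirit of codonW).  ENc is NA when fewer than two
#' degeneracy classes are observed or an observed class has zero mean
#' homozygosity.
#'
#' @param counts a `codon_count_table` (or one named row of it).
#' @return numeric vector of ENc values in `[20, 61]`, one per row.
#' @export
enc <- function(counts) {
  if (is.null(dim(counts)))
    counts <- matrix(counts, nrow = 1L, dimnames = list("x", names(counts)))
  fams <- synonymous_families()
  deg <- vapply(fams, length, integer(1))
  apply(counts, 1L, function(row) {
    fbar <- numeric(0)
    nf <- numeric(0)
    for (k in c(2L, 3L, 4L, 6L)) {
      fam_k <- fams[deg == k]
      fvals <- vapply(fam_k, function(cs) family_homozygosity(row[cs]),
                      numeric(1))
      fbar[as.character(k)] <- if (all(is.na(fvals))) NA_real_
                               else mean(fvals, na.rm = TRUE)
      nf[as.character(k)] <- length(fam_k)
    }
    obs <- !is.na(fbar)
    if (sum(obs) < 2L) return(NA_real_)
    if (is.na(fbar["3"]) && obs["2"] && obs["4"])
      fbar["3"] <- (fbar["2"] + fbar["4"]) / 2
    still <- is.na(fbar)
    if (any(still))
      fbar[still] <- sum(fbar[obs] * nf[obs]) / sum(nf[obs])
    if (any(fbar <= 0)) return(NA_real_)
    min(61, 2 + sum(nf / fbar))
  })
}

#' Expected ENc under no selection on codon usage
#'
#' Wright's null curve `ENc(s) = 2 + s + 29 / (s^2 + (1 - s)^2)` where `s`
#' is GC3; it rises from 31 at s = 0 to its maximum 60.5 at s = 0.5 and
#' falls back to 32 at s = 1.
#'
#' @param s GC3 value(s) in `[0, 1]`.
#' @return expected ENc value(s).
#' @export
expected_enc <- function(s) {
  if (any(s < 0 | s > 1, na.rm = TRUE)) stop("GC3 must lie in [0, 1]")
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' Relative synonymous codon usage
#'
#' `RSCU_c = x_c / mean(x over c's synonymous family)`; values sum to the
#' family's degeneracy within each observed family, and are NA for codons
#' of families with zero total count.
#'
#' @param counts a `codon_count_table` (or one named row).
#' @return matrix of RSCU values with the same shape and dimnames.
#' @export
rscu <- function(counts) {
  if (is.null(dim(counts)))
    counts <- matrix(counts, nrow = 1L, dimnames = list("x", names(counts)))
  fams <- synonymous_families()
  out <- counts * NA_real_
  for (cs in fams) {
    x <- counts[, cs, drop = FALSE]
    fam_mean <- rowMeans(x)
    vals <- x / fam_mean
    vals[fam_mean == 0, ] <- NA_real_
    out[, cs] <- vals
  }
  out
}

#' Amino-acid composition of a protein sequence set
#'
#' Frequencies of the 20 canonical residues over the concatenation of all
#' sequences; gaps and `X` are ignored.  Order of concatenation is
#' irrelevant.
#'
#' @param x a [protein_alignment()], named character vector of protein
#'   sequences, or a single string.
#' @return named numeric 20-vector summing to 1.
#' @export
aa_composition <- function(x) {
  if (inherits(x, "protein_alignment")) x <- x$seqs
  chars <- unlist(strsplit(toupper(x), ""), use.names = FALSE)
  counts <- table(factor(chars, levels = AA_ORDER))
  tot <- sum(counts)
  if (tot == 0L) stop("no canonical residues in input")
  setNames(as.numeric(counts) / tot, AA_ORDER)
}

#' Translate coding sequences to protein
#'
#' Standard-code translation; codons containing N become `X`, stop codons
#' become `*`.
#'
#' @param cds a [coding_set()].
#' @return named character vector of protein sequences.
#' @export
translate_cds <- function(cds) {
  out <- vapply(cds$seqs, function(s) {
    cod <- codon_split(s)
    aa <- GENETIC_CODE_STD[cod]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1))
  setNames(out, cds$names)
}

#' Per-gene codon-usage statistics table
#'
#' @param cds a [coding_set()].
#' @return data frame with `gene`, `n_codons`, `gc`, `gc3`, `enc`,
#'   `expected_enc` (the null-curve value at the gene's GC3).
#' @export
codon_stats <- function(cds) {
  tab <- codon_count_table(cds, by = "gene")
  g3 <- gc3(cds)
  data.frame(
    gene = cds$names,
    n_codons = as.integer(nchar(cds$seqs) %/% 3L),
    gc = as.numeric(gc_content(cds)),
    gc3 = as.numeric(g3),
    enc = as.numeric(enc(tab)),
    expected_enc = as.numeric(expected_enc(g3)),
    stringsAsFactors = FALSE, row.names = NULL)
}
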