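#' Protein alignment container
#'
#' A `protein_alignment` is a named character vector of aligned amino-acid
#' sequences (rows) of equal length over the alphabet of the 20 canonical
#' residues plus gap `-` and unknown `X`.  Gap and `X` are treated as missing
#' data throughout the likelihood machinery.
#'
#' @param seqs named character vector of aligned sequences.
#' @return object of class `protein_alignment`.
#' @export
protein_alignment <- function(seqs) {
  if (length(seqs) == 0L) stop("alignment is empty")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence identifiers: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- toupper(seqs)
  n <- unique(nchar(seqs))
  if (length(n) != 1L)
    stop("ragged alignment: rows differ in length (",
         paste(range(nchar(seqs)), collapse = "-"), ")")
  bad <- grepl(sprintf("[^%s%s]", paste(AA_ORDER, collapse = ""), "X-"), seqs)
  if (any(bad))
    stop("illegal characters in sequence(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  structure(list(names = names(seqs), seqs = unname(seqs), n_sites = n),
            class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("protein alignment:", length(x$names), "sequences x",
      x$n_sites, "sites\n")
  invisible(x)
}

#' In-frame coding sequence set
#'
#' Nucleotide coding sequences read in frame 1.  Lengths must be divisible
#' by three; sequences shorter than `min_codons` codons are dropped (the
#' conventional length filter for codon-usage work), and sequences with
#' internal stop codons are kept but flagged so that downstream codon
#' counting can skip the stops.
#'
#' @param seqs named character vector of nucleotide sequences (A, C, G, T, N).
#' @param min_codons minimum length in codons; shorter records are excluded
#'   with a warning (default 0 = keep everything).
#' @param genetic_code genetic code id; only `"standard"` is implemented.
#' @return object of class `coding_set` with fields `names`, `seqs`,
#'   `genetic_code` and logical `internal_stop`.
#' @export
coding_set <- function(seqs, min_codons = 0L, genetic_code = "standard") {
  if (length(seqs) == 0L) stop("coding set is empty")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  genetic_code <- match.arg(genetic_code, "standard")
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-nucleotide characters in: ", paste(names(seqs)[bad], collapse = ", "))
  off <- nchar(seqs) %% 3L != 0L
  if (any(off))
    stop("sequence length not divisible by 3 (frame error): ",
         paste(names(seqs)[off], collapse = ", "))
  short <- nchar(seqs) < 3L * min_codons
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than ", min_codons,
            " codons discarded")
    seqs <- seqs[!short]
    if (length(seqs) == 0L) stop("no sequences left after length filter")
  }
  stop_hit <- vapply(seqs, function(s) {
    cod <- codon_split(s)
    n <- length(cod)
    any(GENETIC_CODE_STD[cod[-n]] == "*", na.rm = TRUE)
  }, logical(1))
  if (any(stop_hit))
    warning("internal stop codon(s) in: ",
            paste(names(seqs)[stop_hit], collapse = ", "),
            " (stops are excluded from codon counts)")
  structure(list(names = names(seqs), seqs = unname(seqs),
                 genetic_code = genetic_code,
                 internal_stop = unname(stop_hit)),
            class = "coding_set")
}

#' @export
print.coding_set <- function(x, ...) {
  cat("coding sequence set:", length(x$names), "sequences,",
      sum(nchar(x$seqs)) %/% 3L, "codons total\n")
  invisible(x)
}

codon_split <- function(s) {
  n <- nchar(s) %/% 3L
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Read sequences from FASTA
#'
#' Order-preserving FASTA reader returning either a [protein_alignment()]
#' (`type = "protein"`) or a [coding_set()] (`type = "cds"`).
#'
#' @param path file path.
#' @param type `"protein"` or `"cds"`.
#' @param ... passed to the container constructor (e.g. `min_codons`).
#' @return `protein_alignment` or `coding_set`.
#' @export
read_fasta <- function(path, type = c("protein", "cds"), ...) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA records in ", path)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (hdr[i] + 1L > ends[i]) return("")
    paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")
  }, character(1))
  seqs <- gsub("[ \t]", "", seqs)
  if (any(!nzchar(seqs))) stop("empty FASTA record(s): ",
                               paste(ids[!nzchar(seqs)], collapse = ", "))
  names(seqs) <- ids
  if (type == "protein") protein_alignment(seqs, ...) else coding_set(seqs, ...)
}

#' Write sequences to FASTA
#'
#' @param x `protein_alignment`, `coding_set`, or named character vector.
#' @param path output file path.
#' @param width line width for wrapping (default 70).
#' @return invisibly, `path`.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (inherits(x, "protein_alignment") || inherits(x, "coding_set"))
    x <- setNames(x$seqs, x$names)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(paste0(">", names(x)[i]), con)
    s <- x[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a protein alignment in relaxed PHYLIP format
#'
#' Thin wrapper around [phangorn::read.phyDat()] accepting sequential or
#' interleaved PHYLIP.
#'
#' @param path file path.
#' @return a [protein_alignment()].
#' @export
read_phylip <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pd <- phangorn::read.phyDat(path, format = "phylip", type = "AA")
  m <- as.character(pd)
  seqs <- toupper(apply(m, 1L, paste, collapse = ""))
  seqs <- gsub("[?*]", "X", seqs)
  protein_alignment(setNames(seqs, rownames(m)))
}

as_alignment_matrix <- function(aln) {
  stopifnot(inherits(aln, "protein_alignment"))
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(m) <- aln$names
  m
}
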