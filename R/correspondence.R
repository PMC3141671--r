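# Correspondence analysis (CA) of non-negative composition tables and
# within-group CA (WCA) of codon counts.  CA is the standard chi-square
# ordination: with P = X/n, row masses r, column masses c, the SVD of
# D_r^{-1/2} (P - r c') D_c^{-1/2} yields principal inertias (squared
# singular values, summing to chi^2/n) and mass-scaled coordinates.  WCA
# removes between-amino-acid structure before the decomposition: each cell
# is centred on its expectation given the row's family total and the
# global within-family codon profile, so that only synonymous-choice
# variation is ordinated.

ca_core <- function(X, E, tol = 1e-12) {
  n <- sum(X)
  P <- X / n
  r <- rowSums(P)
  c <- colSums(P)
  S <- (P - E) / sqrt(r %o% c)
  sv <- svd(S)
  keep <- which(sv$d^2 > tol * max(sv$d^2, 1e-300))
  keep <- keep[sv$d[keep] > 1e-10]
  d <- sv$d[keep]
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  # sign convention: first nonzero column loading positive
  for (j in seq_along(d)) {
    nz <- which(abs(V[, j]) > 1e-12)
    if (length(nz) && V[nz[1], j] < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }
  if (length(d)) {
    row_coord <- (U * rep(d, each = nrow(U))) / sqrt(r)
    col_coord <- (V * rep(d, each = nrow(V))) / sqrt(c)
  } else {
    row_coord <- matrix(0, nrow(X), 0L)
    col_coord <- matrix(0, ncol(X), 0L)
  }
  axes <- if (length(d)) paste0("CA", seq_along(d)) else character(0)
  dimnames(row_coord) <- list(rownames(X), axes)
  dimnames(col_coord) <- list(colnames(X), axes)
  eig <- d^2
  structure(list(row_coord = row_coord, col_coord = col_coord,
                 eigenvalues = eig,
                 inertia_fraction = if (length(eig)) eig / sum(eig) else numeric(0),
                 total_inertia = sum(eig),
                 row_mass = r, col_mass = c),
            class = "ca_result")
}

#' @export
print.ca_result <- function(x, ...) {
  cat("correspondence analysis:", nrow(x$row_coord), "rows x",
      nrow(x$col_coord), "columns;", length(x$eigenvalues),
      "non-trivial axes\n")
  if (length(x$eigenvalues)) {
    cat("  total inertia:", format(x$total_inertia, digits = 6), "\n")
    cat("  leading axes:",
        paste(sprintf("%.1f%%", 100 * head(x$inertia_fraction, 4L)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

drop_zero_margins <- function(X) {
  zr <- rowSums(X) == 0
  zc <- colSums(X) == 0
  if (any(zr)) warning("dropping all-zero row(s): ",
                       paste(rownames(X)[zr], collapse = ", "))
  if (any(zc)) warning("dropping all-zero column(s): ",
                       paste(colnames(X)[zc], collapse = ", "))
  X[!zr, !zc, drop = FALSE]
}

#' Correspondence analysis
#'
#' @param X non-negative matrix or data frame (e.g. rows = species,
#'   columns = amino acids); all-zero rows/columns are dropped with a
#'   warning.
#' @return object of class `ca_result` with row/column principal
#'   coordinates, eigenvalues (principal inertias), inertia fractions and
#'   total inertia (= Pearson chi-square / grand total).
#' @export
ca <- function(X) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("input must be non-negative")
  X <- drop_zero_margins(X)
  if (nrow(X) < 2L || ncol(X) < 2L)
    stop("need at least two non-empty rows and columns")
  P <- X / sum(X)
  E <- rowSums(P) %o% colSums(P)
  ca_core(X, E)
}

#' Within-group correspondence analysis of codon counts
#'
#' CA of a codon count table after removing between-amino-acid structure:
#' each count is centred on the value expected from the row's total usage
#' of the codon's amino acid and the table-wide within-family codon
#' profile.  Rows with identical within-family codon proportions therefore
#' produce zero inertia regardless of their amino-acid composition.
#'
#' @param X a `codon_count_table` (or any count matrix whose columns can be
#'   partitioned by `groups`).
#' @param groups named character vector or factor mapping each column to
#'   its group (default: the codon-to-amino-acid map for the 59 synonymous
#'   codons).
#' @return a `ca_result`.
#' @export
wca <- function(X, groups = NULL) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("input must be non-negative")
  if (is.null(groups)) {
    fams <- synonymous_families()
    groups <- setNames(rep(names(fams), lengths(fams)),
                       unlist(fams, use.names = FALSE))
  }
  if (!all(colnames(X) %in% names(groups)))
    stop("every column must be assigned to a group")
  X <- drop_zero_margins(X)
  if (nrow(X) < 2L || ncol(X) < 2L)
    stop("need at least two non-empty rows and columns")
  g <- as.character(groups[colnames(X)])
  n <- sum(X)
  P <- X / n
  # global within-family codon profile m_{c|a}
  colp <- colSums(P)
  famp <- tapply(colp, g, sum)[g]            # per column: its family's mass
  m_c <- colp / famp
  # per-row family totals spread back onto columns
  rowfam <- t(apply(P, 1L, function(p) tapply(p, g, sum)[g]))
  colnames(rowfam) <- colnames(X)
  E <- rowfam * rep(m_c, each = nrow(P))
  ca_core(X, E)
}

#' CA of relative synonymous codon usage
#'
#' Convenience mode: CA applied to the RSCU matrix of a codon count table.
#' Codons of families unobserved in a row get the neutral value 1 so the
#' table stays complete.
#'
#' @param counts a `codon_count_table`.
#' @return a `ca_result`.
#' @export
ca_rscu <- function(counts) {
  R <- rscu(counts)
  R[is.na(R)] <- 1
  ca(R)
}

#' Correlation of a leading ordination axis with GC content
#'
#' Pearson correlation of the first (or chosen) row coordinate with a
#' per-row GC measure.  The sign of an ordination axis is arbitrary, so
#' `abs(r)` is the stable quantity; the signed value is reported as
#' obtained.
#'
#' @param result a `ca_result`.
#' @param gc numeric vector aligned with the rows (e.g. per-species GC3).
#' @param axis axis number (default 1).
#' @return list with `r`, `r_squared`, `axis`.
#' @export
axis_gc_correlation <- function(result, gc, axis = 1L) {
  stopifnot(inherits(result, "ca_result"))
  x <- result$row_coord[, axis]
  if (length(gc) != length(x)) stop("gc vector does not align with rows")
  if (sd(gc) == 0 || sd(x) == 0) {
    warning("constant vector: correlation undefined")
    return(list(r = NA_real_, r_squared = NA_real_, axis = axis))
  }
  r <- cor(x, gc)
  list(r = r, r_squared = r^2, axis = axis)
}
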