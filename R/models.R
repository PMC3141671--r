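# Empirical amino-acid substitution models.  Exchangeabilities and stationary
# frequencies for JTT (Jones, Taylor & Thornton 1992) and LG (Le & Gascuel
# 2008) are shipped as plain-text tables under extdata, in the conventional
# A R N D C Q E G H I L K M F P S T W Y V residue order.

model_cache <- new.env(parent = emptyenv())

load_aa_matrix <- function(name = c("JTT", "LG")) {
  name <- match.arg(name)
  if (!is.null(model_cache[[name]])) return(model_cache[[name]])
  file <- system.file("extdata",
                      paste0(tolower(name), "_exchangeabilities.tsv"),
                      package = "dupetime", mustWork = TRUE)
  lines <- readLines(file)
  lines <- lines[!startsWith(lines, "#")]
  fq <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  stopifnot(fq[1] == "frequencies")
  freqs <- as.numeric(fq[-1])
  names(freqs) <- AA_ORDER
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  S <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(20)))
  dimnames(S) <- list(AA_ORDER, AA_ORDER)
  stopifnot(isTRUE(all.equal(S, t(S))), all(S >= 0),
            abs(sum(freqs) - 1) < 1e-6)
  freqs <- freqs / sum(freqs)
  out <- list(S = S, freqs = freqs)
  model_cache[[name]] <- out
  out
}

#' Discretized gamma rate categories
#'
#' Equal-probability discretization of the Gamma(alpha, alpha) rate
#' distribution (mean 1).  Category rates are the means of the
#' inter-quantile slices (Yang's discrete gamma); `method = "median"` uses
#' slice medians rescaled to mean 1 instead.
#'
#' @param alpha gamma shape parameter (> 0).
#' @param k number of categories (>= 1).
#' @param method `"mean"` (default) or `"median"`.
#' @return numeric vector of k strictly increasing rates with mean 1.
#' @export
discretize_gamma <- function(alpha, k = 4L, method = c("mean", "median")) {
  method <- match.arg(method)
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  if (k < 1L) stop("k must be >= 1")
  if (k == 1L) return(1)
  q <- qgamma(seq_len(k - 1L) / k, shape = alpha, rate = alpha)
  if (method == "mean") {
    # E[X ; a < X < b] for X ~ Gamma(alpha, alpha) is
    # F_{alpha+1,alpha}(b) - F_{alpha+1,alpha}(a); each slice has mass 1/k
    cum <- pgamma(q, shape = alpha + 1, rate = alpha)
    rates <- k * diff(c(0, cum, 1))
  } else {
    med <- qgamma((seq_len(k) - 0.5) / k, shape = alpha, rate = alpha)
    rates <- med / mean(med)
  }
  rates
}

#' Construct an amino-acid substitution model
#'
#' Builds the scaled reversible rate matrix Q (expected one substitution per
#' site per unit branch length at stationarity), its spectral decomposition,
#' and the among-site rate model: k discrete gamma categories with shape
#' `alpha` plus an optional invariant-sites class with proportion `p_inv`.
#' With `p_inv` > 0 the variable-category rates are rescaled by
#' 1 / (1 - p_inv) so the overall mean rate stays 1.
#'
#' @param matrix `"JTT"` or `"LG"`.
#' @param alpha gamma shape; `NULL` for no rate variation.
#' @param ncat number of gamma categories (default 4).
#' @param p_inv proportion of invariant sites in `[0, 1)`; default 0.
#' @param frequencies `"model"` (the matrix's published frequencies) or a
#'   numeric 20-vector (e.g. empirical `+F` frequencies, see
#'   [empirical_frequencies()]).
#' @return object of class `substitution_model`.
#' @export
substitution_model <- function(matrix = c("JTT", "LG"), alpha = NULL,
                               ncat = 4L, p_inv = 0,
                               frequencies = "model") {
  matrix <- match.arg(matrix)
  base <- load_aa_matrix(matrix)
  if (identical(frequencies, "model")) {
    pi <- base$freqs
  } else {
    stopifnot(is.numeric(frequencies), length(frequencies) == 20L,
              all(frequencies > 0))
    pi <- frequencies / sum(frequencies)
    names(pi) <- AA_ORDER
  }
  if (!is.numeric(p_inv) || p_inv < 0 || p_inv >= 1)
    stop("p_inv must be in [0, 1)")
  rates <- if (is.null(alpha)) 1 else discretize_gamma(alpha, ncat)
  if (p_inv > 0) rates <- rates / (1 - p_inv)

  Q <- base$S * rep(pi, each = 20L)          # Q_ij = s_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  # spectral decomposition via the symmetrized matrix
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))                 # diag(sq) Q diag(1/sq)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  U <- (1 / sq) * e$vectors                  # diag(1/sq) V
  Uinv <- t(e$vectors) * rep(sq, each = 20L) # V' diag(sq)

  structure(list(name = matrix, S = base$S, freqs = pi, Q = Q,
                 alpha = alpha, ncat = if (is.null(alpha)) 1L else as.integer(ncat),
                 p_inv = p_inv, rates = rates,
                 U = U, Uinv = Uinv, lambda = e$values),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat(sprintf("substitution model %s%s%s%s\n", x$name,
              if (x$p_inv > 0) "+I" else "",
              if (!is.null(x$alpha)) sprintf("+G%d(alpha=%.3g)", x$ncat, x$alpha) else "",
              if (identical(unname(x$freqs), unname(load_aa_matrix(x$name)$freqs))) "" else "+F"))
  invisible(x)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model a [substitution_model()].
#' @param t branch length (expected substitutions per site), >= 0.
#' @param rate rate multiplier (e.g. a gamma category rate).
#' @return 20 x 20 row-stochastic matrix.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  if (t < 0) stop("branch length must be >= 0")
  P <- model$U %*% (exp(model$lambda * t * rate) * model$Uinv)
  P[P < 0] <- 0
  dimnames(P) <- list(AA_ORDER, AA_ORDER)
  P / rowSums(P)
}

#' Empirical residue frequencies of an alignment (+F)
#'
#' Counts over the 20 canonical residues, ignoring gaps and `X`,
#' renormalized to sum 1.  Zero counts are given a small pseudo-frequency
#' so the rate matrix stays irreducible.
#'
#' @param aln a [protein_alignment()].
#' @return named numeric 20-vector.
#' @export
empirical_frequencies <- function(aln) {
  m <- as_alignment_matrix(aln)
  counts <- table(factor(m, levels = AA_ORDER))
  f <- as.numeric(counts)
  if (all(f == 0)) stop("alignment contains no canonical residues")
  f[f == 0] <- 0.5                     # pseudo-count for unseen residues
  setNames(f / sum(f), AA_ORDER)
}
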