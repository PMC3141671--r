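# Topology weighting: normalized likelihood weights, RELL bootstrap
# proportions, and the Kishino-Hasegawa-style one-standard-error candidate
# set of topologies.

#' Normalized likelihood weights
#'
#' `w_t = exp(lnL_t - m) / sum_s exp(lnL_s - m)` with `m = max(lnL)`
#' (log-sum-exp stabilized).  With equal prior probability over candidate
#' topologies this is the approximate posterior probability of each
#' topology; weights are invariant under adding a constant to all values.
#'
#' @param lnl numeric vector of per-topology total log-likelihoods.
#' @return numeric vector of weights summing to 1.
#' @export
likelihood_weights <- function(lnl) {
  if (length(lnl) == 0L) stop("empty log-likelihood vector")
  if (any(!is.finite(lnl))) stop("non-finite log-likelihood")
  w <- exp(lnl - max(lnl))
  w / sum(w)
}

#' RELL bootstrap topology proportions
#'
#' Resampling of estimated log-likelihoods: sites are resampled with
#' replacement `B` times, per-topology totals are recomputed by summation
#' only (no re-optimization), and each topology's weight is the fraction of
#' replicates in which it attains the highest total; exact ties are split
#' equally.
#'
#' @param site_lnl matrix of per-site log-likelihoods, sites x topologies.
#' @param B number of bootstrap replicates (default 10000).
#' @param seed mandatory integer seed.
#' @return numeric vector of weights (length = number of topologies).
#' @export
rell_weights <- function(site_lnl, B = 10000L, seed) {
  site_lnl <- as.matrix(site_lnl)
  n <- nrow(site_lnl)
  k <- ncol(site_lnl)
  if (k < 2L) stop("need at least two topologies")
  if (n < 1L) stop("need at least one site")
  if (B < 1L) stop("B must be >= 1")
  if (missing(seed)) stop("a seed is required for RELL resampling")
  set.seed(seed)
  counts <- rmultinom(B, n, rep.int(1 / n, n))          # n x B
  totals <- crossprod(site_lnl, counts)                 # k x B
  w <- numeric(k)
  mx <- apply(totals, 2L, max)
  hit <- sweep(totals, 2L, mx, `>=`)
  share <- 1 / colSums(hit)
  w <- as.numeric(hit %*% share)
  w / B
}

#' Kishino-Hasegawa standard errors and the 1-sigma candidate set
#'
#' For each topology t, `delta(t) = max(lnL) - lnL_t` and `SE(t)` is the
#' standard error of that log-likelihood difference estimated from
#' per-site differences against the maximum-likelihood topology:
#' `SE(t) = sd_s(d_s) * sqrt(n_sites)`.  The 1-sigma set contains every
#' topology with `delta(t) <= SE(t)`; the ML topology itself is always a
#' member (delta = SE = 0).
#'
#' @param site_lnl matrix of per-site log-likelihoods, sites x topologies.
#' @return data frame with `lnl`, `delta_lnl`, `kh_se`, `in_1sigma_set`.
#' @export
kh_sigma_set <- function(site_lnl) {
  site_lnl <- as.matrix(site_lnl)
  n <- nrow(site_lnl)
  lnl <- colSums(site_lnl)
  best <- which.max(lnl)
  d <- site_lnl[, best] - site_lnl             # per-site differences
  se <- apply(d, 2L, sd) * sqrt(n)
  delta <- lnl[best] - lnl
  data.frame(lnl = lnl, delta_lnl = delta, kh_se = se,
             in_1sigma_set = delta <= se | seq_along(lnl) == best)
}

#' Topology weights for a placement set
#'
#' Wrapper combining total and per-site log-likelihoods into a tidy table
#' of weights plus KH 1-sigma membership.
#'
#' @param site_lnl sites x topologies matrix of per-site log-likelihoods;
#'   column names should be placement ids.
#' @param method `"lw"` (normalized likelihood weights, default) or
#'   `"rell"`.
#' @param B,seed RELL controls (see [rell_weights()]).
#' @return data frame with `placement_id`, `lnl`, `delta_lnl`, `kh_se`,
#'   `weight`, `in_1sigma_set`.
#' @export
topology_weights <- function(site_lnl, method = c("lw", "rell"),
                             B = 10000L, seed = NULL) {
  method <- match.arg(method)
  site_lnl <- as.matrix(site_lnl)
  kh <- kh_sigma_set(site_lnl)
  w <- if (method == "lw") likelihood_weights(kh$lnl)
       else rell_weights(site_lnl, B = B, seed = seed)
  out <- data.frame(
    placement_id = colnames(site_lnl) %||% paste0("p", seq_len(ncol(site_lnl))),
    kh, weight = w, stringsAsFactors = FALSE)
  attr(out, "method") <- method
  out[, c("placement_id", "lnl", "delta_lnl", "kh_se", "weight",
          "in_1sigma_set")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
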