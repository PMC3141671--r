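# Fixed-topology likelihood evaluation.  The heavy lifting (pruning,
# branch-length optimization) lives in src/pruning.cpp; this file prepares
# the tree/alignment encoding and exposes user-facing wrappers.

encode_tree_data <- function(aln, tree) {
  phy <- if (inherits(tree, "rooted_tree")) as_phylo(tree) else tree
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length))
    stop("tree has no branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch length")
  missing_taxa <- setdiff(phy$tip.label, aln$names)
  if (length(missing_taxa))
    stop("taxa missing from alignment: ", paste(missing_taxa, collapse = ", "))
  phy <- ape::reorder.phylo(phy, "postorder")
  m <- as_alignment_matrix(aln)[phy$tip.label, , drop = FALSE]
  idx <- matrix(match(m, AA_ORDER), nrow = nrow(m))   # NA for -, X
  # collapse identical site patterns
  key <- apply(idx, 2L, paste, collapse = ",")
  upat <- !duplicated(key)
  map <- match(key, key[upat])
  patw <- as.numeric(tabulate(map, nbins = sum(upat)))
  states <- idx[, upat, drop = FALSE] - 1L
  states[is.na(states)] <- -1L
  ntip <- length(phy$tip.label)
  el <- numeric(ntip + phy$Nnode)
  el[phy$edge[, 2L]] <- phy$edge.length
  list(phy = phy, edge = phy$edge, ntip = ntip, nnode = ntip + phy$Nnode,
       el = el, states = states, patw = patw, pattern_of_site = map)
}

call_site_loglik <- function(enc, model, el = enc$el) {
  site_loglik_cpp(enc$edge, enc$ntip, enc$nnode, el,
                  enc$states, enc$patw, model$U, model$Uinv, model$lambda,
                  unname(model$freqs), model$rates, model$p_inv)
}

#' Per-site log-likelihood of an alignment on a fixed tree
#'
#' Felsenstein pruning under an empirical amino-acid model with discrete
#' gamma rate categories and an optional invariant-sites class.  Gaps and
#' `X` are treated as missing data.  Under a reversible model the result is
#' invariant to the position of the root.
#'
#' @param aln a [protein_alignment()] containing every tree taxon.
#' @param tree a `rooted_tree` or `phylo` with branch lengths.
#' @param model a [substitution_model()].
#' @return list with `site_loglik` (per-site vector) and `loglik` (sum).
#' @export
pruning_loglik <- function(aln, tree, model) {
  enc <- encode_tree_data(aln, tree)
  res <- call_site_loglik(enc, model)
  sl <- res$pattern_loglik[enc$pattern_of_site]
  if (any(!is.finite(sl))) stop("non-finite site log-likelihood")
  list(site_loglik = sl, loglik = sum(sl))
}

#' Maximum-likelihood branch lengths on a fixed topology
#'
#' Cyclic one-dimensional (Brent) optimization of every branch length in
#' depth-first sweeps, using cached partial likelihoods so each sweep costs
#' one full tree traversal.  Lengths are bounded in `[1e-8, 20]`.  The two
#' branches meeting at the root are not separately identifiable under a
#' reversible model; only their sum is determined.
#'
#' @param aln a [protein_alignment()].
#' @param tree a `rooted_tree` or `phylo`; branch lengths are used as
#'   starting values (missing lengths default to 0.1).
#' @param model a [substitution_model()].
#' @param tol convergence tolerance on the log-likelihood gain per sweep.
#' @param max_sweeps maximum number of sweeps.
#' @return list with `tree` (a `phylo` carrying optimized lengths),
#'   `loglik`, `site_loglik`, `iterations`, `converged`.
#' @export
optimize_branch_lengths <- function(aln, tree, model, tol = 1e-6,
                                    max_sweeps = 50L) {
  phy <- if (inherits(tree, "rooted_tree")) as_phylo(tree) else tree
  if (is.null(phy$edge.length))
    phy$edge.length <- rep(0.1, nrow(phy$edge))
  phy$edge.length[is.na(phy$edge.length)] <- 0.1
  phy$edge.length[phy$edge.length < 1e-8] <- 1e-8
  enc <- encode_tree_data(aln, phy)
  res <- optimize_bl_cpp(enc$edge, enc$ntip, enc$nnode, enc$el,
                         enc$states, enc$patw, model$U, model$Uinv,
                         model$lambda, unname(model$freqs), model$rates,
                         model$p_inv, tol, as.integer(max_sweeps))
  if (!res$converged)
    warning("branch-length optimization did not converge in ",
            max_sweeps, " sweeps (returning last iterate)")
  out <- enc$phy
  out$edge.length <- res$el[out$edge[, 2L]]
  list(tree = out, loglik = res$loglik,
       site_loglik = res$pattern_loglik[enc$pattern_of_site],
       iterations = res$iterations, converged = res$converged)
}

#' Estimate gamma shape (and optionally p_inv) on a fixed topology
#'
#' One- or two-dimensional outer optimization of the among-site rate
#' parameters, re-optimizing branch lengths at every candidate value.  This
#' is intended to be run once on a reference (backbone) topology, after
#' which the fitted model is held fixed across candidate placements.
#'
#' @param aln a [protein_alignment()].
#' @param tree starting tree with branch lengths.
#' @param matrix `"JTT"` or `"LG"`.
#' @param ncat gamma categories.
#' @param estimate_pinv also estimate the invariant-sites proportion.
#' @param frequencies `"model"` or a 20-vector (see [substitution_model()]).
#' @param bl_tol,bl_sweeps inner branch-length optimization controls.
#' @return the fitted [substitution_model()] with attribute `"loglik"`.
#' @export
estimate_rate_model <- function(aln, tree, matrix = "JTT", ncat = 4L,
                                estimate_pinv = FALSE, frequencies = "model",
                                bl_tol = 1e-4, bl_sweeps = 20L) {
  obj1 <- function(log_alpha) {
    m <- substitution_model(matrix, alpha = exp(log_alpha), ncat = ncat,
                            frequencies = frequencies)
    optimize_branch_lengths(aln, tree, m, tol = bl_tol,
                            max_sweeps = bl_sweeps)$loglik
  }
  if (!estimate_pinv) {
    opt <- optimise(obj1, lower = log(0.05), upper = log(50), maximum = TRUE,
                    tol = 1e-3)
    fit <- substitution_model(matrix, alpha = exp(opt$maximum), ncat = ncat,
                              frequencies = frequencies)
    attr(fit, "loglik") <- opt$objective
    return(fit)
  }
  obj2 <- function(par) {
    alpha <- exp(par[1])
    pinv <- plogis_(par[2]) * 0.9
    m <- substitution_model(matrix, alpha = alpha, ncat = ncat, p_inv = pinv,
                            frequencies = frequencies)
    -optimize_branch_lengths(aln, tree, m, tol = bl_tol,
                             max_sweeps = bl_sweeps)$loglik
  }
  opt <- optim(c(0, -2), obj2, method = "Nelder-Mead",
               control = list(maxit = 60, reltol = 1e-5))
  fit <- substitution_model(matrix, alpha = exp(opt$par[1]), ncat = ncat,
                            p_inv = plogis_(opt$par[2]) * 0.9,
                            frequencies = frequencies)
  attr(fit, "loglik") <- -opt$value
  fit
}

plogis_ <- function(x) 1 / (1 + exp(-x))
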