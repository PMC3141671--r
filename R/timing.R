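# Classification of candidate placements into duplication-timing scenarios.
#
# Every internal node of the backbone is a gene duplication; a many-to-one
# event map groups nodes that were created by one and the same event (for
# KCNA, the chromosomal duplication of the tri-gene cluster manifests as
# the three paralog-pair nodes simultaneously).  Grafting the query creates
# the putative cyclostome-gnathostome speciation node S, and each event is
# timed relative to S:
#
#   * "before" the split if any of its nodes is a strict ancestor of S;
#   * otherwise "after" if any of its nodes descends from S;
#   * otherwise "undetermined" (all nodes sit in lineages branching off
#     from ancestors of S -- "uncle" lineages, unordered relative to S).
#
# One refinement follows from the event linkage: an event whose nodes are
# all uncles of S is still necessarily "before" if one of its nodes is an
# ancestor of a node belonging to a "before" event -- it precedes an event
# that precedes the split.  (For KCNA: with the query inside one paralog
# pair, the cluster duplication is "before" via that pair node, and the
# tandem duplications ancestral to the *other* pair nodes are dragged
# "before" with it, giving the all-seven-before extreme.)

#' Duplication event model
#'
#' @param nodes character vector of backbone internal-node labels.
#' @param events parallel character vector of event ids (many-to-one).
#' @param focal the event id whose timing defines the scenarios (before the
#'   split = scenario II, after = scenario I).
#' @return object of class `event_model`.
#' @export
event_model <- function(nodes, events, focal) {
  stopifnot(length(nodes) == length(events), !anyDuplicated(nodes))
  if (!focal %in% events) stop("focal event not among events: ", focal)
  structure(list(nodes = as.character(nodes), events = as.character(events),
                 focal = focal),
            class = "event_model")
}

#' @export
print.event_model <- function(x, ...) {
  cat("event model:", length(unique(x$events)), "events over",
      length(x$nodes), "nodes; focal =", x$focal, "\n")
  invisible(x)
}

#' Event model for the KCNA backbone
#'
#' Maps the three paralog-pair nodes (`P12`, `P36`, `P510`) to the single
#' focal cluster-duplication event, the two nodes inside the ancestral
#' tri-gene cluster (`C1`, `C2`) to separate tandem-duplication events, and
#' the KCNA4- and KCNA7-generating nodes (`A4`, `RN`) to their own events.
#'
#' @return an [event_model()].
#' @export
kcna_events <- function() {
  event_model(
    nodes  = c("P12", "P36", "P510", "C1", "C2", "A4", "RN"),
    events = c("cluster_dup", "cluster_dup", "cluster_dup",
               "tandem_a", "tandem_b", "kcna4_dup", "kcna7_dup"),
    focal = "cluster_dup")
}

#' Read an event map from TSV
#'
#' Expects columns `node_label`, `event_id`, `is_focal` (logical; exactly
#' one event may be flagged focal).
#'
#' @param path TSV file path.
#' @return an [event_model()].
#' @export
read_events <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("node_label", "event_id", "is_focal")
  if (!all(need %in% names(df)))
    stop("event map must have columns: ", paste(need, collapse = ", "))
  focal <- unique(df$event_id[as.logical(df$is_focal)])
  if (length(focal) != 1L) stop("exactly one event must be flagged focal")
  event_model(df$node_label, df$event_id, focal)
}

#' Write an event map as TSV
#' @param events an [event_model()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_events <- function(events, path) {
  write.table(
    data.frame(node_label = events$nodes, event_id = events$events,
               is_focal = events$events == events$focal),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_events <- function(events, tree) {
  internals <- internal_labels(tree)
  missing <- setdiff(internals, events$nodes)
  if (length(missing))
    stop("backbone internal node(s) not mapped to an event: ",
         paste(missing, collapse = ", "))
  # nodes sharing an event must be pairwise non-ancestral
  anc <- ancestor_map(tree)
  for (ev in unique(events$events)) {
    nd <- intersect(events$nodes[events$events == ev], internals)
    for (a in nd)
      if (any(nd %in% anc[[a]]))
        stop("event '", ev, "' contains ancestrally related nodes")
  }
  invisible(TRUE)
}

classify_one <- function(tree, branch_id, events) {
  validate_events(events, tree)
  internals <- internal_labels(tree)
  ctx <- branch_context(tree, branch_id)
  anc_map <- ancestor_map(tree)
  ev_ids <- unique(events$events)
  ev_nodes <- lapply(ev_ids, function(e)
    intersect(events$nodes[events$events == e], internals))
  names(ev_nodes) <- ev_ids

  timing <- vapply(ev_ids, function(e) {
    nd <- ev_nodes[[e]]
    if (any(nd %in% ctx$ancestors)) "before"
    else if (any(nd %in% ctx$descendants)) "after"
    else "undetermined"
  }, character(1))

  # drag uncles that are ancestral to nodes of a "before" event to "before"
  repeat {
    before_nodes <- unlist(ev_nodes[timing == "before"], use.names = FALSE)
    anc_of_before <- unique(unlist(anc_map[before_nodes], use.names = FALSE))
    promote <- timing == "undetermined" &
      vapply(ev_ids, function(e) any(ev_nodes[[e]] %in% anc_of_before),
             logical(1))
    if (!any(promote)) break
    timing[promote] <- "before"
  }

  n_nodes <- vapply(ev_nodes, length, integer(1))
  n_bef <- sum(n_nodes[timing == "before"])
  n_aft <- sum(n_nodes[timing == "after"])
  n_und <- sum(n_nodes[timing == "undetermined"])
  focal_timing <- timing[[events$focal]]
  scenario <- switch(focal_timing, before = "II", after = "I",
                     undetermined = "ambiguous")
  list(event_timing = timing, n_bef = n_bef, n_aft = n_aft, n_und = n_und,
       scenario = scenario)
}

#' Classify placements into duplication-timing scenarios
#'
#' Applies the before/after/undetermined event-timing rule (see the package
#' vignette) to every placement: scenario II if the focal event predates
#' the split implied by the query's attachment point, scenario I if it
#' postdates it, ambiguous otherwise.  Node counts (`n_bef`, `n_aft`,
#' `n_und`) always sum to the number of backbone internal nodes.
#'
#' @param placements a `placement_set` from [enumerate_placements()].
#' @param events an [event_model()]; defaults to the one attached to the
#'   backbone spec.
#' @return data frame with columns `placement_id`, `arrangement_id`,
#'   `branch_id`, `scenario`, `n_bef`, `n_aft`, `n_und`.
#' @export
classify_placements <- function(placements, events = NULL) {
  spec <- attr(placements, "spec")
  if (is.null(events)) events <- spec$events
  if (is.null(events)) stop("no event model supplied")
  res <- lapply(seq_len(nrow(placements)), function(i) {
    tr <- spec$arrangements[[placements$arrangement_id[i]]]
    classify_one(tr, placements$branch_id[i], events)
  })
  data.frame(
    placement_id = placements$placement_id,
    arrangement_id = placements$arrangement_id,
    branch_id = placements$branch_id,
    scenario = vapply(res, `[[`, character(1), "scenario"),
    n_bef = vapply(res, `[[`, numeric(1), "n_bef"),
    n_aft = vapply(res, `[[`, numeric(1), "n_aft"),
    n_und = vapply(res, `[[`, numeric(1), "n_und"),
    stringsAsFactors = FALSE)
}

#' Scenario histogram over a full enumeration
#'
#' @param timings output of [classify_placements()].
#' @return named integer vector with components `I`, `II`, `ambiguous`.
#' @export
scenario_counts <- function(timings) {
  out <- c(I = sum(timings$scenario == "I"),
           II = sum(timings$scenario == "II"),
           ambiguous = sum(timings$scenario == "ambiguous"))
  out
}

#' Probability-weighted scenario summary
#'
#' Combines topology weights with per-placement timing classifications into
#' scenario probabilities and probabilistic duplication counts.  Ambiguous
#' placements contribute mass `ambiguous_prior` to scenario II (default
#' 1/2, i.e. both scenarios equally possible), and their undetermined node
#' counts are split the same way, so that `N_bef + N_aft` always equals the
#' number of backbone internal nodes.
#'
#' @param weights numeric vector of normalized topology weights, aligned
#'   with `timings` rows (or a data frame with columns `placement_id` and
#'   `weight`).
#' @param timings output of [classify_placements()].
#' @param ambiguous_prior mass given to scenario II for ambiguous
#'   placements (default 0.5).
#' @return one-row data frame with `P_I`, `P_II`, `N_bef`, `N_aft`.
#' @export
summarize_scenarios <- function(weights, timings, ambiguous_prior = 0.5) {
  if (is.data.frame(weights)) {
    ord <- match(timings$placement_id, weights$placement_id)
    if (any(is.na(ord))) stop("weights and timings do not align")
    w <- weights$weight[ord]
  } else w <- weights
  if (length(w) != nrow(timings))
    stop("length mismatch between weights and timings")
  if (abs(sum(w) - 1) > 1e-6) stop("weights must sum to 1")
  amb <- timings$scenario == "ambiguous"
  p_ii <- sum(w[timings$scenario == "II"]) + ambiguous_prior * sum(w[amb])
  n_bef <- sum(w * (timings$n_bef + ambiguous_prior * timings$n_und))
  n_aft <- sum(w * (timings$n_aft + (1 - ambiguous_prior) * timings$n_und))
  data.frame(P_I = 1 - p_ii, P_II = p_ii, N_bef = n_bef, N_aft = n_aft)
}
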