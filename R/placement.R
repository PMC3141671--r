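# Constrained enumeration of candidate placements of a query gene on a
# backbone tree.  A backbone specification holds one or more alternative
# binary resolutions ("arrangements") of designated polytomies -- for the
# shaker-related potassium channel (KCNA) family, the three possible
# pairings among the paralog-pair clades (KCNA1,2), (KCNA3,6), (KCNA5,10).

#' Backbone specification
#'
#' @param arrangements named list of `rooted_tree` objects sharing one leaf
#'   set; each is one allowed binary resolution of the backbone.
#' @param events optional [event_model()] shared by all arrangements.
#' @return object of class `backbone_spec`.
#' @export
backbone_spec <- function(arrangements, events = NULL) {
  if (inherits(arrangements, "rooted_tree"))
    arrangements <- list(A1 = arrangements)
  stopifnot(length(arrangements) >= 1L)
  if (is.null(names(arrangements)))
    names(arrangements) <- paste0("A", seq_along(arrangements))
  leafsets <- lapply(arrangements, function(t) sort(tree_leaves(t)))
  if (!all(vapply(leafsets, identical, logical(1), leafsets[[1]])))
    stop("arrangements differ in leaf set")
  structure(list(arrangements = arrangements, events = events),
            class = "backbone_spec")
}

#' @export
print.backbone_spec <- function(x, ...) {
  cat("backbone:", length(tree_leaves(x$arrangements[[1]])), "leaves,",
      length(x$arrangements), "arrangement(s)\n")
  for (nm in names(x$arrangements))
    cat(" ", nm, ":", canonical_topology(x$arrangements[[nm]]), "\n")
  invisible(x)
}

#' The constrained gnathostome KCNA backbone
#'
#' Eight gnathostome KCNA genes with the pair clades (KCNA1,KCNA2),
#' (KCNA3,KCNA6) and (KCNA5,KCNA10) -- the descendants of the tri-gene
#' cluster duplication -- and KCNA4 then KCNA7 branching successively
#' outside them.  All three pairings among the three pair clades are
#' included as equally allowed arrangements.  Internal nodes carry stable
#' labels (`P12`, `P36`, `P510` for the pair nodes; `C1`, `C2` for the two
#' tandem-duplication nodes inside the cluster; `A4` for the KCNA4 stem
#' ancestor; `RN` for the root) that the shipped [kcna_events()] model maps
#' to duplication events.
#'
#' @param terminal,internal default branch lengths (substitutions/site) for
#'   terminal and internal branches.
#' @return a `backbone_spec` with an attached event model.
#' @export
kcna_backbone <- function(terminal = 0.4, internal = 0.2) {
  pair <- function(a, b, lab)
    sprintf("(%s:%g,%s:%g)%s:%g", a, terminal, b, terminal, lab, internal)
  p12 <- pair("KCNA1", "KCNA2", "P12")
  p36 <- pair("KCNA3", "KCNA6", "P36")
  p510 <- pair("KCNA5", "KCNA10", "P510")
  arr <- function(out, in1, in2)
    read_newick(text = sprintf(
      "(((%s,(%s,%s)C2:%g)C1:%g,KCNA4:%g)A4:%g,KCNA7:%g)RN;",
      out, in1, in2, internal, internal, terminal, internal, terminal))
  backbone_spec(
    list(pairing_36_510 = arr(p12, p36, p510),
         pairing_12_510 = arr(p36, p12, p510),
         pairing_12_36  = arr(p510, p12, p36)),
    events = kcna_events())
}

#' Enumerate all placements of a query on a backbone
#'
#' Grafts `query` onto every branch (terminal, internal, and the root
#' branch) of every arrangement.  With a arrangements and n backbone
#' leaves this yields a x (2n - 1) candidate topologies; duplicates (which
#' can arise only through symmetry of the arrangements) are checked for by
#' canonical topology string and rejected.
#'
#' @param spec a [backbone_spec()] (or a single `rooted_tree`).
#' @param query name of the query leaf.
#' @param pendant initial pendant branch length for the query.
#' @return data frame of class `placement_set` with columns `placement_id`,
#'   `arrangement_id`, `branch_id`, and a list column `tree` holding the
#'   grafted `rooted_tree` objects.
#' @export
enumerate_placements <- function(spec, query, pendant = 0.1) {
  if (!inherits(spec, "backbone_spec")) spec <- backbone_spec(spec)
  if (query %in% tree_leaves(spec$arrangements[[1]]))
    stop("query name collides with backbone leaf: ", query)
  rows <- list()
  for (arr_id in names(spec$arrangements)) {
    tr <- spec$arrangements[[arr_id]]
    for (b in tree_branches(tr)) {
      g <- graft(tr, b, query, pendant = pendant)
      rows[[length(rows) + 1L]] <- list(
        arrangement_id = arr_id, branch_id = b, tree = g,
        canonical = canonical_topology(g))
    }
  }
  canon <- vapply(rows, `[[`, character(1), "canonical")
  if (anyDuplicated(canon))
    stop("duplicate topologies among enumerated placements")
  out <- data.frame(
    placement_id = sprintf("p%02d", seq_along(rows)),
    arrangement_id = vapply(rows, `[[`, character(1), "arrangement_id"),
    branch_id = vapply(rows, `[[`, character(1), "branch_id"),
    stringsAsFactors = FALSE)
  out$tree <- lapply(rows, `[[`, "tree")
  attr(out, "query") <- query
  attr(out, "spec") <- spec
  class(out) <- c("placement_set", "data.frame")
  out
}

#' @export
print.placement_set <- function(x, ...) {
  cat("placement set:", nrow(x), "candidate topologies for query '",
      attr(x, "query"), "'\n", sep = "")
  print.data.frame(x[, c("placement_id", "arrangement_id", "branch_id")],
                   row.names = FALSE)
  invisible(x)
}

#' Write a placement set as a multi-tree Newick file plus TSV index
#'
#' @param placements a `placement_set`.
#' @param newick_path output path for one Newick string per line.
#' @param index_path output path for the TSV index.
#' @return invisibly, `newick_path`.
#' @export
write_placements <- function(placements, newick_path, index_path = NULL) {
  writeLines(vapply(placements$tree, write_newick, character(1)), newick_path)
  if (!is.null(index_path))
    write.table(placements[, c("placement_id", "arrangement_id", "branch_id")],
                index_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(newick_path)
}
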