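# Rooted trees are held as a nested list of nodes
#   node = list(label = chr, length = dbl or NA, children = list(node, ...))
# wrapped in class "rooted_tree".  A branch is identified by the label of its
# child node; the (possibly zero-length) branch above the root has the
# reserved id "ROOT".  This small structure makes grafting, de-grafting and
# ancestor queries trivial; conversion to ape's "phylo" is provided for
# likelihood work and I/O.

new_node <- function(label, length = NA_real_, children = list()) {
  list(label = label, length = length, children = children)
}

is_leaf <- function(node) length(node$children) == 0L

#' Read a rooted tree from Newick
#'
#' Quoted labels and bracketed comments are tolerated and stripped.  Internal
#' nodes without labels receive deterministic labels `I1, I2, ...` in
#' post-order.  Backbone use requires a fully binary rooted tree, so a basal
#' trifurcation (the usual signature of an unrooted tree) is rejected unless
#' `require_binary = FALSE`.
#'
#' @param path path to a Newick file, or a Newick string via `text`.
#' @param text Newick string (overrides `path`).
#' @param require_binary reject non-binary nodes (default TRUE).
#' @return object of class `rooted_tree`.
#' @export
read_newick <- function(path = NULL, text = NULL, require_binary = TRUE) {
  if (is.null(text)) {
    if (is.null(path) || !file.exists(path)) stop("file not found: ", path)
    text <- paste(readLines(path), collapse = "")
  }
  text <- gsub("\\[[^]]*\\]", "", text)       # strip comments
  text <- gsub("'([^']*)'", "\\1", text)       # strip quotes
  text <- gsub("\\s", "", text)
  if (!grepl(";$", text)) text <- paste0(text, ";")
  open <- lengths(regmatches(text, gregexpr("\\(", text)))
  close <- lengths(regmatches(text, gregexpr("\\)", text)))
  if (open != close) stop("unbalanced parentheses in Newick string")
  root <- parse_newick_node(sub(";$", "", text))
  tr <- structure(list(root = root), class = "rooted_tree")
  tr <- autolabel_internals(tr)
  lv <- tree_leaves(tr)
  if (anyDuplicated(lv))
    stop("duplicate leaf labels: ", paste(unique(lv[duplicated(lv)]), collapse = ", "))
  if (require_binary) {
    k <- node_degrees(tr$root)
    if (any(k > 2L))
      stop("tree contains a polytomy (basal trifurcation?); ",
           "a binary rooted tree is required")
  }
  tr
}

# recursive descent parser for one node (without trailing ';')
parse_newick_node <- function(s) {
  if (startsWith(s, "(")) {
    # split off the subtree list at the matching ')'
    depth <- 0L
    chars <- strsplit(s, "")[[1]]
    end <- 0L
    for (i in seq_along(chars)) {
      if (chars[i] == "(") depth <- depth + 1L
      if (chars[i] == ")") {
        depth <- depth - 1L
        if (depth == 0L) { end <- i; break }
      }
    }
    if (end == 0L) stop("unbalanced parentheses in Newick string")
    inner <- substr(s, 2L, end - 1L)
    rest <- substr(s, end + 1L, nchar(s))
    parts <- split_top_level(inner)
    children <- lapply(parts, parse_newick_node)
    lab_len <- parse_label_length(rest)
    new_node(lab_len$label, lab_len$length, children)
  } else {
    lab_len <- parse_label_length(s)
    if (!nzchar(lab_len$label)) stop("leaf without a label in Newick string")
    new_node(lab_len$label, lab_len$length)
  }
}

split_top_level <- function(s) {
  depth <- 0L
  cuts <- integer(0)
  chars <- strsplit(s, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (chars[i] == "," && depth == 0L) cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, nchar(s))
  mapply(function(a, b) substr(s, a, b), starts, ends,
         SIMPLIFY = TRUE, USE.NAMES = FALSE)
}

parse_label_length <- function(s) {
  if (grepl(":", s, fixed = TRUE)) {
    bits <- strsplit(s, ":", fixed = TRUE)[[1]]
    list(label = bits[1], length = as.numeric(bits[2]))
  } else list(label = s, length = NA_real_)
}

autolabel_internals <- function(tree) {
  counter <- 0L
  used <- tree_labels(tree)
  walk <- function(node) {
    node$children <- lapply(node$children, walk)
    if (!is_leaf(node) && !nzchar(node$label)) {
      repeat {
        counter <<- counter + 1L
        cand <- paste0("I", counter)
        if (!cand %in% used) break
      }
      node$label <- cand
    }
    node
  }
  tree$root <- walk(tree$root)
  tree
}

node_degrees <- function(node) {
  if (is_leaf(node)) return(integer(0))
  c(length(node$children), unlist(lapply(node$children, node_degrees)))
}

#' Write a rooted tree as Newick
#'
#' @param tree a `rooted_tree`.
#' @param path optional output path; if NULL the string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  fmt <- function(node) {
    core <- if (is_leaf(node)) node$label
            else paste0("(", paste(vapply(node$children, fmt, character(1)),
                                   collapse = ","), ")", node$label)
    if (is.na(node$length)) core
    else paste0(core, ":", format(node$length, digits = digits, trim = TRUE,
                                  scientific = FALSE))
  }
  s <- paste0(fmt(tree$root), ";")
  if (!is.null(path)) { writeLines(s, path); return(invisible(s)) }
  s
}

#' @export
print.rooted_tree <- function(x, ...) {
  cat("rooted tree:", length(tree_leaves(x)), "leaves\n ",
      write_newick(x), "\n")
  invisible(x)
}

tree_labels <- function(tree) {
  walk <- function(node)
    c(node$label, unlist(lapply(node$children, walk)))
  out <- walk(tree$root)
  out[nzchar(out)]
}

#' Leaf labels of a rooted tree
#' @param tree a `rooted_tree`.
#' @return character vector of leaf labels (left-to-right order).
#' @export
tree_leaves <- function(tree) {
  walk <- function(node) {
    if (is_leaf(node)) return(node$label)
    unlist(lapply(node$children, walk))
  }
  walk(tree$root)
}

internal_labels <- function(tree) {
  walk <- function(node) {
    if (is_leaf(node)) return(character(0))
    c(unlist(lapply(node$children, walk)), node$label)
  }
  walk(tree$root)
}

#' Enumerate branch identifiers
#'
#' Every branch of the tree, identified by its child node label, plus the
#' reserved root branch `"ROOT"` (the attachment slot above the root).  A
#' rooted binary tree with n leaves therefore has 2n-1 branches.
#'
#' @param tree a `rooted_tree`.
#' @param include_root include the root branch id (default TRUE).
#' @return character vector of branch ids.
#' @export
tree_branches <- function(tree, include_root = TRUE) {
  walk <- function(node) {
    if (is_leaf(node)) return(node$label)
    c(unlist(lapply(node$children, walk)), node$label)
  }
  ids <- walk(tree$root)
  ids <- ids[ids != tree$root$label]         # the root node itself is not a branch
  if (include_root) ids <- c(ids, "ROOT")
  ids
}

find_node <- function(tree, label) {
  walk <- function(node) {
    if (node$label == label) return(node)
    for (ch in node$children) {
      hit <- walk(ch)
      if (!is.null(hit)) return(hit)
    }
    NULL
  }
  walk(tree$root)
}

#' Graft a query leaf onto a branch
#'
#' A new internal node bisects the chosen branch (each half receives half of
#' the original branch length) and the query is attached to it with pendant
#' length `pendant`.  Grafting onto the root branch creates a new root whose
#' children are the query and the old tree.  The new internal node is
#' labelled `"GRAFT"`.
#'
#' @param tree a `rooted_tree`.
#' @param branch_id branch id as in [tree_branches()].
#' @param query label for the new leaf.
#' @param pendant pendant branch length for the query (default 0.1).
#' @return the grafted `rooted_tree`.
#' @export
graft <- function(tree, branch_id, query, pendant = 0.1) {
  if (query %in% tree_leaves(tree))
    stop("query name collides with a backbone leaf: ", query)
  if (branch_id == "ROOT") {
    old <- tree$root
    old$length <- pendant
    tree$root <- new_node("GRAFT", NA_real_,
                          list(new_node(query, pendant), old))
    return(tree)
  }
  found <- FALSE
  walk <- function(node) {
    node$children <- lapply(node$children, function(ch) {
      if (ch$label == branch_id) {
        found <<- TRUE
        half <- if (is.na(ch$length)) NA_real_ else ch$length / 2
        ch$length <- half
        return(new_node("GRAFT", half,
                        list(new_node(query, pendant), ch)))
      }
      walk(ch)
    })
    node
  }
  tree$root <- walk(tree$root)
  if (!found) stop("unknown branch id: ", branch_id)
  tree
}

#' Remove a grafted leaf, restoring the backbone
#'
#' Removes the leaf `query` and suppresses its (degree-two) parent, summing
#' the two half branch lengths.  Inverse of [graft()] up to the bisected
#' branch length.
#'
#' @param tree a `rooted_tree`.
#' @param query leaf label to remove.
#' @return the pruned `rooted_tree`.
#' @export
degraft <- function(tree, query) {
  if (!query %in% tree_leaves(tree)) stop("no such leaf: ", query)
  prune <- function(node) {
    if (is_leaf(node)) return(node)
    keep <- Filter(function(ch) !(is_leaf(ch) && ch$label == query),
                   node$children)
    if (length(keep) == 1L) {            # suppress degree-two node
      child <- prune(keep[[1]])
      child$length <- if (is.na(node$length)) NA_real_
                      else if (is.na(child$length)) node$length
                      else node$length + child$length
      return(child)
    }
    node$children <- lapply(keep, prune)
    node
  }
  root <- prune(tree$root)
  if (length(root$children) == 1L) {     # query hung off the root
    root <- root$children[[1]]
    root$length <- NA_real_
  }
  if (root$label == "GRAFT" && length(root$children) == 2L) {
    # root graft: the surviving child is the old root
  }
  tree$root <- root
  tree
}

#' Canonical topology string
#'
#' Newick string without branch lengths in which children are sorted by
#' their smallest leaf label; equal rooted topologies map to equal strings,
#' so this is usable for deduplication and stable ordering.
#'
#' @param tree a `rooted_tree`.
#' @param keep_internal_labels keep internal node labels (default FALSE).
#' @return character scalar.
#' @export
canonical_topology <- function(tree, keep_internal_labels = FALSE) {
  walk <- function(node) {
    if (is_leaf(node)) return(list(str = node$label, min = node$label))
    subs <- lapply(node$children, walk)
    ord <- order(vapply(subs, `[[`, character(1), "min"))
    subs <- subs[ord]
    lab <- if (keep_internal_labels) node$label else ""
    list(str = paste0("(", paste(vapply(subs, `[[`, character(1), "str"),
                                 collapse = ","), ")", lab),
         min = subs[[1]]$min)
  }
  paste0(walk(tree$root)$str, ";")
}

#' Convert to / from ape's "phylo"
#'
#' @param tree a `rooted_tree` (or, for `rooted_tree_from_phylo`, a `phylo`).
#' @return `as_phylo` returns a `phylo`; `rooted_tree_from_phylo` a
#'   `rooted_tree`.
#' @export
as_phylo <- function(tree) {
  ape::read.tree(text = write_newick(tree))
}

#' @rdname as_phylo
#' @export
rooted_tree_from_phylo <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  read_newick(text = ape::write.tree(tree))
}

# --- ancestor machinery used by the event-timing classifier ---------------

# list mapping each internal node label -> character vector of internal
# labels strictly ancestral to it (root has none)
ancestor_map <- function(tree) {
  out <- list()
  walk <- function(node, anc) {
    if (is_leaf(node)) return(invisible())
    out[[node$label]] <<- anc
    for (ch in node$children) walk(ch, c(anc, node$label))
  }
  walk(tree$root, character(0))
  out
}

# For a prospective graft point S on `branch_id`: internal labels strictly
# ancestral to S and internal labels that would descend from S.
branch_context <- function(tree, branch_id) {
  internals <- internal_labels(tree)
  if (branch_id == "ROOT")
    return(list(ancestors = character(0), descendants = internals))
  anc <- character(0)
  found <- FALSE
  walk <- function(node, path) {
    if (node$label == branch_id) {
      anc <<- path
      found <<- TRUE
      sub <- if (is_leaf(node)) character(0) else internal_labels(
        structure(list(root = node), class = "rooted_tree"))
      return(sub)
    }
    for (ch in node$children) {
      res <- walk(ch, c(path, node$label))
      if (found) return(res)
    }
    NULL
  }
  desc <- walk(tree$root, character(0))
  if (!found) stop("unknown branch id: ", branch_id)
  list(ancestors = anc[anc %in% internals], descendants = desc)
}
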