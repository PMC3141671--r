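# End-to-end orchestration of the two analysis tracks:
#   run_place_and_time(): alignment + backbone + event map -> enumerated
#     placements -> per-topology likelihoods -> weights -> scenario summary.
#   run_composition(): coding sequences -> GC/GC3/ENc/RSCU -> CA/WCA.

read_alignment_input <- function(x) {
  if (inherits(x, "protein_alignment")) return(x)
  if (!is.character(x) || length(x) != 1L)
    stop("alignment must be a protein_alignment or a file path")
  if (grepl("\\.(phy|phylip)$", x, ignore.case = TRUE)) read_phylip(x)
  else read_fasta(x, type = "protein")
}

subset_alignment <- function(aln, taxa) {
  idx <- match(taxa, aln$names)
  if (any(is.na(idx)))
    stop("taxa missing from alignment: ",
         paste(taxa[is.na(idx)], collapse = ", "))
  protein_alignment(setNames(aln$seqs[idx], taxa))
}

# push optimized phylo edge lengths back onto a nested-list tree, matching
# branches by child-node label
set_branch_lengths <- function(tree, phy) {
  lab <- c(phy$tip.label, phy$node.label)
  el <- setNames(phy$edge.length, lab[phy$edge[, 2L]])
  walk <- function(node, is_root) {
    if (!is_root && node$label %in% names(el))
      node$length <- unname(el[node$label])
    node$children <- lapply(node$children, walk, is_root = FALSE)
    node
  }
  tree$root <- walk(tree$root, TRUE)
  tree
}

#' Place a query gene and time duplication events
#'
#' Full placement-and-timing analysis for a single query gene: enumerate
#' every allowed attachment of the query on the backbone, optimize branch
#' lengths and compute per-site log-likelihoods for each candidate
#' topology, convert log-likelihoods into topology weights, classify each
#' topology's duplication events as before/after the inferred split, and
#' summarize scenario probabilities and probabilistic duplication counts.
#'
#' Branch lengths of each backbone arrangement are first optimized without
#' the query; every placement then starts from those lengths, which makes
#' the per-placement optimization a short polish.
#'
#' @param aln a [protein_alignment()] or path to a FASTA/PHYLIP file; must
#'   contain all backbone taxa plus exactly one extra sequence (the query)
#'   unless `query` is given.
#' @param backbone a [backbone_spec()] (default [kcna_backbone()]).
#' @param events an [event_model()] or TSV path; defaults to the backbone's.
#' @param query query sequence name (default: auto-detected).
#' @param model a [substitution_model()], or `"estimate"` to fit the gamma
#'   shape on the first backbone arrangement before scoring placements.
#' @param matrix,ncat,p_inv,frequencies model settings used when `model`
#'   is `"estimate"`.
#' @param method topology weighting method, `"lw"` or `"rell"`.
#' @param B,seed RELL controls (seed required for `method = "rell"`).
#' @param ambiguous_prior scenario-II mass for ambiguous placements.
#' @param pendant initial query pendant length.
#' @param bl_tol,bl_sweeps branch-length optimization controls.
#' @param outdir optional output directory; when given, placement table,
#'   weight table, per-site log-likelihoods, Newick topologies, the
#'   scenario summary and the run configuration are written as TSV/Newick/
#'   YAML.
#' @return list with `placements`, `weights` (incl. the 1-sigma set),
#'   `timings`, `summary`, `site_loglik`, `model`.
#' @export
run_place_and_time <- function(aln, backbone = kcna_backbone(),
                               events = NULL, query = NULL,
                               model = substitution_model("JTT", alpha = 1),
                               matrix = "JTT", ncat = 4L, p_inv = 0,
                               frequencies = "model",
                               method = c("lw", "rell"), B = 10000L,
                               seed = NULL, ambiguous_prior = 0.5,
                               pendant = 0.1, bl_tol = 1e-6,
                               bl_sweeps = 50L, outdir = NULL) {
  method <- match.arg(method)
  aln <- read_alignment_input(aln)
  if (!inherits(backbone, "backbone_spec")) backbone <- backbone_spec(backbone)
  if (is.character(events)) events <- read_events(events)
  if (is.null(events)) events <- backbone$events
  taxa <- tree_leaves(backbone$arrangements[[1]])
  if (is.null(query)) {
    extra <- setdiff(aln$names, taxa)
    if (length(extra) != 1L)
      stop("expected exactly one query sequence beyond the backbone taxa, ",
           "found: ", paste(extra, collapse = ", "))
    query <- extra
  }
  backbone_aln <- subset_alignment(aln, taxa)
  full_aln <- subset_alignment(aln, c(taxa, query))
  if (identical(frequencies, "empirical"))
    frequencies <- empirical_frequencies(full_aln)

  estimating <- identical(model, "estimate")
  if (estimating)
    model <- substitution_model(matrix, alpha = 1, ncat = ncat,
                                p_inv = p_inv, frequencies = frequencies)

  # warm start: ML branch lengths per arrangement, without the query
  warm <- lapply(backbone$arrangements, function(tr) {
    fit <- optimize_branch_lengths(backbone_aln, tr, model,
                                   tol = max(bl_tol, 1e-4),
                                   max_sweeps = bl_sweeps)
    set_branch_lengths(tr, fit$tree)
  })
  warm_spec <- backbone_spec(warm, events = events)

  if (estimating) {
    model <- estimate_rate_model(backbone_aln, warm[[1]], matrix = matrix,
                                 ncat = ncat,
                                 estimate_pinv = !identical(p_inv, 0),
                                 frequencies = frequencies)
  }

  placements <- enumerate_placements(warm_spec, query, pendant = pendant)
  fits <- lapply(placements$tree, function(tr)
    optimize_branch_lengths(full_aln, tr, model, tol = bl_tol,
                            max_sweeps = bl_sweeps))
  site_lnl <- vapply(fits, `[[`, numeric(full_aln$n_sites), "site_loglik")
  colnames(site_lnl) <- placements$placement_id

  weights <- topology_weights(site_lnl, method = method, B = B, seed = seed)
  timings <- classify_placements(placements, events)
  summary <- summarize_scenarios(weights$weight, timings,
                                 ambiguous_prior = ambiguous_prior)
  summary <- cbind(gene = query, summary)

  out <- list(placements = placements, weights = weights, timings = timings,
              summary = summary, site_loglik = site_lnl, model = model,
              query = query)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    tab <- merge(merge(placements[, c("placement_id", "arrangement_id",
                                      "branch_id")],
                       weights, by = "placement_id"),
                 timings[, c("placement_id", "scenario", "n_bef", "n_aft",
                             "n_und")],
                 by = "placement_id")
    tab <- tab[order(tab$placement_id), ]
    write.table(tab, file.path(outdir, "placements.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(site = seq_len(nrow(site_lnl)), site_lnl),
                file.path(outdir, "site_loglik.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(summary, file.path(outdir, "summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    trees <- vapply(seq_len(nrow(placements)), function(i)
      write_newick(set_branch_lengths(placements$tree[[i]],
                                      fits[[i]]$tree)),
      character(1))
    writeLines(trees, file.path(outdir, "placements.nwk"))
    write_events(events, file.path(outdir, "events.tsv"))
    yaml::write_yaml(list(query = query,
                          model = paste0(model$name,
                                         if (model$p_inv > 0) "+I" else "",
                                         if (!is.null(model$alpha))
                                           sprintf("+G%d", model$ncat) else ""),
                          alpha = model$alpha, p_inv = model$p_inv,
                          weighting = method, rell_replicates = B,
                          seed = seed, ambiguous_prior = ambiguous_prior,
                          pendant = pendant, bl_tol = bl_tol,
                          bl_sweeps = bl_sweeps),
                     file.path(outdir, "config.yaml"))
  }
  out
}

#' Codon-usage and composition analysis
#'
#' Per-gene codon statistics (GC, GC3, ENc and the no-selection ENc
#' expectation), the RSCU table, and an ordination of codon usage by
#' within-group correspondence analysis (default), plain CA, or CA of the
#' RSCU matrix, together with the correlation of the first axis with GC3.
#'
#' @param cds a [coding_set()] or FASTA path (rows = genes), or a named
#'   list of either (rows = species; each species' genes are concatenated,
#'   the species-level convention).
#' @param mode `"wca"`, `"ca"` or `"ca-rscu"`.
#' @param min_codons length filter applied when reading FASTA input.
#' @param outdir optional output directory for TSV results.
#' @return list with `stats` (per row), `counts`, `rscu`, `ordination`
#'   (`NULL` when fewer than two rows or zero inertia), `gc3_correlation`.
#' @export
run_composition <- function(cds, mode = c("wca", "ca", "ca-rscu"),
                            min_codons = 0L, outdir = NULL) {
  mode <- match.arg(mode)
  load_one <- function(x)
    if (inherits(x, "coding_set")) x
    else read_fasta(x, type = "cds", min_codons = min_codons)
  if (is.list(cds) && !inherits(cds, "coding_set")) {
    sets <- lapply(cds, load_one)
    if (is.null(names(sets))) stop("species list must be named")
    concat <- coding_set(setNames(
      vapply(sets, function(s) paste(s$seqs, collapse = ""), character(1)),
      names(sets)))
    counts <- codon_count_table(concat, by = "gene")  # one row per species
    stats <- codon_stats(concat)
    names(stats)[names(stats) == "gene"] <- "species"
  } else {
    set <- load_one(cds)
    counts <- codon_count_table(set, by = "gene")
    stats <- codon_stats(set)
  }
  rscu_tab <- rscu(counts)
  ordination <- NULL
  gc3_cor <- NULL
  if (nrow(counts) >= 2L) {
    ordination <- tryCatch(
      switch(mode, wca = wca(counts), ca = ca(counts),
             `ca-rscu` = ca_rscu(counts)),
      error = function(e) { warning(conditionMessage(e)); NULL })
    if (!is.null(ordination) && ordination$total_inertia < 1e-12) {
      warning("zero inertia: rows are identical in profile, ",
              "ordination skipped")
      ordination <- NULL
    }
    if (!is.null(ordination)) {
      g3 <- stats$gc3[match(rownames(ordination$row_coord), stats[[1]])]
      gc3_cor <- axis_gc_correlation(ordination, g3)
    }
  } else warning("single row: ordination skipped")

  out <- list(stats = stats, counts = counts, rscu = rscu_tab,
              ordination = ordination, gc3_correlation = gc3_cor,
              mode = mode)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write.table(stats, file.path(outdir, "codon_stats.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(row = rownames(rscu_tab), rscu_tab,
                           check.names = FALSE),
                file.path(outdir, "rscu.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (!is.null(ordination)) {
      write.table(data.frame(row = rownames(ordination$row_coord),
                             ordination$row_coord, check.names = FALSE),
                  file.path(outdir, "row_coordinates.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(data.frame(column = rownames(ordination$col_coord),
                             ordination$col_coord, check.names = FALSE),
                  file.path(outdir, "col_coordinates.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(data.frame(axis = seq_along(ordination$eigenvalues),
                             inertia = ordination$eigenvalues,
                             fraction = ordination$inertia_fraction),
                  file.path(outdir, "eigenvalues.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  out
}
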