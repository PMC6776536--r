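#' GO-term coverage of network communities
#'
#' For every (community, term) pair with at least one overlapping gene,
#' reports coverage — the percentage of the term's genes *within the
#' dataset* that fall in the community — together with the one-sided
#' hypergeometric probability of an overlap at least that large arising
#' by chance, given the community size, the term's dataset total and the
#' dataset size.
#'
#' @param partition a `community_partition` (or named node -> community
#'   vector).
#' @param annotations named list term -> genes (e.g. `go_dag$annotations`
#'   or a GMT file read with [read_gmt()]).
#' @param dataset_genes the gene universe; defaults to the partitioned
#'   nodes. Terms with no gene in the dataset are skipped with a message.
#' @return data.frame: community, size, term, overlap, term_total
#'   (dataset-restricted), coverage (percent), p.
#' @export
community_go_coverage <- function(partition, annotations,
                                  dataset_genes = NULL) {
  assignment <- if (inherits(partition, "community_partition"))
    partition$assignment else partition
  if (is.null(dataset_genes)) dataset_genes <- names(assignment)
  n_dataset <- length(dataset_genes)
  ann <- lapply(annotations, intersect, dataset_genes)
  skipped <- names(ann)[vapply(ann, length, 1L) == 0]
  if (length(skipped)) {
    message(length(skipped), " term(s) absent from the dataset, skipped")
  }
  ann <- ann[vapply(ann, length, 1L) > 0]
  if (!length(ann)) return(data.frame())

  comms <- split(names(assignment), assignment)
  rows <- list()
  for (cid in names(comms)) {
    members <- intersect(comms[[cid]], dataset_genes)
    size <- length(members)
    for (term in names(ann)) {
      term_total <- length(ann[[term]])
      overlap <- length(intersect(members, ann[[term]]))
      if (overlap == 0) next
      p <- stats::phyper(overlap - 1, term_total, n_dataset - term_total,
                         size, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        community = cid, size = size, term = term, overlap = overlap,
        term_total = term_total, coverage = 100 * overlap / term_total,
        p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$community, out$p), ]
}

#' Search partitions for co-membership of a gene set
#'
#' For each partition (one per GIN), reports whether all genes of a set
#' that are present in the network share a single community; if not, how
#' the set splits over communities and whether each straggler community
#' shares at least one edge with the majority community ("adjacent").
#' Used e.g. to locate a UPR sensor motif across the study's panels.
#'
#' @param partitions named list of `community_partition`s.
#' @param gene_set nonempty character vector.
#' @param graphs optional named list of graphs (igraph / `augmented_gin`),
#'   parallel to `partitions`; needed for the adjacency flag.
#' @return data.frame: gin, n_present, absent (comma string),
#'   all_in_one, split (community sizes like "2+1"), adjacent.
#' @export
find_comembership <- function(partitions, gene_set, graphs = NULL) {
  stopifnot(length(gene_set) > 0)
  rows <- lapply(names(partitions), function(nm) {
    assignment <- partitions[[nm]]$assignment
    present <- intersect(gene_set, names(assignment))
    absent <- setdiff(gene_set, present)
    if (!length(present)) {
      return(data.frame(gin = nm, n_present = 0L,
                        absent = paste(absent, collapse = ","),
                        all_in_one = NA, split = NA_character_,
                        adjacent = NA, stringsAsFactors = FALSE))
    }
    comm <- assignment[present]
    tab <- sort(table(comm), decreasing = TRUE)
    all_in_one <- length(tab) == 1
    adjacent <- NA
    if (!all_in_one && !is.null(graphs) && nm %in% names(graphs)) {
      g <- as_gin_graph(graphs[[nm]])
      major <- names(tab)[1]
      others <- names(tab)[-1]
      major_nodes <- names(assignment)[assignment == as.integer(major)]
      adjacent <- all(vapply(others, function(oc) {
        oc_nodes <- names(assignment)[assignment == as.integer(oc)]
        sub <- igraph::induced_subgraph(g, c(major_nodes, oc_nodes))
        el <- igraph::as_data_frame(sub, what = "edges")
        any(el$from %in% major_nodes & el$to %in% oc_nodes |
              el$from %in% oc_nodes & el$to %in% major_nodes)
      }, logical(1)))
    }
    data.frame(gin = nm, n_present = length(present),
               absent = paste(absent, collapse = ","),
               all_in_one = all_in_one,
               split = paste(as.integer(tab), collapse = "+"),
               adjacent = adjacent, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
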