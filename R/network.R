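#' Stringent edge filtering
#'
#' Keeps interaction edges whose score magnitude reaches the stringent
#' digenic cutoff and whose p-value is significant:
#' `|weight| >= weight_cutoff` (boundary inclusive) and `p < p_cutoff`.
#'
#' @param edges data.frame with columns weight and p (plus endpoints).
#' @param weight_cutoff score magnitude cutoff (default 0.12).
#' @param p_cutoff p-value cutoff (default 0.05).
#' @return the filtered data.frame.
#' @export
filter_stringent <- function(edges, weight_cutoff = 0.12, p_cutoff = 0.05) {
  keep <- abs(edges$weight) >= weight_cutoff & edges$p < p_cutoff
  edges[keep, , drop = FALSE]
}

#' Assemble an augmented genetic interaction network
#'
#' Starting from the primary screen hits (seed genes), takes the global
#' interaction network, applies stringent edge filtering, and keeps every
#' gene within `hop_bound` BFS hops of at least one seed ("less than two
#' levels of distance apart", i.e. nodes on paths of length <= 3 when
#' `hop_bound = 2`). The result is the induced weighted subgraph with a
#' provenance tag on every node.
#'
#' @param seeds character vector of seed genes; seeds absent from the
#'   global network are dropped with a warning.
#' @param global_gin igraph with edge attributes weight and p, or a list
#'   with a `graph` element ([generate_global_gin()] output), or an edge
#'   data.frame gene_a/gene_b/weight/p.
#' @param hop_bound maximum hop distance from a seed (default 2).
#' @param weight_cutoff,p_cutoff stringent edge filters, see
#'   [filter_stringent()].
#' @return an `augmented_gin`: list with `graph` (igraph; vertex attribute
#'   `provenance` in {"seed","augmented"}), `seeds` (those present),
#'   `hop_bound`.
#' @export
build_augmented_gin <- function(seeds, global_gin, hop_bound = 2,
                                weight_cutoff = 0.12, p_cutoff = 0.05) {
  g <- as_gin_graph(global_gin)
  el <- igraph::as_data_frame(g, what = "edges")
  if (!"p" %in% names(el)) el$p <- 0
  keep <- abs(el$weight) >= weight_cutoff & el$p < p_cutoff
  gf <- igraph::subgraph_from_edges(g, igraph::E(g)[keep], delete.vertices = FALSE)

  present <- intersect(seeds, igraph::V(gf)$name)
  if (!length(present)) {
    stop("no seed gene is present in the global network", call. = FALSE)
  }
  if (length(present) < length(seeds)) {
    warning(sprintf("%d seed gene(s) absent from the global network, dropped",
                    length(seeds) - length(present)), call. = FALSE)
  }

  d <- igraph::distances(gf, v = present, weights = NA)
  min_d <- apply(d, 2, min)
  nodes <- igraph::V(gf)$name[min_d <= hop_bound]
  nodes <- union(nodes, present)  # seeds always retained, even if isolated
  sub <- igraph::induced_subgraph(gf, nodes)
  if (igraph::ecount(sub) == 0 && igraph::vcount(sub) == 0) {
    stop("augmented network is empty after filtering", call. = FALSE)
  }
  igraph::V(sub)$provenance <-
    ifelse(igraph::V(sub)$name %in% present, "seed", "augmented")
  structure(list(graph = sub, seeds = present, hop_bound = hop_bound),
            class = "augmented_gin")
}

#' @export
print.augmented_gin <- function(x, ...) {
  cat(sprintf("augmented_gin: %d nodes (%d seed), %d edges, hop bound %d\n",
              igraph::vcount(x$graph), length(x$seeds),
              igraph::ecount(x$graph), x$hop_bound))
  invisible(x)
}

as_gin_graph <- function(x) {
  if (inherits(x, "igraph")) return(x)
  if (inherits(x, "augmented_gin")) return(x$graph)
  if (is.list(x) && inherits(x$graph, "igraph")) return(x$graph)
  if (is.data.frame(x)) {
    df <- x
    names(df)[match(c("gene_a", "gene_b"), names(df))] <- c("from", "to")
    return(igraph::graph_from_data_frame(df, directed = FALSE))
  }
  stop("cannot interpret object as a network", call. = FALSE)
}

#' Bootstrap test of seed-gene centrality against random gene sets
#'
#' Compares the centrality values of the seed genes with those of `n_boot`
#' random node sets of the same size (pooled), by a two-sided
#' Mann-Whitney rank test. Networks whose seeds are not significantly
#' unusual (p >= 0.05) would be excluded from topology analyses.
#'
#' @param gin an `augmented_gin` or igraph.
#' @param seeds gene set to test (>= 3 genes present in the network).
#' @param metric "BC", "CC" or "EC".
#' @param n_boot number of random sets (default 1000).
#' @param seed RNG seed for the resampling.
#' @param alpha inclusion threshold on the Mann-Whitney p-value.
#' @return list: `metric`, `observed` (seed values), `null` (pooled null
#'   values), `U`, `p`, `included` (p < alpha), `n_boot`.
#' @export
bootstrap_centrality_test <- function(gin, seeds, metric = c("BC", "CC", "EC"),
                                      n_boot = 1000, seed = 1, alpha = 0.05) {
  metric <- match.arg(metric)
  g <- as_gin_graph(gin)
  nodes <- igraph::V(g)$name
  seeds <- intersect(seeds, nodes)
  if (length(seeds) < 3) stop("need >= 3 seed genes in the network",
                              call. = FALSE)
  if (length(seeds) > length(nodes)) stop("more seeds than nodes",
                                          call. = FALSE)
  tab <- compute_centralities(gin)
  vals <- stats::setNames(tab[[metric]], tab$gene)

  set.seed(seed)
  null <- unlist(lapply(seq_len(n_boot), function(i) {
    vals[sample(nodes, length(seeds))]
  }), use.names = FALSE)
  observed <- vals[seeds]
  wt <- suppressWarnings(
    stats::wilcox.test(observed, null, alternative = "two.sided",
                       exact = FALSE, correct = TRUE))
  # degenerate case: identical constant distributions -> p = 1
  p <- if (is.finite(wt$p.value)) wt$p.value else 1
  list(metric = metric, observed = observed, null = null,
       U = unname(wt$statistic), p = p, included = p < alpha,
       n_boot = n_boot)
}

#' Exact two-sided Mann-Whitney test for small samples
#'
#' Thin wrapper over [stats::wilcox.test()] with exact p-values where
#' feasible; used for the small worked examples and as the spec's exact
#' reference (`{1,2}` vs `{3,4}` gives U = 0, p = 1/3).
#'
#' @param x,y numeric samples.
#' @return list with `U` and `p`.
#' @export
mann_whitney_exact <- function(x, y) {
  wt <- stats::wilcox.test(x, y, alternative = "two.sided", exact = TRUE)
  list(U = unname(wt$statistic), p = wt$p.value)
}
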