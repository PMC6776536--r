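#' Simulate a weighted global genetic interaction network
#'
#' Planted-partition (stochastic block model) stand-in for a genome-scale
#' genetic interaction network: genes are split into blocks, gene pairs
#' within a block are connected with probability `p_in`, pairs across
#' blocks with `p_out`, and every edge carries a signed interaction score
#' and a p-value so that stringent edge filtering can be exercised.
#'
#' The default weight law draws |N(0.25, 0.1)| and negates 10% of edges,
#' giving scores that straddle the 0.12 stringent-cutoff magnitude; edge
#' p-values are drawn mostly below 0.05 (90%) with a 10% non-significant
#' tail.
#'
#' @param n_genes number of genes (nodes).
#' @param n_blocks number of planted blocks (>= 2).
#' @param p_in,p_out within- and between-block edge probabilities
#'   (`p_in > p_out`).
#' @param seed integer seed.
#' @param genes optional gene names (default `G0001`...); lets the network
#'   share a namespace with a [generate_library()] library.
#' @param weight_fun function(n) -> n signed weights; default as described.
#' @param p_fun function(n) -> n edge p-values; default as described.
#' @return list with `graph` (igraph, edge attributes `weight` and `p`),
#'   `edges` (data.frame gene_a, gene_b, weight, p) and `partition`
#'   (named integer vector gene -> block).
#' @export
generate_global_gin <- function(n_genes, n_blocks = 8, p_in = 0.05,
                                p_out = 0.003, seed = 1, genes = NULL,
                                weight_fun = NULL, p_fun = NULL) {
  if (n_blocks < 2) stop("n_blocks must be >= 2", call. = FALSE)
  if (any(c(p_in, p_out) < 0) || any(c(p_in, p_out) > 1)) {
    stop("p_in and p_out must lie in [0, 1]", call. = FALSE)
  }
  if (p_in <= p_out) stop("p_in must exceed p_out", call. = FALSE)
  if (is.null(genes)) genes <- sprintf("G%04d", seq_len(n_genes))
  stopifnot(length(genes) == n_genes)
  if (is.null(weight_fun)) {
    weight_fun <- function(n) {
      w <- abs(stats::rnorm(n, mean = 0.25, sd = 0.1))
      sign <- ifelse(stats::runif(n) < 0.10, -1, 1)
      w * sign
    }
  }
  if (is.null(p_fun)) {
    p_fun <- function(n) {
      ifelse(stats::runif(n) < 0.90,
             stats::runif(n, 0, 0.05), stats::runif(n, 0.05, 1))
    }
  }

  set.seed(seed)
  block_sizes <- rep(n_genes %/% n_blocks, n_blocks)
  extra <- n_genes %% n_blocks
  if (extra > 0) block_sizes[seq_len(extra)] <- block_sizes[seq_len(extra)] + 1L
  block <- rep(seq_len(n_blocks), times = block_sizes)

  # vectorised Bernoulli over all unordered pairs
  pairs <- utils::combn(n_genes, 2L)
  same <- block[pairs[1, ]] == block[pairs[2, ]]
  prob <- ifelse(same, p_in, p_out)
  keep <- stats::runif(ncol(pairs)) < prob
  ia <- pairs[1, keep]
  ib <- pairs[2, keep]
  n_edges <- length(ia)

  edges <- data.frame(
    gene_a = genes[ia], gene_b = genes[ib],
    weight = weight_fun(n_edges), p = p_fun(n_edges),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = genes, stringsAsFactors = FALSE)
  )
  partition <- stats::setNames(block, genes)
  list(graph = g, edges = edges, partition = partition)
}
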