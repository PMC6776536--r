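#' SAFE-style spatial analysis of functional enrichment
#'
#' Scores local network neighbourhoods for annotation enrichment, in the
#' spirit of spatial analysis of functional enrichment on network maps.
#' Each edge gets a length equal to the Euclidean distance between its
#' endpoints in a 2D embedding ("map-weighted" distances); a node's
#' neighbourhood is every node within weighted shortest-path distance
#' `radius`; each attribute is tested in each neighbourhood by a one-sided
#' hypergeometric tail against the whole network. Enrichment scores are
#' `-log10(p)` capped at 1e-16 and normalised to `[0, 1]` by dividing by
#' 16.
#'
#' @param gin an `augmented_gin` or igraph.
#' @param attributes named list attribute -> gene set (e.g. functional
#'   regions, GO slim terms, planted blocks).
#' @param embedding matrix/data.frame of node coordinates (rows named by
#'   node, two columns); when NULL a seeded Fruchterman-Reingold layout
#'   is computed, making the result deterministic for a fixed seed.
#' @param radius neighbourhood radius in embedding units (default 7.5).
#' @param alpha significance threshold for the enrichment flag.
#' @param seed seed for the default layout.
#' @return list: `scores` data.frame (node, attribute, n_neighborhood,
#'   attr_in_neighborhood, p, score, significant), `embedding`, `radius`.
#' @export
safe_enrichment <- function(gin, attributes, embedding = NULL, radius = 7.5,
                            alpha = 0.05, seed = 1) {
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  g <- as_gin_graph(gin)
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  if (is.null(embedding)) {
    set.seed(seed)
    # topology-only layout: interaction scores are signed and are not
    # spring weights. The layout is rescaled to a 100-unit bounding-box
    # diagonal, so the default radius of 7.5 reads as 7.5% of the map
    # span — a local patch, as on published network maps; user-supplied
    # embeddings are used exactly as given.
    embedding <- igraph::layout_with_fr(g, weights = NA)
    rownames(embedding) <- nodes
    diag_len <- sqrt(sum((apply(embedding, 2, max) -
                            apply(embedding, 2, min))^2))
    if (is.finite(diag_len) && diag_len > 0) {
      embedding <- embedding * 100 / diag_len
    }
  } else {
    embedding <- as.matrix(embedding)
    missing <- setdiff(nodes, rownames(embedding))
    if (length(missing)) {
      stop("embedding lacks coordinates for: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    embedding <- embedding[nodes, , drop = FALSE]
  }

  el <- igraph::as_data_frame(g, what = "edges")
  lens <- sqrt(rowSums((embedding[el$from, , drop = FALSE] -
                          embedding[el$to, , drop = FALSE])^2))
  d <- igraph::distances(g, weights = lens)
  neigh <- d <= radius  # row i: neighbourhood of node i (includes itself)

  rows <- list()
  for (attr_name in names(attributes)) {
    members <- nodes %in% attributes[[attr_name]]
    K <- sum(members)
    if (K == 0) next
    n_nb <- rowSums(neigh)
    k_nb <- as.numeric(neigh %*% members)
    p <- stats::phyper(k_nb - 1, K, n - K, n_nb, lower.tail = FALSE)
    score <- pmin(-log10(pmax(p, 1e-16)) / 16, 1)
    rows[[attr_name]] <- data.frame(
      node = nodes, attribute = attr_name, n_neighborhood = n_nb,
      attr_in_neighborhood = k_nb, p = p, score = score,
      significant = p < alpha, stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  list(scores = scores, embedding = embedding, radius = radius)
}
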