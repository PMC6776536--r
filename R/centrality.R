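#' Betweenness, closeness and eigenvector centrality of a GIN
#'
#' Shortest paths are taken on hops by default (interaction scores are
#' similarity-like, not distances); set `weighted = TRUE` to use
#' 1/|weight| edge lengths instead.
#'
#' * BC: Brandes betweenness, normalised by `(n-1)(n-2)/2`.
#' * CC: Wasserman-Faust component-scaled closeness,
#'   `((nc-1)/(n-1)) * (nc-1)/sum(d)` with `nc` the node's component size
#'   and the sum over distances within the component; isolated nodes get 0.
#' * EC: eigenvector centrality by power iteration (tolerance 1e-10) on
#'   the absolute-weight adjacency of the largest component, scaled to
#'   unit Euclidean norm; nodes outside the largest component get 0.
#'
#' @param gin an `augmented_gin` or igraph.
#' @param weighted use 1/|weight| distances for BC/CC.
#' @return a `centrality_table` data.frame: gene, BC, CC, EC.
#' @export
compute_centralities <- function(gin, weighted = FALSE) {
  g <- as_gin_graph(gin)
  n <- igraph::vcount(g)
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  if (n == 0) stop("empty network", call. = FALSE)

  lens <- if (weighted) 1 / abs(igraph::E(g)$weight) else NA
  bc <- igraph::betweenness(g, weights = lens, normalized = n > 2)

  d <- igraph::distances(g, weights = lens)
  cc <- vapply(seq_len(n), function(i) {
    finite <- is.finite(d[i, ]) & seq_len(n) != i
    nc <- sum(finite) + 1L
    if (nc == 1L || n == 1L) return(0)
    ((nc - 1) / max(n - 1, 1)) * ((nc - 1) / sum(d[i, finite]))
  }, numeric(1))

  comp <- igraph::components(g)
  giant <- which.max(comp$csize)
  in_giant <- comp$membership == giant
  ec <- numeric(n)
  if (sum(in_giant) == 1) {
    ec[in_giant] <- 1
  } else {
    sub <- igraph::induced_subgraph(g, which(in_giant))
    w_attr <- if ("weight" %in% igraph::edge_attr_names(sub)) "weight" else NULL
    A <- abs(igraph::as_adjacency_matrix(sub, attr = w_attr, sparse = TRUE))
    ec[in_giant] <- power_iteration(A)[igraph::V(sub)$name]
  }

  out <- data.frame(gene = nodes, BC = as.numeric(bc), CC = cc, EC = ec,
                    stringsAsFactors = FALSE)
  class(out) <- c("centrality_table", "data.frame")
  out
}

# leading eigenvector of a nonnegative symmetric sparse matrix, unit 2-norm;
# iterates on A + I (same eigenvector, avoids oscillation on bipartite graphs)
power_iteration <- function(A, tol = 1e-12, max_iter = 100000) {
  n <- nrow(A)
  x <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    y <- as.numeric(A %*% x) + x
    nrm <- sqrt(sum(y^2))
    if (nrm == 0) break
    y <- y / nrm
    delta <- max(abs(y - x))
    x <- y
    if (delta < tol) break
  }
  if (sum(x) < 0) x <- -x
  stats::setNames(x, rownames(A))
}

#' Scan cluster counts over centrality space
#'
#' Standardises the three centrality features and fits both Ward
#' agglomerative and k-means clusterings for every k in `k_range`,
#' reporting silhouette (SI) and Calinski-Harabasz (CH) scores. The
#' optimal k per method is the SI argmax, ties resolved towards smaller k.
#'
#' @param table a `centrality_table`.
#' @param k_range candidate cluster counts (default 2:10).
#' @param seed RNG seed for k-means.
#' @param n_init k-means restarts per k.
#' @return list: `scan` (data.frame k, method, SI, CH), `optimal_k`
#'   (named vector per method).
#' @export
optimize_cluster_count <- function(table, k_range = 2:10, seed = 1,
                                   n_init = 25) {
  X <- standardize_features(table)
  if (nrow(X) < max(k_range) + 1) {
    stop("need more genes than the largest k", call. = FALSE)
  }
  if (all(stats::dist(X) == 0)) {
    stop("all points identical: silhouette undefined", call. = FALSE)
  }
  D <- stats::dist(X)
  hc <- stats::hclust(D, method = "ward.D2")
  rows <- list()
  set.seed(seed)
  for (k in k_range) {
    lab_h <- stats::cutree(hc, k = k)
    lab_k <- stats::kmeans(X, centers = k, nstart = n_init,
                           iter.max = 100)$cluster
    for (m in c("agglomerative", "kmeans")) {
      lab <- if (m == "agglomerative") lab_h else lab_k
      si <- mean(cluster::silhouette(lab, D)[, "sil_width"])
      rows[[length(rows) + 1L]] <- data.frame(
        k = k, method = m, SI = si, CH = calinski_harabasz(X, lab))
    }
  }
  scan <- do.call(rbind, rows)
  optimal_k <- vapply(split(scan, scan$method), function(df) {
    df$k[which.max(df$SI)]  # which.max takes the first (smallest k) on ties
  }, numeric(1))
  list(scan = scan, optimal_k = optimal_k)
}

standardize_features <- function(table, features = c("BC", "CC", "EC")) {
  X <- as.matrix(table[, features])
  rownames(X) <- table$gene
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1  # constant feature carries no information
  scale(X, center = TRUE, scale = sds)
}

calinski_harabasz <- function(X, labels) {
  n <- nrow(X)
  k <- length(unique(labels))
  if (k < 2 || k >= n) return(NA_real_)
  overall <- colMeans(X)
  B <- 0; W <- 0
  for (cl in unique(labels)) {
    Xi <- X[labels == cl, , drop = FALSE]
    ci <- colMeans(Xi)
    B <- B + nrow(Xi) * sum((ci - overall)^2)
    W <- W + sum(sweep(Xi, 2, ci)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Assign centrality clusters alpha-delta
#'
#' k-means (seeded, `n_init` restarts) at fixed k on the standardised
#' centrality features. Clusters are relabelled by ascending mean
#' betweenness so that `delta` is always the highest-betweenness cluster
#' (the bottleneck cluster).
#'
#' @param table a `centrality_table`.
#' @param k number of clusters (default 4 -> labels alpha, beta, gamma,
#'   delta; other k get labels cluster01, ...).
#' @param seed RNG seed.
#' @param n_init k-means restarts.
#' @return the table with a `cluster` factor column added.
#' @export
assign_centrality_clusters <- function(table, k = 4, seed = 1, n_init = 50) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  X <- standardize_features(table)
  if (nrow(X) <= k) stop("fewer genes than clusters", call. = FALSE)
  set.seed(seed)
  km <- stats::kmeans(X, centers = k, nstart = n_init, iter.max = 100)
  mean_bc <- tapply(table$BC, km$cluster, mean)
  ord <- order(mean_bc)  # ascending: last = highest mean BC = delta
  labels <- if (k == 4) c("alpha", "beta", "gamma", "delta")
            else sprintf("cluster%02d", seq_len(k))
  relabel <- stats::setNames(labels, names(mean_bc)[ord])
  table$cluster <- factor(relabel[as.character(km$cluster)], levels = labels)
  table
}

#' Top bottleneck genes by a centrality metric
#'
#' @param table a `centrality_table`.
#' @param metric "BC" (default), "CC" or "EC".
#' @param n how many genes (default 5); if larger than the table, all
#'   genes are returned with a warning.
#' @return data.frame gene, value — sorted by decreasing metric, ties
#'   broken lexicographically by gene name.
#' @export
top_bottleneck_genes <- function(table, metric = c("BC", "CC", "EC"), n = 5) {
  metric <- match.arg(metric)
  if (n > nrow(table)) {
    warning("n exceeds gene count; returning all genes", call. = FALSE)
    n <- nrow(table)
  }
  ord <- order(-table[[metric]], table$gene)
  data.frame(gene = table$gene[ord][seq_len(n)],
             value = table[[metric]][ord][seq_len(n)],
             stringsAsFactors = FALSE)
}
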