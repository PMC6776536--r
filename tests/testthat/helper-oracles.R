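# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and igraph's algorithms) wherever the
# quantity being checked is the package's responsibility.

# random small connected-ish weighted graph as an igraph
random_small_graph <- function(n, p = 0.5, weighted = FALSE) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::ecount(g) > 0) break
  }
  igraph::V(g)$name <- paste0("n", seq_len(n))
  if (weighted) igraph::E(g)$weight <- stats::runif(igraph::ecount(g), 0.1, 2)
  g
}

# all-pairs shortest path lengths by Floyd-Warshall on an adjacency of hops
floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
    }
  }
  d
}

# betweenness by exhaustive enumeration of simple paths (n <= 8)
brute_bc <- function(g) {
  n <- igraph::vcount(g)
  adj <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  d <- floyd_warshall(adj)
  bc <- numeric(n)
  # enumerate all simple paths between every ordered pair via DFS
  paths_between <- function(s, t) {
    out <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == t) {
        out[[length(out) + 1L]] <<- path
        return()
      }
      for (nb in which(adj[last, ])) {
        if (!nb %in% path) walk(c(path, nb))
      }
    }
    walk(s)
    out
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(d[s, t])) next
      ps <- paths_between(s, t)
      lens <- vapply(ps, length, 1L) - 1L
      shortest <- ps[lens == d[s, t]]
      sigma <- length(shortest)
      for (p in shortest) {
        inner <- setdiff(p, c(s, t))
        bc[inner] <- bc[inner] + 1 / sigma
      }
    }
  }
  norm <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  stats::setNames(bc / norm, igraph::V(g)$name)
}

# Wasserman-Faust component-scaled closeness from the definition
brute_cc <- function(g) {
  n <- igraph::vcount(g)
  adj <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  d <- floyd_warshall(adj)
  cc <- vapply(seq_len(n), function(i) {
    reach <- which(is.finite(d[i, ]) & seq_len(n) != i)
    nc <- length(reach) + 1L
    if (nc == 1L) return(0)
    ((nc - 1) / (n - 1)) * ((nc - 1) / sum(d[i, reach]))
  }, numeric(1))
  stats::setNames(cc, igraph::V(g)$name)
}

# eigenvector centrality from dense eigendecomposition of the largest
# component, unit 2-norm, zero elsewhere
brute_ec <- function(g) {
  n <- igraph::vcount(g)
  comp <- igraph::components(g)
  giant <- which.max(comp$csize)
  idx <- which(comp$membership == giant)
  ec <- numeric(n)
  if (length(idx) == 1) {
    ec[idx] <- 1
  } else {
    A <- as.matrix(igraph::as_adjacency_matrix(
      igraph::induced_subgraph(g, idx)))
    ev <- eigen(A, symmetric = TRUE)
    v <- ev$vectors[, which.max(ev$values)]
    if (sum(v) < 0) v <- -v
    ec[idx] <- v / sqrt(sum(v^2))
  }
  stats::setNames(ec, igraph::V(g)$name)
}

# all set partitions of 1..n (Bell-number enumeration, n <= 8)
all_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  smaller <- all_partitions(n - 1)
  out <- list()
  for (p in smaller) {
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# maximum modularity over every partition, via the package's M evaluator
# on each candidate (the exhaustive search itself is the oracle)
exhaustive_best_modularity <- function(g) {
  nodes <- igraph::V(g)$name
  best <- -Inf
  for (p in all_partitions(length(nodes))) {
    asg <- integer(length(nodes))
    for (b in seq_along(p)) asg[p[[b]]] <- b
    m <- modularity_weighted(g, stats::setNames(asg, nodes))
    if (m > best) best <- m
  }
  best
}

# literal two-stage Benjamini-Krieger-Yekutieli step-up, written with
# explicit loops (independent of the package's vectorised version)
naive_bky <- function(p, alpha = 0.05) {
  m <- length(p)
  a1 <- alpha / (1 + alpha)
  step_up <- function(level) {
    ps <- sort(p)
    r <- 0L
    for (i in seq_len(m)) {
      if (ps[i] <= i * level / m) r <- i
    }
    r
  }
  r1 <- step_up(a1)
  if (r1 == 0L) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  r2 <- step_up(a1 * m / (m - r1))
  if (r2 == 0L) return(rep(FALSE, m))
  thresh <- sort(p)[r2]
  p <= thresh
}

# hand-built five-term DAG fixture with known information contents:
# root -> A -> {A1, A2}; root -> B; eight annotated genes
toy_dag <- function() {
  terms <- data.frame(
    id = c("GO:ROOT", "A", "B", "A1", "A2"),
    name = c("root", "A", "B", "A1", "A2"),
    namespace = "biological_process",
    level = c(0L, 1L, 1L, 2L, 2L),
    stringsAsFactors = FALSE)
  parents <- list(A = "GO:ROOT", B = "GO:ROOT", A1 = "A", A2 = "A")
  direct <- list(A1 = c("g1", "g2"), A2 = "g3",
                 B = c("g4", "g5", "g6", "g7", "g8"))
  dag <- structure(
    list(terms = terms, parents = parents, root = "GO:ROOT",
         direct = direct, genes = paste0("g", 1:10)),
    class = "go_dag")
  dag$annotations <- propagate_annotations(dag)
  dag
}

# two dense 15-node modules joined only through a cut-vertex bridge that
# attaches to three anchors on each side (so every cross-module shortest
# path passes the bridge, but each anchor carries only a third of them)
make_bridge_graph <- function(seed) {
  set.seed(seed)
  g1 <- igraph::sample_gnp(15, 0.7)
  g2 <- igraph::sample_gnp(15, 0.7)
  igraph::V(g1)$name <- paste0("m1_", 1:15)
  igraph::V(g2)$name <- paste0("m2_", 1:15)
  g <- igraph::disjoint_union(g1, g2) + igraph::vertices("BRIDGE")
  g + igraph::edges(c("BRIDGE", "m1_1", "BRIDGE", "m1_2", "BRIDGE", "m1_3",
                      "BRIDGE", "m2_1", "BRIDGE", "m2_2", "BRIDGE", "m2_3"))
}

# minimal interaction profile with chosen hits, for set-algebra tests
fake_profile <- function(hits, universe, background, probe) {
  df <- data.frame(gene = universe, ratio = 1, z = ifelse(universe %in% hits, 3, 0),
                   p = ifelse(universe %in% hits, 0.001, 0.5),
                   hit = universe %in% hits, excluded_reason = "none",
                   stringsAsFactors = FALSE)
  attr(df, "background") <- background
  attr(df, "probe") <- probe
  class(df) <- c("interaction_profile", "data.frame")
  df
}
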