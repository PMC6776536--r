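test_that("centralities match hand-enumerated values on canonical graphs", {
  path <- igraph::make_graph(~ A - B, B - C)
  tab <- compute_centralities(path)
  expect_equal(tab$BC[tab$gene == "B"], 1)  # the sole pair's path crosses B
  expect_equal(tab$BC[tab$gene != "B"], c(0, 0))

  star <- igraph::make_graph(~ H - L1, H - L2, H - L3)
  st <- compute_centralities(star)
  # raw BC of the hub is all C(3,2) = 3 leaf pairs
  norm <- (4 - 1) * (4 - 2) / 2
  expect_equal(st$BC[st$gene == "H"] * norm, 3)

  tri <- compute_centralities(igraph::make_graph(~ X - Y, Y - Z, Z - X))
  expect_equal(tri$EC, rep(1 / sqrt(3), 3), tolerance = 1e-9)
  expect_equal(sqrt(sum(tri$EC^2)), 1, tolerance = 1e-9)
})

test_that("centralities equal brute-force definitions on random small graphs", {
  set.seed(5)
  for (rep in 1:25) {
    g <- random_small_graph(sample(4:8, 1), p = 0.5)
    tab <- compute_centralities(g)
    expect_equal(stats::setNames(tab$BC, tab$gene), brute_bc(g),
                 tolerance = 1e-8)
    expect_equal(stats::setNames(tab$CC, tab$gene), brute_cc(g),
                 tolerance = 1e-8)
    expect_equal(stats::setNames(tab$EC, tab$gene), brute_ec(g),
                 tolerance = 1e-8)
  }
})

test_that("centrality values are equivariant under node relabeling", {
  set.seed(11)
  g <- random_small_graph(7, p = 0.5)
  tab <- compute_centralities(g)
  perm <- sample(igraph::vcount(g))
  gp <- igraph::permute(g, perm)
  tabp <- compute_centralities(gp)
  m <- match(tab$gene, tabp$gene)
  expect_equal(tab$BC, tabp$BC[m], tolerance = 1e-10)
  expect_equal(tab$CC, tabp$CC[m], tolerance = 1e-10)
  expect_equal(tab$EC, tabp$EC[m], tolerance = 1e-8)
})

test_that("an engineered bridge between dense modules has top betweenness", {
  for (s in 1:3) {
    tab <- compute_centralities(make_bridge_graph(s))
    top <- top_bottleneck_genes(tab, "BC", 1)
    expect_equal(top$gene, "BRIDGE")
  }
})

test_that("cluster-count scan finds planted blobs and reports SI/CH", {
  set.seed(3)
  centers <- matrix(c(0, 0, 0, 8, 8, 8, 0, 8, 0, 8, 0, 8), ncol = 3,
                    byrow = TRUE)
  X <- do.call(rbind, lapply(1:4, function(b) {
    sweep(matrix(stats::rnorm(30 * 3, sd = 0.3), ncol = 3), 2,
          centers[b, ], `+`)
  }))
  tab <- data.frame(gene = sprintf("g%03d", 1:120),
                    BC = X[, 1], CC = X[, 2], EC = X[, 3])
  class(tab) <- c("centrality_table", "data.frame")
  scan <- optimize_cluster_count(tab, k_range = 2:10, seed = 1)
  expect_equal(unname(scan$optimal_k[["kmeans"]]), 4)
  expect_equal(unname(scan$optimal_k[["agglomerative"]]), 4)
  expect_true(all(scan$scan$SI >= -1 & scan$scan$SI <= 1))
  expect_setequal(unique(scan$scan$k), 2:10)

  # independent silhouette arithmetic at k = 4 (k-means labels)
  Xs <- scale(as.matrix(tab[, c("BC", "CC", "EC")]))
  set.seed(1)
  km <- stats::kmeans(Xs, 4, nstart = 25, iter.max = 100)
  D <- as.matrix(stats::dist(Xs))
  sil <- vapply(seq_len(nrow(Xs)), function(i) {
    own <- km$cluster[i]
    a <- mean(D[i, km$cluster == own & seq_len(nrow(Xs)) != i])
    b <- min(vapply(setdiff(unique(km$cluster), own), function(cl) {
      mean(D[i, km$cluster == cl])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  got <- scan$scan$SI[scan$scan$k == 4 & scan$scan$method == "kmeans"]
  expect_equal(got, mean(sil), tolerance = 1e-6)

  degenerate <- tab
  degenerate$BC <- 1; degenerate$CC <- 1; degenerate$EC <- 1
  expect_error(optimize_cluster_count(degenerate), "identical")
})

test_that("alpha-delta clusters are ordered by mean betweenness", {
  set.seed(4)
  tab <- data.frame(gene = sprintf("g%03d", 1:80),
                    BC = c(stats::rnorm(60, 0, 0.05),
                           stats::rnorm(20, 5, 0.05)),
                    CC = stats::rnorm(80, 0, 0.05),
                    EC = stats::rnorm(80, 0, 0.05))
  class(tab) <- c("centrality_table", "data.frame")
  lab <- assign_centrality_clusters(tab, k = 4, seed = 2)
  expect_setequal(levels(lab$cluster), c("alpha", "beta", "gamma", "delta"))
  expect_false(anyNA(lab$cluster))
  means <- tapply(lab$BC, lab$cluster, mean)
  expect_equal(names(which.max(means)), "delta")
  # the high-BC genes all land in delta
  expect_true(all(lab$cluster[lab$BC > 3] == "delta"))

  lab2 <- assign_centrality_clusters(tab, k = 4, seed = 2)
  expect_identical(lab$cluster, lab2$cluster)
})

test_that("top bottleneck extraction ranks, breaks ties and warns", {
  tab <- data.frame(gene = c("zeb", "apple", "mid"),
                    BC = c(0.5, 0.5, 0.1), CC = 1:3, EC = 1:3)
  class(tab) <- c("centrality_table", "data.frame")
  top <- top_bottleneck_genes(tab, "BC", 2)
  expect_equal(top$gene, c("apple", "zeb"))  # lexicographic on ties
  expect_warning(all3 <- top_bottleneck_genes(tab, "BC", 10), "all genes")
  expect_equal(nrow(all3), 3)
})
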