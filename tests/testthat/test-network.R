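test_that("stringent edge filter keeps |w| >= 0.12 (inclusive) and p < 0.05", {
  edges <- data.frame(
    gene_a = paste0("a", 1:6), gene_b = paste0("b", 1:6),
    weight = c(0.12, 0.5, -0.3, 0.119, 0.2, 0.8),
    p = c(0.01, 0.2, 0.001, 0.01, 0.049, 0.05))
  kept <- filter_stringent(edges)
  expect_equal(kept$gene_a, c("a1", "a3", "a5"))  # boundary weight kept,
  # boundary p dropped
})

test_that("augmented GIN expansion follows BFS hop distance from seeds", {
  chain <- data.frame(gene_a = c("A", "B", "C", "D"),
                      gene_b = c("B", "C", "D", "E"),
                      weight = 1, p = 0.01)
  gin <- build_augmented_gin("A", chain, hop_bound = 2)
  expect_setequal(igraph::V(gin$graph)$name, c("A", "B", "C"))
  expect_equal(sort(unique(igraph::V(gin$graph)$provenance)),
               c("augmented", "seed"))

  gin0 <- build_augmented_gin(c("A", "C"), chain, hop_bound = 0)
  expect_setequal(igraph::V(gin0$graph)$name, c("A", "C"))

  # all-seed saturation: augmented equals the edge-filtered global network
  gin_all <- build_augmented_gin(c("A", "B", "C", "D", "E"), chain,
                                 hop_bound = 2)
  expect_equal(igraph::ecount(gin_all$graph), 4)

  expect_warning(build_augmented_gin(c("A", "ZZ"), chain), "absent")
  expect_error(build_augmented_gin("ZZ", chain), "no seed gene")
})

test_that("augmented size is monotone in hop bound and edge cutoff", {
  set.seed(8)
  gg <- generate_global_gin(150, n_blocks = 5, p_in = 0.2, p_out = 0.02,
                            seed = 8)
  seeds <- sample(igraph::V(gg$graph)$name, 10)
  sizes_by_hop <- vapply(0:3, function(h) {
    igraph::vcount(build_augmented_gin(seeds, gg, hop_bound = h)$graph)
  }, numeric(1))
  expect_true(all(diff(sizes_by_hop) >= 0))

  sizes_by_cut <- vapply(c(0.05, 0.12, 0.2, 0.3), function(wc) {
    igraph::vcount(build_augmented_gin(seeds, gg, hop_bound = 2,
                                       weight_cutoff = wc)$graph)
  }, numeric(1))
  expect_true(all(diff(sizes_by_cut) <= 0))
})

test_that("adjacency matrices round-trip through MatrixMarket exactly", {
  gg <- generate_global_gin(40, n_blocks = 4, p_in = 0.4, p_out = 0.05,
                            seed = 2)
  gin <- build_augmented_gin(igraph::V(gg$graph)$name[1:5], gg)
  prefix <- file.path(withr::local_tempdir(), "adj")
  write_adjacency_mtx(gin, prefix)
  back <- read_adjacency_mtx(prefix)
  orig <- igraph::as_adjacency_matrix(gin$graph, attr = "weight",
                                      sparse = TRUE)
  expect_identical(rownames(back), rownames(orig))
  expect_equal(as.matrix(back), as.matrix(orig))
})

test_that("bootstrap centrality test behaves at its limits and is seeded", {
  gg <- generate_global_gin(60, n_blocks = 3, p_in = 0.3, p_out = 0.05,
                            seed = 4)
  nodes <- igraph::V(gg$graph)$name
  # seeds = all nodes: null and observed coincide -> not included
  r_all <- bootstrap_centrality_test(gg, nodes, "BC", n_boot = 50, seed = 1)
  expect_gt(r_all$p, 0.05)
  expect_false(r_all$included)

  r1 <- bootstrap_centrality_test(gg, nodes[1:10], "CC", n_boot = 100,
                                  seed = 7)
  r2 <- bootstrap_centrality_test(gg, nodes[1:10], "CC", n_boot = 100,
                                  seed = 7)
  expect_identical(r1$p, r2$p)
  expect_equal(r1$n_boot, 100)
  expect_error(bootstrap_centrality_test(gg, nodes[1:2], "BC"), ">= 3")
})

test_that("exact Mann-Whitney matches enumeration on tiny samples", {
  mw <- mann_whitney_exact(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3)  # 2 of C(4,2) = 6 orderings are as extreme
})

test_that("plate and edge tables survive a file round trip", {
  lib <- generate_library(384, density = 384, seed = 1)
  tr <- synthetic_truth(stats::setNames(list("G0002"), truth_key("b", "p")),
                        noise_cv = 0.1)
  pair <- generate_screen_pair(lib, tr, "b", "p", seed = 1)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(pair$control, tmp)
  back <- read_plate_csv(tmp)
  expect_equal(back$size, pair$control$size, tolerance = 1e-12)
  expect_identical(back$gene, pair$control$gene)
  expect_identical(back$border, pair$control$border)

  edges <- generate_global_gin(30, 3, 0.3, 0.02, seed = 5)$edges
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_edges_tsv(edges, tmp2)
  expect_equal(read_edges_tsv(tmp2)$weight, edges$weight, tolerance = 1e-12)
})
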