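test_that("library layout fills plates and respects capacity", {
  lib <- generate_library(1536, density = 1536, seed = 1)
  expect_equal(lib$n_plates, 1L)
  expect_equal(lib$plate_dims, c(32L, 48L))
  expect_false(anyNA(lib$positions$gene))

  lib3 <- generate_library(4200, density = 1536, seed = 7)
  expect_equal(lib3$n_plates, 3L)
  expect_equal(sum(is.na(lib3$positions$gene)), 408L)

  expect_error(generate_library(100, density = 100), "density")
})

test_that("library generation is deterministic and linkage is well-formed", {
  a <- generate_library(100, density = 384, seed = 1)
  b <- generate_library(100, density = 384, seed = 1)
  expect_identical(a, b)

  lib <- generate_library(1536, seed = 2)
  expect_equal(nrow(lib$linkage), length(lib$genes))
  expect_equal(anyDuplicated(lib$linkage$gene), 0L)
  expect_equal(length(unique(lib$linkage$chrom)), 16L)
  filled <- lib$positions[!is.na(lib$positions$gene), ]
  expect_equal(anyDuplicated(filled$gene), 0L)
  # border flags mark exactly the outermost rows/columns
  expect_true(all(lib$positions$border ==
                    (lib$positions$row %in% c(1, 32) |
                       lib$positions$col %in% c(1, 48))))
})

test_that("noise-free screen ratios follow the multiplicative model exactly", {
  lib <- generate_library(384, density = 384, seed = 1)
  hits <- c("G0005", "G0050")
  tr <- synthetic_truth(stats::setNames(list(hits), truth_key("bg", "drug")),
                        effect_size = 0.5, noise_cv = 1e-15)
  pair <- generate_screen_pair(lib, tr, "bg", "drug", inhibition = 0.4,
                               seed = 3)
  ratio <- pair$treated$size / pair$control$size
  gene <- pair$control$gene
  expect_equal(ratio[gene == "G0010"], 0.6, tolerance = 1e-12)
  expect_equal(ratio[gene == "G0005"], 0.3, tolerance = 1e-12)
})

test_that("screen generation is reproducible and validates its inputs", {
  lib <- generate_library(384, density = 384, seed = 1)
  tr <- synthetic_truth(stats::setNames(list("G0001"), truth_key("b", "p")),
                        noise_cv = 0.1)
  a <- generate_screen_pair(lib, tr, "b", "p", seed = 11)
  b <- generate_screen_pair(lib, tr, "b", "p", seed = 11)
  expect_identical(a, b)
  expect_error(generate_screen_pair(lib, tr, "b", "other", seed = 1),
               "planted hit set")
  expect_error(generate_screen_pair(lib, tr, "b", "p", inhibition = 1),
               "inhibition")
  expect_error(synthetic_truth(list(), effect_size = 1.2), "effect_size")
})

test_that("empirical colony CV matches the configured noise level", {
  lib <- generate_library(1536, seed = 5)
  tr <- synthetic_truth(stats::setNames(list(character(0)),
                                        truth_key("b", "p")),
                        noise_cv = 0.10)
  pair <- generate_screen_pair(lib, tr, "b", "p", seed = 9)
  interior <- pair$control$size[!pair$control$border &
                                  !is.na(pair$control$gene)]
  expect_gt(length(interior), 1000)
  cv <- stats::sd(interior) / mean(interior)
  expect_lt(abs(cv - 0.10) / 0.10, 0.10)
})

test_that("planted-partition network matches SBM expectations", {
  # limit case: two blocks, p_in = 1, p_out = 0 -> two disjoint cliques
  gg <- generate_global_gin(10, n_blocks = 2, p_in = 1, p_out = 0, seed = 1)
  comp <- igraph::components(gg$graph)
  expect_equal(comp$no, 2L)
  expect_equal(sort(comp$csize), c(5L, 5L))
  expect_equal(igraph::ecount(gg$graph), 2 * choose(5, 2))

  # edge count within 3 SD of the binomial expectation
  gg2 <- generate_global_gin(200, n_blocks = 8, p_in = 0.3, p_out = 0.02,
                             seed = 3)
  intra_pairs <- sum(choose(table(gg2$partition), 2))
  inter_pairs <- choose(200, 2) - intra_pairs
  mu <- intra_pairs * 0.3 + inter_pairs * 0.02
  sd3 <- 3 * sqrt(intra_pairs * 0.3 * 0.7 + inter_pairs * 0.02 * 0.98)
  expect_lt(abs(igraph::ecount(gg2$graph) - mu), sd3)
  expect_equal(length(gg2$partition), 200L)

  # determinism and domain errors
  expect_identical(generate_global_gin(50, 4, 0.3, 0.02, seed = 2)$edges,
                   generate_global_gin(50, 4, 0.3, 0.02, seed = 2)$edges)
  expect_error(generate_global_gin(50, 4, p_in = 1.5, p_out = 0.1), "0, 1")
  expect_error(generate_global_gin(50, 4, p_in = 0.1, p_out = 0.3), "exceed")
  expect_false(any(gg2$edges$gene_a == gg2$edges$gene_b))
})

test_that("GO DAG obeys the true-path rule and covers annotated genes", {
  genes <- sprintf("G%04d", 1:300)
  dag <- generate_go(genes, n_terms = 40, depth = 3, annotation_rate = 0.08,
                     seed = 4)
  # every direct annotation is present in every ancestor
  for (t in names(dag$direct)) {
    for (anc in go_ancestors(dag, t)) {
      expect_true(all(dag$direct[[t]] %in% dag$annotations[[anc]]),
                  label = paste("true-path", t, "->", anc))
    }
  }
  all_annotated <- unique(unlist(dag$direct, use.names = FALSE))
  expect_setequal(dag$annotations[[dag$root]], all_annotated)
  # every non-root term reaches the root
  non_root <- setdiff(dag$terms$id, dag$root)
  expect_true(all(vapply(non_root, function(t) {
    dag$root %in% c(go_ancestors(dag, t), t)
  }, logical(1))))
  expect_identical(generate_go(genes, 40, 3, 0.08, seed = 4)$parents,
                   dag$parents)
  expect_error(generate_go(genes, 40, depth = 1), "depth")
})
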