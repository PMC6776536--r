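profiles_from_z <- function(Z) {
  # rows = cells, cols = genes; build minimal profiles carrying the z values
  lapply(stats::setNames(seq_len(nrow(Z)), rownames(Z)), function(i) {
    key <- strsplit(rownames(Z)[i], "|", fixed = TRUE)[[1]]
    df <- data.frame(gene = colnames(Z), ratio = 1, z = Z[i, ], p = 0.5,
                     hit = FALSE, excluded_reason = "none",
                     stringsAsFactors = FALSE)
    df <- df[!is.na(df$z), ]
    attr(df, "background") <- key[1]
    attr(df, "probe") <- key[2]
    class(df) <- c("interaction_profile", "data.frame")
    df
  })
}

test_that("min-max normalisation follows the documented conventions", {
  Z <- matrix(c(2, 4,
                1, 1,
                0, 8), nrow = 3, byrow = TRUE,
              dimnames = list(c("a|x", "b|x", "c|x"), c("g1", "g2")))
  pm <- build_profile_matrix(profiles_from_z(Z))
  expect_equal(unname(pm$normalized[, "g1"]), c(1, 0.5, 0))
  expect_equal(unname(pm$normalized[, "g2"]), c(3 / 7, 0, 1))

  # constant columns collapse to zero
  Zc <- matrix(c(5, 5, 5, 1, 2, 3), nrow = 3,
               dimnames = list(c("a|x", "b|x", "c|x"), c("gc", "gv")))
  pmc <- build_profile_matrix(profiles_from_z(Zc))
  expect_equal(unname(pmc$normalized[, "gc"]), c(0, 0, 0))

  # idempotence: re-normalising normalised values changes nothing
  expect_equal(gincompare:::minmax_columns(pm$normalized), pm$normalized)
})

test_that("missing entries are masked and imputed with the column median", {
  Z <- matrix(c(0, 1, NA,
                2, 3, 4,
                4, 5, 8), nrow = 3, byrow = TRUE,
              dimnames = list(c("a|x", "b|x", "c|x"),
                              c("g1", "g2", "g3")))
  pm <- build_profile_matrix(profiles_from_z(Z))
  expect_false(pm$mask["a|x", "g3"])
  expect_true(all(pm$mask[, "g1"]))
  # imputed with the median of the observed normalised values
  obs <- (c(4, 8) - 4) / 4
  expect_equal(pm$normalized["a|x", "g3"], stats::median(obs))
  expect_false(anyNA(pm$normalized))
})

test_that("identical profiles merge first and permutation leaves the tree", {
  set.seed(2)
  Z <- matrix(stats::rnorm(5 * 30), nrow = 5,
              dimnames = list(paste0(letters[1:5], "|x"),
                              sprintf("g%02d", 1:30)))
  Z[2, ] <- Z[1, ]  # duplicate pair
  pm <- build_profile_matrix(profiles_from_z(Z))
  hc <- hierarchical_cluster(pm)
  expect_equal(min(hc$tree$height), 0)
  first <- sort(hc$tree$labels[-hc$tree$merge[1, ]])
  expect_equal(first, c("a|x", "b|x"))

  # row permutation: same merge heights
  perm <- c(3, 5, 1, 2, 4)
  pm2 <- build_profile_matrix(profiles_from_z(Z[perm, ]))
  hc2 <- hierarchical_cluster(pm2)
  expect_equal(sort(hc$tree$height), sort(hc2$tree$height))
})

test_that("planted profile groups are recovered by the three-clade cut", {
  set.seed(9)
  n_genes <- 60
  group_mean <- rbind(c(rep(4, 20), rep(0, 40)),
                      c(rep(0, 20), rep(4, 20), rep(0, 20)),
                      c(rep(0, 40), rep(4, 20)))
  rows <- list()
  for (g in 1:3) {
    for (r in 1:4) {
      rows[[paste0("bg", g, r, "|x")]] <-
        group_mean[g, ] + stats::rnorm(n_genes, sd = 0.3)
    }
  }
  Z <- do.call(rbind, rows)
  colnames(Z) <- sprintf("g%02d", 1:n_genes)
  pm <- build_profile_matrix(profiles_from_z(Z))
  hc <- hierarchical_cluster(pm, n_clades = 3)
  truth <- rep(1:3, each = 4)
  expect_equal(mclust::adjustedRandIndex(hc$clades, truth), 1)
})

test_that("focused subclustering re-normalises a panel and handles misses", {
  set.seed(21)
  Z <- matrix(stats::rnorm(6 * 40), nrow = 6,
              dimnames = list(paste0(letters[1:6], "|x"),
                              sprintf("g%02d", 1:40)))
  pm <- build_profile_matrix(profiles_from_z(Z))

  # panel = all genes reproduces the global clustering
  sub_all <- focused_subcluster(pm, colnames(Z))
  hc <- hierarchical_cluster(pm)
  expect_equal(sort(sub_all$rows$height), sort(hc$tree$height))

  expect_warning(sub <- focused_subcluster(pm, c("g01", "g02", "nope")),
                 "dropped")
  expect_setequal(sub$panel, c("g01", "g02"))
  expect_error(focused_subcluster(pm, "nothere"), "no panel gene")

  # engineered co-scoring: two genes high in 3 of 6 cells cluster those cells
  Z2 <- Z
  Z2[1:3, c("g05", "g06")] <- 8
  pm2 <- build_profile_matrix(profiles_from_z(Z2))
  sub2 <- focused_subcluster(pm2, c("g05", "g06"), n_clades = 2)
  clades <- stats::cutree(sub2$rows, k = 2)
  expect_length(unique(clades[1:3]), 1)
  expect_false(clades[1] %in% clades[4:6])
})

test_that("dendrogram panels surround a focal gene and trees write as Newick", {
  set.seed(30)
  Z <- matrix(stats::rnorm(5 * 25), nrow = 5,
              dimnames = list(paste0(letters[1:5], "|x"),
                              sprintf("g%02d", 1:25)))
  Z[, "g02"] <- Z[, "g01"] + stats::rnorm(5, sd = 0.01)
  pm <- build_profile_matrix(profiles_from_z(Z))
  panel <- dendrogram_panel(pm, "g01", n = 5)
  expect_equal(panel[1], "g01")
  expect_true("g02" %in% panel[1:2])
  expect_length(panel, 5)

  hc <- hierarchical_cluster(pm)
  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(hc$tree, tmp)
  tree <- ape::read.tree(tmp)
  expect_setequal(tree$tip.label, rownames(Z))
})
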