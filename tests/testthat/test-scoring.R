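make_plate <- function(sizes, border = rep(FALSE, length(sizes)),
                       genes = sprintf("g%02d", seq_along(sizes))) {
  structure(data.frame(plate = 1L, row = 1L, col = seq_along(sizes),
                       gene = genes, size = sizes, border = border,
                       stringsAsFactors = FALSE),
            class = c("colony_plate", "data.frame"))
}

test_that("plate normalisation scales the interior median to one", {
  p <- make_plate(rep(500, 30))
  expect_equal(normalize_plate(p)$size, rep(1, 30))

  p2 <- make_plate(rep(c(250, 500, 1000), 10))
  expect_equal(sort(unique(normalize_plate(p2)$size)), c(0.5, 1, 2))

  # inflated border colonies do not shift the interior median
  border <- c(rep(TRUE, 10), rep(FALSE, 20))
  p3 <- make_plate(c(rep(1000, 10), rep(500, 20)), border = border)
  n3 <- normalize_plate(p3)
  expect_equal(stats::median(n3$size[!n3$border]), 1, tolerance = 1e-9)
  expect_equal(unique(n3$size[n3$border]), 2)

  expect_error(normalize_plate(make_plate(rep(0, 30))), "degenerate")
})

test_that("growth ratios divide treated by control with replicate collapse", {
  ctrl <- make_plate(rep(1, 24))
  expect_equal(compute_ratios(ctrl, ctrl)$ratio, rep(1, 24))

  tr <- make_plate(c(0.3, rep(1, 23)))
  r <- compute_ratios(tr, ctrl)
  expect_equal(r$ratio[r$gene == "g01"], 0.3)

  # zero control -> missing, never infinite
  ctrl0 <- make_plate(c(0, rep(1, 23)))
  r0 <- compute_ratios(tr, ctrl0)
  expect_true(r0$missing[r0$gene == "g01"])
  expect_true(is.na(r0$ratio[r0$gene == "g01"]))

  # quadruplicate positions collapse by median
  quad <- make_plate(c(1, 2, 4, 8), genes = rep("gA", 4))
  ctrl_quad <- make_plate(rep(1, 4), genes = rep("gA", 4))
  expect_equal(compute_ratios(quad, ctrl_quad)$ratio, 3)  # median(1,2,4,8)

  expect_error(compute_ratios(make_plate(1:4, genes = paste0("x", 1:4)),
                              ctrl_quad), "gene map")
})

test_that("Z-scores follow the documented orientation and worked example", {
  # ratios {1,1,1,0.5}, plain ratios, mean/SD: mean .875, SD .25 -> z = 1.5
  ratios <- data.frame(gene = paste0("g", 1:4), ratio = c(1, 1, 1, 0.5),
                       border = FALSE, missing = FALSE)
  cfg <- scoring_config(use_log_ratio = FALSE)
  prof <- score_profile(ratios, cfg, min_genes = 4)
  expect_equal(prof$z[prof$gene == "g4"], 1.5)
  expect_false(prof$hit[prof$gene == "g4"])

  # degenerate distribution
  flat <- data.frame(gene = paste0("g", 1:25), ratio = 1,
                     border = FALSE, missing = FALSE)
  expect_error(score_profile(flat, cfg), "zero spread")

  # p is the one-sided normal tail of z for every gene
  set.seed(1)
  rr <- data.frame(gene = paste0("g", 1:200),
                   ratio = stats::rlnorm(200, 0, 0.2),
                   border = FALSE, missing = FALSE)
  pf <- score_profile(rr, scoring_config())
  expect_equal(pf$p, 1 - stats::pnorm(pf$z), tolerance = 1e-12)
  # hit flag is exactly the documented conjunction
  expect_identical(pf$hit, pf$z > 2 & pf$p < 0.05 &
                     pf$excluded_reason == "none")
})

test_that("hit calling applies the z > 2, p < 0.05 rule at the boundary", {
  # craft a profile where one gene sits just above and one just below z = 2
  set.seed(42)
  base <- stats::rnorm(300, 0, 0.1)
  x <- c(base, -10, 10)  # anchors widen the spread predictably
  ratios <- data.frame(gene = paste0("g", seq_along(x)), ratio = 2^x,
                       border = FALSE, missing = FALSE)
  pf <- score_profile(ratios, scoring_config())
  just_above <- pf$z > 2.0 & pf$z < 2.5
  just_below <- pf$z > 1.5 & pf$z <= 2.0
  expect_true(all(pf$hit[just_above]))
  expect_false(any(pf$hit[just_below]))
})

test_that("z-scores are invariant to a global size rescaling", {
  lib <- generate_library(384, density = 384, seed = 1)
  tr <- synthetic_truth(stats::setNames(list("G0007"), truth_key("b", "p")),
                        noise_cv = 0.1)
  pair <- generate_screen_pair(lib, tr, "b", "p", seed = 6)
  scale_plate <- function(p, f) { p$size <- p$size * f; p }
  prof1 <- score_profile(compute_ratios(normalize_plate(pair$treated),
                                        normalize_plate(pair$control)))
  prof2 <- score_profile(compute_ratios(
    normalize_plate(scale_plate(pair$treated, 37)),
    normalize_plate(scale_plate(pair$control, 0.11))))
  expect_equal(prof1$z, prof2$z, tolerance = 1e-9)
})

test_that("linkage exclusion removes the query window on the right chromosome", {
  lib <- generate_library(1536, seed = 1)
  tr <- synthetic_truth(stats::setNames(list(character(0)),
                                        truth_key("b", "p")), noise_cv = 0.1)
  pair <- generate_screen_pair(lib, tr, "b", "p", seed = 2)
  prof <- score_profile(compute_ratios(normalize_plate(pair$treated),
                                       normalize_plate(pair$control)))
  query <- lib$genes[10]
  qrow <- lib$linkage[lib$linkage$gene == query, ]

  # window 0: only the query locus itself
  p0 <- exclude_linkage(prof, query, lib, window_bp = 0)
  expect_identical(p0$gene[p0$excluded_reason == "linkage"], query)

  # 12 kb neighbour excluded at a 25 kb window
  p25 <- exclude_linkage(prof, query, lib, window_bp = 25000)
  excluded <- p25$gene[p25$excluded_reason == "linkage"]
  neighbours <- lib$linkage$gene[lib$linkage$chrom == qrow$chrom &
                                   abs(lib$linkage$start - qrow$start) <= 25000]
  expect_setequal(excluded, neighbours)
  expect_gt(length(excluded), 1)

  # same coordinate on another chromosome is retained
  other <- lib$linkage$gene[lib$linkage$chrom != qrow$chrom &
                              lib$linkage$start == qrow$start][1]
  expect_false(other %in% excluded)
  expect_false(any(p25$hit[p25$excluded_reason != "none"]))
  expect_error(exclude_linkage(prof, "NOPE", lib), "linkage record")
})

test_that("hit-set algebra partitions the union of hits exactly", {
  uni <- paste0("g", 1:40)
  identical_profiles <- list(
    A = fake_profile(paste0("g", 1:5), uni, "A", "drug"),
    B = fake_profile(paste0("g", 1:5), uni, "B", "drug"))
  r <- hit_set_algebra(identical_profiles)
  expect_setequal(r$common_all, paste0("g", 1:5))
  expect_true(all(vapply(r$unique, length, 1L) == 0))

  disjoint <- list(A = fake_profile(paste0("g", 1:3), uni, "A", "drug"),
                   B = fake_profile(paste0("g", 4:6), uni, "B", "drug"))
  rd <- hit_set_algebra(disjoint)
  expect_length(rd$common_all, 0)
  expect_setequal(rd$unique$A, paste0("g", 1:3))

  # four-background design with planned overlap: exact class counts
  hits <- list(A = c("g1", "g2", "g3", "g10", "g11"),
               B = c("g1", "g2", "g3", "g10", "g12"),
               C = c("g1", "g2", "g3", "g13"),
               D = c("g1", "g2", "g3", "g14"))
  profs <- lapply(names(hits), function(b)
    fake_profile(hits[[b]], uni, b, "drug"))
  names(profs) <- names(hits)
  r4 <- hit_set_algebra(profs)
  expect_equal(r4$n_union, 8)
  expect_setequal(r4$common_all, c("g1", "g2", "g3"))
  expect_setequal(r4$combinations[["A+B"]], "g10")
  expect_setequal(r4$unique$C, "g13")
  # the combination classes partition the union
  expect_equal(sum(vapply(r4$combinations, length, 1L)), r4$n_union)
  expect_setequal(unlist(r4$combinations, use.names = FALSE), r4$union)

  mismatched <- list(A = fake_profile("g1", uni, "A", "drug"),
                     B = fake_profile("g1", uni, "B", "otherdrug"))
  expect_error(hit_set_algebra(mismatched), "different probes")
})
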