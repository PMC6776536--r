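#' Define a synthetic probe-by-background study
#'
#' Builds the full in-memory input bundle for a comparative GIN study:
#' a deletion library, planted ground truth for every (background x probe)
#' cell, a weighted planted-partition global interaction network sharing
#' the library's gene namespace, a toy GO DAG with propagated annotations,
#' and the design grid. The default geometry mirrors a five-probe
#' (two drugs + three query genes) by four-background study on a 1536-gene
#' library.
#'
#' Planted hit sets are constructed with deliberate overlap structure so
#' that hit-set algebra is informative: per probe, a small core is shared
#' by all backgrounds, a further slice by the "resistant" backgrounds
#' (all but the first), and the remainder is background-specific.
#'
#' @param backgrounds,probes design labels.
#' @param query_probes subset of `probes` treated as query-gene SGAs
#'   (linkage exclusion applies); each is assigned a query locus gene.
#' @param n_genes library size.
#' @param density plate density (384 or 1536).
#' @param n_planted planted hypersensitive genes per cell.
#' @param n_core,n_shared sizes of the all-background and
#'   resistant-shared slices of each planted set.
#' @param effect_size,noise_cv,inhibition screen parameters (see
#'   [synthetic_truth()] and [generate_screen_pair()]).
#' @param global_n,global_blocks,global_p_in,global_p_out global network
#'   SBM parameters.
#' @param go_terms,go_depth,go_rate GO DAG parameters.
#' @param seed master seed; all per-cell seeds are derived from it.
#' @return a `study_design` list.
#' @export
synthetic_study_design <- function(
    backgrounds = c("S288C", "UWOPS87", "Y55", "YPS606"),
    probes = c("atorvastatin", "cerivastatin", "hmg1", "hmg2", "arv1"),
    query_probes = c("hmg1", "hmg2", "arv1"),
    n_genes = 1536, density = 1536, n_planted = 50,
    n_core = 8, n_shared = 6,
    effect_size = 0.5, noise_cv = 0.10, inhibition = 0.4,
    global_n = 2000, global_blocks = 8,
    global_p_in = 0.05, global_p_out = 0.003,
    go_terms = 60, go_depth = 3, go_rate = 0.05,
    seed = 1) {
  seeds <- derive_seeds(seed, 6 + length(backgrounds) * length(probes))
  library <- generate_library(n_genes, density, seed = seeds[1])

  global_genes <- sprintf("G%04d", seq_len(max(global_n, n_genes)))
  global <- generate_global_gin(length(global_genes),
                                n_blocks = global_blocks,
                                p_in = global_p_in, p_out = global_p_out,
                                seed = seeds[2], genes = global_genes)
  go <- generate_go(global_genes, n_terms = go_terms, depth = go_depth,
                    annotation_rate = go_rate, seed = seeds[3])

  set.seed(seeds[4])
  query_genes <- stats::setNames(
    sample(library$genes, length(query_probes)), query_probes)

  set.seed(seeds[5])
  planted <- list()
  for (pr in probes) {
    pool <- setdiff(library$genes, query_genes)
    core <- sample(pool, n_core)
    shared_res <- sample(setdiff(pool, core), n_shared)
    for (bi in seq_along(backgrounds)) {
      bg <- backgrounds[bi]
      own <- core
      if (bi > 1) own <- c(own, shared_res)
      n_extra <- n_planted - length(own)
      extra <- sample(setdiff(pool, c(core, shared_res)), n_extra)
      planted[[truth_key(bg, pr)]] <- sort(c(own, extra))
    }
  }
  truth <- synthetic_truth(planted, effect_size = effect_size,
                           noise_cv = noise_cv,
                           planted_partition = global$partition)

  grid <- expand.grid(background = backgrounds, probe = probes,
                      stringsAsFactors = FALSE)
  grid$inhibition <- inhibition
  grid$seed <- seeds[6 + seq_len(nrow(grid))]

  structure(list(backgrounds = backgrounds, probes = probes,
                 query_probes = query_probes, query_genes = query_genes,
                 library = library, truth = truth, global = global,
                 go = go, grid = grid, seed = seed),
            class = "study_design")
}

#' Validate a study design before running it
#'
#' Schema and namespace checks: complete design grid, planted hits within
#' the library, query loci with linkage records, overlap between the
#' screen gene namespace and the global network and the annotations.
#'
#' @param design a `study_design`.
#' @return list with `failures` (character; empty when clean) and
#'   `warnings` (character, e.g. screen genes absent from the global
#'   network, with counts).
#' @export
validate_inputs <- function(design) {
  failures <- character(0)
  warnings <- character(0)

  expect_cells <- nrow(design$grid)
  if (expect_cells != length(design$backgrounds) * length(design$probes)) {
    failures <- c(failures, "design grid is incomplete")
  }
  keys <- truth_key(design$grid$background, design$grid$probe)
  missing_truth <- setdiff(keys, names(design$truth$planted_hits))
  if (length(missing_truth)) {
    failures <- c(failures, paste("cells without planted truth:",
                                  paste(missing_truth, collapse = ", ")))
  }
  bad_hits <- setdiff(unlist(design$truth$planted_hits, use.names = FALSE),
                      design$library$genes)
  if (length(bad_hits)) {
    failures <- c(failures,
                  paste("planted hits outside the library:",
                        paste(utils::head(bad_hits, 5), collapse = ", ")))
  }
  no_linkage <- setdiff(design$query_genes, design$library$linkage$gene)
  if (length(no_linkage)) {
    failures <- c(failures, paste("query genes without linkage:",
                                  paste(no_linkage, collapse = ", ")))
  }
  global_nodes <- igraph::V(design$global$graph)$name
  absent <- setdiff(design$library$genes, global_nodes)
  if (length(absent)) {
    warnings <- c(warnings, sprintf(
      "%d screen gene(s) absent from the global network", length(absent)))
  }
  ann_genes <- unique(unlist(design$go$annotations, use.names = FALSE))
  if (!length(intersect(ann_genes, design$library$genes))) {
    failures <- c(failures, "annotations cover no screen gene")
  }
  list(failures = failures, warnings = warnings)
}

#' Check plate CSV files against the expected schema
#'
#' @param paths character vector of plate CSV paths.
#' @return character vector of named schema violations (empty when clean).
#' @export
validate_plate_files <- function(paths) {
  unlist(lapply(paths, function(p) {
    tryCatch({
      read_plate_csv(p)
      character(0)
    }, error = function(e) paste0(basename(p), ": ", conditionMessage(e)))
  }))
}

#' Run the full comparative GIN study
#'
#' For every design cell: simulate (or accept) a screen pair, normalise,
#' compute ratios, score the interaction profile, and apply linkage
#' exclusion for query-gene probes. Across cells: hit-set algebra per
#' probe and hierarchical profile clustering. Per cell: augmented GIN from
#' the hits, Louvain communities, centralities with alpha-delta clusters
#' and top bottleneck genes, community GO coverage, GO enrichment of the
#' community with the best ER-like coverage, and (optionally) SAFE
#' neighbourhood enrichment. A manifest records parameters, seeds and
#' md5 hashes of every file written.
#'
#' @param design a `study_design`.
#' @param out_dir directory for output tables (created); when NULL nothing
#'   is written and only the in-memory bundle is returned.
#' @param config scoring configuration ([scoring_config()]).
#' @param hop_bound,weight_cutoff,p_cutoff augmented-GIN parameters.
#' @param n_clades flat clades over profiles.
#' @param run_safe also run SAFE enrichment per GIN (uses the planted
#'   blocks as attribute regions); slower.
#' @param louvain_seed seed for community detection sweeps.
#' @return a list (`study_result`): `profiles`, `hit_algebra`,
#'   `profile_matrix`, `profile_tree`, `gins`, `partitions`,
#'   `centralities`, `bottlenecks`, `coverage`, `enrichment`, `safe`,
#'   `manifest`, `validation`.
#' @export
run_study <- function(design, out_dir = NULL, config = scoring_config(),
                      hop_bound = 2, weight_cutoff = 0.12, p_cutoff = 0.05,
                      n_clades = 3, run_safe = FALSE, louvain_seed = 42) {
  validation <- validate_inputs(design)
  if (length(validation$failures)) {
    stop("design validation failed: ",
         paste(validation$failures, collapse = "; "), call. = FALSE)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  keys <- truth_key(design$grid$background, design$grid$probe)
  profiles <- vector("list", nrow(design$grid))
  names(profiles) <- keys
  for (i in seq_len(nrow(design$grid))) {
    bg <- design$grid$background[i]
    pr <- design$grid$probe[i]
    pair <- generate_screen_pair(design$library, design$truth, bg, pr,
                                 inhibition = design$grid$inhibition[i],
                                 seed = design$grid$seed[i])
    ratios <- compute_ratios(normalize_plate(pair$treated),
                             normalize_plate(pair$control))
    prof <- score_profile(ratios, config, background = bg, probe = pr)
    if (pr %in% design$query_probes) {
      prof <- exclude_linkage(prof, design$query_genes[[pr]], design$library)
    }
    profiles[[i]] <- prof
  }

  hit_algebra <- if (length(design$backgrounds) >= 2) {
    lapply(stats::setNames(design$probes, design$probes), function(pr) {
      sel <- design$grid$probe == pr
      hit_set_algebra(stats::setNames(profiles[sel],
                                      design$grid$background[sel]))
    })
  } else NULL

  pm <- if (length(profiles) >= 2) build_profile_matrix(profiles) else NULL
  tree <- if (length(profiles) >= 3) {
    hierarchical_cluster(pm, n_clades = min(n_clades, length(profiles)))
  } else NULL

  gins <- list(); partitions <- list(); centralities <- list()
  bottlenecks <- list(); coverage <- list(); enrichment <- list()
  safe <- list()
  global_nodes <- igraph::V(design$global$graph)$name
  lou_seeds <- derive_seeds(louvain_seed, length(keys))
  for (i in seq_along(keys)) {
    key <- keys[i]
    seeds_i <- intersect(hit_genes(profiles[[i]]), global_nodes)
    if (length(seeds_i) < 3) next
    gin <- build_augmented_gin(seeds_i, design$global, hop_bound = hop_bound,
                               weight_cutoff = weight_cutoff,
                               p_cutoff = p_cutoff)
    gins[[key]] <- gin
    part <- louvain_partition(gin, seed = lou_seeds[i])
    partitions[[key]] <- part

    tab <- compute_centralities(gin)
    tab <- assign_centrality_clusters(tab, k = 4, seed = lou_seeds[i])
    centralities[[key]] <- tab
    bottlenecks[[key]] <- top_bottleneck_genes(tab, "BC", 5)

    cov <- suppressMessages(
      community_go_coverage(part, design$go$annotations))
    coverage[[key]] <- cov

    gin_nodes <- igraph::V(gin$graph)$name
    if (nrow(cov)) {
      best_comm <- cov$community[which.min(cov$p)]
      members <- names(part$assignment)[part$assignment ==
                                          as.integer(best_comm)]
      enrichment[[key]] <- enrich_go(members, gin_nodes,
                                     design$go$annotations, design$go)
    }
    if (run_safe) {
      blocks <- design$truth$planted_partition[gin_nodes]
      attrs <- split(gin_nodes, blocks)
      names(attrs) <- paste0("block", names(attrs))
      safe[[key]] <- safe_enrichment(gin, attrs, seed = lou_seeds[i])
    }
  }

  result <- list(design = design, profiles = profiles,
                 hit_algebra = hit_algebra, profile_matrix = pm,
                 profile_tree = tree, gins = gins, partitions = partitions,
                 centralities = centralities, bottlenecks = bottlenecks,
                 coverage = coverage, enrichment = enrichment, safe = safe,
                 validation = validation)
  result$manifest <- if (!is.null(out_dir)) {
    write_study_outputs(result, out_dir)
  } else NULL
  class(result) <- "study_result"
  result
}

# write the per-cell and cross-cell tables and return the manifest
write_study_outputs <- function(result, out_dir) {
  paths <- character(0)
  add <- function(p) paths <<- c(paths, p)

  for (key in names(result$profiles)) {
    fn <- file.path(out_dir, paste0("profile_", gsub("[|]", "_", key), ".tsv"))
    add(write_profile_tsv(result$profiles[[key]], fn))
  }
  for (key in names(result$partitions)) {
    base <- gsub("[|]", "_", key)
    part <- result$partitions[[key]]
    fn <- file.path(out_dir, paste0("communities_", base, ".tsv"))
    utils::write.table(
      data.frame(gene = names(part$assignment),
                 community = unname(part$assignment)),
      fn, sep = "\t", row.names = FALSE, quote = FALSE)
    add(fn)
    fn <- file.path(out_dir, paste0("centrality_", base, ".tsv"))
    utils::write.table(result$centralities[[key]], fn, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    add(fn)
  }
  if (!is.null(result$profile_tree)) {
    fn <- file.path(out_dir, "profile_tree.nwk")
    add(write_tree_newick(result$profile_tree$tree, fn))
  }

  hits <- lapply(result$hit_algebra, function(h) {
    list(n_union = h$n_union, common_all = h$common_all,
         n_unique = vapply(h$unique, length, 1L))
  })
  fn <- file.path(out_dir, "hit_sets.json")
  jsonlite::write_json(hits, fn, auto_unbox = TRUE, pretty = TRUE)
  add(fn)

  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    master_seed = result$design$seed,
    cell_seeds = stats::setNames(as.list(result$design$grid$seed),
                                 truth_key(result$design$grid$background,
                                           result$design$grid$probe)),
    n_profiles = length(result$profiles),
    n_gins = length(result$gins),
    files = lapply(stats::setNames(paths, basename(paths)), function(p) {
      list(md5 = unname(tools::md5sum(p)))
    }))
  fn <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, fn, auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf(
    "study_result: %d profiles, %d augmented GINs, %d community partitions\n",
    length(x$profiles), length(x$gins), length(x$partitions)))
  if (length(x$partitions)) {
    ns <- vapply(x$partitions, `[[`, 1, "n_communities")
    cat(sprintf("communities per GIN: %d-%d (median %.0f)\n",
                min(ns), max(ns), stats::median(ns)))
  }
  invisible(x)
}
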