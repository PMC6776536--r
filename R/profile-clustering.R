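#' Assemble a min-max-normalised profile matrix
#'
#' Stacks interaction profiles (rows = background x probe cells, columns
#' = genes) and min-max-normalises each gene's Z-scores across profiles to
#' `[0, 1]`; constant columns become all 0. Genes unscored in a profile
#' are masked and imputed with the column median (of the normalised
#' values) so distances remain computable without dropping whole genes.
#'
#' @param profiles list of `interaction_profile`s; row names are taken as
#'   "background|probe" from profile attributes unless the list is named.
#' @param gene_universe columns of the matrix; defaults to the union of
#'   profiled genes.
#' @return a `profile_matrix`: list with `normalized` (matrix, imputed),
#'   `raw_z` (matrix with NAs), `mask` (TRUE where observed).
#' @export
build_profile_matrix <- function(profiles, gene_universe = NULL) {
  if (length(profiles) < 2) stop("need at least two profiles", call. = FALSE)
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    names(profiles) <- vapply(profiles, function(p) {
      truth_key(attr(p, "background") %||% "bg", attr(p, "probe") %||% "probe")
    }, character(1))
  }
  if (is.null(gene_universe)) {
    gene_universe <- sort(unique(unlist(lapply(profiles, `[[`, "gene"))))
  }
  if (!length(gene_universe)) stop("empty gene universe", call. = FALSE)

  Z <- matrix(NA_real_, nrow = length(profiles), ncol = length(gene_universe),
              dimnames = list(names(profiles), gene_universe))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    ok <- p$excluded_reason == "none" & p$gene %in% gene_universe
    Z[i, p$gene[ok]] <- p$z[ok]
  }
  norm <- minmax_columns(Z)
  imputed <- norm
  for (j in seq_len(ncol(imputed))) {
    nas <- is.na(imputed[, j])
    if (any(nas)) {
      med <- stats::median(imputed[!nas, j])
      imputed[nas, j] <- if (is.finite(med)) med else 0
    }
  }
  structure(list(normalized = imputed, raw_z = Z, mask = !is.na(Z)),
            class = "profile_matrix")
}

# per-column min-max to [0,1]; constant (or all-NA) columns -> 0
minmax_columns <- function(Z) {
  apply(Z, 2, function(col) {
    obs <- col[!is.na(col)]
    if (!length(obs)) return(rep(NA_real_, length(col)))
    rng <- range(obs)
    if (rng[1] == rng[2]) return(ifelse(is.na(col), NA_real_, 0))
    (col - rng[1]) / (rng[2] - rng[1])
  })
}

#' Hierarchical clustering of interaction profiles
#'
#' Agglomerative tree over profile rows with flat clades from a cut at
#' `n_clades`; cophenetic distances are attached for tree-quality checks.
#'
#' @param matrix a `profile_matrix`.
#' @param linkage "average" (default) or "ward" (ward.D2).
#' @param distance "euclidean" (default) or "correlation"
#'   (1 - Pearson between rows).
#' @param n_clades number of flat clades to cut (default 3; requires >= 3
#'   rows).
#' @return list: `tree` (hclust), `clades` (named vector row -> clade),
#'   `cophenetic` (dist), `distance`, `linkage`.
#' @export
hierarchical_cluster <- function(matrix, linkage = c("average", "ward"),
                                 distance = c("euclidean", "correlation"),
                                 n_clades = 3) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  X <- matrix$normalized
  if (anyNA(X)) stop("profile matrix contains NAs after imputation",
                     call. = FALSE)
  if (nrow(X) < 3) stop("need >= 3 profiles for clade extraction",
                        call. = FALSE)
  D <- profile_dist(X, distance)
  method <- if (linkage == "ward") "ward.D2" else "average"
  tree <- stats::hclust(D, method = method)
  clades <- stats::cutree(tree, k = n_clades)
  list(tree = tree, clades = clades, cophenetic = stats::cophenetic(tree),
       distance = distance, linkage = linkage)
}

profile_dist <- function(X, distance) {
  if (distance == "euclidean") {
    stats::dist(X)
  } else {
    cors <- suppressWarnings(stats::cor(t(X)))
    cors[is.na(cors)] <- 0
    stats::as.dist(1 - cors)
  }
}

#' Focused re-clustering over a gene panel
#'
#' Subsets the raw Z matrix to a panel of genes (e.g. a pathway, or the
#' dendrogram neighbourhood of a focal gene), re-normalises per column and
#' clusters both the profiles and the panel genes.
#'
#' @param matrix a `profile_matrix`.
#' @param gene_panel character vector; genes absent from the matrix are
#'   dropped with a warning.
#' @param linkage,distance as in [hierarchical_cluster()].
#' @param n_clades flat clades over rows (skipped if fewer rows than 3).
#' @return list: `rows` (hclust over profiles), `genes` (hclust over panel
#'   genes, NULL if < 3), `clades`, `matrix` (re-normalised sub-matrix),
#'   `panel` (genes used).
#' @export
focused_subcluster <- function(matrix, gene_panel,
                               linkage = c("average", "ward"),
                               distance = c("euclidean", "correlation"),
                               n_clades = 3) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  panel <- intersect(gene_panel, colnames(matrix$raw_z))
  if (!length(panel)) stop("no panel gene present in the matrix",
                           call. = FALSE)
  if (length(panel) < length(gene_panel)) {
    warning(sprintf("%d panel gene(s) not in the matrix, dropped",
                    length(gene_panel) - length(panel)), call. = FALSE)
  }
  Z <- matrix$raw_z[, panel, drop = FALSE]
  norm <- minmax_columns(Z)
  if (length(panel) == 1) norm <- matrix(norm, ncol = 1,
                                         dimnames = dimnames(Z))
  for (j in seq_len(ncol(norm))) {
    nas <- is.na(norm[, j])
    if (any(nas)) {
      med <- stats::median(norm[!nas, j])
      norm[nas, j] <- if (is.finite(med)) med else 0
    }
  }
  method <- if (linkage == "ward") "ward.D2" else "average"
  rows_hc <- stats::hclust(profile_dist(norm, distance), method = method)
  genes_hc <- if (ncol(norm) >= 3) {
    stats::hclust(profile_dist(t(norm), distance), method = method)
  } else NULL
  clades <- if (nrow(norm) >= 3) stats::cutree(rows_hc, k = n_clades) else NULL
  list(rows = rows_hc, genes = genes_hc, clades = clades,
       matrix = norm, panel = panel)
}

#' Nearest dendrogram neighbours of a focal gene
#'
#' Interprets "contiguous genes around a gene" as the focal gene plus its
#' `n - 1` nearest genes by gene-wise clustering distance.
#'
#' @param matrix a `profile_matrix`.
#' @param focal_gene gene around which to build the panel.
#' @param n panel size including the focal gene (default 10).
#' @param distance distance between gene columns.
#' @return character vector of panel genes.
#' @export
dendrogram_panel <- function(matrix, focal_gene, n = 10,
                             distance = c("euclidean", "correlation")) {
  distance <- match.arg(distance)
  X <- matrix$normalized
  if (!focal_gene %in% colnames(X)) stop("focal gene not in matrix",
                                         call. = FALSE)
  D <- as.matrix(profile_dist(t(X), distance))
  ord <- order(D[focal_gene, ])
  colnames(X)[ord][seq_len(min(n, ncol(X)))]
}

#' Write a profile dendrogram as Newick
#' @param tree an hclust.
#' @param path output file.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
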