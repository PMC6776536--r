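#' Generate a synthetic arrayed deletion library
#'
#' Builds a deletion-mutant array of the kind used in chemical-genetic and
#' SGA screening: genes laid out on rectangular plates (384 = 16x24 or
#' 1536 = 32x48 positions), each gene carrying a chromosomal linkage record
#' so that linkage-group exclusion around a query locus can be exercised.
#'
#' Genes are placed row-major across as many plates as needed; positions on
#' the outermost row or column of each plate are flagged as border positions,
#' mirroring the growth advantage of plate-edge colonies on real arrays.
#' Linkage coordinates spread the genes uniformly over 16 synthetic
#' chromosomes with a fixed 12 kb gene spacing.
#'
#' @param n_genes number of deletion strains in the library.
#' @param density plate density, 384 or 1536.
#' @param seed integer seed; the same seed reproduces the library exactly.
#' @param n_chromosomes number of synthetic chromosomes (default 16).
#' @param gene_spacing_bp spacing between adjacent gene starts in bp.
#' @return an object of class `deletion_library`: list with `genes`
#'   (character), `positions` (data.frame: plate, row, col, gene, border),
#'   `linkage` (data.frame: gene, chrom, start, end), `density`, `n_plates`.
#' @export
generate_library <- function(n_genes, density = 1536, seed = 1,
                             n_chromosomes = 16, gene_spacing_bp = 12000) {
  if (!density %in% c(384L, 1536L)) {
    stop("density must be 384 or 1536", call. = FALSE)
  }
  dims <- if (density == 1536) c(32L, 48L) else c(16L, 24L)
  n_plates <- as.integer(ceiling(n_genes / density))
  capacity <- n_plates * density
  if (n_genes < 1) stop("n_genes must be positive", call. = FALSE)
  if (n_genes > capacity) {
    stop("n_genes exceeds plate capacity", call. = FALSE)  # unreachable by construction
  }

  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))

  grid <- expand.grid(col = seq_len(dims[2]), row = seq_len(dims[1]),
                      plate = seq_len(n_plates))
  grid <- grid[order(grid$plate, grid$row, grid$col), c("plate", "row", "col")]
  grid$gene <- c(genes, rep(NA_character_, capacity - n_genes))
  grid$border <- grid$row == 1L | grid$row == dims[1] |
    grid$col == 1L | grid$col == dims[2]
  rownames(grid) <- NULL

  # uniform layout over synthetic chromosomes: consecutive gene blocks so
  # that neighbouring library genes are also chromosomal neighbours
  per_chrom <- ceiling(n_genes / n_chromosomes)
  chrom <- rep(seq_len(n_chromosomes), each = per_chrom)[seq_len(n_genes)]
  idx_on_chrom <- stats::ave(seq_len(n_genes), chrom, FUN = seq_along)
  start <- (idx_on_chrom - 1L) * gene_spacing_bp + 1L
  linkage <- data.frame(
    gene = genes,
    chrom = paste0("chr", chrom),
    start = start,
    end = start + as.integer(gene_spacing_bp * 0.75),
    stringsAsFactors = FALSE
  )

  structure(
    list(genes = genes, positions = grid, linkage = linkage,
         density = as.integer(density), n_plates = n_plates,
         plate_dims = dims),
    class = "deletion_library"
  )
}

#' @export
print.deletion_library <- function(x, ...) {
  cat(sprintf("deletion_library: %d genes on %d plate(s) of %d (%dx%d)\n",
              length(x$genes), x$n_plates, x$density,
              x$plate_dims[1], x$plate_dims[2]))
  invisible(x)
}

#' Ground-truth description of a synthetic screen study
#'
#' Bundles the planted signal a synthetic study carries: which genes are
#' hypersensitive in which (background x probe) cell, how strong the planted
#' growth defect is, the planted block partition of the global network, and
#' the colony noise level.
#'
#' @param planted_hits named list; names are "background|probe" keys (see
#'   [truth_key()]), values character vectors of hypersensitive genes.
#' @param effect_size fractional extra growth reduction for a planted hit,
#'   strictly between 0 and 1 (0.5 means hit colonies reach half the size
#'   expected from treatment alone).
#' @param noise_cv coefficient of variation of multiplicative colony noise.
#' @param planted_partition optional named integer vector gene -> block id.
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(planted_hits, effect_size = 0.5, noise_cv = 0.10,
                            planted_partition = NULL) {
  stopifnot(is.list(planted_hits))
  if (!(effect_size > 0 && effect_size < 1)) {
    stop("effect_size must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!(noise_cv > 0)) stop("noise_cv must be positive", call. = FALSE)
  structure(
    list(planted_hits = planted_hits, effect_size = effect_size,
         noise_cv = noise_cv, planted_partition = planted_partition),
    class = "synthetic_truth"
  )
}

#' Key used to index planted hit sets
#' @param background background (strain) label.
#' @param probe probe (drug or query-gene) label.
#' @return character scalar "background|probe".
#' @export
truth_key <- function(background, probe) paste(background, probe, sep = "|")
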