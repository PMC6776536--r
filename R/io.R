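#' Read / write the pipeline's plain-text interchange formats
#'
#' Plate tables are CSV with columns plate,row,col,gene,size,border_flag;
#' edge lists are TSV with gene_a,gene_b,weight,p; annotations use GMT
#' (term, description, genes...) plus a child/parent/namespace term TSV;
#' profiles are TSV with gene,ratio,z,p,hit,excluded_reason. Adjacency
#' matrices round-trip as MatrixMarket sparse files with a node-order
#' sidecar.
#'
#' @name gin_io
NULL

#' @rdname gin_io
#' @param plate a `colony_plate` data.frame.
#' @param path output file.
#' @export
write_plate_csv <- function(plate, path) {
  out <- data.frame(plate = plate$plate, row = plate$row, col = plate$col,
                    gene = plate$gene, size = plate$size,
                    border_flag = as.integer(plate$border))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname gin_io
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate", "row", "col", "gene", "size", "border_flag")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("plate CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$border <- as.logical(df$border_flag)
  df$border_flag <- NULL
  df$gene <- as.character(df$gene)
  df$gene[df$gene == "" | df$gene == "NA"] <- NA_character_
  class(df) <- c("colony_plate", "data.frame")
  df
}

#' @rdname gin_io
#' @param edges data.frame gene_a, gene_b, weight, p.
#' @export
write_edges_tsv <- function(edges, path) {
  utils::write.table(edges[, c("gene_a", "gene_b", "weight", "p")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname gin_io
#' @export
read_edges_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "weight", "p")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("edge TSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname gin_io
#' @param annotations named list term -> character vector of genes.
#' @export
write_gmt <- function(annotations, path) {
  lines <- vapply(names(annotations), function(t) {
    paste(c(t, t, annotations[[t]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname gin_io
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname gin_io
#' @param dag a `go_dag`.
#' @export
write_term_tsv <- function(dag, path) {
  rows <- do.call(rbind, lapply(names(dag$parents), function(ch) {
    data.frame(child = ch, parent = dag$parents[[ch]],
               namespace = dag$terms$namespace[match(ch, dag$terms$id)],
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname gin_io
#' @export
read_term_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("child", "parent", "namespace")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("term TSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname gin_io
#' @param profile an `interaction_profile`.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(
    profile[, c("gene", "ratio", "z", "p", "hit", "excluded_reason")],
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname gin_io
#' @export
read_profile_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$hit <- as.logical(df$hit)
  class(df) <- c("interaction_profile", "data.frame")
  df
}

#' @rdname gin_io
#' @param gin an `augmented_gin` (or any igraph with a weight attribute).
#' @param prefix path prefix; writes `<prefix>.mtx` and `<prefix>.nodes.tsv`.
#' @export
write_adjacency_mtx <- function(gin, prefix) {
  g <- if (inherits(gin, "augmented_gin")) gin$graph else gin
  adj <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = TRUE)
  Matrix::writeMM(adj, paste0(prefix, ".mtx"))
  utils::write.table(
    data.frame(node = rownames(adj)), paste0(prefix, ".nodes.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' @rdname gin_io
#' @export
read_adjacency_mtx <- function(prefix) {
  adj <- methods::as(Matrix::readMM(paste0(prefix, ".mtx")), "CsparseMatrix")
  nodes <- utils::read.delim(paste0(prefix, ".nodes.tsv"),
                             stringsAsFactors = FALSE)$node
  dimnames(adj) <- list(nodes, nodes)
  adj
}
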