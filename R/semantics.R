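#' Information content of GO terms
#'
#' `IC(t) = -ln p(t)` where `p(t)` is the fraction of the annotation
#' corpus annotated to `t` (annotations are already propagated to
#' ancestors, so `p` includes descendants and `IC(root) = 0`). The corpus
#' defaults to the DAG's own annotated gene set, matching the practice of
#' estimating term specificity from the analysis dataset rather than a
#' whole-genome reference.
#'
#' @param dag a `go_dag`.
#' @param corpus_genes optional gene universe for the frequency estimate.
#' @return named numeric vector term -> IC (terms with no annotated gene
#'   in the corpus are omitted).
#' @export
term_ic <- function(dag, corpus_genes = NULL) {
  ann <- dag$annotations
  if (!is.null(corpus_genes)) {
    ann <- lapply(ann, intersect, corpus_genes)
  }
  total <- length(unique(unlist(ann, use.names = FALSE)))
  counts <- vapply(ann, length, 1L)
  counts <- counts[counts > 0]
  -log(counts / total)
}

#' Lin semantic similarity between two GO terms
#'
#' `lin(t1, t2) = 2 IC(MICA) / (IC(t1) + IC(t2))`, with MICA the common
#' ancestor (terms count as their own ancestors) of maximum information
#' content. Defined as 0 when both ICs are 0 (e.g. against the root).
#'
#' @param t1,t2 term ids in the same namespace.
#' @param dag a `go_dag`.
#' @param ic optional precomputed [term_ic()] vector.
#' @return similarity in `[0, 1]`.
#' @export
lin_similarity <- function(t1, t2, dag, ic = NULL) {
  ns <- dag$terms$namespace[match(c(t1, t2), dag$terms$id)]
  if (any(is.na(ns))) stop("unknown term", call. = FALSE)
  if (ns[1] != ns[2]) stop("terms from different namespaces", call. = FALSE)
  if (is.null(ic)) ic <- term_ic(dag)
  ic1 <- ic[t1]; ic2 <- ic[t2]
  ic1 <- if (is.na(ic1)) 0 else ic1
  ic2 <- if (is.na(ic2)) 0 else ic2
  if (ic1 + ic2 == 0) return(0)
  anc1 <- c(t1, go_ancestors(dag, t1))
  anc2 <- c(t2, go_ancestors(dag, t2))
  common <- intersect(anc1, anc2)
  mica_ic <- if (!length(common)) 0 else {
    vals <- ic[common]
    vals[is.na(vals)] <- 0
    max(vals)
  }
  unname(2 * mica_ic / (ic1 + ic2))
}

#' REVIGO-style uniqueness of a term within a result set
#'
#' One minus the mean Lin similarity of `term` to every other term of the
#' set; a term semantically orthogonal to the rest scores 1, a duplicated
#' term scores 0. Singleton sets score 1 by convention.
#'
#' @param term term id (must be in `term_set`).
#' @param term_set character vector of term ids.
#' @param dag a `go_dag`.
#' @param ic optional precomputed [term_ic()] vector.
#' @return uniqueness in `[0, 1]`.
#' @export
uniqueness <- function(term, term_set, dag, ic = NULL) {
  if (!term %in% term_set) stop("term not in term_set", call. = FALSE)
  others <- term_set[-match(term, term_set)]  # drop one instance only
  if (!length(others)) return(1)
  if (is.null(ic)) ic <- term_ic(dag)
  sims <- vapply(others, function(o) lin_similarity(term, o, dag, ic),
                 numeric(1))
  1 - mean(sims)
}

#' Uniqueness of every term in a set
#' @inheritParams uniqueness
#' @return data.frame term, uniqueness.
#' @export
uniqueness_table <- function(term_set, dag, ic = NULL) {
  if (is.null(ic)) ic <- term_ic(dag)
  data.frame(
    term = term_set,
    uniqueness = vapply(term_set, function(t) uniqueness(t, term_set, dag, ic),
                        numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' GO enrichment of a study set with BKY FDR and uniqueness
#'
#' Convenience wrapper chaining [hypergeom_enrich()], [bky_fdr()] and
#' [uniqueness_table()] into one result table.
#'
#' @inheritParams hypergeom_enrich
#' @param dag a `go_dag` (for uniqueness; skipped when NULL).
#' @param alpha FDR level.
#' @return data.frame: term, study_count, population_count, coverage,
#'   p_raw, p_adjusted, significant, uniqueness.
#' @export
enrich_go <- function(study, population, annotations, dag = NULL,
                      alpha = 0.05) {
  res <- hypergeom_enrich(study, population, annotations)
  if (!nrow(res)) return(res)
  fdr <- bky_fdr(res$p_raw, alpha)
  res$p_adjusted <- fdr$adjusted
  res$significant <- fdr$reject
  if (!is.null(dag)) {
    ic <- term_ic(dag)
    known <- res$term %in% dag$terms$id
    res$uniqueness <- NA_real_
    if (any(known)) {
      ut <- uniqueness_table(res$term[known], dag, ic)
      res$uniqueness[known] <- ut$uniqueness
    }
  }
  res
}
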