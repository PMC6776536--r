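#' Simulate a small GO-like annotation DAG
#'
#' Builds a rooted acyclic term hierarchy of configurable depth with sparse
#' gene annotations: terms are arranged in levels under a single root, every
#' non-root term has one or (with probability 0.2) two parents in the level
#' above, and genes are annotated directly to randomly chosen terms at rate
#' `annotation_rate` per (gene, leaf-level term) opportunity. Direct
#' annotations are then propagated up to every ancestor (true-path rule).
#'
#' @param genes character vector of annotatable genes.
#' @param n_terms number of terms excluding the root.
#' @param depth number of levels below the root (>= 2).
#' @param annotation_rate probability that a gene is directly annotated to
#'   a given deepest-level term.
#' @param seed integer seed.
#' @param namespace namespace label stored on every term.
#' @return a `go_dag` object: list with `terms` (data.frame id, name,
#'   namespace, level), `parents` (named list term -> parent ids; root has
#'   none), `root`, `direct` and `annotations` (named lists term -> genes,
#'   `annotations` including propagation), `genes`.
#' @export
generate_go <- function(genes, n_terms = 60, depth = 3, annotation_rate = 0.05,
                        seed = 1, namespace = "biological_process") {
  if (depth < 2) stop("depth must be >= 2", call. = FALSE)
  if (n_terms < depth) stop("need at least one term per level", call. = FALSE)
  set.seed(seed)

  root <- "GO:ROOT"
  ids <- sprintf("GO:%06d", seq_len(n_terms))
  # spread terms over levels 1..depth; every level populated
  lv <- sort(rep(seq_len(depth), length.out = n_terms))
  lv[seq_len(depth)] <- seq_len(depth)
  lv <- sort(lv)

  parents <- vector("list", n_terms)
  names(parents) <- ids
  for (i in seq_len(n_terms)) {
    above <- ids[lv < lv[i]]
    if (!length(above)) {
      parents[[i]] <- root
    } else {
      pool <- ids[lv == lv[i] - 1L]
      if (!length(pool)) pool <- above
      n_par <- if (stats::runif(1) < 0.2 && length(pool) > 1) 2L else 1L
      parents[[i]] <- sample(pool, n_par)
    }
  }

  terms <- data.frame(
    id = c(root, ids),
    name = c("root", paste0("term ", sub("GO:", "", ids))),
    namespace = namespace,
    level = c(0L, lv),
    stringsAsFactors = FALSE
  )

  # direct annotations to deepest-level terms only; sparse
  leaf_ids <- ids[lv == depth]
  direct <- lapply(stats::setNames(leaf_ids, leaf_ids), function(t) {
    genes[stats::runif(length(genes)) < annotation_rate]
  })
  direct <- direct[vapply(direct, length, 1L) > 0]

  dag <- structure(
    list(terms = terms, parents = parents, root = root,
         direct = direct, genes = genes),
    class = "go_dag"
  )
  dag$annotations <- propagate_annotations(dag)
  dag
}

#' Ancestors of a term (including the root, excluding the term itself)
#' @param dag a `go_dag`.
#' @param term term id.
#' @return character vector of ancestor ids.
#' @export
go_ancestors <- function(dag, term) {
  if (term == dag$root) return(character(0))
  seen <- character(0)
  frontier <- term
  while (length(frontier)) {
    ps <- unique(unlist(dag$parents[frontier], use.names = FALSE))
    ps <- ps[!is.na(ps)]
    new <- setdiff(ps, seen)
    seen <- c(seen, new)
    frontier <- setdiff(new, dag$root)
  }
  seen
}

#' Apply the true-path rule to direct annotations
#'
#' Every gene directly annotated to a term is annotated to all of the
#' term's ancestors as well.
#'
#' @param dag a `go_dag` with a `direct` term -> genes list.
#' @return named list term -> genes, covering every term that ends up with
#'   at least one gene (the root collects every annotated gene).
#' @export
propagate_annotations <- function(dag) {
  ann <- list()
  for (t in names(dag$direct)) {
    targets <- c(t, go_ancestors(dag, t))
    for (a in targets) {
      ann[[a]] <- union(ann[[a]], dag$direct[[t]])
    }
  }
  ann
}
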