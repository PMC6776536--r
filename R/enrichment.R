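#' Hypergeometric GO over-representation test
#'
#' One-sided hypergeometric tail per term: probability of drawing at least
#' the observed number of term genes when sampling `|study|` genes from
#' the population without replacement. Terms with zero study overlap are
#' skipped.
#'
#' @param study gene set of interest (must be a subset of `population`).
#' @param population background gene universe.
#' @param annotations named list term -> genes.
#' @return data.frame: term, study_count, population_count, coverage
#'   (percent of the term's population genes found in the study), p_raw —
#'   sorted by p_raw.
#' @export
hypergeom_enrich <- function(study, population, annotations) {
  if (!length(study)) stop("empty study set", call. = FALSE)
  extra <- setdiff(study, population)
  if (length(extra)) {
    stop("study genes outside the population: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  N <- length(population)
  n <- length(study)
  rows <- lapply(names(annotations), function(term) {
    pop_genes <- intersect(annotations[[term]], population)
    K <- length(pop_genes)
    k <- length(intersect(study, pop_genes))
    if (k == 0) return(NULL)
    data.frame(term = term, study_count = k, population_count = K,
               coverage = 100 * k / K,
               p_raw = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(0), study_count = integer(0),
                      population_count = integer(0), coverage = numeric(0),
                      p_raw = numeric(0)))
  }
  rownames(out) <- NULL
  out[order(out$p_raw), ]
}

#' Two-stage Benjamini-Krieger-Yekutieli FDR control
#'
#' Adaptive linear step-up procedure: stage one runs Benjamini-Hochberg at
#' `alpha' = alpha / (1 + alpha)` to estimate the number of true nulls
#' `m0 = m - r1`; stage two reruns the linear step-up at
#' `alpha' * m / m0`. If the first stage rejects nothing, nothing is
#' rejected; if it rejects everything, everything is.
#'
#' Because the second-stage level is recalibrated, "adjusted" values are
#' reported as the BH-adjusted p-values scaled by `m0 (1 + alpha) / m`;
#' the rejection flags — not the adjusted values — are the exact contract
#' of the procedure.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param alpha target false discovery rate (default 0.05).
#' @return list: `reject` (logical, original order), `adjusted`, `m0`,
#'   `n_rejected`.
#' @export
bky_fdr <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1 | is.na(p))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  alpha1 <- alpha / (1 + alpha)
  r1 <- bh_reject_count(p, alpha1)
  if (r1 == 0) {
    reject <- rep(FALSE, m)
    m0 <- m
  } else if (r1 == m) {
    reject <- rep(TRUE, m)
    m0 <- 0
  } else {
    m0 <- m - r1
    alpha2 <- alpha1 * m / m0
    r2 <- bh_reject_count(p, alpha2)
    # step-up: everything at or below the critical order statistic rejects
    reject <- if (r2 > 0) p <= sort(p)[r2] else rep(FALSE, m)
  }
  m0_eff <- if (m0 == 0) 1 else m0
  adjusted <- pmin(1, stats::p.adjust(p, method = "BH") * m0_eff / m)
  list(reject = reject, adjusted = adjusted, m0 = m0,
       n_rejected = sum(reject))
}

# number of rejections of the BH linear step-up at level a
bh_reject_count <- function(p, a) {
  m <- length(p)
  ps <- sort(p)
  below <- which(ps <= seq_len(m) * a / m)
  if (!length(below)) 0L else max(below)
}
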