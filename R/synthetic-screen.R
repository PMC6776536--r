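#' Simulate a control/treated screen pair
#'
#' Draws colony sizes for one (background x probe) cell of a study design:
#' an untreated (vehicle / single-mutant) plate set and a treated (drug /
#' double-mutant) plate set over the same library layout. Colony sizes are
#' multiplicative-lognormal around a 500 size-unit baseline median; the
#' treated expectation is scaled by `(1 - inhibition)` globally and by a
#' further `(1 - effect_size)` for genes planted as hypersensitive in this
#' cell. Border colonies get a mild growth boost, as on real plates.
#'
#' @param library a [generate_library()] object.
#' @param truth a [synthetic_truth()] object; must contain a planted hit set
#'   under `truth_key(background, probe)`.
#' @param background,probe labels for this design cell.
#' @param inhibition global fractional growth inhibition by treatment, in
#'   `[0, 1)`; 0.4 emulates a dose chosen to inhibit growth by ~40%.
#' @param seed integer seed; fixed seed reproduces the tables exactly.
#' @param baseline_median baseline colony size median (size units).
#' @param border_boost multiplicative size advantage of border colonies.
#' @return list with `control` and `treated`, each a `colony_plate`
#'   data.frame (plate, row, col, gene, size, border) sharing the library's
#'   position -> gene map, with attributes `background`, `probe`,
#'   `condition`.
#' @export
generate_screen_pair <- function(library, truth, background, probe,
                                 inhibition = 0.4, seed = 1,
                                 baseline_median = 500, border_boost = 1.2) {
  stopifnot(inherits(library, "deletion_library"),
            inherits(truth, "synthetic_truth"))
  if (!(inhibition >= 0 && inhibition < 1)) {
    stop("inhibition must be in [0, 1)", call. = FALSE)
  }
  key <- truth_key(background, probe)
  if (!key %in% names(truth$planted_hits)) {
    stop(sprintf("no planted hit set for cell '%s'", key), call. = FALSE)
  }
  hits <- truth$planted_hits[[key]]
  unknown <- setdiff(hits, library$genes)
  if (length(unknown)) {
    stop("planted hits outside library: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  pos <- library$positions
  filled <- !is.na(pos$gene)
  # lognormal with median = baseline and CV = noise_cv:
  # sdlog = sqrt(log(1 + cv^2)), meanlog = log(median)
  sdlog <- sqrt(log(1 + truth$noise_cv^2))

  set.seed(seed)
  draw <- function(expectation) {
    size <- numeric(nrow(pos))
    size[filled] <- stats::rlnorm(sum(filled),
                                  meanlog = log(expectation[filled]),
                                  sdlog = sdlog)
    size
  }

  base <- rep(baseline_median, nrow(pos))
  base[pos$border] <- base[pos$border] * border_boost
  is_hit <- !is.na(pos$gene) & pos$gene %in% hits

  treat_exp <- base * (1 - inhibition)
  treat_exp[is_hit] <- treat_exp[is_hit] * (1 - truth$effect_size)

  control <- pos
  control$size <- draw(base)
  treated <- pos
  treated$size <- draw(treat_exp)

  for (nm in c("control", "treated")) {
    obj <- get(nm)
    attr(obj, "background") <- background
    attr(obj, "probe") <- probe
    attr(obj, "condition") <- if (nm == "control") "control" else "treated"
    class(obj) <- c("colony_plate", "data.frame")
    assign(nm, obj)
  }
  list(control = control, treated = treated)
}
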