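#' Scoring configuration for interaction calling
#'
#' Hits are interactions with `z > z_threshold` and `p < p_threshold`
#' (defaults 2.0 and 0.05); Z-scores are computed on log2 growth ratios by
#' default, which symmetrises multiplicative colony noise. With
#' `robust_center = TRUE` the centre/spread are median and 1.4826 x MAD
#' instead of mean and SD.
#'
#' @param z_threshold Z-score hit threshold (> 0).
#' @param p_threshold p-value hit threshold (> 0).
#' @param linkage_window_bp half-width of the linkage-exclusion window
#'   around a query locus, in bp.
#' @param use_log_ratio score log2 ratios (default) or plain ratios.
#' @param robust_center use median/MAD instead of mean/SD.
#' @return a `scoring_config` list.
#' @export
scoring_config <- function(z_threshold = 2.0, p_threshold = 0.05,
                           linkage_window_bp = 25000,
                           use_log_ratio = TRUE, robust_center = FALSE) {
  if (z_threshold <= 0 || p_threshold <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  structure(list(z_threshold = z_threshold, p_threshold = p_threshold,
                 linkage_window_bp = linkage_window_bp,
                 use_log_ratio = use_log_ratio,
                 robust_center = robust_center),
            class = "scoring_config")
}

#' Normalise a colony plate to its interior median
#'
#' Divides every colony size by the per-plate median of non-border,
#' non-empty colonies, so the interior median of each returned plate is 1.
#' Border colonies are rescaled by the same factor but do not influence it,
#' because plate edges grow systematically larger.
#'
#' @param plate a `colony_plate` data.frame (may span several plate ids;
#'   each is normalised by its own median).
#' @return the plate with normalised sizes.
#' @export
normalize_plate <- function(plate) {
  stopifnot(is.data.frame(plate))
  filled <- !is.na(plate$gene)
  if (mean(filled) < 0.5) {
    stop("more than half of the plate positions are empty", call. = FALSE)
  }
  for (pid in unique(plate$plate)) {
    sel <- plate$plate == pid
    ref <- sel & filled & !plate$border & plate$size > 0
    med <- stats::median(plate$size[ref])
    if (!is.finite(med) || med <= 0) {
      stop(sprintf("plate %s is degenerate (no positive interior colonies)",
                   pid), call. = FALSE)
    }
    plate$size[sel] <- plate$size[sel] / med
  }
  plate
}

#' Per-gene growth ratios from a treated/control plate pair
#'
#' Computes r(g) = treated(g) / control(g) on normalised sizes. Replicate
#' positions of the same gene (quadruplicate pinning) are collapsed by
#' median before division. Genes with zero control size are returned as NA
#' with reason "missing" rather than infinite ratios.
#'
#' @param treated,control normalised `colony_plate`s sharing a position ->
#'   gene map.
#' @return data.frame gene, ratio, border (TRUE if all replicates were on
#'   a border), missing flag.
#' @export
compute_ratios <- function(treated, control) {
  tg <- treated$gene[!is.na(treated$gene)]
  cg <- control$gene[!is.na(control$gene)]
  if (!identical(sort(unique(tg)), sort(unique(cg)))) {
    stop("treated and control plates do not share a gene map", call. = FALSE)
  }
  collapse <- function(plate) {
    keep <- !is.na(plate$gene)
    med <- tapply(plate$size[keep], plate$gene[keep], stats::median)
    brd <- tapply(plate$border[keep], plate$gene[keep], all)
    data.frame(gene = names(med), size = as.numeric(med),
               border = as.logical(brd), stringsAsFactors = FALSE)
  }
  tr <- collapse(treated)
  ct <- collapse(control)
  ct <- ct[match(tr$gene, ct$gene), ]
  missing <- ct$size <= 0 | is.na(ct$size) | is.na(tr$size)
  ratio <- ifelse(missing, NA_real_, tr$size / ct$size)
  data.frame(gene = tr$gene, ratio = ratio,
             border = tr$border | ct$border, missing = missing,
             stringsAsFactors = FALSE)
}

#' Score growth ratios into an interaction profile
#'
#' Transforms ratios (log2 by default), centres and scales them, and calls
#' hits. The Z-score is oriented so growth *defects* are positive:
#' `z = (center - x) / spread`. The p-value is the one-sided normal tail
#' `1 - pnorm(z)`, since only hypersensitivity (negative genetic
#' interaction) is called. Border genes are scored but excluded from the
#' centre/spread estimate.
#'
#' @param ratios output of [compute_ratios()], or any data.frame with at
#'   least `gene` and `ratio` columns.
#' @param config a [scoring_config()].
#' @param background,probe labels stored on the profile.
#' @param min_genes minimum number of scorable genes (default 20; lower it
#'   only for toy examples).
#' @return an `interaction_profile` data.frame: gene, ratio, z, p, hit,
#'   excluded_reason (none/border-only genes remain scorable; missing
#'   genes carry reason "missing").
#' @export
score_profile <- function(ratios, config = scoring_config(),
                          background = NA_character_, probe = NA_character_,
                          min_genes = 20) {
  if (is.null(ratios$missing)) ratios$missing <- FALSE
  if (is.null(ratios$border)) ratios$border <- FALSE
  scorable <- !ratios$missing & is.finite(ratios$ratio) & ratios$ratio > 0
  if (sum(scorable) < min_genes) {
    stop(sprintf("fewer than %d scorable genes", min_genes), call. = FALSE)
  }
  x <- rep(NA_real_, nrow(ratios))
  x[scorable] <- if (config$use_log_ratio) log2(ratios$ratio[scorable])
                 else ratios$ratio[scorable]

  est <- scorable & !ratios$border
  if (!any(est)) est <- scorable  # all-border fallback
  if (config$robust_center) {
    center <- stats::median(x[est])
    spread <- stats::mad(x[est])  # includes the 1.4826 consistency constant
  } else {
    center <- mean(x[est])
    spread <- stats::sd(x[est])
  }
  if (!is.finite(spread) || spread == 0) {
    stop("degenerate ratio distribution (zero spread)", call. = FALSE)
  }

  z <- (center - x) / spread
  p <- stats::pnorm(z, lower.tail = FALSE)
  reason <- ifelse(ratios$missing | !scorable, "missing", "none")
  hit <- !is.na(z) & z > config$z_threshold & p < config$p_threshold &
    reason == "none"

  out <- data.frame(gene = ratios$gene, ratio = ratios$ratio, z = z, p = p,
                    hit = hit, excluded_reason = reason,
                    stringsAsFactors = FALSE)
  attr(out, "background") <- background
  attr(out, "probe") <- probe
  attr(out, "config") <- config
  attr(out, "center") <- center
  attr(out, "spread") <- spread
  class(out) <- c("interaction_profile", "data.frame")
  out
}

#' Exclude the linkage group of a query gene from a profile
#'
#' Double mutants physically linked to the query locus are under-recovered
#' during meiosis, so apparent interactions near the query are artefacts.
#' Genes on the query's chromosome whose start lies within
#' `+/- window_bp` of the query start are marked with reason "linkage" and
#' their hit flags cleared.
#'
#' @param profile an `interaction_profile`.
#' @param query_gene query gene with linkage coordinates in `library`.
#' @param library a [generate_library()] object (or any list with a
#'   `linkage` data.frame: gene, chrom, start).
#' @param window_bp window half-width; default taken from the profile's
#'   scoring config (25 kb).
#' @return the profile with linkage exclusions applied and hits recomputed.
#' @export
exclude_linkage <- function(profile, query_gene, library, window_bp = NULL) {
  lk <- library$linkage
  qi <- match(query_gene, lk$gene)
  if (is.na(qi)) stop("query gene has no linkage record", call. = FALSE)
  if (is.null(window_bp)) {
    cfg <- attr(profile, "config")
    window_bp <- if (!is.null(cfg)) cfg$linkage_window_bp else 25000
  }
  qchrom <- lk$chrom[qi]
  qstart <- lk$start[qi]
  near <- lk$gene[lk$chrom == qchrom & abs(lk$start - qstart) <= window_bp]
  sel <- profile$gene %in% near & profile$excluded_reason == "none"
  profile$excluded_reason[sel] <- "linkage"
  profile$hit[profile$excluded_reason != "none"] <- FALSE
  profile
}

#' Hit genes of a profile
#' @param profile an `interaction_profile`.
#' @return character vector of hit genes.
#' @export
hit_genes <- function(profile) profile$gene[profile$hit]

#' Common/unique hit-set algebra across backgrounds
#'
#' Given several interaction profiles for the *same* probe in different
#' backgrounds, partitions the union of hits by the exact combination of
#' backgrounds calling them: genes hit in all, genes hit in a specific
#' subset and nowhere else, and genes unique to one background.
#'
#' @param profiles named list of `interaction_profile`s (names =
#'   backgrounds; taken from profile attributes when unnamed).
#' @return list: `probe`, `union` (all hit genes), `n_union`, `common_all`,
#'   `unique` (named list background -> genes hit only there),
#'   `combinations` (named list "bg1+bg2" -> genes hit in exactly that
#'   subset; the classes partition the union).
#' @export
hit_set_algebra <- function(profiles) {
  if (length(profiles) < 2) stop("need at least two profiles", call. = FALSE)
  probes <- unique(vapply(profiles, function(p) {
    pr <- attr(p, "probe"); if (is.null(pr)) NA_character_ else pr
  }, character(1)))
  probes <- probes[!is.na(probes)]
  if (length(probes) > 1) {
    stop("profiles target different probes: ",
         paste(probes, collapse = ", "), call. = FALSE)
  }
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    names(profiles) <- vapply(profiles, function(p) {
      bg <- attr(p, "background"); if (is.null(bg)) NA_character_ else bg
    }, character(1))
  }
  sets <- lapply(profiles, hit_genes)
  all_hits <- sort(unique(unlist(sets, use.names = FALSE)))
  membership <- vapply(sets, function(s) all_hits %in% s,
                       logical(length(all_hits)))
  if (length(all_hits) == 1) membership <- matrix(membership, nrow = 1)
  combo_key <- apply(membership, 1, function(row) {
    paste(names(sets)[row], collapse = "+")
  })
  combos <- split(all_hits, combo_key)
  uniques <- stats::setNames(lapply(names(sets), function(b) {
    combos[[b]] %||% character(0)
  }), names(sets))
  common_all <- combos[[paste(names(sets), collapse = "+")]] %||% character(0)
  list(probe = if (length(probes)) probes else NA_character_,
       union = all_hits, n_union = length(all_hits),
       common_all = common_all, unique = uniques, combinations = combos)
}
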