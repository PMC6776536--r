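#!/usr/bin/env Rscript
# Stage 2 — score every screen into an interaction profile.
#
# For each of the 20 design cells: normalise plates to their interior
# median, form treated/control growth ratios, score log2 ratios into
# Z-scores (growth defects positive), call hits at Z > 2.0 & P < 0.05,
# and apply 25 kb linkage-group exclusion around query-gene loci. Then
# run common/unique hit-set algebra per probe across the four
# backgrounds.

suppressMessages(library(gincompare))

MASTER_SEED <- 1
out <- "results/02_profiles"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design <- synthetic_study_design(seed = MASTER_SEED)
cfg <- scoring_config()

profiles <- list()
for (i in seq_len(nrow(design$grid))) {
  bg <- design$grid$background[i]
  pr <- design$grid$probe[i]
  pair <- generate_screen_pair(design$library, design$truth, bg, pr,
                               inhibition = design$grid$inhibition[i],
                               seed = design$grid$seed[i])
  prof <- score_profile(
    compute_ratios(normalize_plate(pair$treated),
                   normalize_plate(pair$control)),
    cfg, background = bg, probe = pr)
  if (pr %in% design$query_probes) {
    prof <- exclude_linkage(prof, design$query_genes[[pr]], design$library)
  }
  key <- truth_key(bg, pr)
  profiles[[key]] <- prof
  write_profile_tsv(prof, file.path(out, paste0(
    "profile_", gsub("[|]", "_", key), ".tsv")))
}

cat(sprintf("scored %d profiles; hits per cell: %s\n", length(profiles),
            paste(vapply(profiles, function(p) sum(p$hit), 1L),
                  collapse = " ")))

algebra <- lapply(stats::setNames(design$probes, design$probes), function(pr) {
  sel <- vapply(profiles, function(p) attr(p, "probe") == pr, logical(1))
  hit_set_algebra(stats::setNames(
    profiles[sel], vapply(profiles[sel], attr, "", "background")))
})
for (pr in design$probes) {
  a <- algebra[[pr]]
  cat(sprintf("%-14s union %3d | common to all %2d | unique per background: %s\n",
              pr, a$n_union, length(a$common_all),
              paste(vapply(a$unique, length, 1L), collapse = "/")))
}
jsonlite::write_json(
  lapply(algebra, function(a) list(n_union = a$n_union,
                                   common_all = a$common_all,
                                   unique = a$unique)),
  file.path(out, "hit_sets.json"), auto_unbox = TRUE, pretty = TRUE)
cat("wrote", out, "\n")
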