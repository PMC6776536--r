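#!/usr/bin/env Rscript
# Stage 6 — hierarchical clustering of the 20 interaction profiles.
#
# Builds the min-max-normalised Z-score matrix over all profiles, cuts
# the average-linkage tree into three clades, and re-clusters two focused
# gene panels: the dendrogram neighbourhood of a planted core gene, and
# an explicit panel of planted-core genes (the synthetic analogues of a
# pathway panel).

suppressMessages(library(gincompare))

MASTER_SEED <- 1
prof_dir <- "results/02_profiles"
out <- "results/06_profile_clustering"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design <- synthetic_study_design(seed = MASTER_SEED)
files <- list.files(prof_dir, pattern = "^profile_.*tsv$", full.names = TRUE)
stopifnot(length(files) >= 3)
profiles <- lapply(files, read_profile_tsv)
names(profiles) <- sub("^profile_", "", sub("[.]tsv$", "", basename(files)))

pm <- build_profile_matrix(profiles)
hc <- hierarchical_cluster(pm, linkage = "average", distance = "euclidean",
                           n_clades = 3)
write_tree_newick(hc$tree, file.path(out, "profile_tree.nwk"))
utils::write.table(
  data.frame(profile = names(hc$clades), clade = unname(hc$clades)),
  file.path(out, "clades.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
utils::write.table(round(pm$normalized, 4),
                   file.path(out, "normalized_matrix.tsv"),
                   sep = "\t", quote = FALSE)

cat("three-clade cut of the 20 profiles:\n")
for (k in 1:3) {
  cat(sprintf("  clade %d: %s\n", k,
              paste(names(hc$clades)[hc$clades == k], collapse = ", ")))
}

# focused panel 1: ten dendrogram neighbours of a planted core gene
core <- Reduce(intersect, lapply(design$backgrounds, function(bg) {
  design$truth$planted_hits[[truth_key(bg, design$probes[1])]]
}))
focal <- core[1]
panel <- dendrogram_panel(pm, focal, n = 10)
sub <- focused_subcluster(pm, panel)
write_tree_newick(sub$rows, file.path(out, "focused_profiles.nwk"))
if (!is.null(sub$genes)) {
  write_tree_newick(sub$genes, file.path(out, "focused_genes.nwk"))
}
cat(sprintf("panel around %s: %s\n", focal, paste(panel, collapse = ", ")))

# focused panel 2: the planted core itself, both probes' cores combined
core2 <- unique(unlist(lapply(design$probes[1:2], function(pr) {
  Reduce(intersect, lapply(design$backgrounds, function(bg) {
    design$truth$planted_hits[[truth_key(bg, pr)]]
  }))
})))
sub2 <- focused_subcluster(pm, core2)
utils::write.table(round(sub2$matrix, 4),
                   file.path(out, "core_panel_matrix.tsv"),
                   sep = "\t", quote = FALSE)
cat(sprintf("core panel of %d genes re-clustered over %d profiles\n",
            length(sub2$panel), nrow(sub2$matrix)))
cat("wrote", out, "\n")
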