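#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs.
#
# Builds the synthetic counterpart of a five-probe x four-background
# chemical-genetic / SGA study: a 1536-gene deletion library pinned in
# 1536-colony format, planted hypersensitive genes per design cell
# (effect size 0.5 on top of a ~40% global treatment inhibition, 10%
# multiplicative colony noise), a 2000-gene planted-partition global
# interaction network, and a small GO DAG. Every later stage re-derives
# this design deterministically from MASTER_SEED, so plain-text outputs
# here are for inspection, not hand-off.

suppressMessages(library(gincompare))

MASTER_SEED <- 1
out <- "results/01_simulate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design <- synthetic_study_design(seed = MASTER_SEED)
v <- validate_inputs(design)
stopifnot(length(v$failures) == 0)

cat(sprintf("design: %d backgrounds x %d probes = %d cells\n",
            length(design$backgrounds), length(design$probes),
            nrow(design$grid)))
cat(sprintf("library: %d genes on %d plate(s); global GIN: %d genes, %d edges\n",
            length(design$library$genes), design$library$n_plates,
            igraph::vcount(design$global$graph),
            igraph::ecount(design$global$graph)))
cat(sprintf("GO DAG: %d terms, %d annotated\n",
            nrow(design$go$terms), length(design$go$annotations)))

# example raw screen pair for the first cell, as plate CSVs
pair <- generate_screen_pair(design$library, design$truth,
                             design$grid$background[1],
                             design$grid$probe[1],
                             inhibition = design$grid$inhibition[1],
                             seed = design$grid$seed[1])
write_plate_csv(pair$control, file.path(out, "example_control.csv"))
write_plate_csv(pair$treated, file.path(out, "example_treated.csv"))

write_edges_tsv(design$global$edges, file.path(out, "global_gin_edges.tsv"))
write_gmt(design$go$annotations, file.path(out, "annotations.gmt"))
write_term_tsv(design$go, file.path(out, "go_terms.tsv"))
jsonlite::write_json(
  list(seed = MASTER_SEED,
       planted_per_cell = lengths(design$truth$planted_hits),
       effect_size = design$truth$effect_size,
       noise_cv = design$truth$noise_cv,
       query_genes = as.list(design$query_genes)),
  file.path(out, "truth_summary.json"), auto_unbox = TRUE, pretty = TRUE)

cat("wrote", out, "\n")
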