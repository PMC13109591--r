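#!/usr/bin/env Rscript
# Stage 1 — simulate the study-shaped cohort.
#
# Generates a 34-sample count matrix mirroring the iPSC-derived dopaminergic
# neuron cohort (12 healthy / 6 LRRK2 / 16 Parkin samples, two
# differentiation laboratories, two reprogramming methods) with planted
# mutation effects (a shared "convergent PD" component plus LRRK2- and
# Parkin-specific genes, |log2FC| = 2) and an additive place (batch) shift
# on 10% of genes. Writes counts, metadata and the ground truth.

library(dantx)

seed <- 20260924 %% 2147483629
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

effects <- make_study_effects(n_genes = 2000, n_shared = 30, n_lrrk2 = 30,
                              n_parkin = 30, lfc = 2, seed = seed)
design <- simulation_design(n_genes = 2000, effects = effects, seed = seed + 1)
sim <- simulate_counts(design)

write_counts(sim$counts, file.path(out, "counts.tsv"))
write_metadata(sim$metadata, file.path(out, "metadata.tsv"))
jsonlite::write_json(sim$truth$effects, file.path(out, "truth_effects.json"),
                     digits = NA)

message("samples: ", ncol(sim$counts), " (",
        sum(sim$metadata$condition == "PD"), " PD)")
message("genes: ", nrow(sim$counts), "; planted effect rows: ",
        nrow(sim$truth$effects), " (incl. ",
        length(sim$truth$batch_genes), " batch genes)")
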