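#!/usr/bin/env Rscript
# Stage 3 — negative-binomial Wald differential expression.
#
# Fits per-gene NB GLMs with the design place + replicate + condition (or
# mutation) and tests the four study contrasts: PD vs healthy, LRRK2 vs
# healthy, Parkin vs healthy, LRRK2 vs Parkin. DEGs are called at
# FDR < 0.05 and |log2FC| > 1 (strict).

library(dantx)

data_dir <- "results/data"
if (!file.exists(file.path(data_dir, "counts.tsv")))
  stop("run analysis/01_simulate_cohort.R first")
out <- "results/de"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

counts <- read_counts(file.path(data_dir, "counts.tsv"))
md <- read_metadata(file.path(data_dir, "metadata.tsv"), counts)
sf <- size_factors(counts)

de_cond <- run_de(counts, md, factors = c("place", "replicate", "condition"),
                  contrasts = c("condition", "PD", "healthy"), sf = sf)
de_mut <- run_de(counts, md, factors = c("place", "replicate", "mutation"),
                 contrasts = list(LvsH = c("mutation", "LRRK2", "healthy"),
                                  PvsH = c("mutation", "Parkin", "healthy"),
                                  LvsP = c("mutation", "LRRK2", "Parkin")),
                 sf = sf)
tables <- c(list(PDvsH = de_cond), de_mut)

for (nm in names(tables)) {
  write.table(tables[[nm]], file.path(out, paste0("de_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  th <- threshold_degs(tables[[nm]])
  message(sprintf("%s: %d up, %d down", nm, length(th$up), length(th$down)))
}
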