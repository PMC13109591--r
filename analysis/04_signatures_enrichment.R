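#!/usr/bin/env Rscript
# Stage 4 — differentiation signatures, refined condition signatures,
# pre-ranked GSEA and ORA.
#
# Simulates the reference progenitor-to-neuron time course, derives the
# "neurons" / "progenitors" signatures by the all-time-point consistency
# rule, refines the six non-overlapping condition signatures from the four
# DE contrasts, then runs pre-ranked GSEA of the differentiation signatures
# against each contrast and ORA of the PD signature.

library(dantx)

de_dir <- "results/de"
if (!file.exists(file.path(de_dir, "de_PDvsH.tsv")))
  stop("run analysis/03_differential_expression.R first")
out <- "results/signatures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 404

# Couple the time-course truth to the cohort truth: the genes planted as
# convergent PD-up in the cohort double as neuron-maturation markers (and
# PD-down as progenitor markers), emulating the convergence between the
# disease signature and the differentiation axis.
eff <- jsonlite::read_json("results/data/truth_effects.json",
                           simplifyVector = TRUE)
mut <- eff[eff$factor == "mutation", ]
shared <- names(which(table(mut$gene) == 2))
shared_up <- intersect(shared, mut$gene[mut$lfc > 0])
shared_down <- intersect(shared, mut$gene[mut$lfc < 0])
universe <- unique(c(sprintf("G%05d", 1:400), shared_up, shared_down))
tc <- simulate_timecourse(n_per_timepoint = 4, effect_size = 3, seed = seed,
                          genes = universe,
                          neuron_markers = shared_up,
                          progenitor_markers = shared_down)
tmd <- data.frame(sample_id = colnames(tc$counts), time = tc$time)
tc_degs <- lapply(c("wk2", "wk4", "wk6", "wk8"), function(tp) {
  keep <- tc$time %in% c("day0", tp)
  threshold_degs(run_de(count_matrix(unclass(tc$counts)[, keep, drop = FALSE]),
                        tmd[keep, , drop = FALSE], factors = "time",
                        contrasts = c("time", tp, "day0")))
})
diff_sig <- derive_differentiation_signatures(tc_degs)
write_gmt(signatures_to_sets(diff_sig),
          file.path(out, "differentiation_signatures.gmt"))
message("neurons signature: ", length(diff_sig$neurons$genes), " genes (",
        sum(tc$truth$neuron_markers %in% diff_sig$neurons$genes), "/",
        length(tc$truth$neuron_markers), " planted markers)")
message("progenitors signature: ", length(diff_sig$progenitors$genes),
        " genes")

tables <- lapply(c(PDvsH = "PDvsH", LvsH = "LvsH", PvsH = "PvsH",
                   LvsP = "LvsP"),
                 function(nm) read.delim(file.path(de_dir,
                                                   paste0("de_", nm, ".tsv"))))
degs <- lapply(tables, threshold_degs)
sigs <- refine_condition_signatures(degs)
write_gmt(signatures_to_sets(sigs), file.path(out, "condition_signatures.gmt"))
for (s in sigs)
  message(s$name, ": ", length(s$genes), " genes")

ranked <- lapply(tables, make_ranked_list)
gsea <- do.call(rbind, lapply(names(ranked), function(ct) {
  res <- suppressWarnings(
    gsea_prerank(ranked[[ct]], signatures_to_sets(diff_sig),
                 n_perm = 1000, seed = seed + 1))
  if (nrow(res)) cbind(contrast = ct, res) else NULL
}))
if (!is.null(gsea)) {
  write.table(gsea, file.path(out, "gsea_differentiation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message("GSEA rows: ", nrow(gsea), "; significant at FDR < 0.05: ",
          sum(gsea$padj < 0.05))
}

universe <- tables$PDvsH$gene
hits <- intersect(c(sigs$PD_up$genes, sigs$PD_down$genes), universe)
if (length(hits)) {
  ora_tab <- ora(hits, universe, signatures_to_sets(diff_sig))
  write.table(ora_tab, file.path(out, "ora_pd_signature.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message("ORA enrichment ratios: ",
          paste(round(ora_tab$er, 2), collapse = ", "))
}
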