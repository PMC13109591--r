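#' Default pipeline configuration
#'
#' One flat list of every tunable the study-shaped run uses: simulation
#' sizes and planted effects, thresholds, permutation counts and the base
#' seed. Any subset can be overridden via [read_config()] or by passing a
#' modified copy to [run_pipeline()].
#'
#' @return named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    # cohort simulation
    n_genes = 2000, n_shared = 30, n_lrrk2 = 30, n_parkin = 30,
    effect_lfc = 2, batch_frac = 0.1, batch_lfc = 1,
    # reference time course
    tc_n_genes = 400, tc_n_per_timepoint = 4, tc_markers = 20,
    tc_effect = 3,
    # DE thresholds
    fdr = 0.05, lfc = 1,
    # PERMANOVA / GSEA permutations
    permanova_n_perm = 999, gsea_n_perm = 1000,
    gsea_min_size = 5, gsea_max_size = 5000,
    # PPI
    ppi_communities = 3, ppi_p_within = 0.4, ppi_p_between = 0.02,
    string_threshold = 400, mcl_inflation = 2,
    # co-expression
    coexpr_top_n = 1000, coexpr_min_module = 20,
    # pathway activity
    n_pathways = 5, paa_targets = 30, paa_method = "ulm",
    paa_n_perm = 1000, paa_shift = 1
  )
}

# deterministic per-stage seeds below 2^31
stage_seed <- function(seed, k) as.integer((as.numeric(seed) * 97 + k) %%
                                             2147483629)

#' Run the full study-shaped synthetic pipeline
#'
#' Orchestrates simulate -> normalize -> explore -> differential expression
#' (four contrasts) -> signature refinement -> GSEA/ORA -> PPI + MCL ->
#' co-expression -> pathway activity from one configuration, writing every
#' stage output as TSV/GMT/JSON under `outdir` and returning a run manifest
#' (config, per-stage seeds, headline counts, output checksums). Re-running
#' with the same config and seed reproduces byte-identical outputs.
#'
#' @param config configuration list ([default_config()] for the defaults).
#' @param outdir output directory (created if missing).
#' @param seed base seed; default `config$seed`.
#' @return the manifest (invisibly also written to manifest.json).
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("run"),
                         seed = config$seed) {
  cfg <- utils::modifyList(default_config(), config)
  required <- c("n_genes", "fdr", "lfc")
  miss <- required[!vapply(required, function(f) is.numeric(cfg[[f]]),
                           logical(1))]
  if (length(miss))
    stop("invalid config: missing/non-numeric ", paste(miss, collapse = ", "),
         call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(outdir, f)
  warnings_log <- character()

  ## stage 1: cohort simulation with planted truth
  effects <- make_study_effects(cfg$n_genes, cfg$n_shared, cfg$n_lrrk2,
                                cfg$n_parkin, cfg$effect_lfc,
                                seed = stage_seed(seed, 1))
  design <- simulation_design(n_genes = cfg$n_genes, effects = effects,
                              batch_frac = cfg$batch_frac,
                              batch_lfc = cfg$batch_lfc,
                              seed = stage_seed(seed, 2))
  sim <- simulate_counts(design)
  write_counts(sim$counts, path("counts.tsv"))
  write_metadata(sim$metadata, path("metadata.tsv"))
  jsonlite::write_json(sim$truth$effects, path("truth_effects.json"),
                       digits = NA)

  ## stage 2: reference time course and differentiation signatures
  tc <- simulate_timecourse(cfg$tc_n_genes, cfg$tc_n_per_timepoint,
                            cfg$tc_markers, cfg$tc_markers, cfg$tc_effect,
                            seed = stage_seed(seed, 3))
  tc_md <- data.frame(sample_id = colnames(tc$counts), time = tc$time)
  tc_de <- lapply(c("wk2", "wk4", "wk6", "wk8"), function(tp) {
    keep <- tc$time %in% c("day0", tp)
    run_de(count_matrix(unclass(tc$counts)[, keep, drop = FALSE]),
           tc_md[keep, , drop = FALSE], factors = "time",
           contrasts = c("time", tp, "day0"))
  })
  diff_sig <- derive_differentiation_signatures(
    lapply(tc_de, threshold_degs, fdr = cfg$fdr, lfc = cfg$lfc))
  write_gmt(signatures_to_sets(diff_sig), path("differentiation_signatures.gmt"))

  ## stage 3: normalization
  sf <- size_factors(sim$counts)
  vst <- vst_transform(sim$counts, sf)
  utils::write.table(data.frame(sample_id = names(sf), size_factor = sf),
                     path("size_factors.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## stage 4: exploratory structure
  pca <- pca_expr(vst)
  utils::write.table(data.frame(sample_id = rownames(pca$scores),
                                pca$scores[, 1:min(5, ncol(pca$scores))]),
                     path("pca_scores.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  perm <- permanova(vst, sim$metadata,
                    c("mutation", "place", "gender", "reprogramming",
                      "replicate"),
                    n_perm = cfg$permanova_n_perm, seed = stage_seed(seed, 4))
  utils::write.table(perm, path("permanova.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## stage 5: batch correction + post-correction check
  corrected <- remove_batch(vst, sim$metadata, "place", "mutation")
  perm_post <- permanova(corrected, sim$metadata, c("mutation", "place"),
                         n_perm = cfg$permanova_n_perm,
                         seed = stage_seed(seed, 5))
  utils::write.table(perm_post, path("permanova_batch_corrected.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 6: differential expression, four contrasts
  de_cond <- run_de(sim$counts, sim$metadata,
                    factors = c("place", "replicate", "condition"),
                    contrasts = c("condition", "PD", "healthy"), sf = sf)
  de_mut <- run_de(sim$counts, sim$metadata,
                   factors = c("place", "replicate", "mutation"),
                   contrasts = list(
                     LvsH = c("mutation", "LRRK2", "healthy"),
                     PvsH = c("mutation", "Parkin", "healthy"),
                     LvsP = c("mutation", "LRRK2", "Parkin")), sf = sf)
  de_tables <- c(list(PDvsH = de_cond), de_mut)
  for (nm in names(de_tables))
    utils::write.table(de_tables[[nm]], path(paste0("de_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  degs <- lapply(de_tables, threshold_degs, fdr = cfg$fdr, lfc = cfg$lfc)

  ## stage 7: refined non-overlapping signatures
  sigs <- refine_condition_signatures(degs)
  write_gmt(signatures_to_sets(sigs), path("condition_signatures.gmt"))
  prov <- do.call(rbind, lapply(sigs, function(s)
    data.frame(signature = s$name, n_genes = length(s$genes),
               rule = s$provenance)))
  utils::write.table(prov, path("signature_provenance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## stage 8: GSEA of differentiation signatures + ORA of refined sets
  ranked <- lapply(de_tables, make_ranked_list)
  gsea_tabs <- lapply(names(ranked), function(ct) {
    res <- withCallingHandlers(
      gsea_prerank(ranked[[ct]], signatures_to_sets(diff_sig),
                   n_perm = cfg$gsea_n_perm, seed = stage_seed(seed, 6),
                   min_size = cfg$gsea_min_size,
                   max_size = cfg$gsea_max_size),
      warning = function(w) {
        warnings_log <<- c(warnings_log, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (nrow(res)) cbind(contrast = ct, res) else NULL
  })
  gsea_tab <- do.call(rbind, gsea_tabs)
  if (!is.null(gsea_tab))
    utils::write.table(gsea_tab, path("gsea_differentiation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  universe <- de_tables$PDvsH$gene
  ora_hits <- unique(c(sigs$PD_up$genes, sigs$PD_down$genes))
  ora_tab <- if (length(ora_hits))
    ora(intersect(ora_hits, universe), universe,
        signatures_to_sets(diff_sig)) else NULL
  if (!is.null(ora_tab))
    utils::write.table(ora_tab, path("ora_pd_signature.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

  ## stage 9: PPI network over the DEG universe + MCL modules
  deg_union <- unique(unlist(degs))
  ppi_nodes <- max(30, min(120, 3 * length(deg_union)))
  ppi <- simulate_ppi(n_nodes = ppi_nodes,
                      n_communities = cfg$ppi_communities,
                      p_within = cfg$ppi_p_within,
                      p_between = cfg$ppi_p_between,
                      seed = stage_seed(seed, 7))
  # graft gene identifiers onto the simulated interactome: DEGs first
  pool <- c(deg_union, setdiff(universe, deg_union))
  map <- stats::setNames(pool[seq_along(unique(c(ppi$edges$node1,
                                                 ppi$edges$node2)))],
                         sort(unique(c(ppi$edges$node1, ppi$edges$node2))))
  edges <- data.frame(node1 = map[ppi$edges$node1],
                      node2 = map[ppi$edges$node2],
                      combined_score = ppi$edges$combined_score)
  write_edges(edges, path("ppi_edges.tsv"))
  seeds_present <- intersect(deg_union, c(edges$node1, edges$node2))
  ppi_stage <- NULL
  if (length(seeds_present) >= 5) {
    net <- build_seeded_network(edges, seeds_present, cfg$string_threshold)
    net <- expand_network(net, edges, order = 2, max_added = 50,
                          threshold = cfg$string_threshold)
    part <- mcl(net, inflation = cfg$mcl_inflation)
    memb <- data.frame(node = names(part$membership),
                       module = part$membership)
    utils::write.table(memb, path("ppi_modules.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ppi_gsea <- tryCatch(
      suppressWarnings(validate_modules_gsea(part, ranked,
                                             min_size = cfg$gsea_min_size,
                                             n_perm = cfg$gsea_n_perm,
                                             seed = stage_seed(seed, 8))),
      error = function(e) NULL)
    if (!is.null(ppi_gsea))
      utils::write.table(ppi_gsea, path("ppi_module_gsea.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    ppi_stage <- list(n_modules = length(part$modules),
                      module_sizes = lengths(part$modules))
  }

  ## stage 10: co-expression network on the corrected matrix
  coexpr_stage <- NULL
  net_cx <- tryCatch(
    suppressWarnings(build_coexpr_network(corrected, "pearson",
                                          top_n = cfg$coexpr_top_n)),
    error = function(e) NULL)
  part_cx <- NULL
  if (!is.null(net_cx))
    part_cx <- suppressWarnings(detect_modules(net_cx,
                                               min_size = cfg$coexpr_min_module))
  if (!is.null(part_cx) && any(names(part_cx$modules) != "grey")) {
    eig <- module_eigengenes(corrected[net_cx$genes, , drop = FALSE], part_cx)
    utils::write.table(data.frame(sample_id = rownames(eig$eigengenes),
                                  eig$eigengenes),
                       path("coexpr_eigengenes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    mt <- module_trait(eig$eigengenes, sim$metadata)
    utils::write.table(mt$correlations, path("coexpr_module_trait.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    coexpr_stage <- list(n_modules = sum(names(part_cx$modules) != "grey"),
                         n_grey = length(part_cx$modules$grey))
  }

  ## stage 11: pathway activity
  weights <- simulate_weights(rownames(corrected), cfg$n_pathways,
                              cfg$paa_targets, seed = stage_seed(seed, 9))
  write_weights(weights, path("pathway_weights.tsv"))
  pd_samples <- sim$metadata$sample_id[sim$metadata$condition == "PD"]
  shifted <- inject_pathway_shift(corrected, weights, "P01", pd_samples,
                                  cfg$paa_shift)
  activity <- score_pathways(shifted, weights, cfg$paa_method,
                             n_perm = cfg$paa_n_perm,
                             seed = stage_seed(seed, 10))
  utils::write.table(data.frame(pathway = rownames(activity), activity),
                     path("paa_scores.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  assoc <- paa_glm(activity, sim$metadata)
  utils::write.table(assoc, path("paa_association.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## manifest
  files <- list.files(outdir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    config = cfg,
    base_seed = seed,
    stage_seeds = stats::setNames(lapply(1:10, function(k)
      stage_seed(seed, k)), paste0("stage_", 1:10)),
    deg_counts = lapply(degs, lengths),
    signature_sizes = lapply(sigs, function(s) length(s$genes)),
    differentiation_signature_sizes = lapply(diff_sig,
                                             function(s) length(s$genes)),
    permanova_r2 = stats::setNames(as.list(perm$R2[seq_len(nrow(perm) - 2)]),
                                   perm$term[seq_len(nrow(perm) - 2)]),
    ppi = ppi_stage,
    coexpr = coexpr_stage,
    significant_pathways = unique(assoc$pathway[assoc$padj < cfg$fdr]),
    warnings = warnings_log,
    checksums = as.list(tools::md5sum(files))
  )
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
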