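#' Study cohort layout
#'
#' Sample metadata mirroring the study design: six iPSC lines (two healthy
#' donors, one LRRK2 carrier, three Parkin carriers) differentiated
#' independently in two laboratories, 34 samples in total (12 healthy, 6
#' LRRK2, 16 Parkin; 10 Moscow, 24 St. Petersburg). Replicates alternate 1/2
#' within each line-by-place cell.
#'
#' @return metadata data.frame with the seven standard columns plus
#'   `cell_line`.
#' @export
study_metadata <- function() {
  lines <- data.frame(
    cell_line = c("RG4S", "FF9S", "PDL1.6S", "PDP1.5L", "PDP2.1L", "PDP4.4S"),
    gender = c("M", "F", "M", "M", "M", "M"),
    reprogramming = c("sendai", "sendai", "sendai", "lentivirus",
                      "lentivirus", "sendai"),
    mutation = c("healthy", "healthy", "LRRK2", "Parkin", "Parkin", "Parkin"),
    n_spb = c(4, 4, 4, 4, 4, 4),
    n_moscow = c(2, 2, 2, 0, 2, 2),
    stringsAsFactors = FALSE
  )
  rows <- do.call(rbind, lapply(seq_len(nrow(lines)), function(i) {
    l <- lines[i, ]
    place <- c(rep("StPetersburg", l$n_spb), rep("Moscow", l$n_moscow))
    idx <- c(seq_len(l$n_spb), seq_len(l$n_moscow))
    data.frame(
      sample_id = paste(l$cell_line, substr(place, 1, 3), idx, sep = "_"),
      cell_line = l$cell_line,
      condition = ifelse(l$mutation == "healthy", "healthy", "PD"),
      mutation = l$mutation,
      place = place,
      replicate = ((idx - 1) %% 2) + 1,
      gender = l$gender,
      reprogramming = l$reprogramming,
      stringsAsFactors = FALSE
    )
  }))
  validate_metadata(rows)
}

#' Published per-contrast refined signature sizes
#'
#' The study's refined, non-overlapping condition-signature sizes as printed:
#' PD 414 genes (144 up, 270 down), LRRK2 1,644 (503 up, 1,141 down), Parkin
#' 220 (124 up, 96 down). Used for bookkeeping checks of the signature data
#' model; the underlying gene lists derive from deposited raw data and are
#' not recomputable here.
#'
#' @return data.frame(signature, up, down, total).
#' @export
published_signature_counts <- function() {
  data.frame(
    signature = c("PD", "LRRK2", "Parkin"),
    up = c(144L, 503L, 124L),
    down = c(270L, 1141L, 96L),
    total = c(414L, 1644L, 220L)
  )
}

#' Define a simulation design
#'
#' Parameters of the negative-binomial count generator. Defaults emulate the
#' study cohort (34 samples across two laboratories) and typical bulk RNA-seq
#' moments: baseline means log-uniform on [2, 2^12], gene dispersions
#' log-normal around 0.1, library-size factors log-uniform on [0.5, 2], and
#' an additive batch (place) shift of `batch_lfc` log2 units on a random
#' `batch_frac` fraction of genes.
#'
#' @param n_genes number of genes.
#' @param metadata sample metadata (defaults to [study_metadata()]).
#' @param effects planted effect table: data.frame(gene integer index or id,
#'   factor, level, lfc). A sample receives the effect when its metadata value
#'   for `factor` equals `level`.
#' @param baseline_log2_range range of log2 baseline means.
#' @param dispersion either NULL (log-normal draw with `dispersion_meanlog`,
#'   `dispersion_sdlog`) or a single non-negative value used for all genes
#'   (0 = Poisson).
#' @param dispersion_meanlog,dispersion_sdlog log-normal dispersion parameters.
#' @param libsize_range range of library size factors (log-uniform draw).
#' @param batch_frac fraction of genes receiving the place shift.
#' @param batch_lfc log2 magnitude of the place shift.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return list of class `simulation_design`.
#' @export
simulation_design <- function(n_genes = 2000, metadata = study_metadata(),
                              effects = NULL,
                              baseline_log2_range = c(1, 12),
                              dispersion = NULL,
                              dispersion_meanlog = log(0.1),
                              dispersion_sdlog = 1,
                              libsize_range = c(0.5, 2),
                              batch_frac = 0.1, batch_lfc = 1,
                              seed = 1L) {
  if (n_genes < 1 || nrow(metadata) < 1)
    stop("degenerate design: need >=1 gene and >=1 sample", call. = FALSE)
  if (!is.null(effects) && any(!is.finite(effects$lfc)))
    stop("planted effects must be finite", call. = FALSE)
  structure(list(n_genes = n_genes, metadata = metadata, effects = effects,
                 baseline_log2_range = baseline_log2_range,
                 dispersion = dispersion,
                 dispersion_meanlog = dispersion_meanlog,
                 dispersion_sdlog = dispersion_sdlog,
                 libsize_range = libsize_range,
                 batch_frac = batch_frac, batch_lfc = batch_lfc,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' Planted effect table for a study-shaped run
#'
#' Convenience generator for mutation effects with the structure the
#' signature algebra expects: `n_shared` genes shifted in both LRRK2 and
#' Parkin samples (half up, half down; the convergent "PD" component) plus
#' `n_lrrk2` and `n_parkin` mutation-specific genes.
#'
#' @param n_genes gene universe size.
#' @param n_shared,n_lrrk2,n_parkin numbers of planted genes per component.
#' @param lfc planted log2 effect magnitude.
#' @param seed integer seed.
#' @return effect data.frame(gene, factor, level, lfc).
#' @export
make_study_effects <- function(n_genes, n_shared = 30, n_lrrk2 = 30,
                               n_parkin = 30, lfc = 2, seed = 1L) {
  set.seed(seed)
  total <- n_shared + n_lrrk2 + n_parkin
  if (total > n_genes) stop("more planted genes than universe", call. = FALSE)
  g <- sample.int(n_genes, total)
  shared <- g[seq_len(n_shared)]
  lg <- g[n_shared + seq_len(n_lrrk2)]
  pg <- g[n_shared + n_lrrk2 + seq_len(n_parkin)]
  sgn <- function(k) rep_len(c(1, -1), k)
  rbind(
    data.frame(gene = rep(shared, 2),
               factor = "mutation",
               level = rep(c("LRRK2", "Parkin"), each = n_shared),
               lfc = rep(lfc * sgn(n_shared), 2)),
    data.frame(gene = lg, factor = "mutation", level = "LRRK2",
               lfc = lfc * sgn(n_lrrk2)),
    data.frame(gene = pg, factor = "mutation", level = "Parkin",
               lfc = lfc * sgn(n_parkin))
  )
}

#' Simulate a count matrix with planted ground truth
#'
#' Counts are drawn gene-wise from a negative binomial with mean
#' `mu_gs = s_s * q_g * 2^(sum of planted effects active for sample s)` and
#' gene-level dispersion `phi_g` (`var = mu + phi mu^2`); `phi = 0` falls
#' back to Poisson draws. The batch (place) shift is planted on a random
#' fraction of genes and recorded in the ground truth.
#'
#' @param design a [simulation_design()].
#' @return list with `counts` ([count_matrix()]), `metadata`, and `truth`
#'   (planted effect table including batch rows, batch gene ids, dispersions,
#'   size factors).
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed)
  n_g <- design$n_genes
  md <- design$metadata
  n_s <- nrow(md)
  genes <- sprintf("G%05d", seq_len(n_g))
  q <- 2^stats::runif(n_g, design$baseline_log2_range[1],
                      design$baseline_log2_range[2])
  phi <- if (is.null(design$dispersion)) {
    stats::rlnorm(n_g, design$dispersion_meanlog, design$dispersion_sdlog)
  } else rep(design$dispersion, n_g)
  s <- exp(stats::runif(n_s, log(design$libsize_range[1]),
                        log(design$libsize_range[2])))
  effects <- design$effects
  if (!is.null(effects) && nrow(effects)) {
    eg <- effects$gene
    if (is.numeric(eg)) effects$gene <- genes[eg]
    if (!all(effects$gene %in% genes))
      stop("planted effect on gene outside universe", call. = FALSE)
  }
  batch_genes <- character()
  if (design$batch_frac > 0 && design$batch_lfc != 0 &&
      nlevels(md$place) > 1) {
    batch_genes <- sample(genes, round(design$batch_frac * n_g))
    effects <- rbind(effects,
                     data.frame(gene = batch_genes, factor = "place",
                                level = levels(md$place)[2],
                                lfc = design$batch_lfc))
  }
  log2mu <- matrix(log2(q), n_g, n_s, dimnames = list(genes, md$sample_id))
  if (!is.null(effects) && nrow(effects)) {
    for (i in seq_len(nrow(effects))) {
      cols <- as.character(md[[effects$factor[i]]]) == effects$level[i]
      log2mu[effects$gene[i], cols] <- log2mu[effects$gene[i], cols] +
        effects$lfc[i]
    }
  }
  mu <- sweep(2^log2mu, 2, s, `*`)
  counts <- matrix(0, n_g, n_s, dimnames = dimnames(mu))
  for (j in seq_len(n_s)) {
    counts[, j] <- ifelse(phi > 0,
                          stats::rnbinom(n_g, mu = mu[, j], size = 1 / phi),
                          stats::rpois(n_g, mu[, j]))
  }
  list(counts = count_matrix(counts), metadata = md,
       truth = list(effects = effects, batch_genes = batch_genes,
                    dispersions = stats::setNames(phi, genes),
                    size_factors = stats::setNames(s, md$sample_id),
                    baseline = stats::setNames(q, genes)))
}

#' Expected log2 fold change of a planted contrast
#'
#' Sums the planted effects to the true log2 fold change of `levelA` versus
#' `levelB` of `factor` for every gene with a non-zero expectation.
#'
#' @param truth the `truth` element returned by [simulate_counts()].
#' @param factor metadata factor of the contrast.
#' @param levelA,levelB contrast levels (A vs B).
#' @return named numeric vector of true non-zero LFCs.
#' @export
true_lfc <- function(truth, factor, levelA, levelB) {
  eff <- truth$effects
  if (is.null(eff) || !nrow(eff)) return(stats::setNames(numeric(), character()))
  eff <- eff[eff$factor == factor, , drop = FALSE]
  lfc_of <- function(level) {
    sub <- eff[eff$level == level, , drop = FALSE]
    stats::setNames(sub$lfc, sub$gene)
  }
  a <- lfc_of(levelA); b <- lfc_of(levelB)
  genes <- union(names(a), names(b))
  v <- stats::setNames(rep(0, length(genes)), genes)
  v[names(a)] <- v[names(a)] + a
  v[names(b)] <- v[names(b)] - b
  v[v != 0]
}

#' Simulate a progenitor-to-neuron differentiation time course
#'
#' Emulates a reference differentiation series: neuronal progenitors at day 0
#' and neuronal cultures at 2, 4, 6 and 8 weeks. Neuron markers rise
#' monotonically (log2 shift ramping from `effect_size/2` at week 2 to
#' `effect_size` at week 8); progenitor markers fall symmetrically;
#' non-markers stay flat.
#'
#' @param n_genes gene universe size (ignored when `genes` is supplied).
#' @param n_per_timepoint samples per time point.
#' @param n_neuron_markers,n_progenitor_markers planted marker counts
#'   (ignored when explicit marker ids are supplied).
#' @param effect_size log2 shift magnitude at the final time point; 0 plants
#'   no markers.
#' @param seed integer seed.
#' @param dispersion NB dispersion for all genes.
#' @param genes optional explicit gene universe (character), e.g. to share
#'   identifiers with a simulated cohort.
#' @param neuron_markers,progenitor_markers optional explicit marker gene
#'   ids (must lie in the universe), overriding the random draw.
#' @return list(counts, time, truth) where `time` is a factor with levels
#'   day0, wk2, wk4, wk6, wk8 and `truth` carries the marker gene ids.
#' @export
simulate_timecourse <- function(n_genes = 200, n_per_timepoint = 4,
                                n_neuron_markers = 20,
                                n_progenitor_markers = 20,
                                effect_size = 3, seed = 1L,
                                dispersion = 0.05, genes = NULL,
                                neuron_markers = NULL,
                                progenitor_markers = NULL) {
  if (is.null(genes)) genes <- sprintf("G%05d", seq_len(n_genes))
  n_genes <- length(genes)
  explicit <- !is.null(neuron_markers) || !is.null(progenitor_markers)
  if (explicit) {
    if (!all(c(neuron_markers, progenitor_markers) %in% genes))
      stop("markers exceed gene universe", call. = FALSE)
    n_neuron_markers <- length(neuron_markers)
    n_progenitor_markers <- length(progenitor_markers)
  }
  if (n_neuron_markers + n_progenitor_markers > n_genes)
    stop("markers exceed gene universe", call. = FALSE)
  set.seed(seed)
  tps <- c("day0", "wk2", "wk4", "wk6", "wk8")
  time <- factor(rep(tps, each = n_per_timepoint), levels = tps)
  samples <- paste0(rep(tps, each = n_per_timepoint), "_r",
                    rep(seq_len(n_per_timepoint), length(tps)))
  q <- 2^stats::runif(n_genes, 3, 12)
  neuron <- progenitor <- character()
  if (effect_size != 0) {
    if (explicit) {
      neuron <- neuron_markers
      progenitor <- progenitor_markers
    } else {
      idx <- sample.int(n_genes, n_neuron_markers + n_progenitor_markers)
      neuron <- genes[idx[seq_len(n_neuron_markers)]]
      progenitor <- genes[idx[n_neuron_markers +
                                seq_len(n_progenitor_markers)]]
    }
  }
  ramp <- effect_size * c(0, 1 / 2, 2 / 3, 5 / 6, 1)  # per time point
  log2mu <- matrix(log2(q), n_genes, length(samples),
                   dimnames = list(genes, samples))
  for (k in seq_along(tps)[-1]) {
    cols <- time == tps[k]
    log2mu[neuron, cols] <- log2mu[neuron, cols] + ramp[k]
    log2mu[progenitor, cols] <- log2mu[progenitor, cols] - ramp[k]
  }
  mu <- 2^log2mu
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   n_genes, length(samples), dimnames = dimnames(mu))
  list(counts = count_matrix(counts), time = time,
       truth = list(neuron_markers = neuron, progenitor_markers = progenitor,
                    ramp = ramp))
}

#' Simulate a planted-partition protein interaction graph
#'
#' Stochastic block model: node pairs within a community connect with
#' probability `p_within` (scores drawn high, 700-999), pairs across
#' communities with `p_between` (scores 401-700). Used to exercise the
#' Markov clustering stage with known community structure.
#'
#' @param n_nodes total nodes (split as evenly as possible).
#' @param n_communities number of planted communities.
#' @param p_within,p_between edge probabilities.
#' @param seed integer seed.
#' @return list(edges, membership): an edge-list data.frame and the named
#'   integer community assignment.
#' @export
simulate_ppi <- function(n_nodes = 60, n_communities = 3, p_within = 0.4,
                         p_between = 0.02, seed = 1L) {
  if (p_within <= p_between)
    warning("p_within <= p_between: communities are unidentifiable",
            call. = FALSE)
  set.seed(seed)
  nodes <- sprintf("N%04d", seq_len(n_nodes))
  membership <- stats::setNames(rep_len(seq_len(n_communities), n_nodes), nodes)
  pairs <- utils::combn(n_nodes, 2)
  same <- membership[pairs[1, ]] == membership[pairs[2, ]]
  p <- ifelse(same, p_within, p_between)
  keep <- stats::runif(ncol(pairs)) < p
  score <- ifelse(same[keep],
                  round(stats::runif(sum(keep), 700, 999)),
                  round(stats::runif(sum(keep), 401, 700)))
  edges <- data.frame(node1 = nodes[pairs[1, keep]],
                      node2 = nodes[pairs[2, keep]],
                      combined_score = score)
  list(edges = edge_list(edges), membership = membership)
}

#' Simulate expression with planted co-expression modules
#'
#' Latent-factor model: each planted module m has a per-sample latent score
#' z_m ~ N(0, 1); member genes load on it with positive loadings near 1 plus
#' i.i.d. noise (positive loadings because a signed-hybrid network, which
#' zeroes negative correlations, defines a module as a positively
#' co-expressed block). Remaining genes are pure noise.
#' Optionally shifts the latent score of selected modules by `group_shift`
#' per sample, to plant module-trait associations.
#'
#' @param n_samples number of samples.
#' @param module_sizes integer vector of planted module sizes.
#' @param n_noise number of unstructured genes.
#' @param noise_sd residual standard deviation (module genes).
#' @param group_shift optional numeric vector (length `n_samples`) added to
#'   the latent score of `shift_modules`.
#' @param shift_modules indices of modules receiving `group_shift`.
#' @param seed integer seed.
#' @return list(expr, membership): expression matrix (genes x samples,
#'   provenance "batch_corrected") and named module index (0 = noise).
#' @export
simulate_coexpr <- function(n_samples = 30, module_sizes = c(40, 40),
                            n_noise = 60, noise_sd = 0.5,
                            group_shift = NULL, shift_modules = integer(),
                            seed = 1L) {
  set.seed(seed)
  n_mod_genes <- sum(module_sizes)
  n_genes <- n_mod_genes + n_noise
  genes <- sprintf("G%05d", seq_len(n_genes))
  samples <- sprintf("S%03d", seq_len(n_samples))
  expr <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples,
                 dimnames = list(genes, samples))
  membership <- stats::setNames(rep(0L, n_genes), genes)
  offset <- 0
  for (m in seq_along(module_sizes)) {
    z <- stats::rnorm(n_samples)
    if (m %in% shift_modules && !is.null(group_shift)) z <- z + group_shift
    idx <- offset + seq_len(module_sizes[m])
    load <- stats::runif(module_sizes[m], 0.8, 1.2)
    expr[idx, ] <- outer(load, z) +
      noise_sd * matrix(stats::rnorm(module_sizes[m] * n_samples),
                        module_sizes[m], n_samples)
    membership[idx] <- m
    offset <- offset + module_sizes[m]
  }
  attr(expr, "provenance") <- "batch_corrected"
  list(expr = expr, membership = membership)
}

#' Simulate a toy pathway weight matrix
#'
#' Draws `n_targets` target genes per pathway with signed weights of
#' magnitude 0.5-1.5 (half positive, half negative), in the long TSV format
#' consumed by the pathway-activity module.
#'
#' @param genes gene universe (character).
#' @param n_pathways number of pathways.
#' @param n_targets targets per pathway.
#' @param seed integer seed.
#' @return data.frame(pathway, gene, weight).
#' @export
simulate_weights <- function(genes, n_pathways = 5, n_targets = 30,
                             seed = 1L) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_pathways), function(p) {
    tg <- sample(genes, n_targets)
    data.frame(pathway = sprintf("P%02d", p), gene = tg,
               weight = sample(c(-1, 1), n_targets, replace = TRUE) *
                 stats::runif(n_targets, 0.5, 1.5))
  }))
}

#' Plant a pathway activity shift into an expression matrix
#'
#' Adds `delta * weight_g` to the expression of each target gene of
#' `pathway` in the selected samples, i.e., moves targets along their weight
#' signs, which raises the pathway's activity score in those samples.
#'
#' @param expr expression matrix (genes x samples).
#' @param weights long weight table.
#' @param pathway pathway id to shift.
#' @param samples sample ids receiving the shift.
#' @param delta shift magnitude.
#' @return the modified matrix.
#' @export
inject_pathway_shift <- function(expr, weights, pathway, samples, delta) {
  w <- weights[weights$pathway == pathway, , drop = FALSE]
  w <- w[w$gene %in% rownames(expr), , drop = FALSE]
  expr[w$gene, samples] <- expr[w$gene, samples] + delta * w$weight
  expr
}
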