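#' Median-of-ratios size factors
#'
#' For each sample j, s_j is the median over reference genes g of
#' counts[g, j] / geomean_g, where geomean_g is the geometric mean of gene g
#' across samples and the reference set is the genes with geomean_g > 0
#' (i.e., positive counts in every sample).
#'
#' @param counts count matrix.
#' @return named positive numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  log_geo <- rowMeans(log(counts))
  ref <- is.finite(log_geo)
  if (!any(ref))
    stop("no reference gene: every gene has a zero count in some sample",
         call. = FALSE)
  s <- apply(counts[ref, , drop = FALSE], 2, function(col) {
    stats::median(col / exp(log_geo[ref]))
  })
  stats::setNames(as.numeric(s), colnames(counts))
}

#' Size-factor-normalized counts
#' @param counts count matrix.
#' @param sf size factors (defaults to [size_factors()]).
#' @return matrix of counts / s_j with provenance "normalized".
#' @export
normalized_counts <- function(counts, sf = size_factors(counts)) {
  x <- sweep(unclass(counts), 2, sf, `/`)
  attr(x, "provenance") <- "normalized"
  x
}

#' Variance-stabilizing transform (log2 stand-in)
#'
#' Computed as log2(count / s_j + 1): monotone in counts within each sample
#' and finite everywhere (zeros map to zero). This is a deliberate stand-in
#' for a dispersion-trend-based transform; it feeds only the exploratory
#' (PCA, PERMANOVA) and network stages, never the differential-expression
#' test, which works on raw counts.
#'
#' @param counts count matrix.
#' @param sf size factors.
#' @return transformed matrix with provenance "vst".
#' @export
vst_transform <- function(counts, sf = size_factors(counts)) {
  x <- log2(sweep(unclass(counts), 2, sf, `/`) + 1)
  attr(x, "provenance") <- "vst"
  x
}

#' Covariate-preserving batch correction
#'
#' Per gene, a least-squares fit on the design and batch codings
#' (treatment contrasts, first level alphabetically as reference) and
#' subtraction of the fitted batch component only, so design-attributable
#' variation is preserved. Delegates the fit to limma's removeBatchEffect.
#' Idempotent: correcting twice equals correcting once.
#'
#' @param expr expression matrix (genes x samples), typically the VST matrix.
#' @param metadata sample metadata aligned with `expr` columns.
#' @param batch_factor metadata column treated as batch.
#' @param design_factors metadata columns whose variation must be preserved.
#' @return corrected matrix with provenance "batch_corrected".
#' @export
remove_batch <- function(expr, metadata, batch_factor = "place",
                         design_factors = "mutation") {
  miss <- setdiff(c(batch_factor, design_factors), names(metadata))
  if (length(miss))
    stop("metadata missing factor(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  md <- metadata
  for (f in c(batch_factor, design_factors))
    md[[f]] <- factor(as.character(md[[f]]))
  design_factors <- design_factors[vapply(design_factors, function(f)
    nlevels(md[[f]]) >= 2, logical(1))]
  design <- if (length(design_factors)) {
    stats::model.matrix(stats::reformulate(design_factors), data = md)
  } else matrix(1, nrow(md), 1)
  batch <- md[[batch_factor]]
  full <- cbind(design, stats::model.matrix(~batch)[, -1, drop = FALSE])
  qr_full <- qr(full)
  if (qr_full$rank < ncol(full)) {
    dropped <- colnames(full)[qr_full$pivot[-seq_len(qr_full$rank)]]
    stop("design and batch are confounded (aliased column(s): ",
         paste(dropped, collapse = ", "), ")", call. = FALSE)
  }
  out <- limma::removeBatchEffect(expr, batch = batch, design = design)
  attr(out, "provenance") <- "batch_corrected"
  out
}
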