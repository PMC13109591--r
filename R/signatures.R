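#' Construct a gene signature
#'
#' A named gene set with a direction label and provenance recording the
#' intersection rule that produced it.
#'
#' @param name signature name.
#' @param genes character vector of gene ids (de-duplicated, sorted).
#' @param provenance human-readable rule description.
#' @return list of class `gene_signature`.
#' @export
gene_signature <- function(name, genes, provenance = "") {
  structure(list(name = name, genes = sort(unique(genes)),
                 provenance = provenance),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("<gene_signature> ", x$name, ": ", length(x$genes), " genes (",
      x$provenance, ")\n", sep = "")
  invisible(x)
}

#' Derive neuron and progenitor differentiation signatures
#'
#' Given the four thresholded DE comparisons of the reference time course
#' (each neuronal time point versus the progenitor baseline), the "neurons"
#' signature is the intersection of the four up-regulated lists (genes
#' consistently higher at every neuronal time point) and the "progenitors"
#' signature the intersection of the four down-regulated lists.
#'
#' @param deg_list list of exactly four elements, each a list(up, down) of
#'   gene id vectors (e.g. from [threshold_degs()]), one per time point.
#' @return list(neurons, progenitors) of [gene_signature()] objects.
#' @export
derive_differentiation_signatures <- function(deg_list) {
  if (length(deg_list) < 4)
    stop("need four time-point comparisons, got ", length(deg_list),
         call. = FALSE)
  ups <- lapply(deg_list, `[[`, "up")
  downs <- lapply(deg_list, `[[`, "down")
  neurons <- Reduce(intersect, ups)
  progenitors <- Reduce(intersect, downs)
  list(neurons = gene_signature("neurons", neurons,
                                "intersection of up lists across all four time points"),
       progenitors = gene_signature("progenitors", progenitors,
                                    "intersection of down lists across all four time points"))
}

#' Refine non-overlapping condition-specific signatures
#'
#' Applies the intersection algebra over the four study contrasts
#' (PD vs healthy, LRRK2 vs healthy, Parkin vs healthy, LRRK2 vs Parkin):
#' \itemize{
#'   \item PD_up = up(PDvsH) n up(LvsH) n up(PvsH)
#'   \item PD_down = down(PDvsH) n down(LvsH) n down(PvsH) (the healthy
#'     signature)
#'   \item LRRK2_up = up(LvsH) n up(LvsP); LRRK2_down = down(LvsH) n down(LvsP)
#'   \item Parkin_up = up(PvsH) n down(LvsP); Parkin_down = down(PvsH) n up(LvsP)
#' }
#' then removes any gene occurring in two or more of the six outputs from
#' all of them, so the final signatures are pairwise disjoint regardless of
#' input order.
#'
#' @param degs named list with elements `PDvsH`, `LvsH`, `PvsH`, `LvsP`,
#'   each a list(up, down) of gene id vectors.
#' @return named list of six [gene_signature()] objects: PD_up, PD_down,
#'   LRRK2_up, LRRK2_down, Parkin_up, Parkin_down.
#' @export
refine_condition_signatures <- function(degs) {
  need <- c("PDvsH", "LvsH", "PvsH", "LvsP")
  miss <- setdiff(need, names(degs))
  if (length(miss))
    stop("missing contrast(s): ", paste(miss, collapse = ", "), call. = FALSE)
  raw <- list(
    PD_up = Reduce(intersect, list(degs$PDvsH$up, degs$LvsH$up, degs$PvsH$up)),
    PD_down = Reduce(intersect, list(degs$PDvsH$down, degs$LvsH$down,
                                     degs$PvsH$down)),
    LRRK2_up = intersect(degs$LvsH$up, degs$LvsP$up),
    LRRK2_down = intersect(degs$LvsH$down, degs$LvsP$down),
    Parkin_up = intersect(degs$PvsH$up, degs$LvsP$down),
    Parkin_down = intersect(degs$PvsH$down, degs$LvsP$up)
  )
  tab <- table(unlist(raw))
  shared <- names(tab)[tab >= 2]
  rules <- c(
    PD_up = "up(PDvsH) & up(LvsH) & up(PvsH)",
    PD_down = "down(PDvsH) & down(LvsH) & down(PvsH)",
    LRRK2_up = "up(LvsH) & up(LvsP)",
    LRRK2_down = "down(LvsH) & down(LvsP)",
    Parkin_up = "up(PvsH) & down(LvsP)",
    Parkin_down = "down(PvsH) & up(LvsP)"
  )
  out <- lapply(names(raw), function(nm) {
    gene_signature(nm, setdiff(raw[[nm]], shared),
                   paste0(rules[nm], "; overlaps removed"))
  })
  stats::setNames(out, names(raw))
}

#' Export signatures as a gene-set collection
#' @param signatures list of [gene_signature()] objects.
#' @return named list of gene vectors suitable for [write_gmt()].
#' @export
signatures_to_sets <- function(signatures) {
  sets <- lapply(signatures, `[[`, "genes")
  stats::setNames(sets, vapply(signatures, `[[`, "", "name"))
}
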