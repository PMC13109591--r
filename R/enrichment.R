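#' Build a signed -log10(p) ranked gene list
#'
#' Score = sign(LFC) * min(-log10(p), 300); genes are sorted by descending
#' score with ties broken by gene identifier ascending, so the ordering is
#' deterministic.
#'
#' @param de a DE table (gene, lfc, pvalue columns).
#' @return named numeric vector sorted descending.
#' @export
make_ranked_list <- function(de) {
  ok <- !is.na(de$pvalue) & !is.na(de$lfc)
  de <- de[ok, , drop = FALSE]
  score <- sign(de$lfc) * pmin(-log10(pmax(de$pvalue, 1e-300)), 300)
  score[de$pvalue == 0] <- sign(de$lfc)[de$pvalue == 0] * 300
  ord <- order(-score, de$gene)
  stats::setNames(score[ord], de$gene[ord])
}

# Enrichment score of the weighted Kolmogorov-Smirnov running sum, computed
# from the sorted hit positions in O(|S|): hit i contributes its normalized
# weight; the misses between hits contribute -(pos_i - i)/(N - k).
es_from_positions <- function(positions, hit_weights, n_total) {
  k <- length(positions)
  if (k == 0) return(list(es = 0, at = NA_integer_))
  if (k >= n_total) stop("gene set equals the whole universe", call. = FALSE)
  sw <- sum(hit_weights)
  w <- if (sw == 0) rep(1 / k, k) else hit_weights / sw  # all-zero degenerate
  cw <- cumsum(w)
  miss <- (positions - seq_len(k)) / (n_total - k)
  after <- cw - miss          # running sum just after each hit
  before <- c(0, cw[-k]) - miss  # just before each hit
  i_max <- which.max(after)
  i_min <- which.min(before)
  if (after[i_max] >= -before[i_min]) {
    list(es = unname(after[i_max]), at = i_max)
  } else {
    list(es = unname(before[i_min]), at = i_min)
  }
}

#' Pre-ranked gene set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum statistic: hits increment by
#' |score|^weight (normalized over the set's hits), misses decrement by
#' 1/(N - n_set). The null is generated by `n_perm` random same-size gene
#' sets (tag permutation); NES normalizes ES by the mean |null ES| of
#' matching sign; the nominal p is the matching-sign null tail with the +1
#' convention; FDR is BH across sets. The leading edge contains the hits up
#' to the ES extremum.
#'
#' @param ranked named score vector from [make_ranked_list()].
#' @param sets named list of gene sets.
#' @param weight score weight exponent (1 = classic).
#' @param n_perm number of null sets per gene set.
#' @param seed integer seed.
#' @param min_size,max_size set size bounds after intersection with the
#'   ranked universe; sets outside are skipped with a warning.
#' @return data.frame(set, size, es, nes, pvalue, padj, leading_edge).
#' @export
gsea_prerank <- function(ranked, sets, weight = 1, n_perm = 1000, seed = 1L,
                         min_size = 5, max_size = 5000) {
  genes <- names(ranked)
  n <- length(genes)
  idx_of <- stats::setNames(seq_len(n), genes)
  absw <- abs(ranked)^weight
  set.seed(seed)
  rows <- lapply(names(sets), function(nm) {
    hit <- sort(unname(idx_of[intersect(sets[[nm]], genes)]))
    k <- length(hit)
    if (k < min_size || k > max_size) {
      warning("set '", nm, "' outside size bounds after intersection (",
              k, "), skipped", call. = FALSE)
      return(NULL)
    }
    if (k >= n) stop("set '", nm, "' equals the whole universe", call. = FALSE)
    obs <- es_from_positions(hit, absw[hit], n)
    null_es <- vapply(seq_len(n_perm), function(i) {
      pos <- sort(sample.int(n, k))
      es_from_positions(pos, absw[pos], n)$es
    }, numeric(1))
    same <- null_es[sign(null_es) == sign(obs$es)]
    if (length(same)) {
      nes <- sign(obs$es) * abs(obs$es) / mean(abs(same))
      pval <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
    } else {
      nes <- NA_real_
      pval <- 1 / (1 + n_perm)
    }
    le <- if (obs$es >= 0) genes[hit[seq_len(obs$at)]] else
      genes[hit[seq(obs$at, k)]]
    data.frame(set = nm, size = k, es = obs$es, nes = nes, pvalue = pval,
               padj = NA_real_, leading_edge = paste(le, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), pvalue = numeric(), padj = numeric(),
                      leading_edge = character()))
  out$padj <- stats::p.adjust(out$pvalue, "BH")
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation analysis
#'
#' For each set S (intersected with the universe): overlap k = |hits n S|,
#' enrichment ratio ER = (k/|hits|) / (|S|/|universe|), upper-tail
#' hypergeometric p = P(X >= k), BH FDR across sets.
#'
#' @param hits gene list of interest (must be a subset of `universe`).
#' @param universe background gene list.
#' @param sets named list of gene sets.
#' @return data.frame(set, size, overlap, er, pvalue, padj, genes).
#' @export
ora <- function(hits, universe, sets) {
  hits <- unique(hits); universe <- unique(universe)
  if (!length(hits) || !length(universe))
    stop("empty hits or universe", call. = FALSE)
  if (!all(hits %in% universe))
    stop("hits must be a subset of the universe", call. = FALSE)
  n_u <- length(universe); n_h <- length(hits)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    ov <- intersect(hits, s)
    k <- length(ov)
    er <- if (length(s)) (k / n_h) / (length(s) / n_u) else NA_real_
    p <- if (length(s)) stats::phyper(k - 1, length(s), n_u - length(s), n_h,
                                      lower.tail = FALSE) else NA_real_
    data.frame(set = nm, size = length(s), overlap = k, er = er, pvalue = p,
               padj = NA_real_, genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$pvalue, "BH")
  rownames(out) <- NULL
  out
}
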