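#' Pathway activity scores from a weight matrix
#'
#' Two scorers over a (typically batch-corrected) expression matrix:
#' \describe{
#'   \item{ulm}{per sample, the t-statistic of the slope from regressing the
#'     sample's z-scored expression (across genes) on the pathway weight
#'     vector, with zero weight for non-members. Invariant to affine
#'     rescaling of the sample's expression.}
#'   \item{wsum}{the weighted sum of member-gene expression, normalized to a
#'     z-score against `n_perm` gene-label permutations (mean ~ 0 under the
#'     null).}
#' }
#' Pathways with no weighted gene present in the matrix are skipped with a
#' warning.
#'
#' @param expr expression matrix (genes x samples).
#' @param weights long weight table (pathway, gene, weight).
#' @param method "ulm" or "wsum".
#' @param n_perm permutations for the wsum null.
#' @param seed integer seed (wsum).
#' @return pathway x sample score matrix with attribute "method".
#' @export
score_pathways <- function(expr, weights, method = c("ulm", "wsum"),
                           n_perm = 1000, seed = 1L) {
  method <- match.arg(method)
  if (all(weights$weight == 0)) stop("all-zero weights", call. = FALSE)
  pws <- unique(weights$pathway)
  genes <- rownames(expr)
  n_g <- length(genes)
  keep <- vapply(pws, function(p) {
    any(weights$gene[weights$pathway == p] %in% genes)
  }, logical(1))
  if (any(!keep))
    warning("skipping pathway(s) with no gene in matrix: ",
            paste(pws[!keep], collapse = ", "), call. = FALSE)
  pws <- pws[keep]
  scores <- matrix(NA_real_, length(pws), ncol(expr),
                   dimnames = list(pws, colnames(expr)))
  if (method == "ulm") {
    z <- scale(expr)  # z-score each sample (column) across genes
    for (p in pws) {
      w <- stats::setNames(rep(0, n_g), genes)
      sub <- weights[weights$pathway == p & weights$gene %in% genes, ]
      w[sub$gene] <- sub$weight
      r <- drop(stats::cor(z, w))
      r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
      scores[p, ] <- r * sqrt(n_g - 2) / sqrt(1 - r^2)
    }
  } else {
    set.seed(seed)
    for (p in pws) {
      sub <- weights[weights$pathway == p & weights$gene %in% genes, ]
      w <- sub$weight
      k <- length(w)
      obs <- drop(w %*% expr[sub$gene, , drop = FALSE])
      null <- matrix(NA_real_, n_perm, ncol(expr))
      for (i in seq_len(n_perm)) {
        idx <- sample.int(n_g, k)
        null[i, ] <- drop(w %*% expr[idx, , drop = FALSE])
      }
      mu <- colMeans(null)
      sdv <- apply(null, 2, stats::sd)
      sdv[sdv == 0] <- 1
      scores[p, ] <- (obs - mu) / sdv
    }
  }
  attr(scores, "method") <- method
  scores
}

#' Linear-model association of pathway activity with study factors
#'
#' Per pathway, an ordinary least-squares fit of the activity score on the
#' study factors (treatment coding, healthy / alphabetically first level as
#' reference): score ~ mutation + gender + reprogramming + place. Each
#' non-intercept coefficient gets a two-sided p; BH FDR is computed across
#' the pathway x coefficient grid. Degenerate (single-level) factors and
#' aliased factor pairs are errors.
#'
#' @param activity pathway x sample score matrix.
#' @param metadata sample metadata aligned with activity columns.
#' @param factors metadata factor names entering the model.
#' @return data.frame(pathway, term, estimate, se, t, pvalue, padj).
#' @export
paa_glm <- function(activity, metadata,
                    factors = c("mutation", "gender", "reprogramming",
                                "place")) {
  md <- metadata
  for (f in factors) {
    v <- factor(as.character(md[[f]]))
    if (nlevels(droplevels(v)) < 2)
      stop("factor '", f, "' has a single level", call. = FALSE)
    if (f %in% c("mutation", "condition") && "healthy" %in% levels(v))
      v <- stats::relevel(v, ref = "healthy")
    md[[f]] <- v
  }
  mm <- stats::model.matrix(stats::reformulate(factors), md)
  q <- qr(mm)
  if (q$rank < ncol(mm)) {
    aliased <- colnames(mm)[q$pivot[-seq_len(q$rank)]]
    stop("confounded factors: aliased column(s) ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(rownames(activity), function(p) {
    fit <- stats::lm.fit(mm, activity[p, ])
    rdf <- length(fit$residuals) - fit$rank
    s2 <- sum(fit$residuals^2) / rdf
    cov <- chol2inv(chol(crossprod(mm))) * s2
    se <- sqrt(diag(cov))
    tt <- fit$coefficients / se
    pv <- 2 * stats::pt(-abs(tt), rdf)
    keep <- colnames(mm) != "(Intercept)"
    data.frame(pathway = p, term = colnames(mm)[keep],
               estimate = unname(fit$coefficients[keep]),
               se = unname(se[keep]), t = unname(tt[keep]),
               pvalue = unname(pv[keep]), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$pvalue, "BH")
  out
}

#' Correlate co-expression eigengenes with pathway activity
#'
#' Computes the first principal component of the module-eigengene matrix and
#' the Spearman correlation of that component (and of each eigengene) with
#' every pathway's activity profile over the shared samples, with BH FDR.
#'
#' @param eigengenes eigengene matrix (samples x modules).
#' @param activity pathway x sample score matrix.
#' @return list(table, pc1_var): correlation table (component, pathway, rho,
#'   pvalue, padj) and the variance fraction explained by PC1 of the
#'   eigengene matrix.
#' @export
modules_vs_paa <- function(eigengenes, activity) {
  shared <- intersect(rownames(eigengenes), colnames(activity))
  if (length(shared) < 3) stop("fewer than 3 shared samples", call. = FALSE)
  eg <- eigengenes[shared, , drop = FALSE]
  act <- activity[, shared, drop = FALSE]
  cen <- sweep(eg, 2, colMeans(eg))
  sv <- svd(cen)
  pc1 <- sv$u[, 1] * sv$d[1]
  pc1_var <- sv$d[1]^2 / sum(sv$d^2)
  comps <- cbind(PC1 = pc1, eg)
  rows <- list()
  for (cc in colnames(comps)) {
    for (p in rownames(act)) {
      ct <- suppressWarnings(stats::cor.test(comps[, cc], act[p, ],
                                             method = "spearman"))
      rows[[length(rows) + 1]] <- data.frame(
        component = cc, pathway = p, rho = unname(ct$estimate),
        pvalue = ct$p.value)
    }
  }
  tab <- do.call(rbind, rows)
  tab$padj <- stats::p.adjust(tab$pvalue, "BH")
  list(table = tab, pc1_var = pc1_var)
}
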