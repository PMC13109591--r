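#' Build a treatment-coded design matrix for differential expression
#'
#' Factors enter in the given order (batch factors first, the biological
#' factor last, mirroring the design place + replicate + condition). The
#' reference level is "healthy" for condition/mutation and the alphabetically
#' first level otherwise. Errors if the resulting matrix is rank deficient.
#'
#' @param metadata sample metadata.
#' @param factors ordered character vector of metadata columns.
#' @return model matrix with one row per sample.
#' @export
de_model_matrix <- function(metadata, factors) {
  md <- metadata
  for (f in factors) {
    v <- factor(as.character(md[[f]]))
    if (f %in% c("condition", "mutation") && "healthy" %in% levels(v))
      v <- stats::relevel(v, ref = "healthy")
    md[[f]] <- v
  }
  mm <- stats::model.matrix(stats::reformulate(factors), md)
  if (qr(mm)$rank < ncol(mm))
    stop("design matrix is rank deficient for factors: ",
         paste(factors, collapse = " + "), call. = FALSE)
  attr(mm, "factor_levels") <- lapply(stats::setNames(factors, factors),
                                      function(f) levels(md[[f]]))
  mm
}

#' Per-gene dispersion estimation with trend shrinkage
#'
#' A method-of-moments estimate from the residual variance of an ordinary
#' least-squares fit of the size-factor-normalized counts on the design
#' (var = mu + phi mu^2 on the count scale, with the Poisson part scaled by
#' the mean reciprocal size factor on the normalized scale), floored at
#' 1e-8, then shrunk 50/50 on the log scale toward a fitted mean-dispersion
#' trend phi(mu) = a0 + a1 / mu estimated across genes by least squares.
#' All-zero genes get NA (flagged, excluded from testing).
#'
#' @param counts count matrix.
#' @param sf size factors.
#' @param design model matrix from [de_model_matrix()].
#' @return named numeric vector of per-gene dispersions (NA for all-zero
#'   genes); attribute "raw" holds the unshrunk estimates.
#' @export
estimate_dispersions <- function(counts, sf, design) {
  z <- sweep(unclass(counts), 2, sf, `/`)
  n <- ncol(z)
  q <- qr(design)
  if (n - q$rank < 2) stop("need >=2 residual degrees of freedom", call. = FALSE)
  H <- tcrossprod(qr.Q(q)[, seq_len(q$rank), drop = FALSE])
  fitted <- z %*% H
  v <- rowSums((z - fitted)^2) / (n - q$rank)
  mu <- rowMeans(z)
  shot <- mu * mean(1 / sf)
  phi_raw <- pmax((v - shot) / mu^2, 1e-8)
  phi_raw[mu == 0] <- NA
  ok <- is.finite(phi_raw)
  fit <- stats::lm.fit(cbind(1, 1 / mu[ok]), phi_raw[ok])
  trend <- pmax(fit$coefficients[1] + fit$coefficients[2] / mu, 1e-8)
  phi <- exp((log(phi_raw) + log(trend)) / 2)
  phi[!ok] <- NA
  names(phi) <- rownames(counts)
  attr(phi, "raw") <- stats::setNames(phi_raw, rownames(counts))
  phi
}

#' Fit per-gene negative-binomial GLMs (log link, size-factor offset)
#'
#' Iteratively reweighted least squares per gene with fixed dispersion:
#' weights mu / (1 + phi mu), working response eta + (y - mu) / mu, offset
#' log s_j. Non-converging genes are flagged. Returns natural-log
#' coefficients and the inverse Fisher information per gene.
#'
#' @param counts count matrix.
#' @param sf size factors.
#' @param design model matrix.
#' @param dispersions per-gene dispersion vector ([estimate_dispersions()]).
#' @param max_iter,tol IRLS iteration cap and coefficient tolerance.
#' @return list of class `nb_fit`: beta (genes x p), cov (p x p x genes),
#'   converged, base_mean, dispersions, design.
#' @export
nb_fit <- function(counts, sf, design, dispersions,
                   max_iter = 50, tol = 1e-8) {
  y_all <- unclass(counts)
  X <- design
  p <- ncol(X)
  o <- log(sf)
  n_g <- nrow(y_all)
  beta <- matrix(NA_real_, n_g, p, dimnames = list(rownames(y_all), colnames(X)))
  covs <- array(NA_real_, c(p, p, n_g))
  converged <- rep(FALSE, n_g)
  base_mean <- rowMeans(sweep(y_all, 2, sf, `/`))
  for (g in seq_len(n_g)) {
    phi <- dispersions[g]
    if (!is.finite(phi)) next
    y <- y_all[g, ]
    b <- tryCatch(qr.solve(X, log((y + 0.5) / sf)), error = function(e) NULL)
    if (is.null(b)) next
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      eta <- drop(X %*% b) + o
      mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
      w <- mu / (1 + phi * mu)
      zz <- eta - o + (y - mu) / mu
      xtwx <- crossprod(X, w * X)
      b_new <- tryCatch(solve(xtwx, crossprod(X, w * zz)),
                        error = function(e) NULL)
      if (is.null(b_new) || any(!is.finite(b_new))) break
      delta <- max(abs(b_new - b))
      b <- drop(b_new)
      if (delta < tol) { ok <- TRUE; break }
    }
    if (!ok) next
    eta <- drop(X %*% b) + o
    mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
    w <- mu / (1 + phi * mu)
    info <- crossprod(X, w * X)
    cv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(cv)) next
    beta[g, ] <- b
    covs[, , g] <- cv
    converged[g] <- TRUE
  }
  structure(list(beta = beta, cov = covs, converged = converged,
                 base_mean = base_mean, dispersions = dispersions,
                 design = X),
            class = "nb_fit")
}

#' Wald test of a linear contrast on a fitted NB model
#'
#' LFC is the natural-log contrast estimate divided by ln 2; the standard
#' error comes from the inverse Fisher information; the two-sided p uses the
#' normal reference; BH FDR is computed over tested (converged) genes.
#'
#' @param fit an [nb_fit()] object.
#' @param contrast numeric contrast vector over design columns, or a
#'   character triple c(factor, levelA, levelB) resolved against the design
#'   column names (treatment coding, reference absorbed in the intercept).
#' @return data.frame(gene, baseMean, lfc, se, stat, pvalue, padj,
#'   dispersion, converged).
#' @export
wald_test <- function(fit, contrast) {
  X <- fit$design
  if (is.character(contrast)) {
    cn <- colnames(X)
    lv <- attr(X, "factor_levels")
    if (!is.null(lv) && !is.null(lv[[contrast[1]]]) &&
        !all(contrast[2:3] %in% lv[[contrast[1]]]))
      stop("contrast level(s) not observed for factor ", contrast[1],
           call. = FALSE)
    cv <- stats::setNames(rep(0, ncol(X)), cn)
    for (i in 2:3) {
      col <- paste0(contrast[1], contrast[i])
      sgn <- if (i == 2) 1 else -1
      if (col %in% cn) cv[col] <- cv[col] + sgn  # reference level is 0
    }
    contrast <- cv
  }
  stopifnot(length(contrast) == ncol(X))
  est <- drop(fit$beta %*% contrast)
  se_ln <- sqrt(vapply(seq_len(dim(fit$cov)[3]), function(g) {
    drop(t(contrast) %*% fit$cov[, , g] %*% contrast)
  }, numeric(1)))
  stat <- est / se_ln
  pvalue <- 2 * stats::pnorm(-abs(stat))
  pvalue[!fit$converged] <- NA
  out <- data.frame(gene = rownames(fit$beta),
                    baseMean = fit$base_mean,
                    lfc = est / log(2), se = se_ln / log(2),
                    stat = stat, pvalue = pvalue,
                    padj = NA_real_,
                    dispersion = as.numeric(fit$dispersions),
                    converged = fit$converged, row.names = NULL)
  out$padj[!is.na(out$pvalue)] <- stats::p.adjust(out$pvalue[!is.na(out$pvalue)],
                                                  "BH")
  out
}

#' One-call differential expression for one or more contrasts
#'
#' Removes genes with zero counts in all samples, estimates size factors and
#' dispersions, fits the NB GLM once, and evaluates the requested contrasts.
#'
#' @param counts count matrix.
#' @param metadata sample metadata.
#' @param factors design factor order (batch factors first).
#' @param contrasts a single character triple c(factor, A, B) or a named
#'   list of such triples.
#' @param sf optional precomputed size factors.
#' @return a DE table, or a named list of tables when `contrasts` is a list.
#' @export
run_de <- function(counts, metadata,
                   factors = c("place", "replicate", "condition"),
                   contrasts = c("condition", "PD", "healthy"),
                   sf = NULL) {
  keep <- rowSums(unclass(counts)) > 0
  counts <- count_matrix(unclass(counts)[keep, , drop = FALSE])
  if (is.null(sf)) sf <- size_factors(counts)
  mm <- de_model_matrix(metadata, factors)
  phi <- estimate_dispersions(counts, sf, mm)
  fit <- nb_fit(counts, sf, mm, phi)
  if (is.list(contrasts)) {
    lapply(contrasts, function(ct) wald_test(fit, ct))
  } else {
    wald_test(fit, contrasts)
  }
}

#' Threshold a DE table into up/down DEG lists
#'
#' Strict inequalities on both criteria: up = FDR < `fdr` and LFC > `lfc`;
#' down = FDR < `fdr` and LFC < -`lfc`. Genes with NA statistics never pass.
#'
#' @param results DE table from [wald_test()].
#' @param fdr FDR threshold.
#' @param lfc absolute log2-fold-change threshold.
#' @return list(up, down) of gene id vectors.
#' @export
threshold_degs <- function(results, fdr = 0.05, lfc = 1) {
  ok <- !is.na(results$padj) & !is.na(results$lfc)
  list(up = results$gene[ok & results$padj < fdr & results$lfc > lfc],
       down = results$gene[ok & results$padj < fdr & results$lfc < -lfc])
}
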