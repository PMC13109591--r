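#' Principal component analysis of an expression matrix
#'
#' Genes are centered (per-gene mean subtracted) and the sample-space scores
#' and gene loadings are taken from the singular value decomposition. Sign
#' convention: within each component the loading of largest magnitude is
#' made positive, so results are deterministic across SVD implementations.
#'
#' @param expr expression matrix (genes x samples).
#' @param n_components number of components to keep (default: all).
#' @return list(scores, loadings, var_explained): scores are samples x
#'   components, `var_explained` the fractions for all components
#'   (non-increasing, summing to 1 for non-degenerate input).
#' @export
pca_expr <- function(expr, n_components = NULL) {
  n_max <- min(dim(expr))
  if (is.null(n_components)) n_components <- n_max
  if (n_components > n_max)
    stop("n_components exceeds min(genes, samples)", call. = FALSE)
  if (ncol(expr) < 2) stop("need >=2 samples", call. = FALSE)
  x <- t(expr - rowMeans(expr))  # samples x genes, column-centered
  sv <- svd(x)
  tot <- sum(sv$d^2)
  if (tot == 0) {
    warning("degenerate input: no variance across samples", call. = FALSE)
    frac <- rep(0, length(sv$d))
  } else frac <- sv$d^2 / tot
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  loadings <- sv$v
  for (k in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, k]))
    if (loadings[i, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  keep <- seq_len(n_components)
  dimnames(scores) <- list(colnames(expr), paste0("PC", seq_len(ncol(scores))))
  dimnames(loadings) <- list(rownames(expr), paste0("PC", seq_len(ncol(loadings))))
  list(scores = scores[, keep, drop = FALSE],
       loadings = loadings[, keep, drop = FALSE],
       var_explained = frac)
}

#' PERMANOVA variance partitioning
#'
#' Permutational multivariate ANOVA on Euclidean distances between sample
#' expression vectors, with sequential (Type-I) sums of squares in the given
#' factor order (McArdle-Anderson Gower-matrix formulation). The permutation
#' p-value uses the +1 convention, p = (1 + #{F* >= F}) / (1 + n_perm), with
#' free permutation of sample rows; per-factor p-values are BH-adjusted.
#'
#' @param expr expression matrix (genes x samples).
#' @param metadata sample metadata aligned with columns of `expr`.
#' @param factors ordered character vector of metadata factor names.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutations.
#' @param perm_matrix optional integer matrix (one permutation per row) used
#'   instead of random draws, e.g. the exhaustive set for small n.
#' @return data.frame with one row per factor plus Residual and Total rows:
#'   df, SS, R2, F, p, p_adj; attributes record n_perm and seed.
#' @export
permanova <- function(expr, metadata, factors, n_perm = 999, seed = 1L,
                      perm_matrix = NULL) {
  n <- ncol(expr)
  md <- metadata
  for (f in factors) {
    md[[f]] <- factor(md[[f]])
    if (nlevels(droplevels(md[[f]])) < 2)
      stop("factor '", f, "' has a single level among samples", call. = FALSE)
  }
  d2 <- as.matrix(stats::dist(t(expr)))^2
  cm <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * cm %*% d2 %*% cm
  hats <- vector("list", length(factors))
  rank_prev <- 1L  # intercept
  H_prev <- matrix(1 / n, n, n)
  df <- numeric(length(factors))
  for (k in seq_along(factors)) {
    mm <- stats::model.matrix(stats::reformulate(factors[seq_len(k)]), md)
    qr_mm <- qr(mm)
    Q <- qr.Q(qr_mm)[, seq_len(qr_mm$rank), drop = FALSE]
    H <- tcrossprod(Q)
    df[k] <- qr_mm$rank - rank_prev
    hats[[k]] <- H - H_prev
    H_prev <- H
    rank_prev <- qr_mm$rank
  }
  ss_total <- sum(diag(G))
  ss <- vapply(hats, function(dh) sum(dh * G), numeric(1))
  df_res <- n - rank_prev
  ss_res <- ss_total - sum(ss)
  f_obs <- (ss / df) / (ss_res / df_res)

  stat_for <- function(Gp) {
    ssp <- vapply(hats, function(dh) sum(dh * Gp), numeric(1))
    (ssp / df) / ((sum(diag(Gp)) - sum(ssp)) / df_res)
  }
  if (is.null(perm_matrix)) {
    set.seed(seed)
    perm_matrix <- t(replicate(n_perm, sample.int(n)))
  }
  n_perm <- nrow(perm_matrix)
  exceed <- numeric(length(factors))
  for (i in seq_len(n_perm)) {
    p <- perm_matrix[i, ]
    fp <- stat_for(G[p, p])
    exceed <- exceed + (fp >= f_obs - 1e-12)
  }
  pval <- (1 + exceed) / (1 + n_perm)
  out <- data.frame(
    term = c(factors, "Residual", "Total"),
    df = c(df, df_res, n - 1),
    SS = c(ss, ss_res, ss_total),
    R2 = c(ss, ss_res, ss_total) / ss_total,
    F = c(f_obs, NA, NA),
    p = c(pval, NA, NA),
    p_adj = c(stats::p.adjust(pval, "BH"), NA, NA)
  )
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  out
}

#' Per-gene two-way ANOVA batch screen
#'
#' Fixed-effects two-factor ANOVA (sequential SS) on log2(count + 1) of the
#' raw counts, gene by gene, testing the batch factor (place) and the
#' biological factor (condition), with BH correction per factor across
#' genes. Used as the initial screen for laboratory-of-origin effects.
#'
#' @param counts count matrix.
#' @param metadata sample metadata.
#' @param factor1 batch factor (tested first).
#' @param factor2 second factor.
#' @return data.frame(gene, p_factor1, p_factor2, padj_factor1, padj_factor2).
#' @export
anova_batch_screen <- function(counts, metadata, factor1 = "place",
                               factor2 = "condition") {
  y <- log2(unclass(counts) + 1)
  n <- ncol(y)
  md <- metadata
  md[[factor1]] <- factor(md[[factor1]])
  md[[factor2]] <- factor(md[[factor2]])
  hat_of <- function(formula) {
    mm <- stats::model.matrix(formula, md)
    q <- qr(mm)
    tcrossprod(qr.Q(q)[, seq_len(q$rank), drop = FALSE])
  }
  H0 <- matrix(1 / n, n, n)
  H1 <- hat_of(stats::reformulate(factor1))
  H12 <- hat_of(stats::reformulate(c(factor1, factor2)))
  df1 <- nlevels(md[[factor1]]) - 1
  df2 <- sum(diag(H12)) - sum(diag(H1))
  df_res <- n - sum(diag(H12))
  ss <- function(H) rowSums((y %*% H) * y)
  ss1 <- ss(H1) - ss(H0)
  ss2 <- ss(H12) - ss(H1)
  ss_res <- ss(diag(n)) - ss(H12)
  f1 <- (ss1 / df1) / (ss_res / df_res)
  f2 <- (ss2 / df2) / (ss_res / df_res)
  p1 <- stats::pf(f1, df1, df_res, lower.tail = FALSE)
  p2 <- stats::pf(f2, df2, df_res, lower.tail = FALSE)
  data.frame(gene = rownames(y), p_factor1 = p1, p_factor2 = p2,
             padj_factor1 = stats::p.adjust(p1, "BH"),
             padj_factor2 = stats::p.adjust(p2, "BH"),
             row.names = NULL)
}

#' Marker-panel tests: mixed model per mutation, Wilcoxon per place
#'
#' For each marker gene, fits expression ~ mutation + (1 | place) by REML on
#' log2 normalized expression, testing each mutation level against healthy
#' with a normal approximation on the Wald statistic, and separately runs a
#' two-sided Wilcoxon rank-sum test comparing the two places on the pooled
#' normalized expression. Markers absent from the matrix are reported and
#' skipped.
#'
#' @param counts count matrix.
#' @param sf size factors.
#' @param metadata sample metadata with `mutation` and `place`.
#' @param markers character vector of marker gene ids.
#' @return data.frame with one row per marker x contrast: estimate, se, z,
#'   p, random-intercept and residual variances, Wilcoxon W and p.
#' @export
marker_panel <- function(counts, sf, metadata, markers) {
  md <- metadata
  mut <- factor(as.character(md$mutation))
  if ("healthy" %in% levels(mut)) mut <- stats::relevel(mut, ref = "healthy")
  md$mutation <- mut
  if (nlevels(md$mutation) < 2) stop("fewer than 2 mutation groups", call. = FALSE)
  missing <- setdiff(markers, rownames(counts))
  if (length(missing))
    warning("marker(s) not in matrix, skipped: ",
            paste(missing, collapse = ", "), call. = FALSE)
  markers <- setdiff(markers, missing)
  norm <- log2(sweep(unclass(counts), 2, sf, `/`) + 1)
  place <- factor(md$place)
  res <- lapply(markers, function(g) {
    y <- norm[g, ]
    terms_all <- paste0("mutation", levels(md$mutation)[-1])
    if (length(unique(y)) == 1) {
      # degenerate: no variation, nothing to test
      return(data.frame(marker = g, contrast = sub("^mutation", "", terms_all),
                        estimate = 0, se = NA_real_, z = NA_real_, p = 1,
                        place_var = 0, resid_var = 0,
                        wilcox_stat = sum(place == levels(place)[1]) *
                          sum(place == levels(place)[2]) / 2,
                        wilcox_p = 1, row.names = NULL))
    }
    dat <- data.frame(y = y, mutation = md$mutation, place = place)
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(y ~ mutation + (1 | place), data = dat, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    re_var <- vc$vcov[vc$grp == "place"]
    resid_var <- vc$vcov[vc$grp == "Residual"]
    terms <- grep("^mutation", names(beta), value = TRUE)
    if (length(unique(y)) == 1) {
      w_stat <- sum(place == levels(place)[1]) *
        sum(place == levels(place)[2]) / 2
      w_p <- 1
    } else {
      wt <- suppressWarnings(stats::wilcox.test(y ~ place, exact = FALSE))
      w_stat <- unname(wt$statistic)
      w_p <- wt$p.value
      if (!is.finite(w_p)) w_p <- 1
    }
    z <- beta[terms] / se[terms]
    data.frame(marker = g,
               contrast = sub("^mutation", "", terms),
               estimate = unname(beta[terms]), se = unname(se[terms]),
               z = unname(z), p = unname(2 * stats::pnorm(-abs(z))),
               place_var = re_var, resid_var = resid_var,
               wilcox_stat = w_stat, wilcox_p = w_p, row.names = NULL)
  })
  do.call(rbind, res)
}
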