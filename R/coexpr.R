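#' Signed-hybrid weighted co-expression network
#'
#' Genes are filtered to the `top_n` most variable by median absolute
#' deviation (constant genes dropped with a warning); the signed-hybrid
#' adjacency is a_ij = cor_ij^beta for positive correlations and 0
#' otherwise. When `beta` is NULL the soft power is chosen as the smallest
#' integer in 1..20 whose scale-free topology fit (R^2 of the log-log
#' degree regression over 10 connectivity bins) reaches 0.8, falling back to
#' 6. The topological overlap matrix is
#' TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with L = A^2 and
#' TOM_ii = 1.
#'
#' Input must carry a "batch_corrected" provenance tag (batch effects are
#' corrected upstream before network construction) unless
#' `allow_uncorrected = TRUE`.
#'
#' @param expr expression matrix (genes x samples).
#' @param method correlation method, "pearson" or "spearman".
#' @param beta soft power, or NULL for automatic selection.
#' @param top_n variance-filter size.
#' @param allow_uncorrected bypass the provenance check.
#' @return list of class `coexpr_network`: genes, method, beta, adjacency,
#'   tom, scale_free_r2.
#' @export
build_coexpr_network <- function(expr, method = c("pearson", "spearman"),
                                 beta = NULL, top_n = 5000,
                                 allow_uncorrected = FALSE) {
  method <- match.arg(method)
  if (!identical(attr(expr, "provenance"), "batch_corrected") &&
      !allow_uncorrected)
    stop("expression must be batch corrected (provenance tag); ",
         "set allow_uncorrected = TRUE to override", call. = FALSE)
  if (ncol(expr) < 8) stop("need >= 8 samples", call. = FALSE)
  const <- apply(expr, 1, stats::sd) == 0
  if (any(const)) {
    warning("dropping ", sum(const), " constant gene(s)", call. = FALSE)
    expr <- expr[!const, , drop = FALSE]
  }
  mads <- apply(expr, 1, stats::mad)
  if (nrow(expr) > top_n)
    expr <- expr[order(-mads)[seq_len(top_n)], , drop = FALSE]
  cors <- stats::cor(t(expr), method = method)
  sf_r2 <- NA_real_
  if (is.null(beta)) {
    for (b in 1:20) {
      a <- ifelse(cors > 0, cors^b, 0)
      diag(a) <- 0
      r2 <- scale_free_fit(rowSums(a))
      if (is.finite(r2) && r2 >= 0.8) { beta <- b; sf_r2 <- r2; break }
    }
    if (is.null(beta)) beta <- 6
  }
  adj <- ifelse(cors > 0, cors^beta, 0)
  diag(adj) <- 0
  tom <- tom_matrix(adj)
  structure(list(genes = rownames(expr), method = method, beta = beta,
                 adjacency = adj, tom = tom, scale_free_r2 = sf_r2),
            class = "coexpr_network")
}

# R^2 of the scale-free topology regression: log10 p(k) on log10 k over 10
# equal-width connectivity bins.
scale_free_fit <- function(k) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(NA_real_)
  bins <- cut(k, 10)
  df <- data.frame(k_mean = tapply(k, bins, mean),
                   p = as.numeric(table(bins)) / length(k))
  df <- df[df$p > 0 & is.finite(df$k_mean), ]
  if (nrow(df) < 3) return(NA_real_)
  summary(stats::lm(log10(df$p) ~ log10(df$k_mean)))$r.squared
}

# Topological overlap from an adjacency with zero diagonal.
tom_matrix <- function(adj) {
  k <- rowSums(adj)
  l <- adj %*% adj
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- (l + adj) / denom
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules by TOM clustering
#'
#' Average-linkage hierarchical clustering on 1 - TOM; the tree is cut by
#' scanning cut heights from 0.99 downward (step 0.01) until at least two
#' clusters of size >= `min_size` emerge; the first such height is used.
#' Genes in clusters below `min_size` are labeled "grey". If no height
#' qualifies (as for unstructured data, whose average-linkage splits are too
#' unbalanced to yield two clusters of size >= `min_size`), every gene is
#' labeled grey and a warning is issued.
#'
#' @param network a `coexpr_network`.
#' @param min_size minimum module size.
#' @return `module_partition` with modules named module_01, ... plus "grey".
#' @export
detect_modules <- function(network, min_size = 30) {
  tom <- network$tom
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  chosen <- NULL
  for (h in seq(0.99, 0.01, by = -0.01)) {
    cl <- stats::cutree(hc, h = h)
    sizes <- table(cl)
    if (sum(sizes >= min_size) >= 2) { chosen <- cl; break }
  }
  if (is.null(chosen)) {
    warning("no cut height yields two modules of size >= min_size; ",
            "labeling all genes grey", call. = FALSE)
    membership <- stats::setNames(rep(0L, length(network$genes)),
                                  network$genes)
    return(structure(list(modules = list(grey = network$genes),
                          membership = membership, converged = TRUE,
                          params = list(min_size = min_size)),
                     class = "module_partition"))
  }
  sizes <- table(chosen)
  big <- as.integer(names(sizes)[sizes >= min_size])
  # stable module ids ordered by decreasing size then first gene
  big <- big[order(-sizes[as.character(big)], names(chosen)[match(big, chosen)])]
  membership <- stats::setNames(rep(0L, length(chosen)), names(chosen))
  modules <- list()
  for (i in seq_along(big)) {
    g <- names(chosen)[chosen == big[i]]
    modules[[sprintf("module_%02d", i)]] <- g
    membership[g] <- i
  }
  grey <- names(chosen)[membership == 0]
  if (length(grey)) modules$grey <- grey
  structure(list(modules = modules, membership = membership,
                 converged = TRUE, params = list(min_size = min_size)),
            class = "module_partition")
}

#' Module eigengenes
#'
#' Per module, the first principal component of the per-gene standardized
#' (z-scored) member expression, unit-norm across samples, with the sign
#' fixed so the eigengene correlates positively with the module's mean
#' standardized expression. One-gene modules return that gene's z-score
#' (normalized). The "grey" pseudo-module is skipped.
#'
#' @param expr expression matrix covering the module genes.
#' @param partition a `module_partition`.
#' @return list(eigengenes, var_explained): eigengene matrix
#'   (samples x modules) and per-module explained-variance fraction.
#' @export
module_eigengenes <- function(expr, partition) {
  mods <- partition$modules[names(partition$modules) != "grey"]
  if (!length(mods)) stop("no module to summarize", call. = FALSE)
  eg <- matrix(NA_real_, ncol(expr), length(mods),
               dimnames = list(colnames(expr), names(mods)))
  ve <- stats::setNames(numeric(length(mods)), names(mods))
  for (m in names(mods)) {
    x <- expr[mods[[m]], , drop = FALSE]
    sds <- apply(x, 1, stats::sd)
    sds[sds == 0] <- 1
    z <- (x - rowMeans(x)) / sds
    sv <- svd(t(z))  # samples x genes
    e <- sv$u[, 1]
    # sign: align with mean member expression; for balanced anti-correlated
    # modules that mean is flat, fall back to the largest-|loading| gene
    anchor <- colMeans(z)
    if (stats::sd(anchor) == 0) anchor <- z[which.max(abs(sv$v[, 1])), ]
    s <- suppressWarnings(stats::cor(e, anchor))
    if (is.finite(s) && s < 0) e <- -e
    eg[, m] <- e
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = eg, var_explained = ve)
}

#' Module-trait association
#'
#' Traits are one-hot indicators of the levels of the requested metadata
#' factors. Per module x trait, Pearson and Spearman correlations with
#' two-sided p-values, BH-adjusted over the module x trait grid within each
#' method; additionally a per-module linear model eigengene ~ group with the
#' overall-group F-test p, BH-adjusted across modules.
#'
#' @param eigengenes eigengene matrix (samples x modules).
#' @param metadata sample metadata aligned with eigengene rows.
#' @param traits metadata factor names to one-hot code.
#' @param group factor for the per-module GLM (default "mutation").
#' @return list(correlations, glm): long data.frame of correlations and a
#'   per-module GLM table.
#' @export
module_trait <- function(eigengenes, metadata, traits = c("condition",
                                                          "mutation"),
                         group = "mutation") {
  onehot <- do.call(cbind, lapply(traits, function(f) {
    v <- factor(metadata[[f]])
    m <- sapply(levels(v), function(l) as.numeric(v == l))
    colnames(m) <- paste(f, levels(v), sep = ".")
    m
  }))
  rows <- list()
  for (m in colnames(eigengenes)) {
    e <- eigengenes[, m]
    for (tr in colnames(onehot)) {
      for (meth in c("pearson", "spearman")) {
        if (stats::sd(e) == 0) {
          rows[[length(rows) + 1]] <- data.frame(
            module = m, trait = tr, method = meth, cor = NA_real_,
            pvalue = NA_real_)
          next
        }
        ct <- suppressWarnings(stats::cor.test(e, onehot[, tr], method = meth))
        rows[[length(rows) + 1]] <- data.frame(
          module = m, trait = tr, method = meth,
          cor = unname(ct$estimate), pvalue = ct$p.value)
      }
    }
  }
  cors <- do.call(rbind, rows)
  cors$padj <- NA_real_
  for (meth in unique(cors$method)) {
    i <- cors$method == meth
    cors$padj[i] <- stats::p.adjust(cors$pvalue[i], "BH")
  }
  grp <- factor(metadata[[group]])
  glm_tab <- do.call(rbind, lapply(colnames(eigengenes), function(m) {
    fit <- stats::lm(eigengenes[, m] ~ grp)
    an <- suppressWarnings(stats::anova(fit))  # perfect fits are legitimate
    data.frame(module = m, F = an$`F value`[1], pvalue = an$`Pr(>F)`[1])
  }))
  glm_tab$padj <- stats::p.adjust(glm_tab$pvalue, "BH")
  list(correlations = cors, glm = glm_tab)
}

#' Inter-module eigengene correlations
#'
#' Pairwise correlations between module eigengenes with two-sided p-values
#' and BH FDR.
#'
#' @param eigengenes eigengene matrix (samples x modules).
#' @param method correlation method.
#' @return data.frame(module1, module2, cor, pvalue, padj).
#' @export
module_cor <- function(eigengenes, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  mods <- colnames(eigengenes)
  if (length(mods) < 2) stop("need >= 2 modules", call. = FALSE)
  pairs <- utils::combn(mods, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    ct <- suppressWarnings(stats::cor.test(eigengenes[, pairs[1, i]],
                                           eigengenes[, pairs[2, i]],
                                           method = method))
    data.frame(module1 = pairs[1, i], module2 = pairs[2, i],
               cor = unname(ct$estimate), pvalue = ct$p.value)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$pvalue, "BH")
  out
}
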