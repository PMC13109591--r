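test_that("PCA satisfies the SVD identities and sign convention", {
  set.seed(1)
  expr <- matrix(rnorm(30 * 8), 30, 8,
                 dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:8)))
  p <- pca_expr(expr)
  recon <- p$scores %*% t(p$loadings)
  centered <- t(expr - rowMeans(expr))
  expect_equal(unname(recon), unname(centered), tolerance = 1e-8)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_equal(sum(p$var_explained), 1, tolerance = 1e-12)
  for (k in 1:3)
    expect_gt(p$loadings[which.max(abs(p$loadings[, k])), k], 0)
  # data on a line: PC1 carries everything
  line <- outer(rnorm(10), seq_len(6)) +
    matrix(rnorm(10), 10, 6)  # rank-1 after centering? make exact:
  line <- outer(rnorm(10), seq_len(6))
  dimnames(line) <- list(paste0("g", 1:10), paste0("s", 1:6))
  pl <- pca_expr(line)
  expect_equal(pl$var_explained[1], 1, tolerance = 1e-12)
  expect_error(pca_expr(expr, n_components = 100), "exceeds")
  dup <- matrix(1, 5, 2, dimnames = list(paste0("g", 1:5), c("a", "b")))
  expect_warning(pca_expr(dup), "degenerate")
})

test_that("PERMANOVA matches the per-variable ANOVA decomposition and vegan", {
  set.seed(3)
  md <- data.frame(f1 = factor(rep(c("x", "y"), each = 6)),
                   f2 = factor(rep(c("u", "v", "w"), 4)))
  expr <- matrix(rnorm(15 * 12), 15, 12,
                 dimnames = list(paste0("g", 1:15), paste0("s", 1:12)))
  expr[1:5, md$f1 == "y"] <- expr[1:5, md$f1 == "y"] + 1
  res <- permanova(expr, md, c("f1", "f2"), n_perm = 99, seed = 1)
  ss <- bf_permanova_ss(expr, md, c("f1", "f2"))
  expect_equal(res$SS[1:3], unname(ss), tolerance = 1e-10)
  vg <- vegan::adonis2(t(expr) ~ f1 + f2, data = md, method = "euclidean",
                       permutations = 99, by = "terms")
  expect_equal(res$SS[1:2], vg$SumOfSqs[1:2], tolerance = 1e-10)
  expect_equal(res$R2[1:2], vg$R2[1:2], tolerance = 1e-10)
  expect_equal(res$F[1:2], vg$F[1:2], tolerance = 1e-10)
})

test_that("sequential decomposition sums to the total regardless of order", {
  set.seed(4)
  md <- data.frame(a = factor(rep(c("x", "y"), 5)),
                   b = factor(rep(c("u", "u", "v", "v", "v"), 2)))
  expr <- matrix(rnorm(8 * 10), 8, 10,
                 dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
  r1 <- permanova(expr, md, c("a", "b"), n_perm = 49, seed = 1)
  r2 <- permanova(expr, md, c("b", "a"), n_perm = 49, seed = 1)
  expect_equal(sum(r1$SS[1:2]), sum(r2$SS[1:2]), tolerance = 1e-10)
  expect_equal(r1$SS[4], r2$SS[4], tolerance = 1e-10)
  expect_equal(sum(r1$R2[1:3]), 1, tolerance = 1e-12)
})

test_that("PERMANOVA p is exact under exhaustive permutations at n = 6", {
  set.seed(5)
  md <- data.frame(g = factor(rep(c("a", "b"), each = 3)))
  expr <- matrix(rnorm(4 * 6), 4, 6,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  perms <- all_permutations(6)
  res <- permanova(expr, md, "g", perm_matrix = perms)
  # oracle: recompute pseudo-F for every permutation from scratch via
  # univariate ANOVA sums
  f_of <- function(ord) {
    e <- expr[, ord, drop = FALSE]
    ssf <- ssr <- 0
    for (i in seq_len(nrow(e))) {
      an <- anova(lm(e[i, ] ~ md$g))
      ssf <- ssf + an$`Sum Sq`[1]
      ssr <- ssr + an$`Sum Sq`[2]
    }
    (ssf / 1) / (ssr / 4)
  }
  f_obs <- f_of(1:6)
  f_perm <- apply(perms, 1, f_of)
  p_oracle <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + nrow(perms))
  expect_equal(res$F[1], f_obs, tolerance = 1e-10)
  expect_equal(res$p[1], p_oracle, tolerance = 1e-12)
})

test_that("PERMANOVA flags single-level factors and separates planted groups", {
  md <- data.frame(g = factor(rep("a", 6)))
  expr <- matrix(rnorm(12), 2, 6,
                 dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
  expect_error(permanova(expr, md, "g"), "single level")
  set.seed(6)
  md2 <- data.frame(g = factor(rep(c("a", "b"), each = 8)))
  sep <- matrix(rnorm(10 * 16, sd = 0.2), 10, 16,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:16)))
  sep[, md2$g == "b"] <- sep[, md2$g == "b"] + 5
  rs <- permanova(sep, md2, "g", n_perm = 199, seed = 2)
  expect_gt(rs$R2[1], 0.5)
  # permutations that only reorder within groups reproduce F exactly, so the
  # minimum attainable p can be hit with one such collision among 199 draws
  expect_lte(rs$p[1], 2 / 200)
})

test_that("two-way ANOVA screen matches per-gene aov", {
  set.seed(7)
  md <- validate_metadata(data.frame(
    sample_id = sprintf("s%02d", 1:16),
    condition = rep(c("healthy", "PD"), 8),
    mutation = rep(c("healthy", "LRRK2"), 8),
    place = rep(c("A", "B"), each = 8), replicate = 1, gender = "M",
    reprogramming = "sendai"))
  cm <- rand_counts(15, 16, seed = 7)
  colnames(cm) <- md$sample_id
  scr <- anova_batch_screen(cm, md, "place", "condition")
  for (g in c(1, 7, 15)) {
    y <- log2(unclass(cm)[g, ] + 1)
    an <- anova(lm(y ~ md$place + md$condition))
    expect_equal(scr$p_factor1[g], an$`Pr(>F)`[1], tolerance = 1e-10)
    expect_equal(scr$p_factor2[g], an$`Pr(>F)`[2], tolerance = 1e-10)
  }
  expect_equal(scr$padj_factor1, bf_bh(scr$p_factor1), tolerance = 1e-12)
})

test_that("marker panel reduces to OLS when between-place variance is zero", {
  set.seed(8)
  md <- study_metadata()
  cm <- rand_counts(5, 34, seed = 8)
  rownames(cm)[1] <- "MAP2"
  colnames(cm) <- md$sample_id
  # no place effect planted: REML variance should hit the boundary
  sf <- rep(1, 34); names(sf) <- md$sample_id
  res <- marker_panel(cm, sf, md, "MAP2")
  y <- log2(unclass(cm)["MAP2", ] + 1)
  ols <- summary(lm(y ~ relevel(factor(as.character(md$mutation)), "healthy")))
  expect_equal(res$estimate, unname(ols$coefficients[2:3, 1]),
               tolerance = 1e-4)
  expect_true(all(res$place_var < 1e-4))
})

test_that("marker panel detects a planted mutation shift and handles edge cases", {
  md <- study_metadata()
  sf <- rep(1, 34); names(sf) <- md$sample_id
  hits <- 0; n_rep <- 20
  for (seed in seq_len(n_rep)) {
    set.seed(100 + seed)
    base <- matrix(rnbinom(2 * 34, mu = 200, size = 10), 2, 34,
                   dimnames = list(c("TH", "FLAT"), md$sample_id))
    base["TH", md$mutation == "LRRK2"] <-
      rnbinom(sum(md$mutation == "LRRK2"), mu = 200 * 4, size = 10)
    res <- marker_panel(count_matrix(base), sf, md, c("TH", "FLAT"))
    p_l <- res$p[res$marker == "TH" & res$contrast == "LRRK2"]
    if (p_l < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
  # constant gene: all-tie Wilcoxon degenerates to p = 1
  const <- matrix(7, 2, 34, dimnames = list(c("A", "B"), md$sample_id))
  resc <- marker_panel(count_matrix(const), sf, md, "A")
  expect_equal(unique(resc$wilcox_p), 1)
  expect_warning(marker_panel(count_matrix(const), sf, md, c("A", "NOPE")),
                 "NOPE")
})
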