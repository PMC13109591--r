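make_two_group <- function(n_genes, n_per, mu = 100, phi = 0.1, lfc_genes = NULL,
                           lfc = 2, seed = 1) {
  set.seed(seed)
  md <- validate_metadata(data.frame(
    sample_id = sprintf("s%02d", seq_len(2 * n_per)),
    condition = rep(c("healthy", "PD"), each = n_per),
    mutation = rep(c("healthy", "LRRK2"), each = n_per),
    place = "A", replicate = 1, gender = "M", reprogramming = "sendai"))
  mus <- matrix(mu, n_genes, 2 * n_per)
  if (!is.null(lfc_genes))
    mus[lfc_genes, md$condition == "PD"] <- mu * 2^lfc
  counts <- matrix(if (phi > 0) rnbinom(length(mus), mu = mus, size = 1 / phi)
                   else rpois(length(mus), mus),
                   n_genes, 2 * n_per,
                   dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                   md$sample_id))
  list(counts = count_matrix(counts), md = md)
}

test_that("dispersion estimates track the simulation truth", {
  # Poisson data: estimates collapse toward the floor
  sim <- make_two_group(200, 10, mu = 200, phi = 0, seed = 1)
  mm <- de_model_matrix(sim$md, "condition")
  sf <- size_factors(sim$counts)
  phi <- estimate_dispersions(sim$counts, sf, mm)
  expect_lt(median(phi, na.rm = TRUE), 0.01)
  # phi = 0.5 recovered within a factor of ~1.5 across seeds
  meds <- vapply(1:10, function(s) {
    sim <- make_two_group(200, 10, mu = 200, phi = 0.5, seed = s)
    phi <- estimate_dispersions(sim$counts, size_factors(sim$counts), mm)
    median(phi, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(meds > 0.3 & meds < 0.7))
})

test_that("all-zero genes are flagged and excluded from testing", {
  sim <- make_two_group(20, 6, seed = 2)
  m <- unclass(sim$counts); m[3, ] <- 0
  cm <- count_matrix(m)
  mm <- de_model_matrix(sim$md, "condition")
  phi <- estimate_dispersions(cm, size_factors(cm), mm)
  expect_true(is.na(phi[3]))
  expect_false(anyNA(phi[-3]))
})

test_that("NB Wald coefficients match an independent fixed-theta GLM fit", {
  sim <- make_two_group(30, 8, mu = 150, phi = 0.15,
                        lfc_genes = 1:5, lfc = 1.5, seed = 3)
  sf <- size_factors(sim$counts)
  mm <- de_model_matrix(sim$md, "condition")
  phi <- estimate_dispersions(sim$counts, sf, mm)
  fit <- nb_fit(sim$counts, sf, mm, phi)
  res <- wald_test(fit, c("condition", "PD", "healthy"))
  for (g in c(1, 3, 17)) {
    y <- unclass(sim$counts)[g, ]
    ref <- glm(y ~ sim$md$condition + offset(log(sf)),
               family = MASS::negative.binomial(theta = 1 / phi[g]))
    expect_equal(unname(fit$beta[g, 2]), unname(coef(ref)[2]),
                 tolerance = 1e-6)
    # dispersion = 1: pure inverse-Fisher-information standard errors
    ref_se <- summary(ref, dispersion = 1)$coefficients[2, 2]
    expect_equal(res$se[g], unname(ref_se) / log(2), tolerance = 1e-4)
  }
})

test_that("planted DEGs are recovered with high sensitivity and bounded FDR", {
  sens <- fdr_obs <- numeric(10)
  for (s in 1:10) {
    sim <- make_two_group(300, 8, mu = 150, phi = 0.1,
                          lfc_genes = 1:30, lfc = 2, seed = 10 + s)
    de <- run_de(sim$counts, sim$md, factors = "condition",
                 contrasts = c("condition", "PD", "healthy"))
    hits <- unlist(threshold_degs(de))
    truth <- rownames(sim$counts)[1:30]
    sens[s] <- mean(truth %in% hits)
    fdr_obs[s] <- if (length(hits)) mean(!hits %in% truth) else 0
    if (s == 1) {
      called <- de[de$gene %in% truth, ]
      expect_lt(abs(mean(called$lfc) - 2), 0.25)
    }
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fdr_obs), 0.1)
})

test_that("degenerate and symmetric cases behave exactly", {
  sim <- make_two_group(10, 6, seed = 5)
  m <- unclass(sim$counts); m[4, ] <- 50  # identical counts everywhere
  cm <- count_matrix(m)
  sf <- setNames(rep(1, 12), colnames(m))
  mm <- de_model_matrix(sim$md, "condition")
  phi <- estimate_dispersions(cm, sf, mm)
  fit <- nb_fit(cm, sf, mm, phi)
  fwd <- wald_test(fit, c("condition", "PD", "healthy"))
  expect_equal(fwd$lfc[4], 0, tolerance = 1e-10)
  expect_gt(fwd$pvalue[4], 0.99)
  rev <- wald_test(fit, c("condition", "healthy", "PD"))
  expect_equal(rev$lfc, -fwd$lfc, tolerance = 1e-12)
  expect_equal(rev$pvalue, fwd$pvalue, tolerance = 1e-12)
})

test_that("with vanishing dispersion the Wald p approaches the Poisson GLM p", {
  sim <- make_two_group(40, 10, mu = 300, phi = 0, seed = 6)
  sf <- setNames(rep(1, 20), colnames(sim$counts))
  mm <- de_model_matrix(sim$md, "condition")
  phi <- setNames(rep(1e-8, 40), rownames(sim$counts))
  fit <- nb_fit(sim$counts, sf, mm, phi)
  res <- wald_test(fit, c("condition", "PD", "healthy"))
  for (g in c(2, 9, 33)) {
    y <- unclass(sim$counts)[g, ]
    pg <- glm(y ~ sim$md$condition, family = poisson())
    p_pois <- summary(pg)$coefficients[2, 4]
    expect_equal(res$pvalue[g], p_pois, tolerance = 1e-4)
  }
})

test_that("BH adjustment equals the brute-force oracle", {
  for (s in 1:50) {
    set.seed(s)
    p <- runif(sample(5:60, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bf_bh(p), tolerance = 1e-12)
  }
  sim <- make_two_group(50, 6, phi = 0.2, lfc_genes = 1:5, seed = 7)
  de <- run_de(sim$counts, sim$md, factors = "condition",
               contrasts = c("condition", "PD", "healthy"))
  ok <- !is.na(de$pvalue)
  expect_equal(de$padj[ok], bf_bh(de$pvalue[ok]), tolerance = 1e-12)
})

test_that("DEG thresholding uses strict inequalities and matches a filter oracle", {
  res <- data.frame(gene = paste0("g", 1:6),
                    lfc = c(1.0, 1.2, -1.2, -0.9, 3, -3),
                    pvalue = rep(0.001, 6),
                    padj = c(0.01, 0.05, 0.01, 0.01, 0.04, NA))
  th <- threshold_degs(res)
  # g1 sits exactly at |LFC| = 1 and g2 exactly at FDR = 0.05: both excluded
  expect_identical(th$up, "g5")
  expect_identical(th$down, "g3")
  res2 <- data.frame(gene = paste0("g", 1:200),
                     lfc = runif(200, -3, 3),
                     pvalue = runif(200),
                     padj = runif(200))
  th2 <- threshold_degs(res2, fdr = 0.2, lfc = 0.5)
  expect_identical(th2$up,
                   res2$gene[res2$padj < 0.2 & res2$lfc > 0.5])
  expect_identical(th2$down,
                   res2$gene[res2$padj < 0.2 & res2$lfc < -0.5])
})
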