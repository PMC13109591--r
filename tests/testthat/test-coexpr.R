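test_that("signed-hybrid adjacency zeroes negatives and saturates at 1", {
  set.seed(1)
  z <- rnorm(20)
  expr <- rbind(g1 = z, g2 = z, g3 = -z,
                g4 = rnorm(20))
  colnames(expr) <- sprintf("s%02d", 1:20)
  attr(expr, "provenance") <- "batch_corrected"
  net <- build_coexpr_network(expr, "pearson", beta = 4, top_n = 10)
  expect_equal(net$adjacency["g1", "g2"], 1, tolerance = 1e-12)
  expect_equal(net$adjacency["g1", "g3"], 0)
  # adjacency is non-increasing in beta
  net2 <- build_coexpr_network(expr, "pearson", beta = 8, top_n = 10)
  expect_true(all(net2$adjacency <= net$adjacency + 1e-12))
})

test_that("network construction enforces provenance and sample floor", {
  expr <- matrix(rnorm(100), 10, 10,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:10)))
  expect_error(build_coexpr_network(expr, "pearson", beta = 6),
               "batch corrected")
  expect_silent(build_coexpr_network(expr, "pearson", beta = 6,
                                     allow_uncorrected = TRUE))
  small <- expr[, 1:5]
  expect_error(build_coexpr_network(small, "pearson", beta = 6,
                                    allow_uncorrected = TRUE),
               "8 samples")
  withconst <- rbind(expr, const = rep(2, 10))
  attr(withconst, "provenance") <- "batch_corrected"
  expect_warning(build_coexpr_network(withconst, "pearson", beta = 6),
                 "constant")
})

test_that("TOM equals the triple-loop oracle and is symmetric with unit diagonal", {
  cx <- simulate_coexpr(16, c(12, 10), 8, seed = 4)
  net <- build_coexpr_network(cx$expr, "pearson", beta = 6, top_n = 30)
  oracle <- bf_tom(net$adjacency)
  expect_equal(unname(net$tom), unname(oracle), tolerance = 1e-10)
  expect_equal(net$tom, t(net$tom), tolerance = 1e-12)
  expect_true(all(diag(net$tom) == 1))
  expect_true(all(net$tom >= -1e-12 & net$tom <= 1 + 1e-12))
})

test_that("module detection recovers planted blocks and ignores noise", {
  cx <- simulate_coexpr(34, c(40, 40), 60, seed = 1)
  net <- build_coexpr_network(cx$expr, "pearson", beta = 6, top_n = 200)
  part <- detect_modules(net, min_size = 20)
  truth1 <- names(cx$membership)[cx$membership == 1]
  truth2 <- names(cx$membership)[cx$membership == 2]
  found <- part$modules[names(part$modules) != "grey"]
  expect_gte(max(vapply(found, jaccard, numeric(1), truth1)), 0.9)
  expect_gte(max(vapply(found, jaccard, numeric(1), truth2)), 0.9)
  # pure noise: everything grey
  noise <- simulate_coexpr(34, integer(0), 120, seed = 8)
  netn <- build_coexpr_network(noise$expr, "pearson", beta = 6, top_n = 200)
  expect_warning(pn <- detect_modules(netn, min_size = 30), "grey")
  expect_identical(names(pn$modules), "grey")
  # min_size larger than the gene universe falls into the same path
  expect_warning(detect_modules(net, min_size = 1000), "grey")
})

test_that("eigengenes satisfy the rank-1 identities and the SVD oracle", {
  set.seed(2)
  z <- rnorm(12)
  same <- matrix(rep(z, 5), 5, 12, byrow = TRUE,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  part <- structure(list(modules = list(m = rownames(same))),
                    class = "module_partition")
  eg <- module_eigengenes(same, part)
  expect_equal(eg$var_explained[["m"]], 1, tolerance = 1e-12)
  # two perfectly anticorrelated genes still span a rank-1 space
  anti <- rbind(g1 = z, g2 = -z)
  colnames(anti) <- paste0("s", 1:12)
  part2 <- structure(list(modules = list(m = c("g1", "g2"))),
                     class = "module_partition")
  eg2 <- module_eigengenes(anti, part2)
  expect_equal(eg2$var_explained[["m"]], 1, tolerance = 1e-12)
  # random module: equals the SVD-based oracle up to the sign rule
  cx <- simulate_coexpr(15, c(10), 5, seed = 3)
  part3 <- structure(list(modules = list(
    m = names(cx$membership)[cx$membership == 1])),
    class = "module_partition")
  eg3 <- module_eigengenes(cx$expr, part3)
  x <- cx$expr[cx$membership == 1, ]
  zx <- t(scale(t(x)))
  pc <- svd(t(zx))$u[, 1]
  expect_equal(abs(unname(eg3$eigengenes[, 1])), abs(pc), tolerance = 1e-10)
  expect_gt(cor(eg3$eigengenes[, 1], colMeans(zx)), 0)
  # one-gene module: the gene's z-score direction
  part4 <- structure(list(modules = list(solo = rownames(cx$expr)[1])),
                     class = "module_partition")
  eg4 <- module_eigengenes(cx$expr, part4)
  expect_equal(abs(cor(eg4$eigengenes[, 1], cx$expr[1, ])), 1,
               tolerance = 1e-10)
})

test_that("module-trait statistics find planted group shifts", {
  md <- study_metadata()
  shift <- ifelse(md$condition == "PD", 1.5, -1.5)
  hits <- 0
  for (s in 1:10) {
    cx <- simulate_coexpr(34, c(30, 30), 40, group_shift = shift,
                          shift_modules = 1, seed = 40 + s)
    colnames(cx$expr) <- md$sample_id
    net <- build_coexpr_network(cx$expr, "pearson", beta = 6, top_n = 100)
    part <- detect_modules(net, min_size = 20)
    if (!any(names(part$modules) != "grey")) next
    eg <- module_eigengenes(cx$expr, part)
    rownames(eg$eigengenes) <- md$sample_id
    mt <- module_trait(eg$eigengenes, md, traits = "condition")
    pd_cor <- mt$correlations[mt$correlations$trait == "condition.PD" &
                                mt$correlations$method == "pearson", ]
    if (any(pd_cor$padj < 0.05)) hits <- hits + 1
  }
  expect_gte(hits / 10, 0.9)
})

test_that("eigengene = trait indicator gives perfect correlation", {
  md <- study_metadata()
  eg <- cbind(mod1 = as.numeric(md$condition == "PD"),
              mod2 = rnorm(34))
  rownames(eg) <- md$sample_id
  mt <- module_trait(eg, md, traits = "condition")
  r <- mt$correlations
  hit <- r[r$module == "mod1" & r$trait == "condition.PD" &
             r$method == "pearson", ]
  expect_equal(hit$cor, 1, tolerance = 1e-12)
  expect_lt(hit$pvalue, 1e-20)
  glm_row <- mt$glm[mt$glm$module == "mod1", ]
  expect_lt(glm_row$padj, 1e-10)
})

test_that("inter-module correlations are valid and the matrix is PSD", {
  cx <- simulate_coexpr(20, c(15, 15, 15), 20, seed = 6)
  part <- structure(list(modules = split(names(cx$membership)[cx$membership > 0],
                                         cx$membership[cx$membership > 0])),
                    class = "module_partition")
  names(part$modules) <- paste0("m", seq_along(part$modules))
  eg <- module_eigengenes(cx$expr, part)
  tab <- module_cor(eg$eigengenes, "spearman")
  expect_equal(nrow(tab), 3)
  expect_true(all(abs(tab$cor) <= 1))
  cm <- cor(eg$eigengenes)
  expect_true(all(eigen(cm, symmetric = TRUE)$values > -1e-10))
})
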