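# Independent brute-force oracles, deliberately written with naive loops so
# they share no code path with the package implementations they check.

bf_size_factors <- function(counts) {
  n_g <- nrow(counts); n_s <- ncol(counts)
  geo <- numeric(n_g)
  for (g in seq_len(n_g)) geo[g] <- prod(counts[g, ])^(1 / n_s)
  out <- numeric(n_s)
  for (j in seq_len(n_s)) {
    ratios <- c()
    for (g in seq_len(n_g)) if (geo[g] > 0)
      ratios <- c(ratios, counts[g, j] / geo[g])
    out[j] <- median(ratios)
  }
  out
}

# full running-sum enrichment score over the whole ranked list
bf_es <- function(scores, set_genes, weight = 1) {
  genes <- names(scores)
  hit <- genes %in% set_genes
  n <- length(genes); k <- sum(hit)
  wsum <- sum(abs(scores[hit])^weight)
  steps <- numeric(n)
  steps[hit] <- if (wsum == 0) 1 / k else abs(scores[hit])^weight / wsum
  steps[!hit] <- -1 / (n - k)
  run <- cumsum(steps)
  unname(run[which.max(abs(run))])
}

bf_tom <- function(adj) {
  n <- nrow(adj)
  tom <- matrix(0, n, n)
  k <- rowSums(adj)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { tom[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + adj[i, u] * adj[u, j]
    tom[i, j] <- (l + adj[i, j]) / (min(k[i], k[j]) + 1 - adj[i, j])
  }
  tom
}

bf_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[ord[i]] * n / i)
    adj[ord[i]] <- val
    prev <- val
  }
  adj
}

# per-variable sequential ANOVA summed over variables == Euclidean PERMANOVA
bf_permanova_ss <- function(expr, metadata, factors) {
  ss <- matrix(0, nrow(expr), length(factors) + 1)
  for (g in seq_len(nrow(expr))) {
    fml <- stats::reformulate(factors, response = "y")
    dat <- cbind(y = expr[g, ], metadata)
    an <- stats::anova(stats::lm(fml, dat))
    ss[g, ] <- an$`Sum Sq`
  }
  colSums(ss)  # per factor, then residual
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  unname(out)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# small random count matrix for round-trip / oracle tests
rand_counts <- function(n_g = 20, n_s = 6, seed = 1) {
  set.seed(seed)
  m <- matrix(rnbinom(n_g * n_s, mu = 50, size = 2), n_g, n_s,
              dimnames = list(sprintf("g%03d", seq_len(n_g)),
                              sprintf("s%02d", seq_len(n_s))))
  count_matrix(m)
}

# minimal balanced two-group metadata
two_group_md <- function(n_per = 8, levels = c("healthy", "PD")) {
  data.frame(sample_id = sprintf("s%02d", seq_len(2 * n_per)),
             condition = rep(levels, each = n_per),
             stringsAsFactors = FALSE)
}
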