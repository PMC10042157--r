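# shared fixtures, built in code at test time

# small cohort with one planted module; cheap enough for most module tests
tiny_cohort <- function(seed = 42, n_samples = 60, n_genes = 300,
                        n_centers = 2, effect = 1) {
  synth_config(
    n_samples = n_samples, n_genes = n_genes, n_centers = n_centers,
    planted_modules = data.frame(name = "lipid", n_genes = 20L,
                                 log2_effect = effect),
    seed = seed)
}

# deterministic toy count matrix with known totals
toy_counts <- function() {
  m <- matrix(c(10L, 20L, 30L,
                5L,  0L,  0L,
                0L,  0L,  0L,
                100L, 150L, 80L,
                1L, 2L, 3L,
                40L, 60L, 55L),
              nrow = 6, byrow = TRUE,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:3)))
  m
}

# independent TMM oracle: a literal, step-by-step transcription of the
# published trimmed-mean-of-M-values procedure (reference = sample whose
# upper quartile of count/libsize is closest to the mean upper quartile;
# 30% two-sided trim on M, 5% on A; inverse-asymptotic-variance weights;
# factors rescaled to geometric mean 1)
tmm_oracle <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, function(x) stats::quantile(x / sum(x), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j]; rf <- counts[, ref]
    nO <- lib[j]; nR <- lib[ref]
    keep <- obs > 0 & rf > 0
    obs <- obs[keep]; rf <- rf[keep]
    M <- log2((obs / nO) / (rf / nR))
    A <- (log2(obs / nO) + log2(rf / nR)) / 2
    w <- (nO - obs) / (nO * obs) + (nR - rf) / (nR * rf)
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * sum_trim) + 1;      hiS <- n + 1 - loS
    kp <- rank(M) >= loL & rank(M) <= hiL & rank(A) >= loS & rank(A) <= hiS
    2^(sum(M[kp] / w[kp]) / sum(1 / w[kp]))
  }, 1)
  f / exp(mean(log(f)))
}

# brute-force AUC over all positive/negative pairs
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == "high"]; neg <- scores[labels == "low"]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# exact rational hypergeometric upper tail via choose()
hyper_oracle <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# independent Jonckheere-Terpstra oracle: statistic by explicit double loop,
# null distribution by full factorial enumeration of value permutations
jt_stat_oracle <- function(groups) {
  s <- 0
  k <- length(groups)
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k))
    for (a in groups[[i]]) for (b in groups[[j]])
      s <- s + (a < b) + 0.5 * (a == b)
  s
}

jt_perm_oracle <- function(groups, alternative = "increasing") {
  obs <- jt_stat_oracle(groups)
  pooled <- unlist(groups)
  sizes <- lengths(groups)
  n <- length(pooled)
  perms <- matrix(unlist(combinat_perms(seq_len(n))), nrow = n)
  stats <- apply(perms, 2, function(p) {
    v <- pooled[p]
    jt_stat_oracle(split(v, rep(seq_along(sizes), sizes)))
  })
  if (alternative == "increasing") mean(stats >= obs - 1e-9)
  else mean(stats <= obs + 1e-9)
}

# all permutations of a vector (recursive; for n <= 7 only)
combinat_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in combinat_perms(x[-i])) out[[length(out) + 1]] <- c(x[i], p)
  out
}

# step-up BH by the textbook formula
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  pmin(q_sorted, 1)[order(o)]
}
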