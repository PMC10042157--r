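test_that("low-count filter keeps exactly the genes strictly above the total", {
  cts <- matrix(c(0L, 0L, 3L, 2L, 2L, 2L, 4L, 1L, 1L), nrow = 3, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  # totals: a = 0, b = 6, c = 6 with min_total 5 -> b, c kept
  kept <- filter_low_counts(cts, min_total = 5)
  expect_identical(rownames(kept), c("b", "c"))
  # brute-force recomputation on a random matrix
  set.seed(1)
  m <- matrix(rpois(300, 2), 30, 10,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:10)))
  got <- rownames(filter_low_counts(m, 5))
  want <- rownames(m)[sapply(seq_len(nrow(m)), function(i) sum(m[i, ]) > 5)]
  expect_identical(got, want)
  # identity when everything passes
  expect_identical(filter_low_counts(m + 10L, 5), m + 10L)
  # empty result errors
  expect_error(filter_low_counts(m, 1e6), "empty")
})

test_that("TMM factors are 1 for identical or proportional columns", {
  cts <- cbind(s1 = c(10L, 20L, 30L, 40L), s2 = c(10L, 20L, 30L, 40L))
  rownames(cts) <- paste0("g", 1:4)
  f <- tmm_factors(cts)
  expect_equal(f$tmm_factor, c(1, 1), tolerance = 1e-9)
  cts2 <- cbind(cts, s3 = 2L * cts[, 1])
  f2 <- tmm_factors(cts2)
  expect_equal(f2$tmm_factor, c(1, 1, 1), tolerance = 1e-9)
})

test_that("TMM agrees with the edgeR implementation on random matrices", {
  set.seed(19)
  for (rep in 1:5) {
    G <- sample(50:200, 1)
    cts <- matrix(rnbinom(G * 8, mu = sample(5:200, G, TRUE), size = 5), G, 8,
                  dimnames = list(sprintf("g%03d", 1:G), paste0("s", 1:8)))
    storage.mode(cts) <- "integer"
    ours <- tmm_factors(cts)$tmm_factor
    theirs <- edgeR::calcNormFactors(cts, method = "TMM")
    theirs <- theirs / exp(mean(log(theirs)))
    expect_equal(ours, unname(theirs), tolerance = 1e-10)
  }
})

test_that("TMM matches an independent step-by-step oracle", {
  set.seed(7)
  for (rep in 1:5) {
    cts <- matrix(rpois(18, lambda = sample(20:400, 18, TRUE)), 6, 3,
                  dimnames = list(paste0("g", 1:6), paste0("s", 1:3)))
    cts <- cts + 1L                      # keep all genes expressed
    got <- tmm_factors(cts)$tmm_factor
    want <- tmm_oracle(cts)
    expect_equal(got, unname(want), tolerance = 1e-8)
  }
})

test_that("TMM geometric mean is one and factors resist column rescaling", {
  set.seed(3)
  cts <- matrix(rnbinom(600, mu = 50, size = 5), 60, 10,
                dimnames = list(sprintf("g%02d", 1:60), sprintf("s%02d", 1:10)))
  f <- tmm_factors(cts)
  expect_equal(exp(mean(log(f$tmm_factor))), 1, tolerance = 1e-9)
  cts2 <- cts
  cts2[, 4] <- cts2[, 4] * 3L
  f2 <- tmm_factors(cts2)
  # M-values are scale-free; only the inverse-variance weights shift, so the
  # factors move at most in the third decimal
  expect_equal(f2$tmm_factor, f$tmm_factor, tolerance = 0.01)
  expect_equal(f2$lib_size[4], 3 * f$lib_size[4])
  # all-zero sample is named in the error
  cts3 <- cts
  cts3[, 2] <- 0L
  expect_error(tmm_factors(cts3), "s02")
})

test_that("log-CPM follows the stated formula and is monotone", {
  cts <- matrix(c(0L, 10L, 100L, 5L, 50L, 500L), 3, 2,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
  fac <- data.frame(sample_id = c("s1", "s2"),
                    lib_size = c(1e6, 2e6), tmm_factor = c(1, 1))
  lc <- lcpm_transform(cts, fac, prior = 0.5)
  want <- log2((cts[, 1] + 0.5) / (1e6 + 1) * 1e6)
  expect_equal(lc[, 1], want, tolerance = 1e-10)
  expect_equal(lc["g1", "s1"], log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-4)
  # strictly increasing in the count for a fixed sample
  expect_true(all(diff(lc[, 1]) > 0))
  # doubling (count + prior) raises the value by exactly one
  cts2 <- cts
  cts2[1, 1] <- 1L                      # 0 + 0.5 doubled is 1.5 - 0.5
  lc2 <- lcpm_transform(cts2, fac, prior = 0.5)
  expect_equal(lc2["g1", "s1"] - lc["g1", "s1"], log2(1.5 / 0.5),
               tolerance = 1e-10)
  expect_error(lcpm_transform(cts[, 2:1], fac), "align")
})

test_that("batch adjustment is identity for a single batch and zero genes", {
  cts <- toy_counts()
  expect_identical(batch_adjust_counts(cts, rep("c1", 3)), cts)
  set.seed(5)
  m <- matrix(rnbinom(400, mu = 30, size = 5), 40, 10,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:10)))
  storage.mode(m) <- "integer"
  m[3, ] <- 0L
  adj <- batch_adjust_counts(m, rep(c("a", "b"), 5))
  expect_identical(dim(adj), dim(m))
  expect_identical(dimnames(adj), dimnames(m))
  expect_true(all(adj >= 0))
  expect_identical(adj[3, ], m[3, ])
  expect_error(batch_adjust_counts(m, c("a", rep("b", 9))), "single sample")
})

# batch-mean ratio on the depth-normalized (counts-per-total) scale; a batch
# effect shared by every gene is indistinguishable from sequencing depth and
# is the province of TMM/CPM normalization, so recovery is assessed relative
# to depth
cpm_batch_ratio <- function(m, batch, rows) {
  cpm <- sweep(m, 2, colSums(m), `/`) * 1e6
  rowMeans(cpm[rows, batch == "b", drop = FALSE]) /
    rowMeans(cpm[rows, batch == "a", drop = FALSE])
}

planted_batch_fixture <- function(seed, G, n, frac = 0.3, size = NULL) {
  set.seed(seed)
  mu <- exp(rnorm(G, 4, 1))
  batch <- rep(c("a", "b"), each = n / 2)
  planted <- seq_len(round(G * frac))
  eff <- rep(1, G)
  eff[planted] <- 2
  mumat <- outer(mu, rep(1, n))
  mumat[, batch == "b"] <- mumat[, batch == "b"] * eff
  if (is.null(size)) size <- rep(1 / (0.05 + 2 / mu), n)
  cts <- matrix(rnbinom(G * n, mu = mumat, size = size), G, n,
                dimnames = list(sprintf("g%04d", seq_len(G)),
                                sprintf("s%03d", seq_len(n))))
  list(counts = cts, batch = batch, planted = rownames(cts)[planted])
}

test_that("a planted two-fold center effect is removed", {
  fx <- planted_batch_fixture(seed = 11, G = 300, n = 100)
  keep <- intersect(fx$planted, rownames(fx$counts)[rowMeans(fx$counts) > 5])
  before <- cpm_batch_ratio(fx$counts, fx$batch, keep)
  expect_gt(median(before), 1.5)
  adj <- batch_adjust_counts(fx$counts, fx$batch)
  after <- cpm_batch_ratio(adj, fx$batch, keep)
  expect_gte(median(after), 0.9)
  expect_lte(median(after), 1.1)
  # adjusting twice changes little beyond the first pass
  adj2 <- batch_adjust_counts(adj, fx$batch)
  r2 <- cpm_batch_ratio(adj2, fx$batch, keep)
  expect_equal(median(r2), median(after), tolerance = 0.05)
  # totals preserved to within rounding effects
  expect_equal(sum(adj), sum(fx$counts), tolerance = 0.02 * sum(fx$counts))
})

test_that("native batch adjustment agrees with ComBat-seq on planted effects", {
  skip_if_not_installed("sva")
  fx <- planted_batch_fixture(seed = 12, G = 120, n = 60, size = 8)
  keep <- intersect(fx$planted, rownames(fx$counts)[rowMeans(fx$counts) > 5])
  ours <- batch_adjust_counts(fx$counts, fx$batch)
  theirs <- suppressMessages(sva::ComBat_seq(fx$counts, batch = fx$batch))
  # both adjusters flatten the planted depth-relative ratio similarly
  expect_equal(median(cpm_batch_ratio(ours, fx$batch, keep)), 1,
               tolerance = 0.15)
  expect_equal(median(cpm_batch_ratio(theirs, fx$batch, keep)), 1,
               tolerance = 0.15)
  expect_gt(cor(as.vector(log(ours + 1)), as.vector(log(theirs + 1))), 0.95)
})
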