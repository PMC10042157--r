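test_that("resampling plans are deterministic with exact split sizes", {
  ids <- sprintf("s%02d", 1:10)
  plan <- make_resamples(ids, n_runs = 20, seed = 3)
  for (r in plan$runs) {
    expect_length(r$train, 8)
    expect_length(r$test, 2)
    expect_setequal(c(r$train, r$test), ids)
  }
  plan2 <- make_resamples(ids, n_runs = 20, seed = 3)
  expect_identical(plan, plan2)
  expect_error(make_resamples(ids[1:5]), "at least 10")
  expect_error(make_resamples(ids, train_fraction = 1.2), "train_fraction")
})

test_that("every sample lands in the test set about one run in five", {
  ids <- sprintf("s%03d", 1:50)
  plan <- make_resamples(ids, n_runs = 1000, seed = 5)
  freq <- rowMeans(sapply(plan$runs, function(r) ids %in% r$test))
  # binomial(1000, 0.2): +/- 4 sd band
  expect_true(all(abs(freq - 0.2) < 4 * sqrt(0.2 * 0.8 / 1000)))
})

test_that("weight-loss labels split strictly above the subset median", {
  s <- data.frame(sample_id = paste0("s", 1:4),
                  weight_0m = rep(100, 4),
                  weight_8m = c(95, 92, 90, 88))   # WL% 5, 8, 10, 12
  lab <- assign_wl_labels(s)
  expect_equal(unname(lab$threshold), 9)
  expect_identical(unname(lab$labels[c("s3", "s4")]), c("high", "high"))
  expect_identical(unname(lab$labels[c("s1", "s2")]), c("low", "low"))
  expect_false(lab$degenerate)
  # all-equal weight loss: nothing exceeds the median, degenerate flag set
  s2 <- s
  s2$weight_8m <- 90
  lab2 <- assign_wl_labels(s2)
  expect_true(all(lab2$labels == "low"))
  expect_true(lab2$degenerate)
})

test_that("linear SVM decision values order a separable feature correctly", {
  set.seed(1)
  x <- c(rnorm(20, 3), rnorm(20, -3))
  labels <- rep(c("high", "low"), each = 20)
  X <- cbind(f = x)
  rownames(X) <- sprintf("t%02d", 1:40)
  m <- train_linear_svm(X, labels)
  newX <- cbind(f = seq(-4, 4, length.out = 9))
  rownames(newX) <- paste0("n", 1:9)
  dv <- decision_values(m, newX)
  expect_true(all(diff(dv) > 0))        # monotone in the informative feature
  expect_gt(score_auc(decision_values(m, X), labels), 0.99)
  expect_error(train_linear_svm(X, rep("high", 40)), "single-class")
})

test_that("duplicating a feature column preserves the decision ordering", {
  set.seed(12)
  X <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(paste0("s", 1:60), NULL))
  y <- ifelse(X[, 1] + rnorm(60, 0, 0.5) > 0, "high", "low")
  if (length(unique(y)) < 2) y[1:2] <- c("high", "low")
  m1 <- train_linear_svm(X, y)
  m2 <- train_linear_svm(cbind(X, X[, 3]), y)
  d1 <- decision_values(m1, X)
  d2 <- decision_values(m2, cbind(X, X[, 3]))
  # the duplicated column splits its weight; decision values agree up to
  # the optimizer's convergence tolerance
  expect_lt(max(abs(d1 - d2)), 0.02)
  expect_gt(cor(d1, d2), 1 - 1e-6)
})

test_that("AUC equals brute-force pair counting, with tie and swap symmetry", {
  expect_equal(score_auc(c(0.9, 0.4, 0.5, 0.1),
                         c("high", "high", "low", "low")), 0.75)
  expect_equal(score_auc(c(3, 2, 1, 0), c("high", "high", "low", "low")), 1)
  expect_equal(score_auc(rep(1, 6), rep(c("high", "low"), 3)), 0.5)
  set.seed(9)
  for (i in 1:300) {
    n <- sample(4:20, 1)
    labels <- sample(c("high", "low"), n, TRUE)
    if (length(unique(labels)) < 2) next
    scores <- sample(seq(0, 1, 0.1), n, TRUE)   # generates ties
    a <- score_auc(scores, labels)
    expect_identical(a, auc_oracle(scores, labels))
    flipped <- ifelse(labels == "high", "low", "high")
    expect_equal(score_auc(scores, flipped), 1 - a, tolerance = 1e-12)
  }
})

test_that("AUC and DeLong CI agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(10)
  scores <- c(rnorm(30, 1), rnorm(30))
  labels <- rep(c("high", "low"), each = 30)
  ours <- delong_ci(scores, labels)
  pr <- pROC::roc(response = labels, predictor = scores, levels = c("low", "high"),
                  direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(ours$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  expect_equal(ours$lo, ci[1], tolerance = 1e-9)
  expect_equal(ours$hi, ci[3], tolerance = 1e-9)
})

test_that("DeLong interval contains the point AUC and degenerates when perfect", {
  set.seed(2)
  scores <- rnorm(40)
  labels <- rep(c("high", "low"), 20)
  ci <- delong_ci(scores, labels)
  expect_lte(ci$lo, ci$auc)
  expect_gte(ci$hi, ci$auc)
  expect_warning(perfect <- delong_ci(c(2, 3, -2, -3),
                                      c("high", "high", "low", "low")),
                 "degenerate")
  expect_equal(c(perfect$lo, perfect$hi), c(1, 1))
})

test_that("run_model is deterministic and honors the train/test separation", {
  cfg <- tiny_cohort(seed = 71, n_samples = 40, n_genes = 150)
  b <- generate_cohort(cfg)
  plan <- make_resamples(b$samples$sample_id, n_runs = 5, seed = 71)
  genes <- b$truth$module_gene_ids$lipid[1:10]
  r1 <- run_model(b, genes, plan)
  r2 <- run_model(b, genes, plan)
  expect_identical(r1$aucs, r2$aucs)
  expect_equal(r1$median_auc, median(r1$aucs, na.rm = TRUE))
  expect_equal(r1$max_auc, max(r1$aucs, na.rm = TRUE))
  # poisoning the test samples leaves every training-side artifact unchanged
  b2 <- b
  te <- plan$runs[[1]]$test
  b2$counts[, te] <- b2$counts[, te] + 1000L
  p1 <- prepare_runs(b, plan, genes)
  p2 <- prepare_runs(b2, plan, genes)
  expect_identical(p1[[1]]$train, p2[[1]]$train)
  expect_false(identical(p1[[1]]$test, p2[[1]]$test))
})

test_that("a cached block missing signature genes triggers a clean refit", {
  cfg <- tiny_cohort(seed = 72, n_samples = 40, n_genes = 150)
  b <- generate_cohort(cfg)
  plan <- make_resamples(b$samples$sample_id, n_runs = 3, seed = 72)
  genes <- b$truth$module_gene_ids$lipid[1:10]
  other <- setdiff(rownames(b$counts), genes)[1:20]
  prep_other <- prepare_runs(b, plan, other)
  direct <- run_model(b, genes, plan)
  via_fallback <- run_model(b, genes, plan, prepared = prep_other)
  expect_equal(direct$aucs, via_fallback$aucs)
})
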