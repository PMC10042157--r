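test_that("identical configuration yields an identical bundle and annotation", {
  cfg <- tiny_cohort(seed = 5)
  b1 <- generate_cohort(cfg)
  b2 <- generate_cohort(cfg)
  expect_identical(b1$counts, b2$counts)
  expect_identical(b1$samples, b2$samples)
  expect_identical(b1$clinical, b2$clinical)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)
  n1 <- generate_null_cohort(cfg)
  n2 <- generate_null_cohort(cfg)
  expect_identical(n1$counts, n2$counts)
  expect_identical(n1$samples, n2$samples)
})

test_that("module overlap fraction controls genes shared by the first two modules", {
  mods <- data.frame(name = c("a", "b"), n_genes = c(10L, 10L),
                     log2_effect = c(1, 1))
  cfg0 <- synth_config(n_samples = 30, n_genes = 200, n_centers = 2,
                       planted_modules = mods, module_overlap_fraction = 0,
                       seed = 1)
  t0 <- generate_cohort(cfg0)$truth$module_gene_ids
  expect_length(intersect(t0$a, t0$b), 0)
  cfg5 <- synth_config(n_samples = 30, n_genes = 200, n_centers = 2,
                       planted_modules = mods, module_overlap_fraction = 0.5,
                       seed = 1)
  t5 <- generate_cohort(cfg5)$truth$module_gene_ids
  expect_length(intersect(t5$a, t5$b), 5)
})

test_that("annotation has the required structure", {
  cfg <- tiny_cohort(seed = 9)
  ann <- generate_annotation(cfg)
  expect_gte(length(ann$terms), 50)
  expect_true(all(lengths(ann$terms) >= 3))
  expect_true(all(unlist(ann$terms) %in% ann$universe))
  # the module core term contains the module plus a ~25% dilution of
  # non-effect genes (terms are larger than the planted effect set)
  mod <- generate_cohort(cfg)$truth$module_gene_ids$lipid
  core_id <- names(ann$term_names)[ann$term_names == "lipid core process"]
  expect_true(all(mod %in% ann$terms[[core_id]]))
  expect_equal(length(ann$terms[[core_id]]), length(mod) + ceiling(0.25 * length(mod)))
  sib_ids <- names(ann$term_names)[grepl("lipid related", ann$term_names)]
  expect_gte(length(sib_ids), 3)
  for (id in sib_ids)
    expect_gte(jaccard(ann$terms[[id]], ann$terms[[core_id]]), 0.7)
})

test_that("planted class effect doubles module-gene means at log2 effect 1", {
  cfg <- synth_config(n_samples = 200, n_genes = 400, n_centers = 2,
                      planted_modules = data.frame(name = "m", n_genes = 30L,
                                                   log2_effect = 1),
                      module_cor_sd = 0, libsize_sd = 0, batch_sd = 0,
                      seed = 21)
  b <- generate_cohort(cfg)
  hi <- b$truth$true_class == "high"
  m <- b$truth$module_gene_ids$m
  ratio <- rowMeans(b$counts[m, hi]) / rowMeans(b$counts[m, !hi])
  expect_equal(mean(ratio), 2, tolerance = 0.1)
  off <- setdiff(rownames(b$counts), m)
  ratio0 <- rowMeans(b$counts[off, hi]) / rowMeans(b$counts[off, !hi])
  expect_equal(mean(ratio0, na.rm = TRUE), 1, tolerance = 0.1)
})

test_that("count marginals match the NB dispersion trend by moments", {
  cfg <- synth_config(n_samples = 600, n_genes = 200, n_centers = 1,
                      planted_modules = data.frame(name = "m", n_genes = 5L,
                                                   log2_effect = 0),
                      module_cor_sd = 0, libsize_sd = 0, batch_sd = 0,
                      sex_effect_sd = 0, nb_dispersion_model = c(0.1, 2),
                      seed = 33)
  b <- generate_cohort(cfg)
  m <- rowMeans(b$counts)
  v <- apply(b$counts, 1, var)
  est <- (v - m) / m^2
  expected <- 0.1 + 2 / m
  keep <- m > 20            # moment estimates are noisy for rare genes
  expect_equal(median(est[keep] - expected[keep]), 0, tolerance = 0.05)
})

test_that("weight trajectories carry class signal, regainers, and balance", {
  cfg <- tiny_cohort(seed = 13, n_samples = 200)
  b <- generate_cohort(cfg)
  wl <- 100 * (b$samples$weight_0m - b$samples$weight_8m) / b$samples$weight_0m
  hi <- b$truth$true_class == "high"
  expect_gt(mean(wl[hi]) - mean(wl[!hi]), 5)
  # regainers: weight_8m above weight_2m, all in the high class
  reg <- b$truth$regainer_ids
  i <- match(reg, b$samples$sample_id)
  expect_true(all(b$samples$weight_8m[i] > b$samples$weight_2m[i]))
  expect_true(all(b$truth$true_class[reg] == "high"))
  # median split balance
  lab <- assign_wl_labels(b$samples)
  expect_lte(abs(sum(lab$labels == "high") - sum(lab$labels == "low")), 1)
  # regainer_fraction = 0 forces no above-median regainer
  cfg0 <- tiny_cohort(seed = 13, n_samples = 100)
  cfg0$regainer_fraction <- 0
  b0 <- generate_cohort(cfg0)
  ts <- trajectory_stats(b0$samples)
  above <- ts$overall_wl > median(ts$overall_wl)
  gain <- b0$samples$weight_8m > b0$samples$weight_2m
  expect_false(any(above & gain))
})

test_that("null cohort trajectories are independent of expression", {
  cfg <- synth_config(n_samples = 400, n_genes = 300, n_centers = 2,
                      planted_modules = data.frame(name = "m", n_genes = 20L,
                                                   log2_effect = 1),
                      seed = 44)
  b <- generate_null_cohort(cfg)
  expect_true(b$truth$independent_trajectories)
  lab <- assign_wl_labels(b$samples)$labels[b$samples$sample_id]
  hi <- lab == "high"
  m <- b$truth$module_gene_ids$m
  lfc <- log2(rowMeans(b$counts[m, hi]) + 0.5) -
    log2(rowMeans(b$counts[m, !hi]) + 0.5)
  expect_equal(mean(lfc), 0, tolerance = 0.15)
  # per-gene t-test P-values on log counts are near-uniform
  lx <- log2(b$counts + 0.5)
  pv <- apply(lx, 1, function(x) {
    if (sd(x) == 0) return(NA_real_)
    t.test(x[hi], x[!hi])$p.value
  })
  ks <- suppressWarnings(ks.test(na.omit(pv), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_samples = 10), "n_samples")
  expect_error(synth_config(module_overlap_fraction = 1.5), "proportions")
  expect_error(synth_config(nb_dispersion_model = c(-1, 2)), "dispersion")
  expect_error(synth_config(n_genes = 30,
                            planted_modules = data.frame(
                              name = "m", n_genes = 50L, log2_effect = 1)),
               "larger than n_genes")
})
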