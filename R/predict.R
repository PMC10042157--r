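#' Monte-Carlo resampling plan
#'
#' `n_runs` independent, unstratified random splits of the samples into a
#' training fraction and the complementary test set. Stratification is
#' impossible by design: class labels are defined after splitting, by the
#' median weight loss within each subset.
#'
#' @param sample_ids Character vector of sample ids.
#' @param n_runs Number of splits (default 100).
#' @param train_fraction Training fraction (default 0.8).
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @return A `resample_plan`: list with `runs` (list of `list(train, test)`),
#'   `n_runs`, `train_fraction`, `seed`.
#' @export
make_resamples <- function(sample_ids, n_runs = 100L, train_fraction = 0.8,
                           seed = 1L) {
  n <- length(sample_ids)
  if (n < 10L) stop("need at least 10 samples")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  n_train <- round(train_fraction * n)
  runs <- with_seed(derive_seed(seed, "resamples"), {
    lapply(seq_len(n_runs), function(i) {
      tr <- sort(sample(sample_ids, n_train))
      list(train = tr, test = sort(setdiff(sample_ids, tr)))
    })
  })
  names(runs) <- sprintf("run%03d", seq_len(n_runs))
  structure(list(runs = runs, n_runs = as.integer(n_runs),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "resample_plan")
}

#' Weight-loss class labels within a subset
#'
#' Overall weight-loss percentage is `100 * (w0 - w8) / w0`; samples strictly
#' above the subset median are high-WL, the rest low-WL.
#'
#' @param samples Data frame with `sample_id`, `weight_0m`, `weight_8m`.
#' @param subset_ids Sample ids defining the subset (default: all).
#' @return List with `wl_pct` (named vector), `threshold` (subset median),
#'   `labels` (named "high"/"low" vector) and `degenerate` (TRUE when one
#'   class is empty).
#' @export
assign_wl_labels <- function(samples, subset_ids = samples$sample_id) {
  idx <- match(subset_ids, samples$sample_id)
  if (anyNA(idx)) stop("unknown sample ids in subset")
  s <- samples[idx, , drop = FALSE]
  miss <- is.na(s$weight_0m) | is.na(s$weight_8m)
  if (any(miss)) {
    warning(sum(miss), " sample(s) with missing weights excluded")
    s <- s[!miss, , drop = FALSE]
  }
  if (nrow(s) == 0) stop("no samples with weights in subset")
  wl <- 100 * (s$weight_0m - s$weight_8m) / s$weight_0m
  names(wl) <- s$sample_id
  thr <- stats::median(wl)
  labels <- ifelse(wl > thr, "high", "low")
  names(labels) <- s$sample_id
  list(wl_pct = wl, threshold = thr, labels = labels,
       degenerate = length(unique(labels)) < 2L)
}

#' Model configuration for the classifier
#'
#' @param kernel Only `"linear"` is supported.
#' @param cost Soft-margin cost (default 1).
#' @param standardize Standardize features with training statistics
#'   (default TRUE).
#' @return A `model_config` object.
#' @export
model_config <- function(kernel = "linear", cost = 1, standardize = TRUE) {
  if (!identical(kernel, "linear")) stop("only the linear kernel is supported")
  if (cost <= 0) stop("cost must be positive")
  structure(list(kernel = kernel, cost = cost, standardize = standardize),
            class = "model_config")
}

#' Train a linear SVM
#'
#' Soft-margin linear SVM at the configured cost, trained on features
#' standardized with training mean/SD (stored for reuse on test data). The
#' returned model yields continuous decision values oriented so that larger
#' values favor the "high" class.
#'
#' @param features Samples x features numeric matrix (training data).
#' @param labels "high"/"low" per training sample.
#' @param config A [model_config()].
#' @return An `svm_model` list with the fitted e1071 model and the
#'   standardization statistics.
#' @export
train_linear_svm <- function(features, labels, config = model_config()) {
  labels <- factor(as.character(labels), levels = c("high", "low"))
  if (any(is.na(labels))) stop("labels must be 'high'/'low'")
  if (length(unique(labels)) < 2L) stop("single-class training labels")
  ctr <- colMeans(features)
  scl <- apply(features, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  if (!config$standardize) {
    ctr[] <- 0
    scl[] <- 1
  }
  Z <- sweep(sweep(features, 2, ctr), 2, scl, `/`)
  fit <- e1071::svm(Z, labels, kernel = "linear", cost = config$cost,
                    scale = FALSE)
  # linear kernel: the decision function is w'x - rho; libsvm orients the
  # sign toward the first training label encountered
  w <- drop(crossprod(fit$coefs, fit$SV))
  rho <- fit$rho
  pos_first <- fit$levels[fit$labels[1]] == "high"
  if (!pos_first) {
    w <- -w
    rho <- -rho
  }
  structure(list(fit = fit, center = ctr, scale = scl, w = w, rho = rho),
            class = "svm_model")
}

#' Decision values of a trained SVM on new samples
#'
#' @param model An `svm_model` from [train_linear_svm()].
#' @param features Samples x features matrix (test data; standardized with the
#'   training statistics stored in the model).
#' @return Named numeric vector; larger values favor the "high" class.
#' @export
decision_values <- function(model, features) {
  Z <- sweep(sweep(features, 2, model$center), 2, model$scale, `/`)
  stats::setNames(as.numeric(Z %*% model$w - model$rho), rownames(features))
}

#' ROC AUC by pair counting
#'
#' `AUC = (concordant pairs + 0.5 * tied pairs) / (n_pos * n_neg)` over all
#' positive/negative pairs, computed through the rank (Mann-Whitney)
#' identity; "high" is the positive class.
#'
#' @param decision_values Numeric scores.
#' @param labels "high"/"low" per score.
#' @return AUC in `[0, 1]`.
#' @export
score_auc <- function(decision_values, labels) {
  pos <- labels == "high"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes required in test labels")
  r <- rank(decision_values)            # average ranks handle ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' DeLong confidence interval for an AUC
#'
#' Variance from DeLong's placement-value decomposition:
#' `SE^2 = var(V10)/m + var(V01)/n` with placement values
#' `V10_i = mean_j psi(X_i, Y_j)` and `V01_j = mean_i psi(X_i, Y_j)`,
#' `psi = 1, 1/2, 0` for wins/ties/losses of positives over negatives. The
#' interval is `AUC +/- z * SE`, clipped to `[0, 1]`.
#'
#' @param decision_values Numeric scores.
#' @param labels "high"/"low" per score.
#' @param level Confidence level (default 0.95).
#' @return List with `auc`, `lo`, `hi`, `se`.
#' @export
delong_ci <- function(decision_values, labels, level = 0.95) {
  pos <- labels == "high"
  x <- decision_values[pos]
  y <- decision_values[!pos]
  m <- length(x)
  n <- length(y)
  if (m < 2L || n < 2L) stop("need >= 2 samples per class")
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(psi)
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  se <- sqrt(stats::var(v10) / m + stats::var(v01) / n)
  if (!is.finite(se) || se == 0) {
    warning("zero placement variance; degenerate CI")
    return(list(auc = auc, lo = auc, hi = auc, se = 0))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(auc = auc, lo = max(0, auc - z * se), hi = min(1, auc + z * se),
       se = se)
}

# pool batch levels that have fewer than `min_n` samples in a subset so the
# adjuster's >= 2 per batch precondition holds within small test subsets
.merge_small_batches <- function(batch, min_n = 2L) {
  batch <- as.character(batch)
  tab <- table(batch)
  small <- names(tab)[tab < min_n]
  if (length(small) > 0) batch[batch %in% small] <- "_pooled"
  tab <- table(batch)
  if (!is.na(tab["_pooled"]) && tab["_pooled"] < min_n) {
    big <- names(tab)[which.max(tab)]
    batch[batch == "_pooled"] <- big
  }
  batch
}

# one subset's normalized feature block: batch-adjusted counts, TMM factors,
# log-CPM, restricted to `genes`, plus median-split labels. The exact NB
# quantile map is applied to the feature genes; the normalization factors
# and library sizes are computed on the expected-value-adjusted full matrix
# (counts scaled by the fitted mean ratio), which avoids the per-entry
# quantile inversion for genes that never become features.
.prepare_side <- function(bundle, ids, genes, adjust_batch, prior = 0.5) {
  idx <- match(ids, bundle$samples$sample_id)
  cts <- bundle$counts[, idx, drop = FALSE]
  meta <- bundle$samples[idx, , drop = FALSE]
  lab <- assign_wl_labels(bundle$samples, ids)
  b <- .merge_small_batches(meta$center)
  if (adjust_batch && length(unique(b)) > 1L) {
    bf <- .batch_fit(cts, b, meta$sex, meta$age)
    ratio <- bf$mu_free / bf$mu_full
    # ill-fitted sparse genes can give wild or non-finite mean ratios; a
    # batch correction factor beyond 32-fold is never meaningful
    ratio[!is.finite(ratio)] <- 1
    ratio <- pmin(pmax(ratio, 1 / 32), 32)
    norm_mat <- cts * ratio
    norm_mat[bf$flat, ] <- cts[bf$flat, ]
    feat <- cts[genes, , drop = FALSE]
    active <- genes[!bf$flat[genes]]
    feat[active, ] <- .nb_quantile_map(cts, bf, active)
    norm_mat[genes, ] <- feat
  } else {
    norm_mat <- cts
    feat <- cts[genes, , drop = FALSE]
  }
  lib <- colSums(norm_mat)
  f <- .tmm_core(norm_mat)
  stopifnot(all(is.finite(f)), all(f > 0))
  eff <- lib * f
  lc <- t(log2(t(feat + prior) / (eff + 2 * prior) * 1e6))
  list(lcpm = lc, labels = lab)
}

#' Per-run normalized feature blocks
#'
#' For every run of the plan, batch-adjusts and TMM/log-CPM-normalizes the
#' training and testing subsets independently (the pipeline's stated design:
#' no statistic crosses the split), restricts to the requested genes, and
#' attaches the subset-median weight-loss labels.
#'
#' @param bundle A `cohort_bundle`.
#' @param plan A [make_resamples()] plan over the bundle's samples.
#' @param genes Genes to retain as features (default: all).
#' @param adjust_batch Apply [batch_adjust_counts()] per subset (default TRUE).
#' @return List of per-run lists: `train`/`test`, each with `lcpm`
#'   (genes x samples) and `labels`.
#' @export
prepare_runs <- function(bundle, plan, genes = rownames(bundle$counts),
                         adjust_batch = TRUE) {
  stopifnot(inherits(plan, "resample_plan"))
  missing <- setdiff(genes, rownames(bundle$counts))
  if (length(missing) > 0)
    stop("genes absent from counts: ", paste(missing, collapse = ", "))
  lapply(plan$runs, function(r) {
    list(train = .prepare_side(bundle, r$train, genes, adjust_batch),
         test = .prepare_side(bundle, r$test, genes, adjust_batch))
  })
}

# evaluate one gene set on prepared runs; returns per-run AUC (NA for
# degenerate runs) and the max-AUC run's test scores for the DeLong CI
.evaluate_genes <- function(prepared, genes, config) {
  aucs <- rep(NA_real_, length(prepared))
  names(aucs) <- names(prepared)
  best <- NULL
  for (i in seq_along(prepared)) {
    run <- prepared[[i]]
    if (run$train$labels$degenerate || run$test$labels$degenerate) next
    ftr <- t(run$train$lcpm[genes, , drop = FALSE])
    fte <- t(run$test$lcpm[genes, , drop = FALSE])
    model <- train_linear_svm(ftr, run$train$labels$labels[rownames(ftr)], config)
    dv <- decision_values(model, fte)
    lab <- run$test$labels$labels[names(dv)]
    aucs[i] <- score_auc(dv, lab)
    if (is.null(best) || aucs[i] > best$auc)
      best <- list(auc = aucs[i], dv = dv, labels = lab, run = names(prepared)[i])
  }
  list(aucs = aucs, best = best)
}

#' Evaluate a signature over a resampling plan
#'
#' Runs the full per-run loop: independent training/testing normalization,
#' subset-median labels, linear SVM on the signature genes, test AUC; then
#' summarizes median and maximum AUC and the DeLong CI of the best run. Runs
#' whose training or testing subset is single-class are skipped and counted.
#'
#' @param bundle A `cohort_bundle`.
#' @param signature A `gene_signature` (or character vector of gene ids).
#' @param plan A [make_resamples()] plan.
#' @param config A [model_config()].
#' @param prepared Optional precomputed [prepare_runs()] output covering the
#'   signature's genes, to share normalization across many models.
#' @param adjust_batch Passed to [prepare_runs()] when `prepared` is NULL.
#' @return A `model_report`: list with `class_name`, `genes`, `aucs` (per
#'   run), `median_auc`, `max_auc`, `ci` (DeLong at the best run),
#'   `n_skipped`, `empirical_p` (NA until set against a null ensemble).
#' @export
run_model <- function(bundle, signature, plan, config = model_config(),
                      prepared = NULL, adjust_batch = TRUE) {
  genes <- if (inherits(signature, "gene_signature")) signature$genes
           else as.character(signature)
  cls <- if (inherits(signature, "gene_signature")) signature$class_name
         else "custom"
  if (length(genes) == 0) stop("empty signature")
  if (!all(genes %in% rownames(bundle$counts)))
    stop("signature genes missing from counts")
  if (is.null(prepared)) {
    prepared <- prepare_runs(bundle, plan, genes, adjust_batch)
  } else {
    # a cached block may miss some signature genes (it was prepared for a
    # different gene set); recompute just those runs
    for (rn in names(prepared)) {
      if (!all(genes %in% rownames(prepared[[rn]]$train$lcpm)) ||
          !all(genes %in% rownames(prepared[[rn]]$test$lcpm))) {
        prepared[[rn]] <- list(
          train = .prepare_side(bundle, plan$runs[[rn]]$train, genes,
                                adjust_batch),
          test = .prepare_side(bundle, plan$runs[[rn]]$test, genes,
                               adjust_batch))
      }
    }
  }
  ev <- .evaluate_genes(prepared, genes, config)
  ok <- !is.na(ev$aucs)
  ci <- if (!is.null(ev$best))
    suppressWarnings(delong_ci(ev$best$dv, ev$best$labels)) else NULL
  structure(list(class_name = cls, genes = genes, aucs = ev$aucs,
                 median_auc = stats::median(ev$aucs[ok]),
                 max_auc = if (any(ok)) max(ev$aucs[ok]) else NA_real_,
                 best_run = if (!is.null(ev$best)) ev$best$run else NA_character_,
                 ci = ci, n_skipped = sum(!ok), empirical_p = NA_real_),
            class = "model_report")
}

#' Per-run feature discovery (DE, enrichment, map, PCA selection)
#'
#' For every run: differential expression on the raw training counts (class
#' adjusted for sex, age and center), hypergeometric enrichment of the
#' nominal DEG set against the annotation restricted to the training gene
#' universe, enrichment-map construction, keyword labeling of components, and
#' PCA-based selection of the top contributing genes from each labeled
#' component's gene union (on the training subset's adjusted log-CPM). Runs
#' with no significant term are recorded.
#'
#' @param bundle A `cohort_bundle`.
#' @param plan A [make_resamples()] plan.
#' @param annotation A [term_annotation()].
#' @param params A [selection_params()].
#' @param alpha_nominal DEG cutoff (default 0.01).
#' @param p_cut,q_cut,fdr_cut Enrichment cutoffs (defaults 0.05, 0.2, 0.05).
#' @param min_total Low-count filter threshold (default 5).
#' @param adjust_batch Batch-adjust before the PCA feature extraction.
#' @param feature_genes Optional gene ids: when supplied, the per-run
#'   normalized blocks ([prepare_runs()] format) covering the union of these
#'   genes and each run's component genes are returned as `prepared`, so a
#'   subsequent evaluation phase over the same plan can reuse the per-run
#'   normalization instead of recomputing it.
#' @return List with `selections` (class -> run -> ranked genes),
#'   `discovery_counts` (class -> number of runs discovered),
#'   `runs_no_significant` (run ids with an empty significant set),
#'   `n_runs` and `prepared` (NULL unless `feature_genes` was given).
#' @export
discover_features <- function(bundle, plan, annotation,
                              params = selection_params(),
                              alpha_nominal = 0.01, p_cut = 0.05,
                              q_cut = 0.2, fdr_cut = 0.05, min_total = 5,
                              adjust_batch = TRUE, feature_genes = NULL) {
  stopifnot(inherits(plan, "resample_plan"))
  selections <- list()
  runs_no_sig <- character()
  prepared <- if (!is.null(feature_genes)) list() else NULL
  for (rn in names(plan$runs)) {
    tr <- plan$runs[[rn]]$train
    te <- plan$runs[[rn]]$test
    idx <- match(tr, bundle$samples$sample_id)
    meta <- bundle$samples[idx, , drop = FALSE]
    cts <- filter_low_counts(bundle$counts[, idx, drop = FALSE], min_total)
    lab <- assign_wl_labels(bundle$samples, tr)
    comp_genes <- character()
    if (!lab$degenerate) {
      des <- design_spec(lab$labels[tr], sex = meta$sex, age = meta$age,
                         center = meta$center, alpha_nominal = alpha_nominal)
      de <- run_de(cts, des)
      degs <- de$gene_id[de$significant]
      ann_r <- restrict_annotation(annotation, rownames(cts))
      tab <- enrich_terms(degs, ann_r, p_cut = p_cut, q_cut = q_cut,
                          fdr_cut = fdr_cut)
      if (nrow(tab) == 0 || !any(tab$significant)) {
        runs_no_sig <- c(runs_no_sig, rn)
      } else {
        map <- build_map(tab, ann_r)
        labeled_comps <- list()
        for (comp in map$components) {
          cls <- label_component(comp$term_names, params)
          if (cls == "unlabeled") next
          if (!is.null(labeled_comps[[cls]])) next  # best-P component wins
          labeled_comps[[cls]] <- intersect(comp$genes, rownames(cts))
        }
        comp_genes <- sort(unique(unlist(labeled_comps)))
        if (length(comp_genes) > 0) {
          lc_tr <- .prepare_side(bundle, tr,
                                 union(comp_genes,
                                       intersect(feature_genes,
                                                 rownames(bundle$counts))),
                                 adjust_batch)
          for (cls in names(labeled_comps)) {
            genes <- labeled_comps[[cls]]
            if (length(genes) < 2L) next
            picked <- pca_top_contributors(
              t(lc_tr$lcpm[genes, , drop = FALSE]), params)
            if (is.null(selections[[cls]])) selections[[cls]] <- list()
            selections[[cls]][[rn]] <- picked
          }
          if (!is.null(prepared))
            prepared[[rn]] <- list(
              train = lc_tr,
              test = .prepare_side(bundle, te,
                                   union(comp_genes,
                                         intersect(feature_genes,
                                                   rownames(bundle$counts))),
                                   adjust_batch))
        }
      }
    } else {
      runs_no_sig <- c(runs_no_sig, rn)
    }
    if (!is.null(prepared) && is.null(prepared[[rn]]))
      prepared[[rn]] <- list(
        train = .prepare_side(bundle, tr, feature_genes, adjust_batch),
        test = .prepare_side(bundle, te, feature_genes, adjust_batch))
  }
  if (!is.null(prepared)) prepared <- prepared[names(plan$runs)]
  list(selections = selections,
       discovery_counts = vapply(selections, length, 1L),
       runs_no_significant = runs_no_sig,
       n_runs = plan$n_runs,
       prepared = prepared)
}
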