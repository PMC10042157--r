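#' Discovery phase: resampled feature extraction and signature aggregation
#'
#' Runs [discover_features()] over the plan and aggregates every discovered
#' pathway class into a fixed signature with [aggregate_signature()].
#'
#' @param bundle A `cohort_bundle`.
#' @param plan A [make_resamples()] plan.
#' @param annotation A [term_annotation()].
#' @param params A [selection_params()].
#' @param ... Passed to [discover_features()].
#' @return List with `signatures` (class -> `gene_signature`),
#'   `discovery_counts`, `runs_no_significant`, `selections`, `n_runs` and
#'   `prepared` (see [discover_features()]).
#' @export
run_discovery_phase <- function(bundle, plan, annotation,
                                params = selection_params(), ...) {
  disc <- discover_features(bundle, plan, annotation, params, ...)
  signatures <- lapply(names(disc$selections), function(cls)
    aggregate_signature(disc$selections[[cls]], cls, params,
                        n_total_runs = disc$n_runs))
  names(signatures) <- names(disc$selections)
  list(signatures = signatures, discovery_counts = disc$discovery_counts,
       runs_no_significant = disc$runs_no_significant,
       selections = disc$selections, n_runs = disc$n_runs,
       prepared = disc$prepared)
}

# per-run evaluation of arbitrary per-sample feature rows (clinical-only and
# hybrid models); expression features come from `prepared`, clinical columns
# are appended with training statistics
.evaluate_with_clinical <- function(prepared, genes, clin, factor_ids, config) {
  aucs <- rep(NA_real_, length(prepared))
  names(aucs) <- names(prepared)
  best <- NULL
  for (i in seq_along(prepared)) {
    run <- prepared[[i]]
    if (run$train$labels$degenerate || run$test$labels$degenerate) next
    ftr <- if (length(genes) > 0) t(run$train$lcpm[genes, , drop = FALSE])
           else matrix(0, length(run$train$labels$labels), 0,
                       dimnames = list(names(run$train$labels$labels), NULL))
    fte <- if (length(genes) > 0) t(run$test$lcpm[genes, , drop = FALSE])
           else matrix(0, length(run$test$labels$labels), 0,
                       dimnames = list(names(run$test$labels$labels), NULL))
    atr <- augment_features(ftr, clin, factor_ids)
    ate <- augment_features(fte, clin, factor_ids,
                            center = atr$center, scale = atr$scale)
    keep_tr <- stats::complete.cases(atr$features)
    keep_te <- stats::complete.cases(ate$features)
    Xtr <- atr$features[keep_tr, , drop = FALSE]
    Xte <- ate$features[keep_te, , drop = FALSE]
    lab_tr <- run$train$labels$labels[rownames(Xtr)]
    lab_te <- run$test$labels$labels[rownames(Xte)]
    if (length(unique(lab_tr)) < 2L || length(unique(lab_te)) < 2L) next
    model <- train_linear_svm(Xtr, lab_tr, config)
    dv <- decision_values(model, Xte)
    aucs[i] <- score_auc(dv, lab_te)
    if (is.null(best) || aucs[i] > best$auc)
      best <- list(auc = aucs[i], dv = dv, labels = lab_te)
  }
  ok <- !is.na(aucs)
  ci <- if (!is.null(best))
    suppressWarnings(delong_ci(best$dv, best$labels)) else NULL
  list(aucs = aucs, median_auc = stats::median(aucs[ok]),
       max_auc = if (any(ok)) max(aucs[ok]) else NA_real_, ci = ci,
       n_skipped = sum(!ok))
}

#' Evaluation phase: signatures, combinations, null, clinical, diagnostics
#'
#' Evaluates each aggregated signature against a shared random-gene null
#' ensemble (empirical P per model), forms the set-algebra combinations of
#' the first two signatures, fits the clinical-only model and the requested
#' expression+clinical hybrids (with paired-AUC comparisons against the base
#' signature model), and computes trajectory diagnostics.
#'
#' @param bundle A `cohort_bundle`.
#' @param signatures Named list of `gene_signature`s (possibly empty for a
#'   clinical-only study).
#' @param plan A [make_resamples()] plan.
#' @param config A [model_config()].
#' @param n_null_sets Size of the random-gene null ensemble (default 100).
#' @param null_seed Seed for null-set sampling (default derived from plan).
#' @param hybrid_factors Clinical factor ids to append one at a time to the
#'   first two signatures (default none).
#' @param combine First-two-signature combinations to evaluate
#'   (default TRUE when at least two signatures are supplied).
#' @return A `study_report` list.
#' @export
run_evaluation_phase <- function(bundle, signatures, plan,
                                 config = model_config(),
                                 n_null_sets = 100L, null_seed = NULL,
                                 hybrid_factors = character(),
                                 combine = length(signatures) >= 2L) {
  if (is.null(null_seed)) null_seed <- derive_seed(plan$seed, "null-ensemble")
  models <- list()
  sigs <- signatures
  if (combine && length(signatures) >= 2L) {
    a <- signatures[[1]]
    b <- signatures[[2]]
    extra <- list(combine_signatures(a, b, "union"),
                  combine_signatures(a, b, "a_minus_b"),
                  combine_signatures(b, a, "a_minus_b"))
    extra <- extra[vapply(extra, function(s) length(s$genes) > 0, TRUE)]
    names(extra) <- vapply(extra, function(s) s$class_name, "")
    sigs <- c(sigs, extra)
  }

  null_sets <- sample_random_genesets(bundle$counts, n_sets = n_null_sets,
                                      seed = null_seed)
  all_genes <- sort(unique(c(unlist(lapply(sigs, `[[`, "genes")),
                             unlist(null_sets))))
  prepared <- prepare_runs(bundle, plan, all_genes)
  null_medians <- null_model_aucs(bundle, null_sets, plan, config,
                                  prepared = prepared)

  for (nm in names(sigs)) {
    rep_i <- run_model(bundle, sigs[[nm]], plan, config, prepared = prepared)
    rep_i$empirical_p <- empirical_pvalue(rep_i$median_auc, null_medians)
    models[[nm]] <- rep_i
  }

  # clinical-only model on the sex/age-adjusted, skew-transformed table
  clinical <- NULL
  hybrids <- list()
  if (!is.null(bundle$clinical)) {
    ts <- transform_skewed(bundle$clinical)
    clin <- adjust_for_sex_age(ts$table, bundle$samples$sex,
                               bundle$samples$age)
    clinical <- .evaluate_with_clinical(prepared, character(), clin,
                                        colnames(clin), config)
    clinical$empirical_p <- empirical_pvalue(clinical$median_auc, null_medians)
    for (sg in utils::head(names(signatures), 2L)) {
      base <- models[[sg]]
      for (fid in hybrid_factors) {
        hy <- .evaluate_with_clinical(prepared, signatures[[sg]]$genes, clin,
                                      fid, config)
        hy$empirical_p <- empirical_pvalue(hy$median_auc, null_medians)
        hy$comparison <- paired_auc_comparison(base$aucs, hy$aucs)
        hybrids[[paste(sg, fid, sep = "+")]] <- hy
      }
    }
  }

  traj <- trajectory_stats(bundle$samples)
  wl_corr <- pearson_corr(traj$overall_wl, traj$maint_wl)
  regainers <- traj$sample_id[traj$regainer]
  diagnostics <- lapply(models, function(m)
    suppressWarnings(stratify_runs_by_auc(m$aucs, plan, regainers)))

  structure(list(models = models, null_medians = null_medians,
                 null_sets = null_sets, clinical = clinical,
                 hybrids = hybrids,
                 diagnostics = list(trajectories = traj,
                                    overall_vs_maintenance = wl_corr,
                                    regainer_ids = regainers,
                                    by_model = diagnostics),
                 plan_seed = plan$seed),
            class = "study_report")
}

#' Persist a study report
#'
#' Writes a JSON master summary, per-run AUC tables (TSV) and the trajectory
#' table into `outdir` (created if missing).
#'
#' @param report A `study_report`.
#' @param outdir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  summarize <- function(m) list(
    median_auc = m$median_auc, max_auc = m$max_auc,
    ci = if (!is.null(m$ci)) m$ci[c("lo", "hi")] else NULL,
    empirical_p = m$empirical_p, n_skipped = m$n_skipped)
  master <- list(
    models = lapply(report$models, summarize),
    clinical = if (!is.null(report$clinical)) summarize(report$clinical),
    hybrids = lapply(report$hybrids, function(h)
      c(summarize(h), list(paired_t_p = h$comparison$pvalue,
                           run_classes = as.list(h$comparison$counts)))),
    null_median_of_medians = stats::median(report$null_medians),
    overall_vs_maintenance_r = report$diagnostics$overall_vs_maintenance$r,
    n_regainers = length(report$diagnostics$regainer_ids),
    jt_by_model = lapply(report$diagnostics$by_model, function(d)
      if (!is.null(d$test)) d$test[c("statistic", "pvalue")] else NULL),
    plan_seed = report$plan_seed)
  p <- file.path(outdir, "report.json")
  jsonlite::write_json(master, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, p)

  if (length(report$models) > 0) {
    auc_tab <- data.frame(run = names(report$models[[1]]$aucs),
                          sapply(report$models, `[[`, "aucs"),
                          check.names = FALSE)
    p <- file.path(outdir, "per_run_aucs.tsv")
    utils::write.table(auc_tab, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }

  p <- file.path(outdir, "trajectories.tsv")
  utils::write.table(report$diagnostics$trajectories, p, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)

  p <- file.path(outdir, "null_medians.tsv")
  utils::write.table(data.frame(set = seq_along(report$null_medians),
                                median_auc = report$null_medians),
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, p))
}
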