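#!/usr/bin/env Rscript
# Weight-trajectory diagnostics: overall vs maintenance weight-loss
# correlation, regainer identification (above-median overall losers who
# regain more than 4% of baseline weight during maintenance), and the
# Jonckheere-Terpstra test asking whether high-AUC runs trained on fewer
# regainers than low-AUC runs.

source("analysis/00_config.R")

cfg <- study_config()
bundle <- generate_cohort(cfg)
plan <- study_plan(bundle)

traj <- trajectory_stats(bundle$samples)
write.table(traj, file.path(RESULTS, "trajectories.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

corr <- pearson_corr(traj$overall_wl, traj$maint_wl)
cat(sprintf("overall vs maintenance weight loss: r = %.2f (P = %.2e, n = %d)\n",
            corr$r, corr$pvalue, corr$n))
regainers <- traj$sample_id[traj$regainer]
cat(sprintf("regainers: %d of %d samples\n", length(regainers), nrow(traj)))

auc_file <- file.path(RESULTS, "evaluation", "per_run_aucs.tsv")
if (!file.exists(auc_file))
  stop("no per-run AUCs found; run analysis/03_evaluate.R first")
aucs <- read.delim(auc_file, check.names = FALSE)

out <- list()
for (model in setdiff(colnames(aucs), "run")) {
  v <- setNames(aucs[[model]], aucs$run)
  strat <- suppressWarnings(stratify_runs_by_auc(v, plan, regainers,
                                                 threshold = 0.6))
  if (strat$skipped) {
    cat(sprintf("  %-16s trend test skipped (degenerate stratification)\n",
                model))
    next
  }
  cat(sprintf("  %-16s regainers in training: low-AUC runs mean %.2f vs high-AUC runs mean %.2f; JT P = %.3f\n",
              model, mean(strat$groups$low_auc), mean(strat$groups$high_auc),
              strat$test$pvalue))
  out[[model]] <- list(jt_statistic = strat$test$statistic,
                       jt_pvalue = strat$test$pvalue,
                       n_low = length(strat$groups$low_auc),
                       n_high = length(strat$groups$high_auc))
}
jsonlite::write_json(out, file.path(RESULTS, "regainer_diagnostics.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
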