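#' Random gene sets for the empirical null
#'
#' Draws `n_sets` uniform without-replacement gene sets of size `set_size`
#' from the pool of genes with total reads strictly above `min_total_reads`
#' across all samples. Sets may overlap each other.
#'
#' @param counts Gene x sample integer matrix (unfiltered).
#' @param n_sets Number of sets (default 100).
#' @param set_size Genes per set (default 10).
#' @param min_total_reads Strict pool threshold (default 5).
#' @param seed Integer seed.
#' @return List of character vectors of gene ids.
#' @export
sample_random_genesets <- function(counts, n_sets = 100L, set_size = 10L,
                                   min_total_reads = 5, seed = 1L) {
  pool <- rownames(filter_low_counts(counts, min_total_reads))
  if (length(pool) < set_size)
    stop("filtered pool (", length(pool), ") smaller than set_size")
  with_seed(derive_seed(seed, "nullsets"), {
    lapply(seq_len(n_sets), function(i) sort(sample(pool, set_size)))
  })
}

#' Median AUCs of random-gene models
#'
#' Evaluates every random gene set with [run_model()] on the same resampling
#' plan as the focal signature (so AUC differences reflect features, not
#' splits) and returns each set's median AUC.
#'
#' @param bundle A `cohort_bundle`.
#' @param sets List of gene-id vectors from [sample_random_genesets()].
#' @param plan A [make_resamples()] plan.
#' @param config A [model_config()].
#' @param prepared Optional [prepare_runs()] output covering the union of all
#'   set genes; computed once here otherwise.
#' @return Numeric vector of per-set median AUCs.
#' @export
null_model_aucs <- function(bundle, sets, plan, config = model_config(),
                            prepared = NULL) {
  genes <- sort(unique(unlist(sets)))
  if (is.null(prepared)) prepared <- prepare_runs(bundle, plan, genes)
  vapply(sets, function(g) {
    ev <- .evaluate_genes(prepared, g, config)
    stats::median(ev$aucs, na.rm = TRUE)
  }, 1)
}

#' Empirical P-value against the random-gene null
#'
#' The fraction of null models whose median AUC is strictly greater than the
#' focal model's median AUC. No continuity correction is applied, so P can
#' be exactly 0 when the model beats every null set.
#'
#' @param model_median_auc Median AUC of the focal model.
#' @param null_medians Numeric vector of null-set median AUCs.
#' @return P in `[0, 1]`.
#' @export
empirical_pvalue <- function(model_median_auc, null_medians) {
  if (length(null_medians) == 0) stop("empty null ensemble")
  mean(null_medians > model_median_auc)
}
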