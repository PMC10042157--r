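# Shared study configuration for the analysis scripts.
#
# One global seed fans out to stage seeds through derive_seed(), so each
# numbered script can regenerate exactly the objects it needs without
# passing binary state around; everything re-derives from this file.

library(wlsig)

GLOBAL_SEED <- 20230324L

# Synthetic stand-in for the multicenter cohort: 281 participants across 8
# centers, three overlapping planted pathway modules (the lipid/virus pair
# sharing half the virus genes, plus a weaker mitosis-like module), and a
# 3,000-gene expression background (desk-scale stand-in for a genome-wide
# matrix).
study_config <- function() {
  synth_config(
    n_samples = 281L,
    n_genes = 3000L,
    n_centers = 8L,
    planted_modules = data.frame(
      name = c("lipid", "virus", "mitosis"),
      n_genes = c(20L, 10L, 15L),
      log2_effect = c(1, 1, 0.5)),
    module_overlap_fraction = 0.5,
    regainer_fraction = 0.2,
    seed = derive_seed(GLOBAL_SEED, "cohort"))
}

study_params <- function() {
  selection_params(class_keywords = list(Lipid = "lipid",
                                         Virus = "virus",
                                         Mitosis = "mitosis"))
}

study_plan <- function(bundle) {
  make_resamples(bundle$samples$sample_id, n_runs = 100L,
                 seed = derive_seed(GLOBAL_SEED, "plan"))
}

RESULTS <- "results"
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)
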