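#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure of a multicenter dietary
#' intervention cohort with baseline adipose-tissue RNA-seq: negative-binomial
#' counts with a gene-wise dispersion trend, multiplicative center (batch) and
#' sex effects, planted overlapping "pathway" modules whose expression differs
#' between weight-loss classes, weight trajectories with a low-calorie-diet
#' (LCD) loss phase and a maintenance phase containing a regainer
#' subpopulation, and weakly informative clinical covariates.
#'
#' @param n_samples Number of samples (default 281, the analysis cohort size).
#' @param n_genes Number of genes (default 5000; a desk-scale stand-in for a
#'   genome-wide matrix).
#' @param n_centers Number of study centers, used as batch levels (default 8).
#' @param planted_modules Data frame with columns `name`, `n_genes`,
#'   `log2_effect` giving, per planted module, its size and the log2
#'   expression shift of its genes in the high-WL class.
#' @param module_overlap_fraction Fraction of the second module's genes shared
#'   with the first (emulating the lipid/virus gene overlap). In `[0, 1]`.
#' @param regainer_fraction Fraction of high-loss samples whose maintenance
#'   phase reverses (weight at 8 months above weight at 2 months).
#' @param clinical_n_factors Number of clinical covariates (default 30).
#' @param clinical_n_informative How many clinical factors correlate with the
#'   weight-loss class (default 4).
#' @param clinical_r Target correlation of informative factors with class.
#' @param clinical_n_skewed How many clinical factors are right-skewed
#'   (log-normal; default 8). Exercises the skewness > 1 log-transform rule.
#' @param nb_dispersion_model Numeric `(a0, a1)`; gene dispersion is
#'   `a0 + a1 / mean`, an edgeR-style decreasing trend.
#' @param batch_sd Log2-scale SD of per-center, per-gene batch effects.
#' @param module_cor_sd Log2-scale SD of the latent per-sample module
#'   activity shared by a module's genes (default 0.8). Pathway genes are
#'   co-expressed beyond any class effect; this factor emulates that
#'   co-regulation, which the PCA-based gene selection relies on.
#' @param sex_effect_sd Log2-scale SD of per-gene sex effects.
#' @param libsize_sd Log-normal SD of per-sample library-size factors.
#' @param lcd_loss Per-class mean/SD of the 2-month LCD weight-loss percentage,
#'   list with `high = c(mean, sd)` and `low = c(mean, sd)`.
#' @param maint_change Per-class mean/SD of the maintenance-phase weight-loss
#'   percentage (baseline-weight denominator) for non-regainers.
#' @param regainer_change Mean/SD of the maintenance weight-loss percentage for
#'   the regainer mixture component (negative values mean regain).
#' @param seed Integer seed; the whole bundle is a deterministic function of
#'   the configuration including this seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_samples = 281L,
                         n_genes = 5000L,
                         n_centers = 8L,
                         planted_modules = data.frame(
                           name = c("lipid", "virus", "mitosis"),
                           n_genes = c(20L, 10L, 15L),
                           log2_effect = c(1, 1, 0.5)),
                         module_overlap_fraction = 0.5,
                         regainer_fraction = 0.2,
                         clinical_n_factors = 30L,
                         clinical_n_informative = 4L,
                         clinical_r = 0.3,
                         clinical_n_skewed = 8L,
                         nb_dispersion_model = c(0.05, 2),
                         batch_sd = 0.15,
                         module_cor_sd = 0.8,
                         sex_effect_sd = 0.1,
                         libsize_sd = 0.2,
                         lcd_loss = list(high = c(12.3, 2.9), low = c(10.0, 1.9)),
                         maint_change = list(high = c(4.0, 2.5), low = c(-4.2, 2.8)),
                         regainer_change = c(-3, 1.5),
                         seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    n_centers = as.integer(n_centers), planted_modules = planted_modules,
    module_overlap_fraction = module_overlap_fraction,
    regainer_fraction = regainer_fraction,
    clinical_n_factors = as.integer(clinical_n_factors),
    clinical_n_informative = as.integer(clinical_n_informative),
    clinical_r = clinical_r, clinical_n_skewed = as.integer(clinical_n_skewed),
    nb_dispersion_model = nb_dispersion_model, batch_sd = batch_sd,
    module_cor_sd = module_cor_sd,
    sex_effect_sd = sex_effect_sd, libsize_sd = libsize_sd,
    lcd_loss = lcd_loss, maint_change = maint_change,
    regainer_change = regainer_change, seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_samples < 20L) stop("n_samples must be >= 20")
  pm <- cfg$planted_modules
  if (!all(c("name", "n_genes", "log2_effect") %in% names(pm)))
    stop("planted_modules needs columns name, n_genes, log2_effect")
  if (anyDuplicated(pm$name)) stop("duplicate module names")
  if (any(pm$n_genes > cfg$n_genes))
    stop("a planted module is larger than n_genes")
  if (sum(pm$n_genes) > cfg$n_genes)
    stop("n_genes too small to host the requested modules")
  props <- c(cfg$module_overlap_fraction, cfg$regainer_fraction)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (!all(is.finite(pm$log2_effect))) stop("effect sizes must be finite")
  if (length(cfg$nb_dispersion_model) != 2L)
    stop("nb_dispersion_model must be (a0, a1)")
  if (cfg$nb_dispersion_model[1] <= 0)
    stop("dispersion intercept a0 must be positive")
  if (cfg$clinical_n_informative > cfg$clinical_n_factors)
    stop("more informative factors than factors")
  invisible(cfg)
}

# deterministic module -> gene id assignment, honouring the overlap between
# the first two modules
assign_module_genes <- function(cfg, gene_ids) {
  pm <- cfg$planted_modules
  out <- list()
  pool <- gene_ids
  take <- function(k) {
    picked <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    picked
  }
  for (i in seq_len(nrow(pm))) {
    if (i == 2L && nrow(pm) >= 2L) {
      n_shared <- round(cfg$module_overlap_fraction * pm$n_genes[2])
      n_shared <- min(n_shared, pm$n_genes[1])
      shared <- out[[pm$name[1]]][seq_len(n_shared)]
      fresh <- take(pm$n_genes[2] - n_shared)
      out[[pm$name[2]]] <- c(shared, fresh)
    } else {
      out[[pm$name[i]]] <- take(pm$n_genes[i])
    }
  }
  out
}

#' Generate a synthetic term-to-gene annotation
#'
#' Builds a flat gene-set annotation (the stand-in for a biological-process
#' ontology) over the configuration's gene universe: one dedicated term per
#' planted module, several high-similarity "sibling" terms per module
#' (Jaccard similarity at least 0.7 with the module term, exercising the
#' redundancy collapse), a few medium-similarity relatives (exercising map
#' edges), and random background terms, at least 50 terms in total with at
#' least 3 genes each. Term names embed the module name so keyword labeling
#' can recognise them.
#'
#' @param config A [synth_config()].
#' @return A `term_annotation` object (see [term_annotation()]).
#' @export
generate_annotation <- function(config) {
  validate_synth_config(config)
  gene_ids <- sprintf("g%05d", seq_len(config$n_genes))
  with_seed(derive_seed(config$seed, "annotation"), {
    modules <- assign_module_genes(config, gene_ids)
    terms <- list()
    term_names <- character()
    add <- function(id, nm, genes) {
      terms[[id]] <<- sort(unique(genes))
      term_names[id] <<- nm
    }
    ti <- 0L
    next_id <- function() {
      ti <<- ti + 1L
      sprintf("T%04d", ti)
    }
    for (m in names(modules)) {
      # annotation terms are larger than the planted effect set: real
      # gene-set terms carry many genes without differential expression,
      # and the dilution keeps two overlapping modules' term similarity
      # below the map's edge threshold (their components stay distinct)
      g <- c(modules[[m]],
             sample(setdiff(gene_ids, unlist(modules)),
                    ceiling(0.25 * length(modules[[m]]))))
      add(next_id(), sprintf("%s core process", m), g)
      # high-similarity siblings: drop ~10% of module genes, add one outsider
      for (s in 1:3) {
        n_drop <- max(0L, floor(length(g) * 0.1))
        kept <- if (n_drop > 0) g[-sample(length(g), n_drop)] else g
        extra <- sample(setdiff(gene_ids, g), 1L)
        add(next_id(), sprintf("%s related process %d", m, s), c(kept, extra))
      }
      # medium-similarity relatives: ~40% of module genes plus a modest
      # random fill (half the kept size), keeping the Jaccard with the core
      # term in the edge band [0.2, 0.7)
      for (s in 1:2) {
        kept <- sample(g, max(3L, ceiling(length(g) * 0.4)))
        fill <- sample(setdiff(gene_ids, g), ceiling(length(kept) / 2))
        add(next_id(), sprintf("%s adjacent pathway %d", m, s), c(kept, fill))
      }
    }
    n_bg <- max(50L - length(terms), 30L)
    for (s in seq_len(n_bg)) {
      sz <- sample(5:40, 1L)
      add(next_id(), sprintf("background process %d", s),
          sample(gene_ids, sz))
    }
    term_annotation(terms, term_names, universe = gene_ids)
  })
}

truncnorm1 <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

# weight trajectories for a class vector; returns data.frame(w0, w2, w8)
# plus the regainer assignment among high-loss samples
make_trajectories <- function(cfg, traj_class) {
  n <- length(traj_class)
  w0 <- truncnorm1(n, 100, 15, lower = 50)
  hi <- traj_class == "high"
  lcd <- numeric(n)
  lcd[hi] <- stats::rnorm(sum(hi), cfg$lcd_loss$high[1], cfg$lcd_loss$high[2])
  lcd[!hi] <- stats::rnorm(sum(!hi), cfg$lcd_loss$low[1], cfg$lcd_loss$low[2])
  maint <- numeric(n)
  maint[hi] <- stats::rnorm(sum(hi), cfg$maint_change$high[1], cfg$maint_change$high[2])
  maint[!hi] <- stats::rnorm(sum(!hi), cfg$maint_change$low[1], cfg$maint_change$low[2])
  regainer <- rep(FALSE, n)
  if (cfg$regainer_fraction > 0 && any(hi)) {
    idx <- which(hi)
    k <- round(cfg$regainer_fraction * length(idx))
    if (k > 0) {
      pick <- sample(idx, k)
      # regainers: maintenance change strictly negative (weight rises 2m -> 8m)
      m <- stats::rnorm(k, cfg$regainer_change[1], cfg$regainer_change[2])
      maint[pick] <- pmin(m, -0.1)
      regainer[pick] <- TRUE
    }
  } else if (cfg$regainer_fraction == 0) {
    # forced construction: nobody regains, so no above-median loser can
    maint <- pmax(maint, 0.1)
  }
  w2 <- w0 * (1 - lcd / 100)
  w8 <- w0 * (1 - (lcd + maint) / 100)
  list(w0 = w0, w2 = w2, w8 = w8, regainer = regainer)
}

make_clinical <- function(cfg, traj_class) {
  n <- length(traj_class)
  p <- cfg$clinical_n_factors
  ids <- sprintf("clin%02d", seq_len(p))
  informative <- ids[seq_len(cfg$clinical_n_informative)]
  skewed <- ids[seq(p, by = -1L, length.out = min(cfg$clinical_n_skewed, p))]
  z <- ifelse(traj_class == "high", 1, -1)
  z <- (z - mean(z)) / stats::sd(z)
  X <- matrix(NA_real_, n, p, dimnames = list(NULL, ids))
  r <- cfg$clinical_r
  for (j in seq_len(p)) {
    base <- if (ids[j] %in% informative)
      r * z + sqrt(1 - r^2) * stats::rnorm(n)
    else stats::rnorm(n)
    X[, j] <- if (ids[j] %in% skewed) exp(base) else base
  }
  list(table = X, informative = informative, skewed = skewed)
}

#' Generate a synthetic cohort bundle
#'
#' Draws a full cohort: NB counts whose log2 mean combines a gene baseline,
#' center batch effects, sex effects and a class effect on planted module
#' genes; weight trajectories whose overall weight-loss percentage correlates
#' with the expression-driving class; and a clinical covariate table. Ground
#' truth (module gene sets, the driving class, regainer ids, informative
#' clinical factors) travels with the bundle for parameter-recovery tests.
#'
#' @param config A [synth_config()].
#' @return A `cohort_bundle`: list with `counts` (genes x samples integer
#'   matrix), `samples` (data frame: sample_id, sex, age, center, weight_0m,
#'   weight_2m, weight_8m), `clinical` (sample x factor matrix) and `truth`.
#' @export
generate_cohort <- function(config) {
  .generate_bundle(config, null_trajectories = FALSE)
}

#' Generate a null cohort (trajectories independent of expression)
#'
#' Identical to [generate_cohort()] except that the weight trajectories are
#' driven by a class label drawn independently of the one shaping expression,
#' so any association between expression and weight-loss class is spurious.
#'
#' @param config A [synth_config()].
#' @return A `cohort_bundle`; `truth$independent_trajectories` is `TRUE`.
#' @export
generate_null_cohort <- function(config) {
  .generate_bundle(config, null_trajectories = TRUE)
}

.generate_bundle <- function(config, null_trajectories) {
  validate_synth_config(config)
  cfg <- config
  gene_ids <- sprintf("g%05d", seq_len(cfg$n_genes))
  sample_ids <- sprintf("s%04d", seq_len(cfg$n_samples))
  with_seed(derive_seed(cfg$seed, "cohort"), {
    modules <- assign_module_genes(cfg, gene_ids)

    n <- cfg$n_samples
    center <- sprintf("c%02d", rep_len(seq_len(cfg$n_centers), n))
    sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.65, 0.35))
    age <- round(stats::rnorm(n, 42, 6), 1)
    true_class <- sample(rep_len(c("high", "low"), n))

    base_log2 <- stats::rnorm(cfg$n_genes, 5, 1.8)
    sex_eff <- stats::rnorm(cfg$n_genes, 0, cfg$sex_effect_sd)
    batch_eff <- matrix(stats::rnorm(cfg$n_genes * cfg$n_centers, 0, cfg$batch_sd),
                        cfg$n_genes, cfg$n_centers,
                        dimnames = list(gene_ids, sprintf("c%02d", seq_len(cfg$n_centers))))
    class_eff <- numeric(cfg$n_genes)
    names(class_eff) <- gene_ids
    for (i in seq_len(nrow(cfg$planted_modules))) {
      m <- cfg$planted_modules$name[i]
      class_eff[modules[[m]]] <- class_eff[modules[[m]]] + cfg$planted_modules$log2_effect[i]
    }
    libfac <- exp(stats::rnorm(n, 0, cfg$libsize_sd))

    log2mu <- base_log2 +
      batch_eff[, center] +
      outer(sex_eff, as.numeric(sex == "M")) +
      outer(class_eff, as.numeric(true_class == "high"))
    # latent module activity: genes of one module share a per-sample factor,
    # giving the within-module co-expression the PCA selection exploits
    if (cfg$module_cor_sd > 0) {
      for (m in names(modules)) {
        activity <- stats::rnorm(n, 0, cfg$module_cor_sd)
        log2mu[modules[[m]], ] <- log2mu[modules[[m]], ] +
          matrix(activity, length(modules[[m]]), n, byrow = TRUE)
      }
    }
    mu <- sweep(2^log2mu, 2, libfac, `*`)
    disp <- cfg$nb_dispersion_model[1] + cfg$nb_dispersion_model[2] / pmax(2^base_log2, 1e-8)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = rep(1 / disp, n)),
                     cfg$n_genes, n, dimnames = list(gene_ids, sample_ids))
    storage.mode(counts) <- "integer"

    traj_class <- if (null_trajectories)
      sample(rep_len(c("high", "low"), n)) else true_class
    traj <- make_trajectories(cfg, traj_class)
    clin <- make_clinical(cfg, traj_class)

    samples <- data.frame(
      sample_id = sample_ids, sex = sex, age = age, center = center,
      weight_0m = traj$w0, weight_2m = traj$w2, weight_8m = traj$w8,
      stringsAsFactors = FALSE)
    clinical <- clin$table
    rownames(clinical) <- sample_ids

    truth <- list(
      module_gene_ids = modules,
      true_class = stats::setNames(true_class, sample_ids),
      trajectory_class = stats::setNames(traj_class, sample_ids),
      regainer_ids = sample_ids[traj$regainer],
      informative_clinical_ids = clin$informative,
      skewed_clinical_ids = clin$skewed,
      independent_trajectories = null_trajectories)

    bundle <- list(counts = counts, samples = samples, clinical = clinical,
                   truth = truth, config = cfg)
    class(bundle) <- "cohort_bundle"
    validate_bundle(bundle)
    bundle
  })
}

#' Validate a cohort bundle
#'
#' @param bundle A `cohort_bundle`.
#' @return `bundle`, invisibly.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  validate_counts(bundle$counts)
  s <- bundle$samples
  if (!identical(colnames(bundle$counts), s$sample_id))
    stop("sample ids of counts and metadata disagree")
  if (!is.null(bundle$clinical) &&
      !identical(rownames(bundle$clinical), s$sample_id))
    stop("sample ids of clinical table disagree")
  if (any(s$weight_0m <= 0 | s$weight_2m <= 0 | s$weight_8m <= 0))
    stop("weights must be strictly positive")
  if (!is.null(bundle$truth)) {
    tr <- bundle$truth
    if (!all(unlist(tr$module_gene_ids) %in% rownames(bundle$counts)))
      stop("truth module genes not in count matrix")
    if (!all(tr$regainer_ids %in% s$sample_id))
      stop("truth regainer ids not in sample table")
  }
  invisible(bundle)
}
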