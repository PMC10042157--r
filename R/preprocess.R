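#' Drop genes with low total counts
#'
#' Retains exactly the genes whose total read count across all samples is
#' strictly greater than `min_total` (the pipeline's default pool definition:
#' genes with more than 5 mapped reads across all samples). Gene order is
#' preserved.
#'
#' @param counts Gene x sample integer matrix.
#' @param min_total Strict lower bound on the per-gene total (default 5).
#' @return The filtered count matrix.
#' @export
filter_low_counts <- function(counts, min_total = 5) {
  validate_counts(counts)
  keep <- rowSums(counts) > min_total
  if (!any(keep)) stop("no gene exceeds min_total reads; empty matrix")
  counts[keep, , drop = FALSE]
}

#' TMM normalization factors
#'
#' Computes trimmed-mean-of-M-values scaling factors: per-sample log-ratios
#' against a reference sample are trimmed (30% on log-ratios, 5% on absolute
#' intensity), inverse-variance weighted and averaged; the reference is the
#' sample whose upper quartile of scaled counts is closest to the mean upper
#' quartile. Factors are rescaled so their geometric mean is 1. The
#' computation is delegated to the canonical implementation in edgeR.
#'
#' @param counts Gene x sample integer matrix.
#' @param ref_sample Optional sample id to use as reference; default picks the
#'   upper-quartile-closest-to-mean sample.
#' @param logratio_trim,sum_trim Trim fractions (defaults 0.3 and 0.05).
#' @return A data frame with `sample_id`, `lib_size`, `tmm_factor`; the
#'   factors have geometric mean 1 to within 1e-9.
#' @export
tmm_factors <- function(counts, ref_sample = NULL,
                        logratio_trim = 0.3, sum_trim = 0.05) {
  validate_counts(counts)
  f <- .tmm_core(counts, ref_sample, logratio_trim, sum_trim)
  data.frame(sample_id = colnames(counts),
             lib_size = as.numeric(colSums(counts)),
             tmm_factor = as.numeric(f), stringsAsFactors = FALSE)
}

# average ranks via a radix order; identical to rank() but faster on the
# long vectors inside the TMM loop
.fastrank <- function(x) {
  n <- length(x)
  o <- order(x, method = "radix")
  s <- x[o]
  new <- c(TRUE, s[-1] != s[-n])
  first <- which(new)
  last <- c(first[-1] - 1L, n)
  avg <- (first + last) / 2
  r <- numeric(n)
  r[o] <- avg[cumsum(new)]
  r
}

# vectorized TMM over all columns: per-column trimmed (30% on M, 5% on A),
# inverse-asymptotic-variance weighted mean of log-ratios against the
# reference column, factors rescaled to geometric mean 1. Accepts the
# fractional expected-adjusted matrices used internally.
.tmm_core <- function(counts, ref_sample = NULL,
                      logratio_trim = 0.3, sum_trim = 0.05) {
  lib <- colSums(counts)
  if (any(lib == 0)) {
    bad <- colnames(counts)[lib == 0]
    stop("sample(s) with all-zero counts: ", paste(bad, collapse = ", "))
  }
  x <- counts[rowSums(counts > 0) > 0, , drop = FALSE]
  if (!is.null(ref_sample)) {
    ref <- match(ref_sample, colnames(counts))
    if (is.na(ref)) stop("unknown ref_sample: ", ref_sample)
  } else {
    # reference: upper quartile of scaled counts closest to the mean
    uq <- apply(x, 2, stats::quantile, probs = 0.75) / lib
    ref <- which.min(abs(uq - mean(uq)))
  }
  rc <- x[, ref]
  nR <- lib[ref]
  f <- vapply(seq_len(ncol(x)), function(j) {
    obs <- x[, j]
    nO <- lib[j]
    M <- log2((obs / nO) / (rc / nR))
    A <- (log2(obs / nO) + log2(rc / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - rc) / nR / rc
    fin <- is.finite(M) & is.finite(A) & A > -1e10
    M <- M[fin]; A <- A[fin]; v <- v[fin]
    if (length(M) == 0 || max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * sum_trim) + 1;      hiS <- n + 1 - loS
    rM <- .fastrank(M)
    rA <- .fastrank(A)
    keep <- rM >= loL & rM <= hiL & rA >= loS & rA <= hiS
    out <- sum(M[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
    if (!is.finite(out)) out <- 0
    2^out
  }, 1)
  f / geomean(f)
}

#' Log2 counts-per-million with TMM-effective library sizes
#'
#' `value = log2((count + prior) / (lib_size * tmm_factor + 2 * prior) * 1e6)`.
#' The prior keeps zeros finite; the doubled prior in the denominator is the
#' usual log-CPM convention.
#'
#' @param counts Gene x sample matrix.
#' @param factors Data frame from [tmm_factors()], aligned with `counts`.
#' @param prior Prior count (default 0.5).
#' @return Real matrix of the same shape, all entries finite.
#' @export
lcpm_transform <- function(counts, factors, prior = 0.5) {
  if (!identical(colnames(counts), factors$sample_id))
    stop("sample sets of counts and factors do not align")
  eff <- factors$lib_size * factors$tmm_factor
  t(log2(t(counts + prior) / (eff + 2 * prior) * 1e6))
}

# moment dispersion of normalized counts, floored; used by the batch adjuster
# and exported through estimate_dispersion()
.moment_dispersion <- function(counts, sf, floor = 1e-8) {
  norm <- sweep(counts, 2, sf, `/`)
  n <- ncol(norm)
  m <- rowMeans(norm)
  v <- (rowSums(norm^2) - n * m^2) / (n - 1)
  pmax((v - m) / pmax(m^2, 1e-12), floor)
}

#' Remove center (batch) effects from a count matrix
#'
#' A simplified NB-quantile batch adjustment: for every gene a log-link
#' negative-binomial regression with batch indicators plus sex and age terms
#' is fitted (via edgeR's GLM machinery, with a moment dispersion estimate);
#' each observation is then quantile-mapped from its batch-specific fitted NB
#' distribution to the batch-free fitted NB whose batch term is replaced by
#' the sample-size-weighted average batch effect, preserving total signal up
#' to rounding. Sex, age and any biology encoded in the residuals are left in
#' place. This is a deliberately simple scheme with the same contract as the
#' ComBat-seq family of adjusters; recovery of planted batch effects is the
#' tested contract, not bit-equality with any external tool.
#'
#' @param counts Gene x sample integer matrix.
#' @param batch Character/factor vector of center ids, one per sample.
#' @param sex,age Optional covariate vectors preserved by the adjustment.
#' @return Non-negative integer matrix of identical shape and dimnames.
#' @export
batch_adjust_counts <- function(counts, batch, sex = NULL, age = NULL) {
  validate_counts(counts)
  batch <- as.factor(as.character(batch))
  if (length(batch) != ncol(counts)) stop("batch length mismatch")
  if (nlevels(batch) == 1L) return(counts)
  tab <- table(batch)
  if (any(tab < 2L))
    stop("batch level(s) with a single sample: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  bf <- .batch_fit(counts, batch, sex, age)
  # genes with (numerically) no batch component, and all-zero genes, pass
  # through untouched
  full <- counts
  active <- rownames(counts)[!bf$flat]
  full[active, ] <- .nb_quantile_map(counts, bf, active)
  dimnames(full) <- dimnames(counts)
  storage.mode(full) <- "integer"
  full
}

# gene-wise NB regression with batch indicators plus sex/age covariates;
# returns the fitted means with (mu_full) and without (mu_free) the
# gene-specific batch component, the dispersions, and the flat-gene mask
.batch_fit <- function(counts, batch, sex = NULL, age = NULL) {
  batch <- as.factor(as.character(batch))
  tab <- table(batch)
  covars <- NULL
  if (!is.null(sex)) covars <- cbind(covars, sexM = as.numeric(as.factor(sex)) - 1)
  if (!is.null(age)) covars <- cbind(covars, age = as.numeric(scale(age)))
  X <- stats::model.matrix(~ 0 + batch)
  if (!is.null(covars)) X <- cbind(X, covars)

  lib <- colSums(counts)
  sf <- lib / geomean(lib)
  disp <- .moment_dispersion(counts, sf)

  fit <- edgeR::glmFit(counts, design = X, dispersion = disp,
                       offset = log(lib), prior.count = 0.125)
  beta <- fit$coefficients                      # natural log scale
  bcols <- seq_len(nlevels(batch))
  w <- as.numeric(tab[levels(batch)]) / ncol(counts)
  beta_free <- beta
  avg <- beta[, bcols, drop = FALSE] %*% w      # weighted mean batch effect
  for (j in bcols) beta_free[, j] <- avg
  off <- matrix(log(lib), nrow(counts), ncol(counts), byrow = TRUE)
  mu_full <- exp(beta %*% t(X) + off)
  mu_free <- exp(beta_free %*% t(X) + off)
  dimnames(mu_full) <- dimnames(counts)
  dimnames(mu_free) <- dimnames(counts)
  dev <- abs(beta[, bcols, drop = FALSE] - as.numeric(avg))
  flat <- rowSums(!is.finite(dev)) > 0 |
    apply(dev, 1, function(z) max(z, na.rm = FALSE)) < 1e-10 |
    rowSums(counts) == 0
  flat[is.na(flat)] <- TRUE
  list(mu_full = mu_full, mu_free = mu_free, disp = disp, flat = flat)
}

# mid-p NB quantile map for the selected genes: monotone and roughly
# unbiased, mapping each observation from its batch-specific fitted NB to
# the batch-free fitted NB
.nb_quantile_map <- function(counts, bf, genes) {
  y <- counts[genes, , drop = FALSE]
  mu1 <- bf$mu_full[genes, , drop = FALSE]
  mu0 <- bf$mu_free[genes, , drop = FALSE]
  size <- matrix(1 / pmax(bf$disp[genes], 1e-8), length(genes), ncol(y))
  p_hi <- stats::pnbinom(y, mu = mu1, size = size)
  p_lo <- stats::pnbinom(y - 1, mu = mu1, size = size)
  u <- pmin(pmax((p_hi + p_lo) / 2, 1e-12), 1 - 1e-12)
  adj <- stats::qnbinom(u, mu = mu0, size = size)
  adj[adj == 0] <- 0          # qnbinom can emit negative zero at edge u
  dimnames(adj) <- dimnames(y)
  adj
}
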