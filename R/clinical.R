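#' Adjusted Fisher-Pearson skewness
#'
#' The adjusted (sample-size corrected) standardized third moment:
#' `g1 * sqrt(n (n-1)) / (n-2)` with `g1 = m3 / m2^(3/2)`.
#'
#' @param values Numeric vector, `n >= 3`, nonzero variance.
#' @return Skewness, or `NA` with a warning for zero variance.
#' @export
skewness <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 3L) stop("need at least 3 values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    warning("zero variance; skewness undefined")
    return(NA_real_)
  }
  g1 <- mean((x - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Log-transform highly skewed clinical factors
#'
#' Factors with `|skewness| > 1` are log_e-scaled. Flagged factors that are
#' not strictly positive are shifted by `1 - min` first (with a message).
#' Transformed flags are recorded so a second pass is a no-op.
#'
#' @param table Sample x factor numeric matrix.
#' @param flags Optional logical vector of already-transformed factors.
#' @return List with `table` (transformed), `skewness` (pre-transform),
#'   `transformed` (named logical).
#' @export
transform_skewed <- function(table, flags = NULL) {
  if (is.null(flags)) flags <- stats::setNames(rep(FALSE, ncol(table)),
                                               colnames(table))
  sk <- apply(table, 2, function(v) suppressWarnings(skewness(v)))
  out <- table
  done <- flags
  for (j in colnames(table)) {
    if (isTRUE(flags[j])) next
    if (!is.na(sk[j]) && abs(sk[j]) > 1) {
      v <- table[, j]
      if (min(v, na.rm = TRUE) <= 0) {
        message("factor ", j, " shifted before log transform")
        v <- v + 1 - min(v, na.rm = TRUE)
      }
      out[, j] <- log(v)
      done[j] <- TRUE
    }
  }
  list(table = out, skewness = sk, transformed = done)
}

#' Non-parametric sex/age adjustment of clinical factors
#'
#' Per factor: sex-stratum location/scale differences are removed by
#' median/MAD alignment (each stratum is mapped onto the pooled median and
#' MAD), and the linear age trend is residualized out; the overall median is
#' preserved. Strata with fewer than 3 samples leave the factor unadjusted
#' with a warning.
#'
#' @param table Sample x factor numeric matrix.
#' @param sex Character/factor vector, both sexes present.
#' @param age Numeric vector.
#' @return Adjusted matrix of identical shape.
#' @export
adjust_for_sex_age <- function(table, sex, age) {
  sex <- as.factor(as.character(sex))
  if (nlevels(sex) < 2L) stop("both sexes must be present")
  out <- table
  for (j in colnames(table)) {
    v <- table[, j]
    if (any(table(sex[!is.na(v)]) < 3L)) {
      warning("factor ", j, " left unadjusted (degenerate sex stratum)")
      next
    }
    pooled_med <- stats::median(v, na.rm = TRUE)
    pooled_mad <- stats::mad(v, na.rm = TRUE)
    w <- v
    for (lv in levels(sex)) {
      i <- sex == lv
      med <- stats::median(v[i], na.rm = TRUE)
      md <- stats::mad(v[i], na.rm = TRUE)
      if (md > 0 && pooled_mad > 0)
        w[i] <- (v[i] - med) / md * pooled_mad + pooled_med
      else w[i] <- v[i] - med + pooled_med
    }
    # residualize the linear age trend, keeping the overall median
    fitv <- stats::lm(w ~ age, na.action = stats::na.exclude)
    res <- stats::residuals(fitv)
    out[, j] <- res - stats::median(res, na.rm = TRUE) +
      stats::median(w, na.rm = TRUE)
  }
  out
}

#' Append standardized clinical factors to an expression feature matrix
#'
#' @param expr_features Samples x genes matrix (training or test features).
#' @param table Sample x factor clinical matrix aligned with the features.
#' @param factor_ids Factors to append (possibly none).
#' @param center,scale Optional training statistics for the appended columns;
#'   computed from `table` rows when NULL (training side).
#' @return List with `features` (augmented matrix), `center`, `scale`.
#' @export
augment_features <- function(expr_features, table, factor_ids,
                             center = NULL, scale = NULL) {
  if (length(factor_ids) == 0)
    return(list(features = expr_features, center = NULL, scale = NULL))
  if (!all(factor_ids %in% colnames(table))) stop("unknown clinical factors")
  if (!all(rownames(expr_features) %in% rownames(table)))
    stop("clinical table does not cover the feature samples")
  add <- table[rownames(expr_features), factor_ids, drop = FALSE]
  if (is.null(center)) {
    center <- colMeans(add, na.rm = TRUE)
    scale <- apply(add, 2, stats::sd, na.rm = TRUE)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  addz <- sweep(sweep(add, 2, center), 2, scale, `/`)
  list(features = cbind(expr_features, addz), center = center, scale = scale)
}

#' Paired comparison of two per-run AUC vectors
#'
#' Paired t-test on per-run AUC differences (`b - a`), plus a per-run
#' classification at the `delta` threshold: `unchanged` when `|diff| < delta`,
#' `improved` when `diff >= delta`, `worsened` when `diff <= -delta`.
#'
#' @param aucs_a,aucs_b Equal-length AUC vectors paired by run.
#' @param delta Classification threshold (default 0.1).
#' @return List with `statistic`, `pvalue`, `classification` (factor per run),
#'   `counts`.
#' @export
paired_auc_comparison <- function(aucs_a, aucs_b, delta = 0.1) {
  if (length(aucs_a) != length(aucs_b)) stop("unpaired AUC vectors")
  ok <- !is.na(aucs_a) & !is.na(aucs_b)
  if (sum(ok) < 2L) stop("need >= 2 paired runs")
  d <- aucs_b[ok] - aucs_a[ok]
  if (all(d == 0)) {
    tstat <- 0
    p <- 1
  } else {
    tt <- stats::t.test(aucs_b[ok], aucs_a[ok], paired = TRUE)
    tstat <- unname(tt$statistic)
    p <- tt$p.value
  }
  cls <- rep(NA_character_, length(aucs_a))
  dall <- aucs_b - aucs_a
  cls[ok] <- ifelse(abs(dall[ok]) < delta, "unchanged",
                    ifelse(dall[ok] >= delta, "improved", "worsened"))
  cls <- factor(cls, levels = c("unchanged", "improved", "worsened"))
  list(statistic = tstat, pvalue = p, classification = cls,
       counts = table(cls))
}

#' Baseline group-comparison table
#'
#' Group means and SDs of baseline variables by weight-loss class with
#' two-sided tests: Pearson chi-square (no continuity correction) for sex,
#' unpaired t-test for continuous variables; variables flagged as skewed
#' (`|skewness| > 1`) are log_e-transformed before testing, with the printed
#' means/SDs kept on the original scale.
#'
#' @param bundle A `cohort_bundle`.
#' @param labels Output of [assign_wl_labels()] over the bundle's samples.
#' @param variables Continuous variables to test; default: age plus all
#'   clinical factors.
#' @return Data frame: variable, mean_high, sd_high, mean_low, sd_low,
#'   statistic, pvalue, test, transformed.
#' @export
baseline_group_table <- function(bundle, labels, variables = NULL) {
  lab <- labels$labels[bundle$samples$sample_id]
  if (length(unique(stats::na.omit(lab))) < 2L)
    stop("both groups must be non-empty")
  hi <- !is.na(lab) & lab == "high"
  lo <- !is.na(lab) & lab == "low"

  vals <- cbind(age = bundle$samples$age, bundle$clinical)
  rownames(vals) <- bundle$samples$sample_id
  if (is.null(variables)) variables <- colnames(vals)

  rows <- list()
  # sex: 2x2 chi-square without continuity correction
  tab <- table(bundle$samples$sex, lab)
  cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  rows[["sex"]] <- data.frame(
    variable = "sex", mean_high = mean(bundle$samples$sex[hi] == "F") * 100,
    sd_high = NA_real_, mean_low = mean(bundle$samples$sex[lo] == "F") * 100,
    sd_low = NA_real_, statistic = unname(cs$statistic),
    pvalue = cs$p.value, test = "chi-square", transformed = FALSE,
    stringsAsFactors = FALSE)

  for (v in variables) {
    x <- vals[, v]
    sk <- suppressWarnings(skewness(x))
    tx <- x
    transformed <- FALSE
    if (!is.na(sk) && abs(sk) > 1) {
      if (min(x, na.rm = TRUE) <= 0) tx <- x + 1 - min(x, na.rm = TRUE)
      tx <- log(tx)
      transformed <- TRUE
    }
    if (stats::sd(tx[hi], na.rm = TRUE) == 0 &&
        stats::sd(tx[lo], na.rm = TRUE) == 0) next
    tt <- stats::t.test(tx[hi], tx[lo], var.equal = FALSE)
    rows[[v]] <- data.frame(
      variable = v, mean_high = mean(x[hi], na.rm = TRUE),
      sd_high = stats::sd(x[hi], na.rm = TRUE),
      mean_low = mean(x[lo], na.rm = TRUE),
      sd_low = stats::sd(x[lo], na.rm = TRUE),
      statistic = unname(tt$statistic), pvalue = tt$p.value,
      test = "t-test", transformed = transformed, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
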