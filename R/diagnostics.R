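#' Weight-trajectory statistics
#'
#' All percentages share the baseline-weight denominator, so the identity
#' `overall = LCD + maintenance` holds exactly: overall WL% =
#' `100 (w0 - w8) / w0`, LCD WL% = `100 (w0 - w2) / w0`, maintenance WL% =
#' `100 (w2 - w8) / w0`. A regainer is a sample losing more than the cohort
#' median overall while its maintenance WL% falls below `-regain_cut`
#' (default 4% of baseline weight regained between months 2 and 8).
#'
#' @param weights Data frame with `sample_id`, `weight_0m`, `weight_2m`,
#'   `weight_8m` (kg, strictly positive).
#' @param regain_cut Regain threshold in percent of baseline weight.
#' @return Data frame: sample_id, overall_wl, lcd_wl, maint_wl, regainer.
#' @export
trajectory_stats <- function(weights, regain_cut = 4) {
  w0 <- weights$weight_0m
  w2 <- weights$weight_2m
  w8 <- weights$weight_8m
  if (any(stats::na.omit(c(w0, w2, w8)) <= 0)) stop("weights must be positive")
  overall <- 100 * (w0 - w8) / w0
  lcd <- 100 * (w0 - w2) / w0
  maint <- 100 * (w2 - w8) / w0
  med <- stats::median(overall, na.rm = TRUE)
  regainer <- overall > med & maint < -regain_cut
  data.frame(sample_id = weights$sample_id, overall_wl = overall,
             lcd_wl = lcd, maint_wl = maint, regainer = regainer,
             stringsAsFactors = FALSE)
}

#' Pearson correlation with t-approximation P-value
#'
#' @param x,y Numeric vectors, `n >= 3`, nonzero variances.
#' @return List with `r`, `pvalue`, `n`.
#' @export
pearson_corr <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(list(r = NA_real_, pvalue = NA_real_, n = sum(ok)))
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), pvalue = ct$p.value, n = sum(ok))
}

# JT statistic over ordered groups: sum of pairwise Mann-Whitney counts with
# 0.5 credit for ties
.jt_stat <- function(groups) {
  k <- length(groups)
  s <- 0
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    xi <- groups[[i]]
    yj <- groups[[j]]
    s <- s + sum(outer(xi, yj, function(a, b) (a < b) + 0.5 * (a == b)))
  }
  s
}

# enumerate all assignments of pooled values to groups of the given sizes
.jt_exact_dist <- function(pooled, sizes) {
  out <- numeric(0)
  recurse <- function(avail, gs, acc) {
    if (length(gs) == 1L) {
      out[length(out) + 1L] <<- .jt_stat(c(acc, list(pooled[avail])))
      return(invisible())
    }
    combs <- utils::combn(avail, gs[1], simplify = FALSE)
    for (cb in combs)
      recurse(setdiff(avail, cb), gs[-1], c(acc, list(pooled[cb])))
  }
  recurse(seq_along(pooled), sizes, list())
  out
}

#' Jonckheere-Terpstra trend test over ordered groups
#'
#' The statistic is the sum over ordered group pairs of Mann-Whitney counts
#' (ties credited 0.5). For total `n <= exact_n` the P-value is computed by
#' full permutation enumeration; otherwise by normal approximation with tie
#' correction and a 0.5 continuity correction.
#'
#' @param groups List of numeric vectors in increasing group order.
#' @param alternative `"increasing"` (values rise with group order) or
#'   `"decreasing"`.
#' @param exact_n Exact-enumeration cutoff (default 12).
#' @return List with `statistic`, `pvalue`, `method`.
#' @export
jonckheere_terpstra <- function(groups,
                                alternative = c("increasing", "decreasing"),
                                exact_n = 12L) {
  alternative <- match.arg(alternative)
  if (length(groups) < 2L) stop("need at least 2 ordered groups")
  if (any(lengths(groups) == 0L)) stop("empty group")
  jt <- .jt_stat(groups)
  pooled <- unlist(groups)
  N <- length(pooled)
  if (N <= exact_n) {
    dist <- .jt_exact_dist(pooled, lengths(groups))
    p <- if (alternative == "increasing") mean(dist >= jt - 1e-9)
         else mean(dist <= jt + 1e-9)
    return(list(statistic = jt, pvalue = p, method = "exact"))
  }
  ns <- lengths(groups)
  ties <- table(pooled)
  mu <- (N^2 - sum(ns^2)) / 4
  t1 <- N * (N - 1) * (2 * N + 5) -
    sum(ns * (ns - 1) * (2 * ns + 5)) -
    sum(ties * (ties - 1) * (2 * ties + 5))
  t2 <- sum(ns * (ns - 1) * (ns - 2)) * sum(ties * (ties - 1) * (ties - 2))
  t3 <- sum(ns * (ns - 1)) * sum(ties * (ties - 1))
  v <- t1 / 72 + t2 / (36 * N * (N - 1) * (N - 2)) + t3 / (8 * N * (N - 1))
  if (v <= 0) return(list(statistic = jt, pvalue = 1, method = "normal"))
  z <- if (alternative == "increasing") (jt - mu - 0.5) / sqrt(v)
       else (jt - mu + 0.5) / sqrt(v)
  p <- if (alternative == "increasing")
    stats::pnorm(z, lower.tail = FALSE) else stats::pnorm(z)
  list(statistic = jt, pvalue = p, method = "normal")
}

#' Regainer burden of training sets, stratified by run AUC
#'
#' Counts how many regainer samples each run's training set contains and
#' splits the runs into two ordered groups (AUC at or below the threshold,
#' AUC above it). The Jonckheere-Terpstra test with the "decreasing"
#' alternative asks whether high-AUC runs trained on fewer regainers.
#'
#' @param aucs Named per-run AUC vector (names are run ids).
#' @param plan The [make_resamples()] plan that produced the runs.
#' @param regainer_ids Sample ids flagged as regainers.
#' @param threshold AUC stratification point (default 0.6).
#' @return List with `groups` (low-AUC counts, high-AUC counts), `test`
#'   (JT result, or NULL with `skipped = TRUE` when a stratum is empty or
#'   there are no regainers).
#' @export
stratify_runs_by_auc <- function(aucs, plan, regainer_ids, threshold = 0.6) {
  ok <- !is.na(aucs)
  counts <- vapply(names(aucs), function(rn)
    length(intersect(plan$runs[[rn]]$train, regainer_ids)), 1L)
  low <- counts[ok & aucs <= threshold]
  high <- counts[ok & aucs > threshold]
  if (length(low) == 0 || length(high) == 0 || length(regainer_ids) == 0 ||
      all(counts == 0)) {
    warning("degenerate stratification; trend test skipped")
    return(list(groups = list(low_auc = low, high_auc = high),
                test = NULL, skipped = TRUE))
  }
  test <- jonckheere_terpstra(list(low_auc = low, high_auc = high),
                              alternative = "decreasing")
  list(groups = list(low_auc = low, high_auc = high), test = test,
       skipped = FALSE)
}
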