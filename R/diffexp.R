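#' Design specification for the class comparison
#'
#' @param outcome Per-sample binary class ("high"/"low" weight loss); the log2
#'   fold change reported is high versus low.
#' @param sex,age,center Adjustment covariates (vectors aligned with samples).
#' @param alpha_nominal Nominal significance cutoff for the DEG set
#'   (default 0.01).
#' @return A `design_spec` object.
#' @export
design_spec <- function(outcome, sex = NULL, age = NULL, center = NULL,
                        alpha_nominal = 0.01) {
  outcome <- as.character(outcome)
  if (!all(outcome %in% c("high", "low")))
    stop("outcome must be 'high'/'low'")
  if (length(unique(outcome)) < 2L) stop("both classes must be present")
  if (alpha_nominal <= 0 || alpha_nominal >= 1)
    stop("alpha_nominal must lie in (0, 1)")
  structure(list(outcome = outcome, sex = sex, age = age, center = center,
                 alpha_nominal = alpha_nominal),
            class = "design_spec")
}

# design matrix: intercept, class (high=1), then covariates; center enters as
# fixed-effect indicators with the lexicographically first center as reference
.design_matrix <- function(design, n) {
  stopifnot(length(design$outcome) == n)
  df <- data.frame(class_high = as.numeric(design$outcome == "high"))
  if (!is.null(design$sex)) df$sexM <- as.numeric(as.factor(design$sex)) - 1
  if (!is.null(design$age)) df$age <- as.numeric(scale(design$age))
  X <- stats::model.matrix(~ ., df)
  if (!is.null(design$center)) {
    cen <- factor(as.character(design$center),
                  levels = sort(unique(as.character(design$center))))
    if (nlevels(cen) > 1L)
      X <- cbind(X, stats::model.matrix(~ cen)[, -1, drop = FALSE])
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is not full rank")
  X
}

# median-of-ratios size factors: ratio of each sample to the geometric-mean
# reference gene profile, median over genes expressed everywhere
.size_factors <- function(counts) {
  lgm <- rowMeans(log(counts))
  use <- is.finite(lgm)
  if (sum(use) < 10) {                     # sparse fallback: library sizes
    lib <- colSums(counts)
    return(lib / geomean(lib))
  }
  sf <- apply(exp(sweep(log(counts[use, , drop = FALSE]), 1, lgm[use])), 2,
              stats::median)
  sf / geomean(sf)
}

#' Per-gene NB dispersion estimates
#'
#' Method-of-moments dispersion on library-size-normalized counts, shrunk
#' toward a fitted mean-dispersion trend `a0 + a1/mean` (an edgeR-style
#' decreasing trend), floored at 1e-8. Shrinkage weight `w` is the weight of
#' the trend value.
#'
#' @param counts Gene x sample integer matrix.
#' @param design A [design_spec()] (only checked for class balance).
#' @param shrink Weight of the trend in the shrunk estimate (default 0.25).
#' @return Named numeric vector of per-gene dispersions, all >= 1e-8.
#' @export
estimate_dispersion <- function(counts, design = NULL, shrink = 0.25) {
  validate_counts(counts)
  if (!is.null(design) && min(table(design$outcome)) < 2L)
    stop("need at least 2 samples per class")
  lib <- colSums(counts)
  sf <- lib / geomean(lib)
  norm <- sweep(counts, 2, sf, `/`)
  n <- ncol(norm)
  m <- rowMeans(norm)
  v <- (rowSums(norm^2) - n * m^2) / (n - 1)
  mom <- pmax((v - m) / pmax(m^2, 1e-12), 1e-8)
  # fit the trend on informative genes only
  ok <- m > 1 & mom > 1e-6
  if (sum(ok) >= 10) {
    tf <- stats::lm(mom[ok] ~ I(1 / m[ok]))
    a0 <- max(stats::coef(tf)[1], 1e-4)
    a1 <- max(stats::coef(tf)[2], 0)
  } else {
    a0 <- stats::median(mom)
    a1 <- 0
  }
  trend <- a0 + a1 / pmax(m, 1e-8)
  out <- pmax((1 - shrink) * mom + shrink * trend, 1e-8)
  stats::setNames(out, rownames(counts))
}

# Wald statistics for the class coefficient from an edgeR GLM fit:
# SE from the observed Fisher information X' W X, W = mu / (1 + phi * mu).
# The per-gene information matrices are assembled in one matrix product
# (genes x design-pairs), then inverted gene by gene.
.wald_from_fit <- function(fit, X, disp, coef = "class_high") {
  j <- match(coef, colnames(X))
  G <- nrow(fit$coefficients)
  p <- ncol(X)
  beta <- fit$coefficients[, j]            # natural log
  mu <- fit$fitted.values
  W <- mu / (1 + matrix(disp, G, ncol(mu)) * mu)   # disp varies by gene (row)
  pairs <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  XX <- X[, pairs[, 1], drop = FALSE] * X[, pairs[, 2], drop = FALSE]
  IW <- W %*% XX                           # G x p(p+1)/2
  se <- rep(NA_real_, G)
  info <- matrix(0, p, p)
  for (g in seq_len(G)) {
    info[cbind(pairs[, 1], pairs[, 2])] <- IW[g, ]
    info[cbind(pairs[, 2], pairs[, 1])] <- IW[g, ]
    cv <- tryCatch(solve(info), error = function(e) NULL)
    if (!is.null(cv) && cv[j, j] > 0) se[g] <- sqrt(cv[j, j])
  }
  lfc <- beta / log(2)
  se2 <- se / log(2)
  z <- beta / se
  pv <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  data.frame(gene_id = rownames(fit$coefficients), lfc = lfc, se = se2,
             stat = z, pvalue = pv, stringsAsFactors = FALSE)
}

#' NB Wald test for a single gene
#'
#' Fits a log-link negative-binomial GLM (class + covariates, log effective
#' library size offsets) at a fixed dispersion and returns the two-sided Wald
#' test of the class coefficient.
#'
#' @param counts_g Integer vector of per-sample counts for one gene.
#' @param design A [design_spec()].
#' @param dispersion NB dispersion (1/size) for the gene.
#' @param offsets Log effective library sizes (default: log column totals are
#'   not available for a single gene, so offsets must be supplied).
#' @return List with `lfc` (log2), `se` (log2), `stat`, `pvalue`.
#' @export
nb_wald_test <- function(counts_g, design, dispersion, offsets) {
  n <- length(counts_g)
  X <- .design_matrix(design, n)
  y <- matrix(as.integer(round(counts_g)), 1, n,
              dimnames = list("gene", names(counts_g)))
  fit <- edgeR::glmFit(y, design = X, dispersion = dispersion,
                       offset = offsets, prior.count = 0)
  w <- .wald_from_fit(fit, X, dispersion)
  list(lfc = w$lfc, se = w$se, stat = w$stat, pvalue = w$pvalue)
}

#' Differential expression over all genes
#'
#' Applies [estimate_dispersion()] and the per-gene NB Wald test (class
#' adjusted for sex, age and center) to every gene of a filtered count
#' matrix. The significant set is `pvalue < alpha_nominal` — nominal, not
#' FDR-adjusted, as the DEG filter feeding enrichment.
#'
#' @param counts Gene x sample integer matrix (already low-count filtered).
#' @param design A [design_spec()].
#' @param shrink Dispersion shrinkage weight passed through.
#' @return Data frame: gene_id, lfc, se, stat, pvalue, significant.
#' @export
run_de <- function(counts, design, shrink = 0.25) {
  validate_counts(counts)
  X <- .design_matrix(design, ncol(counts))
  disp <- estimate_dispersion(counts, design, shrink = shrink)
  # median-of-ratios size factors as offsets (the convention of NB-GLM DE
  # tools): robust to composition differences between the classes
  sf <- .size_factors(counts)
  fit <- edgeR::glmFit(counts, design = X, dispersion = disp,
                       offset = log(sf * mean(colSums(counts))),
                       prior.count = 0)
  out <- .wald_from_fit(fit, X, disp)
  out$significant <- !is.na(out$pvalue) & out$pvalue < design$alpha_nominal
  rownames(out) <- NULL
  out
}
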