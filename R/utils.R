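#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed`, then restores
#' the caller's RNG state, so seeded helpers do not perturb the global stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage-specific child seed from a global seed
#'
#' One global seed fans out to per-stage seeds so that stages (simulation,
#' resampling, null sampling, ...) are independently reproducible. The
#' derivation is a fixed affine map modulo 2^31 - 1, keeping the result a
#' valid 32-bit integer seed.
#'
#' @param seed Integer global seed.
#' @param stage Character tag naming the stage.
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807) %% (m - 1) + 1)
}

# geometric mean of strictly positive values
geomean <- function(x) exp(mean(log(x)))

#' Validate a count matrix
#'
#' Checks the invariants every count-matrix consumer relies on: an integer-like
#' non-negative matrix with unique, non-empty gene and sample identifiers and
#' at least two samples.
#'
#' @param counts Numeric matrix, genes in rows, samples in columns.
#' @return `counts`, invisibly, after validation.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix (genes x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) stop("counts must be integers")
  invisible(counts)
}
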