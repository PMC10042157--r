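#' Default pathway-class keyword sets
#'
#' Keyword lists used to label enrichment-map components as Lipid, Mitosis or
#' Virus classes by case-insensitive substring match on term names. The
#' defaults transcribe the published descriptions of the three pathway
#' classes (fatty-acid metabolism, mitosis/meiosis, response to virus); they
#' also include the bare class names so synthetic module terms match.
#'
#' @return Named list of character keyword vectors.
#' @export
default_class_keywords <- function() {
  list(
    Lipid = c("lipid", "fatty acid metabolic process",
              "fatty acid derivative metabolic process",
              "long-chain fatty acid metabolic process",
              "fatty acid derivative biosynthetic process",
              "fatty-acyl-CoA biosynthetic process",
              "long-chain fatty acid biosynthetic process",
              "acyl-CoA metabolic process", "thioester metabolic process",
              "nucleoside bisphosphate metabolic process",
              "acyl-CoA biosynthetic process", "demethylation",
              "thioester biosynthetic process",
              "triglyceride biosynthetic process",
              "retinoic acid metabolic process", "retinol metabolic process",
              "steroid biosynthetic process", "xenobiotic metabolic process",
              "steroid metabolic process", "drug metabolic process",
              "regulation of lipid metabolic process",
              "ribose phosphate metabolic process"),
    Mitosis = c("mitosis", "meiotic sister chromatid cohesion",
                "meiotic sister chromatid segregation", "meiotic cell cycle",
                "chromosome segregation", "nuclear division",
                "sister chromatid segregation", "mitotic nuclear division",
                "chromosome localization", "mitotic cell cycle checkpoint",
                "chromosome condensation", "microtubule-based movement",
                "cytokinesis", "G2/M transition of mitotic cell cycle",
                "mitotic spindle assembly checkpoint",
                "cholesterol metabolic process", "hormone metabolic process"),
    Virus = c("virus", "response to virus",
              "negative regulation of viral genome replication",
              "defense response to virus", "estrogen metabolic process"))
}

#' Gene-selection parameters
#'
#' @param variance_threshold Cumulative explained-variance threshold choosing
#'   how many leading principal components count (default 0.70).
#' @param n_genes Signature size (default 10).
#' @param class_keywords Named list mapping class name to keyword vector; see
#'   [default_class_keywords()].
#' @param standardize Standardize genes before PCA (default TRUE).
#' @param weighted Use eigenvalue-weighted squared loadings as the
#'   contribution metric (default TRUE; FALSE sums unweighted squared
#'   loadings).
#' @return A `selection_params` object.
#' @export
selection_params <- function(variance_threshold = 0.70, n_genes = 10L,
                             class_keywords = default_class_keywords(),
                             standardize = TRUE, weighted = TRUE) {
  if (variance_threshold <= 0 || variance_threshold > 1)
    stop("variance_threshold must lie in (0, 1]")
  if (n_genes < 1L) stop("n_genes must be >= 1")
  structure(list(variance_threshold = variance_threshold,
                 n_genes = as.integer(n_genes),
                 class_keywords = class_keywords,
                 standardize = standardize, weighted = weighted),
            class = "selection_params")
}

#' Top PCA-contributing genes of a component
#'
#' Standardizes the genes (columns), runs PCA, takes the smallest set of
#' leading components whose cumulative explained variance reaches the
#' threshold, scores every gene by its eigenvalue-weighted squared loading
#' over those components (normalized to sum to 1), and returns the top
#' `n_genes` by contribution. Constant genes are dropped with a warning.
#'
#' @param expr Samples x genes real matrix (e.g. training log-CPM restricted
#'   to a component's gene union).
#' @param params A [selection_params()].
#' @return Character vector of gene ids, ranked by decreasing contribution,
#'   with attributes `contributions` (the full normalized contribution vector)
#'   and `n_dims` (number of components used).
#' @export
pca_top_contributors <- function(expr, params = selection_params()) {
  if (!is.matrix(expr) || nrow(expr) < 2L) stop("need >= 2 samples")
  if (anyNA(expr)) stop("missing values in expression matrix")
  sds <- apply(expr, 2, stats::sd)
  if (all(sds == 0)) stop("all genes constant")
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) dropped before PCA")
    expr <- expr[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(expr, center = TRUE, scale. = params$standardize)
  lambda <- pc$sdev^2
  cum <- cumsum(lambda) / sum(lambda)
  d <- which(cum >= params$variance_threshold)[1]
  L2 <- pc$rotation[, seq_len(d), drop = FALSE]^2
  contrib <- if (params$weighted)
    drop(L2 %*% lambda[seq_len(d)]) / sum(lambda[seq_len(d)])
  else rowSums(L2) / d
  contrib <- contrib / sum(contrib)
  ord <- order(-contrib, names(contrib))
  out <- names(contrib)[ord][seq_len(min(params$n_genes, length(contrib)))]
  attr(out, "contributions") <- contrib[ord]
  attr(out, "n_dims") <- d
  out
}

#' Label an enrichment-map component by keyword match
#'
#' Assigns the class whose keyword list matches the most component term names
#' (case-insensitive substring, fixed strings). Ties and zero matches give
#' `"unlabeled"`.
#'
#' @param component_term_names Character vector of term display names.
#' @param params A [selection_params()] carrying `class_keywords`.
#' @return A class name or `"unlabeled"`.
#' @export
label_component <- function(component_term_names, params = selection_params()) {
  if (length(component_term_names) == 0) stop("empty component")
  nm <- tolower(component_term_names)
  hits <- vapply(params$class_keywords, function(kw) {
    sum(vapply(nm, function(t)
      any(vapply(tolower(kw), function(k) grepl(k, t, fixed = TRUE), TRUE)),
      TRUE))
  }, 1L)
  if (all(hits == 0)) return("unlabeled")
  best <- which(hits == max(hits))
  if (length(best) > 1L) return("unlabeled")
  names(hits)[best]
}

#' Aggregate per-run gene selections into a signature
#'
#' The discovery frequency of a gene is the percentage of all runs (including
#' runs where the class was not discovered) in which it was selected. The
#' signature keeps the top `n_genes` by frequency; ties are broken by better
#' (smaller) mean within-run rank, then by gene id.
#'
#' @param per_run_selections Named list, run id -> character vector of genes
#'   selected in that run (ranked).
#' @param class_name Pathway-class label for the signature.
#' @param params A [selection_params()].
#' @param n_total_runs Total number of runs in the resampling design
#'   (default: number of entries in `per_run_selections`).
#' @return A `gene_signature`: list with `class_name`, `genes`,
#'   `frequencies` (percent), `mean_rank`, `provenance` (contributing run ids).
#' @export
aggregate_signature <- function(per_run_selections, class_name,
                                params = selection_params(),
                                n_total_runs = length(per_run_selections)) {
  sel <- per_run_selections[lengths(per_run_selections) > 0]
  if (length(sel) == 0) stop("no run contributed a selection")
  if (!is.numeric(n_total_runs) || length(n_total_runs) != 1L ||
      n_total_runs < 1)
    stop("n_total_runs must be a positive count")
  genes <- unique(unlist(sel))
  n_runs_feat <- vapply(genes, function(g)
    sum(vapply(sel, function(s) g %in% s, TRUE)), 1L)
  mean_rank <- vapply(genes, function(g) {
    r <- vapply(sel, function(s) match(g, s), 1L)
    mean(r, na.rm = TRUE)
  }, 1)
  freq <- 100 * n_runs_feat / n_total_runs
  ord <- order(-freq, mean_rank, genes)
  top <- seq_len(min(params$n_genes, length(genes)))
  structure(list(class_name = class_name,
                 genes = genes[ord][top],
                 frequencies = unname(freq[ord][top]),
                 mean_rank = unname(mean_rank[ord][top]),
                 provenance = names(sel)),
            class = "gene_signature")
}

#' Set-algebra combination of two signatures
#'
#' @param a,b `gene_signature` objects.
#' @param mode `"union"` (genes of either) or `"a_minus_b"` (genes of `a`
#'   absent from `b`).
#' @return A `gene_signature` with a concatenated class name. Frequencies are
#'   carried over from the source signatures (union: `a`'s value wins for
#'   shared genes).
#' @export
combine_signatures <- function(a, b, mode = c("union", "a_minus_b")) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "gene_signature"), inherits(b, "gene_signature"))
  if (length(a$genes) == 0 || length(b$genes) == 0)
    stop("both signatures must be non-empty")
  freq <- c(stats::setNames(a$frequencies, a$genes),
            stats::setNames(b$frequencies, b$genes))
  freq <- freq[!duplicated(names(freq))]
  if (mode == "union") {
    genes <- union(a$genes, b$genes)
    nm <- paste0(a$class_name, "+", b$class_name)
  } else {
    genes <- setdiff(a$genes, b$genes)
    nm <- paste0(a$class_name, "-", b$class_name)
    if (length(genes) == 0)
      warning("empty signature from ", nm)
  }
  structure(list(class_name = nm, genes = genes,
                 frequencies = unname(freq[genes]),
                 mean_rank = rep(NA_real_, length(genes)),
                 provenance = union(a$provenance, b$provenance)),
            class = "gene_signature")
}
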