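#' Flat term-to-gene annotation
#'
#' A minimal container for a gene-set annotation: a named list of term gene
#' sets, display names, and the background universe. Terms are flat gene sets
#' (no ontology DAG semantics).
#'
#' @param terms Named list, term_id -> character vector of gene ids.
#' @param term_names Named character vector, term_id -> display name.
#' @param universe Character vector of background gene ids.
#' @return A `term_annotation` object.
#' @export
term_annotation <- function(terms, term_names, universe) {
  if (length(terms) == 0) stop("no terms")
  if (is.null(names(terms)) || anyDuplicated(names(terms)))
    stop("terms must have unique names")
  if (any(lengths(terms) == 0)) stop("empty terms are not allowed")
  terms <- lapply(terms, function(g) sort(unique(as.character(g))))
  if (!all(unlist(terms) %in% universe))
    stop("term genes must be a subset of the universe")
  term_names <- term_names[names(terms)]
  structure(list(terms = terms, term_names = term_names,
                 universe = sort(unique(universe))),
            class = "term_annotation")
}

# restrict an annotation to a (sub-)universe, dropping terms left with < min
# genes; used to align the annotation with the filtered training gene pool
restrict_annotation <- function(annotation, universe, min_genes = 3L) {
  terms <- lapply(annotation$terms, function(g) intersect(g, universe))
  keep <- lengths(terms) >= min_genes
  if (!any(keep)) stop("no term survives restriction to the universe")
  term_annotation(terms[keep], annotation$term_names[keep], universe)
}

#' Upper-tail hypergeometric P-value
#'
#' `P = sum_{j=k}^{min(K,n)} C(K,j) C(N-K,n-j) / C(N,n)`: the probability of
#' observing at least `k` annotated genes in a selection of size `n` from a
#' universe of `N` genes of which `K` carry the term.
#'
#' @param k Observed overlap.
#' @param K Term size.
#' @param n Selection size.
#' @param N Universe size.
#' @return P-value in (0, 1].
#' @export
hypergeom_test <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 0) || any(k > pmin(K, n)) ||
      any(K > N) || any(n > N))
    stop("inconsistent hypergeometric counts")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted P-values
#'
#' Step-up q-values `q_i = min_{j >= i} (m * p_(j) / j)` clipped at 1,
#' returned in input order.
#'
#' @param pvalues Numeric vector of P-values in `[0, 1]`.
#' @return Numeric vector of q-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("P-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Term over-representation in a gene selection
#'
#' Tests every annotation term overlapping the selection (k >= 1) with the
#' upper-tail hypergeometric test against the annotation universe, adjusts by
#' Benjamini-Hochberg, and flags terms passing all three cutoffs: nominal
#' `P < p_cut`, `q < q_cut` (the enrichment tool's default gate) and
#' `q < fdr_cut` (the stricter FDR significance call). Selected genes outside
#' the universe are dropped with a message.
#'
#' @param selected Character vector of selected gene ids (e.g. the DEG set).
#' @param annotation A [term_annotation()].
#' @param p_cut,q_cut,fdr_cut Cutoffs (defaults 0.05, 0.2, 0.05).
#' @return Data frame: term_id, term_name, k, K, n, N, pvalue, qvalue,
#'   significant — one row per tested term, ordered by pvalue.
#' @export
enrich_terms <- function(selected, annotation,
                         p_cut = 0.05, q_cut = 0.2, fdr_cut = 0.05) {
  empty <- data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), pvalue = numeric(), qvalue = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  selected <- unique(as.character(selected))
  outside <- setdiff(selected, annotation$universe)
  if (length(outside) > 0) {
    message(length(outside), " selected gene(s) outside the universe dropped")
    selected <- setdiff(selected, outside)
  }
  if (length(selected) == 0) {
    warning("empty selection; empty enrichment table")
    return(empty)
  }
  N <- length(annotation$universe)
  n <- length(selected)
  k <- vapply(annotation$terms, function(g) length(intersect(g, selected)), 1L)
  K <- lengths(annotation$terms)
  tested <- k >= 1L
  if (!any(tested)) return(empty)
  p <- hypergeom_test(k[tested], K[tested], n, N)
  q <- bh_adjust(p)
  out <- data.frame(term_id = names(annotation$terms)[tested],
                    term_name = unname(annotation$term_names[tested]),
                    k = unname(k[tested]), K = unname(K[tested]), n = n, N = N,
                    pvalue = unname(p), qvalue = unname(q),
                    significant = unname(p < p_cut & q < q_cut & q < fdr_cut),
                    stringsAsFactors = FALSE)
  out[order(out$pvalue, out$term_id), , drop = FALSE]
}

#' Jaccard similarity of two gene sets
#'
#' @param a,b Non-empty character vectors of gene ids.
#' @return `|a intersect b| / |a union b|`, in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 || length(b) == 0) stop("empty gene set")
  length(intersect(a, b)) / length(union(a, b))
}

#' Build an enrichment map from significant terms
#'
#' Three steps over the significant terms of an enrichment table:
#' redundancy collapse — among pairs with Jaccard similarity >=
#' `redundancy_cut` the larger-P term is dropped (smaller P kept, ties broken
#' by lexicographic term_id), iterating until no redundant pair remains;
#' edges — retained term pairs with similarity >= `edge_cut` are connected;
#' components — connected components of that graph (singletons included),
#' each carrying its gene union and a class-label slot.
#'
#' Similarity is computed on each term's full annotated gene set.
#'
#' @param table Enrichment table from [enrich_terms()].
#' @param annotation The [term_annotation()] the table was computed against.
#' @param redundancy_cut Collapse threshold (default 0.7).
#' @param edge_cut Edge threshold (default 0.2).
#' @param use_significant Restrict to rows flagged significant (default TRUE).
#' @return An `enrichment_map`: list with `nodes` (data frame), `similarity`
#'   (matrix over retained terms), `edges` (data frame), `components` (list of
#'   term-id sets with `term_names`, `genes`, `label`).
#' @export
build_map <- function(table, annotation, redundancy_cut = 0.7, edge_cut = 0.2,
                      use_significant = TRUE) {
  tab <- if (use_significant) table[table$significant, , drop = FALSE] else table
  if (nrow(tab) == 0) {
    return(structure(list(nodes = tab, similarity = NULL,
                          edges = data.frame(), components = list()),
                     class = "enrichment_map"))
  }
  tab <- tab[order(tab$pvalue, tab$term_id), , drop = FALSE]
  ids <- tab$term_id
  sets <- annotation$terms[ids]
  sim <- outer(seq_along(ids), seq_along(ids),
               Vectorize(function(i, j) jaccard(sets[[i]], sets[[j]])))
  dimnames(sim) <- list(ids, ids)

  # redundancy collapse: repeatedly drop the worse term of the most redundant
  # pair; with rows pre-sorted by (P, id), dropping the later-sorted member of
  # any >= cut pair is order-independent
  keep <- rep(TRUE, length(ids))
  repeat {
    dropped <- FALSE
    for (i in seq_along(ids)) {
      if (!keep[i]) next
      for (j in seq_along(ids)) {
        if (j <= i || !keep[j]) next
        if (sim[i, j] >= redundancy_cut) {
          keep[j] <- FALSE
          dropped <- TRUE
        }
      }
    }
    if (!dropped) break
  }
  ids2 <- ids[keep]
  sim2 <- sim[ids2, ids2, drop = FALSE]

  pairs <- which(upper.tri(sim2) & sim2 >= edge_cut, arr.ind = TRUE)
  edges <- data.frame(from = ids2[pairs[, 1]], to = ids2[pairs[, 2]],
                      similarity = sim2[pairs], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = ids2))
  comp <- igraph::components(g)
  components <- lapply(seq_len(comp$no), function(ci) {
    members <- sort(names(comp$membership)[comp$membership == ci])
    list(term_ids = members,
         term_names = unname(annotation$term_names[members]),
         genes = sort(unique(unlist(annotation$terms[members]))),
         label = NA_character_)
  })
  # deterministic component order: by best member P, then first term id
  best_p <- vapply(components, function(co)
    min(tab$pvalue[tab$term_id %in% co$term_ids]), 1)
  components <- components[order(best_p,
                                 vapply(components, function(co) co$term_ids[1], ""))]
  structure(list(nodes = tab[keep, , drop = FALSE], similarity = sim2,
                 edges = edges, components = components),
            class = "enrichment_map")
}
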