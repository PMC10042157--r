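test_that("hypergeometric P equals exact rational enumeration", {
  # worked examples
  expect_equal(hypergeom_test(5, 5, 5, 10), 1 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(hypergeom_test(3, 5, 6, 20), hyper_oracle(3, 5, 6, 20),
               tolerance = 1e-12)
  expect_equal(hyper_oracle(3, 5, 6, 20), 0.13132, tolerance = 1e-4)
  expect_equal(hypergeom_test(0, 5, 6, 20), 1)
  # random instances, N <= 30
  set.seed(2)
  for (i in 1:200) {
    N <- sample(5:30, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_test(k, K, n, N), hyper_oracle(k, K, n, N),
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_test(6, 5, 6, 20), "inconsistent")
})

test_that("BH adjustment matches the step-up formula", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(6)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    # monotone in the input order of P
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("jaccard similarity follows the set definition", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a", "b"), c("c", "d")), 0)
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_error(jaccard(character(), "a"), "empty")
})

toy_annotation <- function() {
  uni <- sprintf("g%02d", 1:60)
  terms <- list(
    T1 = uni[1:10],                    # planted
    T2 = c(uni[1:9], uni[11]),         # redundant with T1 (J = 9/11)
    T3 = c(uni[1:4], uni[21:24]),      # edge-level similarity with T1
    T4 = uni[31:38],
    T5 = c(uni[31:36], uni[41:42]),    # redundant with T4 (J = 6/10)... below 0.7
    T6 = uni[45:50],
    T7 = c(uni[45:47], uni[51:53]),
    T8 = uni[55:60])
  term_annotation(terms, setNames(paste("term", 1:8), names(terms)), uni)
}

test_that("enrichment testing covers overlapping terms with the three cutoffs", {
  ann <- toy_annotation()
  sel <- sprintf("g%02d", 1:10)        # exactly the planted term
  tab <- enrich_terms(sel, ann)
  expect_equal(tab$term_id[1], "T1")   # minimum P by construction
  expect_equal(tab$pvalue[1], hyper_oracle(10, 10, 10, 60), tolerance = 1e-12)
  # term disjoint from the selection is not tested
  expect_false("T8" %in% tab$term_id)
  # selection = universe makes every P equal 1
  tab_all <- enrich_terms(ann$universe, ann)
  expect_true(all(abs(tab_all$pvalue - 1) < 1e-12))
  # empty selection warns and returns an empty table
  expect_warning(tab0 <- enrich_terms(character(), ann), "empty")
  expect_equal(nrow(tab0), 0)
  # genes outside the universe are dropped with a message
  expect_message(enrich_terms(c(sel, "zzz"), ann), "outside")
})

test_that("the enrichment map collapses redundant terms and finds components", {
  ann <- toy_annotation()
  tab <- enrich_terms(sprintf("g%02d", c(1:10, 31:38)), ann,
                      p_cut = 1, q_cut = 1.1, fdr_cut = 1.1)
  tab$significant <- TRUE
  map <- build_map(tab, ann)
  ids <- map$nodes$term_id
  # T2 (J = 9/11 with the better-P T1) is collapsed away
  expect_true("T1" %in% ids)
  expect_false("T2" %in% ids)
  # pair collapse keeps the smaller P
  two <- tab[tab$term_id %in% c("T1", "T2"), ]
  expect_lt(tab$pvalue[tab$term_id == "T1"], tab$pvalue[tab$term_id == "T2"])
  # components equal brute-force union-find on the thresholded similarity
  sets <- ann$terms[ids]
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && jaccard(sets[[i]], sets[[j]]) >= 0.2)
      parent[find(i)] <- find(j)
  }
  roots <- vapply(seq_len(n), find, 1L)
  want <- unname(lapply(split(ids, roots), sort))
  got <- unname(lapply(map$components, function(co) sort(co$term_ids)))
  expect_setequal(vapply(got, paste, "", collapse = ","),
                  vapply(want, paste, "", collapse = ","))
  # component gene union equals the union of member term genes
  for (co in map$components)
    expect_setequal(co$genes, unique(unlist(ann$terms[co$term_ids])))
})

test_that("map construction is invariant to the input term order", {
  ann <- toy_annotation()
  tab <- enrich_terms(sprintf("g%02d", c(1:10, 31:38, 45:47)), ann,
                      p_cut = 1, q_cut = 1.1, fdr_cut = 1.1)
  tab$significant <- TRUE
  m1 <- build_map(tab, ann)
  m2 <- build_map(tab[rev(seq_len(nrow(tab))), ], ann)
  expect_identical(m1$nodes$term_id, m2$nodes$term_id)
  expect_identical(lapply(m1$components, `[[`, "term_ids"),
                   lapply(m2$components, `[[`, "term_ids"))
})

test_that("three terms with pairwise similarity above the edge cut form one component", {
  uni <- sprintf("g%02d", 1:30)
  terms <- list(A = uni[1:8], B = uni[5:12], C = uni[9:16])
  ann <- term_annotation(terms, setNames(c("a", "b", "c"), names(terms)), uni)
  tab <- enrich_terms(uni[1:16], ann, p_cut = 1, q_cut = 1.1, fdr_cut = 1.1)
  tab$significant <- TRUE
  map <- build_map(tab, ann)
  expect_length(map$components, 1)
  expect_setequal(map$components[[1]]$term_ids, c("A", "B", "C"))
})
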