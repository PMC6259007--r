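net_from <- function(edges, labels) {
  p <- length(labels)
  W <- matrix(0, p, p, dimnames = list(labels, labels))
  for (e in edges) W[e[[1]], e[[2]]] <- W[e[[2]], e[[1]]] <- e[[3]]
  symptom_network(W, labels)
}

test_that("invariance statistics follow their definitions", {
  labs <- c("a", "b", "c")
  A <- net_from(list(list("a", "b", 0.5)), labs)
  B0 <- net_from(list(), labs)
  expect_equal(stat_structure(A, A), 0)
  expect_equal(stat_structure(A, B0), 0.5)
  expect_equal(stat_global_strength(A, A), 0)
  expect_equal(stat_global_strength(A, B0), 0.5)
  # sign flip leaves global strength unchanged
  Aneg <- net_from(list(list("a", "b", -0.5)), labs)
  expect_equal(stat_global_strength(Aneg, B0), 0.5)
  # signed cancellation distinguishes global EI from global strength
  AB <- net_from(list(list("a", "b", 0.3), list("b", "c", -0.3)), labs)
  expect_equal(stat_global_ei(AB, B0), 0)
  expect_equal(stat_global_strength(AB, B0), 0.6)
  A4 <- net_from(list(list("a", "b", 0.4)), labs)
  A1 <- net_from(list(list("a", "b", 0.1)), labs)
  expect_equal(stat_global_ei(A4, A1), 0.3)
  # brute-force elementwise maximum oracle on random pairs
  set.seed(29)
  for (r in 1:3) {
    W1 <- matrix(0, 5, 5); W2 <- matrix(0, 5, 5)
    W1[upper.tri(W1)] <- runif(10, -0.5, 0.5)
    W2[upper.tri(W2)] <- runif(10, -0.5, 0.5)
    W1 <- W1 + t(W1); W2 <- W2 + t(W2)
    n1 <- symptom_network(W1, letters[1:5])
    n2 <- symptom_network(W2, letters[1:5])
    m <- 0
    for (i in 1:4) for (j in (i + 1):5)
      m <- max(m, abs(W1[i, j] - W2[i, j]))
    expect_equal(stat_structure(n1, n2), m)
  }
  # all statistics are symmetric in the two groups
  expect_equal(stat_structure(A4, A1), stat_structure(A1, A4))
  expect_equal(stat_global_strength(A4, A1), stat_global_strength(A1, A4))
  expect_equal(stat_global_ei(A4, A1), stat_global_ei(A1, A4))
  # label mismatch errors
  expect_error(stat_structure(A, net_from(list(), c("a", "b", "d"))),
               "different node labels")
})

test_that("comparing a dataset with its copy is maximally non-significant", {
  spec <- preset_ptsd17("clinical", n = 120, seed = 83)
  d <- sample_ordinal(spec)
  res <- nct(d, d, iterations = 99, seed = 7, estimator = "unregularized")
  expect_equal(res$observed$M, 0)
  expect_equal(res$observed$S, 0)
  expect_equal(res$observed$global_ei, 0)
  expect_equal(res$p$M, 1)
  expect_equal(res$p$S, 1)
  expect_equal(res$p$global_ei, 1)
  expect_true(all(res$node_table$p == 1))
  # one p-value per node and per edge pair; M consistency
  expect_equal(nrow(res$node_table), 17L)
  expect_equal(nrow(res$edge_table), 17L * 16L / 2L)
  expect_equal(res$observed$M, max(res$observed$edges))
})

test_that("the permutation test is reproducible and supports both estimators", {
  spec <- preset_ptsd17("clinical", n = 150, seed = 89,
                        connectivity_scale = 0.5)
  g <- two_group_scenario(spec)
  r1 <- nct(g$a, g$b, iterations = 50, seed = 11, estimator = "unregularized")
  r2 <- nct(g$a, g$b, iterations = 50, seed = 11, estimator = "unregularized")
  expect_identical(r1$p, r2$p)
  expect_identical(r1$edge_table, r2$edge_table)
  # regularized estimator runs end to end through the same API
  r3 <- nct(g$a, g$b, iterations = 5, seed = 11, estimator = "regularized")
  expect_true(all(unlist(r3$p) > 0 & unlist(r3$p) <= 1))
  # holm adjustment is monotone on the none-adjusted p-values
  r4 <- nct(g$a, g$b, iterations = 50, seed = 11,
            estimator = "unregularized", edge_correction = "holm")
  expect_true(all(r4$edge_table$p >= r1$edge_table$p - 1e-12))
})

test_that("a node with strengthened edges is flagged by centrality invariance", {
  base <- preset_ptsd17("clinical", n = 500, seed = 1)
  P <- base$partials
  Pb <- P
  Pb["B1", ] <- Pb["B1", ] * 2
  Pb[, "B1"] <- t(Pb["B1", ])
  spec_a <- scenario_spec(Pb, thresholds = base$thresholds, n = 500,
                          items = base$items)
  spec_b <- scenario_spec(P, thresholds = base$thresholds, n = 500,
                          items = base$items)
  hits <- vapply(1:100, function(s) {
    da <- sample_ordinal(spec_a, seed = derive_seed(600, s))
    db <- sample_ordinal(spec_b, seed = derive_seed(700, s))
    tab <- centrality_invariance(da, db, iterations = 200,
                                 seed = derive_seed(800, s),
                                 estimator = "unregularized")
    tab$p[tab$node == "B1"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.70)
})

test_that("group balancing subsamples the larger group reproducibly", {
  spec <- preset_ptsd17("clinical", seed = 97)
  big <- sample_ordinal(spec, n = 912)
  small <- sample_ordinal(spec, n = 138, seed = 5)
  bal <- balance_groups(big, small, seed = 3)
  expect_equal(n_cases(bal$a), 138L)
  expect_equal(n_cases(bal$b), 138L)
  # the subsample consists of original cases
  key <- function(m) apply(m, 1, paste, collapse = ",")
  expect_true(all(key(bal$a$scores) %in% key(big$scores)))
  # reproducible
  bal2 <- balance_groups(big, small, seed = 3)
  expect_identical(bal$a$scores, bal2$a$scores)
  # order preserved when the second group is larger
  rev_bal <- balance_groups(small, big, seed = 3)
  expect_equal(n_cases(rev_bal$a), 138L)
  expect_equal(n_cases(rev_bal$b), 138L)
  expect_warning(balance_groups(small, small, seed = 1), "equal size")
})
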