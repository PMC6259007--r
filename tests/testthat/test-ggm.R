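test_that("pearson correlations match the direct sum formula", {
  x <- matrix(c(0, 1, 2, 3, 4,
                4, 3, 1, 2, 0,
                1, 1, 3, 0, 2), 5, 3)
  colnames(x) <- c("a", "b", "c")
  S <- suppressWarnings(cor_matrix(x))
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(S$values[i, j], direct_pearson(x[, i], x[, j]),
                 tolerance = 1e-12)
  expect_equal(diag(S$values), c(a = 1, b = 1, c = 1))
  # perfect dependence
  y <- cbind(a = x[, 1], b = x[, 1], c = 4 - x[, 1])
  Sy <- suppressWarnings(cor_matrix(y))
  expect_equal(Sy$values["a", "b"], 1)
  expect_equal(Sy$values["a", "c"], -1)
  # zero-variance item is named in the error
  z <- cbind(a = x[, 1], b = rep(2, 5))
  expect_error(suppressWarnings(cor_matrix(z)), "zero-variance item: b")
})

test_that("polychoric estimates recover known latent correlations", {
  thr <- qnorm(c(0.2, 0.45, 0.7, 0.9))
  set.seed(11)
  n <- 50000
  z1 <- rnorm(n)
  # independent pair
  z2 <- rnorm(n)
  x1 <- findInterval(z1, thr); x2 <- findInterval(z2, thr)
  expect_lt(abs(polychoric_correlation(x1, x2)), 0.02)
  # latent rho = 0.5
  z3 <- 0.5 * z1 + sqrt(1 - 0.25) * rnorm(n)
  x3 <- findInterval(z3, thr)
  expect_equal(polychoric_correlation(x1, x3), 0.5, tolerance = 0.02)
  # perfect concordance hits the solver cap
  expect_gte(polychoric_correlation(x1, x1), 0.99)
  # degenerate input
  expect_error(polychoric_correlation(rep(1, 10), rep(1, 10)),
               ">= 2 observed categories")
})

test_that("glasso at lambda 0 equals direct inversion and saturates at lambda max", {
  set.seed(3)
  for (p in c(4, 8)) {
    A <- matrix(rnorm(p * p), p)
    S <- cov2cor(crossprod(A) / p + diag(p))
    K <- glasso_fit(S, 0, tol = 1e-9)$K
    expect_lt(max(abs(K - solve(S))), 1e-6)
    # penalty saturation: empty network
    lmax <- max(abs(S[upper.tri(S)]))
    Ksat <- glasso_fit(S, lmax)$K
    expect_true(all(abs(Ksat[upper.tri(Ksat)]) < 1e-10))
  }
})

test_that("glasso agrees with an independent ADMM reference at moderate penalty", {
  # 4-variable chain graph
  P <- matrix(0, 4, 4)
  for (i in 1:3) P[i, i + 1] <- P[i + 1, i] <- 0.4
  K_true <- build_precision(P)
  S <- cov2cor(solve(K_true$K))
  for (lambda in c(0.05, 0.15)) {
    K_cd <- glasso_fit(S, lambda, tol = 1e-9)$K
    K_ref <- admm_glasso(S, lambda)
    expect_lt(max(abs(K_cd - K_ref)), 1e-4)
  }
})

test_that("partial correlations follow the precision-matrix formula", {
  K <- matrix(c(2, -1, -1, 2), 2)
  expect_equal(precision_to_partial(K)$weights[1, 2], 0.5)
  # diagonal K gives the empty network
  expect_true(all(precision_to_partial(diag(3) * 2)$weights == 0))
  # matches direct inversion route for a random PD matrix
  set.seed(7)
  A <- matrix(rnorm(36), 6)
  KK <- crossprod(A) / 6 + diag(6)
  net <- precision_to_partial(KK)
  expect_true(max(abs(net$weights)) <= 1)
  expect_equal(net$weights, t(net$weights))
  expect_error(precision_to_partial(matrix(c(-1, 0, 0, 1), 2)),
               "non-positive diagonal")
})

test_that("the EBIC formula matches direct arithmetic and its limits", {
  expect_equal(ebic(-123.4, 0, 50, 17, 0.5), 246.8)
  expect_equal(ebic(-100, 5, 100, 17, 0),
               200 + 5 * log(100))
  expect_equal(ebic(-100, 5, 100, 17, 0.5),
               200 + 5 * log(100) + 10 * log(17))
})

test_that("EBIC selection recovers a sparse generator and prunes null data", {
  # moderate chain graph: all true edges found, most true zeros kept at zero
  P <- matrix(0, 6, 6)
  for (i in 1:5) P[i, i + 1] <- P[i + 1, i] <- 0.18
  P[2, 5] <- P[5, 2] <- 0.18
  ut <- upper.tri(P)
  tru <- P[ut] != 0
  spec_rates <- vapply(1:5, function(s) {
    x <- sample_latent(P, n = 5000, seed = 20 + s)
    fit <- estimate_network(x)
    est <- fit$network$weights[ut] != 0
    expect_true(all(est[tru])) # every true edge detected
    mean(!est[!tru])
  }, numeric(1))
  expect_gte(mean(spec_rates), 0.80) # most true zeros exactly zero
  # independent items: empty selected network
  set.seed(22)
  x0 <- matrix(rnorm(5000 * 6), ncol = 6)
  fit0 <- estimate_network(x0)
  expect_equal(sum(fit0$network$weights != 0), 0)
  # determinism
  x <- sample_latent(P, n = 2000, seed = 29)
  expect_identical(estimate_network(x)$network$weights,
                   estimate_network(x)$network$weights)
})

test_that("edge count grows along the decreasing penalty path and the minimum is selected", {
  spec <- preset_ptsd17("clinical", n = 800, seed = 13)
  d <- sample_ordinal(spec)
  fit <- estimate_network(d)
  # E is near-monotone in lambda: the active set may shrink transiently by
  # an edge or two at adjacent path points, but the trend is strict
  E <- fit$ebic_path$E
  expect_equal(E[1], 0L) # empty network at lambda_max
  expect_true(all(diff(E) >= -2))
  # dips never undo more than a sliver of the growth
  expect_lte(max(cummax(E) - E), ceiling(0.05 * max(E)))
  expect_lt(mean(diff(E) < 0), 0.15)
  expect_gt(E[length(E)], 0.7 * max(E))
  expect_equal(fit$lambda_selected,
               fit$ebic_path$lambda[which.min(fit$ebic_path$ebic)])
  E_sel <- sum(fit$network$weights[upper.tri(fit$network$weights)] != 0)
  expect_equal(E_sel, fit$ebic_path$E[which.min(fit$ebic_path$ebic)])
})

test_that("estimated partials converge to the generator at large n", {
  P <- sparse6_partials()
  tn <- precision_to_partial(build_precision(P))
  x <- sample_latent(P, n = 20000, seed = 31)
  fit <- estimate_network(x)
  expect_lt(max(abs(fit$network$weights - tn$weights)), 0.05)
})

test_that("PSD repair is idempotent and bounded by its tolerance", {
  R <- matrix(c(1, 0.9, 0.3, 0.9, 1, 0.9, 0.3, 0.9, 1), 3) # indefinite
  expect_lt(min(eigen(R)$values), 0)
  r1 <- symptomnet:::repair_psd(R)
  expect_true(r1$repaired)
  expect_gte(min(eigen(r1$values)$values), 1e-10)
  r2 <- symptomnet:::repair_psd(r1$values)
  expect_lt(max(abs(r2$values - r1$values)), 1e-7)
  # PSD input untouched
  ok <- diag(3)
  expect_false(symptomnet:::repair_psd(ok)$repaired)
})

test_that("mean edge weight averages the upper triangle", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.3
  W[1, 3] <- W[3, 1] <- 0.1
  W[2, 3] <- W[3, 2] <- -0.2
  net <- symptom_network(W, letters[1:3])
  expect_equal(mean_edge_weight(net), 0.2 / 3, tolerance = 1e-12)
  expect_equal(mean_edge_weight(symptom_network(matrix(0, 3, 3),
                                                letters[1:3])), 0)
  # linearity under scaling
  net2 <- symptom_network(W * 2, letters[1:3])
  expect_equal(mean_edge_weight(net2), 2 * mean_edge_weight(net))
  # nonzero-only convention
  expect_equal(mean_edge_weight(net, nonzero_only = TRUE), 0.2 / 3)
})

test_that("the force-directed layout is seed-deterministic", {
  spec <- preset_ptsd17("clinical", n = 200, seed = 17)
  net <- unregularized_network(sample_ordinal(spec))
  xy1 <- layout_fruchterman_reingold(net, seed = 5)
  xy2 <- layout_fruchterman_reingold(net, seed = 5)
  expect_identical(xy1, xy2)
  expect_true(all(is.finite(xy1)))
  expect_identical(rownames(xy1), net$labels)
  # single node sits at the origin
  one <- symptom_network(matrix(0, 1, 1), "A")
  expect_equal(unname(layout_fruchterman_reingold(one)), matrix(0, 1, 2))
  # disconnected nodes never coincide
  disc <- symptom_network(matrix(0, 4, 4), letters[1:4])
  xyd <- layout_fruchterman_reingold(disc, seed = 2)
  expect_equal(anyDuplicated(round(xyd, 6)), 0L)
})
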