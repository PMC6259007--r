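fast_boot <- function(B, seed = 9, ...) bootstrap_config(B = B, seed = seed, ...)

test_that("edge bootstrap is reproducible and its CIs summarize the draws", {
  spec <- scenario_spec(sparse6_partials(), thresholds = rep(2, 6),
                        n = 600, seed = 61)
  d <- sample_ordinal(spec)
  b1 <- bootstrap_edges(d, fast_boot(40))
  b2 <- bootstrap_edges(d, fast_boot(40))
  expect_identical(b1$ci, b2$ci)
  expect_identical(b1$draws, b2$draws)
  # CI bounds are the empirical quantiles of the draws by construction
  k <- which(b1$ci$edge == "V1--V2")
  expect_equal(b1$ci$lower[k],
               unname(quantile(b1$draws[, "V1--V2"], 0.025)))
  expect_equal(b1$ci$upper[k],
               unname(quantile(b1$draws[, "V1--V2"], 0.975)))
  expect_true(all(b1$ci$lower <= b1$ci$upper))
})

test_that("a strong generator edge has a CI excluding zero", {
  P <- matrix(c(0, 0.4, 0.4, 0), 2)
  spec <- scenario_spec(P, thresholds = rep(2, 2), n = 2000, seed = 67)
  d <- sample_ordinal(spec)
  b <- bootstrap_edges(d, fast_boot(100), estimator = "unregularized")
  k <- which(b$ci$edge == "V1--V2")
  expect_gt(b$ci$lower[k], 0)
})

test_that("bootstrap replicate failures are retried, counted and capped", {
  # one item is almost constant: resamples frequently lose its variance
  set.seed(3)
  sc <- matrix(sample(0:4, 60 * 3, replace = TRUE), 60, 3)
  sc[, 3] <- 0L
  sc[1, 3] <- 1L
  d <- symptom_dataset(sc, items = c("a", "b", "c"))
  expect_error(bootstrap_edges(d, fast_boot(50, max_fail = 0.02)),
               "replicates failed")
})

test_that("case dropping respects the retained-n contract and redundancy", {
  spec <- scenario_spec(strong8_partials(), thresholds = rep(2, 8),
                        n = 40, seed = 71)
  d_small <- sample_ordinal(spec)
  # 75% drop of 40 cases retains 10 < p + 5 = 13: skipped with a warning
  expect_warning(
    st <- case_dropping(d_small, fast_boot(5, drop_proportions = c(0.1, 0.75)),
                        estimator = "unregularized"),
    "retained n < p \\+ 5")
  expect_equal(st$proportions, 0.1)
  # duplicated cases: half-sample centralities reproduce the full sample
  d <- sample_ordinal(spec, n = 4000)
  dup <- symptom_dataset(rbind(d$scores, d$scores), items = d$items)
  st2 <- case_dropping(dup, fast_boot(20, drop_proportions = 0.5),
                       estimator = "unregularized")
  med <- median(st2$correlations$expected_influence[1, ], na.rm = TRUE)
  expect_gt(med, 0.95)
})

test_that("the CS rule returns the largest prefix-satisfying proportion", {
  props <- seq(0.05, 0.75, by = 0.05)
  fake <- function(M) {
    structure(list(correlations = list(expected_influence = M),
                   proportions = props, config = bootstrap_config(B = ncol(M))),
              class = "stability_result")
  }
  # perfect stability: ceiling
  expect_equal(cs_coefficient(fake(matrix(1, 15, 40))), 0.75)
  # fails immediately: floor
  expect_equal(cs_coefficient(fake(matrix(0.2, 15, 40))), 0)
  # prefix rule: a dip at 0.30 caps CS at 0.25 even if later rows recover
  M <- matrix(1, 15, 40)
  M[6, ] <- 0.1
  expect_equal(cs_coefficient(fake(M)), 0.25)
})

test_that("stability never improves when the generator weakens", {
  css <- vapply(c(1, 0.5, 0.12), function(s) {
    spec <- scenario_spec(strong8_partials() * s, thresholds = rep(2, 8),
                          n = 3000, seed = 73)
    d <- sample_ordinal(spec)
    st <- case_dropping(d, fast_boot(25), estimator = "unregularized")
    cs_coefficient(st, "expected_influence")
  }, numeric(1))
  expect_true(all(diff(css) <= 0))
})

test_that("bootstrapped difference tests behave like a paired contrast", {
  P <- matrix(0, 3, 3)
  P[1, 2] <- P[2, 1] <- 0.5 # strong edge; V1--V3 absent
  spec <- scenario_spec(P, thresholds = rep(2, 3), n = 2000, seed = 79)
  d <- sample_ordinal(spec)
  b <- bootstrap_edges(d, fast_boot(100), estimator = "unregularized")
  # an element against itself: degenerate CI, not significant
  self <- difference_test(b, "V1--V2", "V1--V2")
  expect_equal(self$ci, c(0, 0))
  expect_false(self$significant)
  # strong edge vs absent edge: significant
  ab <- difference_test(b, "V1--V2", "V1--V3")
  expect_true(ab$significant)
  expect_gt(ab$ci[1], 0)
  # antisymmetry
  ba <- difference_test(b, "V1--V3", "V1--V2")
  expect_equal(ba$ci, -rev(ab$ci))
  expect_equal(ba$difference, -ab$difference)
  # centrality contrast runs on node labels
  ei <- difference_test(b, "V1", "V3", type = "expected_influence")
  expect_true(is.logical(ei$significant))
  # different runs are rejected
  b2 <- bootstrap_edges(d, fast_boot(100, seed = 10),
                        estimator = "unregularized")
  expect_error(difference_test(b, "V1--V2", "V1--V3", boot_b = b2),
               "different bootstrap runs")
})

test_that("edge CIs cover generator values at close to nominal rate", {
  P <- sparse6_partials()
  tn <- precision_to_partial(build_precision(P))
  ut <- upper.tri(tn$weights)
  truth <- tn$weights[ut]
  nsim <- 200
  covered <- 0L
  total <- 0L
  for (s in seq_len(nsim)) {
    x <- sample_latent(P, n = 500, seed = 8000 + s)
    colnames(x) <- paste0("V", 1:6)
    b <- bootstrap_edges(x, fast_boot(200, seed = 9000 + s))
    covered <- covered + sum(b$ci$lower <= truth & truth <= b$ci$upper)
    total <- total + length(truth)
  }
  expect_gte(covered / total, 0.85)
})
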