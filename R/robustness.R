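#' Bootstrap configuration
#'
#' @param B number of bootstrap replicates (study default 2000; tests use
#'   less).
#' @param seed random seed.
#' @param drop_proportions case-dropping proportions for stability analysis.
#' @param ci_level confidence level for edge-accuracy intervals.
#' @param cs_cor_threshold correlation retained by the CS-coefficient rule.
#' @param cs_probability required probability of retaining the correlation.
#' @param max_fail largest tolerated fraction of failed-and-retried
#'   replicates before erroring.
#' @return list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(B = 2000L, seed = 1L,
                             drop_proportions = seq(0.05, 0.75, by = 0.05),
                             ci_level = 0.95, cs_cor_threshold = 0.7,
                             cs_probability = 0.95, max_fail = 0.05) {
  stopifnot(B >= 1, all(drop_proportions > 0), all(drop_proportions < 0.95),
            ci_level > 0, ci_level < 1,
            cs_cor_threshold > 0, cs_cor_threshold < 1,
            cs_probability > 0, cs_probability < 1)
  structure(list(B = as.integer(B), seed = as.integer(seed),
                 drop_proportions = sort(drop_proportions),
                 ci_level = ci_level, cs_cor_threshold = cs_cor_threshold,
                 cs_probability = cs_probability, max_fail = max_fail),
            class = "bootstrap_config")
}

# shared estimator dispatch for resampling machinery
fit_network_matrix <- function(x, estimator, ...) {
  if (estimator == "regularized") estimate_network(x, ...)$network
  else unregularized_network(x, ...)
}

# resampling machinery accepts either a symptom_dataset or a numeric matrix
scores_of <- function(data) {
  if (inherits(data, "symptom_dataset")) return(data$scores)
  x <- as.matrix(data)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  x
}

#' Edge-weight accuracy bootstrap
#'
#' Non-parametric bootstrap of the full estimation pipeline: cases are
#' resampled with replacement, the network re-estimated, and per-edge
#' bootstrap distributions summarized as quantile confidence intervals.
#' Node expected influence and strength are recorded per replicate as well,
#' so [difference_test()] can compare either edges or centralities.
#' Replicates in which estimation fails (e.g. a constant item after
#' resampling) are retried with a fresh resample; retries are counted and
#' capped at `max_fail * B`.
#'
#' @param data a [symptom_dataset()].
#' @param boot a [bootstrap_config()].
#' @param estimator `"regularized"` (EBIC graphical lasso) or
#'   `"unregularized"`.
#' @param ... further arguments to [estimate_network()] /
#'   [unregularized_network()].
#' @return object of class `edge_bootstrap` with the point estimates, the
#'   per-replicate draws, and a `ci` data frame (one row per node pair:
#'   `estimate`, `boot_mean`, `lower`, `upper`).
#' @export
bootstrap_edges <- function(data, boot = bootstrap_config(),
                            estimator = c("regularized", "unregularized"),
                            ...) {
  stopifnot(inherits(boot, "bootstrap_config"))
  estimator <- match.arg(estimator)
  x <- scores_of(data)
  n <- nrow(x)
  full <- fit_network_matrix(x, estimator, ...)
  ed <- edge_pairs(full)
  enames <- edge_label(ed$node_i, ed$node_j)
  ut <- upper.tri(full$weights)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(boot$seed)
  B <- boot$B
  draws <- matrix(NA_real_, B, length(enames),
                  dimnames = list(NULL, enames))
  ei_draws <- str_draws <- matrix(NA_real_, B, n_nodes(full),
                                  dimnames = list(NULL, full$labels))
  failures <- 0L
  max_failures <- ceiling(boot$max_fail * B)
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      net <- tryCatch(fit_network_matrix(x[idx, , drop = FALSE],
                                         estimator, ...),
                      error = function(e) NULL)
      if (!is.null(net)) break
      failures <- failures + 1L
      if (failures > max_failures)
        stop_validation("more than %d bootstrap replicates failed",
                        max_failures)
    }
    draws[b, ] <- net$weights[ut]
    ei_draws[b, ] <- expected_influence(net)
    str_draws[b, ] <- node_strength(net)
  }
  alpha <- (1 - boot$ci_level) / 2
  ci <- data.frame(edge = enames, node_i = ed$node_i, node_j = ed$node_j,
                   estimate = ed$weight,
                   boot_mean = colMeans(draws),
                   lower = apply(draws, 2, quantile, probs = alpha),
                   upper = apply(draws, 2, quantile, probs = 1 - alpha),
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(list(network = full, ci = ci, draws = draws,
                 ei_point = expected_influence(full), ei_draws = ei_draws,
                 strength_point = node_strength(full),
                 strength_draws = str_draws,
                 estimator = estimator, config = boot, failures = failures,
                 run_id = sprintf("boot-%d-%d-%d", boot$seed, B, n)),
            class = "edge_bootstrap")
}

#' Case-dropping stability bootstrap
#'
#' Repeatedly drops a proportion of cases (subsampling without replacement),
#' re-estimates the network, and correlates the subsample centralities with
#' the full-sample centralities, for each drop proportion and each of the
#' four centrality indices. Proportions whose retained subsample would be
#' smaller than p + 5 cases are skipped with a warning. Replicates with a
#' constant centrality vector (correlation undefined) are recorded as
#' missing.
#'
#' @inheritParams bootstrap_edges
#' @return object of class `stability_result`: per-index matrices of
#'   bootstrap correlations (proportions x replicates), the proportions, and
#'   the per-index CS-coefficients.
#' @export
case_dropping <- function(data, boot = bootstrap_config(),
                          estimator = c("regularized", "unregularized"),
                          ...) {
  stopifnot(inherits(boot, "bootstrap_config"))
  estimator <- match.arg(estimator)
  x <- scores_of(data)
  n <- nrow(x)
  p <- ncol(x)
  full <- fit_network_matrix(x, estimator, ...)
  full_cent <- list(strength = node_strength(full),
                    expected_influence = expected_influence(full),
                    closeness = closeness_centrality(full),
                    betweenness = betweenness_centrality(full))
  props <- boot$drop_proportions
  retained <- round((1 - props) * n)
  usable <- retained >= p + 5
  if (!all(usable))
    warning(sprintf("skipping drop proportion(s) %s: retained n < p + 5",
                    paste(props[!usable], collapse = ", ")), call. = FALSE)
  props <- props[usable]
  retained <- retained[usable]
  B <- boot$B
  cors <- lapply(full_cent, function(.)
    matrix(NA_real_, length(props), B,
           dimnames = list(sprintf("%.2f", props), NULL)))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(boot$seed)
  failures <- 0L
  max_failures <- ceiling(boot$max_fail * B * max(1, length(props)))
  for (k in seq_along(props)) {
    m <- retained[k]
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, m, replace = FALSE)
        net <- tryCatch(fit_network_matrix(x[idx, , drop = FALSE],
                                           estimator, ...),
                        error = function(e) NULL)
        if (!is.null(net)) break
        failures <- failures + 1L
        if (failures > max_failures)
          stop_validation("more than %d case-dropping replicates failed",
                          max_failures)
      }
      sub_cent <- list(strength = node_strength(net),
                       expected_influence = expected_influence(net),
                       closeness = closeness_centrality(net),
                       betweenness = betweenness_centrality(net))
      for (ix in names(cors)) {
        a <- full_cent[[ix]]; s <- sub_cent[[ix]]
        cors[[ix]][k, b] <- if (sd(a) == 0 || sd(s) == 0) NA_real_ else
          cor(a, s)
      }
    }
  }
  res <- structure(list(correlations = cors, proportions = props,
                        full_centrality = full_cent, config = boot,
                        estimator = estimator, failures = failures),
                   class = "stability_result")
  res$cs <- vapply(names(cors), function(ix) cs_coefficient(res, ix),
                   numeric(1))
  res
}

#' Correlation-stability (CS) coefficient
#'
#' The largest drop proportion at which the subsample centralities still
#' correlate at least `cs_cor_threshold` (default 0.7) with the full-sample
#' centralities with probability `cs_probability` (default 0.95) — evaluated
#' as the empirical 5th percentile of the bootstrap correlations staying at
#' or above the threshold. Proportions are scanned in increasing order and
#' the largest prefix-satisfying proportion is returned; 0 if the condition
#' already fails at the smallest proportion.
#'
#' @param stability a `stability_result` from [case_dropping()].
#' @param index one of `"strength"`, `"expected_influence"`, `"closeness"`,
#'   `"betweenness"`.
#' @return CS-coefficient (a drop proportion, or 0).
#' @export
cs_coefficient <- function(stability, index = "expected_influence") {
  stopifnot(inherits(stability, "stability_result"))
  if (!index %in% names(stability$correlations))
    stop_validation("unknown centrality index '%s'", index)
  cfg <- stability$config
  M <- stability$correlations[[index]]
  cs <- 0
  for (k in seq_along(stability$proportions)) {
    q <- if (all(is.na(M[k, ]))) NA_real_ else
      quantile(M[k, ], probs = 1 - cfg$cs_probability, na.rm = TRUE,
               names = FALSE, type = 7)
    if (is.na(q) || q < cfg$cs_cor_threshold) break
    cs <- stability$proportions[k]
  }
  cs
}

#' Bootstrapped difference test
#'
#' Tests whether two elements of the same bootstrap run — two edges, or two
#' node centralities — differ, by forming the bootstrap distribution of
#' their difference and checking whether the quantile interval excludes
#' zero. No multiple-testing correction is applied, mirroring the source
#' methodology of this literature; interpret accordingly.
#'
#' @param boot an `edge_bootstrap` from [bootstrap_edges()].
#' @param element_a,element_b edge labels (`"B1--B2"`) for `type = "edge"`,
#'   node labels otherwise.
#' @param type `"edge"`, `"expected_influence"` or `"strength"`.
#' @param ci_level confidence level (default the bootstrap config's level).
#' @param boot_b optional second bootstrap object for `element_b`; must be
#'   the same run as `boot` (same data, seed and size), otherwise an error.
#' @return list with `difference` (point estimate), `ci`, `significant`.
#' @export
difference_test <- function(boot, element_a, element_b,
                            type = c("edge", "expected_influence", "strength"),
                            ci_level = NULL, boot_b = NULL) {
  stopifnot(inherits(boot, "edge_bootstrap"))
  type <- match.arg(type)
  if (!is.null(boot_b)) {
    stopifnot(inherits(boot_b, "edge_bootstrap"))
    if (!identical(boot_b$run_id, boot$run_id))
      stop_validation("elements come from different bootstrap runs")
  } else boot_b <- boot
  ci_level <- ci_level %||% boot$config$ci_level
  get_elem <- function(bt, el) {
    switch(type,
      edge = {
        cn <- colnames(bt$draws)
        el2 <- paste(rev(strsplit(el, "--", fixed = TRUE)[[1]]),
                     collapse = "--")
        hit <- if (el %in% cn) el else if (el2 %in% cn) el2 else
          stop_validation("unknown edge '%s'", el)
        list(point = bt$ci$estimate[match(hit, bt$ci$edge)],
             draws = bt$draws[, hit])
      },
      expected_influence = {
        if (!el %in% colnames(bt$ei_draws))
          stop_validation("unknown node '%s'", el)
        list(point = unname(bt$ei_point[el]), draws = bt$ei_draws[, el])
      },
      strength = {
        if (!el %in% colnames(bt$strength_draws))
          stop_validation("unknown node '%s'", el)
        list(point = unname(bt$strength_point[el]),
             draws = bt$strength_draws[, el])
      })
  }
  a <- get_elem(boot, element_a)
  b <- get_elem(boot_b, element_b)
  d <- a$draws - b$draws
  alpha <- (1 - ci_level) / 2
  ci <- unname(quantile(d, probs = c(alpha, 1 - alpha)))
  list(difference = a$point - b$point, ci = ci,
       significant = ci[1] > 0 || ci[2] < 0)
}
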