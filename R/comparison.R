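#' Network structure invariance statistic
#'
#' The largest absolute edge-weight difference between two networks on the
#' same nodes, `M = max_{i<j} |w_ij^A - w_ij^B|`.
#'
#' @param net_a,net_b [symptom_network()]s with identical node labels.
#' @return the statistic `M`.
#' @export
stat_structure <- function(net_a, net_b) {
  check_same_labels(net_a, net_b)
  max(abs(net_a$weights - net_b$weights))
}

#' Global strength invariance statistic
#'
#' Absolute difference in overall connectivity, connectivity being the sum
#' of all absolute edge weights:
#' `S = | sum_{i<j} |w^A_ij| - sum_{i<j} |w^B_ij| |`.
#'
#' @inheritParams stat_structure
#' @return the statistic `S`.
#' @export
stat_global_strength <- function(net_a, net_b) {
  check_same_labels(net_a, net_b)
  ut <- upper.tri(net_a$weights)
  abs(sum(abs(net_a$weights[ut])) - sum(abs(net_b$weights[ut])))
}

#' Global expected influence statistic
#'
#' Like global strength invariance but on signed edge sums — positive and
#' negative edges may cancel:
#' `| sum_{i<j} w^A_ij - sum_{i<j} w^B_ij |`.
#'
#' @inheritParams stat_structure
#' @return the statistic.
#' @export
stat_global_ei <- function(net_a, net_b) {
  check_same_labels(net_a, net_b)
  ut <- upper.tri(net_a$weights)
  abs(sum(net_a$weights[ut]) - sum(net_b$weights[ut]))
}

check_same_labels <- function(net_a, net_b) {
  stopifnot(inherits(net_a, "symptom_network"),
            inherits(net_b, "symptom_network"))
  if (!identical(net_a$labels, net_b$labels))
    stop_validation("networks have different node labels or node order")
  invisible(TRUE)
}

#' Permutation-based network comparison test
#'
#' Compares the symptom networks of two independent groups on structure
#' invariance (`M`, the maximum edge difference), global strength invariance
#' (`S`), global expected influence, per-edge differences and per-node
#' expected-influence differences. Cases are pooled and repeatedly
#' reassigned at random to groups of the original sizes; the full estimation
#' pipeline is re-run on each permuted split, and p-values are
#' `(1 + #{perm >= observed}) / (1 + iterations)`. Iterations in which
#' estimation fails (e.g. a constant item in a permuted group) are
#' resampled and counted.
#'
#' @param data_a,data_b [symptom_dataset()]s on the same items.
#' @param iterations number of permutations (default 1000).
#' @param seed random seed.
#' @param estimator `"regularized"` (EBIC graphical lasso) or
#'   `"unregularized"` (direct pseudo-inverse partial correlations).
#' @param edge_correction `"none"` (default, matching the conventions of
#'   this literature) or `"holm"` for the per-edge and per-node p-values.
#' @param ... further arguments to the network estimator.
#' @return object of class `comparison_result` with observed statistics,
#'   permutation p-values, per-edge and per-node tables, group sizes and the
#'   estimator used.
#' @export
nct <- function(data_a, data_b, iterations = 1000L, seed = 1L,
                estimator = c("regularized", "unregularized"),
                edge_correction = c("none", "holm"), ...) {
  stopifnot(iterations >= 1)
  estimator <- match.arg(estimator)
  edge_correction <- match.arg(edge_correction)
  xa <- scores_of(data_a)
  xb <- scores_of(data_b)
  if (!identical(colnames(xa), colnames(xb)))
    stop_validation("datasets measure different item sets")
  na <- nrow(xa); nb <- nrow(xb)
  pooled <- rbind(xa, xb)
  ntot <- na + nb

  net_a <- fit_network_matrix(xa, estimator, ...)
  net_b <- fit_network_matrix(xb, estimator, ...)
  ut <- upper.tri(net_a$weights)
  ed <- edge_pairs(net_a)
  enames <- edge_label(ed$node_i, ed$node_j)

  obs <- list(
    M = stat_structure(net_a, net_b),
    S = stat_global_strength(net_a, net_b),
    global_ei = stat_global_ei(net_a, net_b),
    edges = abs(net_a$weights - net_b$weights)[ut],
    nodes = abs(expected_influence(net_a) - expected_influence(net_b)))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cnt <- list(M = 0L, S = 0L, global_ei = 0L,
              edges = numeric(length(obs$edges)),
              nodes = numeric(length(obs$nodes)))
  failures <- 0L
  max_failures <- 5L * iterations
  it <- 0L
  while (it < iterations) {
    idx <- sample.int(ntot, na)
    pa <- tryCatch(fit_network_matrix(pooled[idx, , drop = FALSE],
                                      estimator, ...),
                   error = function(e) NULL)
    pb <- if (is.null(pa)) NULL else
      tryCatch(fit_network_matrix(pooled[-idx, , drop = FALSE],
                                  estimator, ...),
               error = function(e) NULL)
    if (is.null(pa) || is.null(pb)) {
      failures <- failures + 1L
      if (failures > max_failures)
        stop_validation("permutation estimation failed more than %d times",
                        max_failures)
      next
    }
    it <- it + 1L
    dW <- abs(pa$weights - pb$weights)[ut]
    eps <- 1e-12
    cnt$M <- cnt$M + (max(dW) >= obs$M - eps)
    cnt$S <- cnt$S + (stat_global_strength(pa, pb) >= obs$S - eps)
    cnt$global_ei <- cnt$global_ei +
      (stat_global_ei(pa, pb) >= obs$global_ei - eps)
    cnt$edges <- cnt$edges + (dW >= obs$edges - eps)
    dn <- abs(expected_influence(pa) - expected_influence(pb))
    cnt$nodes <- cnt$nodes + (dn >= obs$nodes - eps)
  }
  pval <- function(k) (1 + k) / (1 + iterations)
  p_edges <- pval(cnt$edges)
  p_nodes <- pval(cnt$nodes)
  if (edge_correction == "holm") {
    p_edges <- stats::p.adjust(p_edges, "holm")
    p_nodes <- stats::p.adjust(p_nodes, "holm")
  }
  structure(list(
    observed = obs,
    p = list(M = pval(cnt$M), S = pval(cnt$S),
             global_ei = pval(cnt$global_ei)),
    edge_table = data.frame(edge = enames, diff = obs$edges, p = p_edges,
                            stringsAsFactors = FALSE),
    node_table = data.frame(node = net_a$labels, diff = unname(obs$nodes),
                            p = unname(p_nodes), stringsAsFactors = FALSE),
    network_a = net_a, network_b = net_b,
    n = c(a = na, b = nb), iterations = as.integer(iterations),
    estimator = estimator, edge_correction = edge_correction,
    failures = failures, seed = seed),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison_result> n = (%d, %d), %d permutations, %s estimator\n",
    x$n["a"], x$n["b"], x$iterations, x$estimator))
  cat(sprintf("  structure invariance      M = %.4f  (p = %.4g)\n",
              x$observed$M, x$p$M))
  cat(sprintf("  global strength           S = %.4f  (p = %.4g)\n",
              x$observed$S, x$p$S))
  cat(sprintf("  global expected influence   = %.4f  (p = %.4g)\n",
              x$observed$global_ei, x$p$global_ei))
  invisible(x)
}

#' Per-node centrality invariance test
#'
#' Permutation test of per-node expected-influence differences between two
#' groups (same machinery as [nct()], reported per node).
#'
#' @inheritParams nct
#' @return data frame with `node`, observed `ei_a`, `ei_b`, `diff` and
#'   permutation `p`.
#' @export
centrality_invariance <- function(data_a, data_b, iterations = 1000L,
                                  seed = 1L,
                                  estimator = c("regularized",
                                                "unregularized"), ...) {
  res <- nct(data_a, data_b, iterations = iterations, seed = seed,
             estimator = estimator, ...)
  out <- res$node_table
  out$ei_a <- unname(expected_influence(res$network_a))
  out$ei_b <- unname(expected_influence(res$network_b))
  out[, c("node", "ei_a", "ei_b", "diff", "p")]
}

#' Balance two groups by subsampling the larger one
#'
#' Permutation comparison tests are unstable when group sizes differ
#' greatly; this draws a random subsample (without replacement) of the
#' larger group of the size of the smaller group. Seed-reproducible; equal
#' sizes are returned unchanged with a warning.
#'
#' @param data_a,data_b [symptom_dataset()]s.
#' @param seed subsampling seed.
#' @return list with elements `a` and `b` in the original order.
#' @export
balance_groups <- function(data_a, data_b, seed = 1L) {
  stopifnot(inherits(data_a, "symptom_dataset"),
            inherits(data_b, "symptom_dataset"))
  na <- n_cases(data_a); nb <- n_cases(data_b)
  if (na == nb) {
    warning("groups already have equal size; returning unchanged",
            call. = FALSE)
    return(list(a = data_a, b = data_b))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (na > nb) {
    list(a = subset_cases(data_a, sample.int(na, nb)), b = data_b)
  } else {
    list(a = data_a, b = subset_cases(data_b, sample.int(nb, na)))
  }
}

#' Subset the cases of a symptom dataset
#'
#' @param data a [symptom_dataset()].
#' @param idx case indices to keep.
#' @return a [symptom_dataset()] with the selected cases.
#' @export
subset_cases <- function(data, idx) {
  stopifnot(inherits(data, "symptom_dataset"))
  symptom_dataset(data$scores[idx, , drop = FALSE], items = data$items,
                  group = if (!is.null(data$group)) data$group[idx],
                  covariates = if (!is.null(data$covariates))
                    data$covariates[idx, , drop = FALSE])
}
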