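#' Graphical lasso fit at a fixed penalty
#'
#' Estimates a sparse precision (inverse covariance) matrix by maximizing
#' the L1-penalized Gaussian log-likelihood
#' `log det K - trace(S K) - lambda * sum_{i != j} |k_ij|`
#' (diagonal unpenalized) with block coordinate descent. At `lambda = 0` the
#' solution is the ordinary inverse of `S`; for
#' `lambda >= max_{i != j} |S_ij|` the solution is diagonal (empty network).
#'
#' @param S a [cor_matrix()] or symmetric PSD matrix.
#' @param lambda penalty, `lambda >= 0`.
#' @param tol relative convergence tolerance on the working covariance
#'   (default 1e-6; scaled by the mean absolute off-diagonal of `S`).
#' @param maxit maximum outer sweeps (default 1000).
#' @return object of class `precision_matrix`: list with `K`, `labels`,
#'   `lambda`, `iters`.
#' @export
glasso_fit <- function(S, lambda, tol = 1e-6, maxit = 1000L) {
  labels <- if (inherits(S, "cor_matrix")) S$labels else
    colnames(S) %||% paste0("V", seq_len(nrow(S)))
  M <- if (inherits(S, "cor_matrix")) S$values else as.matrix(S)
  if (lambda < 0) stop_validation("lambda must be >= 0")
  fit <- .glasso_cpp(M, lambda, tol, as.integer(maxit), 10000L)
  if (!fit$converged)
    stop_validation(
      "graphical lasso did not converge in %d sweeps (lambda=%.4g, p=%d)",
      maxit, lambda, nrow(M))
  K <- fit$K
  dimnames(K) <- list(labels, labels)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop_validation("estimated precision matrix is not positive definite")
  structure(list(K = K, labels = labels, lambda = lambda, iters = fit$iters),
            class = "precision_matrix")
}

#' Partial correlations from a precision matrix
#'
#' `w_ij = -k_ij / sqrt(k_ii * k_jj)` with a zero diagonal; for a positive
#' definite precision matrix all entries lie in \[-1, 1\].
#'
#' @param K a `precision_matrix` or positive-definite matrix.
#' @param meta optional metadata list stored on the network.
#' @return a [symptom_network()].
#' @export
precision_to_partial <- function(K, meta = list()) {
  labels <- NULL
  if (inherits(K, "precision_matrix")) {
    labels <- K$labels
    meta$lambda <- meta$lambda %||% K$lambda
    K <- K$K
  }
  K <- as.matrix(K)
  labels <- labels %||% colnames(K) %||% paste0("V", seq_len(nrow(K)))
  d <- diag(K)
  if (any(d <= 0))
    stop_validation("precision matrix has a non-positive diagonal entry")
  W <- -K / tcrossprod(sqrt(d))
  diag(W) <- 0
  W <- (W + t(W)) / 2
  W[abs(W) > 1] <- sign(W[abs(W) > 1]) # numerical guard at |w| = 1
  symptom_network(W, labels, meta = meta)
}

#' Extended Bayesian information criterion
#'
#' `EBIC = -2 loglik + E log(n) + 4 E gamma log(p)` where `E` is the number
#' of nonzero upper-triangle edges. `gamma = 0` reduces to the ordinary BIC;
#' larger `gamma` prefers sparser models.
#'
#' @param loglik Gaussian log-likelihood of the fitted precision matrix.
#' @param E edge count (nonzero upper-triangle entries).
#' @param n sample size.
#' @param p node count.
#' @param gamma EBIC hyperparameter, `gamma >= 0` (0.5 typical).
#' @return the EBIC score.
#' @export
ebic <- function(loglik, E, n, p, gamma) {
  stopifnot(n > 0, p > 1, E >= 0, gamma >= 0)
  -2 * loglik + E * log(n) + 4 * E * gamma * log(p)
}

gaussian_loglik <- function(K, S, n) {
  (n / 2) * (determinant(K, logarithm = TRUE)$modulus[1] - sum(S * K))
}

#' Estimate a regularized partial-correlation network
#'
#' The full estimation pipeline: item correlation matrix, graphical lasso
#' solved along a log-spaced path of `n_lambda` penalties from
#' `lambda_max = max |S_ij|` down to `lambda_max * lambda_min_ratio`, EBIC
#' model selection, and conversion of the selected precision matrix to
#' partial correlations. Edges below `clamp` in absolute value are set to
#' exactly zero so that edge presence is well defined.
#'
#' @param data a [symptom_dataset()] or numeric matrix.
#' @param method correlation method passed to [cor_matrix()].
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambda number of penalties on the path (default 100).
#' @param lambda_min_ratio ratio of smallest to largest penalty (default 0.01).
#' @param tol,maxit convergence controls passed to [glasso_fit()].
#' @param clamp absolute threshold below which selected edges are set to 0.
#' @return object of class `network_fit`: list with `network`
#'   (a [symptom_network()]), `lambda_selected`, `ebic_path` (data frame of
#'   lambda, loglik, E, ebic), and `correlation` (the input [cor_matrix()]).
#' @export
estimate_network <- function(data, method = "pearson", gamma = 0.5,
                             n_lambda = 100L, lambda_min_ratio = 0.01,
                             tol = 1e-6, maxit = 1000L, clamp = 1e-10) {
  stopifnot(gamma >= 0, n_lambda >= 2, lambda_min_ratio > 0,
            lambda_min_ratio < 1)
  S <- if (inherits(data, "cor_matrix")) data else cor_matrix(data, method)
  p <- length(S$labels)
  n <- S$n
  lambda_max <- max(abs(S$values[upper.tri(S$values)]))
  if (lambda_max <= clamp) {
    # items are empirically uncorrelated; the empty network is immediate
    net <- symptom_network(matrix(0, p, p), S$labels,
                           meta = list(method = S$method, lambda = 0,
                                       gamma = gamma, n = n))
    path <- data.frame(lambda = 0, loglik = gaussian_loglik(diag(p) /
                         diag(S$values), S$values, n), E = 0L)
    path$ebic <- ebic(path$loglik, path$E, n, p, gamma)
    return(structure(list(network = net, lambda_selected = 0,
                          ebic_path = path, correlation = S),
                     class = "network_fit"))
  }
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                     length.out = n_lambda))
  fit <- .glasso_path_cpp(S$values, lambdas, tol, as.integer(maxit), 10000L)
  if (!all(fit$converged))
    stop_validation("graphical lasso failed to converge at %d path point(s)",
                    sum(!fit$converged))
  ut <- upper.tri(S$values)
  stats_path <- vapply(seq_along(lambdas), function(l) {
    K <- fit$K[, , l]
    Wp <- -K / tcrossprod(sqrt(diag(K)))
    diag(Wp) <- 0
    E <- sum(abs(Wp[ut]) > clamp)
    c(loglik = gaussian_loglik(K, S$values, n), E = E)
  }, numeric(2))
  path <- data.frame(lambda = lambdas, loglik = stats_path["loglik", ],
                     E = as.integer(stats_path["E", ]))
  path$ebic <- ebic(path$loglik, path$E, n, p, gamma)
  sel <- which.min(path$ebic)
  K <- fit$K[, , sel]
  dimnames(K) <- list(S$labels, S$labels)
  net <- precision_to_partial(K, meta = list(method = S$method,
                                             lambda = lambdas[sel],
                                             gamma = gamma, n = n))
  W <- net$weights
  W[abs(W) < clamp] <- 0
  net <- symptom_network(W, net$labels, meta = net$meta)
  structure(list(network = net, lambda_selected = lambdas[sel],
                 ebic_path = path, correlation = S),
            class = "network_fit")
}

#' @export
print.network_fit <- function(x, ...) {
  cat(sprintf(
    "<network_fit> %d nodes, %d edges, lambda = %.4g (EBIC-selected of %d)\n",
    length(x$network$labels),
    sum(x$network$weights[upper.tri(x$network$weights)] != 0),
    x$lambda_selected, nrow(x$ebic_path)))
  invisible(x)
}

#' Unregularized partial-correlation network
#'
#' Partial correlations obtained by direct (pseudo-)inversion of the item
#' correlation matrix, with no sparsity penalty. This is the estimator used
#' for sensitivity analyses of permutation comparison results and as the
#' exact counterpart of the graphical lasso at `lambda = 0`.
#'
#' @param data a [symptom_dataset()], numeric matrix or [cor_matrix()].
#' @param method correlation method (ignored if `data` is a [cor_matrix()]).
#' @return a [symptom_network()].
#' @export
unregularized_network <- function(data, method = "pearson") {
  S <- if (inherits(data, "cor_matrix")) data else cor_matrix(data, method)
  K <- tryCatch(solve(S$values), error = function(e) MASS::ginv(S$values))
  dimnames(K) <- list(S$labels, S$labels)
  d <- diag(K)
  d[d <= 0] <- 1e-12 # pseudo-inverse may produce degenerate rows
  W <- -K / tcrossprod(sqrt(d))
  diag(W) <- 0
  W <- (W + t(W)) / 2
  W[W > 1] <- 1; W[W < -1] <- -1
  symptom_network(W, S$labels,
                  meta = list(method = S$method, lambda = 0, n = S$n))
}

#' Force-directed network layout
#'
#' Two-dimensional Fruchterman-Reingold coordinates for plotting, with
#' absolute edge weights acting as attraction strengths. Deterministic for a
#' fixed seed; coincident coordinates (e.g. from fully disconnected layouts)
#' are separated by a small deterministic jitter.
#'
#' @param network a [symptom_network()].
#' @param seed layout seed (default 42).
#' @return p x 2 matrix of coordinates with node labels as row names.
#' @export
layout_fruchterman_reingold <- function(network, seed = 42) {
  stopifnot(inherits(network, "symptom_network"))
  p <- n_nodes(network)
  if (p == 1) {
    xy <- matrix(0, 1, 2, dimnames = list(network$labels, c("x", "y")))
    return(xy)
  }
  g <- igraph_from_network(network)
  w <- abs(edge_weights_of(g))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  xy <- igraph::layout_with_fr(g, weights = if (length(w)) w else NULL)
  dup <- duplicated(round(xy, 9))
  if (any(dup)) {
    jit <- matrix(sin(seq_len(2 * p) + seed), p, 2) * 1e-3
    xy[dup, ] <- xy[dup, , drop = FALSE] + jit[dup, , drop = FALSE]
  }
  dimnames(xy) <- list(network$labels, c("x", "y"))
  xy
}

edge_weights_of <- function(g) {
  w <- igraph::E(g)$weight
  if (is.null(w)) numeric(0) else w
}

igraph_from_network <- function(network) {
  ed <- edge_pairs(network)
  ed <- ed[ed$weight != 0, , drop = FALSE]
  g <- igraph::make_empty_graph(n = n_nodes(network), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = network$labels)
  if (nrow(ed))
    g <- igraph::add_edges(g, rbind(ed$i, ed$j), weight = ed$weight)
  g
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
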