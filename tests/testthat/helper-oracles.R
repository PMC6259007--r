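# Independent reference implementations used to cross-check the package's
# estimators, plus small scenario builders shared across test files.

# ADMM solver for the graphical lasso objective (diagonal unpenalized).
# A different algorithm family than the package's coordinate descent, run to
# tight tolerance, so it can serve as an oracle on small problems.
admm_glasso <- function(S, lambda, rho = 1, iters = 5000, tol = 1e-9) {
  p <- nrow(S)
  Z <- diag(p)
  U <- matrix(0, p, p)
  K <- diag(p)
  for (it in seq_len(iters)) {
    e <- eigen(rho * (Z - U) - S, symmetric = TRUE)
    xi <- (e$values + sqrt(e$values^2 + 4 * rho)) / (2 * rho)
    K <- e$vectors %*% (xi * t(e$vectors))
    A <- K + U
    Znew <- sign(A) * pmax(abs(A) - lambda / rho, 0)
    diag(Znew) <- diag(A)
    r_primal <- max(abs(K - Znew))
    r_dual <- max(abs(Znew - Z))
    Z <- Znew
    U <- U + K - Z
    if (r_primal < tol && r_dual < tol) break
  }
  (Z + t(Z)) / 2
}

# Exhaustive simple-path enumeration on the 1/|w| distance graph.
# Returns shortest-path distances, closeness and Freeman betweenness with
# fractional credit among tied shortest paths. Exponential; p <= 7 only.
brute_force_paths <- function(W, tol = 1e-9) {
  p <- nrow(W)
  L <- 1 / abs(W)
  L[W == 0] <- Inf
  dist <- matrix(Inf, p, p)
  diag(dist) <- 0
  nshort <- matrix(0, p, p)
  through <- matrix(0, p, p * p) # via-vertex counts keyed by (s,t)
  key <- function(s, t) (s - 1) * p + t
  for (s in seq_len(p - 1)) for (t in (s + 1):p) {
    paths <- list()
    lens <- numeric(0)
    rec <- function(v, visited, len) {
      if (v == t) {
        paths[[length(paths) + 1]] <<- visited
        lens[length(lens) + 1] <<- len
        return()
      }
      for (u in seq_len(p)) {
        if (!is.infinite(L[v, u]) && !(u %in% visited))
          rec(u, c(visited, u), len + L[v, u])
      }
    }
    rec(s, s, 0)
    if (!length(lens)) next
    best <- min(lens)
    dist[s, t] <- dist[t, s] <- best
    hit <- which(lens <= best * (1 + tol))
    nshort[s, t] <- nshort[t, s] <- length(hit)
    for (h in hit) {
      inner <- setdiff(paths[[h]], c(s, t))
      for (v in inner)
        through[v, key(s, t)] <- through[v, key(s, t)] + 1
    }
  }
  betw <- numeric(p)
  for (s in seq_len(p - 1)) for (t in (s + 1):p) {
    if (nshort[s, t] > 0)
      betw <- betw + through[, key(s, t)] / nshort[s, t]
  }
  tot <- rowSums(dist)
  closeness <- ifelse(is.finite(tot), (p - 1) / tot, 0)
  list(dist = dist, closeness = closeness, betweenness = betw)
}

# product-moment correlation by the direct sum formula
direct_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# heterogeneous, strongly connected 8-node structure used for stability work
strong8_partials <- function() {
  P <- matrix(0, 8, 8)
  w <- c(0.30, 0.25, 0.22, 0.28, 0.24, 0.26, 0.20, 0.23)
  for (i in 1:8) {
    j <- i %% 8 + 1
    P[i, j] <- P[j, i] <- w[i]
  }
  chords <- rbind(c(1, 4, 0.15), c(2, 6, 0.12), c(3, 7, 0.14),
                  c(5, 8, 0.10), c(1, 5, 0.08), c(2, 7, 0.10))
  for (r in seq_len(nrow(chords))) {
    i <- chords[r, 1]; j <- chords[r, 2]
    P[i, j] <- P[j, i] <- chords[r, 3]
  }
  P
}

# sparse 6-node chain-plus-chord generator for recovery checks
sparse6_partials <- function() {
  P <- matrix(0, 6, 6)
  edges <- rbind(c(1, 2, 0.35), c(2, 3, 0.30), c(3, 4, 0.32),
                 c(4, 5, 0.28), c(5, 6, 0.34), c(2, 5, 0.20))
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    P[i, j] <- P[j, i] <- edges[r, 3]
  }
  P
}

edge_presence_f1 <- function(est_net, true_net) {
  ut <- upper.tri(est_net$weights)
  est <- est_net$weights[ut] != 0
  tru <- true_net$weights[ut] != 0
  tp <- sum(est & tru); fp <- sum(est & !tru); fn <- sum(!est & tru)
  2 * tp / (2 * tp + fp + fn)
}

# latent Gaussian draws for a given partial structure (continuous data)
sample_latent <- function(partials, n, seed) {
  K <- build_precision(partials)
  R <- stats::cov2cor(solve(K$K))
  set.seed(seed)
  matrix(rnorm(n * nrow(R)), n) %*% chol(R)
}

write_demo_csv <- function(path, n = 5, seed = 1, missing_row = NULL,
                           bad_score = NULL) {
  set.seed(seed)
  items <- ptsd_items()
  m <- matrix(sample(0:4, n * 17, replace = TRUE), n, 17,
              dimnames = list(NULL, items))
  df <- as.data.frame(m)
  df$group <- rep(c("full", "subthreshold"), length.out = n)
  df$ces <- sample(0:41, n, replace = TRUE)
  if (!is.null(missing_row)) df[missing_row, "E6"] <- NA
  if (!is.null(bad_score)) df[bad_score, "B1"] <- 5
  write.csv(df, path, row.names = FALSE)
  df
}
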