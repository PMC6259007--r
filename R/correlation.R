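#' Repair a correlation matrix to positive semi-definiteness
#'
#' Clips eigenvalues below `tol` up to `tol`, reconstructs the matrix and
#' rescales it back to unit diagonal. Idempotent up to the clipping
#' tolerance; matrices that are already PSD are returned unchanged.
#'
#' @param R symmetric correlation matrix.
#' @param tol eigenvalue floor (default 1e-8).
#' @return list with `values` (repaired matrix) and `repaired` (logical flag).
#' @keywords internal
repair_psd <- function(R, tol = 1e-8) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= tol) return(list(values = R, repaired = FALSE))
  v <- pmax(e$values, tol)
  M <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(M))
  M <- M / tcrossprod(d)
  diag(M) <- 1
  M <- (M + t(M)) / 2
  dimnames(M) <- dimnames(R)
  list(values = M, repaired = TRUE)
}

#' Correlation matrix of a symptom dataset
#'
#' Computes the item intercorrelation matrix that feeds network estimation.
#' Pearson product-moment correlations on the raw 0-4 scores are the default;
#' Spearman rank correlations and polychoric correlations (two-step maximum
#' likelihood under a latent bivariate normal) are available for ordinal
#' fidelity. The result is repaired to positive semi-definiteness if needed
#' (eigenvalue clipping; the repair is recorded in the result).
#'
#' @param data a [symptom_dataset()] or numeric matrix.
#' @param method `"pearson"` (default), `"spearman"` or `"polychoric"`.
#' @return object of class `cor_matrix`: list with `values`, `labels`,
#'   `method`, `n`, `psd_repaired`.
#' @export
cor_matrix <- function(data, method = c("pearson", "spearman", "polychoric")) {
  method <- match.arg(method)
  x <- if (inherits(data, "symptom_dataset")) data$scores else as.matrix(data)
  labels <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  n <- nrow(x)
  p <- ncol(x)
  vars <- apply(x, 2, stats::var)
  if (any(vars == 0))
    stop_validation("zero-variance item: %s",
                    paste(labels[vars == 0], collapse = ", "))
  if (n < p + 1)
    warning(sprintf("only %d cases for %d items; correlations are unstable",
                    n, p), call. = FALSE)
  R <- switch(method,
    pearson  = cor(x, method = "pearson"),
    spearman = cor(x, method = "spearman"),
    polychoric = {
      R <- diag(p)
      for (i in seq_len(p - 1)) for (j in (i + 1):p)
        R[i, j] <- R[j, i] <- polychoric_correlation(x[, i], x[, j])
      R
    })
  dimnames(R) <- list(labels, labels)
  rep <- repair_psd(R)
  structure(list(values = rep$values, labels = labels, method = method,
                 n = n, psd_repaired = rep$repaired),
            class = "cor_matrix")
}

#' Polychoric correlation of two ordinal items
#'
#' Two-step maximum-likelihood estimate of the latent correlation of a
#' bivariate normal underlying a pair of ordinal items: thresholds are fixed
#' at the inverse-normal transforms of the marginal cumulative frequencies,
#' then the latent correlation is found by one-dimensional maximization of
#' the multinomial likelihood of the contingency table, with cell
#' probabilities computed from the bivariate normal CDF. The estimate is
#' capped at |rho| = 0.999.
#'
#' @param item_x,item_y equal-length ordinal vectors with at least two
#'   observed categories each.
#' @return estimated latent correlation in (-1, 1).
#' @export
polychoric_correlation <- function(item_x, item_y) {
  if (length(item_x) != length(item_y))
    stop_validation("item vectors must have equal length")
  tab <- table(item_x, item_y)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop_validation("polychoric correlation needs >= 2 observed categories per item")
  n <- sum(tab)
  # thresholds from marginal cumulative proportions (drop the final 1)
  cx <- qnorm(cumsum(rowSums(tab))[-nrow(tab)] / n)
  cy <- qnorm(cumsum(colSums(tab))[-ncol(tab)] / n)
  ax <- c(-Inf, cx, Inf)
  ay <- c(-Inf, cy, Inf)
  nr <- nrow(tab); nc <- ncol(tab)

  cell_loglik <- function(rho) {
    # bivariate normal CDF on the grid, rectangles by inclusion-exclusion
    Phi2 <- matrix(0, nr + 1, nc + 1)
    sigma <- matrix(c(1, rho, rho, 1), 2)
    for (i in seq_len(nr + 1)) for (j in seq_len(nc + 1)) {
      Phi2[i, j] <- if (i == 1 || j == 1) 0 else if (is.infinite(ax[i]) &&
        is.infinite(ay[j])) 1 else
        mvtnorm::pmvnorm(upper = c(ax[i], ay[j]), sigma = sigma)[1]
    }
    P <- Phi2[-1, -1, drop = FALSE] + Phi2[-(nr + 1), -(nc + 1), drop = FALSE] -
      Phi2[-1, -(nc + 1), drop = FALSE] - Phi2[-(nr + 1), -1, drop = FALSE]
    P <- pmax(P, 1e-12)
    sum(tab * log(P))
  }
  opt <- optimize(cell_loglik, interval = c(-0.999, 0.999), maximum = TRUE,
                  tol = 1e-6)
  opt$maximum
}
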