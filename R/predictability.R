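#' Nodewise predictability
#'
#' For each item, the in-sample coefficient of determination (R^2) of the
#' least-squares regression of that item on all remaining items: the
#' proportion of a node's variance shared with its surrounding nodes. A
#' linear (Gaussian) nodewise model is used on the common 0-4 severity
#' scale; this is a deliberate, deterministic simplification relative to
#' mixed-graphical-model predictability.
#'
#' @param data a [symptom_dataset()] or numeric matrix (cases x items).
#' @param ridge if the design is singular, fall back to a lightly
#'   ridge-penalized fit instead of erroring (default `FALSE`).
#' @return object of class `predictability_result`: list with `r2` (named
#'   per-node vector in \[0, 1\]) and `mean`.
#' @export
predictability <- function(data, ridge = FALSE) {
  x <- pred_matrix(data)
  labels <- colnames(x)
  r2 <- vapply(seq_len(ncol(x)), function(j) one_node_r2(x, j, ridge),
               numeric(1))
  names(r2) <- labels
  structure(list(r2 = r2, mean = mean(r2)), class = "predictability_result")
}

pred_matrix <- function(data) {
  x <- if (inherits(data, "symptom_dataset")) data$scores else as.matrix(data)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (nrow(x) <= ncol(x))
    stop_validation("need more cases (%d) than items (%d)",
                    nrow(x), ncol(x))
  x
}

one_node_r2 <- function(x, j, ridge) {
  labels <- colnames(x)
  y <- x[, j]
  tss <- sum((y - mean(y))^2)
  if (tss == 0)
    stop_validation("item '%s' has zero variance", labels[j])
  X <- cbind(1, x[, -j, drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    if (!ridge)
      stop_validation(
        "singular design when predicting '%s'; set ridge = TRUE for a penalized fallback",
        labels[j])
    Xc <- scale(x[, -j, drop = FALSE], center = TRUE, scale = FALSE)
    yc <- y - mean(y)
    G <- crossprod(Xc) + diag(1e-8 * nrow(x), ncol(Xc))
    beta <- solve(G, crossprod(Xc, yc))
    rss <- sum((yc - Xc %*% beta)^2)
  } else {
    rss <- sum(qr.resid(qx, y)^2)
  }
  max(0, min(1, 1 - rss / tss))
}

#' @export
print.predictability_result <- function(x, ...) {
  cat(sprintf("<predictability_result> mean R^2 = %.3f over %d nodes\n",
              x$mean, length(x$r2)))
  invisible(x)
}

#' Predictability of a single node
#'
#' @inheritParams predictability
#' @param node node label.
#' @return R^2 of the node regressed on all other nodes.
#' @export
node_predictability <- function(data, node, ridge = FALSE) {
  x <- pred_matrix(data)
  j <- match(node, colnames(x))
  if (is.na(j)) stop_validation("unknown node '%s'", node)
  one_node_r2(x, j, ridge)
}

#' Mean nodewise predictability
#'
#' Arithmetic mean of the per-node R^2 values.
#'
#' @inheritParams predictability
#' @return mean R^2.
#' @export
mean_predictability <- function(data, ridge = FALSE) {
  predictability(data, ridge = ridge)$mean
}
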