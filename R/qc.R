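#' Principal components of samples
#'
#' PCA of the transformed expression matrix with genes centered.
#' Components use a deterministic sign convention: the gene loading
#' with the largest magnitude is positive.
#'
#' @param expr numeric matrix, genes x samples (>= 3 samples).
#' @param n_components number of components to return.
#' @return list with \code{coordinates} (samples x components),
#'   \code{explained_variance} (proportion per returned component) and
#'   \code{loadings}.
#' @export
samplePCA <- function(expr, n_components = 2) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3) stop("at least 3 samples required")
  if (all(apply(expr, 1, var) == 0))
    stop("constant expression matrix")
  pc <- prcomp(t(expr), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  x <- pc$x[, seq_len(k), drop = FALSE]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) {
      rot[, j] <- -rot[, j]
      x[, j] <- -x[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(coordinates = x, explained_variance = ev[seq_len(k)],
       loadings = rot)
}

#' Sample-to-sample Euclidean distance matrix
#'
#' @param expr numeric matrix, genes x samples (>= 2 samples).
#' @return symmetric numeric matrix of Euclidean distances between
#'   sample expression profiles, with attribute \code{metric}.
#' @export
sampleDistances <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2) stop("at least 2 samples required")
  d <- as.matrix(dist(t(expr), method = "euclidean"))
  attr(d, "metric") <- "euclidean"
  d
}
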