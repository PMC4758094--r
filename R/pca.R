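#' Explained variation
#'
#' \eqn{R^2 = 1 - SS(E)/SS(X)}: the fraction of total (column-centered)
#' variation accounted for by a model with residual sum of squares
#' \code{ss_residual}.
#'
#' @param ss_residual residual sum of squares (\eqn{\ge 0}).
#' @param ss_total total sum of squares (> 0).
#' @return \code{1 - ss_residual/ss_total}.
#' @export
r2 <- function(ss_residual, ss_total) {
  if (length(ss_total) != 1 || is.na(ss_total) || ss_total <= 0)
    stop("ss_total must be a single positive number")
  if (length(ss_residual) != 1 || is.na(ss_residual) || ss_residual < 0)
    stop("ss_residual must be a single non-negative number")
  1 - ss_residual / ss_total
}

#' Column-centered principal component analysis
#'
#' PCA of a samples x proteins matrix after column centering with no
#' scaling, the preprocessing convention of chemometric gradient
#' profiling. Components are ordered by explained variation; the sign of
#' each component is fixed so that its largest-magnitude loading entry is
#' positive, making results deterministic across platforms.
#'
#' @param x an \code{\link{expression_matrix}} or numeric matrix
#'   (samples x proteins).
#' @param n_components number of components to extract; at most
#'   \code{min(n_samples - 1, n_proteins)}.
#' @return an object of class \code{pca_model} with elements
#'   \code{col_means}, \code{scores} (samples x A), \code{loadings}
#'   (proteins x A, orthonormal columns), \code{r2x_per_component},
#'   \code{residual} and \code{totss}.
#' @export
fit_pca <- function(x, n_components = 2) {
  X <- as_values(x)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop("need at least 2 samples")
  a_max <- min(n - 1L, p)
  n_components <- as.integer(n_components)
  if (n_components < 1 || n_components > a_max)
    stop(sprintf("n_components must be between 1 and %d", a_max))
  col_means <- colMeans(X)
  Xc <- sweep(X, 2, col_means)
  totss <- ssq(Xc)
  if (totss <= .Machine$double.eps * n * max(p, 1) * max(1, max(abs(X))^2))
    stop("no variance: centered matrix is entirely zero")
  sv <- svd(Xc, nu = n_components, nv = n_components)
  A <- n_components
  scores <- sv$u %*% diag(sv$d[seq_len(A)], A, A)
  loadings <- sv$v
  for (a in seq_len(A)) {                     # deterministic sign convention
    j <- which.max(abs(loadings[, a]))
    if (loadings[j, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  rownames(scores) <- rownames(X)
  rownames(loadings) <- colnames(X)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(A))
  residual <- Xc - scores %*% t(loadings)
  structure(list(col_means = col_means,
                 scores = scores,
                 loadings = loadings,
                 r2x_per_component = sv$d[seq_len(A)]^2 / totss,
                 residual = residual,
                 totss = totss,
                 singular_values = sv$d),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d components, %d samples x %d variables\n",
              ncol(x$scores), nrow(x$scores), nrow(x$loadings)))
  cat("R2X per component:",
      paste(sprintf("%.3f", x$r2x_per_component), collapse = " "), "\n")
  cat(sprintf("cumulative R2X: %.3f\n", sum(x$r2x_per_component)))
  invisible(x)
}
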