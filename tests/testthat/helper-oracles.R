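# Independent oracles and small fixture builders used across the suite.

# truncated-SVD PCA oracle: scores/loadings/r2x from base svd on the
# centered matrix, without the package's sign convention
svd_pca_oracle <- function(X, A) {
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  list(scores = sv$u[, seq_len(A), drop = FALSE] %*%
         diag(sv$d[seq_len(A)], A, A),
       loadings = sv$v[, seq_len(A), drop = FALSE],
       r2x = sv$d[seq_len(A)]^2 / sum(sv$d^2))
}

# closed-form NIPALS PLS1 first component: w = X'y/||X'y||, t = Xw,
# p = X't/(t't); reported in the unit-loading convention (t||p||, p/||p||)
pls1_oracle <- function(X, y) {
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  w <- drop(crossprod(Xc, yc))
  w <- w / sqrt(sum(w^2))
  t1 <- drop(Xc %*% w)
  p1 <- drop(crossprod(Xc, t1)) / sum(t1^2)
  np <- sqrt(sum(p1^2))
  list(scores = t1 * np, loading = p1 / np, w = w)
}

# brute-force two-zone effect oracle: raw mean difference per protein
mean_diff_oracle <- function(em, from_zone, to_zone) {
  z <- em$sample_meta$zone
  colMeans(em$values[z == to_zone, , drop = FALSE]) -
    colMeans(em$values[z == from_zone, , drop = FALSE])
}

# small labelled expression matrix from a plain matrix
make_em <- function(values, zones, tree = NULL, tissue = NULL) {
  colnames(values) <- colnames(values) %||_h% paste0("p", seq_len(ncol(values)))
  meta <- data.frame(sample_id = paste0("s", seq_len(nrow(values))),
                     zone = zones, stringsAsFactors = FALSE)
  if (!is.null(tree)) meta$tree_id <- tree
  if (!is.null(tissue)) meta$tissue_amount <- tissue
  expression_matrix(values, meta)
}

`%||_h%` <- function(a, b) if (is.null(a)) b else a

cosine_sim_h <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# two-zone pure-noise matrix on the log-normal intensity scale
null_two_zone_em <- function(n_per_zone = 8, n_proteins = 500, noise_sd = 0.25) {
  v <- exp(matrix(rnorm(2 * n_per_zone * n_proteins, log(1e5), noise_sd),
                  2 * n_per_zone, n_proteins))
  make_em(v, rep(c("A", "B"), each = n_per_zone))
}

# two-zone matrix with a planted mean shift (log scale) in the first
# n_shift proteins
shifted_two_zone_em <- function(n_per_zone = 8, n_proteins = 50,
                                n_shift = 5, shift = 5 * 0.25,
                                noise_sd = 0.25) {
  n <- 2 * n_per_zone
  lv <- matrix(rnorm(n * n_proteins, log(1e5), noise_sd), n, n_proteins)
  zones <- rep(c("A", "B"), each = n_per_zone)
  if (n_shift > 0)
    lv[zones == "B", seq_len(n_shift)] <-
      lv[zones == "B", seq_len(n_shift)] + shift
  make_em(exp(lv), zones)
}
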