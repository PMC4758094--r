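#' Orthogonal projections to latent structures (single response)
#'
#' Splits the column-centered descriptor matrix X into a single predictive
#' component correlated with the response y and \code{n_orth} orthogonal
#' components describing systematic variation uncorrelated with y:
#' \deqn{X = 1\bar{x} + t_p p_p' + T_o P_o' + E, \qquad
#'       y = \bar{y} + t_p q_p + f.}
#' Orthogonal components are extracted and deflated before the final
#' predictive fit. The predictive loading \code{p_p} is stored with unit
#' Euclidean norm; all magnitude information lives in the score vector
#' \code{t_p}, so that downstream transition profiles satisfy
#' \eqn{\|p_p d\| = d} exactly.
#'
#' @param x an \code{\link{expression_matrix}} or numeric matrix
#'   (samples x variables).
#' @param y numeric response vector with at least two distinct values.
#' @param n_orth number of orthogonal components (\eqn{\ge 0}, default 1).
#' @return an object of class \code{opls_model} with the decomposition
#'   (\code{col_means}, \code{y_mean}, \code{t_p}, \code{p_p}, \code{q_p},
#'   \code{T_o}, \code{P_o}, \code{W_o}, \code{E}, \code{f}) and fit
#'   statistics \code{r2x}, \code{r2y}.
#' @export
fit_opls <- function(x, y, n_orth = 1) {
  X <- as_values(x)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  n_orth <- as.integer(n_orth)
  if (length(y) != n) stop("length of y must equal the number of samples")
  if (n_orth < 0) stop("n_orth must be >= 0")
  if (n < n_orth + 2) stop("too few samples for the requested model")
  if (length(unique(y)) < 2) stop("response is constant")
  col_means <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, col_means)
  yc <- y - y_mean
  totss_x <- ssq(Xc)
  scale_ref <- max(abs(X))^2 + 1
  if (totss_x <= .Machine$double.eps * n * p * scale_ref)
    stop("no variance: centered matrix is entirely zero")

  w <- unit_vec(drop(crossprod(Xc, yc)))
  Xf <- Xc
  T_o <- matrix(0, n, 0)
  P_o <- matrix(0, p, 0)
  W_o <- matrix(0, p, 0)
  for (a in seq_len(n_orth)) {
    t_a <- drop(Xf %*% w)
    if (ssq(t_a) <= .Machine$double.eps * totss_x)
      stop(sprintf("n_orth too large: achievable rank is %d orthogonal component(s)", a - 1L))
    p_a <- drop(crossprod(Xf, t_a)) / ssq(t_a)
    w_o <- p_a - sum(w * p_a) * w
    if (sqrt(ssq(w_o)) <= 1e-10 * sqrt(ssq(p_a)))
      stop(sprintf("n_orth too large: achievable rank is %d orthogonal component(s)", a - 1L))
    w_o <- unit_vec(w_o)
    t_o <- drop(Xf %*% w_o)
    if (ssq(t_o) <= .Machine$double.eps * totss_x)
      stop(sprintf("n_orth too large: achievable rank is %d orthogonal component(s)", a - 1L))
    p_o <- drop(crossprod(Xf, t_o)) / ssq(t_o)
    Xf <- Xf - tcrossprod(t_o, p_o)
    T_o <- cbind(T_o, t_o)
    P_o <- cbind(P_o, p_o)
    W_o <- cbind(W_o, w_o)
  }

  t_raw <- drop(Xf %*% w)
  if (ssq(t_raw) <= .Machine$double.eps * totss_x)
    stop("no predictive variation left after orthogonal filtering")
  p_raw <- drop(crossprod(Xf, t_raw)) / ssq(t_raw)
  q_raw <- sum(yc * t_raw) / ssq(t_raw)
  E <- Xf - tcrossprod(t_raw, p_raw)
  f <- yc - t_raw * q_raw

  # unit-norm predictive loading; magnitude carried by the score vector
  score_scale <- sqrt(ssq(p_raw))
  p_p <- p_raw / score_scale
  t_p <- t_raw * score_scale
  q_p <- q_raw / score_scale

  names(p_p) <- colnames(X)
  if (ncol(T_o)) {
    rownames(P_o) <- rownames(W_o) <- colnames(X)
    colnames(T_o) <- colnames(P_o) <- colnames(W_o) <- paste0("o", seq_len(ncol(T_o)))
  }
  structure(list(col_means = col_means, y_mean = y_mean,
                 t_p = t_p, p_p = p_p, q_p = q_p,
                 T_o = T_o, P_o = P_o, W_o = W_o,
                 E = E, f = f,
                 r2x = 1 - ssq(E) / totss_x,
                 r2y = 1 - ssq(f) / ssq(yc),
                 n_orth = n_orth,
                 weights = w, score_scale = score_scale),
            class = "opls_model")
}

#' Predict from a fitted OPLS model
#'
#' New samples are centered with the training column means, filtered
#' through the orthogonal components, and projected on the predictive
#' weight vector.
#'
#' @param object an \code{opls_model}.
#' @param newdata numeric matrix or \code{expression_matrix} with the same
#'   variables as the training data.
#' @param ... unused.
#' @return list with \code{score} (predictive scores, on the same scale as
#'   \code{object$t_p}) and \code{y} (predicted response).
#' @export
predict.opls_model <- function(object, newdata, ...) {
  X <- as_values(newdata)
  if (ncol(X) != length(object$col_means))
    stop("newdata has the wrong number of variables")
  Xc <- sweep(X, 2, object$col_means)
  for (a in seq_len(object$n_orth)) {
    t_o <- drop(Xc %*% object$W_o[, a])
    Xc <- Xc - tcrossprod(t_o, object$P_o[, a])
  }
  t_p <- drop(Xc %*% object$weights) * object$score_scale
  list(score = t_p, y = object$y_mean + t_p * object$q_p)
}

#' Two-class OPLS discriminant analysis
#'
#' Encodes a binary class label as a \{0, 1\} response (second level = 1),
#' centers it, and fits \code{\link{fit_opls}}. The model is oriented so
#' that the mean predictive score of the second ("to") class is positive;
#' positive loading entries therefore mean higher abundance in the second
#' class.
#'
#' @param x an \code{\link{expression_matrix}} or numeric matrix.
#' @param class_labels factor or character vector with exactly two levels;
#'   the first level is the reference ("from") class. A plain character
#'   vector is ordered by first appearance.
#' @param n_orth number of orthogonal components (default 1).
#' @return an \code{opls_model} with an added \code{classes} element giving
#'   the level order used for coding.
#' @export
fit_oplsda <- function(x, class_labels, n_orth = 1) {
  X <- as_values(x)
  if (is.factor(class_labels)) {
    lev <- levels(droplevels(class_labels))
  } else {
    lev <- unique(as.character(class_labels))
  }
  cls <- as.character(class_labels)
  if (length(lev) != 2)
    stop(sprintf("need exactly 2 classes, got %d", length(lev)))
  counts <- table(factor(cls, levels = lev))
  if (any(counts < 2))
    stop(sprintf("class '%s' has fewer than 2 samples",
                 names(counts)[which(counts < 2)[1]]))
  y <- as.numeric(cls == lev[2])
  m <- fit_opls(X, y, n_orth = n_orth)
  if (mean(m$t_p[y == 1]) < 0) {     # orient toward the "to" class
    m$t_p <- -m$t_p
    m$p_p <- -m$p_p
    m$q_p <- -m$q_p
    m$weights <- -m$weights
  }
  m$classes <- lev
  m
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf("opls_model: 1 predictive + %d orthogonal component(s), n = %d\n",
              x$n_orth, length(x$t_p)))
  if (!is.null(x$classes))
    cat(sprintf("discriminant coding: %s (0) -> %s (1)\n",
                x$classes[1], x$classes[2]))
  cat(sprintf("R2X = %.3f, R2Y = %.3f\n", x$r2x, x$r2y))
  invisible(x)
}
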