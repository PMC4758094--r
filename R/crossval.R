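#' Cross-validated predictive ability and CV-ANOVA
#'
#' k-fold cross-validation of an OPLS (numeric response) or OPLS-DA
#' (two-class response) model. Each fold is held out in turn, the model is
#' refit on the remainder (including the orthogonal filtering), and the
#' held-out response is predicted. Reports
#' \deqn{Q^2 = 1 - PRESS / SS(y - \bar{y})}
#' and a CV-ANOVA style p-value from the F ratio
#' \eqn{((SS - PRESS)/A) / (PRESS/(n - 1 - A))} with \eqn{A} the total
#' number of model components (1 predictive + \code{n_orth}); the F
#' statistic is clamped at 0 when PRESS \eqn{\ge} SS, giving p = 1.
#'
#' Folds for a two-class response are stratified by class. Fold assignment
#' uses the current RNG state unless \code{folds} is supplied.
#'
#' @param x an \code{\link{expression_matrix}} or numeric matrix.
#' @param y numeric response, or factor/character with two classes.
#' @param n_orth number of orthogonal components (default 1).
#' @param n_folds number of folds (default 7, the chemometrics convention).
#' @param folds optional explicit integer fold assignment.
#' @return an object of class \code{cv_report}: list with \code{q2},
#'   \code{cv_anova_p}, \code{n_folds}, \code{fold_assignment},
#'   \code{press}, \code{ss}.
#' @export
cross_validate <- function(x, y, n_orth = 1, n_folds = 7, folds = NULL) {
  X <- as_values(x)
  n <- nrow(X)
  da <- is.factor(y) || is.character(y)
  if (da) {
    lev <- if (is.factor(y)) levels(droplevels(y)) else unique(as.character(y))
    if (length(lev) != 2) stop("discriminant cross-validation needs exactly 2 classes")
    cls <- as.character(y)
    y_num <- as.numeric(cls == lev[2])
  } else {
    y_num <- as.numeric(y)
    cls <- NULL
  }
  if (length(y_num) != n) stop("length of y must equal the number of samples")
  if (is.null(folds)) {
    folds <- make_folds(n, n_folds, strata = cls)
  } else {
    if (length(folds) != n) stop("folds must assign every sample")
    n_folds <- length(unique(folds))
  }
  preds <- rep(NA_real_, n)
  for (g in sort(unique(folds))) {
    test <- folds == g
    train <- !test
    if (da) {
      tr_counts <- table(factor(cls[train], levels = lev))
      if (any(tr_counts == 0))
        stop(sprintf("fold %d leaves class '%s' absent from the training set",
                     g, names(tr_counts)[which(tr_counts == 0)[1]]))
      m <- fit_oplsda(X[train, , drop = FALSE], factor(cls[train], levels = lev),
                      n_orth = n_orth)
    } else {
      m <- fit_opls(X[train, , drop = FALSE], y_num[train], n_orth = n_orth)
    }
    preds[test] <- predict(m, X[test, , drop = FALSE])$y
  }
  press <- ssq(y_num - preds)
  ss <- ssq(y_num - mean(y_num))
  q2 <- 1 - press / ss
  A <- 1L + as.integer(n_orth)
  df2 <- n - 1L - A
  if (df2 < 1) stop("too few samples for CV-ANOVA with this many components")
  f_stat <- if (press >= ss) 0 else ((ss - press) / A) / (press / df2)
  p_val <- stats::pf(f_stat, A, df2, lower.tail = FALSE)
  structure(list(q2 = q2, cv_anova_p = p_val, n_folds = n_folds,
                 fold_assignment = folds, press = press, ss = ss,
                 predictions = preds),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d folds, Q2 = %.3f, CV-ANOVA p = %.3g\n",
              x$n_folds, x$q2, x$cv_anova_p))
  invisible(x)
}
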