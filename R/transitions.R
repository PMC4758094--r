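#' Ordered developmental zone series
#'
#' Describes the ordered zones of a developmental gradient and the list of
#' consecutive zone pairs to model. The default is the wood-formation
#' series phloem (P), cambium (C), expansion zone (E) and four xylem
#' segments (X1-X4), with both cell files emanating from the cambium:
#' C to P outward, and C through E to X4 inward.
#'
#' @param ordered_zones character vector of zone labels in radial order.
#' @param transition_pairs data.frame with columns \code{from} and
#'   \code{to}; default follows the two cambium-rooted files.
#' @return an object of class \code{zone_series}.
#' @export
zone_series <- function(ordered_zones = c("P", "C", "E", "X1", "X2", "X3", "X4"),
                        transition_pairs = NULL) {
  if (anyDuplicated(ordered_zones)) stop("duplicate zone labels")
  if (is.null(transition_pairs)) {
    transition_pairs <- data.frame(
      from = c("C", "C", "E", "X1", "X2", "X3"),
      to   = c("P", "E", "X1", "X2", "X3", "X4"),
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(transition_pairs),
            all(c("from", "to") %in% names(transition_pairs)))
  lab <- paste(transition_pairs$from, transition_pairs$to, sep = "/")
  if (anyDuplicated(lab)) stop("transition pairs must be distinct")
  unknown <- setdiff(unique(c(transition_pairs$from, transition_pairs$to)),
                     ordered_zones)
  if (length(unknown))
    stop(sprintf("transition pair references unknown zone(s): %s",
                 paste(unknown, collapse = ", ")))
  structure(list(ordered_zones = ordered_zones,
                 transition_pairs = transition_pairs,
                 labels = lab),
            class = "zone_series")
}

#' Local OPLS-DA model of one zone transition
#'
#' Fits a two-class OPLS-DA model on the samples of the two zones only
#' (local column centering), and derives the transition effect profile:
#' \deqn{d = \|t_p\|, \qquad p_{dist} = p_p \, d,}
#' the predictive loading direction weighted by the Euclidean norm of the
#' predictive score vector. \code{p_dist} encodes both the direction and
#' the magnitude of the protein-expression change from the first zone to
#' the second; positive entries mean higher abundance in the "to" zone.
#'
#' @param em an \code{\link{expression_matrix}}.
#' @param from_zone,to_zone zone labels present in the metadata, each with
#'   at least 2 samples.
#' @param n_orth number of orthogonal components (default 1).
#' @return an object of class \code{transition_result}: list with
#'   \code{pair}, \code{label}, \code{model}, \code{d}, \code{p_dist},
#'   \code{n_samples}.
#' @export
transition_model <- function(em, from_zone, to_zone, n_orth = 1) {
  stopifnot(inherits(em, "expression_matrix"))
  zones <- em$sample_meta$zone
  for (z in c(from_zone, to_zone)) {
    n_z <- sum(zones == z)
    if (n_z < 2)
      stop(sprintf("zone '%s' %s", z,
                   if (n_z == 0) "is absent from the data"
                   else "has fewer than 2 samples"))
  }
  sub <- subset_zones(em, c(from_zone, to_zone))
  cls <- factor(sub$sample_meta$zone, levels = c(from_zone, to_zone))
  model <- fit_oplsda(sub$values, cls, n_orth = n_orth)
  d <- sqrt(ssq(model$t_p))
  p_dist <- model$p_p * d
  structure(list(pair = c(from = from_zone, to = to_zone),
                 label = paste(from_zone, to_zone, sep = "/"),
                 model = model, d = d, p_dist = p_dist,
                 n_samples = nrow(sub$values)),
            class = "transition_result")
}

#' @export
print.transition_result <- function(x, ...) {
  cat(sprintf("transition %s: d = %.4g, n = %d, R2X = %.3f, R2Y = %.3f\n",
              x$label, x$d, x$n_samples, x$model$r2x, x$model$r2y))
  invisible(x)
}

#' Fit the full series of local transition models
#'
#' One local OPLS-DA model per consecutive zone pair, in series order.
#'
#' @param em an \code{\link{expression_matrix}}.
#' @param series a \code{\link{zone_series}}.
#' @param n_orth number of orthogonal components per local model.
#' @return a list of \code{\link{transition_model}} results (class
#'   \code{transition_series}), named by transition label.
#' @export
stepwise_series <- function(em, series = zone_series(), n_orth = 1) {
  stopifnot(inherits(em, "expression_matrix"), inherits(series, "zone_series"))
  needed <- unique(c(series$transition_pairs$from, series$transition_pairs$to))
  missing_z <- setdiff(needed, unique(em$sample_meta$zone))
  if (length(missing_z))
    stop(sprintf("zone(s) missing from the data: %s",
                 paste(missing_z, collapse = ", ")))
  out <- lapply(seq_len(nrow(series$transition_pairs)), function(i) {
    transition_model(em,
                     series$transition_pairs$from[i],
                     series$transition_pairs$to[i],
                     n_orth = n_orth)
  })
  names(out) <- series$labels
  class(out) <- "transition_series"
  out
}

#' @export
print.transition_series <- function(x, ...) {
  cat(sprintf("transition_series: %d transitions\n", length(x)))
  for (tr in x)
    cat(sprintf("  %-6s d = %.4g (n = %d)\n", tr$label, tr$d, tr$n_samples))
  invisible(x)
}

#' Stack transition profiles into a matrix
#'
#' @param results a \code{transition_series} or list of
#'   \code{transition_result}s.
#' @return numeric matrix, transitions x proteins, rows named by
#'   transition label.
#' @export
pdist_matrix <- function(results) {
  stopifnot(length(results) >= 1)
  lens <- vapply(results, function(r) length(r$p_dist), integer(1))
  if (length(unique(lens)) != 1)
    stop("transition profiles have mismatched protein dimensions")
  m <- do.call(rbind, lapply(results, function(r) r$p_dist))
  rownames(m) <- vapply(results, function(r) r$label, character(1))
  m
}

#' Meta-PCA overview of the transition series
#'
#' Stacks the p_dist profiles of all transitions into a transitions x
#' proteins matrix, column-centers it (no scaling) and fits a PCA. The
#' score plot compares the directions and sizes of the consecutive
#' changes: transitions with similar profiles cluster, opposing regimes
#' (most upregulated proteins becoming downregulated) land on opposite
#' sides of the separating component.
#'
#' @param results a \code{transition_series} (at least 2 transitions).
#' @param n_components number of components; at most
#'   \code{n_transitions - 1}.
#' @return object of class \code{transition_overview}: list with
#'   \code{pdist} (the stacked matrix) and \code{meta_pca} (a
#'   \code{\link{fit_pca}} model whose scores are indexable by transition
#'   label).
#' @export
meta_pca <- function(results, n_components = 2) {
  if (length(results) < 2) stop("need at least 2 transitions")
  m <- pdist_matrix(results)
  model <- fit_pca(m, n_components = n_components)
  structure(list(pdist = m, meta_pca = model), class = "transition_overview")
}

#' @export
print.transition_overview <- function(x, ...) {
  cat(sprintf("transition_overview: %d transitions, %d proteins\n",
              nrow(x$pdist), ncol(x$pdist)))
  print(x$meta_pca)
  invisible(x)
}
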