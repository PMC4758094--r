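#' Samples-by-proteins expression matrix with sample metadata
#'
#' The central container of the package: a numeric matrix with samples as
#' rows and proteins as columns, carrying per-sample metadata (replicate
#' tree, developmental zone, radial position, tissue amount). All model
#' fitting functions accept either an \code{expression_matrix} or a bare
#' numeric matrix.
#'
#' @param values numeric matrix, samples x proteins. Column names are the
#'   protein identifiers and must be unique.
#' @param sample_meta data.frame with one row per sample. Must contain a
#'   \code{sample_id} column (unique) and a \code{zone} column; columns
#'   \code{tree_id}, \code{radial_order} and \code{tissue_amount} are used
#'   by the quantification helpers when present.
#' @return an object of class \code{expression_matrix}: a list with
#'   elements \code{values}, \code{sample_meta} and \code{protein_ids}.
#' @examples
#' m <- matrix(rlnorm(12), 4, 3, dimnames = list(NULL, c("p1", "p2", "p3")))
#' meta <- data.frame(sample_id = paste0("s", 1:4),
#'                    zone = c("C", "C", "P", "P"))
#' em <- expression_matrix(m, meta)
#' @export
expression_matrix <- function(values, sample_meta) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix (samples x proteins)")
  if (!is.data.frame(sample_meta))
    stop("sample_meta must be a data.frame")
  if (nrow(values) != nrow(sample_meta))
    stop(sprintf("values has %d rows but sample_meta has %d",
                 nrow(values), nrow(sample_meta)))
  if (is.null(sample_meta$sample_id)) stop("sample_meta needs a sample_id column")
  if (is.null(sample_meta$zone)) stop("every sample needs a zone label")
  sample_meta$sample_id <- as.character(sample_meta$sample_id)
  sample_meta$zone <- as.character(sample_meta$zone)
  if (anyDuplicated(sample_meta$sample_id))
    stop("duplicate sample ids")
  if (is.null(colnames(values)))
    stop("values needs protein ids as column names")
  if (anyDuplicated(colnames(values)))
    stop("duplicate protein ids")
  if (anyNA(values) || any(!is.finite(values)))
    stop("values must be finite and non-missing")
  rownames(values) <- sample_meta$sample_id
  rownames(sample_meta) <- NULL
  structure(list(values = values,
                 sample_meta = sample_meta,
                 protein_ids = colnames(values)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  zt <- table(x$sample_meta$zone)
  cat(sprintf("expression_matrix: %d samples x %d proteins\n",
              nrow(x$values), ncol(x$values)))
  cat("zones:", paste(sprintf("%s(%d)", names(zt), zt), collapse = " "), "\n")
  if (!is.null(x$sample_meta$tree_id))
    cat("trees:", paste(unique(x$sample_meta$tree_id), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Subset an expression matrix to selected samples
#'
#' @param em an \code{\link{expression_matrix}}.
#' @param idx integer or logical sample index.
#' @return an \code{expression_matrix} with the selected samples.
#' @export
subset_samples <- function(em, idx) {
  stopifnot(inherits(em, "expression_matrix"))
  expression_matrix(em$values[idx, , drop = FALSE],
                    em$sample_meta[idx, , drop = FALSE])
}

#' Subset an expression matrix to selected zones
#'
#' @param em an \code{\link{expression_matrix}}.
#' @param zones character vector of zone labels to keep.
#' @return an \code{expression_matrix} restricted to those zones.
#' @export
subset_zones <- function(em, zones) {
  stopifnot(inherits(em, "expression_matrix"))
  missing_z <- setdiff(zones, unique(em$sample_meta$zone))
  if (length(missing_z))
    stop(sprintf("zone(s) not present in the data: %s",
                 paste(missing_z, collapse = ", ")))
  subset_samples(em, em$sample_meta$zone %in% zones)
}

# coerce expression_matrix or plain matrix to a numeric matrix
as_values <- function(x) {
  if (inherits(x, "expression_matrix")) return(x$values)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("expected an expression_matrix or a numeric matrix")
}
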