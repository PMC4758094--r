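# Readers and writers for the plain-text interchange formats.
# Tables are TSV by default; files ending in .csv are read/written as CSV.

delim_for <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_delim_file <- function(path, sep = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  utils::read.table(path, header = TRUE, sep = delim_for(path, sep),
                    quote = "", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

write_delim_file <- function(df, path, sep = NULL, row_names = FALSE) {
  utils::write.table(df, path, sep = delim_for(path, sep),
                     quote = FALSE, row.names = row_names, col.names = TRUE)
  invisible(path)
}

#' Read a peptide quantification table
#'
#' Expects columns \code{protein_id}, \code{peptide_seq}, \code{sample_id},
#' \code{intensity}, \code{is_unique} (TSV, or CSV for \code{.csv} files).
#'
#' @param path file path.
#' @param sep optional field separator override.
#' @return data.frame validated for downstream quantification.
#' @export
read_peptide_table <- function(path, sep = NULL) {
  df <- read_delim_file(path, sep)
  check_peptide_table(df)
  df$is_unique <- as.logical(df$is_unique)
  df
}

#' Read a section metadata table
#'
#' Expects columns \code{tree_id}, \code{radial_order}, \code{zone},
#' \code{thickness_um}, \code{tissue_amount}, \code{pool_id}.
#'
#' @inheritParams read_peptide_table
#' @return validated data.frame of section records.
#' @export
read_section_table <- function(path, sep = NULL) {
  check_section_table(read_delim_file(path, sep))
}

#' Read an expression matrix and its sample metadata
#'
#' The values file has \code{sample_id} as its first column and one column
#' per protein; the companion metadata file has one row per sample.
#'
#' @param values_path path of the values table.
#' @param meta_path path of the sample metadata table.
#' @param sep optional field separator override.
#' @return an \code{\link{expression_matrix}}.
#' @export
read_expression_matrix <- function(values_path, meta_path, sep = NULL) {
  vals <- read_delim_file(values_path, sep)
  if (names(vals)[1] != "sample_id")
    stop("first column of the values table must be sample_id")
  meta <- read_delim_file(meta_path, sep)
  m <- as.matrix(vals[, -1, drop = FALSE])
  rownames(m) <- vals$sample_id
  meta <- meta[match(vals$sample_id, meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id))
    stop("metadata is missing entries for some samples in the values table")
  expression_matrix(m, meta)
}

#' Write an expression matrix and its sample metadata
#'
#' @param em an \code{\link{expression_matrix}}.
#' @inheritParams read_expression_matrix
#' @return the values path, invisibly.
#' @export
write_expression_matrix <- function(em, values_path, meta_path, sep = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  df <- data.frame(sample_id = em$sample_meta$sample_id,
                   em$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_delim_file(df, values_path, sep)
  write_delim_file(em$sample_meta, meta_path, sep)
  invisible(values_path)
}

#' Write the transition profile table
#'
#' Proteins as rows, transitions as columns (the layout of supplementary
#' effect tables).
#'
#' @param results a \code{transition_series}.
#' @param path output file.
#' @param sep optional separator override.
#' @export
write_pdist_table <- function(results, path, sep = NULL) {
  m <- t(pdist_matrix(results))
  df <- data.frame(protein_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_delim_file(df, path, sep)
}

#' Serialize a fitted model to a plain-text report
#'
#' Writes component counts, explained variation, cross-validation
#' statistics and top loadings in a human-readable key-value format.
#'
#' @param model a \code{pca_model} or \code{opls_model}.
#' @param path output file.
#' @param cv optional \code{cv_report} to include.
#' @param n_top number of top-loading proteins to list.
#' @export
write_model_report <- function(model, path, cv = NULL, n_top = 10) {
  lines <- character(0)
  if (inherits(model, "pca_model")) {
    lines <- c(lines,
               sprintf("model_type\tpca"),
               sprintf("n_components\t%d", ncol(model$scores)),
               sprintf("r2x_per_component\t%s",
                       paste(format(model$r2x_per_component, digits = 6),
                             collapse = ",")),
               sprintf("r2x_cumulative\t%s",
                       format(sum(model$r2x_per_component), digits = 6)))
    ld <- model$loadings[, 1]
  } else if (inherits(model, "opls_model")) {
    lines <- c(lines,
               sprintf("model_type\topls%s",
                       if (!is.null(model$classes)) "-da" else ""),
               sprintf("n_orth\t%d", model$n_orth),
               sprintf("r2x\t%s", format(model$r2x, digits = 6)),
               sprintf("r2y\t%s", format(model$r2y, digits = 6)))
    ld <- model$p_p
  } else stop("unsupported model type")
  if (!is.null(cv))
    lines <- c(lines,
               sprintf("q2\t%s", format(cv$q2, digits = 6)),
               sprintf("cv_anova_p\t%s", format(cv$cv_anova_p, digits = 6)),
               sprintf("n_folds\t%d", cv$n_folds))
  top <- order(abs(ld), decreasing = TRUE)[seq_len(min(n_top, length(ld)))]
  lines <- c(lines, sprintf("top_loading\t%s\t%s",
                            names(ld)[top] %||% top,
                            format(ld[top], digits = 6)))
  writeLines(lines, path)
  invisible(path)
}
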