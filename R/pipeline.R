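#' Coded trend table of differential calls
#'
#' Recodes the complete protein x transition call grid as a matrix of
#' \{-1, 0, +1\} (down / no change / up; in heatmap terms red, black and
#' green respectively), with rows ordered by agglomerative hierarchical
#' clustering (Euclidean distance, average linkage) so proteins with
#' similar trend vectors are adjacent.
#'
#' @param calls a \code{\link{call_differential}} object.
#' @return object of class \code{trend_table}: list with \code{matrix}
#'   (proteins x transitions, clustered row order), \code{row_order}, and
#'   \code{legend}.
#' @export
trend_table <- function(calls) {
  stopifnot(inherits(calls, "differential_calls"))
  df <- calls$calls
  prot <- unique(df$protein_id)
  m <- matrix(0L, length(prot), length(calls$transitions),
              dimnames = list(prot, calls$transitions))
  code <- c(up = 1L, down = -1L, none = 0L)
  m[cbind(match(df$protein_id, prot), match(df$transition, calls$transitions))] <-
    code[df$direction]
  if (nrow(m) > 2) {
    hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                        method = "average")
    ord <- hc$order
  } else {
    ord <- seq_len(nrow(m))
  }
  structure(list(matrix = m[ord, , drop = FALSE],
                 row_order = rownames(m)[ord],
                 legend = c(`-1` = "down (red)", `0` = "no change (black)",
                            `1` = "up (green)")),
            class = "trend_table")
}

#' @export
print.trend_table <- function(x, ...) {
  cat(sprintf("trend_table: %d proteins x %d transitions\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat("legend:", paste(sprintf("%s = %s", names(x$legend), x$legend),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Write a trend table with its legend
#'
#' @param tt a \code{\link{trend_table}}.
#' @param path output TSV path; the legend goes to \code{<path>.legend.txt}.
#' @export
write_trend_table <- function(tt, path) {
  stopifnot(inherits(tt, "trend_table"))
  df <- data.frame(protein_id = rownames(tt$matrix), tt$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_delim_file(df, path)
  writeLines(sprintf("%s\t%s", names(tt$legend), tt$legend),
             paste0(path, ".legend.txt"))
  invisible(path)
}

#' Join user-supplied annotations onto a call table
#'
#' Left join on \code{protein_id}: every call row is kept, unmapped
#' proteins get empty annotations. Duplicate protein ids in the mapping
#' are concatenated with ";" and a warning.
#'
#' @param calls a \code{\link{call_differential}} object.
#' @param mapping data.frame (or path of a TSV/CSV file) with a
#'   \code{protein_id} column plus one or more annotation columns.
#' @return the \code{differential_calls} object with annotation columns
#'   appended to \code{calls$calls}.
#' @export
annotate_calls <- function(calls, mapping) {
  stopifnot(inherits(calls, "differential_calls"))
  if (is.character(mapping) && length(mapping) == 1)
    mapping <- read_delim_file(mapping)
  if (!is.data.frame(mapping) || !"protein_id" %in% names(mapping) ||
      ncol(mapping) < 2)
    stop("mapping must have a protein_id column plus annotation column(s)")
  if (anyDuplicated(mapping$protein_id)) {
    warning("duplicate protein_id in mapping; annotations concatenated")
    ann_cols <- setdiff(names(mapping), "protein_id")
    mapping <- stats::aggregate(mapping[ann_cols],
                                by = list(protein_id = mapping$protein_id),
                                FUN = function(v) paste(v, collapse = ";"))
  }
  merged <- merge(calls$calls, mapping, by = "protein_id",
                  all.x = TRUE, sort = FALSE)
  ann_cols <- setdiff(names(mapping), "protein_id")
  for (cc in ann_cols) merged[[cc]][is.na(merged[[cc]])] <- ""
  # merge() may reorder; restore (transition, protein) call order
  key <- paste(calls$calls$transition, calls$calls$protein_id)
  merged <- merged[match(key, paste(merged$transition, merged$protein_id)), ]
  rownames(merged) <- NULL
  calls$calls <- merged
  calls
}

#' Run the full stepwise transition analysis
#'
#' Orchestrates the complete analysis: quantification (when a peptide
#' table is supplied), tissue normalisation, a global PCA overview of all
#' samples and zones, one local OPLS-DA model per consecutive zone
#' transition with cross-validation, jack-knife differential calls, the
#' meta-PCA over all transition profiles, and the coded trend table.
#' Either supply measured inputs (\code{peptides} + \code{sections}, or a
#' ready \code{expression}) or a \code{\link{synth_config}} to simulate
#' them.
#'
#' @param peptides peptide table (data.frame or file path), measured per
#'   pooled sample.
#' @param sections section metadata (data.frame or file path) defining the
#'   pooling scheme and tissue amounts.
#' @param expression an \code{\link{expression_matrix}}, already pooled;
#'   alternative to \code{peptides}/\code{sections}.
#' @param config a \code{\link{synth_config}}; when given, data are
#'   generated and the other inputs ignored.
#' @param series a \code{\link{zone_series}}.
#' @param n_orth orthogonal components per local model (default 1).
#' @param n_components components of the global PCA (default 3).
#' @param alpha significance level for the jack-knife calls.
#' @param segments jack-knife segments / CV folds (default 7).
#' @param normalize apply \code{\link{total_tissue_normalize}} to the
#'   quantified matrix (default TRUE when tissue amounts are available).
#' @param out_dir optional directory; when given, all result tables, model
#'   reports and a run manifest are written there.
#' @param seed RNG seed for fold assignment (and generation when
#'   \code{config} lacks one); the same seed reproduces every number.
#' @param quiet suppress progress messages.
#' @return object of class \code{pipeline_result}: list with
#'   \code{expression}, \code{global_pca}, \code{transitions}, \code{cv}
#'   (per-transition \code{cv_report}s), \code{cis}, \code{calls},
#'   \code{overview}, \code{trend}, \code{summary} (per-transition d, R2,
#'   Q2, CV-ANOVA p), \code{truth} (for synthetic runs) and \code{params}.
#' @export
run_pipeline <- function(peptides = NULL, sections = NULL, expression = NULL,
                         config = NULL, series = zone_series(), n_orth = 1,
                         n_components = 3, alpha = 0.05, segments = 7,
                         normalize = TRUE, out_dir = NULL, seed = 1,
                         quiet = TRUE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  truth <- NULL
  set.seed(seed)
  if (!is.null(config)) {
    say("stage simulate: generating synthetic dataset (seed %d)", config$seed)
    sim <- generate_dataset(config)
    peptides <- sim$peptides
    sections <- sim$sections
    truth <- sim$truth
    expression <- NULL
  }
  if (is.character(peptides)) peptides <- read_peptide_table(peptides)
  if (is.character(sections)) sections <- read_section_table(sections)

  if (is.null(expression)) {
    if (is.null(peptides) || is.null(sections))
      stop("supply either an expression matrix or a peptide table with sections")
    say("stage quantify: top-3 quantification of %d peptide rows", nrow(peptides))
    vals <- quantify_proteins(peptides)
    meta <- pool_metadata(sections)
    missing_s <- setdiff(rownames(vals), meta$sample_id)
    if (length(missing_s))
      stop(sprintf("samples without section metadata: %s",
                   paste(utils::head(missing_s, 3), collapse = ", ")))
    meta <- meta[match(rownames(vals), meta$sample_id), , drop = FALSE]
    expression <- expression_matrix(vals, meta)
  }
  if (is.null(expression$sample_meta$zone))
    stop("validation: sample metadata lacks a zone column")
  if (normalize && !is.null(expression$sample_meta$tissue_amount)) {
    say("stage normalize: total tissue normalisation")
    expression <- total_tissue_normalize(expression)
  }

  say("stage pca: global overview of %d samples", nrow(expression$values))
  global_pca <- fit_pca(expression, n_components = n_components)

  say("stage transitions: %d local OPLS-DA models", nrow(series$transition_pairs))
  results <- stepwise_series(expression, series, n_orth = n_orth)
  cv <- lapply(results, function(r) {
    sub <- subset_zones(expression, r$pair)
    cross_validate(sub$values,
                   factor(sub$sample_meta$zone, levels = unname(r$pair)),
                   n_orth = n_orth, n_folds = segments)
  })

  say("stage significance: jack-knife intervals (alpha = %g)", alpha)
  cis <- lapply(results, function(r)
    jackknife_ci(expression, r$pair[["from"]], r$pair[["to"]],
                 n_orth = n_orth, alpha = alpha, segments = segments))
  calls <- call_differential(results, cis, alpha = alpha)

  say("stage overview: meta-PCA of transition profiles")
  overview <- meta_pca(results,
                       n_components = min(3L, length(results) - 1L))
  trend <- trend_table(calls)

  summary_df <- data.frame(
    transition = vapply(results, function(r) r$label, character(1)),
    n_samples = vapply(results, function(r) r$n_samples, numeric(1)),
    d = vapply(results, function(r) r$d, numeric(1)),
    r2x = vapply(results, function(r) r$model$r2x, numeric(1)),
    r2y = vapply(results, function(r) r$model$r2y, numeric(1)),
    q2 = vapply(cv, function(z) z$q2, numeric(1)),
    cv_anova_p = vapply(cv, function(z) z$cv_anova_p, numeric(1)),
    n_up = vapply(results, function(r)
      sum(calls$calls$transition == r$label & calls$calls$direction == "up"),
      numeric(1)),
    n_down = vapply(results, function(r)
      sum(calls$calls$transition == r$label & calls$calls$direction == "down"),
      numeric(1)),
    stringsAsFactors = FALSE)
  rownames(summary_df) <- NULL

  params <- list(n_orth = n_orth, n_components = n_components, alpha = alpha,
                 segments = segments, seed = seed, normalize = normalize,
                 zones = series$ordered_zones, transitions = series$labels,
                 synthetic = !is.null(config))
  if (!is.null(config)) params$config <- unclass(config)

  out <- structure(list(expression = expression, global_pca = global_pca,
                        transitions = results, cv = cv, cis = cis,
                        calls = calls, overview = overview, trend = trend,
                        summary = summary_df, truth = truth, params = params),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  print(x$expression)
  cat(sprintf("global PCA R2X: %s (cumulative %.3f)\n",
              paste(sprintf("%.3f", x$global_pca$r2x_per_component),
                    collapse = " "),
              sum(x$global_pca$r2x_per_component)))
  print(x$summary, digits = 4)
  invisible(x)
}

# write every artifact of a pipeline run plus the run manifest
write_pipeline_outputs <- function(res, out_dir) {
  stopifnot(inherits(res, "pipeline_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  write_expression_matrix(res$expression, fp("expression_matrix.tsv"),
                          fp("sample_metadata.tsv"))
  write_pdist_table(res$transitions, fp("pdist_table.tsv"))
  sc <- data.frame(transition = rownames(res$overview$meta_pca$scores),
                   res$overview$meta_pca$scores, check.names = FALSE)
  write_delim_file(sc, fp("overview_scores.tsv"))
  write_delim_file(res$calls$calls, fp("differential_calls.tsv"))
  write_trend_table(res$trend, fp("trend_table.tsv"))
  write_delim_file(res$summary, fp("transition_summary.tsv"))
  write_model_report(res$global_pca, fp("global_pca_report.txt"))
  manifest <- c(sprintf("run_date\t%s", "not recorded (deterministic run)"),
                vapply(names(res$params), function(k) {
                  v <- res$params[[k]]
                  if (is.list(v)) {
                    flat <- vapply(v, function(z)
                      paste(format(z), collapse = ","), character(1))
                    v <- paste(names(flat), flat, sep = "=", collapse = "; ")
                  }
                  sprintf("%s\t%s", k, paste(format(v), collapse = ","))
                }, character(1)))
  writeLines(manifest, fp("run_manifest.tsv"))
  invisible(out_dir)
}
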