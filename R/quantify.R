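#' Top-3 protein quantity from peptide intensities
#'
#' Protein abundance estimated as the sum of the n most intense peptides,
#' the standard label-free "Hi3" estimate. With fewer than \code{n}
#' peptides all available peptides are summed.
#'
#' @param intensities numeric vector of non-negative peptide intensities
#'   for one protein in one sample.
#' @param n how many top peptides to sum (default 3).
#' @return the summed intensity of the top \code{n} peptides.
#' @examples
#' top3_quantity(c(10, 5, 1, 0.5))  # 16
#' @export
top3_quantity <- function(intensities, n = 3) {
  if (length(intensities) == 0) stop("no peptides")
  if (anyNA(intensities) || any(intensities < 0))
    stop("intensities must be non-negative and non-missing")
  keep <- min(as.integer(n), length(intensities))
  sum(sort(intensities, decreasing = TRUE)[seq_len(keep)])
}

check_peptide_table <- function(peptides) {
  need <- c("protein_id", "peptide_seq", "sample_id", "intensity", "is_unique")
  miss <- setdiff(need, names(peptides))
  if (length(miss))
    stop(sprintf("peptide table is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  if (nrow(peptides) && (anyNA(peptides$intensity) || any(peptides$intensity < 0)))
    stop("peptide intensities must be non-negative")
  invisible(peptides)
}

#' Drop proteins without any sequence-unique peptide
#'
#' A protein is considered identified only if at least one of its peptides
#' maps uniquely to it. Proteins failing the rule are removed; for the
#' proteins that pass, all their peptides (unique and shared) are retained
#' for quantification.
#'
#' @param peptides data.frame with columns \code{protein_id},
#'   \code{peptide_seq}, \code{sample_id}, \code{intensity},
#'   \code{is_unique}.
#' @return the filtered peptide table.
#' @export
unique_peptide_filter <- function(peptides) {
  check_peptide_table(peptides)
  if (nrow(peptides) == 0) return(peptides)
  has_unique <- tapply(as.logical(peptides$is_unique), peptides$protein_id, any)
  keep_prot <- names(has_unique)[has_unique]
  peptides[peptides$protein_id %in% keep_prot, , drop = FALSE]
}

#' Assemble a protein x sample quantity matrix from a peptide table
#'
#' Applies the unique-peptide identification rule, then sums the top
#' \code{n_top} peptide intensities per protein and sample. Protein/sample
#' combinations with no detected peptide are recorded as 0 intensity; the
#' logical attribute \code{"detected"} flags which cells were actually
#' observed.
#'
#' @param peptides peptide table (see \code{\link{unique_peptide_filter}}).
#' @param n_top number of top peptides summed per protein (default 3).
#' @param require_unique apply the unique-peptide filter first (default TRUE).
#' @return numeric matrix, samples x proteins, with a \code{"detected"}
#'   attribute of the same shape.
#' @export
quantify_proteins <- function(peptides, n_top = 3, require_unique = TRUE) {
  check_peptide_table(peptides)
  if (require_unique) peptides <- unique_peptide_filter(peptides)
  if (nrow(peptides) == 0) stop("no peptides")
  key <- paste(peptides$sample_id, peptides$protein_id, sep = "\r")
  if (anyDuplicated(paste(key, peptides$peptide_seq, sep = "\r")))
    stop("duplicate (protein, peptide, sample) rows in the peptide table")
  o <- order(peptides$sample_id, peptides$protein_id, -peptides$intensity,
             method = "radix")
  pp <- peptides[o, , drop = FALSE]
  grp <- paste(pp$sample_id, pp$protein_id, sep = "\r")
  rank_in_grp <- sequence(rle(grp)$lengths)
  keep <- rank_in_grp <= n_top
  sums <- rowsum(pp$intensity[keep], grp[keep], reorder = FALSE)
  first <- !duplicated(grp)
  samp_of <- pp$sample_id[first][match(rownames(sums), grp[first])]
  prot_of <- pp$protein_id[first][match(rownames(sums), grp[first])]
  samples <- sort(unique(peptides$sample_id))
  proteins <- sort(unique(peptides$protein_id))
  m <- matrix(0, length(samples), length(proteins),
              dimnames = list(samples, proteins))
  det <- matrix(FALSE, length(samples), length(proteins),
                dimnames = list(samples, proteins))
  ij <- cbind(match(samp_of, samples), match(prot_of, proteins))
  m[ij] <- sums[, 1]
  det[ij] <- TRUE
  attr(m, "detected") <- det
  m
}

#' Normalise each sample by its tissue amount
#'
#' Divides every sample row by the sample's \code{tissue_amount} (mass or
#' volume; only the ratio matters downstream), the "total tissue
#' normalisation" step that puts pooled samples of different sizes on a
#' per-tissue scale.
#'
#' @param em an \code{\link{expression_matrix}} whose metadata carries a
#'   positive \code{tissue_amount} per sample.
#' @return the normalised \code{expression_matrix}; metadata unchanged.
#' @export
total_tissue_normalize <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  ta <- em$sample_meta$tissue_amount
  if (is.null(ta)) stop("sample_meta has no tissue_amount column")
  bad <- which(is.na(ta) | ta <= 0)
  if (length(bad))
    stop(sprintf("non-positive or missing tissue_amount for sample '%s'",
                 em$sample_meta$sample_id[bad[1]]))
  out <- em
  out$values <- em$values / ta
  out
}

check_section_table <- function(sections) {
  need <- c("tree_id", "radial_order", "zone", "thickness_um",
            "tissue_amount", "pool_id")
  miss <- setdiff(need, names(sections))
  if (length(miss))
    stop(sprintf("section table is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  if (any(sections$thickness_um <= 0)) stop("section thickness must be > 0")
  if (any(sections$tissue_amount <= 0)) stop("section tissue_amount must be > 0")
  invisible(sections)
}

# per-pool metadata (shared by pool_sections and the pipeline)
pool_metadata <- function(sections) {
  check_section_table(sections)
  split_idx <- split(seq_len(nrow(sections)), sections$pool_id)
  meta <- lapply(names(split_idx), function(pid) {
    s <- sections[split_idx[[pid]], , drop = FALSE]
    if (length(unique(s$tree_id)) > 1L)
      stop(sprintf("pool '%s' spans more than one tree", pid))
    if (length(unique(s$zone)) > 1L)
      stop(sprintf("pool '%s' spans more than one zone", pid))
    data.frame(sample_id = pid,
               tree_id = s$tree_id[1],
               zone = s$zone[1],
               radial_order = mean(s$radial_order),
               tissue_amount = sum(s$tissue_amount),
               n_sections = nrow(s),
               total_thickness_um = sum(s$thickness_um),
               stringsAsFactors = FALSE)
  })
  meta <- do.call(rbind, meta)
  # radial order within tree, trees in order of first appearance
  tree_rank <- match(meta$tree_id, unique(sections$tree_id))
  meta[order(tree_rank, meta$radial_order), , drop = FALSE]
}

#' Pool section-level measurements into pooled samples
#'
#' Emulates the physical pooling of section extracts before instrumental
#' analysis: every section carries a \code{pool_id}, and each pool becomes
#' one output sample. Pooled values are thickness-weighted means of the
#' member sections (preserving concentration semantics); pooled tissue
#' amount is the sum, pooled radial order the mean.
#'
#' @param sections data.frame with columns \code{tree_id},
#'   \code{radial_order}, \code{zone}, \code{thickness_um},
#'   \code{tissue_amount}, \code{pool_id}.
#' @param section_values numeric matrix of section x protein values, rows
#'   aligned with \code{sections}.
#' @return an \code{\link{expression_matrix}} with one sample per pool.
#' @export
pool_sections <- function(sections, section_values) {
  check_section_table(sections)
  if (!is.matrix(section_values) || nrow(section_values) != nrow(sections))
    stop("section_values must be a matrix with one row per section")
  if (nrow(sections) == 0) stop("empty section table")
  meta <- pool_metadata(sections)
  w <- sections$thickness_um
  num <- rowsum(section_values * w, sections$pool_id)
  den <- rowsum(w, sections$pool_id)
  vals <- num / as.vector(den)
  vals <- vals[meta$sample_id, , drop = FALSE]
  rownames(vals) <- meta$sample_id
  expression_matrix(vals, meta)
}
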