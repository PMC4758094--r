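#' Zone archetype profiles
#'
#' Mean log-abundance profiles (in planted-effect units) over the seven
#' wood-development zones, emulating the protein classes seen in gradient
#' profiling: phloem markers, phloem/cambium proteins, ubiquitous
#' housekeeping proteins, cambial/expansion proteins, transiently induced
#' early-xylem proteins (e.g. laccase-like: up at the expansion-X1
#' boundary, down immediately after), secondary-cell-wall proteins, and
#' mid/late xylem maturation profiles. Steps between consecutive zones are
#' 0 or +/-1 unit so planted effects have a single, known magnitude.
#'
#' @return numeric matrix, archetypes x zones (P, C, E, X1-X4).
#' @export
default_archetypes <- function() {
  zones <- c("P", "C", "E", "X1", "X2", "X3", "X4")
  prof <- rbind(
    phloem_high    = c(1, 0, 0, 0, 0, 0, 0),
    phloem_cambium = c(1, 1, 0, 0, 0, 0, 0),
    ubiquitous     = c(1, 1, 1, 1, 1, 1, 1),
    cambial        = c(0, 1, 1, 0, 0, 0, 0),
    expansion      = c(0, 0, 1, 1, 0, 0, 0),
    transient_x1   = c(0, 0, 0, 1, 0, 0, 0),
    early_xylem    = c(0, 0, 0, 1, 1, 0, 0),
    mid_late_xylem = c(0, 0, 0, 0, 1, 2, 1),
    late_xylem     = c(0, 0, 0, 0, 0, 1, 2))
  colnames(prof) <- zones
  prof
}

default_archetype_mix <- function() {
  c(phloem_high = 0.07, phloem_cambium = 0.08, ubiquitous = 0.10,
    cambial = 0.13, expansion = 0.13, transient_x1 = 0.12,
    early_xylem = 0.13, mid_late_xylem = 0.14, late_xylem = 0.10)
}

#' Configuration for the synthetic wood-development dataset
#'
#' Defaults reproduce the sampling design of a four-tree tangential
#' cryosection study: 110/122/126/124 sections of 20 um pooled into
#' 27/28/28/28 samples across seven ordered zones (phloem and cambium
#' sections analysed singly, expansion-zone extracts pooled in threes, the
#' xylem in larger pools), with log-normal intensities, planted
#' per-transition effects, tree-level random offsets and multiplicative
#' measurement noise.
#'
#' @param n_trees number of replicate trees (default 4).
#' @param sections_per_tree sections cut per tree (recycled; default
#'   c(110, 122, 126, 124)).
#' @param pools_per_tree pooled samples per tree (recycled; default
#'   c(27, 28, 28, 28)).
#' @param n_proteins number of proteins (default 500).
#' @param archetype_mix named proportions over the rows of
#'   \code{\link{default_archetypes}}; must sum to 1.
#' @param effect_size planted per-transition shift in within-zone SD units
#'   (default 3).
#' @param noise_sd within-zone log-scale biological SD (default 0.25,
#'   about a 25 percent CV, typical of label-free LC-MS). Shared by the
#'   sections of a pool: adjacent sections are spatially correlated, so
#'   biological variation operates at the pooled-sample position scale.
#' @param shift_log absolute planted log-shift per unit profile step;
#'   defaults to \code{effect_size * noise_sd}.
#' @param section_sd extra independent per-section log SD (default 0.1);
#'   averages away under pooling.
#' @param tree_sd SD of the per-protein, per-tree random log offset
#'   (default 0.08; replicate trees are consistent).
#' @param gradient_amplitude amplitude (x \code{noise_sd}) of a centered
#'   monotone within-X3 ramp applied to late-xylem proteins, emulating a
#'   near-linear trend through the maturing xylem (default 0.5).
#' @param peptides_per_protein integer range c(min, max) of peptides per
#'   protein (default c(3, 7)).
#' @param peptide_sd per-peptide multiplicative measurement noise on the
#'   log scale (default 0.05).
#' @param unique_prob probability that a non-leading peptide is
#'   sequence-unique (the first peptide of every protein always is).
#' @param base_meanlog,base_sdlog log-normal protein base abundance
#'   parameters.
#' @param thickness_um section thickness (default 20).
#' @param section_mass_mg nominal fresh weight per section (default 0.5).
#' @param seed RNG seed; the same configuration generates bit-identical
#'   output.
#' @return validated list of class \code{synth_config}.
#' @export
synth_config <- function(n_trees = 4,
                         sections_per_tree = c(110, 122, 126, 124),
                         pools_per_tree = c(27, 28, 28, 28),
                         n_proteins = 500,
                         archetype_mix = default_archetype_mix(),
                         effect_size = 3,
                         noise_sd = 0.25,
                         shift_log = NULL,
                         section_sd = 0.1,
                         tree_sd = 0.08,
                         gradient_amplitude = 0.5,
                         peptides_per_protein = c(3, 7),
                         peptide_sd = 0.05,
                         unique_prob = 0.8,
                         base_meanlog = log(1e5),
                         base_sdlog = 1,
                         thickness_um = 20,
                         section_mass_mg = 0.5,
                         seed = 1) {
  if (abs(sum(archetype_mix) - 1) > 1e-8)
    stop("archetype_mix proportions must sum to 1")
  if (any(archetype_mix < 0)) stop("archetype_mix proportions must be >= 0")
  unknown <- setdiff(names(archetype_mix), rownames(default_archetypes()))
  if (length(unknown))
    stop(sprintf("unknown archetype(s): %s", paste(unknown, collapse = ", ")))
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (noise_sd < 0 || section_sd < 0 || tree_sd < 0)
    stop("noise SDs must be >= 0")
  if (n_proteins < 2) stop("need at least 2 proteins")
  stopifnot(length(peptides_per_protein) == 2,
            peptides_per_protein[1] >= 1,
            peptides_per_protein[2] >= peptides_per_protein[1])
  structure(list(
    n_trees = as.integer(n_trees),
    sections_per_tree = rep_len(as.integer(sections_per_tree), n_trees),
    pools_per_tree = rep_len(as.integer(pools_per_tree), n_trees),
    n_proteins = as.integer(n_proteins),
    archetype_mix = archetype_mix,
    effect_size = effect_size,
    noise_sd = noise_sd,
    shift_log = shift_log %||% (effect_size * noise_sd),
    section_sd = section_sd,
    tree_sd = tree_sd,
    gradient_amplitude = gradient_amplitude,
    peptides_per_protein = as.integer(peptides_per_protein),
    peptide_sd = peptide_sd,
    unique_prob = unique_prob,
    base_meanlog = base_meanlog,
    base_sdlog = base_sdlog,
    thickness_um = thickness_um,
    section_mass_mg = section_mass_mg,
    seed = as.integer(seed)),
    class = "synth_config")
}

# pooling layout for one tree: data.frame(zone, size) per pool, radial order.
# Phloem and cambium sections are analysed singly (6 + 6), the expansion
# zone in pools of three, and the xylem in 12 larger pools (3 per segment).
tree_pooling_layout <- function(n_sections, n_pools) {
  nP <- 6L; nC <- 6L
  nE_pools <- n_pools - nP - nC - 12L
  if (nE_pools < 1L)
    stop(sprintf("cannot build a pooling layout with %d pools", n_pools))
  nX_sections <- n_sections - nP - nC - 3L * nE_pools
  if (nX_sections < 12L)
    stop(sprintf("too few sections (%d) for the pooling layout", n_sections))
  base <- nX_sections %/% 12L
  extra <- nX_sections %% 12L
  x_sizes <- rep(base, 12L)
  if (extra > 0) x_sizes[seq_len(extra)] <- base + 1L
  data.frame(
    zone = c(rep("P", nP), rep("C", nC), rep("E", nE_pools),
             rep(c("X1", "X2", "X3", "X4"), each = 3L)),
    size = c(rep(1L, nP + nC), rep(3L, nE_pools), x_sizes),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic wood-development proteomics dataset
#'
#' Produces, from one seed, the full chain of objects the analysis
#' consumes: a section table with the pooling scheme, a section x protein
#' value matrix, the pooled \code{\link{expression_matrix}}, a pooled-level
#' peptide quantification table (peptide intensities decompose the pooled
#' protein quantities with per-peptide ionisation efficiencies and
#' multiplicative noise, so top-3 recovery is testable), and the planted
#' ground truth for every protein x transition cell.
#'
#' @param config a \code{\link{synth_config}}.
#' @return object of class \code{synth_data}: list with \code{sections},
#'   \code{section_values}, \code{expression} (pooled
#'   \code{expression_matrix}), \code{peptides}, \code{truth}
#'   (\code{synth_truth}: archetype per protein, direction and log-shift
#'   matrices, and the expected raw-scale per-transition delta vectors),
#'   and \code{config}.
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  prof <- default_archetypes()
  zones <- colnames(prof)
  mix <- config$archetype_mix
  P <- config$n_proteins

  protein_ids <- sprintf("PROT%04d", seq_len(P))
  archetype <- sample(names(mix), P, replace = TRUE, prob = mix)
  base_log <- stats::rnorm(P, config$base_meanlog, config$base_sdlog)
  tree_fx <- matrix(stats::rnorm(P * config$n_trees, 0, config$tree_sd),
                    nrow = config$n_trees)
  zone_eff <- config$shift_log * prof[archetype, , drop = FALSE]  # P x 7

  # section table across trees
  sec_list <- vector("list", config$n_trees)
  for (t in seq_len(config$n_trees)) {
    layout <- tree_pooling_layout(config$sections_per_tree[t],
                                  config$pools_per_tree[t])
    pool_idx <- rep(seq_len(nrow(layout)), layout$size)
    n_sec <- length(pool_idx)
    sec_list[[t]] <- data.frame(
      tree_id = sprintf("tree%d", t),
      radial_order = seq_len(n_sec) - 1L,
      zone = layout$zone[pool_idx],
      thickness_um = config$thickness_um,
      tissue_amount = config$section_mass_mg *
        exp(stats::rnorm(n_sec, 0, 0.05)),
      pool_id = sprintf("t%d_p%02d", t, pool_idx),
      stringsAsFactors = FALSE)
  }
  sections <- do.call(rbind, sec_list)
  rownames(sections) <- NULL
  n_sec_total <- nrow(sections)
  pool_ids <- unique(sections$pool_id)
  n_pools <- length(pool_ids)

  # log values: base + zone effect + tree effect + within-X3 ramp
  #             + pool-level biological noise + section-level noise
  tree_num <- match(sections$tree_id, sprintf("tree%d", seq_len(config$n_trees)))
  zone_num <- match(sections$zone, zones)
  logv <- matrix(base_log, n_sec_total, P, byrow = TRUE)
  logv <- logv + t(zone_eff)[zone_num, , drop = FALSE]
  logv <- logv + tree_fx[tree_num, , drop = FALSE]
  ramp <- numeric(n_sec_total)
  for (t in seq_len(config$n_trees)) {
    idx <- which(sections$tree_id == sprintf("tree%d", t) & sections$zone == "X3")
    if (length(idx) > 1)
      ramp[idx] <- seq(-0.5, 0.5, length.out = length(idx))
  }
  late <- archetype == "late_xylem"
  if (any(late))
    logv[, late] <- logv[, late] +
      config$gradient_amplitude * config$noise_sd * ramp
  pool_noise <- matrix(stats::rnorm(n_pools * P, 0, config$noise_sd),
                       n_pools, P, dimnames = list(pool_ids, NULL))
  logv <- logv + pool_noise[match(sections$pool_id, pool_ids), , drop = FALSE]
  if (config$section_sd > 0)
    logv <- logv + matrix(stats::rnorm(n_sec_total * P, 0, config$section_sd),
                          n_sec_total, P)
  section_values <- exp(logv)
  colnames(section_values) <- protein_ids

  expression <- pool_sections(sections, section_values)

  # peptide table at the pooled-sample level
  rng <- config$peptides_per_protein
  n_pep <- if (rng[1] == rng[2]) rep(rng[1], P) else
    sample(seq(rng[1], rng[2]), P, replace = TRUE)
  pep_prot <- rep(seq_len(P), n_pep)
  tot_pep <- length(pep_prot)
  eff <- stats::rlnorm(tot_pep, meanlog = 0, sdlog = 0.7)
  first_pep <- !duplicated(pep_prot)
  is_unique <- first_pep | (stats::runif(tot_pep) < config$unique_prob)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")
  pep_len <- sample(8:15, tot_pep, replace = TRUE)
  pep_seq <- vapply(pep_len, function(L)
    paste(sample(aa, L, replace = TRUE), collapse = ""), character(1))
  pep_seq <- make.unique(pep_seq, sep = "")
  # extensive protein amount per pool: concentration x pooled tissue
  amount <- expression$values *
    expression$sample_meta$tissue_amount  # pools x proteins
  pool_rep <- rep(seq_len(n_pools), each = tot_pep)
  pep_rep <- rep(seq_len(tot_pep), times = n_pools)
  inten <- amount[cbind(pool_rep, pep_prot[pep_rep])] * eff[pep_rep] *
    exp(stats::rnorm(n_pools * tot_pep, 0, config$peptide_sd))
  peptides <- data.frame(
    protein_id = protein_ids[pep_prot[pep_rep]],
    peptide_seq = pep_seq[pep_rep],
    sample_id = expression$sample_meta$sample_id[pool_rep],
    intensity = inten,
    is_unique = is_unique[pep_rep],
    stringsAsFactors = FALSE)

  # planted truth per protein x transition
  series <- zone_series(ordered_zones = zones)
  pairs <- series$transition_pairs
  n_tr <- nrow(pairs)
  step_units <- prof[archetype, pairs$to, drop = FALSE] -
    prof[archetype, pairs$from, drop = FALSE]          # P x transitions
  colnames(step_units) <- series$labels
  rownames(step_units) <- protein_ids
  shift_log <- config$shift_log * step_units
  direction <- matrix("none", P, n_tr,
                      dimnames = list(protein_ids, series$labels))
  direction[shift_log > 0] <- "up"
  direction[shift_log < 0] <- "down"
  tree_mean_factor <- colMeans(exp(tree_fx))           # length P
  delta <- matrix(NA_real_, n_tr, P,
                  dimnames = list(series$labels, protein_ids))
  for (k in seq_len(n_tr)) {
    e_to <- exp(config$shift_log * prof[archetype, pairs$to[k]])
    e_from <- exp(config$shift_log * prof[archetype, pairs$from[k]])
    delta[k, ] <- tree_mean_factor * exp(base_log) * (e_to - e_from)
  }
  truth <- structure(list(archetype = stats::setNames(archetype, protein_ids),
                          direction = direction,
                          shift_log = shift_log,
                          delta = delta,
                          series = series),
                     class = "synth_truth")

  structure(list(sections = sections,
                 section_values = section_values,
                 expression = expression,
                 peptides = peptides,
                 truth = truth,
                 config = config),
            class = "synth_data")
}

#' @export
print.synth_data <- function(x, ...) {
  cat(sprintf("synth_data: %d sections -> %d pooled samples, %d proteins, seed %d\n",
              nrow(x$sections), nrow(x$expression$values),
              x$config$n_proteins, x$config$seed))
  invisible(x)
}

#' Confusion of differential calls against planted truth
#'
#' Partitions every protein x transition cell: a true positive is a call
#' that matches the planted direction; any non-"none" call that disagrees
#' with the truth (planted "none" or opposite sign) is a false positive;
#' a missed planted change is a false negative.
#'
#' @param calls a \code{\link{call_differential}} object.
#' @param truth the \code{synth_truth} from \code{\link{generate_dataset}}.
#' @return list with \code{per_transition} (data.frame of TP/FP/FN/TN,
#'   sensitivity and false-discovery proportion per transition) and
#'   \code{overall} (the same pooled over transitions).
#' @export
truth_confusion <- function(calls, truth) {
  stopifnot(inherits(calls, "differential_calls"),
            inherits(truth, "synth_truth"))
  df <- calls$calls
  if (!setequal(unique(df$protein_id), rownames(truth$direction)))
    stop("call table and truth cover different protein sets")
  if (!setequal(unique(df$transition), colnames(truth$direction)))
    stop("call table and truth cover different transition sets")
  true_dir <- truth$direction[cbind(match(df$protein_id, rownames(truth$direction)),
                                    match(df$transition, colnames(truth$direction)))]
  called <- df$direction != "none"
  planted <- true_dir != "none"
  tp <- called & planted & df$direction == true_dir
  fp <- called & !tp
  fn <- !called & planted
  tn <- !called & !planted
  summarise <- function(sel) {
    TP <- sum(tp[sel]); FP <- sum(fp[sel]); FN <- sum(fn[sel]); TN <- sum(tn[sel])
    data.frame(TP = TP, FP = FP, FN = FN, TN = TN,
               sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
               fdr = FP / max(TP + FP, 1))
  }
  per_tr <- do.call(rbind, lapply(calls$transitions, function(tr)
    cbind(transition = tr, summarise(df$transition == tr))))
  overall <- summarise(rep(TRUE, nrow(df)))
  list(per_transition = per_tr, overall = overall)
}
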