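test_that("the default design emits 482 sections pooled to 27+28+28+28 samples", {
  d <- generate_dataset(synth_config(n_proteins = 10, seed = 2))
  expect_equal(nrow(d$sections), 482)
  pools_by_tree <- tapply(d$expression$sample_meta$sample_id,
                          d$expression$sample_meta$tree_id,
                          length)
  expect_equal(as.vector(pools_by_tree[paste0("tree", 1:4)]),
               c(27L, 28L, 28L, 28L))
  expect_equal(nrow(d$expression$values), 111)
  # section counts per tree follow the configuration
  expect_equal(as.vector(table(d$sections$tree_id)[paste0("tree", 1:4)]),
               c(110L, 122L, 126L, 124L))
  # every zone is represented and radial order is strictly increasing per tree
  expect_setequal(unique(d$sections$zone),
                  c("P", "C", "E", "X1", "X2", "X3", "X4"))
  for (t in paste0("tree", 1:4)) {
    ro <- d$sections$radial_order[d$sections$tree_id == t]
    expect_true(all(diff(ro) > 0))
  }
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- synth_config(n_proteins = 30, seed = 77)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$expression$values, d2$expression$values)
  expect_identical(d1$peptides, d2$peptides)
  expect_identical(d1$truth$direction, d2$truth$direction)
  d3 <- generate_dataset(synth_config(n_proteins = 30, seed = 78))
  expect_false(identical(d1$expression$values, d3$expression$values))
})

test_that("zero effect size plants no differential truth", {
  d <- generate_dataset(synth_config(n_proteins = 40, effect_size = 0,
                                     seed = 5))
  expect_true(all(d$truth$direction == "none"))
  expect_true(all(d$truth$shift_log == 0))
})

test_that("within-zone log SD of pooled samples tracks the configured noise", {
  d <- generate_dataset(synth_config(n_proteins = 120, seed = 9))
  lv <- log(d$expression$values)
  meta <- d$expression$sample_meta
  # per-protein, per-zone SD within one tree (no tree effect, no zone shift);
  # ubiquitous proteins in a non-gradient zone follow noise_sd
  ub <- names(d$truth$archetype)[d$truth$archetype == "ubiquitous"]
  sel <- meta$zone == "C"
  sds <- apply(lv[sel, ub, drop = FALSE], 2, function(v)
    sd(v - ave(v, meta$tree_id[sel])))
  pooled_sd <- sqrt(mean(sds^2))
  expect_lt(abs(pooled_sd - d$config$noise_sd) / d$config$noise_sd, 0.10)
})

test_that("planted deltas are recoverable by the mean-difference oracle at zero noise", {
  cfg <- synth_config(n_proteins = 60, noise_sd = 0, section_sd = 0,
                      tree_sd = 0, shift_log = 0.75, seed = 13)
  d <- generate_dataset(cfg)
  for (k in seq_len(nrow(d$truth$series$transition_pairs))) {
    fz <- d$truth$series$transition_pairs$from[k]
    tz <- d$truth$series$transition_pairs$to[k]
    obs <- mean_diff_oracle(d$expression, fz, tz)
    expect_gte(cosine_sim_h(obs, d$truth$delta[k, ]), 0.99)
  }
})

test_that("the generated section table satisfies the pooling invariants", {
  d <- generate_dataset(synth_config(n_proteins = 5, seed = 3))
  s <- d$sections
  expect_true(all(s$thickness_um > 0))
  expect_true(all(s$tissue_amount > 0))
  by_pool <- split(s, s$pool_id)
  expect_true(all(vapply(by_pool, function(g)
    length(unique(g$tree_id)) == 1 && length(unique(g$zone)) == 1,
    logical(1))))
  # pooled expression matrix equals pooling the emitted section values
  em2 <- pool_sections(d$sections, d$section_values)
  expect_equal(em2$values, d$expression$values, tolerance = 1e-12)
})

test_that("peptide decomposition supports top-3 recovery of pooled quantities", {
  d <- generate_dataset(synth_config(n_proteins = 25, seed = 21,
                                     peptide_sd = 0))
  m <- quantify_proteins(d$peptides)
  m <- m[d$expression$sample_meta$sample_id, d$expression$protein_ids]
  amount <- d$expression$values * d$expression$sample_meta$tissue_amount
  # per protein, top-3 sum = amount x (sum of its top-3 efficiencies):
  # correlation per protein across samples should be essentially exact
  cors <- vapply(seq_len(25), function(j) cor(m[, j], amount[, j]), numeric(1))
  expect_true(all(cors > 1 - 1e-10))
})

test_that("truth_confusion partitions cells and computes the stated rates", {
  direction <- matrix("none", 3, 2,
                      dimnames = list(paste0("P", 1:3), c("A/B", "B/C")))
  direction[1, 1] <- "up"; direction[2, 2] <- "down"
  truth <- structure(list(direction = direction), class = "synth_truth")
  calls_df <- expand.grid(protein_id = paste0("P", 1:3),
                          transition = c("A/B", "B/C"),
                          stringsAsFactors = FALSE)
  calls_df$estimate <- 0; calls_df$ci_low <- -1; calls_df$ci_high <- 1
  calls_df$direction <- "none"
  # perfect calls
  perfect <- calls_df
  perfect$direction[perfect$protein_id == "P1" & perfect$transition == "A/B"] <- "up"
  perfect$direction[perfect$protein_id == "P2" & perfect$transition == "B/C"] <- "down"
  cc <- structure(list(calls = perfect, alpha = 0.05,
                       transitions = c("A/B", "B/C")),
                  class = "differential_calls")
  conf <- truth_confusion(cc, truth)
  expect_equal(conf$overall$sensitivity, 1)
  expect_equal(conf$overall$fdr, 0)
  # all-none calls: zero sensitivity
  cc0 <- structure(list(calls = calls_df, alpha = 0.05,
                        transitions = c("A/B", "B/C")),
                   class = "differential_calls")
  conf0 <- truth_confusion(cc0, truth)
  expect_equal(conf0$overall$sensitivity, 0)
  expect_equal(conf0$overall$TP + conf0$overall$FP +
                 conf0$overall$FN + conf0$overall$TN, 6)
  # constructed counts: 8 TP, 2 FP, 2 FN -> sensitivity 0.8, FDR 0.2
  dir2 <- matrix("up", 4, 3,
                 dimnames = list(paste0("Q", 1:4), c("A/B", "B/C", "C/D")))
  dir2[1, 1] <- "none"; dir2[2, 1] <- "none"   # 10 planted, 2 null cells
  truth2 <- structure(list(direction = dir2), class = "synth_truth")
  grid2 <- expand.grid(protein_id = paste0("Q", 1:4),
                       transition = c("A/B", "B/C", "C/D"),
                       stringsAsFactors = FALSE)
  grid2$estimate <- 0; grid2$ci_low <- 0; grid2$ci_high <- 0
  grid2$direction <- "up"                       # both null cells called: 2 FP
  grid2$direction[grid2$protein_id == "Q3" & grid2$transition == "A/B"] <- "none"
  grid2$direction[grid2$protein_id == "Q4" & grid2$transition == "A/B"] <- "none"
  cc2 <- structure(list(calls = grid2, alpha = 0.05,
                        transitions = c("A/B", "B/C", "C/D")),
                   class = "differential_calls")
  conf2 <- truth_confusion(cc2, truth2)
  expect_equal(conf2$overall$TP, 8)
  expect_equal(conf2$overall$FP, 2)
  expect_equal(conf2$overall$FN, 2)
  expect_equal(conf2$overall$sensitivity, 0.8)
  expect_equal(conf2$overall$fdr, 0.2)
  # mismatched protein sets are rejected
  bad <- cc; bad$calls$protein_id <- sub("P3", "P9", bad$calls$protein_id)
  expect_error(truth_confusion(bad, truth), "different protein sets")
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(archetype_mix = c(ubiquitous = 0.5)), "sum to 1")
  expect_error(synth_config(archetype_mix = c(nope = 1)), "unknown archetype")
  expect_error(synth_config(effect_size = -1), "effect_size")
})
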