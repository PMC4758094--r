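test_that("the default zone series covers the two cambium-rooted files", {
  zs <- zone_series()
  expect_equal(zs$ordered_zones, c("P", "C", "E", "X1", "X2", "X3", "X4"))
  expect_equal(zs$labels, c("C/P", "C/E", "E/X1", "X1/X2", "X2/X3", "X3/X4"))
  expect_error(zone_series(transition_pairs = data.frame(from = "X4",
                                                         to = "X5")),
               "unknown zone")
  expect_error(zone_series(ordered_zones = c("A", "A", "B")), "duplicate")
})

test_that("a clean two-group shift gives the hand-computed d and p_dist", {
  delta <- c(3, 4, rep(0, 8))
  X <- rbind(matrix(0, 5, 10), matrix(rep(delta, each = 5), 5, 10))
  em <- make_em(X, rep(c("E", "X1"), each = 5))
  tr <- transition_model(em, "E", "X1", n_orth = 0)
  # centered rows are -delta/2 and +delta/2; scores +-|delta|/2,
  # d = sqrt(10)*|delta|/2
  expect_equal(tr$d, sqrt(10) * 5 / 2, tolerance = 1e-10)
  expect_equal(unname(tr$p_dist[1:2]), c(4.7434165, 6.3245553),
               tolerance = 1e-6)
  expect_equal(tr$d, sqrt(sum(tr$model$t_p^2)), tolerance = 1e-12)
  expect_equal(sqrt(sum(tr$p_dist^2)), tr$d, tolerance = 1e-12)
  # doubling the shift doubles d and keeps the direction
  em2 <- make_em(2 * X, rep(c("E", "X1"), each = 5))
  tr2 <- transition_model(em2, "E", "X1", n_orth = 0)
  expect_equal(tr2$d, 2 * tr$d, tolerance = 1e-10)
  expect_equal(unname(tr2$model$p_p), unname(tr$model$p_p), tolerance = 1e-10)
})

test_that("swapping the zone pair negates p_dist exactly", {
  set.seed(31)
  em <- shifted_two_zone_em(n_per_zone = 7, n_proteins = 30, n_shift = 6)
  em$sample_meta$zone <- sub("A", "E", sub("B", "X1", em$sample_meta$zone))
  fwd <- transition_model(em, "E", "X1", n_orth = 1)
  rev <- transition_model(em, "X1", "E", n_orth = 1)
  expect_equal(rev$p_dist, fwd$p_dist * -1, tolerance = 1e-10)
  expect_equal(rev$d, fwd$d, tolerance = 1e-10)
})

test_that("d is invariant to protein reordering and p_dist permutes along", {
  set.seed(32)
  em <- shifted_two_zone_em(n_per_zone = 6, n_proteins = 25, n_shift = 5)
  perm <- sample(25)
  em_p <- expression_matrix(em$values[, perm], em$sample_meta)
  tr <- transition_model(em, "A", "B", n_orth = 1)
  tr_p <- transition_model(em_p, "A", "B", n_orth = 1)
  expect_equal(tr_p$d, tr$d, tolerance = 1e-10)
  expect_equal(unname(tr_p$p_dist), unname(tr$p_dist[perm]), tolerance = 1e-10)
})

test_that("underpopulated or absent zones are reported by name", {
  em <- make_em(matrix(rnorm(20), 5, 4), c("C", "C", "P", "P", "E"))
  expect_error(transition_model(em, "C", "X1"), "X1")
  expect_error(transition_model(em, "E", "P"), "'E'")
})

test_that("stepwise_series returns one result per pair in order", {
  set.seed(33)
  zones <- rep(c("P", "C", "E", "X1", "X2", "X3", "X4"), each = 4)
  lv <- matrix(rnorm(length(zones) * 40, log(1e4), 0.3),
               length(zones), 40)
  lv[, 1:10] <- lv[, 1:10] + outer(as.numeric(zones %in% c("X2", "X3", "X4")),
                                   rep(1, 10))
  em <- make_em(exp(lv), zones)
  res <- stepwise_series(em, zone_series(), n_orth = 1)
  expect_s3_class(res, "transition_series")
  expect_equal(names(res), c("C/P", "C/E", "E/X1", "X1/X2", "X2/X3", "X3/X4"))
  # two-zone series gives a single result
  zs2 <- zone_series(c("A", "B"), data.frame(from = "A", to = "B"))
  em2 <- make_em(exp(matrix(rnorm(8 * 6), 8, 6)), rep(c("A", "B"), each = 4))
  expect_length(stepwise_series(em2, zs2), 1)
  # a missing zone is listed in the error
  em_noX4 <- subset_samples(em, em$sample_meta$zone != "X4")
  expect_error(stepwise_series(em_noX4, zone_series()), "X4")
})

test_that("meta-PCA reflects exactly opposed transitions through the origin", {
  set.seed(34)
  base <- matrix(rnorm(4 * 30, sd = 0.1), 4, 30)
  v <- rnorm(30) * 3
  pd <- rbind(base, v, -v)
  fake <- lapply(seq_len(6), function(i)
    structure(list(label = paste0("T", i), p_dist = pd[i, ],
                   d = sqrt(sum(pd[i, ]^2))),
              class = "transition_result"))
  ov <- meta_pca(fake, n_components = 2)
  sc <- ov$meta_pca$scores
  # the component dominated by the opposed pair sees mirror-image scores
  comp <- which.max(abs(sc[5, ]))
  expect_gt(abs(sc[5, comp]), 3 * max(abs(sc[1:4, comp])))
  expect_equal(unname(sc[6, comp]), -unname(sc[5, comp]), tolerance = 0.15)
  # oracle agreement on the stacked matrix
  o <- svd_pca_oracle(pd, 2)
  expect_equal(abs(unname(ov$meta_pca$scores)), abs(o$scores),
               tolerance = 1e-8)
})

test_that("meta-PCA rejects degenerate input", {
  fake_same <- lapply(1:3, function(i)
    structure(list(label = paste0("T", i), p_dist = c(1, 2, 3), d = 1),
              class = "transition_result"))
  expect_error(meta_pca(fake_same), "no variance")
  one <- fake_same[1]
  expect_error(meta_pca(one), "at least 2")
  bad_dim <- fake_same
  bad_dim[[2]]$p_dist <- c(1, 2)
  expect_error(meta_pca(bad_dim), "mismatch")
  # at most n_transitions - 1 informative components
  set.seed(35)
  fake6 <- lapply(1:6, function(i)
    structure(list(label = paste0("T", i), p_dist = rnorm(20), d = 1),
              class = "transition_result"))
  expect_error(meta_pca(fake6, n_components = 6), "n_components")
  expect_silent(meta_pca(fake6, n_components = 5))
})
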