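test_that("top3_quantity sums the top peptides, all of them when fewer than n", {
  expect_equal(top3_quantity(c(10, 5, 1, 0.5)), 16)
  expect_equal(top3_quantity(7), 7)
  expect_equal(top3_quantity(rep(2, 6)), 6)
  expect_equal(top3_quantity(c(1, 5, 10, 0.5)), top3_quantity(c(10, 5, 1, 0.5)))
  expect_error(top3_quantity(numeric(0)), "no peptides")
  expect_error(top3_quantity(c(1, -2)), "non-negative")
})

test_that("top3_quantity is monotone under adding peptides", {
  set.seed(11)
  for (i in 1:20) {
    v <- runif(sample(1:6, 1), 0, 100)
    extra <- runif(1, 0, 100)
    expect_gte(top3_quantity(c(v, extra)), top3_quantity(v))
  }
})

pep_table <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  names(df) <- c("protein_id", "peptide_seq", "sample_id", "intensity",
                 "is_unique")[seq_along(df)]
  df
}

test_that("unique_peptide_filter keeps all peptides of identified proteins", {
  tbl <- pep_table(c("A", "A", "A", "B", "B"),
                   c("AAK", "ACK", "SHRD", "SHRD", "TTK"),
                   rep("s1", 5),
                   c(10, 5, 2, 2, 8),
                   c(TRUE, TRUE, FALSE, FALSE, FALSE))
  out <- unique_peptide_filter(tbl)
  expect_setequal(unique(out$protein_id), "A")
  expect_equal(nrow(out), 3)  # shared peptide of A retained
  empty <- tbl[0, ]
  expect_equal(nrow(unique_peptide_filter(empty)), 0)
})

test_that("quantify_proteins builds the top-3 matrix with imputed zeros flagged", {
  tbl <- pep_table(rep(c("A", "B"), c(4, 1)),
                   c("P1", "P2", "P3", "P4", "Q1"),
                   rep("s1", 5),
                   c(10, 5, 1, 0.5, 7),
                   rep(TRUE, 5))
  tbl2 <- tbl; tbl2$sample_id <- "s2"; tbl2 <- tbl2[tbl2$protein_id == "A", ]
  m <- quantify_proteins(rbind(tbl, tbl2))
  expect_equal(m["s1", "A"], 16)
  expect_equal(m["s1", "B"], 7)
  expect_equal(m["s2", "B"], 0)        # undetected -> recorded as zero
  det <- attr(m, "detected")
  expect_true(det["s1", "B"])
  expect_false(det["s2", "B"])
})

test_that("total_tissue_normalize divides by tissue amount and round-trips", {
  v <- matrix(c(100, 30, 50, 20), 2, 2)
  em <- make_em(v, c("C", "P"), tissue = c(2, 4))
  norm <- total_tissue_normalize(em)
  expect_equal(norm$values[1, 1], 50)
  back <- norm$values * em$sample_meta$tissue_amount
  expect_equal(max(abs(back - em$values)), 0, tolerance = 1e-12)
  em1 <- make_em(v, c("C", "P"), tissue = c(1, 1))
  expect_equal(total_tissue_normalize(em1)$values, em1$values)
  em0 <- make_em(v, c("C", "P"), tissue = c(0, 1))
  expect_error(total_tissue_normalize(em0), "s1")
})

section_df <- function(n, tree = "tree1", zone = "E", pool = "pl1",
                       thickness = 20, radial0 = 0) {
  data.frame(tree_id = tree, radial_order = radial0 + seq_len(n) - 1,
             zone = zone, thickness_um = thickness, tissue_amount = 0.5,
             pool_id = pool, stringsAsFactors = FALSE)
}

test_that("pool_sections averages by thickness and aggregates metadata", {
  secs <- section_df(3)
  vals <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "pA"))
  em <- pool_sections(secs, vals)
  expect_equal(unname(em$values[1, 1]), 2)  # equal weights -> plain mean
  expect_equal(em$sample_meta$tissue_amount, 1.5)
  expect_equal(em$sample_meta$radial_order, 1)
  # single-section pool is the identity
  em1 <- pool_sections(section_df(1), matrix(4.2, 1, 1,
                                             dimnames = list(NULL, "pA")))
  expect_equal(unname(em1$values[1, 1]), 4.2)
  # unequal thickness: weighted mean
  secs_w <- section_df(2); secs_w$thickness_um <- c(20, 60)
  em_w <- pool_sections(secs_w, matrix(c(1, 5), 2, 1,
                                       dimnames = list(NULL, "pA")))
  expect_equal(unname(em_w$values[1, 1]), (1 * 20 + 5 * 60) / 80)
})

test_that("pool_sections rejects pools spanning trees or zones", {
  secs <- section_df(2)
  secs$tree_id <- c("tree1", "tree2")
  vals <- matrix(1:2, 2, 1, dimnames = list(NULL, "pA"))
  expect_error(pool_sections(secs, vals), "tree")
  secs2 <- section_df(2); secs2$zone <- c("E", "X1")
  expect_error(pool_sections(secs2, vals), "zone")
})

test_that("pooling conserves thickness-weighted totals", {
  set.seed(5)
  secs <- rbind(section_df(3, pool = "a"),
                section_df(4, pool = "b", radial0 = 3),
                section_df(2, pool = "c", zone = "X1", radial0 = 7))
  secs$thickness_um <- runif(nrow(secs), 10, 40)
  vals <- matrix(runif(nrow(secs) * 5), nrow(secs), 5,
                 dimnames = list(NULL, paste0("p", 1:5)))
  em <- pool_sections(secs, vals)
  pooled_total <- colSums(em$values * em$sample_meta$total_thickness_um)
  section_total <- colSums(vals * secs$thickness_um)
  expect_equal(pooled_total, section_total, tolerance = 1e-9)
})
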