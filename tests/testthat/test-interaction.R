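library(dplyr)

test_that("residue aggregation sums only detrimental substitutions", {
  sc <- fake_scores(pos = rep(10L, 3L), alt = c("K", "R", "W"),
                    score = c(-2, -3, 1))
  res <- residue_aggregate(sc)
  expect_equal(res$R_i, -5)
  expect_equal(res$n_sub, 2L)
  # all substitutions at or above tau -> 0
  res0 <- residue_aggregate(fake_scores(11L, "K", 0.4))
  expect_equal(res0$R_i, 0)
  expect_equal(res0$n_sub, 0L)
  # 19 floored substitutions -> 19 * floor
  res19 <- residue_aggregate(
    fake_scores(rep(12L, 19L), setdiff(aa_order(), "A"), rep(-5, 19L),
                status = "floored"))
  expect_equal(res19$R_i, -95)
  # missing variants are excluded
  resm <- residue_aggregate(
    fake_scores(rep(13L, 2L), c("K", "R"), c(-2, NA),
                status = c("scored", "missing")))
  expect_equal(resm$R_i, -2)
})

test_that("residue aggregation is monotone in substitution scores", {
  set.seed(5)
  base <- fake_scores(rep(20L, 19L), setdiff(aa_order(), "A"),
                      rnorm(19, -1, 2))
  r0 <- residue_aggregate(base)$R_i
  worse <- base
  worse$score[7] <- worse$score[7] - 3
  expect_lte(residue_aggregate(worse)$R_i, r0)
})

test_that("separation-of-function classes cover the (s_A, s_B) grid", {
  grid <- expand.grid(s_A = c(-5, -1.5, 0), s_B = c(-5, -1.5, 0))
  ta <- fake_scores(seq_len(nrow(grid)) + 100L, "K", grid$s_A)
  tb <- fake_scores(seq_len(nrow(grid)) + 100L, "K", grid$s_B, bait = "B")
  calls <- classify_sof(ta, tb)
  expected <- c("both_lost", "indeterminate", "B_specific_loss",
                "indeterminate", "indeterminate", "indeterminate",
                "A_specific_loss", "indeterminate", "both_retained")
  expect_equal(calls$sof_class, expected)
  # every scored variant receives exactly one class
  expect_equal(nrow(calls), nrow(grid))
  expect_error(classify_sof(ta, tb, tau_loss = -1, tau_ret = -2),
               "tau_loss")
})

test_that("variants missing in either table are skipped and counted", {
  ta <- fake_scores(c(1L, 2L), "K", c(-5, 0),
                    status = c("scored", "missing"))
  tb <- fake_scores(c(1L, 2L), "K", c(0, 0), bait = "B")
  calls <- classify_sof(ta, tb)
  expect_equal(nrow(calls), 1L)
  expect_equal(attr(calls, "n_skipped"), 1L)
  expect_equal(calls$sof_class, "A_specific_loss")
})

test_that("perfect separation gives AUC 1 and identity gives Spearman 1", {
  n <- 40L
  ta <- fake_scores(seq_len(n), "K", c(rep(-5, 20), rep(0, 20)))
  tb <- fake_scores(seq_len(n), "K", c(rep(-5, 20), rep(0, 20)), bait = "B")
  ann <- tibble(pos = seq_len(n), alt = "K",
                annotation = c(rep("pathogenic", 20), rep("benign", 20)))
  rep1 <- external_concordance(ta, tb, ann, group_pos = "pathogenic",
                               group_neg = "benign")
  expect_equal(unname(rep1$auc["combined"]), 1.0)
  num <- tibble(pos = seq_len(n), alt = "K",
                annotation = pmin(ta$score, tb$score))
  rep2 <- external_concordance(ta, tb, num)
  expect_equal(unname(rep2$spearman["combined"]), 1.0)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(9)
  n <- 60L
  s <- rnorm(n)
  lab <- rep(c("pathogenic", "benign"), each = n / 2)
  ann <- tibble(pos = seq_len(n), alt = "K", annotation = lab)
  ta <- fake_scores(seq_len(n), "K", s)
  tb <- fake_scores(seq_len(n), "K", s + 10, bait = "B")  # min() picks A
  a1 <- external_concordance(ta, tb, ann, "pathogenic", "benign")$auc
  ta2 <- fake_scores(seq_len(n), "K", exp(s))
  tb2 <- fake_scores(seq_len(n), "K", exp(s) + 10, bait = "B")
  a2 <- external_concordance(ta2, tb2, ann, "pathogenic", "benign")$auc
  expect_equal(unname(a1["combined"]), unname(a2["combined"]))
})

test_that("VUS variants below the loss threshold are flagged", {
  ta <- fake_scores(1:3, "K", c(-5, -0.2, -4))
  tb <- fake_scores(1:3, "K", c(-4.5, 0, 0.5), bait = "B")
  ann <- tibble(pos = 1:3, alt = "K",
                annotation = c("VUS", "VUS", "VUS"))
  rep <- external_concordance(ta, tb, ann)
  expect_equal(rep$vus_flagged$pos, c(1L, 3L))
})

test_that("heatmap matrix has 214 x 20 layout with WT and floor masks", {
  d <- screen_design()
  eff <- draw_effects(d, effect_config(baits = "A"), seed = 2L)
  cnt <- simulate_counts(d, eff, depth_config(n_per_sample = 3e4), seed = 2L)
  sc <- score_screen(cnt, d)
  m <- heatmap_matrix(sc, d)
  expect_equal(dim(m$score), c(214L, 20L))
  expect_equal(colnames(m$score), aa_order())
  expect_equal(rownames(m$score)[1], "1646")
  expect_true(all(rowSums(m$status == "wt") == 1L))
  floored <- which(m$status == "floored")
  expect_gt(length(floored), 0L)
  expect_true(all(m$score[floored] == -5))
  expect_true(all(is.na(m$score[m$status == "missing"])))
})

test_that("residue attribute export round-trips byte-identically", {
  res <- tibble(pos = c(1646L, 1700L), R_i = c(-3.25, 0), n_sub = c(2L, 0L))
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_residue_attributes(res, "bindingLoss", f1)
  lines <- readLines(f1)
  expect_equal(sum(grepl("^\t:", lines)), 2L)
  parsed <- read_residue_attributes(f1)
  expect_equal(parsed$attr_name, "bindingLoss")
  expect_equal(parsed$residues$pos, res$pos)
  write_residue_attributes(parsed$residues, parsed$attr_name, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(write_residue_attributes(res, "", f1), "non-empty")
  expect_error(write_residue_attributes(res[0, ], "x", f1), "empty")
})
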