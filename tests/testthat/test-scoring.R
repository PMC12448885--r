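library(dplyr)

test_that("replicate_score reproduces its closed form on frozen examples", {
  expect_equal(replicate_score(100, 100, 100, 100)$s_r, 0)
  expect_equal(replicate_score(10, 100, 100, 100)$s_r,
               log(10.5 / 100.5), tolerance = 1e-12)
  expect_equal(round(replicate_score(10, 100, 100, 100)$s_r, 3), -2.259)
  expect_equal(replicate_score(0, 999, 999, 999)$s_r,
               log(0.5 / 999.5), tolerance = 1e-12)
  expect_equal(replicate_score(0, 999, 999, 999)$s_r, -7.601,
               tolerance = 1e-3)
  expect_error(replicate_score(-1, 10, 10, 10), "non-negative")
})

test_that("replicate_score matches independent evaluation on 1,000 quadruples", {
  set.seed(71)
  q <- matrix(rpois(4000, lambda = 50), ncol = 4)
  got <- replicate_score(q[, 1], q[, 2], q[, 3], q[, 4])
  # independent direct evaluation, written separately from the package path
  p <- 0.5
  s_ref <- log((q[, 1] + p) / (q[, 3] + p)) - log((q[, 2] + p) / (q[, 4] + p))
  se_ref <- sqrt(1 / (q[, 1] + p) + 1 / (q[, 2] + p) +
                   1 / (q[, 3] + p) + 1 / (q[, 4] + p))
  expect_true(max(abs(got$s_r - s_ref)) < 1e-12)
  expect_true(max(abs(got$se_r - se_ref)) < 1e-12)
  expect_true(all(got$se_r > 0))
})

test_that("score is monotone in selective and non-selective counts", {
  c_sel <- 0:200
  s <- replicate_score(c_sel, 50, 80, 80)$s_r
  expect_true(all(diff(s) > 0))
  s2 <- replicate_score(50, c_sel, 80, 80)$s_r
  expect_true(all(diff(s2) < 0))
})

test_that("depth scaling perturbs the score only within the pseudocount bound", {
  p <- 0.5
  for (k in c(2, 10, 100)) {
    c_sel <- 20; c_non <- 60; w <- 100
    s1 <- replicate_score(c_sel, c_non, w, w)$s_r
    s2 <- replicate_score(k * c_sel, k * c_non, k * w, k * w)$s_r
    bound <- abs(log((c_sel + p) / (k * c_sel + p)) -
                   log((w + p) / (k * w + p))) +
      abs(log((c_non + p) / (k * c_non + p)) - log((w + p) / (k * w + p)))
    expect_lte(abs(s2 - s1), bound + 1e-12)
  }
  # the perturbation vanishes as counts grow
  big <- replicate_score(2e6, 6e6, 1e7, 1e7)$s_r
  sml <- replicate_score(2e3, 6e3, 1e4, 1e4)$s_r
  expect_lt(abs(big - sml), 1e-3)
})

test_that("replicate combination is a convex weighted mean", {
  eq <- combine_replicates(c(-1, -2, -3), c(0.3, 0.3, 0.3))
  expect_equal(eq$s, -2)
  one <- combine_replicates(-2, 0.3)
  expect_equal(one$s, -2)
  expect_equal(one$se, 0.3)
  set.seed(12)
  for (i in 1:20) {
    s_r <- rnorm(3, -2, 1)
    se_r <- runif(3, 0.1, 0.6)
    cmb <- combine_replicates(s_r, se_r)
    expect_gte(cmb$s, min(s_r))
    expect_lte(cmb$s, max(s_r))
  }
  expect_error(combine_replicates(numeric(0), numeric(0)), "no replicates")
})

test_that("random-effects combination matches metafor's DerSimonian-Laird", {
  library(metafor)
  set.seed(31)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    s_r <- rnorm(k, -1, 1.5)
    se_r <- runif(k, 0.1, 0.8)
    ours <- combine_replicates(s_r, se_r)
    ref <- rma(yi = s_r, sei = se_r, method = "DL")
    expect_equal(ours$s, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(ours$se, ref$se, tolerance = 1e-8)
    expect_equal(ours$sigma2_b, ref$tau2, tolerance = 1e-8)
  }
})

test_that("vectorized row combination agrees with the scalar operation", {
  set.seed(41)
  s_mat <- matrix(rnorm(30), ncol = 3)
  se_mat <- matrix(runif(30, 0.1, 0.5), ncol = 3)
  rows <- satscreen:::combine_rows(s_mat, se_mat)
  for (i in 1:10) {
    ref <- combine_replicates(s_mat[i, ], se_mat[i, ])
    expect_equal(rows$score[i], ref$s)
    expect_equal(rows$se[i], ref$se)
  }
})

test_that("identical overlap scores give zero offsets; shifts are recovered", {
  set.seed(55)
  truth <- tibble(pos = 1:60, wt = "A", alt = "K",
                  score = rnorm(60, -1, 1), se = 0.2, class = "missense")
  frag_tables <- bind_rows(
    truth %>% filter(pos <= 25) %>% mutate(fragment = 1L),
    truth %>% filter(pos >= 20, pos <= 45) %>% mutate(fragment = 2L),
    truth %>% filter(pos >= 40) %>% mutate(fragment = 3L)
  )
  same <- normalize_fragments(frag_tables)
  expect_equal(attr(same, "offsets")$offset, c(0, 0, 0))
  expect_equal(
    same %>% arrange(pos) %>% pull(score),
    truth$score
  )
  # constant shifts (0, +1, +2) -> cumulative offsets (0, -1, -2)
  shifted <- frag_tables %>%
    mutate(score = score + c(0, 1, 2)[fragment])
  fixed <- normalize_fragments(shifted)
  expect_equal(attr(fixed, "offsets")$offset, c(0, -1, -2))
  expect_equal(fixed %>% arrange(pos) %>% pull(score), truth$score)
})

test_that("an injected fragment offset is recovered exactly without noise", {
  set.seed(77)
  truth <- tibble(pos = 1:40, wt = "A", alt = "K",
                  score = rnorm(40, -1, 1), se = 0.2, class = "missense")
  ft <- bind_rows(
    truth %>% filter(pos <= 22) %>% mutate(fragment = 1L),
    truth %>% filter(pos >= 16) %>%
      mutate(fragment = 2L, score = score + 1.3)
  )
  out <- normalize_fragments(ft)
  expect_equal(attr(out, "offsets")$offset[2], -1.3, tolerance = 1e-12)
})

test_that("sparse junctions fall back to a zero offset with a warning", {
  ft <- tibble(
    fragment = c(1L, 1L, 2L, 2L), pos = c(1L, 2L, 2L, 3L),
    wt = "A", alt = "K", class = "missense",
    score = c(-1, -2, -1, -3), se = 0.2
  )
  expect_warning(out <- normalize_fragments(ft), "offset set to 0")
  expect_equal(attr(out, "offsets")$offset, c(0, 0))
})

test_that("dropout curation floors selection-absent, input-present variants", {
  cnt <- one_variant_counts(non = c(50L, 60L, 40L), sel = c(0L, 0L, 0L))
  sc <- score_screen(cnt)
  v <- sc %>% filter(class == "missense", pos == 12)
  expect_equal(v$status, "floored")
  expect_equal(v$score, -5)
  # detected in selection in any replicate -> scored, value untouched
  cnt2 <- one_variant_counts(non = c(50L, 60L, 40L), sel = c(0L, 3L, 0L))
  v2 <- score_screen(cnt2) %>% filter(class == "missense", pos == 12)
  expect_equal(v2$status, "scored")
  expect_lt(v2$score, 0)
  expect_gt(v2$score, -5)
  # absent from the input pool too -> missing, no score
  cnt3 <- one_variant_counts(non = c(0L, 0L, 0L), sel = c(0L, 0L, 0L))
  v3 <- score_screen(cnt3) %>% filter(class == "missense", pos == 12)
  expect_equal(v3$status, "missing")
  expect_true(is.na(v3$score))
})

test_that("marked WT scores exactly zero and every variant has one status", {
  d <- mini_design()
  eff <- draw_effects(d, effect_config(baits = "A", injections = NULL),
                      seed = 8L)
  cnt <- simulate_counts(d, eff, depth_config(n_per_sample = 2e4), seed = 8L)
  sc <- score_screen(cnt, d)
  expect_equal(sc$score[sc$class == "marked_wt"], 0)
  ms <- sc %>% filter(class == "missense")
  expect_equal(nrow(ms), 19L * d$domain$length)
  expect_equal(anyDuplicated(paste(ms$pos, ms$alt)), 0L)
  expect_true(all(ms$status %in% c("scored", "floored", "missing")))
  expect_true(all(ms$se[ms$status == "scored"] > 0))
  # per-replicate marked-WT score is identically zero by construction
  expect_equal(replicate_score(123, 456, 123, 456)$s_r, 0)
})

test_that("a missing marked-WT reference is an error", {
  cnt <- one_variant_counts(non = c(50L, 60L, 40L), sel = c(10L, 9L, 11L)) %>%
    filter(class != "marked_wt")
  expect_error(score_screen(cnt), "marked_wt")
})
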