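test_that("linearity index follows (T - L)/(T + L) with zero-forcing", {
  expect_equal(compute_linearity_index(2, 2), 0)
  expect_equal(compute_linearity_index(5, 0), 1)
  expect_equal(compute_linearity_index(1, 2), -1 / 3)
  expect_equal(compute_linearity_index(-0.2, 1), -1)  # clamped T = 0
  expect_equal(compute_linearity_index(1, -0.5), 1)   # clamped L = 0
  expect_true(is.na(compute_linearity_index(0, -1)))
  x <- compute_linearity_index(runif(20, 0, 3), runif(20, 0, 3))
  expect_true(all(x >= -1 & x <= 1))
})

test_that("interaction-map cells are gated by the significance rule", {
  # no significant response anywhere -> all cells invalid
  rt0 <- fake_rt(grid_mat(1), tt_sig = matrix(FALSE, 9, 9),
                 center_sig = FALSE, df_sig = rep(FALSE, 9))
  m0 <- build_interaction_map(rt0, "r1", test_cells = FALSE)
  expect_false(any(m0$valid))
  expect_true(all(is.na(m0$li)))

  # one significant two-tone pair, one significant dF tone
  sig <- matrix(FALSE, 9, 9)
  sig[3, 5] <- TRUE
  df_sig <- rep(FALSE, 9); df_sig[7] <- TRUE
  rt1 <- fake_rt(grid_mat(1), tt_sig = sig, center_sig = FALSE,
                 df_sig = df_sig)
  m1 <- build_interaction_map(rt1, "r1", test_cells = FALSE)
  want <- matrix(FALSE, 9, 9)
  want[3, 5] <- TRUE     # the significant pair itself
  want[7, ] <- TRUE      # every pair containing the significant dF tone
  expect_equal(unname(m1$valid), want)

  # significant center tone gates the whole grid
  rt2 <- fake_rt(grid_mat(1), tt_sig = matrix(FALSE, 9, 9),
                 center_sig = TRUE, df_sig = rep(FALSE, 9))
  expect_true(all(build_interaction_map(rt2, "r1",
                                        test_cells = FALSE)$valid))
})

test_that("noise-free forward model returns its LI kernel exactly", {
  set.seed(21)
  k <- grid_mat(0)
  k[] <- runif(81, -0.8, 0.8)
  nf <- noise_free_rt(k)
  m <- build_interaction_map(nf$rt, nf$cell$id, test_cells = FALSE)
  expect_true(all(m$valid))
  expect_lt(max(abs(m$li - k)), 1e-6)
})

test_that("mask-aware smoothing preserves constants and renormalizes", {
  u <- grid_mat(0.37)
  expect_equal(smooth_map(u), u)
  # a single valid cell keeps its own value
  one <- grid_mat(NA_real_)
  one[4, 6] <- 0.8
  sm <- smooth_map(one)
  expect_equal(sm[4, 6], 0.8)
  expect_equal(unname(sm[1, 1]), 0.8)  # renormalized, not dragged to 0
  # delta map on a fully valid grid: hand-computed normalized weights
  d <- matrix(0, 3, 3); d[2, 2] <- 1
  sm3 <- smooth_map(d, valid = matrix(TRUE, 3, 3), sigma_grid = 0.4)
  w1 <- exp(-1 / (2 * 0.4^2)); w2 <- exp(-2 / (2 * 0.4^2))
  denom_center <- 1 + 4 * w1 + 4 * w2
  expect_equal(sm3[2, 2], 1 / denom_center)
  # at (1,2): squared distances to the 9 cells are 0,1,1,1,2,2,4,5,5
  w4 <- exp(-4 / (2 * 0.4^2)); w5 <- exp(-5 / (2 * 0.4^2))
  denom_edge <- 1 + 3 * w1 + 2 * w2 + w4 + 2 * w5
  expect_equal(sm3[1, 2], w1 / denom_edge)
})

test_that("nonlinearity test uses the 25-combination resampled null", {
  res <- test_nonlinearity(rep(1, 5), rnorm(5), rnorm(5))
  expect_equal(res$n_null, 25)
  # two-tone identical to every pairwise sum -> none
  expect_equal(test_nonlinearity(rep(2, 5), rep(1, 5), rep(1, 5))$type,
               "none")
  # full separation above: facilitative at the exact enumerated p
  # (tie-free component amplitudes so the rank-sum test stays exact)
  ctr <- c(0.11, 0.23, 0.34, 0.42, 0.57)
  dfa <- c(0.013, 0.019, 0.028, 0.036, 0.049)
  res_f <- test_nonlinearity(c(10, 11, 12, 13, 14), ctr, dfa)
  expect_equal(res_f$type, "facilitative")
  expect_equal(res_f$p, 2 / choose(30, 5), tolerance = 1e-12)
  # full separation below: suppressive
  expect_equal(test_nonlinearity(-(1:5), ctr, dfa)$type, "suppressive")
  # alpha gates the call
  expect_equal(test_nonlinearity(c(10, 11, 12, 13, 14), ctr, dfa,
                                 alpha = 1e-9)$type, "none")
})

test_that("normalized magnitude profile averages per-pair max-normalized tuning", {
  # single pair peaking at dT = 0
  amp <- grid_mat(0)
  amp[5, ] <- c(1, 1, 2, 3, 6, 3, 2, 1, 1)
  sig <- matrix(FALSE, 9, 9); sig[5, 5] <- TRUE
  p1 <- normalized_magnitude_profile(fake_rt(amp, tt_sig = sig))
  expect_equal(p1$n_pairs, 1)
  expect_equal(unname(p1$profile),
               c(1, 1, 2, 3, 6, 3, 2, 1, 1) / 6)
  # all amplitudes equal -> profile identically 1
  pe <- normalized_magnitude_profile(
    fake_rt(grid_mat(2), tt_sig = matrix(TRUE, 9, 9)))
  expect_true(all(pe$profile == 1))
  # two pairs with known vectors -> hand-averaged profile
  amp2 <- grid_mat(0)
  amp2[1, ] <- c(4, 0, 0, 0, 0, 0, 0, 0, 0)   # one-hot at dT = -100
  amp2[2, ] <- rep(2, 9)                      # flat
  sig2 <- matrix(FALSE, 9, 9); sig2[1, 1] <- TRUE; sig2[2, 1] <- TRUE
  p2 <- normalized_magnitude_profile(fake_rt(amp2, tt_sig = sig2))
  expect_equal(p2$n_pairs, 2)
  expect_equal(unname(p2$profile),
               (c(1, 0, 0, 0, 0, 0, 0, 0, 0) + rep(1, 9)) / 2)
})

test_that("timing-preference rules classify by the 1.5x ratio", {
  mk <- function(coin, shift_neg, shift_pos) {
    amp <- grid_mat(0)
    amp[, DT_GRID == 0] <- coin
    amp[, DT_GRID < 0] <- shift_neg
    amp[, DT_GRID > 0] <- shift_pos
    fake_rt(amp, tt_sig = matrix(TRUE, 9, 9))
  }
  expect_equal(classify_timing_preference(mk(1.6, 1, 1), "r1")$label,
               "coincident_preferring")
  expect_equal(classify_timing_preference(mk(1, 1.6, 1.6), "r1")$label,
               "symmetric_shift_preferring")
  expect_equal(classify_timing_preference(mk(1, 2.56, 1.6), "r1")$label,
               "negative_dT_preferring")
  expect_equal(classify_timing_preference(mk(1, 1.6, 2.56), "r1")$label,
               "positive_dT_preferring")
  expect_equal(classify_timing_preference(mk(1.2, 1, 1), "r1")$label,
               "unclassified")
  # with ratio -> 1, only exact ties stay unclassified
  set.seed(13)
  for (i in 1:25) {
    amp <- grid_mat(0); amp[] <- runif(81)
    cl <- classify_timing_preference(fake_rt(amp), "r1", ratio = 1 + 1e-12)
    expect_true(cl$label != "unclassified")
  }
})

test_that("asymmetry index contrasts positive- and negative-dT responses", {
  mk <- function(pos_amp, neg_amp) {
    amp <- grid_mat(0)
    amp[, DT_GRID > 0] <- pos_amp
    amp[, DT_GRID < 0] <- neg_amp
    fake_rt(amp)
  }
  expect_equal(asymmetry_index(mk(2, 2), "r1"), 0)
  expect_equal(asymmetry_index(mk(1, 0), "r1"), 1)
  expect_equal(asymmetry_index(mk(3 / 36, 1 / 36), "r1"), 0.5)
  expect_true(is.na(asymmetry_index(mk(0, 0), "r1")))
})

test_that("population maps average cell-wise over defined entries", {
  mk_map <- function(li, valid) {
    structure(list(li = ifelse(valid, li, NA_real_), valid = valid,
                   li_smoothed = ifelse(valid, li, NA_real_),
                   dF = DF_GRID, dT = DT_GRID, roi = "m"),
              class = "interaction_map")
  }
  v1 <- matrix(FALSE, 9, 9); v1[1, 1] <- TRUE
  v2 <- matrix(FALSE, 9, 9); v2[9, 9] <- TRUE
  m1 <- mk_map(grid_mat(0.5), v1)
  m2 <- mk_map(grid_mat(-0.5), v2)
  # one map -> itself
  ag1 <- aggregate_population_map(list(m1), use_smoothed = FALSE)
  expect_equal(ag1$mean_li, m1$li)
  # disjoint valid cells -> union with n = 1 each
  ag <- aggregate_population_map(list(m1, m2), use_smoothed = FALSE)
  expect_equal(unname(ag$mean_li[1, 1]), 0.5)
  expect_equal(unname(ag$mean_li[9, 9]), -0.5)
  expect_equal(sum(ag$n), 2)
  # opposite values at one cell average to zero
  m3 <- mk_map(grid_mat(0.5), v1)
  m4 <- mk_map(grid_mat(-0.5), v1)
  expect_equal(unname(aggregate_population_map(
    list(m3, m4), use_smoothed = FALSE)$mean_li[1, 1]), 0)
})

test_that("coincidence templates yield mostly coincidence-preferring cells", {
  pr <- build_protocol(include_fm = FALSE, seed = 2)
  cells_a2 <- simulate_population(30, "a2_coincident", seed = 2,
                                  trial_noise_cv = 0.1,
                                  include_sweeps = FALSE)
  rt_a2 <- simulate_experiment(cells_a2, pr, seed = 2)
  cls_a2 <- classify_population(rt_a2)
  expect_gt(cls_a2$fractions[["coincident_preferring"]], 0.5)

  cells_a1 <- simulate_population(30, "a1_asymmetric", seed = 2,
                                  trial_noise_cv = 0.1,
                                  include_sweeps = FALSE)
  rt_a1 <- simulate_experiment(cells_a1, pr, seed = 2)
  cls_a1 <- classify_population(rt_a1)
  expect_gt(cls_a2$fractions[["coincident_preferring"]],
            cls_a1$fractions[["coincident_preferring"]])
})
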