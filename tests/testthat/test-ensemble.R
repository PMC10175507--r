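make_pv <- function(n_roi = 5, seed = 1, sig_p = 1) {
  set.seed(seed)
  tabs <- lapply(seq_len(n_roi), function(i) {
    amp <- grid_mat(0); amp[] <- runif(81, 0, 2)
    fake_rt(amp, tt_sig = matrix(runif(81) < sig_p, 9, 9),
            center_amp = runif(1, 0.5, 1.5),
            df_amp = runif(9, 0.2, 1.2),
            roi = sprintf("r%02d", i))
  })
  population_vectors(combine_response_tables(tabs))
}

test_that("population vectors are significance-gated and share ROI order", {
  # no significant ROI -> zero vector
  rt0 <- fake_rt(grid_mat(1), tt_sig = matrix(FALSE, 9, 9))
  pv0 <- population_vectors(rt0)
  expect_true(all(build_population_vector(pv0, "tt_+0.25_+050") == 0))
  # one significant ROI with amplitude a -> one-hot x a
  sig <- matrix(FALSE, 9, 9); sig[6, 7] <- TRUE
  tabs <- list(fake_rt(grid_mat(0.9), tt_sig = sig, roi = "a"),
               fake_rt(grid_mat(0.9), tt_sig = matrix(FALSE, 9, 9),
                       roi = "b"))
  pv <- population_vectors(combine_response_tables(tabs))
  v <- build_population_vector(pv, sprintf("tt_%+.2f_%+04d",
                                           DF_GRID[6], DT_GRID[7]))
  expect_equal(unname(v), c(0.9, 0))
  # negative amplitudes clamp to zero even when significant
  rtn <- fake_rt(grid_mat(-0.4), tt_sig = matrix(TRUE, 9, 9))
  expect_true(all(population_vectors(rtn)$V[, 1:81] == 0))
  expect_error(build_population_vector(pv, "nope"), "unknown condition")
})

test_that("ROI permutation permutes all vectors consistently", {
  pv <- make_pv(6, seed = 4)
  perm <- c(4, 1, 6, 2, 5, 3)
  pv2 <- pv
  pv2$V <- pv$V[perm, ]
  pv2$rois <- pv$rois[perm]
  for (cid in c("tt_+0.50_-025", "st_center"))
    expect_equal(build_population_vector(pv2, cid),
                 build_population_vector(pv, cid)[perm])
  # correlations are invariant to a consistent permutation
  expect_equal(correlate_conditions(pv2), correlate_conditions(pv))
})

test_that("linear-sum vectors add zero-forced single-tone vectors", {
  expect_equal(linear_sum_vector(c(1, 2, 3), c(0, 0, 0)), c(1, 2, 3))
  expect_equal(linear_sum_vector(rep(0, 4), rep(0, 4)), rep(0, 4))
  expect_equal(linear_sum_vector(c(1, 0, 2), c(0, 3, 1)), c(1, 3, 3))
  expect_error(linear_sum_vector(1:3, 1:4), "mismatch")
})

test_that("two-tone vectors equal to the linear sum give r = 1 at every dT", {
  set.seed(6)
  tabs <- lapply(1:6, function(i) {
    ctr <- runif(1, 0.5, 1.5)
    dfa <- runif(9, 0.2, 1.2)
    amp <- grid_mat(0)
    amp[] <- ctr + dfa  # recycles dfa down rows: T = center + dF amp
    fake_rt(amp, center_amp = ctr, df_amp = dfa,
            roi = sprintf("r%02d", i))
  })
  pv <- population_vectors(combine_response_tables(tabs))
  cc <- correlate_conditions(pv)
  expect_equal(cc$r_linear_sum, rep(1, 9))
  # scaling the two-tone vectors leaves r unchanged
  pv2 <- pv
  pv2$V[, grep("^tt_", colnames(pv2$V))] <-
    2 * pv2$V[, grep("^tt_", colnames(pv2$V))]
  expect_equal(correlate_conditions(pv2)$r_linear_sum, rep(1, 9))
})

test_that("disjoint one-hot vectors give the closed-form binary correlation", {
  n <- 6
  x <- c(1, rep(0, n - 1))
  y <- c(0, 1, rep(0, n - 2))
  expect_equal(cor(x, y), -1 / (n - 1))
  tabs <- lapply(seq_len(n), function(i) {
    sig <- matrix(FALSE, 9, 9); if (i == 1) sig[2, 3] <- TRUE
    fake_rt(grid_mat(1), tt_sig = sig, center_amp = 1,
            center_sig = i == 2, df_sig = rep(FALSE, 9),
            roi = sprintf("r%02d", i))
  })
  pv <- population_vectors(combine_response_tables(tabs))
  tt <- build_population_vector(pv, sprintf("tt_%+.2f_%+04d",
                                            DF_GRID[2], DT_GRID[3]))
  ls <- linear_sum_vector(build_population_vector(pv, "st_center"),
                          build_population_vector(pv, "st_df_-0.75"))
  expect_equal(cor(tt, ls), -1 / (n - 1))
})

test_that("coincident vs shifted ANOVA behaves under null and shift", {
  set.seed(9)
  mk_pairs <- function(offset_coin = 0) {
    g <- expand.grid(dF = DF_GRID[DF_GRID != 0], dT = DT_GRID,
                     KEEP.OUT.ATTRS = FALSE)
    g$timing <- ifelse(g$dT == 0, "coincident", "shifted")
    g$r <- rnorm(nrow(g), 0.7, 0.05) +
      ifelse(g$timing == "coincident", offset_coin, 0)
    g
  }
  # same distribution in all cells: no significant effects expected
  res0 <- compare_coincident_shifted(list(A1 = mk_pairs(), A2 = mk_pairs()))
  expect_true(all(res0$anova$p > 0.01))
  # constant offset on coincident pairs: timing main effect detected
  res1 <- compare_coincident_shifted(list(A1 = mk_pairs(-0.3),
                                          A2 = mk_pairs(-0.3)))
  expect_lt(res1$anova$p[res1$anova$term == "timing"], 1e-6)
  # swapping area labels swaps the corresponding contrasts
  pa <- mk_pairs(-0.2); pb <- mk_pairs(0)
  r_ab <- compare_coincident_shifted(list(A1 = pa, A2 = pb))
  r_ba <- compare_coincident_shifted(list(A1 = pb, A2 = pa))
  expect_equal(unname(r_ab$tukey$area[, "diff"]),
               -unname(r_ba$tukey$area[, "diff"]))
})

test_that("two-tone-only recruitment fractions follow the designed flags", {
  mk <- function(roi, single, coin, shift) {
    tt_sig <- matrix(FALSE, 9, 9)
    if (coin) tt_sig[4, DT_GRID == 0] <- TRUE
    if (shift) tt_sig[4, 2] <- TRUE
    fake_rt(grid_mat(1), tt_sig = tt_sig, center_sig = single,
            df_sig = rep(FALSE, 9), roi = roi)
  }
  # all ROIs tone-responsive -> undefined
  all_resp <- combine_response_tables(list(mk("a", TRUE, FALSE, FALSE)))
  expect_true(is.na(two_tone_only_fraction(all_resp)$fraction))
  # a single two-tone-only responder -> fraction 1
  one <- combine_response_tables(list(mk("a", FALSE, TRUE, FALSE)))
  expect_equal(two_tone_only_fraction(one)$fraction, 1)
  # designed prevalence: 2 of 4 non-responsive ROIs recruited
  des <- combine_response_tables(list(
    mk("a", FALSE, TRUE, FALSE), mk("b", FALSE, FALSE, TRUE),
    mk("c", FALSE, FALSE, FALSE), mk("d", FALSE, FALSE, FALSE),
    mk("e", TRUE, TRUE, TRUE)))
  res <- two_tone_only_fraction(des)
  expect_equal(res$n_single_nonresponsive, 4L)
  expect_equal(res$fraction, 0.5)
  expect_equal(res$coincident_only, 0.25)
  expect_equal(res$shifted_only, 0.25)
  expect_equal(res$both, 0)
})

test_that("linear populations approach r = 1 as noise vanishes", {
  pr <- build_protocol(include_fm = FALSE, seed = 5)
  run_rl <- function(cv, bsd) {
    cells <- simulate_population(25, "linear", seed = 5,
                                 trial_noise_cv = cv, baseline_sd = bsd,
                                 kernel_jitter_sd = 0,
                                 include_sweeps = FALSE)
    rt <- simulate_experiment(cells, pr, seed = 5, sd_floor = 1e-6)
    mean(correlate_conditions(population_vectors(rt))$r_linear_sum)
  }
  low <- run_rl(0.02, 0.01)
  high <- run_rl(0.3, 0.05)
  expect_gt(low, 0.98)
  expect_gt(low, high)
})

test_that("coincidence kernels depress the linear-sum correlation at dT = 0", {
  pr <- build_protocol(include_fm = FALSE, seed = 8)
  run_curve <- function(template) {
    cells <- simulate_population(30, template, seed = 8,
                                 include_sweeps = FALSE)
    rt <- simulate_experiment(cells, pr, seed = 8)
    correlate_conditions(population_vectors(rt))
  }
  cc <- run_curve("a2_coincident")
  r_coin <- cc$r_linear_sum[cc$dT == 0]
  r_shift <- mean(cc$r_linear_sum[cc$dT != 0])
  expect_lt(r_coin, r_shift)
  # flattening the coincidence column closes the gap
  cc_flat <- run_curve("sublinear_uniform")
  gap_flat <- mean(cc_flat$r_linear_sum[cc_flat$dT != 0]) -
    cc_flat$r_linear_sum[cc_flat$dT == 0]
  expect_lt(abs(gap_flat), (r_shift - r_coin) / 2)
})
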