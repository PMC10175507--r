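# shared fixtures: hand-specified response tables and small grids

DF_GRID <- seq(-1, 1, by = 0.25)
DT_GRID <- seq(-100, 100, by = 25)
FM_RATES <- c(2.5, 5, 10, 20, 40, 80)

# a response_table built directly from mean-amplitude grids and
# significance flags, bypassing trace synthesis (trial rows empty)
fake_rt <- function(tt_amp, tt_sig = NULL, center_amp = 1,
                    center_sig = TRUE, df_amp = NULL, df_sig = NULL,
                    fm_amp = NULL, fm_sig = NULL, roi = "r1") {
  if (is.null(tt_sig)) tt_sig <- matrix(TRUE, 9, 9)
  if (is.null(df_amp)) df_amp <- rep(1, 9)
  if (is.null(df_sig)) df_sig <- rep(TRUE, 9)
  g <- expand.grid(dF = DF_GRID, dT = DT_GRID, KEEP.OUT.ATTRS = FALSE)
  rows <- data.frame(
    roi = roi,
    condition_id = c(sprintf("tt_%+.2f_%+04d", g$dF, g$dT),
                     "st_center", sprintf("st_df_%+.2f", DF_GRID)),
    type = c(rep("twotone", 81), rep("single", 10)),
    dF = c(g$dF, NA, DF_GRID), dT = c(g$dT, rep(NA, 10)),
    rate = NA_real_, direction = NA_character_,
    mean_amp = c(as.vector(tt_amp), center_amp, df_amp),
    significant = c(as.vector(tt_sig), center_sig, df_sig),
    stringsAsFactors = FALSE)
  if (!is.null(fm_amp)) {
    fm <- expand.grid(rate = FM_RATES, direction = c("up", "down"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows <- rbind(rows, data.frame(
      roi = roi, condition_id = sprintf("fm_%s_%g", fm$direction, fm$rate),
      type = "fm", dF = NA_real_, dT = NA_real_,
      rate = fm$rate, direction = fm$direction,
      mean_amp = as.vector(fm_amp),
      significant = if (is.null(fm_sig)) TRUE else as.vector(fm_sig),
      stringsAsFactors = FALSE))
  }
  structure(list(trials = rows[0, c(1, 2)], summary = rows,
                 conditions = NULL, frame_rate = 30, n_trials = 5,
                 dF_oct = DF_GRID, dT_ms = DT_GRID,
                 fm_rates = if (is.null(fm_amp)) numeric(0) else FM_RATES),
            class = "response_table")
}

grid_mat <- function(fill = 0) {
  matrix(fill, 9, 9, dimnames = list(DF_GRID, DT_GRID))
}

# noise-free single cell processed through the full forward pipeline
noise_free_rt <- function(kernel, base_amp = 0.7, seed = 1,
                          include_fm = FALSE) {
  pr <- build_protocol(seed = seed, include_fm = include_fm)
  amp_df <- stats::setNames(rep(0.4, 9), DF_GRID)
  cell <- ground_truth_cell(base_amp, amp_df, kernel,
                            trial_noise_cv = 0, baseline_sd = 0)
  tr <- synthesize_trial_traces(cell, pr, seed = seed)
  list(rt = compute_response_table(tr, sd_floor = 1e-9), cell = cell,
       protocol = pr)
}
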