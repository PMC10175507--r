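#' Compute dF/F from raw fluorescence with background subtraction
#'
#' `F(t) = raw(t) - bg_coef * background(t)`, then
#' `dF/F = (F - F0) / (F0 + offset)` where `F0` is the baseline estimate
#' (mean over `baseline_frames` if given, otherwise the trace median) and
#' `offset` (default 20 a.u.) guards against division by near-zero
#' baselines.
#'
#' @param raw raw cell fluorescence trace, a.u.
#' @param background background (neuropil) trace, same length, or NULL.
#' @param offset additive baseline offset, a.u. (> 0).
#' @param bg_coef background subtraction coefficient (default 0.9).
#' @param baseline_frames indices used for F0; NULL = median of trace.
#' @return dF/F trace.
#' @export
compute_dff <- function(raw, background = NULL, offset = 20, bg_coef = 0.9,
                        baseline_frames = NULL) {
  if (!is.null(background) && length(background) != length(raw))
    stop("raw and background traces must have equal length")
  if (offset <= 0) stop("offset must be > 0")
  f <- if (is.null(background)) raw else raw - bg_coef * background
  f0 <- if (is.null(baseline_frames)) stats::median(f)
        else mean(f[baseline_frames])
  (f - f0) / (f0 + offset)
}

#' Exclude background pixels contaminated by neighboring cells
#'
#' Flags background-ring pixels whose dF/F shows large transient events —
#' at least `min_event_frames` consecutive frames above `event_sd` times
#' the pixel's robust (MAD-based) dF/F SD — while being uncorrelated with
#' the cell ROI trace (Pearson r below `cor_threshold`), i.e. activity
#' that cannot come from the cell itself. Retained pixels are averaged
#' into the background trace. If every pixel is excluded the unfiltered
#' mean is returned with a warning.
#'
#' @param pixels matrix (pixels x frames) of raw pixel traces, a.u.
#' @param cell_trace raw cell ROI trace, a.u.
#' @param event_sd event threshold in SD units (default 3). The SD is
#'   estimated robustly (MAD) so a pixel's own events do not mask
#'   themselves.
#' @param cor_threshold correlation below which events count as foreign
#'   (default 0.2).
#' @param min_event_frames consecutive supra-threshold frames required to
#'   call an event (default 5), so isolated noise excursions do not count.
#' @param offset passed to [compute_dff()].
#' @return list with `retained` (pixel indices), `excluded`, and
#'   `background` (mean trace over retained pixels, a.u.).
#' @export
exclude_contaminated_pixels <- function(pixels, cell_trace, event_sd = 3,
                                        cor_threshold = 0.2,
                                        min_event_frames = 5, offset = 20) {
  stopifnot(is.matrix(pixels), nrow(pixels) >= 1,
            ncol(pixels) == length(cell_trace))
  cell_dff <- compute_dff(cell_trace, offset = offset)
  bad <- vapply(seq_len(nrow(pixels)), function(i) {
    px <- compute_dff(pixels[i, ], offset = offset)
    s <- stats::mad(px)
    if (s == 0) return(FALSE)
    has_events <- max_run(px > event_sd * s) >= min_event_frames
    if (!has_events) return(FALSE)
    r <- suppressWarnings(stats::cor(px, cell_dff))
    is.na(r) || r < cor_threshold
  }, logical(1))
  retained <- which(!bad)
  if (length(retained) == 0L) {
    warning("all background pixels excluded; falling back to unfiltered mean")
    retained <- seq_len(nrow(pixels))
  }
  list(retained = retained, excluded = which(bad),
       background = colMeans(pixels[retained, , drop = FALSE]))
}

#' Brightness quality filter for cell ROIs
#'
#' A cell ROI is kept only if its mean fluorescence is at least
#' `min_ratio` (default 1.03, i.e. 3% brighter) times the mean of its
#' background ring, ensuring robust neuropil subtraction.
#'
#' @param cell_mean,background_mean mean raw fluorescence, a.u. (>= 0).
#' @param min_ratio inclusion threshold (inclusive).
#' @return logical.
#' @export
qc_brightness_filter <- function(cell_mean, background_mean,
                                 min_ratio = 1.03) {
  stopifnot(cell_mean >= 0, background_mean >= 0)
  cell_mean >= min_ratio * background_mean
}

# frame indices of a condition's response window within the trial snippet
window_idx <- function(protocol, win_frames) {
  if (protocol$onset_frame + win_frames - 1L > protocol$n_frames)
    stop("response window extends past trace end")
  seq(protocol$onset_frame, protocol$onset_frame + win_frames - 1L)
}

#' Per-trial response amplitudes for one condition
#'
#' Baseline-subtracted mean dF/F over the condition's response-detection
#' window, one value per trial. Negative values are preserved here;
#' zero-forcing happens in the downstream index computations (LI, DSI,
#' asymmetry).
#'
#' @param traces a `roi_traces` object (see [synthesize_trial_traces()]).
#' @param condition_id condition to quantify.
#' @return numeric vector, one amplitude per trial of the condition.
#' @export
response_amplitude <- function(traces, condition_id) {
  pr <- traces$protocol
  ci <- match(condition_id, pr$conditions$condition_id)
  if (is.na(ci)) stop("unknown condition: ", condition_id)
  rows <- which(traces$schedule$condition_id == condition_id)
  win <- window_idx(pr, pr$conditions$win_frames[ci])
  base <- seq_len(pr$baseline_frames)
  m <- traces$dff[rows, , drop = FALSE]
  rowMeans(m[, win, drop = FALSE]) - rowMeans(m[, base, drop = FALSE])
}

# longest run of TRUE in a logical vector
max_run <- function(x) {
  r <- rle(x)
  if (!any(r$values)) 0L else max(r$lengths[r$values])
}

#' Detect a significant excitatory response
#'
#' Dual criterion: (1) in strictly more than half of trials the
#' baseline-subtracted dF/F exceeds the threshold for at least
#' `min_dur_s` seconds of consecutive frames within the response window,
#' and (2) the trial-averaged trace does so too. The threshold is
#' `threshold_sd` (default 3.3) times the baseline-period SD; a zero
#' baseline SD is a configuration error unless an absolute floor
#' `sd_floor` is set.
#'
#' @param trial_mat matrix (trials x frames) of dF/F for one condition.
#' @param win frame indices of the response window.
#' @param baseline frame indices of the baseline window.
#' @param frame_rate Hz.
#' @param threshold_sd threshold multiplier (default 3.3).
#' @param min_dur_s minimum consecutive supra-threshold duration, seconds;
#'   frames required = `ceiling(min_dur_s * frame_rate)`.
#' @param baseline_sd optional pre-computed baseline SD (e.g. pooled
#'   across all trials of the ROI); computed from `trial_mat` if NULL.
#' @param sd_floor absolute lower bound applied to the baseline SD.
#' @return logical.
#' @export
detect_significant_response <- function(trial_mat, win, baseline,
                                        frame_rate,
                                        threshold_sd = 3.3,
                                        min_dur_s = 0.5,
                                        baseline_sd = NULL,
                                        sd_floor = 0) {
  stopifnot(is.matrix(trial_mat), nrow(trial_mat) >= 2)
  base_means <- rowMeans(trial_mat[, baseline, drop = FALSE])
  if (is.null(baseline_sd)) {
    resid <- trial_mat[, baseline, drop = FALSE] - base_means
    baseline_sd <- stats::sd(as.vector(resid))
  }
  baseline_sd <- max(baseline_sd, sd_floor)
  if (baseline_sd == 0)
    stop("zero baseline SD degenerates the threshold; set sd_floor > 0")
  thr <- threshold_sd * baseline_sd
  min_frames <- as.integer(ceiling(min_dur_s * frame_rate))
  sub <- trial_mat[, win, drop = FALSE] - base_means
  n_pass <- sum(apply(sub > thr, 1L, max_run) >= min_frames)
  if (n_pass <= nrow(trial_mat) / 2) return(FALSE)
  max_run(colMeans(sub) > thr) >= min_frames
}

#' Quantify all conditions of one ROI into a response table
#'
#' Computes, per (condition, trial), the baseline-subtracted mean-dF/F
#' amplitude and the baseline-subtracted area under the curve, and per
#' condition the dual-criterion significance flag. The baseline SD used
#' for the significance threshold is pooled over the baseline windows of
#' all trials of the ROI.
#'
#' @param traces a `roi_traces` object.
#' @param threshold_sd,min_dur_s,sd_floor see
#'   [detect_significant_response()].
#' @return object of class `response_table`: list with `trials`
#'   (data.frame roi, condition_id, trial, amplitude, auc), `summary`
#'   (data.frame roi, condition_id, type, dF, dT, rate, direction,
#'   mean_amp, significant), `conditions`, `frame_rate`, `n_trials`.
#' @export
compute_response_table <- function(traces, threshold_sd = 3.3,
                                   min_dur_s = 0.5, sd_floor = 0) {
  pr <- traces$protocol
  conds <- pr$conditions
  base <- seq_len(pr$baseline_frames)
  base_means_all <- rowMeans(traces$dff[, base, drop = FALSE])
  pooled_sd <- stats::sd(as.vector(traces$dff[, base, drop = FALSE] -
                                     base_means_all))
  trial_rows <- vector("list", nrow(conds))
  sig <- logical(nrow(conds))
  mean_amp <- numeric(nrow(conds))
  for (i in seq_len(nrow(conds))) {
    rows <- which(traces$schedule$condition_id == conds$condition_id[i])
    win <- window_idx(pr, conds$win_frames[i])
    m <- traces$dff[rows, , drop = FALSE]
    bm <- base_means_all[rows]
    amp <- rowMeans(m[, win, drop = FALSE]) - bm
    auc <- (rowSums(m[, win, drop = FALSE]) - length(win) * bm) /
      pr$frame_rate
    trial_rows[[i]] <- data.frame(
      roi = traces$roi, condition_id = conds$condition_id[i],
      trial = seq_along(rows), amplitude = amp, auc = auc,
      stringsAsFactors = FALSE, row.names = NULL)
    mean_amp[i] <- mean(amp)
    sig[i] <- detect_significant_response(
      m, win, base, pr$frame_rate, threshold_sd = threshold_sd,
      min_dur_s = min_dur_s, baseline_sd = pooled_sd, sd_floor = sd_floor)
  }
  structure(list(
    trials = do.call(rbind, trial_rows),
    summary = data.frame(
      roi = traces$roi, condition_id = conds$condition_id,
      type = conds$type, dF = conds$dF, dT = conds$dT, rate = conds$rate,
      direction = conds$direction, mean_amp = mean_amp, significant = sig,
      stringsAsFactors = FALSE, row.names = NULL),
    conditions = conds, frame_rate = pr$frame_rate,
    n_trials = pr$n_trials,
    dF_oct = pr$dF_oct, dT_ms = pr$dT_ms, fm_rates = pr$fm_rates),
    class = "response_table")
}

#' Combine response tables of several ROIs
#'
#' @param tables list of `response_table` objects sharing one protocol.
#' @return a single `response_table` with all ROIs.
#' @export
combine_response_tables <- function(tables) {
  stopifnot(length(tables) >= 1)
  out <- tables[[1]]
  out$trials <- do.call(rbind, lapply(tables, `[[`, "trials"))
  out$summary <- do.call(rbind, lapply(tables, `[[`, "summary"))
  out
}

#' Simulate and process a whole population
#'
#' Synthesizes trial traces for each ground-truth cell (per-cell seed
#' substreams derived from `seed`) and quantifies them into one combined
#' response table. Traces are discarded after processing, so memory stays
#' flat in the number of cells.
#'
#' @param cells list of [ground_truth_cell()] (e.g. from
#'   [simulate_population()]).
#' @param protocol a [build_protocol()] object.
#' @param seed global seed.
#' @param threshold_sd,min_dur_s,sd_floor processing parameters.
#' @return combined `response_table`.
#' @export
simulate_experiment <- function(cells, protocol, seed = 1L,
                                threshold_sd = 3.3, min_dur_s = 0.5,
                                sd_floor = 0) {
  tables <- lapply(seq_along(cells), function(i) {
    tr <- synthesize_trial_traces(cells[[i]], protocol,
                                  seed = cell_seed(seed, i) + 1L)
    compute_response_table(tr, threshold_sd = threshold_sd,
                           min_dur_s = min_dur_s, sd_floor = sd_floor)
  })
  combine_response_tables(tables)
}
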