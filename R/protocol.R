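#' Build a two-tone / FM-sweep stimulus protocol
#'
#' Constructs the full condition table and a randomized block schedule for a
#' two-tone spectrotemporal interaction experiment: a 9 x 9 grid of two-tone
#' conditions (frequency offset dF in octaves x onset interval dT in ms),
#' single-tone controls (the fixed center tone plus each dF tone alone), and
#' optionally logarithmic FM sweeps (6 rates x 2 directions). Each block of
#' trials contains every condition exactly once in randomized order;
#' `n_trials` blocks are concatenated.
#'
#' Response-detection windows are attached per condition: 1 s from sound
#' onset for two-tone and component-tone stimuli, 1.2 s for 1-s pure tones
#' (not part of the default condition set), and sound onset to 0.3 s after
#' sound offset for FM sweeps (sweep duration = octave span / rate).
#'
#' @param n_trials trials per condition (blocks); default 5.
#' @param iti_s inter-trial interval, seconds; default 5.
#' @param frame_rate imaging frame rate, Hz; default 30.
#' @param dF_oct two-tone frequency offsets, octaves.
#' @param dT_ms two-tone onset-to-onset intervals, ms (negative = dF tone leads).
#' @param include_fm include FM sweep conditions.
#' @param fm_rates FM sweep rates, oct/s.
#' @param fm_span_oct FM sweep frequency span, octaves (4-64 kHz = 4 oct).
#' @param baseline_s pre-onset baseline duration used for dF/F statistics.
#' @param twotone_window_s response window for two-tone and component tones.
#' @param fm_post_offset_s extra window time after FM sweep offset.
#' @param seed integer seed controlling block randomization.
#' @return An object of class `stim_protocol`: list with `conditions`
#'   (data.frame: condition_id, type, dF, dT, rate, direction, window_s,
#'   win_frames), `schedule` (data.frame: trial, block, condition_id,
#'   onset_time_s), and timing fields (`frame_rate`, `baseline_frames`,
#'   `onset_frame`, `n_frames`, `n_trials`, `iti_s`).
#' @examples
#' pr <- build_protocol(n_trials = 1, include_fm = FALSE)
#' nrow(pr$schedule)  # 91 = 81 two-tone + 10 single-tone conditions
#' @export
build_protocol <- function(n_trials = 5, iti_s = 5, frame_rate = 30,
                           dF_oct = seq(-1, 1, by = 0.25),
                           dT_ms = seq(-100, 100, by = 25),
                           include_fm = TRUE,
                           fm_rates = c(2.5, 5, 10, 20, 40, 80),
                           fm_span_oct = 4,
                           baseline_s = 1,
                           twotone_window_s = 1,
                           fm_post_offset_s = 0.3,
                           seed = 1L) {
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1 ||
      n_trials != round(n_trials))
    stop("invalid protocol config: n_trials must be a positive integer")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("invalid protocol config: frame_rate must be positive")
  if (iti_s < 0 || baseline_s <= 0)
    stop("invalid protocol config: iti_s must be >= 0 and baseline_s > 0")

  tt <- expand.grid(dF = dF_oct, dT = dT_ms, KEEP.OUT.ATTRS = FALSE)
  conditions <- data.frame(
    condition_id = c(sprintf("tt_%+.2f_%+04d", tt$dF, tt$dT),
                     "st_center",
                     sprintf("st_df_%+.2f", dF_oct)),
    type = c(rep("twotone", nrow(tt)), rep("single", 1L + length(dF_oct))),
    dF = c(tt$dF, NA, dF_oct),
    dT = c(tt$dT, rep(NA, 1L + length(dF_oct))),
    rate = NA_real_, direction = NA_character_,
    window_s = twotone_window_s,
    stringsAsFactors = FALSE)
  if (include_fm) {
    fm <- expand.grid(rate = fm_rates, direction = c("up", "down"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    conditions <- rbind(conditions, data.frame(
      condition_id = sprintf("fm_%s_%g", fm$direction, fm$rate),
      type = "fm", dF = NA_real_, dT = NA_real_,
      rate = fm$rate, direction = fm$direction,
      window_s = fm_span_oct / fm$rate + fm_post_offset_s,
      stringsAsFactors = FALSE))
  }
  conditions$win_frames <- as.integer(round(conditions$window_s * frame_rate))

  baseline_frames <- as.integer(round(baseline_s * frame_rate))
  onset_frame <- baseline_frames + 1L
  # snippet long enough for the longest window plus half a second of decay
  n_frames <- baseline_frames + max(conditions$win_frames) +
    as.integer(ceiling(0.5 * frame_rate))

  set.seed(as.integer(seed))
  n_cond <- nrow(conditions)
  order_idx <- unlist(lapply(seq_len(n_trials),
                             function(b) sample.int(n_cond)))
  trial_dur <- n_frames / frame_rate
  schedule <- data.frame(
    trial = seq_len(n_cond * n_trials),
    block = rep(seq_len(n_trials), each = n_cond),
    condition_id = conditions$condition_id[order_idx],
    stringsAsFactors = FALSE)
  schedule$onset_time_s <- (schedule$trial - 1L) * (trial_dur + iti_s) +
    baseline_s

  structure(list(conditions = conditions, schedule = schedule,
                 n_trials = as.integer(n_trials), iti_s = iti_s,
                 frame_rate = frame_rate, baseline_s = baseline_s,
                 baseline_frames = baseline_frames,
                 onset_frame = onset_frame, n_frames = n_frames,
                 dF_oct = dF_oct, dT_ms = dT_ms,
                 fm_rates = if (include_fm) fm_rates else numeric(0),
                 fm_span_oct = fm_span_oct),
            class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat("Stimulus protocol:", nrow(x$conditions), "conditions x",
      x$n_trials, "trials (", nrow(x$schedule), "trials total )\n")
  cat("  ", sum(x$conditions$type == "twotone"), "two-tone,",
      sum(x$conditions$type == "single"), "single-tone,",
      sum(x$conditions$type == "fm"), "FM sweep\n")
  cat("  frame rate", x$frame_rate, "Hz, baseline", x$baseline_s,
      "s, ITI", x$iti_s, "s\n")
  invisible(x)
}

#' Equivalent FM rate of a two-tone (dF, dT) pair
#'
#' A pair of tones separated by `dF` octaves with onset interval `dT` ms
#' sweeps frequency at |dF| / (|dT| / 1000) octaves per second; e.g. dF =
#' 0.25 oct at dT = 100 ms corresponds to 2.5 oct/s, and dF = 1 oct at
#' dT = 25 ms to 40 oct/s. Undefined for coincident tones (dT = 0).
#'
#' @param dF_oct frequency offset, octaves.
#' @param dT_ms onset interval, ms; must be non-zero.
#' @return rate in oct/s.
#' @export
map_two_tone_to_fm_rate <- function(dF_oct, dT_ms) {
  if (any(dT_ms == 0))
    stop("FM rate is undefined for coincident tones (dT = 0)")
  abs(dF_oct) / (abs(dT_ms) / 1000)
}
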