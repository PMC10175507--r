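#' Unit-peak calcium transient kernel
#'
#' Difference-of-exponentials impulse response normalized to peak 1,
#' emulating slow GCaMP6s kinetics (defaults: 0.2 s rise, 1.5 s decay).
#'
#' @param rise_tau,decay_tau time constants, seconds.
#' @param frame_rate sampling rate, Hz.
#' @param n_frames number of post-onset frames to evaluate.
#' @return numeric vector of length `n_frames`, first sample at t = 0.
#' @export
calcium_kernel <- function(rise_tau = 0.2, decay_tau = 1.5,
                           frame_rate = 30, n_frames = 75) {
  stopifnot(rise_tau > 0, decay_tau > 0, rise_tau < decay_tau)
  t <- (seq_len(n_frames) - 1L) / frame_rate
  k <- exp(-t / decay_tau) - exp(-t / rise_tau)
  k / max(k)
}

#' Synthesize trial-aligned dF/F traces for one cell
#'
#' Forward model: each trial's trace is the cell's ground-truth amplitude
#' for that condition, multiplied by lognormal trial noise (mean 1, CV =
#' `trial_noise_cv`), times a unit-peak calcium transient placed at the
#' sound onset frame, plus additive Gaussian baseline noise. Traces are
#' emitted directly in dF/F units, trial-aligned (baseline frames before
#' onset), one row per trial of the protocol schedule.
#'
#' @param cell a [ground_truth_cell()].
#' @param protocol a [build_protocol()] object.
#' @param seed integer seed (generation is bit-reproducible).
#' @return object of class `roi_traces`: list with `dff` (matrix trials x
#'   frames), `schedule`, `protocol`, `roi`, and the generating `cell`.
#' @export
synthesize_trial_traces <- function(cell, protocol, seed = 1L) {
  stopifnot(inherits(cell, "ground_truth_cell"),
            inherits(protocol, "stim_protocol"))
  set.seed(as.integer(seed))
  conds <- protocol$conditions
  amp_by_cond <- vapply(seq_len(nrow(conds)),
                        function(i) true_amplitude(cell, conds[i, ]),
                        numeric(1))
  names(amp_by_cond) <- conds$condition_id
  amps <- amp_by_cond[protocol$schedule$condition_id]

  n_trials <- length(amps)
  if (cell$trial_noise_cv > 0) {
    sdlog <- sqrt(log(1 + cell$trial_noise_cv^2))
    amps <- amps * stats::rlnorm(n_trials, -sdlog^2 / 2, sdlog)
  }
  n_post <- protocol$n_frames - protocol$baseline_frames
  k <- c(rep(0, protocol$baseline_frames),
         calcium_kernel(cell$rise_tau, cell$decay_tau,
                        protocol$frame_rate, n_post))
  dff <- outer(unname(amps), k)
  if (cell$baseline_sd > 0)
    dff <- dff + matrix(stats::rnorm(length(dff), 0, cell$baseline_sd),
                        nrow(dff), ncol(dff))
  structure(list(dff = dff, schedule = protocol$schedule,
                 protocol = protocol, roi = cell$id, cell = cell),
            class = "roi_traces")
}

#' Mean transient kernel gain over a response window
#'
#' The windowed-mean amplitude estimate of a transient of true peak `a` is
#' `a * gain`; this returns that gain (the mean of the unit-peak kernel
#' over the window), used for kernel-shape correction when recovering
#' absolute amplitudes.
#'
#' @param protocol a [build_protocol()] object.
#' @param win_frames window length in frames.
#' @param rise_tau,decay_tau kernel time constants, seconds.
#' @return scalar gain in (0, 1].
#' @export
kernel_window_gain <- function(protocol, win_frames,
                               rise_tau = 0.2, decay_tau = 1.5) {
  k <- calcium_kernel(rise_tau, decay_tau, protocol$frame_rate,
                      protocol$n_frames - protocol$baseline_frames)
  mean(k[seq_len(win_frames)])
}

#' Synthesize raw pixel-level fluorescence with neuropil contamination
#'
#' Generates a session-long raw fluorescence trace for one cell together
#' with a ring of background pixels, to exercise background subtraction and
#' contaminated-pixel exclusion. The cell's measured trace is its true
#' fluorescence plus `contamination_alpha` times the shared neuropil
#' signal; every background pixel carries the neuropil signal plus its own
#' baseline and noise, and `n_contaminated` pixels additionally carry large
#' transient events uncorrelated with the cell (emulating overlapping
#' somata/processes of neighboring cells).
#'
#' @param cell a [ground_truth_cell()] (kinetics and noise reused).
#' @param n_pixels number of background pixels.
#' @param n_contaminated how many carry foreign transients.
#' @param contamination_alpha neuropil mixing fraction in `[0, 1]`.
#' @param n_frames session length, frames.
#' @param frame_rate Hz.
#' @param cell_f0,bg_f0 baseline fluorescence, a.u.
#' @param n_events number of true cell transients.
#' @param pixel_noise_sd per-pixel additive noise SD, a.u.
#' @param seed integer seed.
#' @return list with `measured` (cell trace, a.u.), `pixels` (matrix
#'   n_pixels x n_frames, a.u.), `true` (uncontaminated cell trace),
#'   `true_dff`, `neuropil`, `contaminated` (indices), `alpha`,
#'   `frame_rate`.
#' @export
synthesize_pixel_traces <- function(cell, n_pixels = 20, n_contaminated = 3,
                                    contamination_alpha = 0.9,
                                    n_frames = 3000, frame_rate = 30,
                                    cell_f0 = 200, bg_f0 = 100,
                                    n_events = 12, pixel_noise_sd = 1,
                                    seed = 1L) {
  stopifnot(contamination_alpha >= 0, contamination_alpha <= 1,
            n_contaminated <= n_pixels)
  set.seed(as.integer(seed))
  k <- calcium_kernel(cell$rise_tau, cell$decay_tau, frame_rate,
                      min(n_frames, as.integer(6 * frame_rate)))
  place_events <- function(times, amps) {
    tr <- numeric(n_frames)
    for (j in seq_along(times)) {
      idx <- times[j]:min(n_frames, times[j] + length(k) - 1L)
      tr[idx] <- tr[idx] + amps[j] * k[seq_along(idx)]
    }
    tr
  }
  ev_t <- sort(sample.int(n_frames - length(k), n_events))
  true_dff <- place_events(ev_t, stats::rlnorm(n_events, log(0.8), 0.3))
  true_trace <- cell_f0 * (1 + true_dff)

  # shared neuropil: slow noisy signal plus a faint copy of cell activity
  neuropil <- bg_f0 * (1 + 0.1 * true_dff) +
    as.numeric(stats::filter(stats::rnorm(n_frames, 0, 2), rep(1 / 15, 15),
                             circular = TRUE))
  pixels <- matrix(rep(neuropil, each = n_pixels), n_pixels, n_frames)
  pixels <- pixels + stats::rnorm(length(pixels), 0, pixel_noise_sd)
  contaminated <- integer(0)
  if (n_contaminated > 0) {
    contaminated <- seq_len(n_contaminated)
    # foreign transients land while the cell is quiet, so they are
    # uncorrelated with the cell trace by construction
    quiet <- which(true_dff[seq_len(n_frames - length(k))] < 0.02)
    for (px in contaminated) {
      ft <- sort(sample(quiet, 8))
      pixels[px, ] <- pixels[px, ] +
        bg_f0 * place_events(ft, stats::rlnorm(8, log(1.5), 0.3))
    }
  }
  measured <- true_trace + contamination_alpha * neuropil
  list(measured = measured, pixels = pixels, true = true_trace,
       true_dff = true_dff, neuropil = neuropil,
       contaminated = contaminated, alpha = contamination_alpha,
       frame_rate = frame_rate)
}
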