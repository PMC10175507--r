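#' Ground-truth linearity-index kernel templates
#'
#' Builds a 9 x 9 matrix of true linearity-index (LI) values over the
#' (dF, dT) stimulus grid, used by the synthetic generator as a cell's
#' interaction kernel. Rows follow `dF_oct`, columns `dT_ms`.
#'
#' Templates:
#' \describe{
#'   \item{a2_coincident}{supralinear coincidence column: positive LI at
#'     dT = 0 (Gaussian over dF, peak `peak`), uniform sublinearity `off`
#'     (< 0) at all shifted dTs. Emulates coincidence-tuned integration.}
#'   \item{a1_asymmetric}{a supralinear cluster (peak `peak`) centered in
#'     one off-axis quadrant on a sublinear background `off`; the
#'     background is asymmetric between the Upward (dF*dT > 0) and
#'     Downward (dF*dT < 0) regions by factor `supp_asym`, so suppression
#'     differs between regions. Emulates FM-feature-extracting cells.}
#'   \item{sublinear_uniform}{constant `off` everywhere.}
#'   \item{linear}{all zeros.}
#' }
#' Values are clipped to `li_cap` in magnitude so the kernel inversion
#' (T from L and LI) stays finite.
#'
#' @param name template name.
#' @param dF_oct,dT_ms grid axes.
#' @param peak supralinear peak LI (a2 column / a1 cluster).
#' @param off baseline sublinear LI (negative).
#' @param sigma_f Gaussian width of the coincidence column over dF, octaves.
#' @param quadrant a1 cluster quadrant, one of "df_neg_dt_neg",
#'   "df_pos_dt_pos", "df_neg_dt_pos", "df_pos_dt_neg".
#' @param supp_asym a1 suppression asymmetry in (-1, 1): background LI is
#'   `off * (1 - supp_asym)` in the Upward region and `off * (1 + supp_asym)`
#'   in the Downward region. Positive values mean weaker suppression in the
#'   Upward region (predicting upward direction selectivity).
#' @param li_cap magnitude cap applied to the result (default 0.95).
#' @return 9 x 9 numeric matrix with dimnames from the grid axes.
#' @export
kernel_template <- function(name = c("a2_coincident", "a1_asymmetric",
                                     "sublinear_uniform", "linear"),
                            dF_oct = seq(-1, 1, by = 0.25),
                            dT_ms = seq(-100, 100, by = 25),
                            peak = 0.6, off = -0.25, sigma_f = 0.5,
                            quadrant = c("df_neg_dt_neg", "df_pos_dt_pos",
                                         "df_neg_dt_pos", "df_pos_dt_neg"),
                            supp_asym = 0, li_cap = 0.95) {
  name <- match.arg(name)
  quadrant <- match.arg(quadrant)
  k <- matrix(0, length(dF_oct), length(dT_ms),
              dimnames = list(dF_oct, dT_ms))
  if (name == "a2_coincident") {
    k[] <- off
    k[, dT_ms == 0] <- peak * exp(-dF_oct^2 / (2 * sigma_f^2))
  } else if (name == "a1_asymmetric") {
    up <- outer(sign(dF_oct), sign(dT_ms)) > 0
    down <- outer(sign(dF_oct), sign(dT_ms)) < 0
    k[] <- off
    k[up] <- off * (1 - supp_asym)
    k[down] <- off * (1 + supp_asym)
    ctr <- switch(quadrant,
                  df_neg_dt_neg = c(-0.5, -50), df_pos_dt_pos = c(0.5, 50),
                  df_neg_dt_pos = c(-0.5, 50), df_pos_dt_neg = c(0.5, -50))
    blob <- outer(exp(-(dF_oct - ctr[1])^2 / (2 * 0.3^2)),
                  exp(-(dT_ms - ctr[2])^2 / (2 * 30^2)))
    # the cluster replaces the sublinear background rather than adding to
    # it, so facilitation strength is set by `peak` alone and stays
    # independent of the suppression asymmetry
    core <- blob > 0.3
    k[core] <- (peak * blob)[core]
  } else if (name == "sublinear_uniform") {
    k[] <- off
  }
  pmin(pmax(k, -li_cap), li_cap)
}

#' Construct a ground-truth synthetic cell
#'
#' Bundles the response model of one simulated neuron: single-tone
#' amplitudes, a true LI kernel over the two-tone grid, FM sweep
#' amplitudes, GCaMP6s-like transient kinetics, and noise levels.
#'
#' @param base_amp_center center-tone response amplitude, dF/F units (>= 0).
#' @param amp_dF named numeric vector of dF-tone amplitudes (names = dF in
#'   octaves), all >= 0.
#' @param li_kernel 9 x 9 matrix of true LI values in `[-1, 1]`.
#' @param sweep_amp matrix rates x c("up","down") of FM response
#'   amplitudes, >= 0; may be NULL if sweeps are not simulated.
#' @param rise_tau,decay_tau calcium transient time constants, seconds (> 0).
#' @param trial_noise_cv coefficient of variation of multiplicative
#'   (lognormal) trial-to-trial amplitude noise.
#' @param baseline_sd additive Gaussian baseline noise SD, dF/F units.
#' @param id cell identifier.
#' @return object of class `ground_truth_cell`.
#' @export
ground_truth_cell <- function(base_amp_center, amp_dF, li_kernel,
                              sweep_amp = NULL,
                              rise_tau = 0.2, decay_tau = 1.5,
                              trial_noise_cv = 0.2, baseline_sd = 0.05,
                              id = "cell1") {
  stopifnot(is.matrix(li_kernel))
  if (any(li_kernel < -1 | li_kernel > 1))
    stop("li_kernel values must lie in [-1, 1]")
  if (base_amp_center < 0 || any(amp_dF < 0) ||
      (!is.null(sweep_amp) && any(sweep_amp < 0)))
    stop("amplitude fields must be >= 0")
  if (rise_tau <= 0 || decay_tau <= 0)
    stop("kinetics taus must be > 0")
  if (trial_noise_cv < 0 || baseline_sd < 0)
    stop("noise parameters must be >= 0")
  structure(list(base_amp_center = base_amp_center, amp_dF = amp_dF,
                 li_kernel = li_kernel, sweep_amp = sweep_amp,
                 rise_tau = rise_tau, decay_tau = decay_tau,
                 trial_noise_cv = trial_noise_cv, baseline_sd = baseline_sd,
                 id = id),
            class = "ground_truth_cell")
}

#' Invert the LI definition to get a two-tone amplitude
#'
#' Given a cell's linear-sum amplitude L (center-tone + dF-tone) and its
#' true LI at a (dF, dT) grid point, returns the two-tone amplitude
#' T = L (1 + LI) / (1 - LI), so that (T - L) / (T + L) recovers LI
#' exactly. LI = -1 maps to full suppression (T = 0); LI = 1 with L > 0 is
#' unrepresentable and raises an error (templates cap |LI| below 1).
#'
#' @param cell a `ground_truth_cell`.
#' @param dF,dT grid coordinates (must match kernel dimnames).
#' @return two-tone amplitude, dF/F units.
#' @export
two_tone_amplitude_from_kernel <- function(cell, dF, dT) {
  li <- cell$li_kernel[as.character(dF), as.character(dT)]
  L <- cell$base_amp_center + unname(cell$amp_dF[as.character(dF)])
  if (li >= 1 && L > 0)
    stop("LI = 1 with L > 0 is unrepresentable; cap template LI below 1")
  L * (1 + li) / (1 - li)
}

# ground-truth amplitude for any condition row of the protocol table
true_amplitude <- function(cell, cond) {
  switch(cond$type,
         twotone = two_tone_amplitude_from_kernel(cell, cond$dF, cond$dT),
         single = if (cond$condition_id == "st_center") cell$base_amp_center
                  else unname(cell$amp_dF[as.character(cond$dF)]),
         fm = {
           if (is.null(cell$sweep_amp)) 0
           else cell$sweep_amp[as.character(cond$rate), cond$direction]
         },
         stop("unknown condition type: ", cond$type))
}

# deterministic per-cell substream: cell i always gets the same seed for a
# given global seed, so changing the cell count does not reshuffle cells
cell_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + 7919 * i) %% 2147483647)
}

#' Simulate a population of ground-truth cells
#'
#' Draws `n_cells` cells from a kernel template with per-cell variability:
#' lognormal center-tone amplitudes, Gaussian dF tuning of variable width,
#' cell-to-cell jitter on the LI kernel (clipped to the cap), and FM sweep
#' amplitudes whose direction asymmetry can be coupled to the kernel's
#' suppressive asymmetry.
#'
#' For `a1_asymmetric` cells, each cell draws a suppression asymmetry
#' `a ~ U(-supp_asym_range, supp_asym_range)` and a random cluster
#' quadrant; its sweep direction preference is
#' `s = tanh(sweep_bias_coupling * a + N(0, dsi_noise_sd))`, with
#' `U = A (1 + s)`, `D = A (1 - s)` at each rate, so direction selectivity
#' is driven by the suppressive LI bias when coupling is positive and is
#' pure noise when `sweep_bias_coupling = 0`. Other templates have
#' symmetric suppression (a = 0), so their DSI is noise-only.
#'
#' @param n_cells number of cells.
#' @param template kernel template name (see [kernel_template()]).
#' @param seed global seed; each cell uses a counter-derived substream.
#' @param mean_amp median center-tone amplitude, dF/F.
#' @param amp_sdlog lognormal sdlog of center-tone amplitudes.
#' @param tuning_sigma_oct mean Gaussian dF-tuning width, octaves.
#' @param peak_range per-cell range of the kernel's supralinear peak LI
#'   (uniform draw); the resulting cell-to-cell heterogeneity in
#'   nonlinear gain is what makes two-tone ensembles diverge from
#'   linear-sum predictions.
#' @param kernel_jitter_sd per-cell SD of LI kernel jitter.
#' @param supp_asym_range half-range of a1 suppression asymmetry.
#' @param sweep_bias_coupling coupling of sweep direction preference to the
#'   kernel suppression asymmetry (default 1; 0 = uncoupled).
#' @param dsi_noise_sd SD of the direction-preference noise term.
#' @param trial_noise_cv,baseline_sd per-trial noise levels (see
#'   [ground_truth_cell()]).
#' @param include_sweeps generate FM sweep amplitudes.
#' @param fm_rates FM rates, oct/s.
#' @param dF_oct,dT_ms stimulus grid.
#' @param li_cap kernel magnitude cap.
#' @return list of `ground_truth_cell`, with the template name stored in
#'   attribute "template".
#' @export
simulate_population <- function(n_cells, template = "a2_coincident",
                                seed = 1L,
                                mean_amp = 0.5, amp_sdlog = 0.4,
                                tuning_sigma_oct = 0.6,
                                peak_range = c(0.3, 0.9),
                                kernel_jitter_sd = 0.08,
                                supp_asym_range = 0.8,
                                sweep_bias_coupling = 1,
                                dsi_noise_sd = 0.2,
                                trial_noise_cv = 0.2, baseline_sd = 0.05,
                                include_sweeps = TRUE,
                                fm_rates = c(2.5, 5, 10, 20, 40, 80),
                                dF_oct = seq(-1, 1, by = 0.25),
                                dT_ms = seq(-100, 100, by = 25),
                                li_cap = 0.95) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  quads <- c("df_neg_dt_neg", "df_pos_dt_pos", "df_neg_dt_pos",
             "df_pos_dt_neg")
  cells <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    set.seed(cell_seed(seed, i))
    amp_c <- stats::rlnorm(1, log(mean_amp), amp_sdlog)
    sig_f <- tuning_sigma_oct * stats::runif(1, 0.7, 1.3)
    amp_df <- amp_c * pmax(exp(-dF_oct^2 / (2 * sig_f^2)), 0.05)
    names(amp_df) <- dF_oct
    a <- if (template == "a1_asymmetric")
      stats::runif(1, -supp_asym_range, supp_asym_range) else 0
    k <- kernel_template(template, dF_oct = dF_oct, dT_ms = dT_ms,
                         peak = stats::runif(1, peak_range[1], peak_range[2]),
                         quadrant = sample(quads, 1), supp_asym = a,
                         li_cap = li_cap)
    tmpl <- k
    k <- k + matrix(stats::rnorm(length(k), 0, kernel_jitter_sd),
                    nrow(k), ncol(k))
    # jitter varies magnitudes but preserves the template's sign
    # structure: supralinear cells stay supralinear, suppressive stay
    # suppressive
    k[tmpl > 0] <- pmax(k[tmpl > 0], 0.02)
    k[tmpl < 0] <- pmin(k[tmpl < 0], -0.02)
    k <- pmin(pmax(k, -li_cap), li_cap)
    sweep <- NULL
    if (include_sweeps) {
      s <- tanh(sweep_bias_coupling * a + stats::rnorm(1, 0, dsi_noise_sd))
      # slow sweeps carry more energy: amplitude tapers with rate
      A <- amp_c * seq(1, 0.5, length.out = length(fm_rates))
      sweep <- cbind(up = A * (1 + s), down = A * (1 - s))
      rownames(sweep) <- fm_rates
    }
    cells[[i]] <- ground_truth_cell(
      base_amp_center = amp_c, amp_dF = amp_df, li_kernel = k,
      sweep_amp = sweep, trial_noise_cv = trial_noise_cv,
      baseline_sd = baseline_sd, id = sprintf("cell%04d", i))
  }
  attr(cells, "template") <- template
  cells
}
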