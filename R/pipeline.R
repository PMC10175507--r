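#' Default pipeline configuration
#'
#' Collects every tunable parameter of the pipeline with its default:
#' detection threshold 3.3 x baseline SD, nonlinearity-test alpha 0.1,
#' timing-preference ratio 1.5, map-smoothing sigma 0.4 grid units,
#' background subtraction coefficient 0.9, dF/F offset 20 a.u.,
#' brightness QC ratio 1.03, 5 trials per condition, 5 s ITI, 30 Hz
#' frames, and the classification dF set. Override any field via `...`.
#'
#' @param seed global seed.
#' @param ... named overrides of any default field.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_cells = 60L,
    template = "a2_coincident",
    n_trials = 5L, iti_s = 5, frame_rate = 30,
    include_fm = TRUE,
    threshold_sd = 3.3, min_dur_s = 0.5, sd_floor = 0,
    alpha = 0.1, ratio = 1.5, sigma_grid = 0.4,
    bg_coef = 0.9, offset = 20, brightness_ratio = 1.03,
    class_dF_set = c(-1, -0.5, 0, 0.5, 1),
    mid_rates = c(10, 20, 40),
    trial_noise_cv = 0.2, baseline_sd = 0.05,
    mean_amp = 0.5,
    sweep_bias_coupling = 1,
    test_cells = FALSE,
    out_dir = NULL)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "pipeline_config"
  cfg
}

#' Short provenance hash of a configuration
#'
#' FNV-1a hash of the JSON-serialized config, stamped into pipeline
#' outputs so results can be traced to their exact parameter set.
#'
#' @param cfg a `pipeline_config`.
#' @return 8-character hex string.
#' @export
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                        null = "null")
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Read / write a pipeline configuration as YAML
#'
#' @param cfg a `pipeline_config`.
#' @param path file path.
#' @return `read_config` returns a `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, c(list(seed = cfg$seed),
                             cfg[setdiff(names(cfg), "seed")]))
}

#' Run the full simulate-process-analyze pipeline
#'
#' Generates a synthetic population from the configured template,
#' synthesizes and quantifies trial traces, then runs the two-tone,
#' FM-sweep (if included) and ensemble analyses. Re-running with the same
#' config reproduces the result bit-identically. If `cfg$out_dir` is set,
#' summary tables (CSV) and a JSON stats report embedding the full config
#' are written there.
#'
#' @param cfg a [pipeline_config()].
#' @return list with `config`, `config_hash`, `protocol`, `cells`,
#'   `responses` (response_table), `twotone` (classification fractions,
#'   population map, asymmetry indices, normalized magnitude profile),
#'   `fm` (per-ROI DSI/bias table and correlations; NULL without FM),
#'   `ensemble` (correlation curves and pair table), `funnel` (ROI counts
#'   passing each stage).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (cfg$n_cells < 1) stop("config error: n_cells must be >= 1")
  pr <- build_protocol(n_trials = cfg$n_trials, iti_s = cfg$iti_s,
                       frame_rate = cfg$frame_rate,
                       include_fm = cfg$include_fm, seed = cfg$seed)
  cells <- simulate_population(
    cfg$n_cells, template = cfg$template, seed = cfg$seed,
    mean_amp = cfg$mean_amp, trial_noise_cv = cfg$trial_noise_cv,
    baseline_sd = cfg$baseline_sd, include_sweeps = cfg$include_fm,
    sweep_bias_coupling = cfg$sweep_bias_coupling)
  rt <- simulate_experiment(cells, pr, seed = cfg$seed,
                            threshold_sd = cfg$threshold_sd,
                            min_dur_s = cfg$min_dur_s,
                            sd_floor = cfg$sd_floor)
  rois <- unique(rt$summary$roi)

  cls <- classify_population(rt, rois, ratio = cfg$ratio,
                             dF_set = cfg$class_dF_set)
  maps <- lapply(rois, function(r)
    build_interaction_map(rt, r, alpha = cfg$alpha,
                          sigma_grid = cfg$sigma_grid,
                          test_cells = cfg$test_cells))
  names(maps) <- rois
  has_map <- vapply(maps, function(m) any(m$valid), logical(1))
  asym <- vapply(rois, function(r) asymmetry_index(rt, r), numeric(1))
  twotone <- list(
    classification = cls,
    population_map = aggregate_population_map(maps[has_map]),
    asymmetry = asym,
    magnitude_profile = normalized_magnitude_profile(rt, rois),
    maps = maps)

  fm <- NULL
  if (cfg$include_fm) {
    tun <- lapply(rois, function(r) sweep_tuning(rt, r,
                                                 mid_rates = cfg$mid_rates))
    names(tun) <- rois
    bias <- lapply(maps, linearity_bias)
    fm_tab <- data.frame(
      roi = rois,
      dsi_mid = vapply(tun, `[[`, numeric(1), "dsi_mid"),
      bias_fac = vapply(bias, `[[`, numeric(1), "bias_fac"),
      bias_supp = vapply(bias, `[[`, numeric(1), "bias_supp"),
      row.names = NULL)
    ok <- is.finite(fm_tab$dsi_mid) & is.finite(fm_tab$bias_supp)
    fm <- list(
      table = fm_tab,
      responsive_fraction = responsive_fraction_by_rate(rt, rois),
      cor_supp = if (sum(ok) >= 3)
        correlate_dsi_bias(fm_tab$dsi_mid, fm_tab$bias_supp) else NULL,
      cor_fac = if (sum(ok) >= 3)
        correlate_dsi_bias(fm_tab$dsi_mid, fm_tab$bias_fac) else NULL)
  }

  pv <- population_vectors(rt, rois)
  ens <- list(curves = correlate_conditions(pv),
              pairs = ensemble_pair_correlations(pv),
              two_tone_only = two_tone_only_fraction(rt, rois))

  funnel <- c(n_cells = length(rois),
              sound_responsive = sum(vapply(rois, function(r)
                any(rt$summary$significant[rt$summary$roi == r]),
                logical(1))),
              twotone_responsive = cls$n_responsive,
              li_map = sum(has_map))

  out <- list(config = unclass(cfg), config_hash = config_hash(cfg),
              protocol = pr, cells = cells, responses = rt,
              twotone = twotone, fm = fm, ensemble = ens, funnel = funnel)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cfg$out_dir)
  out
}

#' Compare two proportions with a chi-square test
#'
#' 2 x 2 chi-square test on (successes, failures) per group, without
#' Yates continuity correction by default. Degenerate tables (an empty
#' margin) yield NA.
#'
#' @param k1,n1,k2,n2 successes and totals per group.
#' @param correct apply continuity correction (default FALSE).
#' @return list with `chi2`, `p`.
#' @export
compare_proportions <- function(k1, n1, k2, n2, correct = FALSE) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  m <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE)
  if (any(colSums(m) == 0))
    return(list(chi2 = NA_real_, p = NA_real_))
  ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(chi2 = unname(ct$statistic), p = ct$p.value)
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` per p value, for a declared family of `m` tests.
#'
#' @param p p values in `[0, 1]`.
#' @param m family size; must be at least `length(p)`.
#' @return adjusted p values.
#' @export
adjust_bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must be in [0, 1]")
  if (m < length(p)) stop("m must be >= number of tests")
  pmin(1, p * m)
}

# write the result bundle as CSV tables + a JSON report embedding the config
write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$responses$summary,
                   file.path(dir, "response_summary.csv"), row.names = FALSE)
  utils::write.csv(interaction_maps_to_df(res$twotone$maps),
                   file.path(dir, "interaction_maps.csv"), row.names = FALSE)
  utils::write.csv(res$ensemble$curves,
                   file.path(dir, "ensemble_curves.csv"), row.names = FALSE)
  if (!is.null(res$fm))
    utils::write.csv(res$fm$table, file.path(dir, "fm_dsi_bias.csv"),
                     row.names = FALSE)
  report <- list(
    config = res$config, config_hash = res$config_hash,
    funnel = as.list(res$funnel),
    classification_fractions = as.list(res$twotone$classification$fractions),
    two_tone_only = res$ensemble$two_tone_only,
    fm_correlations = if (is.null(res$fm)) NULL else
      list(supp = res$fm$cor_supp, fac = res$fm$cor_fac))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' Flatten interaction maps into a tidy table
#'
#' @param maps named list of `interaction_map`.
#' @return data.frame: roi, dF, dT, li, valid, smoothed, fac_sig, supp_sig.
#' @export
interaction_maps_to_df <- function(maps) {
  do.call(rbind, lapply(maps, function(m) {
    g <- expand.grid(dF = m$dF, dT = m$dT, KEEP.OUT.ATTRS = FALSE)
    data.frame(roi = m$roi, g, li = as.vector(m$li),
               valid = as.vector(m$valid),
               smoothed = as.vector(m$li_smoothed),
               fac_sig = as.vector(m$fac_sig),
               supp_sig = as.vector(m$supp_sig), row.names = NULL)
  }))
}
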