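#' Linearity index
#'
#' LI = (T - L) / (T + L) for a two-tone response amplitude T against the
#' linear sum L of the component-tone responses. Negative amplitudes are
#' forced to 0 first, keeping LI in `[-1, 1]`: positive = supralinear
#' (facilitative), negative = sublinear (suppressive), 0 = linear
#' summation. Undefined (NA) when both clamp to 0.
#'
#' @param T_amp two-tone amplitude (may be negative; clamped to >= 0).
#' @param L_amp linear-sum amplitude (clamped likewise). Vectorized.
#' @return LI values in `[-1, 1]`, NA where T = L = 0.
#' @export
compute_linearity_index <- function(T_amp, L_amp) {
  t_c <- pmax(T_amp, 0)
  l_c <- pmax(L_amp, 0)
  s <- t_c + l_c
  ifelse(s == 0, NA_real_, (t_c - l_c) / s)
}

# per-ROI amplitude/significance grids from a response table
roi_grids <- function(rt, roi) {
  s <- rt$summary[rt$summary$roi == roi, ]
  if (nrow(s) == 0) stop("unknown roi: ", roi)
  dF <- rt$dF_oct; dT <- rt$dT_ms
  tt <- s[s$type == "twotone", ]
  idx <- cbind(match(tt$dF, dF), match(tt$dT, dT))
  amp <- sig <- matrix(NA, length(dF), length(dT), dimnames = list(dF, dT))
  amp[idx] <- tt$mean_amp
  sig[idx] <- tt$significant
  st <- s[s$type == "single", ]
  if (!any(st$condition_id == "st_center"))
    stop("missing single-tone condition st_center")
  ctr <- st[st$condition_id == "st_center", ]
  dfr <- st[st$condition_id != "st_center", ]
  ord <- match(dF, dfr$dF)
  list(tt_amp = amp, tt_sig = sig == 1,
       center_amp = ctr$mean_amp, center_sig = ctr$significant,
       df_amp = stats::setNames(dfr$mean_amp[ord], dF),
       df_sig = stats::setNames(dfr$significant[ord], dF),
       dF = dF, dT = dT)
}

# trial amplitudes of one (roi, condition)
trial_amps <- function(rt, roi, condition_id) {
  t <- rt$trials
  t$amplitude[t$roi == roi & t$condition_id == condition_id]
}

#' Test one dF-dT pair for significant nonlinear integration
#'
#' Builds the null distribution of linear sums as all pairwise sums of the
#' component-tone trial amplitudes (n_center x n_dF values; 5 x 5 = 25
#' combinations at the default trial count) and compares the two-tone
#' trial amplitudes against it with a two-sided Wilcoxon rank-sum test.
#' The interaction direction is read from the sign of (mean two-tone -
#' mean null). The default alpha of 0.1 is deliberately permissive given
#' the small trial counts.
#'
#' @param tt_amps two-tone trial amplitudes.
#' @param center_amps,df_amps component-tone trial amplitudes.
#' @param alpha significance level (default 0.1).
#' @return list with `type` ("facilitative", "suppressive" or "none"),
#'   `p`, and `n_null` (size of the pairwise-sum null set).
#' @export
test_nonlinearity <- function(tt_amps, center_amps, df_amps, alpha = 0.1) {
  stopifnot(length(tt_amps) >= 2, length(center_amps) >= 2,
            length(df_amps) >= 2)
  nullset <- as.vector(outer(center_amps, df_amps, "+"))
  if (length(unique(c(tt_amps, nullset))) == 1L)
    return(list(type = "none", p = 1, n_null = length(nullset)))
  p <- suppressWarnings(stats::wilcox.test(tt_amps, nullset)$p.value)
  d <- mean(tt_amps) - mean(nullset)
  type <- if (p < alpha && d > 0) "facilitative"
          else if (p < alpha && d < 0) "suppressive"
          else "none"
  list(type = type, p = p, n_null = length(nullset))
}

#' Mask-aware Gaussian smoothing of an LI grid
#'
#' Gaussian-weighted average (SD `sigma_grid` grid units; 0.4 by default,
#' i.e. 0.1 oct along dF and 10 ms along dT) computed over valid cells
#' only, with the kernel renormalized over the available support at every
#' position, so grid edges and invalid cells do not drag estimates toward
#' zero. Defined wherever at least one valid cell exists.
#'
#' @param li numeric matrix of LI values (NA allowed).
#' @param valid logical mask; defaults to `!is.na(li)`.
#' @param sigma_grid Gaussian SD in grid units (> 0).
#' @return smoothed matrix, NA where no valid support.
#' @export
smooth_map <- function(li, valid = NULL, sigma_grid = 0.4) {
  stopifnot(is.matrix(li), sigma_grid > 0)
  if (is.null(valid)) valid <- !is.na(li)
  nr <- nrow(li); nc <- ncol(li)
  out <- matrix(NA_real_, nr, nc, dimnames = dimnames(li))
  vi <- which(valid, arr.ind = TRUE)
  if (nrow(vi) == 0) return(out)
  vals <- li[valid]
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    w <- exp(-((vi[, 1] - i)^2 + (vi[, 2] - j)^2) / (2 * sigma_grid^2))
    out[i, j] <- sum(w * vals) / sum(w)
  }
  out
}

#' Build a per-ROI spectrotemporal interaction map
#'
#' Computes LI over the 9 x 9 (dF, dT) grid from trial-mean amplitudes. A
#' grid cell is valid only if a significant excitatory response was evoked
#' by the dF-dT pair itself, the center tone, or the dF tone; cells where
#' both T and L clamp to zero are additionally invalid. The map is
#' smoothed with [smooth_map()], and (optionally) each valid cell is
#' tested for significant facilitative/suppressive interaction with
#' [test_nonlinearity()].
#'
#' @param rt a `response_table`.
#' @param roi ROI identifier.
#' @param alpha nonlinearity-test significance level.
#' @param sigma_grid smoothing SD, grid units.
#' @param test_cells run the per-cell nonlinearity tests (default TRUE).
#' @return object of class `interaction_map`: list with `li`, `valid`,
#'   `li_smoothed`, `fac_sig`, `supp_sig` (all 9 x 9, dF rows x dT cols),
#'   `dF`, `dT`, `roi`.
#' @export
build_interaction_map <- function(rt, roi, alpha = 0.1, sigma_grid = 0.4,
                                  test_cells = TRUE) {
  g <- roi_grids(rt, roi)
  T_amp <- pmax(g$tt_amp, 0)
  L_amp <- pmax(g$center_amp, 0) +
    matrix(pmax(g$df_amp, 0), length(g$dF), length(g$dT))
  gate <- g$tt_sig | g$center_sig |
    matrix(g$df_sig, length(g$dF), length(g$dT))
  li <- compute_linearity_index(g$tt_amp, L_amp)
  valid <- gate & !is.na(li)
  li[!valid] <- NA_real_
  fac <- supp <- matrix(FALSE, length(g$dF), length(g$dT),
                        dimnames = dimnames(li))
  if (test_cells && any(valid)) {
    ctr <- trial_amps(rt, roi, "st_center")
    for (ij in which(valid)) {
      i <- (ij - 1L) %% length(g$dF) + 1L
      j <- (ij - 1L) %/% length(g$dF) + 1L
      tt_id <- sprintf("tt_%+.2f_%+04d", g$dF[i], g$dT[j])
      df_id <- sprintf("st_df_%+.2f", g$dF[i])
      res <- test_nonlinearity(trial_amps(rt, roi, tt_id), ctr,
                               trial_amps(rt, roi, df_id), alpha = alpha)
      if (res$type == "facilitative") fac[ij] <- TRUE
      if (res$type == "suppressive") supp[ij] <- TRUE
    }
  }
  structure(list(li = li, valid = valid,
                 li_smoothed = smooth_map(li, valid, sigma_grid),
                 fac_sig = fac, supp_sig = supp,
                 dF = g$dF, dT = g$dT, roi = roi),
            class = "interaction_map")
}

#' @export
print.interaction_map <- function(x, ...) {
  cat("Interaction map for", x$roi, "-", sum(x$valid), "of",
      length(x$valid), "cells valid; mean LI",
      round(mean(x$li[x$valid]), 3), "\n")
  invisible(x)
}

#' Average interaction map across a population
#'
#' Cell-wise mean of LI over the maps in which the cell is defined,
#' reporting per-cell n. Uses the smoothed per-ROI maps by default
#' (matching how single-neuron maps are rendered); set
#' `use_smoothed = FALSE` to average raw LI over valid cells only.
#'
#' @param maps list of `interaction_map`.
#' @param use_smoothed average `li_smoothed` (default) or raw `li`.
#' @return list with `mean_li` (matrix) and `n` (contributing maps per
#'   cell).
#' @export
aggregate_population_map <- function(maps, use_smoothed = TRUE) {
  stopifnot(length(maps) >= 1)
  field <- if (use_smoothed) "li_smoothed" else "li"
  arr <- vapply(maps, `[[`, maps[[1]]$li, field)
  n <- apply(!is.na(arr), c(1, 2), sum)
  s <- apply(arr, c(1, 2), function(v) sum(v, na.rm = TRUE))
  mean_li <- ifelse(n > 0, s / n, NA_real_)
  dimnames(mean_li) <- dimnames(maps[[1]]$li)
  list(mean_li = mean_li, n = n)
}

#' Normalized response-magnitude profile along dT
#'
#' For every ROI-dF pair with a significant excitatory response at >= 1
#' dT, the 9 dT amplitudes (clamped to >= 0) are divided by their maximum,
#' then averaged across all contributing pairs, yielding a 9-point profile
#' in `[0, 1]` describing timing tuning irrespective of absolute response
#' size. Pairs whose maximum amplitude is <= 0 are excluded.
#'
#' @param rt a `response_table`.
#' @param rois ROI identifiers to pool (default: all).
#' @return list with `profile` (named 9-vector over dT), `n_pairs`.
#' @export
normalized_magnitude_profile <- function(rt, rois = unique(rt$summary$roi)) {
  dT <- rt$dT_ms
  acc <- matrix(NA_real_, 0, length(dT))
  for (roi in rois) {
    g <- roi_grids(rt, roi)
    amp <- pmax(g$tt_amp, 0)
    for (i in seq_along(g$dF)) {
      if (!any(g$tt_sig[i, ])) next
      mx <- max(amp[i, ])
      if (mx <= 0) next
      acc <- rbind(acc, amp[i, ] / mx)
    }
  }
  list(profile = stats::setNames(colMeans(acc), dT), n_pairs = nrow(acc))
}

#' Classify a neuron's two-tone timing preference
#'
#' Compares mean response amplitudes (clamped to >= 0) for coincident
#' (dT = 0) versus temporally shifted two tones, each averaged over the
#' configured dF set (default 5 dFs: -1, -0.5, 0, 0.5, 1 oct; shifted =
#' the same dFs x 8 shifted dTs = 40 pairs). A neuron is
#' coincidence-preferring if the coincident amplitude exceeds `ratio`
#' (default 1.5) times the shifted amplitude, and shift-preferring in the
#' converse case; shift-preferring neurons are subdivided into negative- /
#' positive-dT-preferring by the same ratio rule on the negative- vs
#' positive-dT averages, otherwise symmetric. Neurons satisfying neither
#' rule are unclassified.
#'
#' @param rt a `response_table`.
#' @param roi ROI identifier.
#' @param ratio preference ratio (default 1.5).
#' @param dF_set dF values averaged over.
#' @return list with `label` (one of "coincident_preferring",
#'   "negative_dT_preferring", "positive_dT_preferring",
#'   "symmetric_shift_preferring", "unclassified"), `coincident_amp`,
#'   `shifted_amp`, `neg_amp`, `pos_amp`, `responsive` (any significant
#'   two-tone response).
#' @export
classify_timing_preference <- function(rt, roi, ratio = 1.5,
                                       dF_set = c(-1, -0.5, 0, 0.5, 1)) {
  g <- roi_grids(rt, roi)
  amp <- pmax(g$tt_amp, 0)
  ri <- match(dF_set, g$dF)
  if (any(is.na(ri))) stop("dF_set values not on the stimulus grid")
  coin <- mean(amp[ri, g$dT == 0])
  shift <- mean(amp[ri, g$dT != 0])
  neg <- mean(amp[ri, g$dT < 0])
  pos <- mean(amp[ri, g$dT > 0])
  label <- if (coin > ratio * shift) "coincident_preferring"
  else if (shift > ratio * coin) {
    if (neg > ratio * pos) "negative_dT_preferring"
    else if (pos > ratio * neg) "positive_dT_preferring"
    else "symmetric_shift_preferring"
  } else "unclassified"
  list(label = label, coincident_amp = coin, shifted_amp = shift,
       neg_amp = neg, pos_amp = pos, responsive = any(g$tt_sig))
}

#' Timing-preference composition of a population
#'
#' Classifies every two-tone-responsive ROI (>= 1 significant two-tone
#' condition) and tabulates label fractions.
#'
#' @param rt a `response_table`.
#' @param rois ROIs to consider (default all).
#' @param ratio,dF_set passed to [classify_timing_preference()].
#' @return list with `labels` (named character vector over responsive
#'   ROIs), `fractions` (proportion per label), `n_responsive`.
#' @export
classify_population <- function(rt, rois = unique(rt$summary$roi),
                                ratio = 1.5,
                                dF_set = c(-1, -0.5, 0, 0.5, 1)) {
  labs <- character(0)
  for (roi in rois) {
    cl <- classify_timing_preference(rt, roi, ratio = ratio, dF_set = dF_set)
    if (cl$responsive) labs[roi] <- cl$label
  }
  lv <- c("coincident_preferring", "negative_dT_preferring",
          "positive_dT_preferring", "symmetric_shift_preferring",
          "unclassified")
  frac <- table(factor(labs, levels = lv)) / max(length(labs), 1L)
  list(labels = labs, fractions = c(frac), n_responsive = length(labs))
}

#' Asymmetry index of a two-tone response map
#'
#' |(P - N) / (P + N)| where P and N are the summed response amplitudes
#' (clamped to >= 0) over all two-tone conditions with positive and
#' negative dT respectively. 0 = symmetric timing tuning, 1 = fully
#' one-sided. NA when P = N = 0.
#'
#' @param rt a `response_table`.
#' @param roi ROI identifier.
#' @return value in `[0, 1]`, or NA.
#' @export
asymmetry_index <- function(rt, roi) {
  g <- roi_grids(rt, roi)
  amp <- pmax(g$tt_amp, 0)
  P <- sum(amp[, g$dT > 0])
  N <- sum(amp[, g$dT < 0])
  if (P + N == 0) return(NA_real_)
  abs((P - N) / (P + N))
}
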