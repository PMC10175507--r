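#' Direction selectivity index
#'
#' DSI = (U - D) / (U + D) for upward (U) and downward (D) FM sweep
#' response amplitudes, clamped to >= 0 first so DSI stays in `[-1, 1]`.
#' NA when both clamp to zero. Vectorized; antisymmetric under swapping
#' U and D.
#'
#' @param U,D response amplitudes, dF/F units.
#' @return DSI in `[-1, 1]`, NA where undefined.
#' @export
compute_dsi <- function(U, D) {
  u <- pmax(U, 0); d <- pmax(D, 0)
  s <- u + d
  ifelse(s == 0, NA_real_, (u - d) / s)
}

#' FM sweep tuning of one ROI
#'
#' Collects mean response amplitudes by (rate, direction), flags rates
#' with a significant excitatory response in at least one direction, and
#' computes per-rate DSI (defined only for responsive rates) plus a
#' single summary DSI from amplitudes averaged over the mid rates
#' (10-40 oct/s by default) via [dsi_summary()].
#'
#' @param rt a `response_table` containing FM conditions.
#' @param roi ROI identifier.
#' @param mid_rates rates averaged for the summary DSI.
#' @return object of class `sweep_tuning`: list with `amp` (matrix rates x
#'   up/down, clamped >= 0), `sig` (same shape), `responsive_rates`,
#'   `dsi_per_rate`, `dsi_mid`, `roi`.
#' @export
sweep_tuning <- function(rt, roi, mid_rates = c(10, 20, 40)) {
  s <- rt$summary[rt$summary$roi == roi & rt$summary$type == "fm", ]
  if (nrow(s) == 0) stop("no FM conditions for roi ", roi)
  rates <- sort(unique(s$rate))
  amp <- sig <- matrix(NA, length(rates), 2,
                       dimnames = list(rates, c("up", "down")))
  for (k in seq_len(nrow(s)))
    amp[as.character(s$rate[k]), s$direction[k]] <- s$mean_amp[k]
  for (k in seq_len(nrow(s)))
    sig[as.character(s$rate[k]), s$direction[k]] <- s$significant[k]
  amp <- pmax(amp, 0)
  responsive <- rates[rowSums(sig == 1) > 0]
  dsi <- rep(NA_real_, length(rates))
  names(dsi) <- rates
  in_resp <- rates %in% responsive
  dsi[in_resp] <- compute_dsi(amp[in_resp, "up"], amp[in_resp, "down"])
  tun <- structure(list(amp = amp, sig = sig == 1,
                        responsive_rates = responsive,
                        dsi_per_rate = dsi, roi = roi),
                   class = "sweep_tuning")
  tun$dsi_mid <- dsi_summary(tun, rates = mid_rates)
  tun
}

#' Summary DSI over a rate subset
#'
#' Averages the upward and downward amplitudes over the qualifying rates
#' first (those in `rates` with a significant response in >= 1 direction),
#' then computes a single DSI from the averaged amplitudes — not the mean
#' of per-rate DSIs. NA when no rate qualifies.
#'
#' @param tuning a `sweep_tuning`.
#' @param rates rate subset, oct/s (default 10, 20, 40).
#' @return scalar DSI or NA.
#' @export
dsi_summary <- function(tuning, rates = c(10, 20, 40)) {
  qual <- intersect(rates, tuning$responsive_rates)
  if (length(qual) == 0) return(NA_real_)
  idx <- as.character(qual)
  compute_dsi(mean(tuning$amp[idx, "up"]), mean(tuning$amp[idx, "down"]))
}

#' Fraction of ROIs responsive at each absolute FM rate
#'
#' Per rate, the fraction of ROIs with a significant excitatory response
#' to at least one sweep direction (FM window: sound onset to 0.3 s after
#' sweep offset, set by the protocol).
#'
#' @param rt a `response_table` containing FM conditions.
#' @param rois ROIs to pool (default all); must be non-empty.
#' @return named numeric vector of fractions, one per rate.
#' @export
responsive_fraction_by_rate <- function(rt, rois = unique(rt$summary$roi)) {
  if (length(rois) == 0) stop("empty ROI set")
  counts <- responsive_counts_by_rate(rt, rois)
  counts / length(rois)
}

# number of ROIs significant in >= 1 direction at each absolute rate
responsive_counts_by_rate <- function(rt, rois) {
  s <- rt$summary[rt$summary$type == "fm" & rt$summary$roi %in% rois, ]
  rates <- sort(unique(s$rate))
  cnt <- vapply(rates, function(r) {
    sr <- s[s$rate == r, ]
    sum(tapply(sr$significant, sr$roi, any))
  }, numeric(1))
  names(cnt) <- rates
  cnt
}

#' Compare responsive fractions between two ROI groups
#'
#' Chi-square tests per absolute rate with Bonferroni correction over the
#' number of rates.
#'
#' @param rt1,rt2 response tables of the two groups.
#' @param rois1,rois2 ROI sets.
#' @return data.frame: rate, frac1, frac2, chi2, p, p_adj.
#' @export
compare_responsive_fractions <- function(rt1, rt2,
                                         rois1 = unique(rt1$summary$roi),
                                         rois2 = unique(rt2$summary$roi)) {
  k1 <- responsive_counts_by_rate(rt1, rois1)
  k2 <- responsive_counts_by_rate(rt2, rois2)
  rates <- as.numeric(names(k1))
  n1 <- length(rois1); n2 <- length(rois2)
  f1 <- k1 / n1; f2 <- k2 / n2
  res <- lapply(seq_along(rates), function(i)
    compare_proportions(k1[i], n1, k2[i], n2))
  p <- vapply(res, `[[`, numeric(1), "p")
  data.frame(rate = rates, frac1 = unname(f1), frac2 = unname(f2),
             chi2 = vapply(res, `[[`, numeric(1), "chi2"),
             p = p, p_adj = adjust_bonferroni(p, length(rates)))
}

#' Facilitative and suppressive linearity-index bias
#'
#' Splits the raw (unsmoothed) LI map into the Upward region (dF > 0,
#' dT > 0 and dF < 0, dT < 0 quadrants) and the Downward region (the two
#' opposite quadrants), excluding the dF = 0 row and dT = 0 column, and
#' returns the difference of summed LI between regions separately for
#' facilitative (LI > 0) and suppressive (LI < 0) values, over valid map
#' cells only:
#' `bias_fac = sum(LI > 0, Upward) - sum(LI > 0, Downward)` and
#' `bias_supp = sum(LI < 0, Upward) - sum(LI < 0, Downward)`.
#' With this orientation a positive `bias_supp` (weaker suppression in the
#' Upward region) predicts upward direction selectivity. Both NA when the
#' map has no valid off-axis cell.
#'
#' @param map an `interaction_map`.
#' @return list with `bias_fac`, `bias_supp`.
#' @export
linearity_bias <- function(map) {
  sgn <- outer(sign(map$dF), sign(map$dT))
  up <- sgn > 0; down <- sgn < 0
  ok <- map$valid & (up | down)
  if (!any(ok)) return(list(bias_fac = NA_real_, bias_supp = NA_real_))
  li <- map$li
  psum <- function(m) sum(li[m & ok & !is.na(li) & li > 0])
  nsum <- function(m) sum(li[m & ok & !is.na(li) & li < 0])
  list(bias_fac = psum(up) - psum(down),
       bias_supp = nsum(up) - nsum(down))
}

#' Correlate DSI with linearity-index bias
#'
#' Pearson correlation between per-neuron DSI values and bias scores,
#' with the p value from the two-sided t-test on R with n - 2 degrees of
#' freedom. NA pairs are dropped; requires >= 3 complete pairs and
#' non-zero variance in both variables.
#'
#' @param dsi,bias paired numeric vectors.
#' @return list with `R`, `p`, `n`.
#' @export
correlate_dsi_bias <- function(dsi, bias) {
  ok <- is.finite(dsi) & is.finite(bias)
  dsi <- dsi[ok]; bias <- bias[ok]
  if (length(dsi) < 3) stop("need >= 3 complete (dsi, bias) pairs")
  if (stats::sd(dsi) == 0 || stats::sd(bias) == 0)
    return(list(R = NA_real_, p = NA_real_, n = length(dsi)))
  ct <- stats::cor.test(dsi, bias, method = "pearson")
  list(R = unname(ct$estimate), p = ct$p.value, n = length(dsi))
}
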