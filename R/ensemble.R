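#' Significance-gated population response vectors
#'
#' Builds, for every condition, the vector of trial-mean response
#' amplitudes over all pooled ROIs (one shared ROI ordering), with
#' amplitudes clamped to >= 0 and non-significant (ROI, condition) entries
#' forced exactly to 0 for de-noising.
#'
#' @param rt a combined `response_table` (ROIs concatenated across
#'   animals).
#' @param rois ROI ordering to use (default: order of appearance).
#' @return object of class `population_vectors`: list with `V` (matrix
#'   roi x condition), `conditions`, `rois`, `dF_oct`, `dT_ms`.
#' @export
population_vectors <- function(rt, rois = unique(rt$summary$roi)) {
  s <- rt$summary[rt$summary$roi %in% rois, ]
  conds <- unique(s$condition_id)
  V <- matrix(0, length(rois), length(conds),
              dimnames = list(rois, conds))
  val <- ifelse(s$significant, pmax(s$mean_amp, 0), 0)
  V[cbind(match(s$roi, rois), match(s$condition_id, conds))] <- val
  structure(list(V = V, conditions = conds, rois = rois,
                 dF_oct = rt$dF_oct, dT_ms = rt$dT_ms),
            class = "population_vectors")
}

#' Population vector of one condition
#'
#' @param pv a `population_vectors` object.
#' @param condition_id condition identifier.
#' @return numeric vector over the shared ROI ordering.
#' @export
build_population_vector <- function(pv, condition_id) {
  if (!condition_id %in% colnames(pv$V))
    stop("unknown condition: ", condition_id)
  pv$V[, condition_id]
}

#' Linear-sum population vector
#'
#' Elementwise sum of the two zero-forced single-tone vectors (center
#' tone and dF tone); the prediction of two-tone ensemble activity under
#' linear summation.
#'
#' @param center_vec,df_vec equal-length population vectors.
#' @return numeric vector.
#' @export
linear_sum_vector <- function(center_vec, df_vec) {
  if (length(center_vec) != length(df_vec))
    stop("vector length mismatch")
  center_vec + df_vec
}

# internal: correlation skipping zero-variance pairs
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Ensemble correlations per (dF, dT) pair
#'
#' Pearson correlation between each two-tone population vector and its
#' linear-sum prediction (center-tone vector + dF-tone vector), one row
#' per (dF, dT) pair. dF = 0 pairs are excluded by default (the dF tone
#' duplicates the center tone there). Zero-variance pairs yield NA.
#'
#' @param pv a `population_vectors` object.
#' @param exclude_dF0 drop dF = 0 conditions (default TRUE).
#' @return data.frame: dF, dT, timing ("coincident"/"shifted"), r.
#' @export
ensemble_pair_correlations <- function(pv, exclude_dF0 = TRUE) {
  dFs <- pv$dF_oct
  if (exclude_dF0) dFs <- dFs[dFs != 0]
  ctr <- build_population_vector(pv, "st_center")
  out <- expand.grid(dF = dFs, dT = pv$dT_ms, KEEP.OUT.ATTRS = FALSE)
  out$timing <- ifelse(out$dT == 0, "coincident", "shifted")
  out$r <- vapply(seq_len(nrow(out)), function(i) {
    tt <- build_population_vector(
      pv, sprintf("tt_%+.2f_%+04d", out$dF[i], out$dT[i]))
    ls <- linear_sum_vector(
      ctr, build_population_vector(pv, sprintf("st_df_%+.2f", out$dF[i])))
    safe_cor(tt, ls)
  }, numeric(1))
  out
}

#' Ensemble correlation curves along dT
#'
#' Per dT: the mean over dFs of the correlation between the two-tone
#' population vector and (a) the linear-sum prediction and (b) the
#' single-tone vectors (averaged over dFs and both component tones).
#' Zero-variance pairs are skipped.
#'
#' @param pv a `population_vectors` object.
#' @param exclude_dF0 drop dF = 0 conditions (default TRUE).
#' @return data.frame: dT, r_linear_sum, r_single_tone, n_pairs.
#' @export
correlate_conditions <- function(pv, exclude_dF0 = TRUE) {
  dFs <- pv$dF_oct
  if (exclude_dF0) dFs <- dFs[dFs != 0]
  ctr <- build_population_vector(pv, "st_center")
  res <- lapply(pv$dT_ms, function(dt) {
    r_ls <- r_st <- c()
    for (df in dFs) {
      tt <- build_population_vector(pv, sprintf("tt_%+.2f_%+04d", df, dt))
      dfv <- build_population_vector(pv, sprintf("st_df_%+.2f", df))
      r_ls <- c(r_ls, safe_cor(tt, linear_sum_vector(ctr, dfv)))
      r_st <- c(r_st, safe_cor(tt, ctr), safe_cor(tt, dfv))
    }
    data.frame(dT = dt, r_linear_sum = mean(r_ls, na.rm = TRUE),
               r_single_tone = mean(r_st, na.rm = TRUE),
               n_pairs = sum(!is.na(r_ls)))
  })
  do.call(rbind, res)
}

#' Compare coincident vs shifted ensemble correlations across areas
#'
#' Two-way ANOVA (area x timing) on (dF, dT)-pair-level linear-sum
#' correlations, followed by Tukey's honest significant difference test
#' for pairwise contrasts.
#'
#' @param pairs_by_area named list of data.frames from
#'   [ensemble_pair_correlations()], one per area.
#' @return list with `anova` (data.frame of F and p per term), `tukey`
#'   (TukeyHSD contrast tables), `data`.
#' @export
compare_coincident_shifted <- function(pairs_by_area) {
  stopifnot(length(pairs_by_area) >= 2, !is.null(names(pairs_by_area)))
  d <- do.call(rbind, lapply(names(pairs_by_area), function(a) {
    x <- pairs_by_area[[a]]
    data.frame(area = a, timing = x$timing, r = x$r)
  }))
  d <- d[is.finite(d$r), ]
  if (any(table(d$area, d$timing) == 0))
    stop("empty design cell in area x timing")
  d$area <- factor(d$area)
  d$timing <- factor(d$timing)
  fit <- stats::aov(r ~ area * timing, data = d)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  keep <- terms != "Residuals"
  list(anova = data.frame(term = terms[keep],
                          F = tab[keep, "F value"],
                          p = tab[keep, "Pr(>F)"]),
       tukey = stats::TukeyHSD(fit), data = d)
}

#' Fraction of single-tone non-responsive neurons recruited by two tones
#'
#' Among ROIs with no significant response to any single tone, the
#' fraction showing a significant response to at least one two-tone
#' condition, split into coincident-only (dT = 0 conditions only),
#' shifted-only, and both. NA when every ROI is single-tone responsive.
#'
#' @param rt a `response_table`.
#' @param rois ROIs to consider (default all).
#' @return list with `fraction`, `n_single_nonresponsive`, `coincident_only`,
#'   `shifted_only`, `both` (fractions of the same denominator).
#' @export
two_tone_only_fraction <- function(rt, rois = unique(rt$summary$roi)) {
  s <- rt$summary[rt$summary$roi %in% rois, ]
  res <- lapply(rois, function(roi) {
    sr <- s[s$roi == roi, ]
    st <- sr$type == "single"
    tt <- sr$type == "twotone"
    coin <- tt & !is.na(sr$dT) & sr$dT == 0
    shif <- tt & !is.na(sr$dT) & sr$dT != 0
    c(single = any(sr$significant[st]),
      coin = any(sr$significant[coin]),
      shift = any(sr$significant[shif]))
  })
  m <- do.call(rbind, res)
  nonresp <- !m[, "single"]
  n <- sum(nonresp)
  if (n == 0)
    return(list(fraction = NA_real_, n_single_nonresponsive = 0L,
                coincident_only = NA_real_, shifted_only = NA_real_,
                both = NA_real_))
  coin <- m[nonresp, "coin"]; shif <- m[nonresp, "shift"]
  list(fraction = mean(coin | shif), n_single_nonresponsive = n,
       coincident_only = mean(coin & !shif),
       shifted_only = mean(shif & !coin),
       both = mean(coin & shif))
}
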