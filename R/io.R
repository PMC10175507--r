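#' Write a synthetic dataset to a plain-text directory container
#'
#' Serializes a protocol, per-ROI trial traces, and (optionally) the
#' generating ground truth into a directory of portable text files:
#' `conditions.csv`, `schedule.csv`, `traces.csv` (long format: roi,
#' trial, frame, dff), `ground_truth.json`, and `protocol.yaml`. Suitable
#' for small datasets and interchange; large populations are better kept
#' in memory and processed per cell.
#'
#' @param trace_list list of `roi_traces` (one per ROI, shared protocol).
#' @param dir output directory (created if needed).
#' @param ground_truth include each cell's ground-truth parameters.
#' @return the directory path, invisibly.
#' @export
write_dataset <- function(trace_list, dir, ground_truth = TRUE) {
  stopifnot(length(trace_list) >= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pr <- trace_list[[1]]$protocol
  utils::write.csv(pr$conditions, file.path(dir, "conditions.csv"),
                   row.names = FALSE)
  utils::write.csv(pr$schedule, file.path(dir, "schedule.csv"),
                   row.names = FALSE)
  long <- do.call(rbind, lapply(trace_list, function(tr) {
    d <- tr$dff
    data.frame(roi = tr$roi,
               trial = rep(seq_len(nrow(d)), times = ncol(d)),
               frame = rep(seq_len(ncol(d)), each = nrow(d)),
               dff = as.vector(d))
  }))
  utils::write.csv(long, file.path(dir, "traces.csv"), row.names = FALSE)
  yaml::write_yaml(list(n_trials = pr$n_trials, iti_s = pr$iti_s,
                        frame_rate = pr$frame_rate,
                        baseline_s = pr$baseline_s,
                        n_frames = pr$n_frames,
                        include_fm = length(pr$fm_rates) > 0),
                   file.path(dir, "protocol.yaml"))
  if (ground_truth) {
    gt <- lapply(trace_list, function(tr) {
      if (is.null(tr$cell)) return(NULL)
      c <- tr$cell
      list(id = c$id, base_amp_center = c$base_amp_center,
           amp_dF = as.list(c$amp_dF),
           li_kernel = apply(c$li_kernel, 1, as.list),
           rise_tau = c$rise_tau, decay_tau = c$decay_tau,
           trial_noise_cv = c$trial_noise_cv, baseline_sd = c$baseline_sd)
    })
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}

#' Read a dataset container written by [write_dataset()]
#'
#' Reconstructs the protocol and the per-ROI trial trace objects from the
#' text container. Ground truth, if present, is attached to each ROI as a
#' plain list (not a `ground_truth_cell`).
#'
#' @param dir container directory.
#' @return list of `roi_traces`.
#' @export
read_dataset <- function(dir) {
  conds <- utils::read.csv(file.path(dir, "conditions.csv"),
                           stringsAsFactors = FALSE)
  sched <- utils::read.csv(file.path(dir, "schedule.csv"),
                           stringsAsFactors = FALSE)
  meta <- yaml::read_yaml(file.path(dir, "protocol.yaml"))
  pr <- build_protocol(n_trials = meta$n_trials, iti_s = meta$iti_s,
                       frame_rate = meta$frame_rate,
                       baseline_s = meta$baseline_s,
                       include_fm = meta$include_fm)
  pr$conditions <- conds
  pr$schedule <- sched
  long <- utils::read.csv(file.path(dir, "traces.csv"),
                          stringsAsFactors = FALSE)
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) jsonlite::read_json(gt_path) else NULL
  rois <- unique(long$roi)
  out <- lapply(seq_along(rois), function(i) {
    sub <- long[long$roi == rois[i], ]
    d <- matrix(NA_real_, max(sub$trial), max(sub$frame))
    d[cbind(sub$trial, sub$frame)] <- sub$dff
    structure(list(dff = d, schedule = sched, protocol = pr,
                   roi = rois[i],
                   cell = if (is.null(gt)) NULL else gt[[i]]),
              class = "roi_traces")
  })
  names(out) <- rois
  out
}
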