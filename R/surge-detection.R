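#' Per-voxel activation threshold from the active-wake distribution
#'
#' For each in-brain voxel, the threshold is the mean plus one population
#' standard deviation (Z > 1) of its normalized CBV over all active-wake
#' frames.
#'
#' @param movie a normalized `doppler_movie`.
#' @param hyp hypnogram tibble containing AW intervals.
#' @param labels optional `region_labels`; background voxels get `NA`.
#' @param z threshold in SD units above the AW mean (default 1).
#' @return numeric matrix (rows x cols) of thresholds, % CBV.
#' @export
activation_threshold <- function(movie, hyp, labels = NULL, z = 1) {
  stopifnot(inherits(movie, "doppler_movie"))
  if (!movie$normalized) abort("movie must be normalized first")
  st <- state_at(hyp, movie$frame_times_s)
  aw <- !is.na(st) & st == "AW"
  if (!any(aw)) {
    abort("no active-wake frames: supply a threshold image explicitly")
  }
  d <- dim(movie$data)
  flat <- matrix(movie$data, d[1] * d[2], d[3])[, aw, drop = FALSE]
  mu <- rowMeans(flat)
  sdp <- sqrt(rowMeans(flat^2) - mu^2)  # population SD
  thr <- matrix(mu + z * sdp, d[1], d[2])
  if (!is.null(labels)) thr[labels$labels == 0L] <- NA_real_
  thr
}

#' Fraction of in-brain voxels above their activation threshold, per frame
#'
#' @param movie a normalized `doppler_movie`.
#' @param thr threshold matrix from [activation_threshold()]; `NA` voxels
#'   (background) are excluded from the count.
#' @return tibble (`time_s`, `active_fraction` in `[0, 1]`).
#' @export
activity_trace <- function(movie, thr) {
  stopifnot(inherits(movie, "doppler_movie"))
  d <- dim(movie$data)
  if (!all(dim(thr) == d[1:2])) abort("threshold grid does not match movie")
  flat <- matrix(movie$data, d[1] * d[2], d[3])
  tv <- as.numeric(thr)
  keep <- is.finite(tv)
  frac <- colMeans(flat[keep, , drop = FALSE] > tv[keep])
  tibble::tibble(time_s = movie$frame_times_s, active_fraction = frac)
}

#' Detect vascular surges by the population activity threshold
#'
#' A frame is surge-active when strictly more than `ratio_thr` of in-brain
#' voxels exceed their per-voxel activation threshold (strict `>` at both
#' levels). Maximal runs of active frames, restricted to the given states
#' (REM by default), are kept as surges when they last at least
#' `min_dur_s`. Each surge is annotated with the intensity and
#' activity-ratio metrics of [surge_metrics()].
#'
#' @param movie normalized, uniformly resampled `doppler_movie`.
#' @param thr threshold matrix from [activation_threshold()].
#' @param hyp hypnogram tibble.
#' @param ratio_thr active-voxel fraction threshold (default 0.5).
#' @param min_dur_s minimum surge duration, seconds (default 5).
#' @param states states to scan (default `"REM"`; use `NULL` for the whole
#'   recording).
#' @return list: `surges` tibble (`start_s`, `end_s`, `duration_s`,
#'   `mean_intensity`, `max_intensity`, `mean_activity_ratio`,
#'   `max_activity_ratio`) and `trace` from [activity_trace()].
#' @export
detect_surges <- function(movie, thr, hyp, ratio_thr = 0.5, min_dur_s = 5,
                          states = "REM") {
  if (!movie$normalized) abort("movie must be normalized first")
  trace <- activity_trace(movie, thr)
  active <- trace$active_fraction > ratio_thr
  if (!is.null(states)) {
    st <- state_at(hyp, trace$time_s)
    active <- active & !is.na(st) & st %in% states
  }
  iv <- runs_to_intervals(active, trace$time_s)
  iv <- iv[iv$end_s - iv$start_s >= min_dur_s, , drop = FALSE]
  surges <- purrr::map_dfr(seq_len(nrow(iv)), function(i) {
    surge_metrics(iv$start_s[i], iv$end_s[i], movie, trace, thr)
  })
  if (nrow(iv) == 0) {
    surges <- tibble::tibble(start_s = numeric(), end_s = numeric(),
                             duration_s = numeric(),
                             mean_intensity = numeric(),
                             max_intensity = numeric(),
                             mean_activity_ratio = numeric(),
                             max_activity_ratio = numeric())
  }
  list(surges = surges, trace = trace)
}

#' Metrics of one surge interval
#'
#' Instantaneous surge intensity is the spatial mean over all in-brain
#' voxels; the mean/max over the surge frames give the intensity metrics
#' (% CBV) and the activity trace gives the mean/max active-voxel ratios
#' (reported in %).
#'
#' @param start_s,end_s surge interval (half-open), seconds.
#' @param movie normalized `doppler_movie`.
#' @param trace tibble from [activity_trace()].
#' @param thr threshold matrix (defines the in-brain voxel set via `NA`).
#' @return one-row tibble of surge metrics.
#' @export
surge_metrics <- function(start_s, end_s, movie, trace, thr = NULL) {
  sel <- movie$frame_times_s >= start_s & movie$frame_times_s < end_s
  if (!any(sel)) abort("invalid interval: no frames inside surge")
  d <- dim(movie$data)
  flat <- matrix(movie$data, d[1] * d[2], d[3])[, sel, drop = FALSE]
  if (!is.null(thr)) flat <- flat[is.finite(as.numeric(thr)), , drop = FALSE]
  inten <- colMeans(flat)
  tsel <- trace$time_s >= start_s & trace$time_s < end_s
  ratio <- trace$active_fraction[tsel] * 100
  tibble::tibble(start_s = start_s, end_s = end_s,
                 duration_s = end_s - start_s,
                 mean_intensity = mean(inten), max_intensity = max(inten),
                 mean_activity_ratio = mean(ratio),
                 max_activity_ratio = max(ratio))
}

#' Per-recording surge summary
#'
#' Counts and mean +/- SD (population convention) of the five surge
#' metrics. Recordings with fewer than 5 surges are flagged `low_n`.
#'
#' @param surges surge tibble from [detect_surges()].
#' @param n_rem_episodes optional REM episode count to report alongside.
#' @return one-row tibble of summary statistics.
#' @export
surge_summary <- function(surges, n_rem_episodes = NA_integer_) {
  if (nrow(surges) < 1) abort("no surges to summarise")
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  tibble::tibble(
    n_surges = nrow(surges),
    n_rem_episodes = n_rem_episodes,
    low_n = nrow(surges) < 5,
    duration_mean = mean(surges$duration_s),
    duration_sd = sd_pop(surges$duration_s),
    mean_intensity_mean = mean(surges$mean_intensity),
    mean_intensity_sd = sd_pop(surges$mean_intensity),
    max_intensity_mean = mean(surges$max_intensity),
    max_intensity_sd = sd_pop(surges$max_intensity),
    mean_ratio_mean = mean(surges$mean_activity_ratio),
    mean_ratio_sd = sd_pop(surges$mean_activity_ratio),
    max_ratio_mean = mean(surges$max_activity_ratio),
    max_ratio_sd = sd_pop(surges$max_activity_ratio)
  )
}

#' Interval-level precision/recall/F1 against reference intervals
#'
#' Greedy one-to-one matching by overlap: a detected interval matches an
#' unmatched reference interval when they overlap at all.
#'
#' @param detected,reference tibbles with `start_s`, `end_s`.
#' @return tibble (`tp`, `fp`, `fn`, `precision`, `recall`, `f1`).
#' @export
interval_f1 <- function(detected, reference) {
  used <- rep(FALSE, nrow(reference))
  tp <- 0L
  for (i in seq_len(nrow(detected))) {
    ov <- which(!used &
                  detected$start_s[i] < reference$end_s &
                  detected$end_s[i] > reference$start_s)
    if (length(ov) > 0) {
      used[ov[1]] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- nrow(detected) - tp
  fn <- nrow(reference) - tp
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (isTRUE(prec + rec > 0)) 2 * prec * rec / (prec + rec) else 0
  tibble::tibble(tp = tp, fp = fp, fn = fn,
                 precision = prec, recall = rec, f1 = f1)
}
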