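#' Run the full analysis pipeline on a recording bundle
#'
#' Orchestrates the whole analysis: sleep scoring (thresholds estimated
#' from the data), CBV normalization against the quiet-wake baseline,
#' resampling to 1 Hz, regional averaging, vascular-surge detection and
#' the REM tonic/phasic split, band envelope extraction, CBV/LFP peak
#' pairing with pooled peak correlation and delay statistics, per-episode
#' cross-correlation lag estimation, state-wise connectivity matrices and
#' state summaries. Every artifact is written to `out_dir` as CSV/JSON and
#' listed, with MD5 checksums, in a machine-readable `run_manifest.json`.
#' The pipeline is deterministic: same bundle, same outputs.
#'
#' @param bundle a `recording_bundle` from [read_bundle()] or the list
#'   returned by [simulate_recording()].
#' @param out_dir output directory.
#' @param bands band names to analyse (default theta, mid-gamma,
#'   high-gamma).
#' @param cbv_anchor_window pairing window for CBV-anchored pairing,
#'   seconds.
#' @param min_episode_s minimum REM episode length for cross-correlation.
#' @return list of in-memory results (`hypnogram`, `surges`, `regional`,
#'   `pairs`, `peak_cor`, `delays`, `xcorr`, `connectivity`, `summary`,
#'   `manifest_path`), invisibly.
#' @export
run_pipeline <- function(bundle, out_dir, bands = c("theta", "mid-gamma",
                                                    "high-gamma"),
                         cbv_anchor_window = c(-4, 1), min_episode_s = 30) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  thr <- stage("scoring", estimate_thresholds(bundle$emg, bundle$acc,
                                              bundle$lfp))
  hyp <- stage("scoring", score_sleep(bundle$emg, bundle$acc, bundle$lfp,
                                      thresholds = thr))
  norm <- stage("normalize", normalize_cbv(bundle$movie, hyp))
  norm <- stage("resample", resample_movie(norm, 1))
  regional <- stage("regions", region_average(norm, bundle$labels))

  thr_img <- stage("surges", activation_threshold(norm, hyp, bundle$labels))
  det <- stage("surges", detect_surges(norm, thr_img, hyp))
  hyp_split <- stage("surges", split_rem_phasic(hyp, det$surges))

  # band envelopes at the CBV rate
  cbv_groups <- regional[regional$is_group, ]
  grid <- sort(unique(cbv_groups$time_s))
  envs <- lapply(setNames(bands, bands), function(b) {
    stage("envelopes",
          resample_signal(band_power(bundle$lfp, b), grid))
  })

  # peak pairing: group CBV anchors x band envelope candidates
  groups <- setdiff(unique(cbv_groups$region), "whole")
  cbv_peaks <- lapply(setNames(groups, groups), function(g) {
    ser <- cbv_groups[cbv_groups$region == g, c("time_s", "cbv")]
    names(ser) <- c("time_s", "value")
    detect_peaks(ser, min_prominence = 0.5, min_separation_s = 1,
                 refine = TRUE)
  })
  env_peaks <- lapply(envs, function(e) {
    detect_peaks(e, min_prominence = 0.5, min_separation_s = 0.5,
                 refine = TRUE)
  })
  pairs <- stage("coupling", purrr::map_dfr(groups, function(g) {
    purrr::map_dfr(bands, function(b) {
      pp <- pair_peaks(cbv_peaks[[g]], env_peaks[[b]], cbv_anchor_window)
      if (nrow(pp) == 0) return(NULL)
      pp$group <- g
      pp$band <- b
      as.data.frame(pp)
    })
  }))
  cooc <- stage("coupling", co_occurrence(cbv_peaks, env_peaks))
  peak_cor <- NULL
  if (nrow(pairs) >= 3) {
    best_band <- bands[length(bands)]
    sel <- pairs[pairs$band == best_band, ]
    if (nrow(sel) >= 3) peak_cor <- peak_correlation(sel)
  }
  delays <- if (nrow(pairs) >= 4) {
    delay_stats(pairs[pairs$band == bands[length(bands)], ])
  } else NULL

  rem_iv <- hyp[hyp$state == "REM", c("start_s", "end_s")]
  rem_iv <- rem_iv[rem_iv$end_s - rem_iv$start_s > min_episode_s, ]
  xcorr <- NULL
  if (nrow(rem_iv) > 0) {
    hip <- cbv_groups[cbv_groups$region == "hippocampus",
                      c("time_s", "cbv")]
    names(hip) <- c("time_s", "value")
    xcorr <- tryCatch(
      suppressWarnings(
        cross_correlation(envs[[length(envs)]], hip, rem_iv,
                          max_lag_s = min(10, min_episode_s / 3))),
      error = function(e) NULL)
  }

  conn <- list()
  for (st in c("QW", "AW", "NREM", "REM")) {
    conn[[st]] <- tryCatch(connectivity_matrix(regional, hyp, st),
                           error = function(e) NULL)
  }
  summ <- stage("summary", state_summary(regional, hyp_split))

  # artifacts
  write_hypnogram(hyp_split, p("hypnogram_scored.csv"))
  utils::write.csv(det$surges, p("surges.csv"), row.names = FALSE)
  utils::write.csv(det$trace, p("activity_trace.csv"), row.names = FALSE)
  utils::write.csv(regional, p("regional_cbv.csv"), row.names = FALSE)
  utils::write.csv(pairs, p("peak_pairs.csv"), row.names = FALSE)
  utils::write.csv(cooc, p("co_occurrence.csv"), row.names = FALSE)
  utils::write.csv(summ, p("state_summary.csv"), row.names = FALSE)
  if (!is.null(xcorr)) {
    utils::write.csv(tidy(xcorr), p("correlogram.csv"), row.names = FALSE)
  }
  for (st in names(conn)) {
    if (!is.null(conn[[st]])) {
      utils::write.csv(tidy(conn[[st]]),
                       p(sprintf("connectivity_%s.csv", st)),
                       row.names = FALSE)
    }
  }
  results_json <- list(
    thresholds = unclass(thr),
    n_surges = nrow(det$surges),
    peak_correlation = if (!is.null(peak_cor)) {
      list(r = peak_cor$r, t = peak_cor$t, p = peak_cor$p, n = peak_cor$n)
    },
    mean_peak_lag_s = if (!is.null(xcorr)) xcorr$mean_peak_lag_s,
    mean_peak_r = if (!is.null(xcorr)) xcorr$mean_peak_r
  )
  jsonlite::write_json(results_json, p("results.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  arts <- sort(list.files(out_dir, pattern = "\\.(csv|json)$"))
  arts <- setdiff(arts, "run_manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("remsurge")),
    seed = bundle$config$seed %||% NA,
    thresholds = unclass(thr),
    artifacts = lapply(setNames(arts, arts), function(f) {
      list(md5 = unname(tools::md5sum(p(f))))
    })
  )
  jsonlite::write_json(manifest, p("run_manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(hypnogram = hyp_split, thresholds = thr,
                 surges = det$surges, trace = det$trace,
                 regional = regional, pairs = tibble::as_tibble(pairs),
                 co_occurrence = cooc, peak_cor = peak_cor,
                 delays = delays, xcorr = xcorr, connectivity = conn,
                 summary = summ, manifest_path = p("run_manifest.json")))
}
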