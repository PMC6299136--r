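#' Per-epoch scoring features from EMG, accelerometer and LFP
#'
#' Chops the recording into fixed epochs and computes, per epoch: EMG RMS,
#' accelerometer RMS, mean theta/delta envelope ratio and mean ripple-band
#' envelope. These are the inputs of both threshold estimation and scoring.
#'
#' @param emg,acc,lfp signal tibbles on a common clock.
#' @param epoch_s epoch length, seconds (default 5).
#' @return tibble (`epoch`, `start_s`, `end_s`, `emg_rms`, `acc_rms`,
#'   `td_ratio`, `ripple_env`).
#' @export
sleep_features <- function(emg, acc, lfp, epoch_s = 5) {
  check_signal(emg, "emg"); check_signal(acc, "acc"); check_signal(lfp, "lfp")
  rng <- range(lfp$time_s)
  if (abs(emg$time_s[1] - lfp$time_s[1]) > 1e-6 ||
      abs(max(emg$time_s) - max(lfp$time_s)) > 1e-3 ||
      nrow(emg) != nrow(lfp) || nrow(acc) != nrow(lfp)) {
    abort("alignment error: emg/acc/lfp must share one sampling grid")
  }
  fs <- signal_rate(lfp)
  th <- band_power(lfp, "theta")$value
  de <- band_power(lfp, "delta")$value
  rp <- band_power(lfp, "ripple")$value
  n_ep <- floor((rng[2] - rng[1] + 1 / fs) / epoch_s)
  if (n_ep < 1) abort("recording shorter than one epoch")
  ep <- pmin(floor((lfp$time_s - rng[1]) / epoch_s) + 1L, n_ep)
  f <- factor(ep, levels = seq_len(n_ep))
  agg <- function(v, fun) as.numeric(tapply(v, f, fun))
  tibble::tibble(
    epoch = seq_len(n_ep),
    start_s = rng[1] + (seq_len(n_ep) - 1L) * epoch_s,
    end_s = rng[1] + seq_len(n_ep) * epoch_s,
    emg_rms = agg(emg$value, function(z) sqrt(mean(z^2))),
    acc_rms = agg(acc$value, function(z) sqrt(mean(z^2))),
    td_ratio = agg(th, mean) / pmax(agg(de, mean), 1e-300),
    ripple_env = agg(rp, mean)
  )
}

#' Estimate scoring thresholds from the data
#'
#' EMG threshold: antimode of a two-component Gaussian mixture fitted to
#' log epoch EMG RMS (wake and sleep clusters); if the mixture is not
#' clearly bimodal the median is used and flagged. Movement threshold: half
#' the 95th percentile of epoch accelerometer RMS. Ripple threshold: 75th
#' percentile of the ripple envelope over provisionally-scored sleep
#' epochs. Theta/delta ratio threshold defaults to 2.
#'
#' @inheritParams sleep_features
#' @param min_sleep_s sustained low-EMG duration required to enter sleep.
#' @return a `scoring_thresholds` list: `emg_thr`, `movement_thr`,
#'   `td_ratio_thr`, `ripple_thr`, `min_sleep_s`, `epoch_s`, `fallback`.
#' @importFrom mclust Mclust mclustBIC
#' @export
estimate_thresholds <- function(emg, acc, lfp, epoch_s = 5,
                                min_sleep_s = 20) {
  ft <- sleep_features(emg, acc, lfp, epoch_s)
  lo <- log(pmax(ft$emg_rms, 1e-12))
  fallback <- FALSE
  emg_thr <- NA_real_
  if (length(unique(round(lo, 10))) >= 3 && sd(lo) > 1e-8) {
    fit <- tryCatch(
      Mclust(lo, G = 2, modelNames = "V", verbose = FALSE),
      error = function(e) NULL)
    if (!is.null(fit)) {
      m <- fit$parameters$mean
      s <- sqrt(fit$parameters$variance$sigmasq)
      if (length(s) == 1) s <- rep(s, 2)
      sep <- abs(diff(m)) / max(mean(s), 1e-12)
      if (sep > 2 && abs(diff(m)) > 0.5) {  # relative and absolute gap
        grid <- seq(min(m), max(m), length.out = 512)
        dens <- fit$parameters$pro[1] * dnorm(grid, m[1], s[1]) +
          fit$parameters$pro[2] * dnorm(grid, m[2], s[2])
        emg_thr <- exp(grid[which.min(dens)])
      }
    }
  }
  if (!is.finite(emg_thr)) {
    warn("EMG distribution not clearly bimodal; median fallback threshold")
    emg_thr <- exp(median(lo))
    fallback <- TRUE
  }
  movement_thr <- max(0.5 * quantile(ft$acc_rms, 0.95, names = FALSE), 1e-6)
  low <- ft$emg_rms < emg_thr
  sleep_prov <- sustained_runs(low, epoch_s, min_sleep_s)
  rip_src <- if (any(sleep_prov)) ft$ripple_env[sleep_prov] else ft$ripple_env
  ripple_thr <- quantile(rip_src, 0.75, names = FALSE)
  structure(list(emg_thr = emg_thr, movement_thr = movement_thr,
                 td_ratio_thr = 2, ripple_thr = ripple_thr,
                 min_sleep_s = min_sleep_s, epoch_s = epoch_s,
                 fallback = fallback),
            class = "scoring_thresholds")
}

# TRUE where a run of TRUEs lasts strictly longer than min_s
sustained_runs <- function(flag, epoch_s, min_s) {
  r <- rle(flag)
  r$values <- r$values & (r$lengths * epoch_s > min_s)
  inverse.rle(r)
}

#' Score a recording into QW / AW / NREM / REM
#'
#' Epoch-based implementation of the classical rodent rules. Sleep onset:
#' epochs where the EMG RMS stays below `emg_thr` for more than
#' `min_sleep_s` (the sustained run is labelled sleep as a whole; shorter
#' low-EMG runs stay wake). Within sleep, REM requires a theta/delta ratio
#' at or above `td_ratio_thr` together with ripple envelope below
#' `ripple_thr`; everything else is NREM. Within wake, accelerometer RMS at
#' or above `movement_thr` marks active wake, otherwise quiet wake. Labels
#' are majority-smoothed over 3 epochs and merged into intervals.
#'
#' @inheritParams sleep_features
#' @param thresholds a `scoring_thresholds` (e.g. from
#'   [estimate_thresholds()]); `NULL` estimates them from the recording.
#' @param smooth majority-smooth over 3 epochs (default TRUE).
#' @return hypnogram tibble (`start_s`, `end_s`, `state`).
#' @export
score_sleep <- function(emg, acc, lfp, thresholds = NULL, epoch_s = 5,
                        smooth = TRUE) {
  if (is.null(thresholds)) {
    thresholds <- estimate_thresholds(emg, acc, lfp, epoch_s)
  }
  thr <- thresholds
  ft <- sleep_features(emg, acc, lfp, epoch_s = thr$epoch_s %||% epoch_s)
  lab <- score_epochs(ft, thr)
  if (smooth) lab <- majority_smooth(lab)
  merge_hypnogram(tibble::tibble(start_s = ft$start_s, end_s = ft$end_s,
                                 state = lab))
}

# rule table on a feature frame
score_epochs <- function(ft, thr) {
  low <- ft$emg_rms < thr$emg_thr
  asleep <- sustained_runs(low, ft$end_s[1] - ft$start_s[1], thr$min_sleep_s)
  lab <- ifelse(asleep,
                ifelse(ft$td_ratio >= thr$td_ratio_thr &
                         ft$ripple_env < thr$ripple_thr, "REM", "NREM"),
                ifelse(ft$acc_rms >= thr$movement_thr, "AW", "QW"))
  lab
}

majority_smooth <- function(lab) {
  n <- length(lab)
  if (n < 3) return(lab)
  out <- lab
  for (i in 2:(n - 1)) {
    if (lab[i - 1] == lab[i + 1] && lab[i] != lab[i - 1]) {
      out[i] <- lab[i - 1]
    }
  }
  out
}

#' Split REM intervals into tonic and phasic sub-states
#'
#' Within each REM interval of the hypnogram, periods covered by detected
#' vascular surges are relabelled `REM-phasic` and the remainder
#' `REM-tonic`; other states are untouched and total REM time is conserved.
#' Surge intervals extending beyond REM are clipped with a warning.
#'
#' @param hyp hypnogram tibble.
#' @param surges tibble with `start_s`, `end_s` (e.g. from
#'   [detect_surges()]).
#' @return hypnogram tibble with `REM-tonic` / `REM-phasic` labels.
#' @export
split_rem_phasic <- function(hyp, surges) {
  rem <- hyp[hyp$state == "REM", , drop = FALSE]
  rest <- hyp[hyp$state != "REM", , drop = FALSE]
  if (nrow(rem) == 0) return(hyp)
  if (nrow(surges) > 0) {
    inside <- purrr::map_lgl(seq_len(nrow(surges)), function(i) {
      any(surges$start_s[i] >= rem$start_s - 1e-9 &
            surges$end_s[i] <= rem$end_s + 1e-9)
    })
    if (!all(inside)) {
      warn("surge outside REM clipped to the containing REM interval")
    }
  }
  pieces <- purrr::map_dfr(seq_len(nrow(rem)), function(i) {
    s0 <- rem$start_s[i]; e0 <- rem$end_s[i]
    sv <- clip_intervals(surges[, c("start_s", "end_s"), drop = FALSE],
                         tibble::tibble(start_s = s0, end_s = e0))
    if (nrow(sv) == 0) {
      return(tibble::tibble(start_s = s0, end_s = e0, state = "REM-tonic"))
    }
    sv <- dplyr::arrange(sv, .data$start_s)
    cuts <- sort(unique(c(s0, sv$start_s, sv$end_s, e0)))
    mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
    st <- ifelse(purrr::map_lgl(mids, function(m) {
      any(m >= sv$start_s & m < sv$end_s)
    }), "REM-phasic", "REM-tonic")
    tibble::tibble(start_s = cuts[-length(cuts)], end_s = cuts[-1],
                   state = st)
  })
  merge_hypnogram(dplyr::arrange(dplyr::bind_rows(rest, pieces),
                                 .data$start_s))
}

#' Epoch-wise agreement between two hypnograms
#'
#' Fraction of epochs whose majority state agrees; REM sub-states count as
#' REM.
#'
#' @param a,b hypnogram tibbles over the same time range.
#' @param epoch_s comparison epoch, seconds.
#' @return agreement fraction in `[0, 1]`.
#' @export
hypnogram_agreement <- function(a, b, epoch_s = 5) {
  t_max <- min(max(a$end_s), max(b$end_s))
  mids <- seq(epoch_s / 2, t_max - epoch_s / 2 + 1e-9, by = epoch_s)
  norm <- function(x) ifelse(x %in% c("REM-tonic", "REM-phasic"), "REM", x)
  mean(norm(state_at(a, mids)) == norm(state_at(b, mids)), na.rm = TRUE)
}
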