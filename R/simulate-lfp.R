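#' Simulate state-dependent LFP, EMG and accelerometer traces
#'
#' NREM segments carry dominant delta (1-4 Hz) activity with sporadic ripple
#' (150-250 Hz) packets; active wake and REM carry a theta carrier
#' (`theta_freq`, default 8 Hz). During REM (and optionally AW), fast-gamma
#' bursts in `burst_band` are injected at `burst_rate_rem` per minute; each
#' burst's instantaneous amplitude is modulated by theta phase and is
#' maximal on the ascending phase (~135 deg from the trough). EMG is
#' high-amplitude noise during wake and low during sleep; the accelerometer
#' is nonzero only during active wake. Burst times and normalized powers are
#' returned as ground truth.
#'
#' @param hyp hypnogram tibble covering `[0, duration_s)`.
#' @param config a [sim_config()].
#' @return list with signal tibbles `lfp`, `emg`, `acc` and the `bursts`
#'   tibble of [simulate_bursts()].
#' @export
simulate_lfp <- function(hyp, config) {
  stopifnot(inherits(config, "sim_config"))
  if (max(hyp$end_s) < config$duration_s - 1e-6) {
    abort("hypnogram does not cover the requested duration")
  }
  set.seed(sim_seed(config, "lfp"))
  fs <- config$lfp_rate
  n <- round(config$duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  st <- state_at(hyp, t)
  st[is.na(st)] <- "QW"

  lfp <- rnorm(n, 0, config$noise_sd_lfp)

  # delta in NREM: two incommensurate slow sines, random phases
  nrem <- st == "NREM"
  if (any(nrem)) {
    ph <- runif(2, 0, 2 * pi)
    delta <- 1.5 * (sin(2 * pi * 1.7 * t + ph[1]) +
                      0.7 * sin(2 * pi * 3.1 * t + ph[2])) / 1.7
    lfp[nrem] <- lfp[nrem] + delta[nrem]
  }

  # theta carrier in AW and REM; trough at phase 0 deg
  theta_on <- st %in% c("AW", "REM")
  theta_phase <- 2 * pi * config$theta_freq * t
  if (any(theta_on)) {
    lfp[theta_on] <- lfp[theta_on] - cos(theta_phase[theta_on])
  }

  # gamma bursts, theta-phase modulated (max near 135 deg after trough)
  bursts <- simulate_bursts(hyp, config)
  set.seed(sim_seed(config, "lfp") + 1L)
  if (nrow(bursts) > 0) {
    mod <- 0.5 + 0.5 * cos(theta_phase - 135 * pi / 180)
    for (i in seq_len(nrow(bursts))) {
      tc <- bursts$time_s[i]
      i0 <- max(1L, floor((tc - 4 * config$burst_sigma_s) * fs) + 1L)
      i1 <- min(n, ceiling((tc + 4 * config$burst_sigma_s) * fs) + 1L)
      idx <- i0:i1
      env <- exp(-0.5 * ((t[idx] - tc) / config$burst_sigma_s)^2)
      carrier <- sin(2 * pi * bursts$freq_hz[i] * (t[idx] - tc))
      lfp[idx] <- lfp[idx] +
        sqrt(bursts$power[i]) * env * mod[idx] * carrier
    }
  }

  # ripple packets in NREM
  if (any(nrem) && config$ripple_rate_nrem > 0) {
    nrem_iv <- hyp[hyp$state == "NREM", ]
    rip_t <- draw_poisson_times(nrem_iv, config$ripple_rate_nrem / 60)
    for (tc in rip_t) {
      i0 <- max(1L, floor((tc - 0.12) * fs) + 1L)
      i1 <- min(n, ceiling((tc + 0.12) * fs) + 1L)
      idx <- i0:i1
      f <- runif(1, 160, 230)
      lfp[idx] <- lfp[idx] + 0.6 *
        exp(-0.5 * ((t[idx] - tc) / 0.03)^2) *
        sin(2 * pi * f * (t[idx] - tc))
    }
  }

  emg_sd <- ifelse(st %in% c("QW", "AW"), config$emg_wake, config$emg_sleep)
  emg <- rnorm(n, 0, 1) * emg_sd
  acc <- rnorm(n, 0, 1) * (st == "AW")

  list(lfp = tibble::tibble(time_s = t, value = lfp),
       emg = tibble::tibble(time_s = t, value = emg),
       acc = tibble::tibble(time_s = t, value = acc),
       bursts = bursts)
}

# Poisson event times within a set of intervals, given rate per second
draw_poisson_times <- function(intervals, rate_hz) {
  out <- numeric()
  for (i in seq_len(nrow(intervals))) {
    len <- intervals$end_s[i] - intervals$start_s[i]
    k <- rpois(1, rate_hz * len)
    if (k > 0) out <- c(out, sort(runif(k, intervals$start_s[i],
                                        intervals$end_s[i])))
  }
  sort(out)
}

#' Draw gamma-burst events for a hypnogram
#'
#' Burst times are Poisson within REM (and optionally AW) intervals, kept
#' away from interval edges and thinned to a 5 s minimum separation so each
#' event has a resolvable vascular response. The candidate intensity is
#' dead-time corrected, `rate / (1 - rate * 5 s)`, so the realized burst
#' count per REM minute matches `burst_rate_rem` despite the thinning.
#' Powers are log-normal (median 0.6); carrier frequencies uniform in
#' `burst_band`. Uses its own RNG sub-stream, so burst ground truth is
#' identical whether or not the LFP waveform is synthesized.
#'
#' @param hyp hypnogram tibble.
#' @param config a [sim_config()].
#' @return burst tibble (`time_s`, `power`, `freq_hz`, `state`).
#' @export
simulate_bursts <- function(hyp, config) {
  set.seed(sim_seed(config, "bursts"))
  dead <- 5
  take <- function(states, rate_per_min, margin_lo, margin_hi) {
    iv <- hyp[hyp$state %in% states, , drop = FALSE]
    if (nrow(iv) == 0 || rate_per_min <= 0) return(NULL)
    full <- sum(iv$end_s - iv$start_s)
    iv$start_s <- iv$start_s + margin_lo
    iv$end_s <- iv$end_s - margin_hi
    iv <- iv[iv$end_s > iv$start_s, , drop = FALSE]
    if (nrow(iv) == 0) return(NULL)
    trimmed <- sum(iv$end_s - iv$start_s)
    lam <- rate_per_min / 60
    lam_adj <- lam * (full / trimmed) / max(1 - lam * dead, 0.25)
    tt <- draw_poisson_times(iv, lam_adj)
    if (length(tt) == 0) return(NULL)
    tibble::tibble(time_s = tt, state = state_at(hyp, tt))
  }
  b <- dplyr::bind_rows(
    take("REM", config$burst_rate_rem, 2, 4),
    take("AW", config$burst_rate_aw, 2, 4)
  )
  if (is.null(b) || nrow(b) == 0) {
    return(tibble::tibble(time_s = numeric(), power = numeric(),
                          freq_hz = numeric(), state = character()))
  }
  b <- dplyr::arrange(b, .data$time_s)
  keep <- logical(nrow(b))
  last <- -Inf
  for (i in seq_len(nrow(b))) {
    if (b$time_s[i] - last >= dead) {
      keep[i] <- TRUE
      last <- b$time_s[i]
    }
  }
  b <- b[keep, ]
  b$power <- rlnorm(nrow(b), meanlog = log(0.6), sdlog = 0.4)
  b$freq_hz <- runif(nrow(b), config$burst_band[1], config$burst_band[2])
  dplyr::select(b, "time_s", "power", "freq_hz", "state")
}
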