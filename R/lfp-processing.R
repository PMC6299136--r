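#' Canonical hippocampal LFP frequency bands
#'
#' The standard band table used throughout: delta (1-4 Hz), theta (6-10 Hz),
#' low-gamma (20-50 Hz), mid-gamma (50-100 Hz), high-gamma (100-150 Hz) and
#' ripple (150-250 Hz).
#'
#' @return tibble with columns `band`, `f_lo`, `f_hi` (Hz).
#' @export
lfp_bands <- function() {
  tibble::tribble(
    ~band,        ~f_lo, ~f_hi,
    "delta",          1,     4,
    "theta",          6,    10,
    "low-gamma",     20,    50,
    "mid-gamma",     50,   100,
    "high-gamma",   100,   150,
    "ripple",       150,   250
  )
}

band_edges <- function(band) {
  if (is.character(band)) {
    tb <- lfp_bands()
    row <- tb[tb$band == band, ]
    if (nrow(row) == 0) abort(paste0("unknown band name: ", band))
    return(c(row$f_lo, row$f_hi))
  }
  stopifnot(is.numeric(band), length(band) == 2)
  band
}

#' Zero-phase band-pass filter a signal
#'
#' 4th-order Butterworth band-pass applied forward-backward
#' (`signal::filtfilt`), so the filter is exactly zero-phase — essential
#' here because second-scale LFP-CBV delays are the scientific readout.
#' Narrow low-frequency bands (f_hi below rate/25) are filtered on an
#' anti-aliased decimated copy and linearly interpolated back, which keeps
#' the recursion numerically stable without affecting band content.
#'
#' @param x signal tibble (`time_s`, `value`).
#' @param band band name from [lfp_bands()] or numeric `c(f_lo, f_hi)` Hz.
#' @return filtered signal tibble.
#' @export
band_filter <- function(x, band) {
  check_signal(x)
  fs <- signal_rate(x)
  edges <- band_edges(band)
  f_lo <- edges[1]; f_hi <- edges[2]
  if (!(f_lo > 0 && f_lo < f_hi)) abort("invalid band: need 0 < f_lo < f_hi")
  if (f_hi >= fs / 2) {
    abort(sprintf("invalid band: f_hi = %g Hz >= Nyquist (%g Hz)",
                  f_hi, fs / 2))
  }
  v <- x$value
  dec <- 1L
  if (f_hi < fs / 25) {
    dec <- max(1L, floor(fs / (25 * f_hi)))
    if (dec > 1L) {
      # zero-phase anti-alias + subsample (keeps the whole chain zero-phase)
      lp <- signal::butter(4, 0.8 / dec, type = "low")
      v <- signal::filtfilt(lp, v)[seq(1, length(v), by = dec)]
    }
  }
  fs_d <- fs / dec
  bf <- signal::butter(4, c(f_lo, f_hi) / (fs_d / 2), type = "pass")
  y <- signal::filtfilt(bf, v)
  if (dec > 1L) {
    t_d <- x$time_s[1] + (seq_along(y) - 1L) * dec / fs
    y <- approx(t_d, y, xout = x$time_s, rule = 2)$y
  }
  tibble::tibble(time_s = x$time_s, value = y)
}

#' Power envelope of a band-filtered signal
#'
#' The instantaneous band power: the squared signal convolved with a
#' unit-area Gaussian kernel of characteristic width `width_s`
#' (interpreted as the Gaussian sigma). The envelope keeps the input
#' sampling rate; downsampling for coupling analyses is an explicit,
#' separate step ([resample_signal()]).
#'
#' @param x band-filtered signal tibble.
#' @param width_s Gaussian sigma in seconds (default 0.5).
#' @return signal tibble of nonnegative power values.
#' @export
band_envelope <- function(x, width_s = 0.5) {
  check_signal(x)
  if (width_s <= 0) abort("invalid parameter: width_s must be > 0")
  fs <- signal_rate(x)
  p <- gauss_smooth(x$value^2, width_s * fs)
  tibble::tibble(time_s = x$time_s, value = pmax(p, 0))
}

#' Band power envelope in one call
#'
#' [band_filter()] then [band_envelope()].
#'
#' @inheritParams band_filter
#' @inheritParams band_envelope
#' @return signal tibble of band power.
#' @export
band_power <- function(x, band, width_s = 0.5) {
  band_envelope(band_filter(x, band), width_s)
}

#' Frequency-compensated Morlet wavelet spectrogram
#'
#' Continuous wavelet transform with an analytic Morlet wavelet; each
#' frequency row is the squared magnitude of the wavelet coefficient, and
#' with `f_compensate = TRUE` row `f` is multiplied by `f` to offset the
#' 1/f attenuation of high frequencies.
#'
#' @param x signal tibble.
#' @param freqs frequency grid, Hz (all below Nyquist).
#' @param n_cycles Morlet width in cycles (time-frequency trade-off).
#' @param f_compensate multiply row `f` by `f`.
#' @param t_decimate keep every `t_decimate`-th time column.
#' @return a `spectrogram` object: list with `freqs`, `times`, `power`
#'   (freq x time), `f_compensated`.
#' @export
lfp_spectrogram <- function(x, freqs = seq(1, 150, by = 1), n_cycles = 6,
                            f_compensate = TRUE, t_decimate = 1L) {
  check_signal(x)
  if (length(freqs) == 0) abort("invalid parameter: empty frequency grid")
  fs <- signal_rate(x)
  if (max(freqs) >= fs / 2) abort("invalid parameter: freqs reach Nyquist")
  n <- nrow(x)
  nf <- stats::nextn(2L * n, 2)
  X <- fft(c(x$value, numeric(nf - n)))
  fftfreq <- c(seq(0, nf / 2), seq(-nf / 2 + 1, -1)) * fs / nf
  cols <- seq(1L, n, by = t_decimate)
  pow <- matrix(0, length(freqs), length(cols))
  for (i in seq_along(freqs)) {
    f0 <- freqs[i]
    sigma_f <- f0 / n_cycles
    # analytic Morlet in the frequency domain (Gaussian at +f0)
    H <- exp(-0.5 * ((fftfreq - f0) / sigma_f)^2)
    w <- fft(X * H, inverse = TRUE)[seq_len(n)] / nf
    pow[i, ] <- Mod(w[cols])^2
    if (f_compensate) pow[i, ] <- pow[i, ] * f0
  }
  structure(list(freqs = freqs, times = x$time_s[cols], power = pow,
                 f_compensated = f_compensate),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d freqs (%g-%g Hz) x %d times%s\n",
              length(x$freqs), min(x$freqs), max(x$freqs), length(x$times),
              if (x$f_compensated) ", f-compensated" else ""))
  invisible(x)
}

#' @export
tidy.spectrogram <- function(x, ...) {
  tibble::tibble(
    time_s = rep(x$times, each = length(x$freqs)),
    freq_hz = rep(x$freqs, times = length(x$times)),
    power = as.numeric(x$power)
  )
}

#' Instantaneous theta phase (0 deg at the trough)
#'
#' Theta-filters the signal, takes the analytic-signal (Hilbert) phase and
#' shifts it so that theta troughs map to 0 deg and peaks to 180 deg.
#'
#' @param x raw LFP signal tibble.
#' @param band theta band (default 6-10 Hz).
#' @return tibble (`time_s`, `phase_deg` in `[0, 360)`).
#' @export
theta_phase <- function(x, band = c(6, 10)) {
  filt <- band_filter(x, band)
  ph <- Arg(analytic_signal(filt$value)) * 180 / pi  # 0 deg at peak (cos)
  tibble::tibble(time_s = x$time_s,
                 phase_deg = (ph + 180) %% 360)
}

#' Theta-phase / band-amplitude coupling profile
#'
#' Bins the envelope power by simultaneous theta phase and reports the mean
#' power per bin plus the power-weighted circular mean (preferred phase).
#' With a flat profile, the preferred phase is undefined and flagged.
#'
#' @param phase tibble from [theta_phase()].
#' @param env envelope signal tibble at the same sampling rate.
#' @param n_bins number of phase bins covering `[0, 360)` (default 18).
#' @return a `pac_profile`: list with `profile` (tibble `phase_deg`,
#'   `mean_power`), `preferred_phase_deg`, `modulation_depth`, `defined`.
#' @export
phase_amplitude_coupling <- function(phase, env, n_bins = 18) {
  if (n_bins < 2) abort("invalid parameter: n_bins must be >= 2")
  if (nrow(phase) != nrow(env)) {
    abort("phase and envelope must share a common sampling grid")
  }
  edges <- seq(0, 360, length.out = n_bins + 1)
  bin <- findInterval(phase$phase_deg, edges, rightmost.closed = FALSE)
  bin[bin > n_bins] <- n_bins
  mp <- tapply(env$value, factor(bin, levels = seq_len(n_bins)), mean)
  mp[is.na(mp)] <- 0
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  w <- as.numeric(mp)
  tot <- sum(w)
  defined <- tot > 0 && (max(w) - min(w)) / max(mean(w), 1e-300) > 1e-6
  pref <- NA_real_
  depth <- NA_real_
  if (defined) {
    cx <- sum(w * cos(centers * pi / 180)) / tot
    sx <- sum(w * sin(centers * pi / 180)) / tot
    r <- sqrt(cx^2 + sx^2)
    defined <- r > 1e-8
    if (defined) {
      pref <- (atan2(sx, cx) * 180 / pi) %% 360
      depth <- r
    }
  }
  structure(list(
    profile = tibble::tibble(phase_deg = centers, mean_power = w),
    preferred_phase_deg = pref, modulation_depth = depth,
    defined = defined, n_bins = n_bins
  ), class = "pac_profile")
}

#' @export
print.pac_profile <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("<pac_profile> %d bins, preferred phase %.1f deg (depth %.3f)\n",
                x$n_bins, x$preferred_phase_deg, x$modulation_depth))
  } else {
    cat(sprintf("<pac_profile> %d bins, flat profile (preferred phase undefined)\n",
                x$n_bins))
  }
  invisible(x)
}

#' @export
tidy.pac_profile <- function(x, ...) x$profile

#' Sliding theta/delta power ratio
#'
#' Ratio of the theta-band to delta-band envelope, each averaged over a
#' sliding boxcar window. Frames with zero delta power are reported as
#' `Inf` and flagged via the `flagged` attribute.
#'
#' @param x raw LFP signal tibble.
#' @param window_s sliding window length, seconds (>= 1).
#' @return signal tibble of the ratio (attribute `flagged` marks +Inf).
#' @export
theta_delta_ratio <- function(x, window_s = 5) {
  if (window_s < 1) abort("invalid parameter: window_s must be >= 1 s")
  fs <- signal_rate(x)
  th <- band_power(x, "theta")
  de <- band_power(x, "delta")
  k <- max(1L, round(window_s * fs))
  box <- function(v) as.numeric(stats::filter(v, rep(1 / k, k), sides = 2))
  th_m <- box(th$value)
  de_m <- box(de$value)
  ratio <- ifelse(de_m > 0, th_m / de_m, Inf)
  out <- tibble::tibble(time_s = x$time_s, value = ratio)
  attr(out, "flagged") <- any(is.infinite(ratio), na.rm = TRUE)
  out
}
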