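# Shared internal helpers: sampled-signal tibbles, interval algebra, smoothing.

#' Build a sampled-signal tibble
#'
#' Signals are plain tibbles with a `time_s` column (seconds, uniform
#' sampling) and a `value` column, so they pipe through dplyr like any other
#' data frame.
#'
#' @param value numeric vector of samples.
#' @param rate sampling rate in Hz.
#' @param t0 time of the first sample, seconds.
#' @return tibble with columns `time_s`, `value`.
#' @export
signal_tbl <- function(value, rate, t0 = 0) {
  stopifnot(is.numeric(value), rate > 0)
  tibble::tibble(time_s = t0 + (seq_along(value) - 1L) / rate,
                 value = as.numeric(value))
}

# infer sampling rate from a signal tibble; errors on wildly non-uniform grids
signal_rate <- function(x) {
  dt <- diff(x$time_s)
  if (length(dt) < 1L) abort("signal needs at least 2 samples")
  m <- median(dt)
  if (any(abs(dt - m) > 0.01 * m + 1e-9)) {
    abort("signal is not uniformly sampled; resample first")
  }
  1 / m
}

check_signal <- function(x, arg = "signal") {
  if (!is.data.frame(x) || !all(c("time_s", "value") %in% names(x))) {
    abort(paste0("`", arg, "` must be a data frame with columns time_s, value"))
  }
  invisible(x)
}

# unit-area Gaussian smoothing by FFT convolution with reflect padding
gauss_smooth <- function(x, sigma_samp) {
  n <- length(x)
  if (sigma_samp <= 0) abort("smoothing width must be positive")
  half <- min(n, ceiling(4 * sigma_samp))
  k <- exp(-0.5 * ((-half:half) / sigma_samp)^2)
  k <- k / sum(k)
  xp <- c(rev(x[seq_len(half)]), x, rev(x[n - seq_len(half) + 1L]))
  m <- length(xp) + length(k) - 1L
  nf <- stats::nextn(m, 2)
  X <- fft(c(xp, numeric(nf - length(xp))))
  K <- fft(c(k, numeric(nf - length(k))))
  y <- Re(fft(X * K, inverse = TRUE)) / nf
  y[(2L * half + 1L):(2L * half + n)]
}

# analytic signal via FFT (Hilbert transform)
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# logical run-length encoding into half-open intervals on a uniform grid
runs_to_intervals <- function(active, times) {
  stopifnot(length(active) == length(times))
  if (!any(active)) {
    return(tibble::tibble(start_s = numeric(), end_s = numeric()))
  }
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  dt <- if (length(times) > 1) median(diff(times)) else 1
  tibble::tibble(start_s = times[starts[keep]],
                 end_s = times[ends[keep]] + dt)
}

# intersect a set of intervals with a second set; returns clipped pieces
clip_intervals <- function(x, bounds) {
  if (nrow(x) == 0L || nrow(bounds) == 0L) return(x[0, , drop = FALSE])
  out <- purrr::map_dfr(seq_len(nrow(x)), function(i) {
    s <- pmax(x$start_s[i], bounds$start_s)
    e <- pmin(x$end_s[i], bounds$end_s)
    ok <- s < e
    if (!any(ok)) return(NULL)
    d <- x[rep(i, sum(ok)), , drop = FALSE]
    d$start_s <- s[ok]
    d$end_s <- e[ok]
    d
  })
  out
}

#' State label at arbitrary times from a hypnogram
#'
#' @param hyp hypnogram tibble (`start_s`, `end_s`, `state`), half-open
#'   intervals.
#' @param times numeric vector of times, seconds.
#' @return character vector of state labels (`NA` outside all intervals).
#' @export
state_at <- function(hyp, times) {
  out <- rep(NA_character_, length(times))
  for (i in seq_len(nrow(hyp))) {
    sel <- times >= hyp$start_s[i] & times < hyp$end_s[i]
    out[sel] <- hyp$state[i]
  }
  out
}

# parabolic vertex refinement around discrete argmax (returns offset, value)
parabolic_refine <- function(ym1, y0, yp1) {
  denom <- ym1 - 2 * y0 + yp1
  if (!is.finite(denom) || abs(denom) < 1e-12) return(c(0, y0))
  d <- 0.5 * (ym1 - yp1) / denom
  d <- max(min(d, 0.5), -0.5)
  v <- y0 - 0.25 * (ym1 - yp1) * d
  c(d, v)
}

# linear resampling of a signal tibble onto arbitrary times
#' Resample a signal onto new time points by linear interpolation
#'
#' @param x signal tibble (`time_s`, `value`).
#' @param times numeric vector of target times, seconds. Times outside the
#'   original range take the nearest endpoint value.
#' @return signal tibble on `times`.
#' @export
resample_signal <- function(x, times) {
  check_signal(x)
  tibble::tibble(time_s = times,
                 value = approx(x$time_s, x$value, xout = times,
                                rule = 2)$y)
}
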