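#' Detect local maxima of a uniformly sampled series
#'
#' Zero-derivative peak detection (discrete sign change of the first
#' difference), optionally filtered by prominence (in units of the series
#' SD) and by a minimum separation, keeping the higher peak on conflict.
#' Setting both filters to 0 reproduces the bare maxima rule. With
#' `refine = TRUE`, peak time and value are refined by fitting a parabola
#' through the three samples around each maximum — useful when the
#' sampling period (e.g. 1 s Doppler frames) would otherwise quantize peak
#' timings.
#'
#' @param x signal tibble (`time_s`, `value`), uniform sampling.
#' @param min_prominence minimum prominence as a fraction of the series SD
#'   (default 0.5; 0 disables).
#' @param min_separation_s minimum peak separation, seconds (0 disables).
#' @param refine parabolic sub-sample refinement of peak time/value.
#' @return peak tibble (`time_s`, `value`, `prominence`), times strictly
#'   increasing. Constant series yield an empty tibble.
#' @export
detect_peaks <- function(x, min_prominence = 0.5, min_separation_s = 0,
                         refine = FALSE) {
  check_signal(x)
  v <- x$value
  n <- length(v)
  empty <- tibble::tibble(time_s = numeric(), value = numeric(),
                          prominence = numeric())
  if (n < 3 || max(v) == min(v)) return(empty)
  d <- diff(v)
  cand <- which(d[-length(d)] > 0 & d[-1] < 0) + 1L
  # plateau peaks: rising edge followed by flat then falling
  flat <- which(d == 0)
  if (length(flat) > 0) {
    for (i in flat) {
      if (i > 1 && d[i - 1] > 0) {
        j <- i + 1L
        while (j <= length(d) && d[j] == 0) j <- j + 1L
        if (j <= length(d) && d[j] < 0) cand <- c(cand, i)
      }
    }
    cand <- sort(unique(cand))
  }
  if (length(cand) == 0) return(empty)
  prom <- vapply(cand, function(i) peak_prominence(v, i), numeric(1))
  keep <- prom >= min_prominence * sd(v)
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand) == 0) return(empty)
  tt <- x$time_s[cand]
  vv <- v[cand]
  if (min_separation_s > 0 && length(cand) > 1) {
    ord <- order(vv, decreasing = TRUE)
    sel <- logical(length(cand))
    for (k in ord) {
      if (!any(sel & abs(tt - tt[k]) < min_separation_s)) sel[k] <- TRUE
    }
    cand <- cand[sel]; prom <- prom[sel]
    tt <- tt[sel]; vv <- vv[sel]
  }
  if (refine) {
    dt <- 1 / signal_rate(x)
    for (k in seq_along(cand)) {
      i <- cand[k]
      if (i > 1 && i < n) {
        rf <- parabolic_refine(v[i - 1], v[i], v[i + 1])
        tt[k] <- tt[k] + rf[1] * dt
        vv[k] <- rf[2]
      }
    }
  }
  ord <- order(tt)
  tibble::tibble(time_s = tt[ord], value = vv[ord],
                 prominence = prom[ord])
}

# topographic prominence: drop to the higher of the two key saddles
peak_prominence <- function(v, i) {
  n <- length(v)
  lo_l <- v[i]
  j <- i - 1L
  while (j >= 1 && v[j] <= v[i]) {
    lo_l <- min(lo_l, v[j]); j <- j - 1L
  }
  if (j < 1) lo_l <- min(v[seq_len(i)])
  lo_r <- v[i]
  j <- i + 1L
  while (j <= n && v[j] <= v[i]) {
    lo_r <- min(lo_r, v[j]); j <- j + 1L
  }
  if (j > n) lo_r <- min(v[i:n])
  v[i] - max(lo_l, lo_r)
}

#' Pair anchor peaks with the closest candidate peak in a timing window
#'
#' For each anchor peak at time `t`, candidate peaks with times inside
#' `[t + window[1], t + window[2]]` are considered and the nearest in time
#' is selected (ties: the earlier candidate). Anchors with no candidate are
#' left unpaired but counted in the pairing ratio. With CBV peaks as
#' anchors and LFP peaks as candidates and the canonical window
#' `c(-4, 1)`, `delta_t = t_anchor - t_candidate` is the LFP-to-CBV delay.
#'
#' @param anchors,candidates peak tibbles (`time_s`, `value`).
#' @param window numeric `c(lo, hi)` seconds relative to the anchor.
#' @return a `paired_peaks` tibble (`t_anchor`, `v_anchor`, `t_candidate`,
#'   `v_candidate`, `delta_t`) with attributes `n_anchors` and
#'   `pairing_ratio`.
#' @export
pair_peaks <- function(anchors, candidates, window = c(-4, 1)) {
  if (length(window) != 2 || window[1] >= window[2]) {
    abort("invalid parameter: window must satisfy lo < hi")
  }
  n_anchor <- nrow(anchors)
  rows <- purrr::map_dfr(seq_len(n_anchor), function(i) {
    t0 <- anchors$time_s[i]
    sel <- which(candidates$time_s >= t0 + window[1] &
                   candidates$time_s <= t0 + window[2])
    if (length(sel) == 0) return(NULL)
    dist <- abs(candidates$time_s[sel] - t0)
    best <- sel[order(dist, candidates$time_s[sel])[1]]
    tibble::tibble(t_anchor = t0, v_anchor = anchors$value[i],
                   t_candidate = candidates$time_s[best],
                   v_candidate = candidates$value[best],
                   delta_t = t0 - candidates$time_s[best])
  })
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(t_anchor = numeric(), v_anchor = numeric(),
                           t_candidate = numeric(), v_candidate = numeric(),
                           delta_t = numeric())
  }
  attr(rows, "n_anchors") <- n_anchor
  attr(rows, "pairing_ratio") <- if (n_anchor > 0) nrow(rows) / n_anchor else
    NA_real_
  class(rows) <- c("paired_peaks", class(rows))
  rows
}

#' Pairing ratio of a paired-peak set
#' @param pairs a `paired_peaks` tibble.
#' @return fraction of anchors that found a partner.
#' @export
pairing_ratio <- function(pairs) attr(pairs, "pairing_ratio")

#' Co-occurrence counts and ratios for region x band peak trains
#'
#' Computes both pairing directions for every (region, band) combination:
#' CBV-anchored (window `cbv_window`, default `[-4, +1]` s) and
#' LFP-anchored (window `lfp_window`, default `[-1, +4]` s).
#'
#' @param cbv_peaks named list of peak tibbles, one per region.
#' @param env_peaks named list of peak tibbles, one per LFP band.
#' @param cbv_window,lfp_window pairing windows, seconds.
#' @return tibble (`region`, `band`, `direction`, `n_anchors`, `n_paired`,
#'   `ratio`).
#' @export
co_occurrence <- function(cbv_peaks, env_peaks, cbv_window = c(-4, 1),
                          lfp_window = c(-1, 4)) {
  purrr::map_dfr(names(cbv_peaks), function(rg) {
    purrr::map_dfr(names(env_peaks), function(bd) {
      a <- pair_peaks(cbv_peaks[[rg]], env_peaks[[bd]], cbv_window)
      b <- pair_peaks(env_peaks[[bd]], cbv_peaks[[rg]], lfp_window)
      tibble::tibble(
        region = rg, band = bd,
        direction = c("cbv-anchored", "lfp-anchored"),
        n_anchors = c(attr(a, "n_anchors"), attr(b, "n_anchors")),
        n_paired = c(nrow(a), nrow(b)),
        ratio = c(attr(a, "pairing_ratio"), attr(b, "pairing_ratio"))
      )
    })
  })
}

#' Pooled correlation between paired peak values
#'
#' Within each recording, anchor and candidate peak values are min-max
#' normalized to `[0, 1]` before pooling (guarding against between-recording
#' Simpson effects), then the Pearson correlation is computed over all
#' pooled pairs with the standard significance test:
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#'
#' @param pairs paired-peak tibble with `v_anchor`, `v_candidate` and
#'   (optionally) a `recording` column; absent, all pairs form one
#'   recording.
#' @return a `peak_correlation` object (list: `r`, `t`, `p`, `n`,
#'   `pairs`).
#' @export
peak_correlation <- function(pairs) {
  if (!all(c("v_anchor", "v_candidate") %in% names(pairs))) {
    abort("pairs must have v_anchor and v_candidate columns")
  }
  if (nrow(pairs) < 3) abort("need at least 3 pairs")
  rec <- pairs[["recording"]] %||% rep(1L, nrow(pairs))
  mm <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) return(rep(NA_real_, length(v)))
    (v - rng[1]) / diff(rng)
  }
  df <- tibble::tibble(recording = rec,
                       va = pairs$v_anchor, vc = pairs$v_candidate) |>
    dplyr::group_by(.data$recording) |>
    dplyr::mutate(va = mm(.data$va), vc = mm(.data$vc)) |>
    dplyr::ungroup() |>
    dplyr::filter(is.finite(.data$va), is.finite(.data$vc))
  if (nrow(df) < 3 || sd(df$va) == 0 || sd(df$vc) == 0) {
    warn("degenerate peak values: correlation undefined")
    out <- list(r = NA_real_, t = NA_real_, p = NA_real_, n = nrow(df),
                pairs = df)
    class(out) <- "peak_correlation"
    return(out)
  }
  r <- cor(df$va, df$vc)
  n <- nrow(df)
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * pt(-abs(tval), df = n - 2)
  structure(list(r = r, t = tval, p = p, n = n, pairs = df),
            class = "peak_correlation")
}

#' @export
print.peak_correlation <- function(x, ...) {
  cat(sprintf("<peak_correlation> r = %.3f, t = %.2f, p = %.3g, n = %d\n",
              x$r, x$t, x$p, x$n))
  invisible(x)
}

#' @export
glance.peak_correlation <- function(x, ...) {
  tibble::tibble(r = x$r, statistic = x$t, p.value = x$p, n = x$n)
}

#' Delay statistics per group of paired peaks
#'
#' Per group (band or region): mean and SEM of the delays, plus a
#' one-sample location test against zero reported as the normal (Z)
#' approximation of the Wilcoxon signed-rank statistic. Where two groups
#' share anchor peaks (same anchor times), their delays are compared by a
#' paired Student t-test.
#'
#' @param pairs tibble with `delta_t`, a `group` column, and `t_anchor`
#'   (used to match shared anchors across groups).
#' @return a `delay_stats` object: list with `groups` (per-group tibble)
#'   and `pairwise` (paired-comparison tibble).
#' @export
delay_stats <- function(pairs) {
  if (!all(c("delta_t", "group") %in% names(pairs))) {
    abort("pairs must have delta_t and group columns")
  }
  gs <- split(pairs, pairs$group)
  groups <- purrr::map_dfr(names(gs), function(g) {
    d <- gs[[g]]$delta_t
    if (length(d) < 2) {
      warn(paste0("group skipped (n < 2): ", g))
      return(NULL)
    }
    z <- signed_rank_z(d)
    tibble::tibble(group = g, n = length(d), mean_delay_s = mean(d),
                   sem_s = sd(d) / sqrt(length(d)), z = z,
                   p = 2 * pnorm(-abs(z)))
  })
  combos <- if (length(gs) >= 2) utils::combn(names(gs), 2) else
    matrix(character(), 2, 0)
  # groups share events through the candidate peak when present (e.g. one
  # LFP burst paired with several regional CBV peaks), else the anchor
  key <- if ("t_candidate" %in% names(pairs)) "t_candidate" else "t_anchor"
  pairwise <- purrr::map_dfr(seq_len(ncol(combos)), function(k) {
    a <- gs[[combos[1, k]]]; b <- gs[[combos[2, k]]]
    m <- dplyr::inner_join(
      a[, c(key, "delta_t")], b[, c(key, "delta_t")],
      by = key, suffix = c("_a", "_b"))
    if (nrow(m) < 2) return(NULL)
    tt <- t.test(m$delta_t_a, m$delta_t_b, paired = TRUE)
    tibble::tibble(group_a = combos[1, k], group_b = combos[2, k],
                   n_shared = nrow(m),
                   mean_diff_s = mean(m$delta_t_a - m$delta_t_b),
                   t = unname(tt$statistic), p = tt$p.value)
  })
  structure(list(groups = groups, pairwise = pairwise),
            class = "delay_stats")
}

# normal approximation of the Wilcoxon signed-rank statistic (ties: midranks)
signed_rank_z <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n < 2) return(NA_real_)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
  (w - mu) / sigma
}

#' @export
print.delay_stats <- function(x, ...) {
  cat("<delay_stats>\n")
  print(x$groups)
  invisible(x)
}

#' @export
tidy.delay_stats <- function(x, ...) x$groups

#' Per-episode LFP-CBV cross-correlation and lag estimation
#'
#' For each episode, computes the Pearson correlation between the LFP band
#' envelope and the regional CBV series at every lag on the sampling grid
#' within `[-max_lag_s, +max_lag_s]` (positive lag: LFP leads CBV), takes
#' the per-episode peak lag (parabolic sub-sample refinement around the
#' argmax), and forms the mean correlogram (pointwise mean of per-episode
#' r) with its own peak. Episodes shorter than `2 * max_lag_s` are skipped
#' with a warning. Both inputs must share one uniform sampling grid
#' (resample the envelope with [resample_signal()] first).
#'
#' @param env envelope signal tibble at the CBV rate.
#' @param cbv regional CBV signal tibble on the same grid.
#' @param episodes tibble (`start_s`, `end_s`), e.g. REM intervals.
#' @param max_lag_s maximum lag, seconds (default 10).
#' @return a `crosscorrelogram` object: list with `by_episode` (long
#'   tibble `episode`, `lag_s`, `r`), `peaks` (per-episode `peak_lag_s`,
#'   `peak_r`), `mean_correlogram` (tibble `lag_s`, `r`),
#'   `mean_peak_lag_s`, `mean_peak_r`.
#' @export
cross_correlation <- function(env, cbv, episodes, max_lag_s = 10) {
  check_signal(env, "env"); check_signal(cbv, "cbv")
  if (nrow(env) != nrow(cbv) ||
      max(abs(env$time_s - cbv$time_s)) > 1e-6) {
    abort("env and cbv must share one sampling grid")
  }
  dt <- 1 / signal_rate(cbv)
  K <- floor(max_lag_s / dt)
  lags <- (-K:K) * dt
  out <- list(); pk <- list()
  for (i in seq_len(nrow(episodes))) {
    sel <- env$time_s >= episodes$start_s[i] &
      env$time_s < episodes$end_s[i]
    n <- sum(sel)
    if ((episodes$end_s[i] - episodes$start_s[i]) <= 2 * max_lag_s ||
        n <= 2 * K + 2) {
      warn(sprintf("episode %d too short for max_lag %g s; skipped",
                   i, max_lag_s))
      next
    }
    e <- env$value[sel]; c_ <- cbv$value[sel]
    r <- vapply(-K:K, function(k) {
      if (k >= 0) {
        a <- e[seq_len(n - k)]; b <- c_[(1 + k):n]
      } else {
        a <- e[(1 - k):n]; b <- c_[seq_len(n + k)]
      }
      if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
      cor(a, b)
    }, numeric(1))
    j <- which.max(r)
    lag_hat <- lags[j]; r_hat <- r[j]
    if (j > 1 && j < length(r) && all(is.finite(r[(j - 1):(j + 1)]))) {
      rf <- parabolic_refine(r[j - 1], r[j], r[j + 1])
      lag_hat <- lags[j] + rf[1] * dt
      r_hat <- rf[2]
    }
    out[[length(out) + 1]] <- tibble::tibble(episode = i, lag_s = lags,
                                             r = r)
    pk[[length(pk) + 1]] <- tibble::tibble(episode = i,
                                           peak_lag_s = lag_hat,
                                           peak_r = r_hat)
  }
  by_ep <- dplyr::bind_rows(out)
  peaks <- dplyr::bind_rows(pk)
  if (nrow(by_ep) == 0) abort("no usable episodes")
  mc <- by_ep |>
    dplyr::group_by(.data$lag_s) |>
    dplyr::summarise(r = mean(.data$r, na.rm = TRUE), .groups = "drop")
  j <- which.max(mc$r)
  mlag <- mc$lag_s[j]; mr <- mc$r[j]
  if (j > 1 && j < nrow(mc)) {
    rf <- parabolic_refine(mc$r[j - 1], mc$r[j], mc$r[j + 1])
    mlag <- mc$lag_s[j] + rf[1] * dt
    mr <- rf[2]
  }
  structure(list(by_episode = by_ep, peaks = peaks, mean_correlogram = mc,
                 mean_peak_lag_s = mlag, mean_peak_r = mr),
            class = "crosscorrelogram")
}

#' @export
print.crosscorrelogram <- function(x, ...) {
  cat(sprintf(
    "<crosscorrelogram> %d episodes; mean peak r = %.3f at lag %.2f s\n",
    nrow(x$peaks), x$mean_peak_r, x$mean_peak_lag_s))
  invisible(x)
}

#' @export
tidy.crosscorrelogram <- function(x, ...) x$by_episode

#' @export
glance.crosscorrelogram <- function(x, ...) {
  tibble::tibble(n_episodes = nrow(x$peaks),
                 mean_peak_lag_s = x$mean_peak_lag_s,
                 mean_peak_r = x$mean_peak_r)
}
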