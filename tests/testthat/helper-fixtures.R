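# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a REM-rich recording with full ground truth (coupling / surge fixtures)
fixture_rem_recording <- function(seed = 7, n_episodes = 6, rem_s = 90) {
  cached(sprintf("rem_%d_%d_%d", seed, n_episodes, rem_s), function() {
    hyp <- rem_cycle_hypnogram(n_episodes = n_episodes, rem_s = rem_s)
    cfg <- sim_config(duration_s = max(hyp$end_s), seed = seed)
    sig <- simulate_lfp(hyp, cfg)
    labels <- simulate_region_labels(cfg)
    cb <- simulate_cbv_movie(hyp, sig$bursts, labels, cfg)
    norm <- resample_movie(normalize_cbv(cb$movie, hyp), 1)
    list(hyp = hyp, cfg = cfg, sig = sig, labels = labels,
         movie = cb$movie, truth = cb$truth, norm = norm)
  })
}

# uniform signal tibble shorthand
sig_tbl <- function(value, rate = 1000, t0 = 0) signal_tbl(value, rate, t0)

# brute-force peak pairing oracle: O(n * m) scan, nearest in window,
# earlier candidate on distance ties
pair_peaks_oracle <- function(anchors, candidates, window) {
  out <- NULL
  for (i in seq_len(nrow(anchors))) {
    t0 <- anchors$time_s[i]
    best <- NA_integer_
    bd <- Inf
    for (j in seq_len(nrow(candidates))) {
      tc <- candidates$time_s[j]
      if (tc < t0 + window[1] || tc > t0 + window[2]) next
      d <- abs(tc - t0)
      if (d < bd - 1e-12 ||
          (abs(d - bd) <= 1e-12 && tc < candidates$time_s[best])) {
        bd <- d
        best <- j
      }
    }
    if (!is.na(best)) {
      out <- rbind(out, data.frame(t_anchor = t0,
                                   t_candidate = candidates$time_s[best]))
    }
  }
  out
}

# frame-by-frame surge scan oracle (no run-length encoding)
surge_scan_oracle <- function(active, times, min_dur_s) {
  dt <- if (length(times) > 1) stats::median(diff(times)) else 1
  out <- NULL
  i <- 1L
  n <- length(active)
  while (i <= n) {
    if (active[i]) {
      j <- i
      while (j < n && active[j + 1L]) j <- j + 1L
      dur <- times[j] + dt - times[i]
      if (dur >= min_dur_s) {
        out <- rbind(out, data.frame(start_s = times[i],
                                     end_s = times[j] + dt))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# exact Mann-Whitney two-sided p by full enumeration of group assignments
mann_whitney_exact_oracle <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(length(pooled), nx)
  us <- apply(combos, 2, function(idx) {
    sum(r[idx]) - nx * (nx + 1) / 2
  })
  mu <- nx * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
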