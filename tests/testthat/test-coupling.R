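# Peak detection, pairing, co-occurrence, peak correlation, delay
# statistics, cross-correlation.

test_that("peak detection finds apexes, crests, and nothing in constants", {
  tri <- sig_tbl(c(seq(0, 1, length.out = 11),
                   seq(0.9, 0, length.out = 10)), rate = 1)
  pk <- detect_peaks(tri, min_prominence = 0)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$time_s, 10)
  tt <- seq(0, 99.9, by = 0.1)
  sine <- tibble::tibble(time_s = tt, value = sin(2 * pi * 0.1 * tt))
  pk10 <- detect_peaks(sine, min_prominence = 0)
  expect_equal(nrow(pk10), 10L)
  expect_equal(nrow(detect_peaks(sig_tbl(rep(3, 50), 1))), 0L)
})

test_that("peak detection matches a brute-force local-maximum scan", {
  set.seed(10)
  for (i in 1:200) {
    n <- sample(10:60, 1)
    v <- rnorm(n)
    x <- sig_tbl(v, rate = 1)
    got <- detect_peaks(x, min_prominence = 0, min_separation_s = 0)
    want <- which(v[-c(1, 2)] < v[-c(1, n)] & v[-c(n - 1, n)] < v[-c(1, n)])
    want <- want + 1L  # strict local maxima, interior only
    expect_equal(got$time_s, as.numeric(want - 1L))
  }
})

test_that("separation filtering keeps the higher of conflicting peaks", {
  v <- c(0, 5, 0, 8, 0, 1, 0)
  x <- sig_tbl(v, rate = 1)
  pk <- detect_peaks(x, min_prominence = 0, min_separation_s = 3)
  expect_equal(pk$time_s, 3)  # 8 at t=3 wins; neighbours within 3 s dropped
  expect_equal(pk$value, 8)
})

test_that("pairing selects the closest candidate inside the window", {
  anchors <- tibble::tibble(time_s = 10, value = 1)
  cands <- tibble::tibble(time_s = c(7, 9), value = c(0.5, 0.8))
  pp <- pair_peaks(anchors, cands, c(-4, 1))
  expect_equal(pp$t_candidate, 9)
  expect_equal(pp$delta_t, 1)
  # sole candidate outside the window stays unpaired
  pp2 <- pair_peaks(anchors, tibble::tibble(time_s = 11.5, value = 1),
                    c(-4, 1))
  expect_equal(nrow(pp2), 0L)
  expect_equal(pairing_ratio(pp2), 0)
  # equidistant candidates: earlier wins
  pp3 <- pair_peaks(anchors, tibble::tibble(time_s = c(9, 11),
                                            value = c(1, 2)), c(-4, 4))
  expect_equal(pp3$t_candidate, 9)
  expect_error(pair_peaks(anchors, cands, c(2, -2)), "window")
})

test_that("pairing matches the O(n*m) brute-force oracle", {
  set.seed(11)
  for (i in 1:300) {
    na <- sample(0:12, 1)
    nc <- sample(0:12, 1)
    anchors <- tibble::tibble(time_s = sort(runif(na, 0, 50)),
                              value = rnorm(na))
    cands <- tibble::tibble(time_s = sort(runif(nc, 0, 50)),
                            value = rnorm(nc))
    w <- sort(runif(2, -6, 6))
    if (w[1] == w[2]) next
    got <- pair_peaks(anchors, cands, w)
    want <- pair_peaks_oracle(anchors, cands, w)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$t_anchor, want$t_anchor)
      expect_equal(got$t_candidate, want$t_candidate)
    }
  }
})

test_that("pairing is equivariant to a common time shift", {
  set.seed(12)
  anchors <- tibble::tibble(time_s = sort(runif(20, 0, 100)),
                            value = rnorm(20))
  cands <- tibble::tibble(time_s = sort(runif(30, 0, 100)),
                          value = rnorm(30))
  a <- pair_peaks(anchors, cands, c(-4, 1))
  sh <- function(d) dplyr::mutate(d, time_s = time_s + 13.7)
  b <- pair_peaks(sh(anchors), sh(cands), c(-4, 1))
  expect_equal(b$delta_t, a$delta_t)
  expect_equal(pairing_ratio(b), pairing_ratio(a))
})

test_that("co-occurrence ratios hit their extremes and the causal asymmetry", {
  train <- tibble::tibble(time_s = seq(10, 90, by = 10), value = 1)
  co_same <- co_occurrence(list(r = train), list(b = train))
  expect_true(all(co_same$ratio == 1))
  far <- dplyr::mutate(train, time_s = time_s + 500)
  co_far <- co_occurrence(list(r = train), list(b = far))
  expect_true(all(co_far$ratio == 0))
  # causal generation: every LFP burst causes a lagged CBV peak, plus
  # distractor bursts with no vascular counterpart
  set.seed(13)
  lfp_t <- sort(runif(30, 0, 600))
  cbv <- tibble::tibble(time_s = sort(lfp_t + 1.5), value = 1)
  lfp <- tibble::tibble(time_s = sort(c(lfp_t, runif(15, 0, 600))),
                        value = 1)
  co <- co_occurrence(list(hip = cbv), list(gamma = lfp))
  r_cbv <- co$ratio[co$direction == "cbv-anchored"]
  r_lfp <- co$ratio[co$direction == "lfp-anchored"]
  expect_gte(r_cbv, r_lfp)
  expect_equal(r_cbv, 1)
})

test_that("pooled peak correlation recovers exact and null relationships", {
  exact <- tibble::tibble(v_anchor = 1:20, v_candidate = (1:20) * 2 + 1)
  pc <- peak_correlation(exact)
  expect_equal(pc$r, 1, tolerance = 1e-9)
  expect_lt(pc$p, 1e-10)
  set.seed(14)
  nulls <- vapply(1:60, function(i) {
    peak_correlation(simulate_coupled_peaks(500, 0, n_recordings = 1))$r
  }, numeric(1))
  expect_gte(mean(abs(nulls) < 0.1), 0.9)
  expect_error(peak_correlation(exact[1:2, ]), "3 pairs")
  expect_warning(
    pc0 <- peak_correlation(tibble::tibble(v_anchor = rep(1, 5),
                                           v_candidate = 1:5)),
    "degenerate")
  expect_true(is.na(pc0$r))
})

test_that("per-recording min-max normalization guards against Simpson effects", {
  # two recordings on different scales, same within-recording slope sign
  set.seed(15)
  x1 <- runif(50)
  x2 <- runif(50)
  d <- tibble::tibble(
    recording = rep(1:2, each = 50),
    v_candidate = c(x1, x2 * 10 + 100),
    v_anchor = c(2 * x1, (2 * x2) * 10 + 500) + rnorm(100, 0, 0.01))
  pc <- peak_correlation(d)
  expect_gt(pc$r, 0.95)
})

test_that("delay statistics summarize groups and compare shared events", {
  d <- tibble::tibble(t_anchor = 1:10, t_candidate = 1:10 - 1.5,
                      delta_t = rep(1.5, 10), group = "hip")
  ds <- delay_stats(d)
  expect_equal(ds$groups$mean_delay_s, 1.5)
  expect_equal(ds$groups$sem_s, 0)
  # symmetric delays around zero: test rarely rejects
  set.seed(16)
  rejections <- vapply(1:40, function(i) {
    dd <- tibble::tibble(t_anchor = 1:30, t_candidate = 0,
                         delta_t = rnorm(30), group = "g")
    delay_stats(dd)$groups$p < 0.05
  }, logical(1))
  expect_gte(mean(!rejections), 0.9)
  expect_warning(delay_stats(tibble::tibble(t_anchor = 1, t_candidate = 0,
                                            delta_t = 1, group = "solo")),
                 "skipped")
})

test_that("cross-correlation nails exact shifts and its self-peak", {
  tt <- 0:299
  set.seed(17)
  base <- as.numeric(stats::filter(rnorm(320), rep(1, 5), sides = 1))
  base[is.na(base)] <- 0
  env <- tibble::tibble(time_s = tt, value = base[3:302])
  cbv <- tibble::tibble(time_s = tt, value = base[1:300] * 3 + 7)
  ep <- tibble::tibble(start_s = 0, end_s = 300)
  xc <- cross_correlation(env, cbv, ep)
  expect_equal(xc$peaks$peak_lag_s, 2, tolerance = 0.2)
  expect_gt(xc$peaks$peak_r, 0.99)
  # self correlation peaks at exactly zero with r = 1
  xs <- cross_correlation(env, env, ep)
  expect_equal(xs$mean_peak_lag_s, 0)
  expect_equal(xs$mean_peak_r, 1, tolerance = 1e-9)
})

test_that("independent series stay inside the null envelope", {
  set.seed(18)
  tt <- 0:299
  env <- tibble::tibble(time_s = tt, value = rnorm(300))
  cbv <- tibble::tibble(time_s = tt, value = rnorm(300))
  xc <- cross_correlation(env, cbv, tibble::tibble(start_s = 0,
                                                   end_s = 300))
  expect_lt(abs(xc$mean_peak_r), 4 / sqrt(280))
})

test_that("short episodes are skipped with a warning", {
  tt <- 0:99
  env <- tibble::tibble(time_s = tt, value = rnorm(100))
  eps <- tibble::tibble(start_s = c(0, 50), end_s = c(15, 100))
  expect_warning(xc <- cross_correlation(env, env, eps, max_lag_s = 10),
                 "skipped")
  expect_equal(nrow(xc$peaks), 1L)
})

test_that("generator kernel lag is recovered from REM episodes", {
  fx <- fixture_rem_recording()
  env <- band_power(fx$sig$lfp, fx$cfg$burst_band)
  env_r <- resample_signal(env, fx$norm$frame_times_s)
  reg <- region_average(fx$norm, fx$labels)
  hip <- reg[reg$region == "hippocampus", c("time_s", "cbv")]
  names(hip) <- c("time_s", "value")
  rem <- fx$hyp[fx$hyp$state == "REM", c("start_s", "end_s")]
  xc <- cross_correlation(env_r, hip, rem)
  expect_lt(abs(xc$mean_peak_lag_s - fx$cfg$kernel_lag_s[["hippocampus"]]),
            0.5)
  expect_true(all(xc$peaks$peak_lag_s > 0))
})
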