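# LFP processing: band filters, envelopes, spectrograms, theta phase,
# phase-amplitude coupling, theta/delta ratio.

fs <- 1000
tt <- (0:19999) / fs

test_that("the canonical band table matches the hippocampal convention", {
  b <- lfp_bands()
  expect_equal(b$f_lo[b$band == "theta"], 6)
  expect_equal(b$f_hi[b$band == "theta"], 10)
  expect_equal(b$f_lo[b$band == "delta"], 1)
  expect_equal(b$f_hi[b$band == "ripple"], 250)
})

test_that("band filter passes in-band tones and rejects out-of-band tones", {
  mid <- 8000:12000
  th8 <- band_filter(sig_tbl(sin(2 * pi * 8 * tt)), "theta")
  expect_equal(max(abs(th8$value[mid])), 1, tolerance = 0.1)
  th30 <- band_filter(sig_tbl(sin(2 * pi * 30 * tt)), "theta")
  expect_lt(max(abs(th30$value[mid])), 0.01)
  de2 <- band_filter(sig_tbl(sin(2 * pi * 2 * tt)), "delta")
  expect_equal(max(abs(de2$value[mid])), 1, tolerance = 0.1)
  expect_error(band_filter(sig_tbl(rnorm(1000)), c(400, 600)), "Nyquist")
  expect_error(band_filter(sig_tbl(rnorm(1000)), c(10, 5)), "f_lo")
})

test_that("envelope implements the squared-signal Gaussian integral", {
  z <- band_envelope(sig_tbl(numeric(5000)))
  expect_true(all(z$value == 0))
  e <- band_envelope(sig_tbl(2 * sin(2 * pi * 40 * tt)))
  expect_equal(mean(e$value[5000:15000]), 2, tolerance = 0.02)  # A^2/2
  # quadratic scaling across an amplitude step
  amp <- c(rep(1, 10000), rep(2, 10000))
  es <- band_envelope(sig_tbl(amp * sin(2 * pi * 40 * tt)))
  expect_equal(mean(es$value[17000:19000]) / mean(es$value[2000:4000]), 4,
               tolerance = 0.05)
  expect_error(band_envelope(sig_tbl(rnorm(100)), width_s = 0), "width")
})

test_that("envelope is shift-equivariant away from edges", {
  set.seed(1)
  x <- as.numeric(stats::filter(rnorm(12000), rep(1, 5), sides = 2))
  x[is.na(x)] <- 0
  shift <- 500L
  e1 <- band_envelope(sig_tbl(x))$value
  e2 <- band_envelope(sig_tbl(c(numeric(shift), x[1:(12000 - shift)])))$value
  core <- 3000:9000
  expect_equal(e2[core + shift], e1[core], tolerance = 1e-6)
})

test_that("spectrogram localizes tones and f-compensation lifts high rows", {
  x <- sig_tbl(sin(2 * pi * 8 * tt[1:10000]))
  sp <- lfp_spectrogram(x, freqs = 1:20, t_decimate = 20)
  mid <- sp$times > 2 & sp$times < 8
  expect_equal(sp$freqs[which.max(rowMeans(sp$power[, mid]))], 8)
  set.seed(2)
  xn <- sig_tbl(rnorm(10000))
  spn <- lfp_spectrogram(xn, freqs = seq(5, 150, 5), t_decimate = 20)
  tau <- cor(spn$freqs, rowMeans(spn$power), method = "kendall")
  expect_gt(tau, 0)
  sp0 <- lfp_spectrogram(sig_tbl(numeric(2000)), freqs = c(5, 10))
  expect_true(all(sp0$power == 0))
  expect_error(lfp_spectrogram(x, freqs = numeric()), "empty")
  expect_error(lfp_spectrogram(x, freqs = c(10, 600)), "Nyquist")
})

test_that("theta phase puts 0 deg at the trough and advances with time", {
  ph <- theta_phase(sig_tbl(-cos(2 * pi * 8 * tt)))
  at <- function(t0) ph$phase_deg[which.min(abs(tt - t0))]
  tr <- at(5.0) %% 360
  expect_lt(min(tr, 360 - tr), 1)                   # trough (circular)
  expect_equal(at(5.0625), 180, tolerance = 2)      # half cycle later
  # total advance over 1 s of 8 Hz theta: 8 full cycles
  seg <- ph$phase_deg[tt >= 4 & tt <= 5]
  adv <- sum((diff(seg) + 180) %% 360 - 180)
  expect_equal(adv, 8 * 360, tolerance = 8 * 360 * 0.01)
})

test_that("phase estimate tracks known phase within 5 deg RMS at high SNR", {
  set.seed(3)
  true_deg <- (360 * 8 * tt) %% 360
  x <- -cos(2 * pi * 8 * tt) + rnorm(length(tt), 0, sqrt(0.5 / 10))
  ph <- theta_phase(sig_tbl(x))
  core <- tt > 2 & tt < 18
  err <- (ph$phase_deg[core] - true_deg[core] + 180) %% 360 - 180
  expect_lt(sqrt(mean(err^2)), 5)
})

test_that("phase-amplitude coupling finds the programmed preferred phase", {
  gam <- sin(2 * pi * 90 * tt) *
    (0.5 + 0.5 * cos(2 * pi * 8 * tt - 135 * pi / 180))
  x <- sig_tbl(gam - cos(2 * pi * 8 * tt))
  ph <- theta_phase(x)
  env <- band_power(x, c(80, 110), width_s = 0.02)
  keep <- tt > 1 & tt < 19
  pac <- phase_amplitude_coupling(ph[keep, ], env[keep, ], 18)
  expect_true(pac$defined)
  expect_gte(pac$preferred_phase_deg, 90)
  expect_lte(pac$preferred_phase_deg, 180)
  # conservation: mean of per-bin means weighted equally = overall mean
  expect_equal(mean(pac$profile$mean_power), mean(env$value[keep]),
               tolerance = 0.05)
})

test_that("flat envelopes leave the preferred phase undefined", {
  ph <- theta_phase(sig_tbl(-cos(2 * pi * 8 * tt[1:5000])))
  env <- tibble::tibble(time_s = tt[1:5000], value = rep(1, 5000))
  pac <- phase_amplitude_coupling(ph, env, 18)
  expect_false(pac$defined)
  expect_true(is.na(pac$preferred_phase_deg))
  expect_error(phase_amplitude_coupling(ph, env, 1), "n_bins")
})

test_that("theta/delta ratio separates theta from delta regimes", {
  r_th <- theta_delta_ratio(sig_tbl(sin(2 * pi * 8 * tt)))
  expect_gt(median(r_th$value, na.rm = TRUE), 10)
  r_de <- theta_delta_ratio(sig_tbl(sin(2 * pi * 2 * tt)))
  expect_lt(median(r_de$value, na.rm = TRUE), 0.1)
  r_mix <- theta_delta_ratio(sig_tbl(sin(2 * pi * 8 * tt) +
                                       sin(2 * pi * 2 * tt)))
  expect_equal(median(r_mix$value, na.rm = TRUE), 1, tolerance = 0.15)
  expect_error(theta_delta_ratio(sig_tbl(rnorm(5000)), window_s = 0.5),
               "window")
})

test_that("band envelope power is bounded by the total mean square", {
  set.seed(4)
  x <- sig_tbl(rnorm(20000))
  bands <- lfp_bands()
  tot <- sum(vapply(seq_len(nrow(bands)), function(i) {
    e <- band_power(x, c(bands$f_lo[i], bands$f_hi[i]))
    mean(e$value[3000:17000])
  }, numeric(1)))
  expect_lte(tot, 1.02 * mean(x$value[3000:17000]^2))
})
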