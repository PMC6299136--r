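# Synthetic-data generator: state chain, LFP content, CBV coupling, IQ
# stacks, label volumes.

test_that("hypnogram partitions the recording and respects the chain rules", {
  for (s in c(1, 5, 9, 13)) {
    cfg <- sim_config(duration_s = 1200, seed = s)
    hyp <- simulate_hypnogram(cfg)
    expect_equal(hyp$start_s[1], 0)
    expect_equal(max(hyp$end_s), cfg$duration_s)
    expect_equal(sum(hyp$end_s - hyp$start_s), cfg$duration_s)
    expect_true(all(abs(hyp$start_s[-1] - head(hyp$end_s, -1)) < 1e-9))
    # REM only after NREM; REM followed by wake
    idx <- which(hyp$state == "REM")
    if (length(idx) > 0) {
      expect_true(all(hyp$state[idx - 1] == "NREM"))
      after <- idx[idx < nrow(hyp)] + 1
      expect_true(all(hyp$state[after] %in% c("QW", "AW")))
    }
  }
})

test_that("degenerate chain with only QW yields a single interval", {
  cfg <- sim_config(duration_s = 300, seed = 2, allowed_states = "QW")
  hyp <- simulate_hypnogram(cfg)
  expect_equal(nrow(hyp), 1L)
  expect_equal(hyp$state, "QW")
  expect_equal(c(hyp$start_s, hyp$end_s), c(0, 300))
})

test_that("dwell times follow the configured shifted-exponential mean", {
  cfg <- sim_config(seed = 1)
  set.seed(1)
  m <- 90
  draws <- cfg$min_dwell_s + rexp(10000, 1 / (m - cfg$min_dwell_s))
  expect_lt(abs(mean(draws) - m) / m, 0.05)
  # and realized REM dwells across seeds carry that mean
  dwells <- unlist(lapply(1:30, function(s) {
    hyp <- simulate_hypnogram(sim_config(duration_s = 3000, seed = s,
                                         state_dwell_means = c(QW = 60,
                                                               AW = 40,
                                                               NREM = 90,
                                                               REM = 90)))
    d <- hyp[hyp$state == "REM", ]
    d$end_s - d$start_s
  }))
  expect_gt(length(dwells), 50)
  expect_lt(abs(mean(dwells) - 90), 3 * sd(dwells) / sqrt(length(dwells)) + 9)
})

test_that("generator is deterministic given the config seed", {
  cfg <- sim_config(duration_s = 300, seed = 4)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$hypnogram, b$hypnogram)
  expect_identical(a$lfp, b$lfp)
  expect_identical(a$movie$data, b$movie$data)
  expect_identical(a$bursts, b$bursts)
})

test_that("REM LFP is theta-dominated in the 1-20 Hz range", {
  hyp <- tibble::tibble(start_s = 0, end_s = 60, state = "REM")
  cfg <- sim_config(duration_s = 60, seed = 3)
  sig <- simulate_lfp(hyp, cfg)
  sp <- lfp_spectrogram(sig$lfp, freqs = 1:20, t_decimate = 50)
  mid <- sp$times > 5 & sp$times < 55
  prof <- rowMeans(sp$power[, mid])
  expect_true(sp$freqs[which.max(prof)] >= 6 && sp$freqs[which.max(prof)] <= 10)
})

test_that("zero burst rate leaves the REM gamma envelope peak-free", {
  hyp <- tibble::tibble(start_s = 0, end_s = 120, state = "REM")
  cfg <- sim_config(duration_s = 120, seed = 5, burst_rate_rem = 0)
  sig <- simulate_lfp(hyp, cfg)
  expect_equal(nrow(sig$bursts), 0L)
  env <- band_power(sig$lfp, cfg$burst_band)
  mid <- env$value[env$time_s > 2 & env$time_s < 118]
  expect_lt(max(mid), mean(mid) + 5 * sd(mid))
  # with bursts enabled the same statistic is far exceeded
  cfg_b <- sim_config(duration_s = 120, seed = 5)
  env_b <- band_power(simulate_lfp(hyp, cfg_b)$lfp, cfg_b$burst_band)
  mid_b <- env_b$value[env_b$time_s > 2 & env_b$time_s < 118]
  expect_gt(max(mid_b), mean(mid_b) + 5 * sd(mid_b))
})

test_that("NREM-only recordings have EMG below the wake level and no acc", {
  hyp <- tibble::tibble(start_s = 0, end_s = 60, state = "NREM")
  cfg <- sim_config(duration_s = 60, seed = 6)
  sig <- simulate_lfp(hyp, cfg)
  expect_lt(sqrt(mean(sig$emg$value^2)), 0.2)
  expect_true(all(sig$acc$value == 0))
})

test_that("burst count per REM minute matches the configured rate", {
  tot <- 0
  rem_min <- 0
  for (s in 1:40) {
    hyp <- rem_cycle_hypnogram(n_episodes = 4, rem_s = 90)
    cfg <- sim_config(duration_s = max(hyp$end_s), seed = s)
    b <- simulate_bursts(hyp, cfg)
    tot <- tot + sum(b$state == "REM")
    d <- hypnogram_durations(hyp)
    rem_min <- rem_min + d$seconds[d$state == "REM"] / 60
  }
  rate <- tot / rem_min
  # Poisson sampling error on the aggregate count
  tol <- 3 * sqrt(4 * rem_min) / rem_min
  expect_lt(abs(rate - 4), tol + 0.2)
})

test_that("a single noise-free burst produces the configured peak response", {
  hyp <- rem_cycle_hypnogram(n_episodes = 1, rem_s = 120)
  cfg <- sim_config(duration_s = max(hyp$end_s), seed = 1,
                    coupling_gain = 30, noise_sd_cbv = 1e-9)
  labels <- simulate_region_labels(cfg)
  rem_start <- hyp$start_s[hyp$state == "REM"][1]
  bursts <- tibble::tibble(time_s = rem_start + 30, power = 1,
                           freq_hz = 95, state = "REM")
  cb <- simulate_cbv_movie(hyp, bursts, labels, cfg)
  dr <- cb$truth$drive
  off <- cfg$state_cbv_offsets
  rem_off <- off$offset_pct[off$state == "REM" & off$group == "hippocampus"]
  resp <- 30 * dr$hippocampus
  expect_equal(max(resp), 30, tolerance = 1e-6)
  expect_equal(dr$time_s[which.max(dr$hippocampus)] - (rem_start + 30),
               cfg$kernel_lag_s[["hippocampus"]], tolerance = 0.11)
  expect_true(rem_off >= 0)
})

test_that("zero gain and zero offsets yield a surge-free noise movie", {
  hyp <- rem_cycle_hypnogram(n_episodes = 3, rem_s = 60)
  off <- default_state_offsets()
  off$offset_pct <- 0
  cfg <- sim_config(duration_s = max(hyp$end_s), seed = 8,
                    coupling_gain = 0, state_cbv_offsets = off)
  labels <- simulate_region_labels(cfg)
  cb <- simulate_cbv_movie(hyp, simulate_bursts(hyp, cfg), labels, cfg)
  expect_equal(nrow(cb$truth$surge_intervals), 0L)
  norm <- resample_movie(normalize_cbv(cb$movie, hyp), 1)
  expect_lt(abs(mean(norm$data)), 0.5)
  thr <- activation_threshold(norm, hyp, labels)
  det <- detect_surges(norm, thr, hyp)
  expect_lte(nrow(det$surges), 1L)  # false-positive tolerance
})

test_that("label maps and volumes partition their grids", {
  cfg <- sim_config()
  labels <- simulate_region_labels(cfg)
  expect_true(all(labels$labels %in% c(0L, labels$names$label)))
  expect_setequal(unique(labels$names$group),
                  c("cortex", "hippocampus", "thalamus"))
  vol <- simulate_label_volume()
  expect_true(all(vol$labels %in% 0:4))
  bnd <- boundary_voxels(vol)
  counts <- table(bnd$class)
  expect_setequal(names(counts), c("outer-cortex", "inner-cortex",
                                   "midline", "dentate-gyrus-edge"))
  expect_true(all(counts >= 10))
  sl <- slice_volume(vol, 3L, vol$dims[3] %/% 2)
  expect_true(all(sl %in% 0:4))
  expect_equal(dim(sl), vol$dims[1:2])
})

test_that("IQ stacks have orthogonal components and a faithful blood truth", {
  s <- simulate_iq_stack(n_vox = 400, n_frames = 120, tissue_rank = 5,
                         seed = 2)
  expect_equal(sum(Mod(s$iq)^2), sum(s$energies), tolerance = 1e-9)
  s0 <- simulate_iq_stack(n_vox = 200, n_frames = 100, blood_amp = 0,
                          seed = 3)
  expect_true(all(s0$blood_truth == 0))
  expect_error(simulate_iq_stack(n_vox = 50, n_frames = 20,
                                 tissue_rank = 15),
               "n_frames")
})

test_that("invalid configs are rejected", {
  expect_error(sim_config(duration_s = 0), "duration")
  expect_error(sim_config(coupling_gain = -1), "coupling_gain")
  expect_error(sim_config(state_dwell_means = c(QW = -5, AW = 40,
                                                NREM = 120, REM = 60)),
               "dwell")
  off <- default_state_offsets()[-1, ]
  expect_error(sim_config(state_cbv_offsets = off), "state x group")
  labels <- simulate_region_labels(sim_config())
  hyp <- rem_cycle_hypnogram(1)
  cfg <- sim_config(duration_s = max(hyp$end_s), grid_shape = c(10L, 10L))
  expect_error(simulate_cbv_movie(hyp, simulate_bursts(hyp, cfg),
                                  labels, cfg),
               "grid")
})
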