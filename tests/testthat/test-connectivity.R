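# Functional connectivity and the statistical toolkit.

reg_tbl <- function(series, times = seq_along(series[[1]]) - 1) {
  purrr::map_dfr(names(series), function(nm) {
    tibble::tibble(time_s = times, region = nm, group = nm,
                   cbv = series[[nm]], is_group = FALSE)
  })
}

test_that("connectivity matrices are symmetric with unit diagonal", {
  set.seed(20)
  x <- rnorm(200)
  reg <- reg_tbl(list(a = x, b = x, c = rnorm(200)))
  hyp <- tibble::tibble(start_s = 0, end_s = 200, state = "REM")
  cm <- connectivity_matrix(reg, hyp, "REM")
  expect_equal(cm$r, t(cm$r))
  expect_equal(diag(cm$r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cm$r["a", "b"], 1)
  expect_true(all(cm$r >= -1 & cm$r <= 1))
  expect_error(connectivity_matrix(reg, hyp, "NREM"), "frames")
})

test_that("independent series give near-zero off-diagonals", {
  set.seed(21)
  hits <- vapply(1:30, function(i) {
    reg <- reg_tbl(list(a = rnorm(1000), b = rnorm(1000)))
    hyp <- tibble::tibble(start_s = 0, end_s = 1000, state = "QW")
    abs(connectivity_matrix(reg, hyp, "QW")$r["a", "b"]) < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("a shared REM driver raises REM connectivity above QW", {
  fx <- fixture_rem_recording()
  reg <- region_average(fx$norm, fx$labels)
  rem <- connectivity_matrix(reg, fx$hyp, "REM")
  qw <- connectivity_matrix(reg, fx$hyp, "QW")
  expect_gt(mean_offdiag(rem), mean_offdiag(qw))
})

test_that("constant regions are flagged undefined", {
  reg <- reg_tbl(list(a = rnorm(50), b = rep(3, 50)))
  hyp <- tibble::tibble(start_s = 0, end_s = 50, state = "QW")
  cm <- connectivity_matrix(reg, hyp, "QW")
  expect_equal(cm$undefined, "b")
  expect_true(is.na(cm$r["a", "b"]))
  expect_equal(diag(cm$r), rep(1, 2), ignore_attr = TRUE)
})

test_that("Fisher confidence intervals match the closed form", {
  ci <- fisher_ci(0, 103)
  expect_equal(ci$hi, tanh(1.96 / 10), tolerance = 1e-3)
  expect_equal(ci$lo, -ci$hi, tolerance = 1e-12)
  ci5 <- fisher_ci(0.5, 30)
  expect_true(ci5$lo < 0.5 && 0.5 < ci5$hi)
  expect_equal(ci5$lo, tanh(atanh(0.5) - qnorm(0.975) / sqrt(27)),
               tolerance = 1e-12)
  expect_error(fisher_ci(1, 30), "degenerate")
  expect_error(fisher_ci(0.5, 3), "n must")
})

test_that("the two-correlation Z is antisymmetric and exact", {
  expect_equal(compare_pearson(0.4, 50, 0.4, 50)$z, 0)
  a <- compare_pearson(0.6, 40, 0.3, 60)
  b <- compare_pearson(0.3, 60, 0.6, 40)
  expect_equal(a$z, -b$z)
  want <- (atanh(0.6) - atanh(0.3)) / sqrt(1 / 37 + 1 / 57)
  expect_equal(a$z, want, tolerance = 1e-12)
  expect_error(compare_pearson(0.5, 3, 0.5, 10), "n must")
})

test_that("Cohen's d matches its defining cases", {
  set.seed(22)
  x <- rnorm(2000)
  expect_equal(cohens_d(x, x), 0)
  y <- rnorm(5000)
  expect_equal(cohens_d(y + 1, y), 1, tolerance = 0.05)
  z <- rnorm(10000)
  expect_equal(cohens_d(z + 0.5, rnorm(10000)), 0.5, tolerance = 0.03)
  expect_warning(d0 <- cohens_d(rep(1, 5), rep(1, 5)), "pooled SD")
  expect_true(is.na(d0))
})

test_that("Mann-Whitney p agrees with exact enumeration for small n", {
  set.seed(23)
  for (i in 1:12) {
    nx <- sample(3:8, 1)
    ny <- sample(3:8, 1)
    x <- rnorm(nx)
    y <- rnorm(ny, 0.5)
    got <- mann_whitney(x, y)
    want <- mann_whitney_exact_oracle(x, y)
    expect_equal(got$p, want, tolerance = 1e-12)
  }
})

test_that("state summaries use 30 s window means with t intervals", {
  hyp <- tibble::tibble(start_s = c(0, 300), end_s = c(300, 600),
                        state = c("QW", "REM"))
  reg <- tibble::tibble(time_s = 0:599, region = "hippocampus",
                        group = "hippocampus",
                        cbv = c(rep(0, 300), rep(12, 300)), is_group = TRUE)
  sm <- state_summary(reg, hyp)
  rem <- sm[sm$state == "REM", ]
  expect_equal(rem$mean, 12)
  expect_equal(rem$ci_lo, 12)
  expect_equal(rem$ci_hi, 12)
  expect_equal(rem$n_windows, 10)
  expect_lt(rem$p_vs_qw, 0.05)
})

test_that("window means widen intervals on autocorrelated series", {
  set.seed(24)
  hyp <- tibble::tibble(start_s = 0, end_s = 600, state = "QW")
  ar <- as.numeric(stats::arima.sim(list(ar = 0.95), 600))
  reg <- tibble::tibble(time_s = 0:599, region = "g", group = "g",
                        cbv = ar, is_group = TRUE)
  sm <- state_summary(reg, hyp)
  w_window <- sm$ci_hi - sm$ci_lo
  # naive CI from raw 1 Hz samples, ignoring autocorrelation
  w_naive <- 2 * qt(0.975, 599) * sd(ar) / sqrt(600)
  expect_gt(w_window, w_naive)
})

test_that("generated state offsets are recovered with significance", {
  fx <- fixture_rem_recording()
  reg <- region_average(fx$norm, fx$labels)
  sm <- state_summary(reg[reg$is_group, ], fx$hyp)
  hip_rem <- sm[sm$region == "hippocampus" & sm$state == "REM", ]
  expect_lt(hip_rem$p_vs_qw, 0.05)
  expect_gt(hip_rem$mean, 4)
  amp <- amplification_ratios(sm)
  hip_amp <- amp$amplification_pct[amp$region == "hippocampus" &
                                     amp$state == "REM"]
  qw_m <- sm$mean[sm$region == "hippocampus" & sm$state == "QW"]
  expect_equal(hip_amp, hip_rem$mean - qw_m, tolerance = 1e-12)
  expect_error(amplification_ratios(sm[sm$state != "QW", ]), "QW")
})

test_that("entrywise averaging of matrices preserves structure", {
  set.seed(25)
  hyp <- tibble::tibble(start_s = 0, end_s = 100, state = "QW")
  mats <- lapply(1:3, function(i) {
    reg <- reg_tbl(list(a = rnorm(100), b = rnorm(100)))
    connectivity_matrix(reg, hyp, "QW")
  })
  avg <- average_connectivity(mats)
  expect_equal(avg$r["a", "b"],
               mean(vapply(mats, function(m) m$r["a", "b"], numeric(1))))
  expect_equal(diag(avg$r), rep(1, 2), ignore_attr = TRUE)
})
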