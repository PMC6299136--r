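#' State-restricted functional connectivity matrix
#'
#' Zero-lag Pearson correlations between all pairs of regional CBV series,
#' computed over the frames scored as `state`. No Fisher transform, no
#' filtering. Regions with zero variance within the state are flagged and
#' their rows/columns set to `NA` (diagonal kept at 1).
#'
#' @param regional long tibble from [region_average()] (`time_s`,
#'   `region`, `cbv`); group-level rows (`is_group`) are excluded if
#'   present.
#' @param hyp hypnogram tibble.
#' @param state state label to restrict to (REM sub-states count as REM
#'   when `state = "REM"`).
#' @param min_frames minimum frames required (default 10).
#' @return a `connectivity_matrix`: list with `state`, `regions`, `r`
#'   (symmetric matrix, unit diagonal), `n`, `undefined` (flagged
#'   regions).
#' @export
connectivity_matrix <- function(regional, hyp, state, min_frames = 10) {
  df <- regional
  if ("is_group" %in% names(df)) df <- df[!df$is_group, ]
  wide <- tidyr::pivot_wider(df[, c("time_s", "region", "cbv")],
                             names_from = "region", values_from = "cbv")
  st <- state_at(hyp, wide$time_s)
  if (state == "REM") st[st %in% c("REM-tonic", "REM-phasic")] <- "REM"
  sel <- !is.na(st) & st == state
  if (sum(sel) < min_frames) {
    abort(sprintf("state %s has %d frames; need >= %d", state, sum(sel),
                  min_frames))
  }
  m <- as.matrix(wide[sel, -1])
  sds <- apply(m, 2, sd)
  undefined <- colnames(m)[sds == 0]
  r <- suppressWarnings(cor(m))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- 1
  structure(list(state = state, regions = colnames(m), r = r,
                 n = sum(sel), undefined = undefined),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> state %s, %d regions, n = %d frames\n",
              x$state, length(x$regions), x$n))
  invisible(x)
}

#' @export
tidy.connectivity_matrix <- function(x, ...) {
  tibble::tibble(
    region_a = rep(x$regions, times = length(x$regions)),
    region_b = rep(x$regions, each = length(x$regions)),
    r = as.numeric(x$r),
    state = x$state
  )
}

#' Mean of the off-diagonal entries of a connectivity matrix
#' @param x a `connectivity_matrix`.
#' @return mean off-diagonal Pearson r.
#' @export
mean_offdiag <- function(x) {
  r <- x$r
  mean(r[row(r) != col(r)], na.rm = TRUE)
}

#' Entrywise average of connectivity matrices across recordings
#'
#' Plain entrywise mean (no Fisher transform), matching how group matrices
#' are assembled from per-recording matrices.
#'
#' @param mats list of `connectivity_matrix` objects with identical
#'   regions and state.
#' @return a `connectivity_matrix` with the averaged entries.
#' @export
average_connectivity <- function(mats) {
  stopifnot(length(mats) >= 1)
  r <- Reduce(`+`, lapply(mats, function(m) m$r)) / length(mats)
  structure(list(state = mats[[1]]$state, regions = mats[[1]]$regions,
                 r = r, n = sum(vapply(mats, function(m) m$n, numeric(1))),
                 undefined = character()),
            class = "connectivity_matrix")
}

#' Fisher-transform confidence interval for a Pearson correlation
#'
#' `atanh(r) +/- z_{alpha/2} / sqrt(n - 3)`, back-transformed.
#'
#' @param r Pearson correlation, `|r| < 1`.
#' @param n sample size (>= 4).
#' @param level confidence level (default 0.95).
#' @return tibble (`r`, `n`, `lo`, `hi`).
#' @export
fisher_ci <- function(r, n, level = 0.95) {
  if (any(n < 4)) abort("invalid parameter: n must be >= 4")
  if (any(abs(r) >= 1)) abort("degenerate: |r| must be < 1")
  z <- qnorm(1 - (1 - level) / 2)
  h <- z / sqrt(n - 3)
  tibble::tibble(r = r, n = n, lo = tanh(atanh(r) - h),
                 hi = tanh(atanh(r) + h))
}

#' Z comparison of two independent Pearson correlations
#'
#' `Z = (atanh(rA) - atanh(rB)) / sqrt(1/(nA-3) + 1/(nB-3))`, two-sided
#' normal p-value.
#'
#' @param r_a,r_b correlations, `|r| < 1`.
#' @param n_a,n_b sample sizes (> 3).
#' @return tibble (`z`, `p`).
#' @export
compare_pearson <- function(r_a, n_a, r_b, n_b) {
  if (any(c(n_a, n_b) <= 3)) abort("invalid parameter: n must be > 3")
  if (any(abs(c(r_a, r_b)) >= 1)) abort("degenerate: |r| must be < 1")
  z <- (atanh(r_a) - atanh(r_b)) / sqrt(1 / (n_a - 3) + 1 / (n_b - 3))
  tibble::tibble(z = z, p = 2 * pnorm(-abs(z)))
}

#' Cohen's d with pooled standard deviation
#'
#' @param x,y numeric samples (n >= 2 each).
#' @return standardized mean difference `(mean(x) - mean(y)) / s_pooled`;
#'   `NA` with a warning when the pooled SD is zero.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2, ny >= 2)
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  if (sp == 0) {
    warn("zero pooled SD: Cohen's d undefined")
    return(NA_real_)
  }
  (mean(x) - mean(y)) / sp
}

#' Two-tailed Mann-Whitney test
#'
#' Thin wrapper over `stats::wilcox.test` (exact for small samples without
#' ties) reporting the U statistic and two-sided p.
#'
#' @param x,y numeric samples.
#' @return tibble (`u`, `p`).
#' @export
mann_whitney <- function(x, y) {
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  tibble::tibble(u = unname(wt$statistic), p = wt$p.value)
}

#' Per-state CBV level summaries from 30-s window means
#'
#' For each region group and state, the state-restricted series is chunked
#' into non-overlapping windows of `window_s` (partial terminal windows
#' dropped); window means form the sample from which the mean, its 95%
#' t confidence interval, and a two-tailed Mann-Whitney p versus the
#' quiet-wake sample are computed. Windowing decimates the autocorrelated
#' 1 Hz series so the intervals are not artificially narrow.
#'
#' @param regional long tibble (`time_s`, `region`, `cbv`), typically the
#'   group-level rows of [region_average()].
#' @param hyp hypnogram tibble (REM sub-states are kept distinct if
#'   present, and also aggregated into REM).
#' @param window_s window length, seconds (default 30).
#' @return tibble (`region`, `state`, `n_windows`, `mean`, `ci_lo`,
#'   `ci_hi`, `p_vs_qw`).
#' @export
state_summary <- function(regional, hyp, window_s = 30) {
  if ("is_group" %in% names(regional)) {
    regional <- regional[regional$is_group, ]
  }
  states <- unique(hyp$state)
  if (any(states %in% c("REM-tonic", "REM-phasic"))) {
    rem <- hyp[hyp$state %in% c("REM", "REM-tonic", "REM-phasic"), ]
    rem$state <- "REM"
    hyp <- dplyr::bind_rows(hyp, merge_hypnogram(rem))
    states <- unique(hyp$state)
  }
  purrr::map_dfr(unique(regional$region), function(rg) {
    ser <- regional[regional$region == rg, ]
    win_means <- function(state) {
      iv <- hyp[hyp$state == state, , drop = FALSE]
      unlist(purrr::map(seq_len(nrow(iv)), function(i) {
        sel <- ser$time_s >= iv$start_s[i] & ser$time_s < iv$end_s[i]
        v <- ser$cbv[sel]
        tt <- ser$time_s[sel]
        if (length(v) == 0) return(numeric())
        w <- floor((tt - iv$start_s[i]) / window_s)
        full <- w < floor((iv$end_s[i] - iv$start_s[i]) / window_s)
        if (!any(full)) return(numeric())
        as.numeric(tapply(v[full], w[full], mean))
      }))
    }
    qw <- win_means("QW")
    purrr::map_dfr(sort(unique(hyp$state)), function(st) {
      wm <- win_means(st)
      if (length(wm) < 2) return(NULL)
      se <- sd(wm) / sqrt(length(wm))
      ci <- mean(wm) + c(-1, 1) * qt(0.975, length(wm) - 1) * se
      p <- if (st == "QW" || length(qw) < 2) NA_real_ else
        mann_whitney(wm, qw)$p
      tibble::tibble(region = rg, state = st, n_windows = length(wm),
                     mean = mean(wm), ci_lo = ci[1], ci_hi = ci[2],
                     p_vs_qw = p)
    })
  })
}

#' Vascular amplification relative to quiet wake
#'
#' Differences of per-state mean CBV levels from the quiet-wake mean, per
#' region group.
#'
#' @param summaries tibble from [state_summary()].
#' @return tibble (`region`, `state`, `amplification_pct`).
#' @export
amplification_ratios <- function(summaries) {
  qw <- summaries[summaries$state == "QW", c("region", "mean")]
  if (nrow(qw) == 0) abort("QW summary missing")
  names(qw)[2] <- "qw_mean"
  summaries |>
    dplyr::filter(.data$state != "QW") |>
    dplyr::inner_join(qw, by = "region") |>
    dplyr::transmute(region = .data$region, state = .data$state,
                     amplification_pct = .data$mean - .data$qw_mean)
}
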