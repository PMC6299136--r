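#' Simulate a 2-D region label map for the imaging plane
#'
#' Builds an elliptical "brain" on the imaging grid, split by depth into a
#' cortical shell, a hippocampal band and a thalamic base, each divided into
#' left/right named regions. Voxels outside the ellipse are background
#' (label 0).
#'
#' @param config a [sim_config()] (only `grid_shape` is used).
#' @return a `region_labels` object: list with `labels` (rows x cols integer
#'   matrix) and `names` (tibble `label`, `region`, `group`).
#' @export
simulate_region_labels <- function(config) {
  shp <- config$grid_shape
  nr <- shp[1]; nc <- shp[2]
  r <- matrix(rep(seq_len(nr), nc), nr, nc)
  c_ <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  inside <- ((r - cy) / (0.48 * nr))^2 + ((c_ - cx) / (0.48 * nc))^2 <= 1
  depth <- (r - min(r[inside])) / (max(r[inside]) - min(r[inside]))
  left <- c_ <= cx
  lab <- matrix(0L, nr, nc)
  band <- ifelse(depth < 0.42, 1L, ifelse(depth < 0.72, 2L, 3L))
  lab[inside] <- (band[inside] - 1L) * 2L + ifelse(left[inside], 1L, 2L)
  names <- tibble::tribble(
    ~label, ~region,     ~group,
    1L, "Cortex-L",      "cortex",
    2L, "Cortex-R",      "cortex",
    3L, "Hippocampus-L", "hippocampus",
    4L, "Hippocampus-R", "hippocampus",
    5L, "Thalamus-L",    "thalamus",
    6L, "Thalamus-R",    "thalamus"
  )
  structure(list(labels = lab, names = names), class = "region_labels")
}

# gamma-variate hemodynamic kernel, unit peak at t = lag
hemo_kernel <- function(t, lag_s, fwhm_s) {
  if (lag_s <= 0) {
    return(as.numeric(t == 0))
  }
  a <- pmax(8 * log(2) * (lag_s / fwhm_s)^2, 1.05)
  h <- numeric(length(t))
  pos <- t > 0
  h[pos] <- (t[pos] / lag_s)^a * exp(-a * (t[pos] - lag_s) / lag_s)
  h
}

#' Simulate a power-Doppler (CBV) movie driven by gamma bursts
#'
#' Each voxel's raw signal is `baseline * (1 + offset/100 + gain/100 *
#' drive + noise)`, where `offset` is the configured per-state CBV offset of
#' the voxel's region group and `drive` is the burst power train convolved
#' with a gamma-variate hemodynamic kernel peaking `kernel_lag_s` seconds
#' after each burst (per group, preserving the configured thalamus <
#' hippocampus < cortex lag ordering). Ground-truth vascular-surge intervals
#' are the periods where the noise-free active-voxel fraction exceeds the
#' surge rule (voxel active when its noise-free percent signal exceeds its
#' active-wake level by one noise SD; fraction > 1/2 sustained >= 5 s),
#' clipped to REM.
#'
#' @param hyp hypnogram tibble.
#' @param bursts burst tibble from [simulate_lfp()] (`time_s`, `power`).
#' @param labels a `region_labels` object matching `grid_shape`.
#' @param config a [sim_config()].
#' @return list `movie` (a `doppler_movie`) and `truth` (list with
#'   `hypnogram`, `bursts`, `surge_intervals`, `kernel_lag_s`,
#'   `coupling_gain`, `drive` per group at 10 Hz).
#' @export
simulate_cbv_movie <- function(hyp, bursts, labels, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(dim(labels$labels) == config$grid_shape)) {
    abort("label grid does not match config grid_shape")
  }
  set.seed(sim_seed(config, "cbv"))
  dur <- config$duration_s
  groups <- c("cortex", "hippocampus", "thalamus")

  # group drive at a fine internal rate, then sampled at frame times
  fs_int <- 10
  t_int <- seq(0, dur, by = 1 / fs_int)
  drive <- matrix(0, length(t_int), length(groups),
                  dimnames = list(NULL, groups))
  if (nrow(bursts) > 0) {
    for (g in groups) {
      lag <- config$kernel_lag_s[[g]]
      for (i in seq_len(nrow(bursts))) {
        drive[, g] <- drive[, g] + bursts$power[i] *
          hemo_kernel(t_int - bursts$time_s[i], lag, config$kernel_fwhm_s)
      }
    }
  }

  st_int <- state_at(hyp, t_int)
  st_int[is.na(st_int)] <- "QW"
  offs <- config$state_cbv_offsets
  off_lookup <- function(states, g) {
    o <- offs$offset_pct[offs$group == g]
    names(o) <- offs$state[offs$group == g]
    unname(o[states])
  }
  pct_int <- sapply(groups, function(g) {
    off_lookup(st_int, g) + config$coupling_gain * drive[, g]
  })

  # ground-truth surge rule on the noise-free signal
  aw_off <- sapply(groups, function(g) off_lookup("AW", g))
  thr_true <- aw_off + config$noise_sd_cbv
  lab <- labels$labels
  n_g <- sapply(groups, function(g) {
    sum(lab %in% labels$names$label[labels$names$group == g])
  })
  active_g <- sapply(groups, function(g) pct_int[, g] > thr_true[[g]])
  frac_true <- as.numeric(active_g %*% n_g) / sum(n_g)
  truth_iv <- runs_to_intervals(frac_true > 0.5, t_int)
  rem_iv <- hyp[hyp$state == "REM", c("start_s", "end_s")]
  truth_iv <- clip_intervals(truth_iv, rem_iv)
  if (nrow(truth_iv) > 0) {
    truth_iv <- truth_iv[truth_iv$end_s - truth_iv$start_s >= 5, ]
  }

  # frames
  frame_times <- seq(0, dur - 1 / config$cbv_rate, by = 1 / config$cbv_rate)
  idx <- round(frame_times * fs_int) + 1L
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  nt <- length(frame_times)
  baseline <- matrix(runif(nr * nc, 80, 120), nr, nc)
  baseline[lab == 0L] <- 1  # background: unit level, noise only
  group_of_label <- setNames(labels$names$group, labels$names$label)
  pct_vox <- matrix(0, nr * nc, nt)
  for (g in groups) {
    sel <- lab %in% labels$names$label[labels$names$group == g]
    pct_vox[sel, ] <- matrix(pct_int[idx, g], sum(sel), nt, byrow = TRUE)
  }
  noise <- matrix(rnorm(nr * nc * nt, 0, config$noise_sd_cbv / 100),
                  nr * nc, nt)
  tensor <- array(as.numeric(baseline) * (1 + pct_vox / 100 + noise),
                  dim = c(nr, nc, nt))

  movie <- doppler_movie(tensor, frame_times)
  truth <- list(hypnogram = hyp, bursts = bursts,
                surge_intervals = tibble::as_tibble(truth_iv),
                kernel_lag_s = config$kernel_lag_s,
                coupling_gain = config$coupling_gain,
                drive = tibble::tibble(time_s = t_int,
                                       cortex = drive[, "cortex"],
                                       hippocampus = drive[, "hippocampus"],
                                       thalamus = drive[, "thalamus"]))
  list(movie = movie, truth = truth)
}

#' Construct a Doppler movie object
#'
#' @param tensor numeric array rows x cols x frames.
#' @param frame_times_s frame timestamps, seconds, strictly increasing.
#' @param normalized logical; `TRUE` once expressed as % change vs baseline.
#' @param voxel_size_mm numeric (row, col) voxel size.
#' @return a `doppler_movie` object.
#' @export
doppler_movie <- function(tensor, frame_times_s, normalized = FALSE,
                          voxel_size_mm = c(0.1, 0.1)) {
  stopifnot(length(dim(tensor)) == 3,
            dim(tensor)[3] == length(frame_times_s))
  if (any(diff(frame_times_s) <= 0)) {
    abort("frame times must be strictly increasing")
  }
  structure(list(data = tensor, frame_times_s = as.numeric(frame_times_s),
                 normalized = normalized, voxel_size_mm = voxel_size_mm),
            class = "doppler_movie")
}

#' @export
print.doppler_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<doppler_movie> %d x %d voxels, %d frames, %.3g-%.3g s, %s\n",
              d[1], d[2], d[3], min(x$frame_times_s), max(x$frame_times_s),
              if (x$normalized) "% change vs baseline" else "raw power"))
  invisible(x)
}

#' Simulate an end-to-end synthetic recording with ground truth
#'
#' Convenience wrapper chaining [simulate_hypnogram()], [simulate_lfp()],
#' [simulate_region_labels()] and [simulate_cbv_movie()].
#'
#' @param config a [sim_config()].
#' @return list with `hypnogram`, `lfp`, `emg`, `acc`, `bursts`, `labels`,
#'   `movie`, `truth`, `config`.
#' @export
simulate_recording <- function(config = sim_config()) {
  hyp <- simulate_hypnogram(config)
  sig <- simulate_lfp(hyp, config)
  labels <- simulate_region_labels(config)
  cb <- simulate_cbv_movie(hyp, sig$bursts, labels, config)
  list(hypnogram = hyp, lfp = sig$lfp, emg = sig$emg, acc = sig$acc,
       bursts = sig$bursts, labels = labels, movie = cb$movie,
       truth = cb$truth, config = config)
}

#' Simulate paired burst/surge peak amplitudes with a known correlation
#'
#' Draws `n` (LFP burst power, CBV surge amplitude) pairs from a bivariate
#' normal with population Pearson correlation `rho`, on positive scales
#' matching the generator's burst-power law. Used to validate the pooled
#' peak-correlation estimator against a known population value.
#'
#' @param n number of pairs.
#' @param rho population correlation in `[-1, 1]`.
#' @param n_recordings pairs are split evenly across this many pseudo
#'   recordings (min-max normalization is per recording downstream).
#'   Default 1: with several recordings the data-dependent min-max ranges
#'   attenuate the pooled correlation and widen its sampling spread, which
#'   is a property of the pooled estimator, not of the generator.
#' @return tibble (`recording`, `v_anchor`, `v_candidate`) mimicking a
#'   paired-peak value table.
#' @export
simulate_coupled_peaks <- function(n, rho, n_recordings = 1) {
  stopifnot(n >= 4, abs(rho) <= 1)
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  # linear maps onto the generator's scales keep the population Pearson
  tibble::tibble(
    recording = rep_len(seq_len(n_recordings), n),
    v_candidate = 0.6 + 0.2 * x,  # LFP burst power scale
    v_anchor = 30 + 8 * y         # % CBV surge amplitude scale
  )
}
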