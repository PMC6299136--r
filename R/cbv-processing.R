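#' SVD clutter filter for ultrafast Doppler IQ stacks
#'
#' Removes the `n_remove` leading singular components (by descending
#' singular value) of the voxels x frames complex matrix — the high-energy,
#' spatially-coherent tissue clutter — and returns the power-Doppler image:
#' per-voxel mean squared magnitude of the residual over frames. With
#' `n_remove = 0` this is just the per-voxel mean squared magnitude of the
#' input.
#'
#' @param iq complex matrix, voxels x frames (>= 2 frames, finite values).
#' @param n_remove number of leading components to remove (default 60).
#' @return numeric vector of per-voxel power (length = number of voxels).
#' @export
svd_clutter_filter <- function(iq, n_remove = 60) {
  stopifnot(is.matrix(iq))
  if (ncol(iq) < 2) abort("IQ stack needs at least 2 frames")
  if (any(!is.finite(Re(iq))) || any(!is.finite(Im(iq)))) {
    abort("IQ stack contains non-finite values")
  }
  if (n_remove < 0 || n_remove >= min(dim(iq))) {
    abort("invalid parameter: n_remove must be in [0, min(voxels, frames))")
  }
  if (n_remove == 0) return(rowMeans(Mod(iq)^2))
  sv <- svd(iq, nu = n_remove, nv = n_remove)
  clutter <- sv$u %*% (sv$d[seq_len(n_remove)] * Conj(t(sv$v)))
  rowMeans(Mod(iq - clutter)^2)
}

#' Normalize a Doppler movie to percent change vs a quiet-wake baseline
#'
#' Baseline frames are the first 3 minutes of quiet wake, plus — for
#' recordings longer than one hour — the first 3 minutes of quiet wake
#' after each subsequent full-hour mark (drift compensation). Each voxel is
#' normalized independently: `(v - mean_baseline) / mean_baseline * 100`.
#'
#' @param movie a raw `doppler_movie`.
#' @param hyp hypnogram tibble containing at least 3 min of QW.
#' @param baseline_min minutes of quiet wake per baseline block (default 3).
#' @return normalized `doppler_movie` (units: % change).
#' @export
normalize_cbv <- function(movie, hyp, baseline_min = 3) {
  stopifnot(inherits(movie, "doppler_movie"))
  tt <- movie$frame_times_s
  st <- state_at(hyp, tt)
  qw <- !is.na(st) & st == "QW"
  need <- baseline_min * 60
  dt <- median(diff(tt))
  n_need <- round(need / dt)
  base_idx <- logical(length(tt))
  hours <- seq(0, max(tt), by = 3600)
  for (h in hours) {
    cand <- which(qw & tt >= h & tt < h + 3600)
    base_idx[head(cand, n_need)] <- TRUE
  }
  got_s <- sum(tt >= 0 & tt < 3600 & base_idx) * dt
  if (sum(base_idx) < 2 || got_s < need - dt / 2) {
    abort(sprintf(
      "insufficient baseline: need %.0f s of QW, found %.0f s", need, got_s))
  }
  d <- dim(movie$data)
  flat <- matrix(movie$data, d[1] * d[2], d[3])
  mu <- rowMeans(flat[, base_idx, drop = FALSE])
  mu[mu == 0] <- NA_real_
  out <- sweep(sweep(flat, 1, mu, "-"), 1, mu, "/") * 100
  res <- doppler_movie(array(out, d), tt, normalized = TRUE,
                       voxel_size_mm = movie$voxel_size_mm)
  attr(res, "baseline_frames") <- which(base_idx)
  res
}

#' Resample a Doppler movie to a uniform frame rate
#'
#' Per-voxel linear interpolation onto a uniform grid at `target_rate`
#' spanning the original time range.
#'
#' @param movie a `doppler_movie` with >= 2 frames.
#' @param target_rate target frame rate, Hz (default 1).
#' @return resampled `doppler_movie`.
#' @export
resample_movie <- function(movie, target_rate = 1) {
  stopifnot(inherits(movie, "doppler_movie"))
  tt <- movie$frame_times_s
  if (length(tt) < 2) abort("movie needs at least 2 frames to resample")
  new_t <- seq(tt[1], tt[length(tt)], by = 1 / target_rate)
  if (length(new_t) == length(tt) && max(abs(new_t - tt)) < 1e-9) {
    return(movie)
  }
  d <- dim(movie$data)
  flat <- matrix(movie$data, d[1] * d[2], d[3])
  out <- t(apply(flat, 1, function(v) approx(tt, v, xout = new_t)$y))
  doppler_movie(array(out, c(d[1], d[2], length(new_t))), new_t,
                normalized = movie$normalized,
                voxel_size_mm = movie$voxel_size_mm)
}

#' Regional and group-level mean CBV time series
#'
#' Per region, the unweighted mean over its voxels per frame; group-level
#' series (cortex / hippocampus / thalamus / whole brain, excluding
#' background) are appended. Empty regions are dropped with a warning.
#'
#' @param movie a `doppler_movie`.
#' @param labels a `region_labels` with the same grid.
#' @return long tibble (`time_s`, `region`, `group`, `cbv`, `is_group`).
#' @export
region_average <- function(movie, labels) {
  stopifnot(inherits(movie, "doppler_movie"))
  d <- dim(movie$data)
  if (!all(dim(labels$labels) == d[1:2])) {
    abort("label grid does not match movie grid")
  }
  flat <- matrix(movie$data, d[1] * d[2], d[3])
  lab <- as.integer(labels$labels)
  rows <- purrr::map_dfr(seq_len(nrow(labels$names)), function(i) {
    l <- labels$names$label[i]
    sel <- lab == l
    if (!any(sel)) {
      warn(paste0("empty region excluded: ", labels$names$region[i]))
      return(NULL)
    }
    tibble::tibble(time_s = movie$frame_times_s,
                   region = labels$names$region[i],
                   group = labels$names$group[i],
                   cbv = colMeans(flat[sel, , drop = FALSE]),
                   is_group = FALSE)
  })
  groups <- unique(labels$names$group)
  grows <- purrr::map_dfr(c(as.list(groups), list("whole")), function(g) {
    sel <- if (identical(g, "whole")) {
      lab %in% labels$names$label
    } else {
      lab %in% labels$names$label[labels$names$group == g]
    }
    if (!any(sel)) return(NULL)
    tibble::tibble(time_s = movie$frame_times_s, region = g, group = g,
                   cbv = colMeans(flat[sel, , drop = FALSE]),
                   is_group = TRUE)
  })
  dplyr::bind_rows(rows, grows)
}
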