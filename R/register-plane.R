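#' Build a 9-parameter plane transform
#'
#' Maps a point `(row, col)` on the imaging plane into 3-D volume
#' coordinates: the plane point is embedded as `(x = col, y = row, z = 0)`,
#' scaled component-wise, rotated about x then y then z (applied as
#' `Rz %*% Ry %*% Rx`), then translated. The convention is serialized with
#' the transform.
#'
#' @param offsets numeric (3), voxels.
#' @param scalings numeric (3), strictly positive.
#' @param rotations numeric (3), degrees in `(-180, 180]`, about x, y, z.
#' @return a `plane_transform` list.
#' @export
plane_transform <- function(offsets = c(0, 0, 0), scalings = c(1, 1, 1),
                            rotations = c(0, 0, 0)) {
  if (any(scalings <= 0)) abort("scalings must be strictly positive")
  if (any(rotations <= -180 | rotations > 180)) {
    abort("rotations must lie in (-180, 180] degrees")
  }
  structure(list(offsets = as.numeric(offsets),
                 scalings = as.numeric(scalings),
                 rotations = as.numeric(rotations),
                 convention = "scale;rotate x->y->z;translate"),
            class = "plane_transform")
}

rotation_matrix <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Apply a plane transform to image landmarks
#'
#' @param points matrix or data frame with columns `row`, `col` (image
#'   coordinates on the plane).
#' @param tf a [plane_transform()].
#' @return numeric matrix n x 3 of volume coordinates (x, y, z).
#' @export
apply_plane_transform <- function(points, tf) {
  points <- as.data.frame(points)
  p <- rbind(x = points$col, y = points$row, z = 0)
  p <- p * tf$scalings
  t(rotation_matrix(tf$rotations) %*% p + tf$offsets)
}

tf_to_par <- function(tf) c(tf$offsets, log(tf$scalings), tf$rotations)
par_to_tf <- function(par) {
  plane_transform(offsets = par[1:3], scalings = exp(par[4:6]),
                  rotations = ((par[7:9] + 180) %% 360) - 180)
}

# exact Euclidean distance transform to each boundary class, once per volume
class_distance_fields <- function(volume, classes) {
  bnd <- boundary_voxels(volume)
  d <- volume$dims
  lapply(setNames(classes, classes), function(cl) {
    b <- bnd[bnd$class == cl, ]
    if (nrow(b) == 0) return(NULL)
    mask <- array(1, d)
    mask[cbind(b$x, b$y, b$z)] <- 0
    array(as.numeric(EBImage::distmap(mask, metric = "euclidean")), d)
  })
}

# trilinear interpolation of a 3-D field; out-of-grid points are clamped and
# the clamping distance added (keeps the cost finite and increasing outward)
interp3 <- function(field, P) {
  d <- dim(field)
  Pc <- pmin(pmax(P, 1), matrix(d, nrow(P), 3, byrow = TRUE))
  pen <- sqrt(rowSums((P - Pc)^2))
  i0 <- pmin(floor(Pc), matrix(d - 1L, nrow(P), 3, byrow = TRUE))
  fr <- Pc - i0
  val <- numeric(nrow(P))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
      (if (dy) fr[, 2] else 1 - fr[, 2]) *
      (if (dz) fr[, 3] else 1 - fr[, 3])
    val <- val + w * field[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  val + pen
}

# landmark cost: summed distance to the nearest matching-class boundary voxel
registration_cost <- function(par, landmarks, dist_fields) {
  tf <- par_to_tf(par)
  pts <- apply_plane_transform(landmarks, tf)
  total <- 0
  for (cl in names(dist_fields)) {
    sel <- landmarks$class == cl
    if (!any(sel)) next
    total <- total + sum(interp3(dist_fields[[cl]],
                                 pts[sel, , drop = FALSE]))
  }
  total
}

#' Register a 2-D imaging plane into a 3-D label volume
#'
#' Nelder-Mead simplex optimization of the 9 plane parameters (3 offsets,
#' 3 log-scalings, 3 rotations), minimizing the summed Euclidean distance
#' from each transformed landmark to the nearest boundary voxel of its
#' class (evaluated through precomputed exact distance transforms of each
#' boundary class, trilinearly interpolated). Multi-start: `n_starts`
#' simplex runs from `init` and seeded perturbations of it, best result
#' kept. Note the scaling along the plane normal is not constrained by
#' in-plane landmarks; interpret recovered offsets/rotations, not the
#' normal scale.
#'
#' @param landmarks tibble (`row`, `col`, `class`) with classes among those
#'   of [boundary_voxels()].
#' @param volume a `label_volume`.
#' @param init initial [plane_transform()].
#' @param n_starts number of simplex starts (default 5).
#' @param maxit simplex iterations per start.
#' @param seed RNG seed for the start perturbations.
#' @return list: `transform` (best [plane_transform()]), `residual` (final
#'   cost), `mean_residual` (per landmark), `converged`.
#' @export
register_plane <- function(landmarks, volume, init = plane_transform(),
                           n_starts = 5, maxit = 1000, seed = 1L) {
  used <- unique(landmarks$class)
  dist_fields <- class_distance_fields(volume, used)
  missing <- used[vapply(dist_fields, is.null, logical(1))]
  if (length(missing) > 0) {
    abort(paste0("invalid volume: no boundary voxels for class ",
                 paste(missing, collapse = ", ")))
  }
  p0 <- tf_to_par(init)
  set.seed(seed)
  starts <- list(p0)
  for (i in seq_len(max(0, n_starts - 1))) {
    starts[[i + 1]] <- p0 + c(runif(3, -1, 1), runif(3, -0.03, 0.03),
                              runif(3, -3, 3))
  }
  ctrl <- list(maxit = maxit, reltol = 1e-12,
               parscale = c(rep(1, 3), rep(0.02, 3), rep(1, 3)))
  best <- NULL
  for (s in starts) {
    fit <- optim(s, registration_cost, landmarks = landmarks,
                 dist_fields = dist_fields, method = "Nelder-Mead",
                 control = ctrl)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # polish from the best start
  fit <- optim(best$par, registration_cost, landmarks = landmarks,
               dist_fields = dist_fields, method = "Nelder-Mead",
               control = ctrl)
  if (fit$value < best$value) best <- fit
  list(transform = par_to_tf(best$par), residual = best$value,
       mean_residual = best$value / nrow(landmarks),
       converged = best$convergence == 0)
}

#' Sample synthetic landmarks lying on class boundaries near a known plane
#'
#' Picks, per landmark class, boundary voxels lying within
#' `max_plane_dist` of the plane `z = 0` defined by a known transform, and
#' maps them back to image coordinates. Used to build registration test
#' problems with known ground truth.
#'
#' @param volume a `label_volume`.
#' @param tf the true [plane_transform()].
#' @param n_per_class landmarks per class.
#' @param max_plane_dist maximum distance (voxels) from the plane.
#' @param seed RNG seed.
#' @return tibble (`row`, `col`, `class`).
#' @export
simulate_plane_landmarks <- function(volume, tf, n_per_class = 12,
                                     max_plane_dist = 0.4, seed = 1L) {
  set.seed(seed)
  bnd <- boundary_voxels(volume)
  R <- rotation_matrix(tf$rotations)
  out <- purrr::map_dfr(unique(bnd$class), function(cl) {
    B <- as.matrix(bnd[bnd$class == cl, c("x", "y", "z")])
    local <- t(t(B) - tf$offsets) %*% R  # = R^-1 (B - t), rows
    near <- abs(local[, 3]) <= max_plane_dist
    if (!any(near)) return(NULL)
    idx <- which(near)
    if (length(idx) > n_per_class) {
      idx <- sample(idx, n_per_class)
    }
    tibble::tibble(row = local[idx, 2] / tf$scalings[2],
                   col = local[idx, 1] / tf$scalings[1],
                   class = cl)
  })
  out
}
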