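#' Simulate a 3-D label volume with landmark boundary classes
#'
#' A synthetic stand-in for an MRI-based label atlas: nested convex shapes
#' on an integer grid — an ellipsoidal brain whose outer rind is the cortex
#' shell, two ellipsoidal hippocampi, a central thalamus, remaining brain
#' labelled "other". Labels partition the grid (0 = background). Four
#' landmark boundary classes are derivable: outer cortex edge, inner cortex
#' edge, midline plane, and hippocampus (dentate) edges.
#'
#' @param dims integer (nx, ny, nz) grid size; axes are x = mediolateral,
#'   y = dorsoventral, z = anteroposterior.
#' @return a `label_volume`: list with `labels` (3-D integer array; 0
#'   background, 1 cortex, 2 hippocampus, 3 thalamus, 4 other) and `dims`.
#' @export
simulate_label_volume <- function(dims = c(48L, 40L, 40L)) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  ax <- 0.44 * nx; ay <- 0.44 * ny; az <- 0.44 * nz
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny), z = seq_len(nz))
  rho <- ((g$x - cx) / ax)^2 + ((g$y - cy) / ay)^2 + ((g$z - cz) / az)^2
  lab <- integer(nrow(g))
  brain <- rho <= 1
  lab[brain] <- 4L                       # other brain
  lab[brain & rho > 0.64] <- 1L          # cortex shell (outer 20% radius)
  hip <- function(sx) {
    ((g$x - (cx + sx * 0.22 * nx)) / (0.14 * nx))^2 +
      ((g$y - (cy + 0.08 * ny)) / (0.12 * ny))^2 +
      ((g$z - cz) / (0.26 * nz))^2 <= 1
  }
  hsel <- (hip(1) | hip(-1)) & lab == 4L
  lab[hsel] <- 2L
  tsel <- (((g$x - cx) / (0.18 * nx))^2 +
             ((g$y - (cy + 0.26 * ny)) / (0.13 * ny))^2 +
             ((g$z - cz) / (0.22 * nz))^2 <= 1) & lab == 4L
  lab[tsel] <- 3L
  structure(list(labels = array(lab, dim = dims), dims = as.integer(dims)),
            class = "label_volume")
}

# 6-neighbour adjacency test: voxels of `a` touching voxels of `b`
adjacent_to <- function(a, b) {
  d <- dim(a)
  shift <- function(m, dx, dy, dz) {
    out <- array(FALSE, d)
    xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
    xi <- xs - dx; yi <- ys - dy; zi <- zs - dz
    okx <- xi >= 1 & xi <= d[1]; oky <- yi >= 1 & yi <= d[2]
    okz <- zi >= 1 & zi <= d[3]
    out[xs[okx], ys[oky], zs[okz]] <- m[xi[okx], yi[oky], zi[okz]]
    out
  }
  nb <- shift(b, 1, 0, 0) | shift(b, -1, 0, 0) |
    shift(b, 0, 1, 0) | shift(b, 0, -1, 0) |
    shift(b, 0, 0, 1) | shift(b, 0, 0, -1)
  a & nb
}

#' Boundary voxels of a label volume, by landmark class
#'
#' Classes: `outer-cortex` (cortex voxels touching background),
#' `inner-cortex` (cortex voxels touching non-cortex brain), `midline`
#' (in-brain voxels on the mid-sagittal plane), `dentate-gyrus-edge`
#' (hippocampus voxels touching non-hippocampus tissue).
#'
#' @param volume a `label_volume`.
#' @return tibble (`x`, `y`, `z`, `class`), voxel-centre coordinates.
#' @export
boundary_voxels <- function(volume) {
  lab <- volume$labels
  bg <- lab == 0L
  ctx <- lab == 1L
  hip <- lab == 2L
  brain <- lab > 0L
  classes <- list(
    "outer-cortex" = adjacent_to(ctx, bg),
    "inner-cortex" = adjacent_to(ctx, brain & !ctx),
    "dentate-gyrus-edge" = adjacent_to(hip, brain & !hip)
  )
  nx <- dim(lab)[1]
  mid <- array(FALSE, dim(lab))
  mid[ceiling(nx / 2), , ] <- TRUE
  classes[["midline"]] <- brain & mid
  purrr::map_dfr(names(classes), function(cl) {
    w <- which(classes[[cl]], arr.ind = TRUE)
    tibble::tibble(x = w[, 1], y = w[, 2], z = w[, 3], class = cl)
  })
}

#' Extract an axis-aligned 2-D slice of a label volume
#'
#' @param volume a `label_volume`.
#' @param axis which axis to slice across (1 = x, 2 = y, 3 = z).
#' @param index slice index along that axis.
#' @return 2-D integer label matrix.
#' @export
slice_volume <- function(volume, axis = 3L, index) {
  lab <- volume$labels
  switch(axis,
         `1` = lab[index, , ],
         `2` = lab[, index, ],
         `3` = lab[, , index])
}
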