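#' Simulate a complex IQ frame stack with separable tissue/blood/noise
#'
#' Builds a voxels x frames complex matrix as the sum of a low-rank,
#' high-energy "tissue clutter" component, a spatially sparse "blood"
#' component with decorrelated time courses, and white noise. The three
#' components are given mutually orthogonal temporal subspaces (disjoint
#' columns of one random unitary basis), so their energies add exactly and
#' the blood ground truth is unambiguous. This is a statistical stand-in for
#' beamformed ultrafast compound Doppler data, not an acoustic simulation.
#'
#' @param n_vox number of voxels (flattened).
#' @param n_frames number of frames; must exceed `tissue_rank` plus the
#'   blood temporal dimension.
#' @param tissue_rank rank of the clutter component.
#' @param tissue_amp leading tissue singular value (clutter energy scale).
#' @param blood_amp per-voxel blood amplitude scale.
#' @param blood_frac fraction of voxels carrying blood signal.
#' @param noise_amp white-noise amplitude.
#' @param seed RNG seed.
#' @return list: `iq` (complex matrix voxels x frames), `blood_truth`
#'   (per-voxel mean squared magnitude of the blood component alone),
#'   `tissue_rank`, and exact `energies` (tissue, blood, noise).
#' @export
simulate_iq_stack <- function(n_vox = 1024, n_frames = 200, tissue_rank = 5,
                              tissue_amp = 100, blood_amp = 1,
                              blood_frac = 0.1, noise_amp = 0.02,
                              seed = 1L) {
  blood_dim <- n_frames - tissue_rank - 10L
  if (blood_dim < 1) {
    abort("n_frames must exceed tissue_rank + blood temporal dimension")
  }
  blood_dim <- min(60L, blood_dim)
  set.seed(seed)
  cnorm <- function(n) complex(real = rnorm(n), imaginary = rnorm(n)) / sqrt(2)

  # one random unitary temporal basis, columns split between components
  V <- qr.Q(qr(matrix(cnorm(n_frames * n_frames), n_frames, n_frames)))
  V_t <- V[, seq_len(tissue_rank), drop = FALSE]
  V_b <- V[, tissue_rank + seq_len(blood_dim), drop = FALSE]
  V_n <- V[, (tissue_rank + blood_dim + 1L):n_frames, drop = FALSE]

  U_t <- qr.Q(qr(matrix(cnorm(n_vox * tissue_rank), n_vox, tissue_rank)))
  s <- tissue_amp * exp(-0.4 * (seq_len(tissue_rank) - 1L))
  tissue <- U_t %*% (s * Conj(t(V_t)))

  mask <- rbinom(n_vox, 1, blood_frac) == 1
  A_b <- matrix(cnorm(n_vox * blood_dim), n_vox, blood_dim) * blood_amp
  A_b[!mask, ] <- 0
  blood <- A_b %*% Conj(t(V_b))

  A_n <- matrix(cnorm(n_vox * ncol(V_n)), n_vox, ncol(V_n)) * noise_amp
  noise <- A_n %*% Conj(t(V_n))

  iq <- tissue + blood + noise
  list(iq = iq,
       blood_truth = rowMeans(Mod(blood)^2),
       tissue_rank = tissue_rank,
       energies = c(tissue = sum(Mod(tissue)^2),
                    blood = sum(Mod(blood)^2),
                    noise = sum(Mod(noise)^2)))
}
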