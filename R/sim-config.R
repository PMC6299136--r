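#' Configuration for the synthetic multimodal recording generator
#'
#' Collects every tunable of the generator: recording geometry and rates,
#' the semi-Markov sleep-state chain, gamma-burst statistics during REM, the
#' hemodynamic kernel linking burst power to delayed CBV responses, per-state
#' CBV offsets, and noise levels. Defaults describe a typical head-free rat
#' sleep session: wake-dominated onset, NREM/REM cycling with a brief
#' awakening after each REM bout, fast-gamma bursts (80-110 Hz) during REM
#' driving brain-wide vascular surges through a lagged gamma-variate kernel,
#' and a thalamus < hippocampus < cortex ordering of hemodynamic lags.
#'
#' @param seed integer RNG seed; the whole simulation is a deterministic
#'   function of the config including this seed.
#' @param duration_s recording length, seconds.
#' @param lfp_rate,cbv_rate sampling rates (Hz) of electrophysiology and of
#'   the Doppler movie.
#' @param grid_shape integer (rows, cols) of the imaging grid.
#' @param state_dwell_means named numeric, mean dwell time (s) per state
#'   (QW, AW, NREM, REM) of the semi-Markov chain.
#' @param min_dwell_s floor on dwell times, seconds (shifted-exponential law).
#' @param initial_qw_s length of the opening quiet-wake bout, seconds;
#'   recordings start awake so the 3-min quiet-wake baseline exists.
#' @param rem_wake_after_s length of the brief awakening inserted after each
#'   REM bout, seconds.
#' @param allowed_states character subset of the four states to use.
#' @param burst_rate_rem gamma bursts per minute of REM.
#' @param burst_rate_aw distractor burst rate per minute of active wake
#'   (default 0).
#' @param burst_band numeric (lo, hi) Hz of the burst carrier.
#' @param burst_sigma_s Gaussian temporal width (sigma, s) of one burst.
#' @param theta_freq theta carrier frequency, Hz.
#' @param coupling_gain percent CBV per unit normalized burst power.
#' @param kernel_lag_s named numeric, hemodynamic kernel peak delay (s) per
#'   region group (cortex, hippocampus, thalamus).
#' @param kernel_fwhm_s kernel full width at half maximum, seconds.
#' @param state_cbv_offsets data frame (state, group, offset_pct): mean CBV
#'   offset relative to quiet wake, percent, per state and region group.
#' @param noise_sd_lfp,noise_sd_cbv additive noise SDs (LFP units, % CBV).
#' @param emg_wake,emg_sleep EMG noise SD during wake / sleep.
#' @param ripple_rate_nrem ripple packets per minute of NREM.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1L,
                       duration_s = 900,
                       lfp_rate = 1000,
                       cbv_rate = 1,
                       grid_shape = c(40L, 40L),
                       state_dwell_means = c(QW = 60, AW = 40,
                                             NREM = 120, REM = 60),
                       min_dwell_s = 10,
                       initial_qw_s = 200,
                       rem_wake_after_s = 15,
                       allowed_states = c("QW", "AW", "NREM", "REM"),
                       burst_rate_rem = 4,
                       burst_rate_aw = 0,
                       burst_band = c(80, 110),
                       burst_sigma_s = 0.15,
                       theta_freq = 8,
                       coupling_gain = 30,
                       kernel_lag_s = c(cortex = 1.7, hippocampus = 1.5,
                                        thalamus = 1.3),
                       kernel_fwhm_s = 3,
                       state_cbv_offsets = default_state_offsets(),
                       noise_sd_lfp = 0.1,
                       noise_sd_cbv = 2,
                       emg_wake = 1,
                       emg_sleep = 0.1,
                       ripple_rate_nrem = 6) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    abort("invalid config: duration_s must be strictly positive")
  }
  if (lfp_rate <= 0 || cbv_rate <= 0) {
    abort("invalid config: sampling rates must be strictly positive")
  }
  if (any(state_dwell_means <= 0)) {
    abort("invalid config: dwell means must be strictly positive")
  }
  if (coupling_gain < 0) abort("invalid config: coupling_gain must be >= 0")
  if (any(kernel_lag_s < 0)) abort("invalid config: kernel_lag_s must be >= 0")
  states <- c("QW", "AW", "NREM", "REM")
  if (!all(allowed_states %in% states) || length(allowed_states) == 0) {
    abort("invalid config: allowed_states must be a subset of QW/AW/NREM/REM")
  }
  groups <- c("cortex", "hippocampus", "thalamus")
  need <- expand.grid(state = states, group = groups,
                      stringsAsFactors = FALSE)
  have <- paste(state_cbv_offsets$state, state_cbv_offsets$group)
  if (!all(paste(need$state, need$group) %in% have)) {
    abort("invalid config: state_cbv_offsets must cover every state x group")
  }
  if (!setequal(names(kernel_lag_s), groups)) {
    abort("invalid config: kernel_lag_s needs cortex/hippocampus/thalamus")
  }
  structure(list(
    seed = as.integer(seed), duration_s = duration_s, lfp_rate = lfp_rate,
    cbv_rate = cbv_rate, grid_shape = as.integer(grid_shape),
    state_dwell_means = state_dwell_means, min_dwell_s = min_dwell_s,
    initial_qw_s = initial_qw_s, rem_wake_after_s = rem_wake_after_s,
    allowed_states = allowed_states, burst_rate_rem = burst_rate_rem,
    burst_rate_aw = burst_rate_aw, burst_band = burst_band,
    burst_sigma_s = burst_sigma_s, theta_freq = theta_freq,
    coupling_gain = coupling_gain, kernel_lag_s = kernel_lag_s,
    kernel_fwhm_s = kernel_fwhm_s,
    state_cbv_offsets = tibble::as_tibble(state_cbv_offsets),
    noise_sd_lfp = noise_sd_lfp, noise_sd_cbv = noise_sd_cbv,
    emg_wake = emg_wake, emg_sleep = emg_sleep,
    ripple_rate_nrem = ripple_rate_nrem
  ), class = "sim_config")
}

#' Default per-state, per-group CBV offsets (% vs quiet wake)
#'
#' Quiet wake is the reference (0). Active wake sits ~+6% (slightly lower in
#' thalamus), NREM matches baseline with a mildly hypoactive thalamus, and
#' tonic REM matches active-wake levels; surges ride on top of the REM
#' offset through the burst-coupling pathway.
#'
#' @return tibble with columns `state`, `group`, `offset_pct`.
#' @export
default_state_offsets <- function() {
  tibble::tribble(
    ~state, ~group,        ~offset_pct,
    "QW",   "cortex",       0,
    "QW",   "hippocampus",  0,
    "QW",   "thalamus",     0,
    "AW",   "cortex",       6,
    "AW",   "hippocampus",  6,
    "AW",   "thalamus",     5,
    "NREM", "cortex",       0,
    "NREM", "hippocampus",  0,
    "NREM", "thalamus",    -2,
    "REM",  "cortex",       5,
    "REM",  "hippocampus",  6,
    "REM",  "thalamus",     6
  )
}

# deterministic per-component RNG sub-streams derived from the config seed
sim_seed <- function(config, component) {
  offs <- c(hypnogram = 11L, lfp = 23L, cbv = 37L, iq = 51L,
            labels = 67L, landmarks = 83L, bursts = 97L)
  (config$seed %% 100000L) * 1000L + offs[[component]]
}
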