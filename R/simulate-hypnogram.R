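#' Simulate a sleep-state sequence (hypnogram)
#'
#' Draws a semi-Markov chain over quiet wake (QW), active wake (AW), NREM and
#' REM sleep. Dwell times follow a shifted exponential (floor
#' `min_dwell_s`); REM is only entered from NREM and is always followed by a
#' brief awakening, mirroring the robust post-REM arousal seen in rodent
#' sleep. The recording opens with a quiet-wake bout of at least
#' `initial_qw_s` so a quiet-wake normalization baseline always exists.
#'
#' @param config a [sim_config()].
#' @return hypnogram tibble with columns `start_s`, `end_s`, `state`;
#'   half-open intervals partitioning `[0, duration_s)`.
#' @export
simulate_hypnogram <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$duration_s < min(config$state_dwell_means[config$allowed_states])) {
    abort("invalid config: duration shorter than one mean dwell")
  }
  set.seed(sim_seed(config, "hypnogram"))
  allowed <- config$allowed_states
  trans <- list(
    QW   = c(AW = 0.5, NREM = 0.5),
    AW   = c(QW = 0.5, NREM = 0.5),
    NREM = c(REM = 0.5, QW = 0.25, AW = 0.25),
    REM  = c(QW = 1)  # brief awakening, forced
  )
  draw_dwell <- function(state) {
    m <- config$state_dwell_means[[state]]
    f <- config$min_dwell_s
    if (m <= f) return(m)
    f + rexp(1, rate = 1 / (m - f))
  }
  next_state <- function(state) {
    p <- trans[[state]]
    p <- p[names(p) %in% allowed]
    if (length(p) == 0) return(NA_character_)
    sample(names(p), 1L, prob = p)
  }

  t <- 0
  cur <- if ("QW" %in% allowed) "QW" else allowed[1]
  start <- numeric()
  end <- numeric()
  state <- character()
  first <- TRUE
  post_rem <- FALSE
  while (t < config$duration_s) {
    dwell <- if (post_rem) {
      config$rem_wake_after_s
    } else if (first && cur == "QW") {
      max(config$initial_qw_s, draw_dwell(cur))
    } else {
      draw_dwell(cur)
    }
    first <- FALSE
    e <- min(t + dwell, config$duration_s)
    start <- c(start, t)
    end <- c(end, e)
    state <- c(state, cur)
    t <- e
    post_rem <- cur == "REM" && "QW" %in% allowed
    nxt <- next_state(cur)
    if (is.na(nxt)) {
      # absorbing: extend current state to the end
      if (t < config$duration_s) {
        start <- c(start, t); end <- c(end, config$duration_s)
        state <- c(state, cur)
        t <- config$duration_s
      }
      break
    }
    cur <- if (post_rem) "QW" else nxt
  }
  hyp <- tibble::tibble(start_s = start, end_s = end, state = state)
  # merge consecutive identical states
  merge_hypnogram(hyp)
}

#' Build a deterministic REM-cycling hypnogram
#'
#' A fixed state schedule for controlled coupling and surge studies: an
#' opening quiet-wake baseline bout and an active-wake bout (the reference
#' distribution for activation thresholds), then `n_episodes` cycles of
#' NREM -> REM -> brief quiet wake.
#'
#' @param n_episodes number of NREM/REM cycles.
#' @param qw_s opening quiet-wake duration, seconds.
#' @param aw_s active-wake bout duration, seconds.
#' @param nrem_s,rem_s,wake_s cycle segment durations, seconds.
#' @return hypnogram tibble.
#' @export
rem_cycle_hypnogram <- function(n_episodes = 10, qw_s = 200, aw_s = 60,
                                nrem_s = 40, rem_s = 60, wake_s = 15) {
  seg <- tibble::tibble(
    state = c("QW", "AW", rep(c("NREM", "REM", "QW"), n_episodes)),
    dur = c(qw_s, aw_s, rep(c(nrem_s, rem_s, wake_s), n_episodes))
  )
  e <- cumsum(seg$dur)
  tibble::tibble(start_s = c(0, head(e, -1)), end_s = e, state = seg$state)
}

#' Merge consecutive identical-state intervals of a hypnogram
#'
#' @param hyp hypnogram tibble (`start_s`, `end_s`, `state`).
#' @return hypnogram tibble with adjacent same-state intervals fused.
#' @export
merge_hypnogram <- function(hyp) {
  if (nrow(hyp) <= 1) return(hyp)
  keep <- c(TRUE, hyp$state[-1] != hyp$state[-nrow(hyp)] |
              abs(hyp$start_s[-1] - hyp$end_s[-nrow(hyp)]) > 1e-9)
  grp <- cumsum(keep)
  hyp |>
    dplyr::mutate(.grp = grp) |>
    dplyr::group_by(.data$.grp) |>
    dplyr::summarise(start_s = min(.data$start_s), end_s = max(.data$end_s),
                     state = dplyr::first(.data$state), .groups = "drop") |>
    dplyr::select("start_s", "end_s", "state") |>
    dplyr::arrange(.data$start_s)
}

#' Total duration per state of a hypnogram
#' @param hyp hypnogram tibble.
#' @return tibble (`state`, `seconds`).
#' @export
hypnogram_durations <- function(hyp) {
  hyp |>
    dplyr::mutate(seconds = .data$end_s - .data$start_s) |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(seconds = sum(.data$seconds), .groups = "drop")
}
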