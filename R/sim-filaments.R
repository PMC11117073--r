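#' Simulate a population of growing actin filaments
#'
#' Generates per-filament length-vs-time tracks, sampled on the imaging grid,
#' from a continuous-time jump process over plus-end states. Between jumps a
#' filament grows linearly at `state_growth_rate * actin_conc / 370` um/s;
#' visits to `iqgap1_paused` last a Gaussian-distributed time (truncated at 0)
#' rather than an exponential one, matching the observed pause-duration
#' distribution. Sampled lengths carry additive Gaussian localization noise.
#' The ground-truth state intervals are returned alongside the tracks so that
#' downstream estimators can be validated by parameter recovery.
#'
#' @param config A [sim_config()].
#' @param n_filaments Number of filaments to simulate (>= 1).
#' @param seed Optional integer seed; falls back to `config$seed`. When `NULL`
#'   the current RNG state is used.
#' @param condition Condition label attached to every track.
#' @param n_fov Number of fields of view; filaments are assigned uniformly.
#' @param initial_state State of every plus end at nucleation.
#' @param nucleate_at Optional fixed nucleation time(s) in seconds (recycled
#'   to `n_filaments`). By default nucleation times are drawn uniformly over
#'   `[0, movie_duration - 4 * frame_interval]` so filaments appear
#'   throughout the movie and every track has at least four samples.
#'
#' @return An object of class `filament_sim`: a list with
#'   * `tracks`: tibble with columns `filament_id`, `fov_id`, `time` (s),
#'     `length` (um), `condition`;
#'   * `events`: tibble of ground-truth state intervals with columns
#'     `filament_id`, `state`, `start`, `end` (s), tiling each filament's
#'     lifetime from nucleation to movie end;
#'   * `config`: the configuration used.
#' @export
#' @examples
#' cfg <- sim_config(length_noise_sd = 0,
#'                   transition_rates = c("free->iqgap1_paused" = 0.004))
#' sim <- simulate_filaments(cfg, n_filaments = 5, seed = 1)
#' head(sim$tracks)
simulate_filaments <- function(config, n_filaments, seed = NULL,
                               condition = "control", n_fov = 1,
                               initial_state = "free", nucleate_at = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(n_filaments) || n_filaments < 1) {
    abort("`n_filaments` must be >= 1.", class = "plusend_domain_error")
  }
  n_filaments <- as.integer(n_filaments)
  if (!initial_state %in% end_states()) {
    abort("`initial_state` must be one of end_states().",
          class = "plusend_domain_error")
  }
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)

  dt <- config$frame_interval
  dur <- config$movie_duration
  frames <- seq(0, dur, by = dt)
  speeds <- config$state_growth_rates * config$actin_conc /
    ACTIN_SUBUNITS_PER_UM  # um/s per state

  if (is.null(nucleate_at)) {
    t0s <- runif(n_filaments, 0, max(dur - 4 * dt, 0))
  } else {
    t0s <- rep_len(nucleate_at, n_filaments)
    if (any(t0s < 0 | t0s > dur - dt)) {
      abort("`nucleate_at` must lie within [0, movie_duration - frame_interval].",
            class = "plusend_domain_error")
    }
  }
  fovs <- sprintf("FOV-%d", sample.int(n_fov, n_filaments, replace = TRUE))

  tracks <- vector("list", n_filaments)
  events <- vector("list", n_filaments)
  for (i in seq_len(n_filaments)) {
    id <- sprintf("fil-%04d", i)
    ev <- simulate_end_states(config, t0s[i], initial_state)
    ft <- frames[frames >= t0s[i]]
    # cumulative growth at event boundaries, linear in between
    grow <- cumsum(speeds[ev$state] * (ev$end - ev$start))
    knots_t <- c(ev$start[1], ev$end)
    knots_l <- c(0, grow)
    len <- stats::approx(knots_t, knots_l, xout = ft, rule = 2)$y
    if (config$length_noise_sd > 0) {
      len <- len + rnorm(length(len), 0, config$length_noise_sd)
    }
    tracks[[i]] <- tibble(
      filament_id = id, fov_id = fovs[i], time = ft,
      length = pmax(len, 0), condition = condition
    )
    events[[i]] <- tibble(filament_id = id, state = ev$state,
                          start = ev$start, end = ev$end)
  }

  structure(
    list(tracks = bind_rows(tracks), events = bind_rows(events),
         config = config),
    class = "filament_sim"
  )
}

# One filament's jump process from nucleation to movie end.
simulate_end_states <- function(config, t0, initial_state) {
  dur <- config$movie_duration
  trans <- config$transition_rates
  state <- initial_state
  t <- t0
  out_state <- character()
  out_start <- numeric()
  out_end <- numeric()
  while (t < dur) {
    if (state == "iqgap1_paused") {
      dwell <- rnorm_truncated(config$pause_duration_mean,
                               config$pause_duration_sd)
      nxt <- next_state_weighted(trans, state, default = "free")
    } else {
      outgoing <- trans[trans$from == state, , drop = FALSE]
      total <- sum(outgoing$rate)
      if (total <= 0) {
        dwell <- Inf
        nxt <- state
      } else {
        dwell <- rexp(1, total)
        nxt <- sample(outgoing$to, 1, prob = outgoing$rate)
      }
    }
    t_end <- min(t + dwell, dur)
    out_state <- c(out_state, state)
    out_start <- c(out_start, t)
    out_end <- c(out_end, t_end)
    t <- t_end
    state <- nxt
  }
  tibble(state = out_state, start = out_start, end = out_end)
}

# Gaussian truncated at zero by rejection (negative draws resampled).
rnorm_truncated <- function(mean, sd) {
  repeat {
    x <- rnorm(1, mean, sd)
    if (x > 0) return(x)
  }
}

next_state_weighted <- function(trans, state, default) {
  outgoing <- trans[trans$from == state, , drop = FALSE]
  if (nrow(outgoing) == 0 || sum(outgoing$rate) <= 0) return(default)
  sample(outgoing$to, 1, prob = outgoing$rate)
}

#' @export
print.filament_sim <- function(x, ...) {
  cat("<filament_sim>\n")
  cat(sprintf("  %d filaments, %d track rows, %d ground-truth events\n",
              dplyr::n_distinct(x$tracks$filament_id), nrow(x$tracks),
              nrow(x$events)))
  invisible(x)
}

#' Ground-truth pause durations from simulated end-state events
#'
#' Convenience extractor for the durations of `iqgap1_paused` visits in a
#' [simulate_filaments()] ground-truth ledger.
#'
#' @param events Tibble of state intervals (`filament_id`, `state`, `start`,
#'   `end`), as in `filament_sim$events`.
#' @param movie_duration Movie length in seconds; pauses running to the movie
#'   end are flagged as truncated.
#' @param complete_only Drop pauses truncated by the movie end (default TRUE).
#'
#' @return Tibble with `filament_id`, `start`, `end`, `duration`,
#'   `truncated_by_movie_end`.
#' @export
true_pauses <- function(events, movie_duration, complete_only = TRUE) {
  out <- events |>
    filter(.data$state == "iqgap1_paused") |>
    mutate(duration = .data$end - .data$start,
           truncated_by_movie_end = .data$end >= movie_duration) |>
    select("filament_id", "start", "end", "duration",
           "truncated_by_movie_end")
  if (complete_only) out <- filter(out, !.data$truncated_by_movie_end)
  out
}
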