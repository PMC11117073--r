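#' Configuration for the synthetic single-filament TIRF generator
#'
#' Collects and validates every knob of the filament simulator. Defaults are
#' calibrated to the conditions of the in vitro TIRF experiments the package
#' emulates: 1 uM actin imaged every 5 s, a free-end elongation rate of
#' 10.2 subunits s-1 uM-1, formin-driven rates of 7.6 (mDia1 alone) and 52.4
#' (mDia1 + profilin), non-growing capped/paused states, and IQGAP1 pauses
#' whose durations are Gaussian with mean 20.6 s and sd 5 s.
#'
#' @param frame_interval Imaging interval in seconds. Must be > 0.
#' @param movie_duration Movie length in seconds; at least
#'   `3 * frame_interval`.
#' @param actin_conc Actin monomer concentration in uM.
#' @param pixel_size Camera pixel size in um/pixel (metadata only; lengths are
#'   already in um).
#' @param length_noise_sd Additive localization noise on sampled lengths, um.
#' @param state_growth_rates Named numeric vector mapping each end state (see
#'   [end_states()]) to its growth rate in subunits s-1 uM-1. Capped, paused
#'   and decision-complex states must have rate 0.
#' @param transition_rates Named numeric vector of state transition rates in
#'   s-1, with names of the form `"from->to"`, e.g.
#'   `c("free->iqgap1_paused" = 0.004)`. `NULL` means no transitions.
#' @param pause_duration_mean,pause_duration_sd Mean and sd (seconds) of the
#'   Gaussian (truncated at 0) duration of `iqgap1_paused` visits.
#' @param seed Optional integer seed stored with the config; simulator
#'   functions use it unless given their own.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(transition_rates = c("free->iqgap1_paused" = 0.004))
#' cfg
sim_config <- function(frame_interval = 5,
                       movie_duration = 600,
                       actin_conc = 1,
                       pixel_size = 0.16,
                       length_noise_sd = 0.05,
                       state_growth_rates = c(
                         free = 10.2, formin = 7.6, formin_pfn1 = 52.4,
                         cp_capped = 0, decision_complex = 0,
                         iqgap1_paused = 0),
                       transition_rates = NULL,
                       pause_duration_mean = 20.6,
                       pause_duration_sd = 5,
                       seed = NULL) {
  check_positive_scalar(frame_interval, "frame_interval")
  check_positive_scalar(movie_duration, "movie_duration")
  check_positive_scalar(actin_conc, "actin_conc")
  check_positive_scalar(pixel_size, "pixel_size")
  if (!is.numeric(length_noise_sd) || length_noise_sd < 0) {
    abort("`length_noise_sd` must be a non-negative number.",
          class = "plusend_config_error")
  }
  if (movie_duration < 3 * frame_interval) {
    abort("`movie_duration` must be at least 3 * `frame_interval`.",
          class = "plusend_config_error")
  }

  states <- end_states()
  if (is.null(names(state_growth_rates)) ||
      !all(names(state_growth_rates) %in% states)) {
    abort(paste0("`state_growth_rates` must be named with states among: ",
                 paste(states, collapse = ", "), "."),
          class = "plusend_config_error")
  }
  full_rates <- setNames(numeric(length(states)), states)
  full_rates[names(state_growth_rates)] <- state_growth_rates
  if (any(full_rates < 0)) {
    abort("`state_growth_rates` must be non-negative.",
          class = "plusend_config_error")
  }
  bad <- intersect(names(full_rates)[full_rates > 0], nongrowing_states())
  if (length(bad)) {
    abort(paste0("`state_growth_rates`: non-growing state(s) must have rate ",
                 "0: ", paste(bad, collapse = ", "), "."),
          class = "plusend_config_error")
  }

  trans <- parse_transition_rates(transition_rates, states)

  check_positive_scalar(pause_duration_mean, "pause_duration_mean")
  check_positive_scalar(pause_duration_sd, "pause_duration_sd")

  structure(
    list(
      frame_interval = frame_interval,
      movie_duration = movie_duration,
      actin_conc = actin_conc,
      pixel_size = pixel_size,
      length_noise_sd = length_noise_sd,
      state_growth_rates = full_rates,
      transition_rates = trans,
      pause_duration_mean = pause_duration_mean,
      pause_duration_sd = pause_duration_sd,
      seed = seed
    ),
    class = "sim_config"
  )
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(paste0("`", name, "` must be a single positive number."),
          class = "plusend_config_error")
  }
  invisible(x)
}

# "from->to" named vector -> tibble(from, to, rate)
parse_transition_rates <- function(transition_rates, states) {
  if (is.null(transition_rates) || length(transition_rates) == 0) {
    return(tibble(from = character(), to = character(), rate = numeric()))
  }
  nm <- names(transition_rates)
  if (is.null(nm) || !all(grepl("->", nm, fixed = TRUE))) {
    abort("`transition_rates` must be named like \"from->to\".",
          class = "plusend_config_error")
  }
  parts <- strsplit(nm, "->", fixed = TRUE)
  out <- tibble(
    from = vapply(parts, function(p) trimws(p[1]), character(1)),
    to = vapply(parts, function(p) trimws(p[2]), character(1)),
    rate = as.numeric(transition_rates)
  )
  if (!all(c(out$from, out$to) %in% states)) {
    abort(paste0("`transition_rates`: unknown state name; states are: ",
                 paste(states, collapse = ", "), "."),
          class = "plusend_config_error")
  }
  if (any(!is.finite(out$rate) | out$rate < 0)) {
    abort("`transition_rates` must be finite and non-negative.",
          class = "plusend_config_error")
  }
  if (any(out$from == out$to)) {
    abort("`transition_rates` must not contain self-transitions.",
          class = "plusend_config_error")
  }
  out
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  frame interval: %g s, movie: %g s, actin: %g uM\n",
              x$frame_interval, x$movie_duration, x$actin_conc))
  cat(sprintf("  length noise sd: %g um, pixel size: %g um\n",
              x$length_noise_sd, x$pixel_size))
  cat("  growth rates (subunits/s/uM):",
      paste(sprintf("%s=%g", names(x$state_growth_rates),
                    x$state_growth_rates), collapse = ", "), "\n")
  if (nrow(x$transition_rates)) {
    cat("  transitions (/s):",
        paste(sprintf("%s->%s=%g", x$transition_rates$from,
                      x$transition_rates$to, x$transition_rates$rate),
              collapse = ", "), "\n")
  } else {
    cat("  transitions: none\n")
  }
  cat(sprintf("  pause duration ~ N(%g, %g^2) s truncated at 0\n",
              x$pause_duration_mean, x$pause_duration_sd))
  invisible(x)
}
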