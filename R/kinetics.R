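#' Per-filament actin elongation rates
#'
#' Fits an ordinary least-squares slope (um/s) to each filament's
#' length-vs-time track and converts it to a subunit addition rate with the
#' 370 subunits/um linear density of the actin filament:
#' `rate = slope * 370 / actin_conc`, in subunits s-1 uM-1.
#'
#' With `exclude_pauses = TRUE` the fit estimates the growth-phase rate:
#' frames interior to detected pauses (see [detect_pauses()]) are dropped and
#' the remaining time axis is collapsed by the cumulative paused duration, so
#' stalled intervals contribute neither points nor dead time to the slope.
#' The default (`FALSE`) fits the whole track, which is what makes mean rates
#' drop when a pausing factor such as IQGAP1 is present.
#'
#' @param tracks Tibble of tracks with columns `filament_id`, `time`,
#'   `length` (and optionally `fov_id`, `condition`), e.g.
#'   `simulate_filaments(...)$tracks`. Every filament needs at least 4
#'   samples.
#' @param actin_conc Actin concentration in uM (> 0).
#' @param exclude_pauses Estimate the growth-phase rate (see Details).
#' @param stall_epsilon,min_frames Pause-detection parameters, passed to
#'   [detect_pauses()] when `exclude_pauses = TRUE`.
#'
#' @return Tibble with one row per filament: `filament_id`, `slope` (um/s),
#'   `rate` (subunits s-1 uM-1), `n_points`, `fit_r2`. A filament paused for
#'   its entire observed span has no growth phase; with
#'   `exclude_pauses = TRUE` its `slope` and `rate` are `NA`.
#' @export
#' @examples
#' tr <- tibble::tibble(filament_id = "f1", time = seq(0, 20, 5),
#'                      length = seq(0, 2, 0.5))
#' elongation_rates(tr, actin_conc = 1)  # slope 0.1 um/s -> rate 37
elongation_rates <- function(tracks, actin_conc = 1, exclude_pauses = FALSE,
                             stall_epsilon = 0.1, min_frames = 3) {
  tracks <- check_tracks(tracks)
  if (!is.numeric(actin_conc) || length(actin_conc) != 1 || actin_conc <= 0) {
    abort("`actin_conc` must be a single positive number (uM).",
          class = "plusend_domain_error")
  }
  counts <- dplyr::count(tracks, .data$filament_id)
  short <- counts$filament_id[counts$n < 4]
  if (length(short)) {
    abort(paste0("Elongation rates need >= 4 samples per filament; too few ",
                 "for: ", paste(utils::head(short, 5), collapse = ", "),
                 if (length(short) > 5) ", ..." else "", "."),
          class = "plusend_insufficient_data")
  }

  pauses <- if (exclude_pauses) {
    detect_pauses(tracks, stall_epsilon = stall_epsilon,
                  min_frames = min_frames)
  } else NULL

  tracks |>
    group_by(.data$filament_id) |>
    dplyr::group_modify(function(df, key) {
      t <- df$time
      l <- df$length
      if (!is.null(pauses)) {
        pp <- pauses[pauses$filament_id == key$filament_id, , drop = FALSE]
        if (nrow(pp)) {
          drop <- rep(FALSE, length(t))
          collapse <- numeric(length(t))
          for (j in seq_len(nrow(pp))) {
            drop <- drop | (t > pp$start[j] & t < pp$end[j])
            after <- t >= pp$end[j]
            collapse[after] <- collapse[after] + (pp$end[j] - pp$start[j])
          }
          t <- (t - collapse)[!drop]
          l <- l[!drop]
        }
      }
      fit <- ols_line(t, l)
      tibble(slope = fit$slope,
             rate = fit$slope * ACTIN_SUBUNITS_PER_UM / actin_conc,
             n_points = length(t), fit_r2 = fit$r2)
    }) |>
    ungroup()
}

# least-squares line with r2; r2 := 1 for a perfect (including flat) fit.
# Zero time variance (e.g. a filament paused for its whole observed span
# after pause collapsing) has no defined slope and returns NA.
ols_line <- function(t, l) {
  tm <- mean(t)
  lm_ <- mean(l)
  sxx <- sum((t - tm)^2)
  if (sxx <= .Machine$double.eps * max(1, tm^2)) {
    return(list(slope = NA_real_, r2 = NA_real_))
  }
  slope <- sum((t - tm) * (l - lm_)) / sxx
  ss_tot <- sum((l - lm_)^2)
  ss_res <- sum((l - lm_ - slope * (t - tm))^2)
  r2 <- if (ss_tot <= .Machine$double.eps * max(1, lm_^2)) 1 else
    1 - ss_res / ss_tot
  list(slope = slope, r2 = r2)
}

#' Detect pauses in filament elongation
#'
#' A frame-to-frame length increment smaller than `stall_epsilon` in absolute
#' value is "stalled"; every maximal run of at least `min_frames` consecutive
#' stalled increments becomes one pause event. This operationalises the
#' scoring rule of stalled elongation over at least three consecutive imaging
#' frames, giving a minimum resolvable pause of
#' `min_frames * frame_interval` (15 s at a 5-s interval). Two stalled runs
#' separated by at least one growing increment are distinct pauses. Runs that
#' reach the final frame are flagged `truncated_by_movie_end` (their full
#' duration is unknown).
#'
#' @param tracks Track tibble (`filament_id`, `time`, `length`).
#' @param stall_epsilon Stall tolerance in um per frame (> 0). The default
#'   0.1 um is about one pixel and well above sub-pixel localization noise.
#' @param min_frames Minimum number of consecutive stalled increments
#'   (>= 2); default 3.
#'
#' @return Tibble of pause events: `filament_id`, `start`, `end`, `duration`
#'   (s), `n_frames` (stalled increments), `truncated_by_movie_end`.
#' @export
#' @examples
#' tr <- tibble::tibble(filament_id = "f1", time = seq(0, 45, 5),
#'                      length = c(0, .5, 1, 1, 1, 1, 1.5, 2, 2.5, 3))
#' detect_pauses(tr)  # one 15-s pause
detect_pauses <- function(tracks, stall_epsilon = 0.1, min_frames = 3) {
  tracks <- check_tracks(tracks)
  check_positive_scalar(stall_epsilon, "stall_epsilon")
  if (!is.numeric(min_frames) || min_frames < 2) {
    abort("`min_frames` must be >= 2.", class = "plusend_domain_error")
  }

  tracks |>
    group_by(.data$filament_id) |>
    dplyr::group_modify(function(df, key) {
      df <- arrange(df, .data$time)
      t <- df$time
      stalled <- abs(diff(df$length)) < stall_epsilon
      if (!length(stalled)) return(empty_pause_tbl())
      r <- rle(stalled)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      keep <- r$values & r$lengths >= min_frames
      if (!any(keep)) return(empty_pause_tbl())
      i <- starts[keep]  # first stalled increment index
      j <- ends[keep]    # last stalled increment index
      tibble(
        start = t[i], end = t[j + 1],
        duration = t[j + 1] - t[i],
        n_frames = as.integer(j - i + 1),
        truncated_by_movie_end = (j + 1) == length(t)
      )
    }) |>
    ungroup()
}

empty_pause_tbl <- function() {
  tibble(start = numeric(), end = numeric(), duration = numeric(),
         n_frames = integer(), truncated_by_movie_end = logical())
}

#' Minimum resolvable pause duration
#'
#' The shortest pause the imaging setup can score: `frame_interval *
#' min_frames`. At the standard 5-s interval and the 3-frame rule this is
#' 15 s.
#'
#' @param frame_interval Imaging interval in seconds (> 0).
#' @param min_frames Minimum consecutive stalled frames (> 0).
#' @return Duration in seconds.
#' @export
#' @examples
#' min_resolvable_pause(5, 3)    # 15
#' min_resolvable_pause(3.2, 3)  # 9.6
min_resolvable_pause <- function(frame_interval, min_frames = 3) {
  check_positive_scalar(frame_interval, "frame_interval")
  check_positive_scalar(min_frames, "min_frames")
  frame_interval * min_frames
}

#' Count nucleated filaments per field of view
#'
#' The nucleation readout: the number of filaments present in each field of
#' view at `at_time` seconds after the start of polymerization. A filament
#' counts when its track has appeared (first sample at or before `at_time`)
#' and its length at `at_time` (last sample at or before it) is positive.
#'
#' @param tracks Track tibble with `filament_id`, `fov_id`, `time`, `length`.
#' @param at_time Query time in seconds (default 200).
#'
#' @return Tibble with `fov_id` and `n_filaments`.
#' @export
count_nucleation <- function(tracks, at_time = 200) {
  tracks <- check_tracks(tracks, need_fov = TRUE)
  tracks |>
    filter(.data$time <= at_time) |>
    group_by(.data$fov_id, .data$filament_id) |>
    summarise(len_at = .data$length[which.max(.data$time)],
              .groups = "drop") |>
    filter(.data$len_at > 0) |>
    dplyr::count(.data$fov_id, name = "n_filaments")
}

check_tracks <- function(tracks, need_fov = FALSE) {
  if (!is.data.frame(tracks)) {
    abort("`tracks` must be a data frame of filament tracks.",
          class = "plusend_domain_error")
  }
  need <- c("filament_id", "time", "length", if (need_fov) "fov_id")
  missing_cols <- setdiff(need, names(tracks))
  if (length(missing_cols)) {
    abort(paste0("`tracks` is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."),
          class = "plusend_domain_error")
  }
  as_tibble(tracks)
}
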