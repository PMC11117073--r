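#' Simulate step-photobleaching intensity traces
#'
#' Each molecule of an `n_oligomer`-mer carries `k ~ Binomial(n_oligomer,
#' p_label)` active fluorophores under partial labeling. Molecules with
#' `k = 0` are invisible and omitted, mirroring that only fluorescent spots
#' can be scored. A trace starts at `background + k * unit_step` and loses one
#' `unit_step` at each of `k` independent `Exponential(bleach_rate)` bleach
#' times, with additive Gaussian noise on every sample; the final plateau is
#' the background level.
#'
#' @param n_oligomer Oligomeric state being simulated (1 to 4).
#' @param p_label Labeling efficiency, in (0, 1].
#' @param n_molecules Number of molecules drawn (>= 1); the emitted number is
#'   smaller when some draw zero labels.
#' @param bleach_rate Photobleaching rate per fluorophore, s-1.
#' @param noise_sd Gaussian noise sd in the same arbitrary units as
#'   `unit_step`.
#' @param unit_step Intensity contributed by one fluorophore (a.u.).
#' @param background Background plateau intensity (a.u.).
#' @param duration Acquisition length in seconds.
#' @param frame_interval Sampling interval in seconds.
#' @param seed Optional integer seed.
#'
#' @return An object of class `bleach_sim`: list with
#'   * `traces`: tibble `molecule_id`, `time`, `intensity`;
#'   * `truth`: tibble `molecule_id`, `true_step_count`, `bleach_times`
#'     (list-column).
#' @export
#' @examples
#' sim <- simulate_bleach_traces(2, p_label = 0.7, n_molecules = 20, seed = 1)
#' table(sim$truth$true_step_count)
simulate_bleach_traces <- function(n_oligomer, p_label, n_molecules,
                                   bleach_rate = 0.05, noise_sd = 0.1,
                                   unit_step = 1, background = 0,
                                   duration = 120, frame_interval = 0.5,
                                   seed = NULL) {
  if (!is.numeric(n_oligomer) || length(n_oligomer) != 1 ||
      !n_oligomer %in% 1:4) {
    abort("`n_oligomer` must be an integer in 1..4.",
          class = "plusend_domain_error")
  }
  if (!is.numeric(p_label) || length(p_label) != 1 ||
      p_label <= 0 || p_label > 1) {
    abort("`p_label` must lie in (0, 1].", class = "plusend_domain_error")
  }
  if (!is.numeric(n_molecules) || n_molecules < 1) {
    abort("`n_molecules` must be >= 1.", class = "plusend_domain_error")
  }
  check_positive_scalar(bleach_rate, "bleach_rate")
  if (!is.null(seed)) set.seed(seed)

  k <- rbinom(as.integer(n_molecules), n_oligomer, p_label)
  k <- k[k > 0]  # invisible molecules are never scored
  times <- seq(0, duration, by = frame_interval)

  traces <- vector("list", length(k))
  bleach_times <- vector("list", length(k))
  for (i in seq_along(k)) {
    bt <- sort(rexp(k[i], bleach_rate))
    bleach_times[[i]] <- bt
    remaining <- k[i] - findInterval(times, bt)
    intensity <- background + unit_step * remaining
    if (noise_sd > 0) intensity <- intensity + rnorm(length(times), 0, noise_sd)
    traces[[i]] <- tibble(molecule_id = sprintf("mol-%05d", i),
                          time = times, intensity = intensity)
  }

  structure(
    list(
      traces = bind_rows(traces),
      truth = tibble(molecule_id = sprintf("mol-%05d", seq_along(k)),
                     true_step_count = as.integer(k),
                     bleach_times = bleach_times)
    ),
    class = "bleach_sim"
  )
}

#' @export
print.bleach_sim <- function(x, ...) {
  cat("<bleach_sim>\n")
  cat(sprintf("  %d visible molecules, %d samples per trace\n",
              nrow(x$truth),
              if (nrow(x$truth)) sum(x$traces$molecule_id ==
                                       x$truth$molecule_id[1]) else 0L))
  invisible(x)
}
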