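#' Tidy a distribution fit
#'
#' @param x A `dist_fit` from [fit_gaussian()] or [fit_exp_decay()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.dist_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params))
}

#' @rdname tidy.dist_fit
#' @return For `glance()`: a one-row tibble with `model`, `r2`, `n_events`,
#'   `n_bins`.
#' @export
glance.dist_fit <- function(x, ...) {
  tibble(model = x$model, r2 = x$r2, n_events = x$n_events,
         n_bins = nrow(x$data))
}

#' Tidy an oligomeric-state inference
#'
#' @param x An `oligomer_inference` from [infer_oligomer()].
#' @param ... Unused.
#' @return A tibble with one row per candidate state (`n`, `distance`,
#'   `best`).
#' @export
tidy.oligomer_inference <- function(x, ...) {
  mutate(x$candidates, best = .data$n == x$best_n)
}

#' @rdname tidy.oligomer_inference
#' @return For `glance()`: a one-row tibble with `best_n`, `tie`, `p_label`,
#'   `n_molecules`, `small_sample`.
#' @export
glance.oligomer_inference <- function(x, ...) {
  tibble(best_n = x$best_n, tie = x$tie, p_label = x$p_label,
         n_molecules = x$n_molecules, small_sample = x$small_sample)
}
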