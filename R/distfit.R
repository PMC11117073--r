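#' Frequency histogram of pause durations
#'
#' Bins durations into uniform bins of width `bin_width` starting at 0, the
#' form in which pause-duration distributions are displayed and fitted.
#'
#' @param durations Numeric vector of durations in seconds (all >= 0), or a
#'   data frame with a `duration` column (e.g. [detect_pauses()] output).
#' @param bin_width Bin width in seconds (default 5, one frame interval).
#'
#' @return A tibble of class `freq_hist` with columns `bin_left`,
#'   `bin_center`, `count`, `bin_width`. Counts sum to `length(durations)`.
#' @export
#' @examples
#' build_histogram(c(15, 15, 20, 25))
build_histogram <- function(durations, bin_width = 5) {
  if (is.data.frame(durations)) {
    if (!"duration" %in% names(durations)) {
      abort("data-frame input must have a `duration` column.",
            class = "plusend_domain_error")
    }
    durations <- durations$duration
  }
  if (!length(durations)) {
    abort("`durations` is empty; nothing to bin.",
          class = "plusend_insufficient_data")
  }
  if (any(!is.finite(durations) | durations < 0)) {
    abort("`durations` must be finite and >= 0.",
          class = "plusend_domain_error")
  }
  check_positive_scalar(bin_width, "bin_width")

  idx <- floor(durations / bin_width)  # bin 0 is [0, w)
  tab <- table(idx)
  lefts <- as.numeric(names(tab)) * bin_width
  all_lefts <- seq(0, max(lefts), by = bin_width)
  counts <- integer(length(all_lefts))
  counts[match(lefts, all_lefts)] <- as.integer(tab)
  out <- tibble(bin_left = all_lefts, bin_center = all_lefts + bin_width / 2,
                count = counts, bin_width = bin_width)
  class(out) <- c("freq_hist", class(out))
  out
}

#' Fit a Gaussian to a pause-duration histogram
#'
#' Nonlinear least squares of `A * exp(-0.5 * ((x - mean) / sd)^2)` to bin
#' counts, the model used for conditions whose pause durations are normally
#' distributed. Starting values are the weighted bin moments (amplitude = max
#' frequency), making the fit deterministic.
#'
#' @param hist A [build_histogram()] result (needs >= 4 bins with nonzero
#'   counts).
#'
#' @return An object of class `dist_fit` with elements `model`
#'   (`"gaussian"`), `params` (`A`, `mean`, `sd`), `r2`, `n_events`, `data`,
#'   `fitted`. `r2 = 1 - SSres/SStot` on the bin frequencies.
#' @export
#' @examples
#' h <- build_histogram(rnorm(400, 20.6, 5))
#' fit_gaussian(h)
fit_gaussian <- function(hist) {
  hist <- check_hist(hist)
  x <- hist$bin_center
  y <- hist$count
  w <- y / sum(y)
  mu0 <- sum(w * x)
  sd0 <- sqrt(max(sum(w * (x - mu0)^2), 1e-6))
  model <- function(p) p[1] * exp(-0.5 * ((x - p[2]) / p[3])^2)
  # the fitted mean is a duration: keep it inside the observed support, which
  # also blocks the degenerate far-tail solution that can mimic a decay
  p <- lm_fit(model, y, start = c(A = max(y), mean = mu0, sd = sd0),
              lower = c(0, 0, 1e-8),
              upper = c(Inf, max(x) + hist$bin_width[1], Inf),
              label = "Gaussian")
  new_dist_fit("gaussian", params = p, fitted = model(p), hist = hist)
}

#' Fit an exponential decay to a duration histogram
#'
#' Nonlinear least squares of `(Y0 - Dmax) * exp(-k * x) + Dmax` to bin
#' counts, the model that describes non-pausing conditions (durations of
#' apparent stalls are then dominated by short events and decay
#' monotonically). `k` is initialised from a log-linear fit to the first half
#' of the bins, `Y0` from the maximum frequency and `Dmax` from the tail
#' mean.
#'
#' @inheritParams fit_gaussian
#' @return An object of class `dist_fit` with `model = "exp_decay"` and
#'   `params` (`Y0`, `Dmax`, `k`).
#' @export
fit_exp_decay <- function(hist) {
  hist <- check_hist(hist)
  x <- hist$bin_center
  y <- hist$count
  n <- length(x)
  dmax0 <- mean(utils::tail(y, max(2, floor(n / 4))))
  half <- seq_len(max(3, floor(n / 2)))
  pos <- half[y[half] > dmax0]
  k0 <- if (length(pos) >= 2) {
    max(-ols_line(x[pos], log(y[pos] - dmax0 + 1e-9))$slope, 1e-3)
  } else 0.05
  model <- function(p) (p[1] - p[2]) * exp(-p[3] * x) + p[2]
  p <- lm_fit(model, y, start = c(Y0 = max(y), Dmax = dmax0, k = k0),
              lower = c(0, 0, 1e-8), upper = c(Inf, Inf, 100),
              label = "Exponential-decay")
  new_dist_fit("exp_decay", params = p, fitted = model(p), hist = hist)
}

# Levenberg-Marquardt least squares on a parameter vector.
lm_fit <- function(model, y, start, lower, upper, label) {
  fit <- try(minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper,
    fn = function(p) y - model(p),
    control = minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 5000)
  ), silent = TRUE)
  if (inherits(fit, "try-error") || !fit$info %in% 1:4) {
    msg <- if (inherits(fit, "try-error")) attr(fit, "condition")$message
           else fit$message
    abort(paste0(label, " fit failed to converge: ", msg),
          class = "plusend_fit_failure")
  }
  setNames(fit$par, names(start))
}

check_hist <- function(hist) {
  if (!inherits(hist, "freq_hist")) {
    if (is.data.frame(hist) &&
        all(c("bin_center", "count") %in% names(hist))) {
      hist <- as_tibble(hist)
    } else {
      abort("`hist` must be a freq_hist from build_histogram().",
            class = "plusend_domain_error")
    }
  }
  if (sum(hist$count > 0) < 4) {
    abort("Need at least 4 bins with nonzero counts to fit.",
          class = "plusend_insufficient_data")
  }
  hist
}

new_dist_fit <- function(model, params, fitted, hist) {
  y <- hist$count
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(
    list(model = model, params = params,
         r2 = 1 - ss_res / ss_tot, n_events = sum(y),
         data = hist, fitted = as.numeric(fitted)),
    class = "dist_fit"
  )
}

#' @export
print.dist_fit <- function(x, ...) {
  cat(sprintf("<dist_fit: %s>\n", x$model))
  cat("  ", paste(sprintf("%s = %.4g", names(x$params), x$params),
                  collapse = ", "), "\n")
  cat(sprintf("  r2 = %.4f on %d events in %d bins\n", x$r2, x$n_events,
              nrow(x$data)))
  invisible(x)
}

#' Compare Gaussian and exponential-decay fits by R-squared
#'
#' Side-by-side model comparison: the model with higher `r2` wins and the
#' margin is reported. Pausing conditions are expected to select the
#' Gaussian; non-pausing conditions the exponential decay. Equal `r2` is
#' flagged as a tie and no model is selected.
#'
#' @param gauss,decay `dist_fit` objects fitted to the same histogram.
#' @return One-row tibble: `model` (`"gaussian"`, `"exp_decay"`, or `NA` on a
#'   tie), `r2_gaussian`, `r2_exp_decay`, `delta_r2`, `tie`.
#' @export
select_model <- function(gauss, decay) {
  stopifnot(inherits(gauss, "dist_fit"), inherits(decay, "dist_fit"))
  if (gauss$n_events != decay$n_events ||
      nrow(gauss$data) != nrow(decay$data)) {
    abort("Both fits must be on the same histogram.",
          class = "plusend_domain_error")
  }
  d <- gauss$r2 - decay$r2
  tie <- abs(d) < 1e-9
  tibble(
    model = if (tie) NA_character_ else
      if (d > 0) "gaussian" else "exp_decay",
    r2_gaussian = gauss$r2, r2_exp_decay = decay$r2,
    delta_r2 = abs(d), tie = tie
  )
}
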