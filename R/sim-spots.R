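#' Simulate two-channel single-molecule spot fields
#'
#' Channel A spots are a spatial Poisson process of the requested density. A
#' fraction `coloc_fraction` of them receive a channel B partner displaced by
#' isotropic Gaussian jitter; the rest of channel B is an independent Poisson
#' process with density `(1 - coloc_fraction) * density`, so both channels
#' have (on average) equal density. Coordinates are in um with the origin at
#' the field corner; jittered partners are reflected back into the field.
#'
#' @param density Spots per um^2 in each channel.
#' @param coloc_fraction Fraction of channel A spots with a true partner, in
#'   \[0, 1\].
#' @param jitter_sd Gaussian jitter sd (um) applied to partner positions.
#' @param fov_extent Field of view width and height in um, length-2 vector.
#' @param n_fov Number of fields to simulate.
#' @param seed Optional integer seed.
#'
#' @return Tibble with columns `fov_id`, `channel` (`"A"`/`"B"`), `x`, `y`
#'   (um), and `partner_of` (the A spot id a B spot was planted on, `NA`
#'   otherwise — ground truth for recovery tests).
#' @export
#' @examples
#' sp <- simulate_spots(density = 0.02, coloc_fraction = 0.5, seed = 1)
#' dplyr::count(sp, channel)
simulate_spots <- function(density = 0.05, coloc_fraction = 0.5,
                           jitter_sd = 0.02, fov_extent = c(80, 80),
                           n_fov = 1, seed = NULL) {
  if (!is.numeric(density) || density < 0) {
    abort("`density` must be >= 0.", class = "plusend_domain_error")
  }
  if (!is.numeric(coloc_fraction) || coloc_fraction < 0 ||
      coloc_fraction > 1) {
    abort("`coloc_fraction` must lie in [0, 1].",
          class = "plusend_domain_error")
  }
  if (!is.numeric(jitter_sd) || jitter_sd < 0) {
    abort("`jitter_sd` must be >= 0.", class = "plusend_domain_error")
  }
  stopifnot(length(fov_extent) == 2, all(fov_extent > 0))
  if (!is.null(seed)) set.seed(seed)

  area <- prod(fov_extent)
  fields <- vector("list", n_fov)
  for (f in seq_len(n_fov)) {
    fid <- sprintf("FOV-%d", f)
    n_a <- rpois(1, density * area)
    a <- tibble(
      fov_id = fid, channel = "A",
      x = runif(n_a, 0, fov_extent[1]), y = runif(n_a, 0, fov_extent[2]),
      partner_of = NA_character_
    )
    a_id <- sprintf("%s-A-%04d", fid, seq_len(n_a))
    is_partnered <- runif(n_a) < coloc_fraction
    b_part <- tibble(
      fov_id = fid, channel = "B",
      x = reflect_into(a$x[is_partnered] +
                         rnorm(sum(is_partnered), 0, jitter_sd),
                       fov_extent[1]),
      y = reflect_into(a$y[is_partnered] +
                         rnorm(sum(is_partnered), 0, jitter_sd),
                       fov_extent[2]),
      partner_of = a_id[is_partnered]
    )
    n_b_free <- rpois(1, (1 - coloc_fraction) * density * area)
    b_free <- tibble(
      fov_id = fid, channel = "B",
      x = runif(n_b_free, 0, fov_extent[1]),
      y = runif(n_b_free, 0, fov_extent[2]),
      partner_of = NA_character_
    )
    fields[[f]] <- bind_rows(a, b_part, b_free)
  }
  bind_rows(fields)
}

# reflect coordinates back into [0, width]
reflect_into <- function(x, width) {
  x <- abs(x)
  over <- x > width
  x[over] <- 2 * width - x[over]
  pmin(pmax(x, 0), width)
}

#' Simulate a pixel-intensity field of single vs bundled filaments
#'
#' Draws per-pixel intensities from a two-component mixture: pixels on single
#' filaments have unit mean intensity, pixels on bundles have
#' `bundle_multiplier` times that, both with additive Gaussian noise. Bundling
#' produces a bright right tail, which the skewness readout
#' ([intensity_skewness()]) quantifies; with `bundle_fraction` 0 or 1 the
#' field is unimodal and skewness is near 0.
#'
#' @param n_pixels Number of filament pixels sampled.
#' @param bundle_fraction Fraction of pixels belonging to bundles, in
#'   \[0, 1\].
#' @param bundle_multiplier Mean intensity of bundle pixels relative to
#'   singles (>= 2).
#' @param noise_sd Gaussian noise sd (a.u.; single-filament mean is 1).
#' @param seed Optional integer seed.
#'
#' @return Tibble with columns `intensity` and `bundle` (logical ground
#'   truth).
#' @export
#' @examples
#' px <- simulate_bundle_field(1000, bundle_fraction = 0.2, seed = 1)
#' intensity_skewness(px$intensity)
simulate_bundle_field <- function(n_pixels, bundle_fraction,
                                  bundle_multiplier = 4, noise_sd = 0.2,
                                  seed = NULL) {
  if (!is.numeric(bundle_fraction) || bundle_fraction < 0 ||
      bundle_fraction > 1) {
    abort("`bundle_fraction` must lie in [0, 1].",
          class = "plusend_domain_error")
  }
  if (!is.numeric(bundle_multiplier) || bundle_multiplier < 2) {
    abort("`bundle_multiplier` must be >= 2.",
          class = "plusend_domain_error")
  }
  if (!is.null(seed)) set.seed(seed)
  n_pixels <- as.integer(n_pixels)
  bundle <- runif(n_pixels) < bundle_fraction
  mu <- ifelse(bundle, bundle_multiplier, 1)
  tibble(intensity = mu + rnorm(n_pixels, 0, noise_sd), bundle = bundle)
}
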