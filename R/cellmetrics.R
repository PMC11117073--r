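#' Skewness of a pixel-intensity distribution (bundling metric)
#'
#' The third standardised central moment `m3 / m2^(3/2)` of pixel
#' intensities. Filament bundles add a bright right tail to the intensity
#' distribution of a field, so positive skewness reads out bundling; a field
#' of only single filaments (or only bundles) is near-symmetric with
#' skewness about 0.
#'
#' @param pixels Numeric vector of pixel intensities, or a data frame with an
#'   `intensity` column (e.g. [simulate_bundle_field()] output). Needs at
#'   least 3 values with nonzero variance.
#'
#' @return The skewness (a single number); `NA` with a warning when the
#'   variance is zero.
#' @export
#' @examples
#' intensity_skewness(rexp(1e4))  # ~ 2
intensity_skewness <- function(pixels) {
  if (is.data.frame(pixels)) {
    if (!"intensity" %in% names(pixels)) {
      abort("data-frame input must have an `intensity` column.",
            class = "plusend_domain_error")
    }
    pixels <- pixels$intensity
  }
  pixels <- pixels[is.finite(pixels)]
  if (length(pixels) < 3) {
    abort("Need at least 3 pixels.", class = "plusend_insufficient_data")
  }
  m <- mean(pixels)
  m2 <- mean((pixels - m)^2)
  if (m2 <= .Machine$double.eps * max(1, m^2)) {
    warn("Zero variance; skewness undefined.")
    return(NA_real_)
  }
  mean((pixels - m)^3) / m2^1.5
}

#' Circularity of a binary cell mask
#'
#' `4 * pi * area / perimeter^2`, the shape readout used on thresholded cell
#' images: 1 for a disk, approaching 0 for elongated shapes. The perimeter is
#' measured by tracing the 8-connected boundary contour and summing chain
#' steps (1 for orthogonal, sqrt(2) for diagonal) scaled by a corner
#' correction factor of 0.954, because raw raster chain lengths overestimate
#' smooth perimeters; with this calibration a rasterized disk of radius 200
#' pixels scores ~0.99. Values are clipped to at most 1.
#'
#' @param mask Logical or 0/1 matrix with a single connected foreground
#'   component.
#' @param pixel_size Pixel edge length (um/pixel); circularity itself is
#'   scale-free, so this only validates input.
#'
#' @return Circularity in (0, 1].
#' @export
circularity <- function(mask, pixel_size = 1) {
  mask <- check_mask(mask)
  check_positive_scalar(pixel_size, "pixel_size")
  lab <- EBImage::bwlabel(mask)
  n_comp <- max(lab)
  if (n_comp == 0) {
    abort("Mask has no foreground pixels.",
          class = "plusend_degenerate_input")
  }
  if (n_comp > 1) {
    sizes <- tabulate(lab[lab > 0], nbins = n_comp)
    abort(paste0("Mask has ", n_comp, " connected components (sizes: ",
                 paste(sizes, collapse = ", "),
                 "); circularity needs exactly one."),
          class = "plusend_ambiguous_input")
  }
  area <- sum(mask)
  perim <- contour_perimeter(lab)
  min(4 * pi * area / perim^2, 1)
}

# chain-code perimeter of the (single) labelled object, corner-corrected
contour_perimeter <- function(lab) {
  oc <- EBImage::ocontour(lab)[[1]]
  if (nrow(oc) < 2) return(4)  # a single pixel: unit square
  steps <- rbind(diff(oc), oc[1, ] - oc[nrow(oc), ])
  step_len <- sqrt(rowSums(steps^2))
  0.954 * sum(step_len)
}

check_mask <- function(mask) {
  if (!is.matrix(mask) || !length(mask)) {
    abort("`mask` must be a non-empty matrix.",
          class = "plusend_domain_error")
  }
  if (is.logical(mask)) mask <- mask * 1L
  if (!all(mask %in% c(0, 1))) {
    abort("`mask` must be binary (0/1 or logical).",
          class = "plusend_domain_error")
  }
  mask
}

#' Integrated signal per available pixel
#'
#' Thresholded integrated intensity divided by the total number of pixels in
#' the image — the normalised signal readout used to compare cytoskeletal
#' array abundance between micropatterned cells. Pixels below the threshold
#' contribute zero signal but still count in the denominator.
#'
#' @param image Numeric matrix of pixel intensities.
#' @param threshold Pixels strictly below this value are zeroed before
#'   integration (default 0 = no thresholding), or `"otsu"` to derive the
#'   threshold from the image histogram (intensities must then lie in
#'   \[0, 1\]).
#'
#' @return Mean thresholded signal per pixel (a single number).
#' @export
signal_ratio <- function(image, threshold = 0) {
  if (!is.matrix(image) || !is.numeric(image) || !length(image)) {
    abort("`image` must be a non-empty numeric matrix.",
          class = "plusend_domain_error")
  }
  if (identical(threshold, "otsu")) {
    threshold <- EBImage::otsu(EBImage::Image(image))
  }
  sum(image[image >= threshold]) / length(image)
}

#' Normalised wound closure
#'
#' The primary readout is the difference in cell coverage between 12 h and
#' time zero, `coverage_t12 - coverage_t0`; the ratio `t12 / t0` is reported
#' as a secondary field. Coverages are fractions of the field of view
#' occupied by cells.
#'
#' @param coverage_t0,coverage_t12 Cell-coverage fractions in \[0, 1\]
#'   (vectorised).
#'
#' @return Tibble with `closure` (difference, in \[-1, 1\]) and
#'   `closure_ratio` (`NA` when `coverage_t0` is 0).
#' @export
#' @examples
#' wound_closure(0.5, 0.8)  # closure 0.3, ratio 1.6
wound_closure <- function(coverage_t0, coverage_t12) {
  cov <- c(coverage_t0, coverage_t12)
  if (any(!is.finite(cov) | cov < 0 | cov > 1)) {
    abort("Coverages must lie in [0, 1].", class = "plusend_domain_error")
  }
  tibble(
    closure = coverage_t12 - coverage_t0,
    closure_ratio = ifelse(coverage_t0 > 0, coverage_t12 / coverage_t0,
                           NA_real_)
  )
}
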