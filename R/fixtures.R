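#' Write a complete synthetic fixture bundle to disk
#'
#' Simulates one of every input the analysis stages consume — filament
#' tracks with their ground-truth state events, photobleaching traces,
#' dwell records, two-channel spot sets, a bundle pixel field and a small
#' binary mask — and writes them as plain-text tables (UTF-8, tab-delimited,
#' one-line header; times in seconds, lengths/coordinates in um), a 16-bit
#' single-channel TIFF for the mask, a YAML copy of the configuration and a
#' JSON manifest recording the seed and per-file row counts. Re-running with
#' the same seed and configuration reproduces every file byte for byte, and
#' the paired readers ([read_tracks()] and friends) round-trip all tables
#' exactly.
#'
#' @param output_dir Directory to write into (created if needed).
#' @param config A [sim_config()] controlling the filament simulation.
#' @param seed Integer seed for all randomness in the bundle.
#' @param n_filaments,n_molecules Sizes of the simulated populations.
#'
#' @return The manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
write_fixture_bundle <- function(output_dir, config = sim_config(),
                                 seed = 1L, n_filaments = 20,
                                 n_molecules = 50) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(output_dir)) {
    ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) {
      abort(paste0("Cannot create directory: ", output_dir),
            class = "plusend_io_error")
    }
  }

  sim <- simulate_filaments(config, n_filaments, seed = seed)
  bleach <- simulate_bleach_traces(2, p_label = 0.7,
                                   n_molecules = n_molecules,
                                   seed = seed + 1L)
  dwells <- simulate_dwells(c(mDia1 = 300, CP = 500, IQGAP1 = 20),
                            movie_duration = config$movie_duration,
                            n_molecules = n_molecules, seed = seed + 2L)
  spots <- simulate_spots(density = 0.02, coloc_fraction = 0.5,
                          seed = seed + 3L)
  pixels <- simulate_bundle_field(2000, bundle_fraction = 0.2,
                                  seed = seed + 4L)
  mask <- disk_mask(radius = 20, size = 64)

  files <- list(
    tracks = "tracks.tsv", events = "events.tsv", traces = "traces.tsv",
    trace_truth = "trace_truth.tsv", dwells = "dwells.tsv",
    spots = "spots.tsv", bundle_pixels = "bundle_pixels.tsv",
    mask = "mask.tif"
  )
  path <- function(f) file.path(output_dir, f)

  readr::write_tsv(sim$tracks, path(files$tracks))
  readr::write_tsv(sim$events, path(files$events))
  readr::write_tsv(bleach$traces, path(files$traces))
  truth_flat <- bleach$truth |>
    mutate(bleach_times = vapply(.data$bleach_times, paste,
                                 character(1), collapse = ",")) |>
    as_tibble()
  readr::write_tsv(truth_flat, path(files$trace_truth))
  readr::write_tsv(dwells, path(files$dwells))
  readr::write_tsv(spots, path(files$spots))
  readr::write_tsv(pixels, path(files$bundle_pixels))
  tiff::writeTIFF(mask, path(files$mask), bits.per.sample = 16)

  cfg <- config
  cfg$transition_rates <- if (nrow(cfg$transition_rates)) {
    as.list(setNames(
      cfg$transition_rates$rate,
      paste0(cfg$transition_rates$from, "->", cfg$transition_rates$to)))
  } else list()
  yaml::write_yaml(unclass(cfg), file.path(output_dir, "config.yaml"))

  manifest <- list(
    seed = seed,
    files = lapply(seq_along(files), function(i) {
      f <- files[[i]]
      rows <- if (grepl("\\.tsv$", f)) {
        length(readr::read_lines(path(f))) - 1L
      } else NA
      list(name = names(files)[i], file = f, rows = rows)
    }),
    config = "config.yaml"
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

disk_mask <- function(radius, size) {
  g <- expand.grid(r = seq_len(size), c = seq_len(size))
  m <- matrix(0, size, size)
  inside <- (g$r - size / 2)^2 + (g$c - size / 2)^2 <= radius^2
  m[as.matrix(g[inside, ])] <- 1
  m
}

#' Read fixture tables written by [write_fixture_bundle()]
#'
#' Thin wrappers around [readr::read_tsv()] with explicit column types so the
#' written tables round-trip exactly.
#'
#' @param path Path to the `.tsv` file.
#' @return A tibble.
#' @export
read_tracks <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    filament_id = "c", fov_id = "c", time = "d", length = "d",
    condition = "c"))
}

#' @rdname read_tracks
#' @export
read_events <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    filament_id = "c", state = "c", start = "d", end = "d"))
}

#' @rdname read_tracks
#' @export
read_traces <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    molecule_id = "c", time = "d", intensity = "d"))
}

#' @rdname read_tracks
#' @export
read_dwells <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    molecule_id = "c", species = "c", bind_time = "d", release_time = "d",
    censored = "l"))
}

#' @rdname read_tracks
#' @export
read_spots <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    fov_id = "c", channel = "c", x = "d", y = "d", partner_of = "c"))
}

#' Read a binary mask from a single-channel TIFF
#'
#' @param path Path to the TIFF file.
#' @param threshold Pixels above this (on the 0-1 TIFF scale) are foreground.
#' @return A 0/1 matrix.
#' @export
read_mask <- function(path, threshold = 0.5) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  (img > threshold) * 1
}
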