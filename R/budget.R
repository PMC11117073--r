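#' Avogadro constant used for molecule-budget arithmetic
#' @format A single number, 6.02e23 mol-1.
#' @export
AVOGADRO <- 6.02e23

#' Lamellipodium compartment specification
#'
#' Bundles the geometry, regulator concentrations and filament density that
#' feed the molecule-budget arithmetic. The defaults describe an average
#' lamellipodium: a 1 x 10 x 0.2 um slab with 500 actin filaments per um^2,
#' 1 uM capping protein and 100 nM mDia1 (a dimer).
#'
#' @param dimensions Compartment dimensions `(x, y, z)` in um; the `x * y`
#'   footprint carries the filament ends.
#' @param species Data frame with columns `name`, `concentration` (mol/L,
#'   >= 0) and `oligomer_size` (subunits per end-binding unit, >= 1).
#' @param filament_density Filaments per um^2 of footprint (>= 0).
#'
#' @return Object of class `compartment_spec`.
#' @export
#' @examples
#' compartment_spec()
compartment_spec <- function(dimensions = c(1, 10, 0.2),
                             species = tibble::tibble(
                               name = c("CP", "mDia1"),
                               concentration = c(1e-6, 1e-7),
                               oligomer_size = c(1, 2)),
                             filament_density = 500) {
  if (length(dimensions) != 3 || any(!is.finite(dimensions) |
                                       dimensions <= 0)) {
    abort("`dimensions` must be three positive lengths (um).",
          class = "plusend_domain_error")
  }
  if (!is.data.frame(species) ||
      !all(c("name", "concentration", "oligomer_size") %in% names(species))) {
    abort(paste0("`species` needs columns name, concentration, ",
                 "oligomer_size."),
          class = "plusend_domain_error")
  }
  if (any(species$concentration < 0) || any(species$oligomer_size < 1)) {
    abort("Concentrations must be >= 0 and oligomer sizes >= 1.",
          class = "plusend_domain_error")
  }
  if (!is.numeric(filament_density) || filament_density < 0) {
    abort("`filament_density` must be >= 0.",
          class = "plusend_domain_error")
  }
  structure(
    list(dimensions = as.numeric(dimensions),
         species = as_tibble(species),
         filament_density = filament_density),
    class = "compartment_spec"
  )
}

#' Molecule and free-end budget of a lamellipodium
#'
#' Back-of-the-envelope accounting of plus-end regulators in a cellular
#' compartment: the compartment volume is `x * y * z * 1e-15` L, the copy
#' number of each species is `concentration * N_A * volume`, and the number
#' of end-binding units (e.g. dimers for mDia1) is the copy number divided by
#' the oligomer size, rounded down. Available plus ends are
#' `filament_density * footprint area`; the remaining free ends are what is
#' left after every unit occupies one end. With the default spec: ~1,200 CP
#' molecules, <60 mDia1 dimers, 5,000 ends.
#'
#' @param spec A [compartment_spec()].
#'
#' @return Object of class `molecule_budget`: list with `species` (tibble
#'   `name`, `concentration`, `molecules`, `oligomer_size`, `units`),
#'   `volume_l`, `free_ends`, `occupied_ends`, `remaining_ends`.
#' @export
#' @examples
#' molecule_budget(compartment_spec())
molecule_budget <- function(spec) {
  stopifnot(inherits(spec, "compartment_spec"))
  d <- spec$dimensions
  volume_l <- prod(d) * 1e-15
  footprint <- d[1] * d[2]
  sp <- spec$species |>
    mutate(
      molecules = .data$concentration * AVOGADRO * volume_l,
      units = floor(.data$molecules / .data$oligomer_size)
    ) |>
    select("name", "concentration", "molecules", "oligomer_size", "units")
  free_ends <- spec$filament_density * footprint
  occupied <- sum(sp$units)
  structure(
    list(species = sp, volume_l = volume_l, free_ends = free_ends,
         occupied_ends = occupied,
         remaining_ends = free_ends - occupied),
    class = "molecule_budget"
  )
}

#' @export
print.molecule_budget <- function(x, ...) {
  cat("<molecule_budget>\n")
  cat(sprintf("  volume: %.3g L, available ends: %g\n", x$volume_l,
              x$free_ends))
  sp <- x$species
  for (i in seq_len(nrow(sp))) {
    cat(sprintf("  %s: %.4g molecules -> %g end-binding units\n",
                sp$name[i], sp$molecules[i], sp$units[i]))
  }
  cat(sprintf("  occupied: %g, remaining free ends: %g\n", x$occupied_ends,
              x$remaining_ends))
  invisible(x)
}

#' @export
tidy.molecule_budget <- function(x, ...) {
  x$species
}

#' @export
glance.molecule_budget <- function(x, ...) {
  tibble(volume_l = x$volume_l, free_ends = x$free_ends,
         occupied_ends = x$occupied_ends,
         remaining_ends = x$remaining_ends)
}
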