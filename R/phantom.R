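# Phantom, material and beam descriptions for the analytic activation model.

#' Material composition
#'
#' Elemental composition of a homogeneous phantom material, as a density and
#' mass fractions over the elements H, C and O. Fractions must sum to one.
#'
#' @param density_g_cm3 Mass density in g/cm^3.
#' @param mass_fractions Named numeric vector of mass fractions (names among
#'   `"H"`, `"C"`, `"O"`), summing to 1 within 1e-6.
#' @return An object of class `material_composition`.
#' @examples
#' water_gel()
#' @export
material_composition <- function(density_g_cm3, mass_fractions) {
  stopifnot(is.numeric(density_g_cm3), length(density_g_cm3) == 1L)
  if (density_g_cm3 <= 0) stop("density must be positive")
  if (is.null(names(mass_fractions)) || !all(names(mass_fractions) %in% c("H", "C", "O")))
    stop("mass_fractions must be named with elements among H, C, O")
  if (any(mass_fractions < 0)) stop("mass fractions must be non-negative")
  if (abs(sum(mass_fractions) - 1) > 1e-6)
    stop("mass fractions must sum to 1 (got ", format(sum(mass_fractions)), ")")
  structure(list(density_g_cm3 = density_g_cm3,
                 mass_fractions = mass_fractions),
            class = "material_composition")
}

#' Water-gel phantom material
#'
#' The default agar water-gel: density 1.010 g/cm^3, mass fractions
#' H 11.00%, C 4.650%, O 84.35%. Nitrogen is absent by construction, so no
#' nitrogen-activation channels exist in this material.
#'
#' @return A `material_composition`.
#' @export
water_gel <- function() {
  material_composition(1.010, c(H = 0.1100, C = 0.0465, O = 0.8435))
}

#' Phantom geometry
#'
#' A rectangular phantom with its entrance face at z = 0 and the beam axis
#' along +z. Voxel sizes must divide the extents exactly.
#'
#' @param size_mm Extents (x, y, z) in mm. Default 100 x 100 x 400 mm.
#' @param voxel_mm Voxel sizes (dx, dy, dz) in mm. Default c(10, 10, 0.5).
#' @param material A `material_composition`; default [water_gel()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size_mm = c(100, 100, 400),
                         voxel_mm = c(10, 10, 0.5),
                         material = water_gel()) {
  stopifnot(length(size_mm) == 3L, length(voxel_mm) == 3L,
            inherits(material, "material_composition"))
  if (any(size_mm <= 0) || any(voxel_mm <= 0))
    stop("phantom extents and voxel sizes must be positive")
  n <- size_mm / voxel_mm
  if (any(abs(n - round(n)) > 1e-9))
    stop("voxel sizes must divide the phantom extents")
  structure(list(size_mm = as.numeric(size_mm),
                 voxel_mm = as.numeric(voxel_mm),
                 dim = as.integer(round(n)),
                 material = material),
            class = "phantom_spec")
}

#' Pencil-beam specification
#'
#' A monoenergetic pencil beam along +z, entering the phantom face as a
#' uniform disc. The therapeutic sweep spans 45--250 MeV; energies outside
#' that band are accepted with a warning.
#'
#' @param energy_MeV Incident kinetic energy E0 in MeV.
#' @param diameter_mm Beam diameter in mm (default 10).
#' @param entry_mm Beam-axis (x, y) position on the entrance face in mm;
#'   default the face centre (`NULL`).
#' @return An object of class `beam_spec`.
#' @export
beam_spec <- function(energy_MeV, diameter_mm = 10, entry_mm = NULL) {
  stopifnot(is.numeric(energy_MeV), length(energy_MeV) == 1L)
  if (energy_MeV <= 0) stop("beam energy must be positive")
  if (diameter_mm <= 0) stop("beam diameter must be positive")
  if (energy_MeV < 45 || energy_MeV > 250)
    warning("beam energy ", energy_MeV,
            " MeV is outside the calibrated 45-250 MeV band")
  structure(list(energy_MeV = energy_MeV, diameter_mm = diameter_mm,
                 entry_mm = entry_mm),
            class = "beam_spec")
}

#' @export
print.material_composition <- function(x, ...) {
  cat("<material_composition> density", x$density_g_cm3, "g/cm^3;",
      paste(sprintf("%s=%.4f", names(x$mass_fractions), x$mass_fractions),
            collapse = " "), "\n")
  invisible(x)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec>", paste(x$size_mm, collapse = " x "), "mm,",
      paste(x$voxel_mm, collapse = " x "), "mm voxels (",
      paste(x$dim, collapse = " x "), ")\n")
  invisible(x)
}
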