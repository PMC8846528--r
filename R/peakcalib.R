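# Calibration-curve interpolation: offset (and peak depths) against incident
# energy, linear or natural cubic spline, evaluated at 0.1 MeV resolution.
# Given a measured 13N peak depth, the Bragg depth is the measured depth plus
# the interpolated offset.

#' Fit a calibration interpolant
#'
#' Interpolates the three columns of an offset table (Bragg depth, 13N
#' depth, offset) against energy, independently, with either piecewise
#' linear or natural cubic-spline interpolation. Both methods pass through
#' every knot exactly. No extrapolation: evaluation outside the knot range
#' is an error, since offsets outside the simulated band are unvalidated.
#'
#' @param table An `offset_table` (e.g. [offset_table_fixture()] or
#'   [sweep_energies()] output): columns `energy_MeV`, `bragg_mm`, `n13_mm`,
#'   `offset_mm`, energies strictly ascending.
#' @param method `"linear"` or `"cubic_spline"` (natural boundary
#'   conditions).
#' @return Object of class `calibration_curve`.
#' @export
fit_interpolant <- function(table, method = c("linear", "cubic_spline")) {
  method <- match.arg(method)
  stopifnot(all(c("energy_MeV", "bragg_mm", "n13_mm", "offset_mm") %in% names(table)))
  E <- table$energy_MeV
  if (anyDuplicated(E) || any(diff(E) <= 0))
    stop("knot energies must be strictly ascending without duplicates")
  need <- if (method == "linear") 2L else 4L
  if (length(E) < need)
    stop("need at least ", need, " knots for method ", method)
  mk <- function(y) {
    if (method == "linear") stats::approxfun(E, y)
    else stats::splinefun(E, y, method = "natural")
  }
  structure(list(method = method, knots = table,
                 e_min = min(E), e_max = max(E),
                 f_offset = mk(table$offset_mm),
                 f_bragg = mk(table$bragg_mm),
                 f_n13 = mk(table$n13_mm)),
            class = "calibration_curve")
}

check_energy_range <- function(curve, E) {
  bad <- E < curve$e_min - 1e-9 | E > curve$e_max + 1e-9
  if (any(bad))
    stop(sprintf("energy %g MeV outside the calibrated range [%g, %g] MeV",
                 E[which(bad)[1]], curve$e_min, curve$e_max))
  invisible(E)
}

#' Interpolated offset at an energy
#'
#' @param curve A [fit_interpolant()] curve.
#' @param E_MeV Energies within the knot range (vectorised).
#' @return Offset(s) in mm.
#' @examples
#' offset_at(fit_interpolant(offset_table_fixture()), 60)
#' @export
offset_at <- function(curve, E_MeV) {
  stopifnot(inherits(curve, "calibration_curve"))
  check_energy_range(curve, E_MeV)
  curve$f_offset(E_MeV)
}

#' Interpolated Bragg and 13N depths at an energy
#'
#' @inheritParams offset_at
#' @return Data frame: `energy_MeV`, `bragg_mm`, `n13_mm`, `offset_mm`.
#' @export
depths_at <- function(curve, E_MeV) {
  stopifnot(inherits(curve, "calibration_curve"))
  check_energy_range(curve, E_MeV)
  data.frame(energy_MeV = E_MeV,
             bragg_mm = curve$f_bragg(E_MeV),
             n13_mm = curve$f_n13(E_MeV),
             offset_mm = curve$f_offset(E_MeV))
}

#' Export the calibration on a fine energy grid
#'
#' Evaluates the curve every `step_MeV` from the first to the last knot --
#' 0.1 MeV by default, turning the 5 MeV lookup into a 2051-row table for
#' the default 45--250 MeV knots.
#'
#' @inheritParams offset_at
#' @param step_MeV Grid step, MeV (default 0.1).
#' @return Data frame as in [depths_at()], one row per grid energy.
#' @export
export_grid <- function(curve, step_MeV = 0.1) {
  stopifnot(inherits(curve, "calibration_curve"), step_MeV > 0)
  E <- seq(curve$e_min, curve$e_max, by = step_MeV)
  depths_at(curve, E)
}

#' Estimate the Bragg depth from a measured 13N depth
#'
#' The calibration use of the offset table: Bragg depth = measured 13N peak
#' depth + offset(E).
#'
#' @param measured_n13_mm Measured 13N peak depth, mm.
#' @inheritParams offset_at
#' @return Estimated Bragg-peak depth(s), mm.
#' @examples
#' curve <- fit_interpolant(offset_table_fixture())
#' estimate_bragg(48.0, 80, curve)  # 50.0 mm
#' @export
estimate_bragg <- function(measured_n13_mm, E_MeV, curve) {
  measured_n13_mm + offset_at(curve, E_MeV)
}

#' Read / write offset tables as CSV
#'
#' CSV dialect: header `energy_MeV,bragg_mm,n13_mm,offset_mm`.
#'
#' @param path File path.
#' @return `read_offset_table()` returns an `offset_table` data frame.
#' @export
read_offset_table <- function(path) {
  tab <- utils::read.csv(path)
  stopifnot(all(c("energy_MeV", "bragg_mm", "n13_mm", "offset_mm") %in% names(tab)))
  structure(tab, class = c("offset_table", "data.frame"))
}

#' @rdname read_offset_table
#' @param table An `offset_table` data frame.
#' @export
write_offset_table <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, c("energy_MeV", "bragg_mm",
                                            "n13_mm", "offset_mm")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
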