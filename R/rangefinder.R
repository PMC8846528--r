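# Peak localisation and Bragg/13N offset computation: profile reduction,
# peak finding, the 45-250 MeV sweep and the range benchmark arithmetic.

#' Reduce a volume to a depth profile
#'
#' Sums a 3D volume over a lateral region of interest, giving a per-depth
#' profile along the beam axis.
#'
#' @param volume 3D array (x, y, z).
#' @param voxel_mm Voxel sizes (dx, dy, dz), mm.
#' @param lateral_roi Logical (nx x ny) matrix selecting lateral voxels;
#'   `NULL` uses the full cross-section.
#' @return A [depth_profile()].
#' @export
depth_profile_from_volume <- function(volume, voxel_mm, lateral_roi = NULL) {
  stopifnot(length(dim(volume)) == 3L)
  d <- dim(volume)
  if (is.null(lateral_roi)) lateral_roi <- matrix(TRUE, d[1], d[2])
  stopifnot(identical(dim(lateral_roi), d[1:2]))
  if (!any(lateral_roi)) stop("lateral ROI is empty")
  v <- apply(volume, 3, function(slab) sum(slab[lateral_roi]))
  depth_profile((seq_len(d[3]) - 0.5) * voxel_mm[3], v)
}

#' Locate the peak of a depth profile
#'
#' Global maximum of the profile; ties are broken toward the smallest depth.
#' `refine = "parabolic"` fits a parabola through the three bins around the
#' argmax for sub-bin resolution; the default reports the bin centre, the
#' 0.5 mm quantisation of the published tables.
#'
#' @param profile A [depth_profile()].
#' @param refine `"bin_center"` or `"parabolic"`.
#' @return Object of class `peak_estimate`: list with `depth_mm`, `bin`,
#'   `refine`.
#' @export
find_peak <- function(profile, refine = c("bin_center", "parabolic")) {
  refine <- match.arg(refine)
  if (nrow(profile) == 0 || all(profile$value <= 0))
    stop("cannot locate a peak in an all-zero profile")
  k <- which.max(profile$value)   # which.max takes the first of ties
  depth <- profile$depth_mm[k]
  if (refine == "parabolic" && k > 1 && k < nrow(profile)) {
    dz <- profile_dz(profile)
    y1 <- profile$value[k - 1]; y2 <- profile$value[k]; y3 <- profile$value[k + 1]
    den <- y1 - 2 * y2 + y3
    if (den < 0) depth <- depth + 0.5 * dz * (y1 - y3) / den
  }
  structure(list(depth_mm = depth, bin = k, refine = refine),
            class = "peak_estimate")
}

#' Bragg-peak / 13N-peak offset at one energy
#'
#' Runs the depth-dose and 13N production profiles on one grid, locates both
#' peaks and returns their separation, offset = Bragg depth - 13N depth.
#' The 13N peak sits proximal to the Bragg peak because 13N production stops
#' where the residual proton energy falls below the 5.660 MeV threshold.
#'
#' @param E0 Incident energy, MeV.
#' @inheritParams depth_dose_profile
#' @param xs_n13 13N excitation curve (default the packaged fixture).
#' @param refine Peak refinement mode passed to [find_peak()].
#' @return One-row data frame: `energy_MeV`, `bragg_mm`, `n13_mm`,
#'   `offset_mm`.
#' @export
compute_offset <- function(E0, model = stopping_model(), material = water_gel(),
                           dz_mm = 0.5, straggle = TRUE,
                           fluence_lambda_mm = 1000,
                           xs_n13 = xs_fixture("N13"),
                           refine = "bin_center") {
  n13 <- nuclide_registry()$N13
  dose <- depth_dose_profile(E0, model, material, dz_mm = dz_mm,
                             straggle = straggle,
                             fluence_lambda_mm = fluence_lambda_mm)
  prod <- production_profile(E0, n13, xs_n13, model, material, dz_mm = dz_mm,
                             straggle = straggle,
                             fluence_lambda_mm = fluence_lambda_mm)
  pb <- find_peak(dose, refine)$depth_mm
  pn <- find_peak(prod, refine)$depth_mm
  data.frame(energy_MeV = E0, bragg_mm = pb, n13_mm = pn, offset_mm = pb - pn)
}

#' Offset sweep over incident energies
#'
#' [compute_offset()] at each energy of the therapeutic band; the default
#' 45--250 MeV in 5 MeV steps gives 42 records, the structure of the
#' published offset lookup.
#'
#' @param start,stop,step Sweep limits and step, MeV.
#' @inheritParams compute_offset
#' @return Data frame of class `offset_table` with one row per energy.
#' @export
sweep_energies <- function(start = 45, stop = 250, step = 5,
                           model = stopping_model(), material = water_gel(),
                           dz_mm = 0.5, straggle = TRUE,
                           fluence_lambda_mm = 1000,
                           xs_n13 = xs_fixture("N13"), refine = "bin_center") {
  stopifnot(start < stop, step > 0)
  energies <- seq(start, stop, by = step)
  rows <- lapply(energies, compute_offset, model = model, material = material,
                 dz_mm = dz_mm, straggle = straggle,
                 fluence_lambda_mm = fluence_lambda_mm, xs_n13 = xs_n13,
                 refine = refine)
  structure(do.call(rbind, rows), class = c("offset_table", "data.frame"))
}

#' Published offset lookup fixture
#'
#' The packaged energy -> (Bragg depth, 13N depth, offset) table: 42 rows,
#' 45--250 MeV in 5 MeV steps, offsets between 1.0 and 2.0 mm. This is the
#' calibration input of the interpolation stage.
#'
#' @return Data frame of class `offset_table`: `energy_MeV`, `bragg_mm`,
#'   `n13_mm`, `offset_mm`.
#' @export
offset_table_fixture <- function() {
  structure(utils::read.csv(pkg_extdata("offset_table.csv")),
            class = c("offset_table", "data.frame"))
}

#' Range benchmark fixture
#'
#' Packaged two-code range comparison (Monte Carlo vs SRIM tabulation) at
#' 80, 160 and 240 MeV, kept verbatim for benchmark arithmetic only -- the
#' analytic range model is not tuned to it.
#'
#' @return Data frame: `energy_MeV`, `range_mc_mm`, `range_srim_mm`.
#' @export
range_benchmark_fixture <- function() {
  utils::read.csv(pkg_extdata("range_benchmark.csv"))
}

#' Benchmark deviation arithmetic
#'
#' For two independent range estimates: mean = (a + b) / 2, absolute
#' deviation |a - b|, and the deviation as a percentage of the mean
#' (reported to 2 decimals).
#'
#' @param range_a_mm,range_b_mm Positive ranges in mm (vectorised).
#' @return Data frame: `mean_mm`, `deviation_mm`, `percent`.
#' @export
benchmark_deviation <- function(range_a_mm, range_b_mm) {
  if (any(range_a_mm <= 0) || any(range_b_mm <= 0))
    stop("ranges must be positive")
  m <- (range_a_mm + range_b_mm) / 2
  d <- abs(range_a_mm - range_b_mm)
  data.frame(mean_mm = m, deviation_mm = d, percent = round(100 * d / m, 2))
}

#' Default analysis regions of interest
#'
#' Four boxes along the beam: whole phantom; entrance edge (first 10 mm of
#' depth); plateau (20--80% of the Bragg depth); Bragg-peak region (Bragg
#' depth +/- 5 mm). Extents are clipped to the phantom.
#'
#' @param phantom A [phantom_spec()].
#' @param bragg_mm Located Bragg-peak depth, mm.
#' @param edge_mm Depth extent of the edge box (default 10 mm).
#' @param peak_halfwidth_mm Half-width of the peak box (default 5 mm).
#' @return Named list of ROI boxes, each `c(z_lo, z_hi)` in mm (full lateral
#'   extent), class `roi_set`.
#' @export
default_rois <- function(phantom, bragg_mm, edge_mm = 10, peak_halfwidth_mm = 5) {
  zmax <- phantom$size_mm[3]
  if (bragg_mm <= 0 || bragg_mm > zmax)
    stop("Bragg depth must lie inside the phantom")
  clip <- function(z) c(max(z[1], 0), min(z[2], zmax))
  structure(list(
    whole = c(0, zmax),
    edge = clip(c(0, edge_mm)),
    plateau = clip(c(0.2 * bragg_mm, 0.8 * bragg_mm)),
    peak = clip(c(bragg_mm - peak_halfwidth_mm, bragg_mm + peak_halfwidth_mm))
  ), class = "roi_set")
}

#' Logical mask for a depth-interval ROI
#'
#' @param phantom A [phantom_spec()].
#' @param z_range `c(z_lo, z_hi)` in mm (half-open on the right).
#' @return Logical 3D array over the phantom voxel grid.
#' @export
roi_mask <- function(phantom, z_range) {
  zc <- (seq_len(phantom$dim[3]) - 0.5) * phantom$voxel_mm[3]
  inz <- zc >= z_range[1] & zc < z_range[2] + 1e-9
  array(rep(inz, each = phantom$dim[1] * phantom$dim[2]), dim = phantom$dim)
}
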