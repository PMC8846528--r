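# Positron-emitter production: nuclide registry, cross-section curves and
# per-nuclide yield profiles / 3D maps, Y(z) ~ n_target * sigma(E(z)) * Phi(z).

#' Nuclide specification
#'
#' A positron-emitting product nuclide with its production channel. The
#' decay constant is derived as ln(2) / half-life.
#'
#' @param name One of `"C11"`, `"O15"`, `"N13"`.
#' @param half_life_min Physical half-life in minutes.
#' @param reaction Production reaction label.
#' @param threshold_MeV Reaction threshold energy, MeV (> 0).
#' @param target_element Target element symbol ("C" or "O").
#' @param target_A Mass number of the target element.
#' @return An object of class `nuclide_spec`.
#' @export
nuclide_spec <- function(name, half_life_min, reaction, threshold_MeV,
                         target_element, target_A) {
  stopifnot(half_life_min > 0)
  if (threshold_MeV <= 0) stop("threshold energy must be positive")
  structure(list(name = name,
                 half_life_min = half_life_min,
                 half_life_s = half_life_min * 60,
                 decay_constant_s = log(2) / (half_life_min * 60),
                 reaction = reaction,
                 threshold_MeV = threshold_MeV,
                 target_element = target_element,
                 target_A = target_A),
            class = "nuclide_spec")
}

#' Registry of the modelled positron emitters
#'
#' The three activation products of a proton beam in water-gel, with
#' half-lives and threshold energies:
#' C11 (20.39 min, 12C(p,pn)11C, 20.61 MeV), O15 (2.037 min, 16O(p,pn)15O,
#' 16.79 MeV) and N13 (9.965 min, 16O(p,2p2n)13N, 5.660 MeV; the (p,2p2n)
#' channel is inclusive of (p,alpha)). The low 13N threshold is what lets
#' 13N production persist closest to the Bragg peak.
#'
#' @return Named list of [nuclide_spec()] objects (`C11`, `O15`, `N13`).
#' @export
nuclide_registry <- function() {
  list(
    C11 = nuclide_spec("C11", 20.39, "12C(p,pn)11C", 20.61, "C", 12),
    O15 = nuclide_spec("O15", 2.037, "16O(p,pn)15O", 16.79, "O", 16),
    N13 = nuclide_spec("N13", 9.965, "16O(p,2p2n)13N", 5.660, "O", 16)
  )
}

#' Energy-dependent production cross section
#'
#' A threshold-gated excitation curve. Evaluation is linear between knots,
#' constantly extrapolated above the last knot, and identically zero below
#' the threshold.
#'
#' @param energies_MeV Ascending knot energies, MeV.
#' @param sigma_mb Cross-section values at the knots, mb (>= 0).
#' @param threshold_MeV Reaction threshold, MeV.
#' @return An object of class `cross_section`.
#' @export
cross_section <- function(energies_MeV, sigma_mb, threshold_MeV) {
  stopifnot(length(energies_MeV) == length(sigma_mb))
  if (any(diff(energies_MeV) <= 0)) stop("cross-section energies must be ascending")
  if (any(sigma_mb < 0)) stop("cross sections must be non-negative")
  if (any(sigma_mb[energies_MeV < threshold_MeV] > 0))
    stop("cross section must vanish below the threshold")
  f <- stats::approxfun(energies_MeV, sigma_mb, rule = 2, yleft = 0)
  structure(list(energies_MeV = energies_MeV, sigma_mb = sigma_mb,
                 threshold_MeV = threshold_MeV, interp = f),
            class = "cross_section")
}

#' Evaluate a cross section
#'
#' @param xs A [cross_section()].
#' @param E_MeV Energies, MeV.
#' @return Cross section in mb; zero below threshold.
#' @export
sigma_at <- function(xs, E_MeV) {
  out <- xs$interp(E_MeV)
  out[E_MeV < xs$threshold_MeV] <- 0
  out
}

#' Packaged cross-section curves
#'
#' Loads the packaged excitation curve for a nuclide. The curves encode the
#' published shapes of the three production channels: gated at the Table-2
#' thresholds, a near-threshold resonance (about 20 mb near 13 MeV for 13N)
#' and an approximately flat plateau above ~37.5 MeV. Absolute scale is a
#' relative normalisation; the near-threshold shape is what fixes peak
#' positions.
#'
#' @param nuclide Nuclide name (`"C11"`, `"O15"`, `"N13"`) or a
#'   [nuclide_spec()].
#' @return A [cross_section()].
#' @export
xs_fixture <- function(nuclide) {
  if (inherits(nuclide, "nuclide_spec")) nuclide <- nuclide$name
  file <- switch(nuclide,
                 C11 = "xs_c11.csv", O15 = "xs_o15.csv", N13 = "xs_n13.csv",
                 stop("unknown nuclide: ", nuclide))
  thr <- switch(nuclide, C11 = 20.61, O15 = 16.79, N13 = 5.660)
  tab <- utils::read.csv(pkg_extdata(file))
  cross_section(tab$energy_MeV, tab$sigma_mb, thr)
}

#' Default cross-section set
#'
#' @return Named list of the three packaged [cross_section()] curves.
#' @export
xs_set_default <- function() {
  list(C11 = xs_fixture("C11"), O15 = xs_fixture("O15"), N13 = xs_fixture("N13"))
}

# Target nuclei per gram of material (relative units: mass fraction / A).
target_density <- function(nuclide, material) {
  frac <- material$mass_fractions[[nuclide$target_element]]
  if (is.null(frac) || is.na(frac)) frac <- 0
  frac / nuclide$target_A
}

#' Per-nuclide production profile vs depth
#'
#' Yield per depth bin, Y(z) = n_target * sigma(E(z)) * Phi(z), in relative
#' units (nuclei per primary proton per bin, arbitrary normalisation).
#' sigma(E(z)) is averaged over `subsamples` points across each bin so the
#' fast energy variation near the end of range is integrated, not
#' point-sampled; the fluence factor is evaluated at the bin centre. The
#' yield vanishes identically where the residual energy is below the
#' reaction threshold, and range straggling (the same Gaussian as the dose
#' profile) is applied when `straggle = TRUE`.
#'
#' @param E0 Incident energy, MeV.
#' @param nuclide A [nuclide_spec()].
#' @param xs The matching [cross_section()]; its threshold must equal the
#'   nuclide's.
#' @inheritParams depth_dose_profile
#' @param subsamples Sub-points per bin for averaging sigma (default 8).
#' @return A [depth_profile()].
#' @export
production_profile <- function(E0, nuclide, xs = xs_fixture(nuclide),
                               model = stopping_model(), material = water_gel(),
                               dz_mm = 0.5, zmax_mm = NULL, straggle = TRUE,
                               fluence_lambda_mm = 1000, subsamples = 8) {
  if (abs(xs$threshold_MeV - nuclide$threshold_MeV) > 1e-9)
    stop("cross-section threshold (", xs$threshold_MeV,
         " MeV) does not match nuclide ", nuclide$name,
         " (", nuclide$threshold_MeV, " MeV)")
  R <- range_from_energy(E0, model, material)
  sig <- straggling_sigma_mm(R)
  need <- R + (if (straggle) 6 * sig else 0) + 2 * dz_mm
  if (is.null(zmax_mm)) zmax_mm <- need
  if (zmax_mm < need)
    stop(sprintf("depth grid must extend to at least %.1f mm for E0 = %g MeV",
                 need, E0))
  g <- depth_grid(zmax_mm, dz_mm)
  n_t <- target_density(nuclide, material)
  # sigma averaged over sub-bin quadrature points (midpoint rule)
  off <- (seq_len(subsamples) - 0.5) / subsamples * dz_mm
  zs <- rep(g$edges_mm[-length(g$edges_mm)], each = subsamples) + off
  Es <- energy_at_depth(E0, zs, model, material)
  sig_bar <- colMeans(matrix(sigma_at(xs, Es), nrow = subsamples))
  y <- n_t * sig_bar
  if (is.finite(fluence_lambda_mm)) y <- y * exp(-g$depth_mm / fluence_lambda_mm)
  if (straggle) y <- convolve_gauss(y, dz_mm, sig)
  depth_profile(g$depth_mm, y)
}

#' 3D yield maps for a pencil beam in a phantom
#'
#' Distributes each nuclide's 1D production profile over the beam's uniform
#' disc footprint: every z-slab shares the profile value equally among the
#' lateral voxels whose centres lie inside the disc, so summing a map over
#' x and y reproduces the 1D profile bin for bin.
#'
#' @param beam A [beam_spec()]; entry defaults to the face centre and the
#'   footprint must lie inside the phantom face.
#' @param phantom A [phantom_spec()]; its z voxel size sets the depth bins.
#' @param nuclides List of [nuclide_spec()] (default the full registry).
#' @param xs_set Named list of matching [cross_section()] curves.
#' @inheritParams production_profile
#' @return Object of class `yield_map_set`: list with `maps` (named list of
#'   3D arrays), `phantom`, `beam`, and the 1D `profiles`.
#' @export
yield_map_3d <- function(beam, phantom = phantom_spec(),
                         nuclides = nuclide_registry(),
                         xs_set = xs_set_default(),
                         model = stopping_model(), straggle = TRUE,
                         fluence_lambda_mm = 1000) {
  stopifnot(inherits(beam, "beam_spec"), inherits(phantom, "phantom_spec"))
  entry <- beam$entry_mm %||% (phantom$size_mm[1:2] / 2)
  r <- beam$diameter_mm / 2
  if (entry[1] - r < 0 || entry[1] + r > phantom$size_mm[1] ||
      entry[2] - r < 0 || entry[2] + r > phantom$size_mm[2])
    stop("beam footprint falls outside the phantom face")
  xc <- (seq_len(phantom$dim[1]) - 0.5) * phantom$voxel_mm[1]
  yc <- (seq_len(phantom$dim[2]) - 0.5) * phantom$voxel_mm[2]
  disc <- outer(xc, yc, function(x, y) (x - entry[1])^2 + (y - entry[2])^2 <= r^2)
  if (!any(disc)) stop("beam footprint covers no voxel centres")
  w <- disc / sum(disc)
  dz <- phantom$voxel_mm[3]
  zmax <- phantom$size_mm[3]
  maps <- list(); profiles <- list()
  for (nm in names(nuclides)) {
    prof <- production_profile(beam$energy_MeV, nuclides[[nm]], xs_set[[nm]],
                               model = model, material = phantom$material,
                               dz_mm = dz, zmax_mm = NULL,
                               straggle = straggle,
                               fluence_lambda_mm = fluence_lambda_mm)
    nz <- phantom$dim[3]
    v <- numeric(nz)
    n <- min(nz, nrow(prof))
    v[seq_len(n)] <- prof$value[seq_len(n)]
    maps[[nm]] <- outer(w, v)  # dim (nx, ny, nz)
    profiles[[nm]] <- depth_profile((seq_len(nz) - 0.5) * dz, v)
  }
  structure(list(maps = maps, profiles = profiles, phantom = phantom,
                 beam = beam),
            class = "yield_map_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
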