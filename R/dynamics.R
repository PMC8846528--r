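# Time dynamics: decay of the activated nuclei into dynamic PET-like frames.
# t = 0 is the end of irradiation; the irradiation itself is treated as an
# impulse, so each voxel starts with a fixed nuclide inventory N0.

#' Dynamic frame schedule
#'
#' Contiguous, non-overlapping frames. The default is 75 one-minute frames
#' starting at the end of irradiation; delayed acquisitions (e.g. a 15-75 min
#' window) are expressed through `t0_s`.
#'
#' @param n_frames Number of frames (default 75).
#' @param frame_s Frame duration in seconds (default 60).
#' @param t0_s Start of the first frame, seconds after irradiation end.
#' @return Object of class `frame_schedule`: data frame with `start_s`,
#'   `end_s`.
#' @export
frame_schedule <- function(n_frames = 75, frame_s = 60, t0_s = 0) {
  stopifnot(n_frames >= 1, frame_s > 0, t0_s >= 0)
  start <- t0_s + (seq_len(n_frames) - 1) * frame_s
  structure(data.frame(start_s = start, end_s = start + frame_s),
            class = c("frame_schedule", "data.frame"))
}

validate_schedule <- function(schedule) {
  stopifnot(is.data.frame(schedule),
            all(c("start_s", "end_s") %in% names(schedule)))
  if (any(schedule$end_s <= schedule$start_s)) stop("frames must have positive duration")
  if (nrow(schedule) > 1 &&
      any(abs(schedule$start_s[-1] - schedule$end_s[-nrow(schedule)]) > 1e-9))
    stop("frames must be contiguous and non-overlapping")
  invisible(schedule)
}

#' Radioactive decay activity
#'
#' A(t) = lambda * N0 * exp(-lambda t) for an initial inventory of N0 nuclei.
#'
#' @param N0 Initial number of nuclei (>= 0).
#' @param lambda_s Decay constant in 1/s (> 0).
#' @param t_s Time(s) since irradiation end, seconds (>= 0).
#' @return Activity in the same (arbitrary) units as N0 per second.
#' @export
activity_at <- function(N0, lambda_s, t_s) {
  if (any(lambda_s <= 0)) stop("decay constant must be positive")
  stopifnot(all(N0 >= 0), all(t_s >= 0))
  lambda_s * N0 * exp(-lambda_s * t_s)
}

#' Decays integrated over frames
#'
#' Closed-form number of decays of a single nuclide in each frame:
#' N0 * (exp(-lambda t1) - exp(-lambda t2)).
#'
#' @inheritParams activity_at
#' @param schedule A [frame_schedule()].
#' @return Numeric vector, one count per frame.
#' @export
decays_in_frames <- function(N0, lambda_s, schedule) {
  if (any(lambda_s <= 0)) stop("decay constant must be positive")
  validate_schedule(schedule)
  N0 * (exp(-lambda_s * schedule$start_s) - exp(-lambda_s * schedule$end_s))
}

#' Build a dynamic frame series from yield maps
#'
#' Converts per-nuclide 3D inventories into a 4D series of expected decay
#' counts per voxel and frame (no decay correction; the spectral stage works
#' on raw frame counts).
#'
#' @param yields A `yield_map_set` from [yield_map_3d()], or a named list of
#'   3D arrays on a common grid.
#' @param registry Nuclide registry supplying decay constants; names must
#'   cover the yield maps.
#' @param schedule A [frame_schedule()].
#' @param scale Global scale applied to the inventories (sets the count
#'   normalisation of the synthetic study; default 1).
#' @return Object of class `dynamic_series`: list with `counts` (4D array,
#'   x,y,z,frame), `schedule`, and `meta` (beam/phantom/seed when known).
#' @export
build_frames <- function(yields, registry = nuclide_registry(),
                         schedule = frame_schedule(), scale = 1) {
  validate_schedule(schedule)
  maps <- if (inherits(yields, "yield_map_set")) yields$maps else yields
  stopifnot(is.list(maps), length(maps) >= 1)
  dims <- lapply(maps, dim)
  if (length(unique(vapply(dims, paste, collapse = "x", ""))) != 1L)
    stop("yield maps must share one voxel grid")
  d <- dims[[1]]
  nt <- nrow(schedule)
  counts <- array(0, dim = c(d, nt))
  for (nm in names(maps)) {
    nuc <- registry[[nm]]
    if (is.null(nuc)) stop("no registry entry for yield map ", nm)
    w <- exp(-nuc$decay_constant_s * schedule$start_s) -
         exp(-nuc$decay_constant_s * schedule$end_s)
    m <- scale * maps[[nm]]
    for (k in seq_len(nt)) {
      counts[, , , k] <- counts[, , , k] + m * w[k]
    }
  }
  meta <- list(scale = scale)
  if (inherits(yields, "yield_map_set")) {
    meta$beam_energy_MeV <- yields$beam$energy_MeV
    meta$voxel_mm <- yields$phantom$voxel_mm
  }
  structure(list(counts = counts, schedule = schedule, meta = meta),
            class = "dynamic_series")
}

#' Apply Poisson counting noise
#'
#' Replaces every voxel-frame count by a Poisson draw with mean
#' `scale * count`. The draw is seeded and bit-reproducible; the caller's RNG
#' state is left untouched and the seed is recorded in the series metadata.
#'
#' @param series A `dynamic_series`.
#' @param scale Positive factor converting expected decays to expected
#'   detected counts.
#' @param seed Integer seed for the draw.
#' @return A `dynamic_series` with integer counts.
#' @export
add_poisson_noise <- function(series, scale = 1, seed = 1L) {
  stopifnot(inherits(series, "dynamic_series"), scale > 0)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister")
  noisy <- series
  lam <- scale * series$counts
  noisy$counts <- array(stats::rpois(length(lam), lam), dim = dim(lam))
  noisy$meta$noise_seed <- seed
  noisy$meta$noise_scale <- scale
  noisy
}

#' Extract a voxel time-activity curve
#'
#' @param series A `dynamic_series`.
#' @param voxel Integer vector (ix, iy, iz).
#' @return Counts per frame.
#' @export
voxel_tac <- function(series, voxel) {
  series$counts[voxel[1], voxel[2], voxel[3], ]
}
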