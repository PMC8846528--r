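# Spectral analysis: voxel-wise non-negative decomposition of time-activity
# curves onto a log-spaced grid of decaying exponentials, the S_v statistic,
# nuclide banding and component images.
#
# Model: C_v(t) = sum_j alpha_j * IRF_j(t), with IRF_j the frame-averaged
# impulse response exp(-beta_j t) and alpha_j >= 0 solved by non-negative
# least squares. Times are referenced to the start of the acquisition (first
# frame), the convention available for measured data; alpha_j is therefore
# the component activity at scan start, in frame-count units.

#' Logarithmic decay-constant grid
#'
#' M values of beta, log-uniformly spaced with exact endpoints. Defaults:
#' 1e-4 to 0.1 1/s with M = 1000, spanning half-lives of about 2 hours down
#' to 7 seconds; consecutive values differ by a constant factor (~0.7%).
#'
#' @param beta_min,beta_max Grid bounds in 1/s (0 < min < max).
#' @param M Number of grid points (>= 2).
#' @return Object of class `beta_grid`: numeric vector of beta values with
#'   attributes `beta_min`, `beta_max`, `M`.
#' @export
make_beta_grid <- function(beta_min = 1e-4, beta_max = 0.1, M = 1000) {
  if (!(is.numeric(beta_min) && is.numeric(beta_max) && beta_min > 0 && beta_min < beta_max))
    stop("require 0 < beta_min < beta_max")
  if (M < 2 || M != round(M)) stop("M must be an integer >= 2")
  g <- exp(seq(log(beta_min), log(beta_max), length.out = M))
  g[1] <- beta_min; g[M] <- beta_max
  structure(g, beta_min = beta_min, beta_max = beta_max, M = as.integer(M),
            class = c("beta_grid", "numeric"))
}

#' Frame-averaged impulse-response basis
#'
#' Matrix of pre-calculated impulse responses: entry (i, j) is the average of
#' exp(-beta_j t) over frame i,
#' (exp(-beta_j t1) - exp(-beta_j t2)) / (beta_j (t2 - t1)),
#' with frame times re-referenced to the start of the first frame. Every
#' entry lies in (0, 1] and each column decreases over frames.
#'
#' @param schedule A [frame_schedule()].
#' @param grid A [make_beta_grid()].
#' @return Matrix (frames x M) of class `irf_basis` with the grid attached as
#'   attribute `beta`.
#' @export
build_irf_basis <- function(schedule, grid = make_beta_grid()) {
  validate_schedule(schedule)
  t1 <- schedule$start_s - schedule$start_s[1]
  t2 <- schedule$end_s - schedule$start_s[1]
  B <- vapply(as.numeric(grid), function(b) {
    (exp(-b * t1) - exp(-b * t2)) / (b * (t2 - t1))
  }, numeric(nrow(schedule)))
  B <- matrix(B, nrow = nrow(schedule))
  structure(B, beta = as.numeric(grid), class = c("irf_basis", "matrix", "array"))
}

#' Non-negative spectral fit of one time-activity curve
#'
#' Solves min || tac - basis alpha ||_2 subject to alpha >= 0 (Lawson-Hanson
#' active set). The solution is deterministic; an all-zero curve yields an
#' all-zero spectrum with zero residual.
#'
#' @param tac Counts per frame (length = rows of the basis, >= 0).
#' @param basis An [build_irf_basis()] matrix.
#' @return Object of class `spectral_fit`: list with `alpha` (length M,
#'   >= 0), `beta` (the grid), `residual` (L2 norm), `fitted`.
#' @export
fit_voxel <- function(tac, basis) {
  if (length(tac) != nrow(basis))
    stop("tac length (", length(tac), ") does not match basis frames (",
         nrow(basis), ")")
  if (any(tac < 0)) stop("counts must be non-negative")
  beta <- attr(basis, "beta")
  if (all(tac == 0)) {
    alpha <- numeric(ncol(basis))
  } else {
    alpha <- pracma::lsqnonneg(unclass(basis), as.numeric(tac))$x
  }
  fitted <- as.numeric(basis %*% alpha)
  structure(list(alpha = alpha, beta = beta,
                 residual = sqrt(sum((tac - fitted)^2)), fitted = fitted),
            class = "spectral_fit")
}

#' The S_v statistic
#'
#' S_v = sum_j alpha_j beta_j. Weighting each amplitude by its decay rate
#' enhances short-half-life components (15O, 13N) over the long-lived 11C
#' background.
#'
#' @param fit A `spectral_fit`, or a non-negative amplitude vector (then
#'   `beta` must be given).
#' @param beta Grid values when `fit` is a plain vector.
#' @return Non-negative scalar.
#' @export
sv_statistic <- function(fit, beta = NULL) {
  if (inherits(fit, "spectral_fit")) sum(fit$alpha * fit$beta)
  else {
    stopifnot(!is.null(beta), length(fit) == length(beta))
    sum(fit * beta)
  }
}

#' Nuclide bands on the beta grid
#'
#' Splits the grid into per-nuclide intervals \[beta_lo, beta_hi) with
#' boundaries at the geometric midpoints of consecutive registry decay
#' constants -- symmetric in log(beta), the grid's natural metric. NNLS
#' splits a single exponential across adjacent grid points, so component
#' amplitudes are read off as band sums rather than single grid entries.
#'
#' @param registry Nuclide registry (default [nuclide_registry()]).
#' @param grid A [make_beta_grid()] supplying the outer limits.
#' @return Data frame (class `nuclide_bands`): `nuclide`, `beta_lo`,
#'   `beta_hi`, `beta_true`, ordered by increasing beta.
#' @export
nuclide_bands <- function(registry = nuclide_registry(), grid = make_beta_grid()) {
  lam <- sort(vapply(registry, function(n) n$decay_constant_s, 0))
  cuts <- sqrt(lam[-1] * lam[-length(lam)])
  lo <- c(attr(grid, "beta_min"), cuts)
  hi <- c(cuts, attr(grid, "beta_max") * (1 + 1e-12))
  structure(data.frame(nuclide = names(lam), beta_lo = lo, beta_hi = hi,
                       beta_true = lam, row.names = NULL),
            class = c("nuclide_bands", "data.frame"))
}

#' Band summary of a spectral fit
#'
#' Sums amplitudes within each nuclide band and reports the
#' amplitude-weighted mean beta (the robust readout of a component's decay
#' constant under grid discreteness) and the corresponding half-life.
#'
#' @param fit A `spectral_fit`.
#' @param bands A [nuclide_bands()] table.
#' @return Data frame: `nuclide`, `alpha_sum`, `beta_weighted`,
#'   `half_life_min` (NA where a band holds no amplitude).
#' @export
band_summary <- function(fit, bands = nuclide_bands()) {
  stopifnot(inherits(fit, "spectral_fit"))
  out <- lapply(seq_len(nrow(bands)), function(i) {
    sel <- fit$beta >= bands$beta_lo[i] & fit$beta < bands$beta_hi[i]
    a <- fit$alpha[sel]
    s <- sum(a)
    bw <- if (s > 0) sum(a * fit$beta[sel]) / s else NA_real_
    data.frame(nuclide = bands$nuclide[i], alpha_sum = s, beta_weighted = bw,
               half_life_min = if (is.na(bw)) NA_real_ else log(2) / bw / 60)
  })
  do.call(rbind, out)
}

#' Voxel-wise spectral analysis of a dynamic series
#'
#' Fits every voxel in `mask` (default: voxels with any counts). For
#' tractability on full volumes, pass a beam-axis mask; the default
#' synthetic phantoms confine activity to the beam column anyway.
#'
#' @param series A `dynamic_series`.
#' @param grid A [make_beta_grid()].
#' @param mask Logical 3D array selecting voxels; `NULL` fits all voxels
#'   with a positive total count.
#' @return Object of class `spectral_fit_map`: list with `alpha` (voxels x
#'   M matrix), `voxels` (integer matrix of ix, iy, iz), `beta`, `dim`,
#'   `residual`.
#' @export
fit_series <- function(series, grid = make_beta_grid(), mask = NULL) {
  stopifnot(inherits(series, "dynamic_series"))
  d <- dim(series$counts)[1:3]
  tot <- apply(series$counts, 1:3, sum)
  if (is.null(mask)) mask <- tot > 0
  stopifnot(identical(dim(mask), d))
  idx <- which(mask, arr.ind = TRUE)
  basis <- build_irf_basis(series$schedule, grid)
  alpha <- matrix(0, nrow = nrow(idx), ncol = length(grid))
  resid <- numeric(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    tac <- series$counts[idx[i, 1], idx[i, 2], idx[i, 3], ]
    f <- fit_voxel(tac, basis)
    alpha[i, ] <- f$alpha
    resid[i] <- f$residual
  }
  structure(list(alpha = alpha, voxels = idx, beta = as.numeric(grid),
                 dim = d, residual = resid),
            class = "spectral_fit_map")
}

#' S_v map of a fitted series
#'
#' @param fits A `spectral_fit_map`.
#' @return 3D array of S_v values (zero outside the fitted mask).
#' @export
sv_map <- function(fits) {
  stopifnot(inherits(fits, "spectral_fit_map"))
  out <- array(0, dim = fits$dim)
  out[fits$voxels] <- as.numeric(fits$alpha %*% fits$beta)
  out
}

#' Background threshold mask
#'
#' Keeps voxels with S_v strictly greater than the threshold (default 1.5,
#' in the count units of the series normalisation), removing the background
#' region.
#'
#' @param sv 3D array of S_v values (e.g. [sv_map()]).
#' @param threshold Non-negative cut (strict inequality).
#' @return Logical array of the same dimension.
#' @export
threshold_mask <- function(sv, threshold = 1.5) {
  if (threshold < 0) stop("threshold must be non-negative")
  sv > threshold
}

#' Per-nuclide component image
#'
#' Sums each voxel's amplitudes over one nuclide's beta band, isolating that
#' component -- in particular the 13N image whose peak tracks the Bragg peak.
#'
#' @param fits A `spectral_fit_map`.
#' @param bands A [nuclide_bands()] table.
#' @param nuclide Band to extract (default `"N13"`).
#' @return 3D array of band amplitude sums.
#' @export
component_image <- function(fits, bands = nuclide_bands(), nuclide = "N13") {
  stopifnot(inherits(fits, "spectral_fit_map"))
  i <- match(nuclide, bands$nuclide)
  if (is.na(i)) stop("unknown nuclide: ", nuclide)
  sel <- fits$beta >= bands$beta_lo[i] & fits$beta < bands$beta_hi[i]
  out <- array(0, dim = fits$dim)
  out[fits$voxels] <- rowSums(fits$alpha[, sel, drop = FALSE])
  out
}

#' ROI spectrum
#'
#' Sums fitted amplitudes over the voxels of a region of interest and
#' reports the spectrum against half-life (ln 2 / beta), the display used
#' for whole/edge/plateau/peak region comparisons.
#'
#' @param fits A `spectral_fit_map`.
#' @param roi Logical 3D array, or an integer matrix of voxel indices.
#' @return Data frame: `beta_s`, `half_life_min`, `alpha`.
#' @export
roi_spectrum <- function(fits, roi) {
  stopifnot(inherits(fits, "spectral_fit_map"))
  if (is.array(roi) && is.logical(roi)) {
    stopifnot(identical(dim(roi), fits$dim))
    inroi <- roi[fits$voxels]
  } else {
    roi <- as.matrix(roi)
    key <- function(m) paste(m[, 1], m[, 2], m[, 3])
    inroi <- key(fits$voxels) %in% key(roi)
  }
  if (!any(inroi)) stop("ROI contains no fitted voxels")
  a <- colSums(fits$alpha[inroi, , drop = FALSE])
  data.frame(beta_s = fits$beta, half_life_min = log(2) / fits$beta / 60,
             alpha = a)
}

#' Band masses of an ROI spectrum
#'
#' @param spectrum Output of [roi_spectrum()].
#' @param bands A [nuclide_bands()] table.
#' @return Named numeric vector of summed alpha per nuclide band.
#' @export
spectrum_band_mass <- function(spectrum, bands = nuclide_bands()) {
  vapply(seq_len(nrow(bands)), function(i) {
    sel <- spectrum$beta_s >= bands$beta_lo[i] & spectrum$beta_s < bands$beta_hi[i]
    sum(spectrum$alpha[sel])
  }, 0) |> stats::setNames(bands$nuclide)
}
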