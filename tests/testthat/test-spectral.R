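# Spectral analysis: beta grid, IRF basis, NNLS fits, S_v, banding.

test_that("the beta grid is log-uniform with exact endpoints", {
  g <- make_beta_grid()
  expect_length(g, 1000)
  expect_identical(g[1], 1e-4)
  expect_identical(g[1000], 0.1)
  r <- g[-1] / g[-length(g)]
  expect_equal(max(r) / min(r), 1, tolerance = 1e-12)
  expect_equal(as.numeric(make_beta_grid(1e-3, 1e-2, 2)), c(1e-3, 1e-2))
  expect_error(make_beta_grid(0.1, 1e-4), "beta_min < beta_max")
  expect_error(make_beta_grid(0, 0.1), "beta_min")
  expect_error(make_beta_grid(1e-4, 0.1, 1), "M must be")
})

test_that("IRF entries are frame-averaged exponentials", {
  sched <- frame_schedule(10)
  g <- make_beta_grid(1e-4, 0.1, 50)
  B <- build_irf_basis(sched, g)
  expect_equal(dim(B), c(10L, 50L))
  expect_true(all(B > 0 & B <= 1))
  # columns strictly decrease over frames
  expect_true(all(apply(B, 2, function(col) all(diff(col) < 0))))
  # hand value against numerical quadrature for beta = 1e-3, frame [0, 60]
  b <- 1e-3
  oracle <- stats::integrate(function(t) exp(-b * t), 0, 60,
                             rel.tol = 1e-12)$value / 60
  j <- which.min(abs(as.numeric(g) - b))
  Bb <- build_irf_basis(sched, make_beta_grid(b, 0.1, 10))
  expect_equal(Bb[1, 1], oracle, tolerance = 1e-10)
  # slow-decay limit: entry -> 1
  Bs <- build_irf_basis(sched, make_beta_grid(1e-9, 1e-8, 2))
  expect_equal(Bs[1, 1], 1, tolerance = 1e-6)
})

test_that("basis times are referenced to acquisition start", {
  g <- make_beta_grid(1e-3, 1e-2, 5)
  B0 <- build_irf_basis(frame_schedule(10), g)
  B15 <- build_irf_basis(frame_schedule(10, t0_s = 900), g)
  expect_equal(unclass(B0), unclass(B15))
})

test_that("NNLS recovers a mono-exponential within one grid step", {
  sched <- frame_schedule()
  g <- make_beta_grid()
  basis <- build_irf_basis(sched, g)
  step <- (0.1 / 1e-4)^(1 / 999)
  for (b_true in c(3e-4, 1.16e-3, 5.7e-3, 2e-2)) {
    tac <- 50 * (exp(-b_true * sched$start_s) - exp(-b_true * sched$end_s)) / b_true
    f <- fit_voxel(tac, basis)
    bw <- sum(f$alpha * f$beta) / sum(f$alpha)
    expect_lt(abs(log(bw / b_true)), log(step) * 1.0001)
  }
})

test_that("NNLS residual never beats zero but never loses to brute force", {
  sched <- frame_schedule(40)
  g <- make_beta_grid(1e-4, 0.1, 200)
  basis <- build_irf_basis(sched, g)
  set.seed(11)
  for (k in 1:5) {
    lam <- 10^runif(2, -3.5, -1.5)
    tac <- (exp(-lam[1] * sched$start_s) - exp(-lam[1] * sched$end_s)) / lam[1] +
      0.5 * (exp(-lam[2] * sched$start_s) - exp(-lam[2] * sched$end_s)) / lam[2] +
      abs(rnorm(40, sd = 0.5))
    f <- fit_voxel(tac, basis)
    expect_lte(f$residual, brute_force_single(tac, basis) + 1e-9)
    expect_lte(f$residual, sqrt(sum(tac^2)))
  }
})

test_that("fits are deterministic, scale-equivariant, and reject bad input", {
  sched <- frame_schedule(30)
  basis <- build_irf_basis(sched, make_beta_grid(1e-4, 0.1, 100))
  tac <- decays_in_frames(40, 1.2e-3, sched)
  f1 <- fit_voxel(tac, basis)
  f2 <- fit_voxel(tac, basis)
  expect_identical(f1$alpha, f2$alpha)
  f3 <- fit_voxel(3 * tac, basis)
  expect_equal(f3$alpha, 3 * f1$alpha, tolerance = 1e-6)
  z <- fit_voxel(rep(0, 30), basis)
  expect_true(all(z$alpha == 0))
  expect_equal(z$residual, 0)
  expect_error(fit_voxel(tac[-1], basis), "does not match")
  expect_error(fit_voxel(-tac, basis), "non-negative")
})

test_that("S_v weights amplitudes by decay rate", {
  g <- make_beta_grid(1e-4, 0.1, 100)
  a <- numeric(100)
  expect_equal(sv_statistic(a, as.numeric(g)), 0)
  a[40] <- 2.5
  expect_equal(sv_statistic(a, as.numeric(g)), 2.5 * g[40])
  # equal amplitudes: S_v ordered by beta, short half-life enhanced
  reg <- nuclide_registry()
  sched <- frame_schedule()
  basis <- build_irf_basis(sched, make_beta_grid())
  sv <- vapply(reg, function(n) {
    tac <- decays_in_frames(1 / n$decay_constant_s, n$decay_constant_s, sched)
    sv_statistic(fit_voxel(tac, basis))
  }, 0)
  expect_true(sv[["O15"]] > sv[["N13"]])
  expect_true(sv[["N13"]] > sv[["C11"]])
  # linearity of sum(alpha * beta) under combined fits
  a2 <- a; a2[70] <- 1.5
  expect_equal(sv_statistic(a + a2, as.numeric(g)),
               sv_statistic(a, as.numeric(g)) + sv_statistic(a2, as.numeric(g)))
})

test_that("the background threshold is a strict inequality", {
  sv <- array(c(0, 1.5, 1.5000001, 3), c(2, 2, 1))
  m <- threshold_mask(sv)
  expect_equal(as.vector(m), c(FALSE, FALSE, TRUE, TRUE))
  expect_true(all(threshold_mask(sv, 0)[sv > 0]))
  # raising the threshold never adds voxels
  m2 <- threshold_mask(sv, 2)
  expect_true(all(!m2 | m))
  expect_error(threshold_mask(sv, -1), "non-negative")
  expect_false(any(threshold_mask(array(0, c(2, 2, 1)))))
})

test_that("bands are disjoint, ordered, and contain their decay constants", {
  bands <- nuclide_bands()
  expect_equal(bands$nuclide, c("C11", "N13", "O15"))
  expect_true(all(bands$beta_lo < bands$beta_hi))
  expect_true(all(head(bands$beta_hi, -1) <= tail(bands$beta_lo, -1) + 1e-15))
  expect_true(all(bands$beta_true >= bands$beta_lo & bands$beta_true < bands$beta_hi))
  # boundaries at geometric midpoints of the registry decay constants
  expect_equal(bands$beta_lo[2], 8.105e-4, tolerance = 1e-3)
  expect_equal(bands$beta_lo[3], 2.564e-3, tolerance = 1e-3)
})

test_that("band leakage is small for pure single-nuclide curves", {
  reg <- nuclide_registry()
  sched <- frame_schedule()
  basis <- build_irf_basis(sched, make_beta_grid())
  bands <- nuclide_bands()
  for (nm in c("C11", "N13", "O15")) {
    lam <- reg[[nm]]$decay_constant_s
    tac <- decays_in_frames(100, lam, sched)
    f <- fit_voxel(tac, basis)
    bs <- band_summary(f, bands)
    own <- bs$alpha_sum[bs$nuclide == nm]
    expect_gte(own / sum(bs$alpha_sum), 0.90)
  }
  # pure 11C leaks < 1% into the 13N band
  f <- fit_voxel(decays_in_frames(100, reg$C11$decay_constant_s, sched), basis)
  bs <- band_summary(f, bands)
  expect_lt(bs$alpha_sum[bs$nuclide == "N13"] / sum(bs$alpha_sum), 0.01)
})

test_that("a single-voxel ROI spectrum equals that voxel's fit", {
  s <- demo_study_80()
  v <- s$fits$voxels[5, , drop = FALSE]
  sp <- roi_spectrum(s$fits, v)
  expect_equal(sp$alpha, as.numeric(s$fits$alpha[5, ]))
  expect_equal(sp$half_life_min, log(2) / s$fits$beta / 60)
  empty <- array(FALSE, s$fits$dim)
  expect_error(roi_spectrum(s$fits, empty), "no fitted voxels")
})

test_that("the 13N component image peaks where the 13N yield peaks", {
  s <- demo_study_80()
  ci <- component_image(s$fits, nuclide = "N13")
  p_sa <- find_peak(depth_profile_from_volume(ci, s$phantom$voxel_mm))$depth_mm
  p_mc <- find_peak(s$yields$profiles$N13)$depth_mm
  expect_lt(abs(p_sa - p_mc), 1)
  expect_error(component_image(s$fits, nuclide = "XX"), "unknown nuclide")
})
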