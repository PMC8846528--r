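# Range-energy model, residual energy and depth-dose profiles.

test_that("material and geometry validators enforce their invariants", {
  expect_error(material_composition(1.0, c(H = 0.5, C = 0.4)), "sum to 1")
  expect_error(material_composition(-1, c(H = 1)), "density")
  expect_error(material_composition(1, c(H = 0.5, N = 0.5)), "among H, C, O")
  wg <- water_gel()
  expect_equal(wg$density_g_cm3, 1.010)
  expect_equal(sum(wg$mass_fractions), 1)

  expect_error(phantom_spec(c(100, 100, 400), c(3, 10, 0.5)), "divide")
  ph <- phantom_spec()
  expect_equal(ph$dim, c(10L, 10L, 800L))

  expect_warning(beam_spec(30), "outside")
  expect_error(beam_spec(-5), "positive")
  expect_silent(b <- beam_spec(160))
  expect_equal(b$diameter_mm, 10)
})

test_that("range is zero at zero energy, increases with energy, scales with density", {
  m <- stopping_model()
  wg <- water_gel()
  expect_equal(range_from_energy(0, m, wg), 0)
  expect_error(range_from_energy(-1, m, wg), "negative")
  r <- range_from_energy(c(45, 80, 160), m, wg)
  expect_true(all(diff(r) > 0))
  # density scaling is exact in the closed form
  half <- material_composition(wg$density_g_cm3 / 2, wg$mass_fractions)
  expect_equal(range_from_energy(80, m, half), 2 * range_from_energy(80, m, wg))
})

test_that("closed-form range matches integration of the stopping-power table", {
  # independent oracle: trapezoidal integration of 1/S(E) from the packaged
  # table, done here rather than through the table-mode model
  tab <- water_stopping_table()
  E <- seq(0.5, 80, by = 0.05)
  S <- approx(tab$energy_MeV, tab$mass_stopping_MeV_cm2_g, xout = E)$y
  R_oracle <- (sum(0.05 / S) / 1.010) * 10
  expect_equal(R_oracle, 51.3, tolerance = 0.01)
  expect_equal(range_from_energy(80), R_oracle, tolerance = 0.015)
  # and the table-mode model agrees with its own source table
  expect_equal(range_from_energy(80, stopping_model("table")), R_oracle,
               tolerance = 0.005)
})

test_that("table-mode and Bragg-Kleeman ranges agree within 3% after refit", {
  mt <- stopping_model("table")
  E <- seq(45, 250, by = 5)
  Rt <- range_from_energy(E, mt)
  fit <- lm(log(Rt) ~ log(E))
  bk <- stopping_model(bk_alpha = exp(coef(fit)[1]) * 1.010 / 10,
                       bk_p = unname(coef(fit)[2]))
  Rb <- range_from_energy(E, bk)
  expect_true(all(abs(Rb / Rt - 1) < 0.03))
})

test_that("residual energy inverts the range-energy relation", {
  m <- stopping_model()
  expect_equal(energy_at_depth(80, 0, m), 80)
  R <- range_from_energy(80, m)
  expect_equal(energy_at_depth(80, R, m), 0)
  expect_equal(energy_at_depth(80, R + 10, m), 0)
  expect_error(energy_at_depth(80, -1, m), "non-negative")

  # residual-range identity on 100 random (E0, z) pairs
  set.seed(42)
  E0 <- runif(100, 45, 250)
  R0 <- range_from_energy(E0, m)
  z <- runif(100, 0, 0.99) * R0
  Ez <- mapply(function(e, zz) energy_at_depth(e, zz, m), E0, z)
  expect_equal(range_from_energy(Ez, m), R0 - z, tolerance = 1e-6)
  # energy strictly decreasing with depth
  zs <- seq(0, 0.99 * range_from_energy(160, m), length.out = 50)
  expect_true(all(diff(energy_at_depth(160, zs, m)) < 0))
})

test_that("table-mode residual energy satisfies the same identities", {
  mt <- stopping_model("table")
  expect_equal(energy_at_depth(80, 0, mt), 80, tolerance = 1e-6)
  R <- range_from_energy(80, mt)
  expect_equal(energy_at_depth(80, R, mt), 0)
  set.seed(7)
  E0 <- runif(20, 45, 250)
  R0 <- range_from_energy(E0, mt)
  z <- runif(20, 0, 0.95) * R0
  Ez <- mapply(function(e, zz) energy_at_depth(e, zz, mt), E0, z)
  expect_equal(range_from_energy(Ez, mt), R0 - z, tolerance = 1e-4)
})

test_that("depth-dose profile peaks near the printed 80 MeV Bragg depth", {
  p <- depth_dose_profile(80)
  peak <- p$depth_mm[which.max(p$value)]
  expect_lt(abs(peak - 50.0), 2)
  expect_true(all(p$value >= 0))
  # single global maximum: values rise then fall
  k <- which.max(p$value)
  nz <- p$value > max(p$value) * 1e-9
  expect_true(all(diff(p$value[1:k]) >= -1e-12))
  expect_true(all(diff(p$value[k:max(which(nz))]) <= 1e-12))
})

test_that("without straggle the profile integrates to the incident energy", {
  for (E0 in c(45, 80, 160, 250)) {
    p <- depth_dose_profile(E0, straggle = FALSE, fluence_lambda_mm = Inf)
    dz <- diff(p$depth_mm[1:2])
    expect_equal(sum(p$value) * dz, E0, tolerance = 1e-9)
  }
})

test_that("dose vanishes beyond the range plus the straggle tail", {
  R <- range_from_energy(240)
  sig <- straggling_sigma_mm(R)
  p <- depth_dose_profile(240, zmax_mm = R + 8 * sig)
  expect_true(all(p$value[p$depth_mm > R + 5 * sig] < max(p$value) * 1e-6))
})

test_that("a too-short grid is rejected with the required extent named", {
  expect_error(depth_dose_profile(160, zmax_mm = 100), "at least")
})

test_that("Bragg-peak depth increases strictly with energy across the sweep", {
  E <- seq(45, 250, by = 5)
  peaks <- vapply(E, function(e) {
    p <- depth_dose_profile(e)
    p$depth_mm[which.max(p$value)]
  }, 0)
  expect_true(all(diff(peaks) > 0))
})
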