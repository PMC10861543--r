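# Voxel encoding model, motion phase, dephasing and Rician noise.

test_that("static voxel attenuation follows S = S0 exp(-b g'Dg)", {
  g <- c(1, 0, 0)
  s <- encode_voxel(1.578e-3, 1, 350, g)
  expect_equal(s$magnitude, 0.57560, tolerance = 1e-4)   # exp(-0.5523)
  expect_equal(s$phase, 0)
  s2 <- encode_voxel(2.21e-3, 1, 350, g)
  expect_equal(s2$magnitude, 0.46139, tolerance = 1e-4)  # exp(-0.7735)
  # anisotropic tensor: only the projection g'Dg matters
  D <- diag(c(2, 1, 1)) * 1e-3
  sx <- encode_voxel(D, 1, 350, c(1, 0, 0))
  expect_equal(sx$magnitude, exp(-350 * 2e-3))
  sy <- encode_voxel(D, 1, 350, c(0, 1, 0))
  expect_equal(sy$magnitude, exp(-350 * 1e-3))
})

test_that("encode_voxel validates inputs", {
  expect_error(encode_voxel(1e-3, 1, 350, c(1, 1, 0)), "unit vector")
  expect_error(encode_voxel(1e-3, -1, 350, c(1, 0, 0)))
  expect_error(encode_voxel(-1e-3, 1, 350, c(1, 0, 0)), "semi-definite")
  expect_error(encode_voxel(matrix(rnorm(9), 3), 1, 350, c(1, 0, 0)),
               "symmetric")
})

test_that("motion phase equals the brute-force trajectory integral", {
  set.seed(11)
  for (wf in list(wf_m0, wf_m012)) {
    for (i in 1:5) {
      g <- rnorm(3); g <- g / sqrt(sum(g^2))
      mo <- motion_state(r0 = rnorm(3, 0, 1e-3), v = rnorm(3, 0, 0.02),
                         a = rnorm(3, 0, 2))
      s <- encode_voxel(1.5e-3, 1, 350, g, wf = wf, motion = mo)
      expect_equal(s$phase, phase_oracle(wf, g, mo$r0, mo$v, mo$a),
                   tolerance = 1e-10)
    }
  }
})

test_that("moment-nulled encoding is invariant to any rigid motion", {
  set.seed(12)
  static <- encode_voxel(1.5e-3, 1, 350, c(1, 0, 0))
  for (i in 1:10) {
    mo <- motion_state(r0 = rnorm(3, 0, 5e-3), v = rnorm(3, 0, 0.1),
                       a = rnorm(3, 0, 20), v_spread = runif(1, 0, 0.05))
    s <- encode_voxel(1.5e-3, 1, 350, c(1, 0, 0), wf = wf_m012, motion = mo)
    expect_equal(s$phase, 0, tolerance = 1e-6)
    expect_equal(s$magnitude, static$magnitude, tolerance = 1e-9)
  }
})

test_that("Gaussian dephasing matches the isochromat-ensemble oracle", {
  mo <- motion_state(v = c(0.01, 0, 0), v_spread = 0.002)
  g <- c(1, 0, 0)
  closed <- encode_voxel(1.5e-3, 1, 350, g, wf = wf_m0, motion = mo)
  ens <- encode_voxel_ensemble(1.5e-3, 1, 350, g, wf_m0, motion = mo,
                               n_iso = 50000, seed = 4)
  expect_equal(ens$magnitude, closed$magnitude, tolerance = 0.02)
  # moderate dephasing regime: factor well below 1 but well above 0
  expect_lt(closed$magnitude, 0.9 * encode_voxel(1.5e-3, 1, 350, g)$magnitude)
  expect_gt(closed$magnitude, 0)
})

test_that("Rician noise has the Rayleigh mean at zero signal and vanishes at high SNR", {
  x <- array(0, c(100, 100, 100))
  y <- add_rician_noise(x, sigma = 1, seed = 9)
  # Rayleigh mean sigma * sqrt(pi/2) = 1.25331; MC se ~ 0.0007
  expect_equal(mean(y), 1.25331, tolerance = 3e-3)
  z <- add_rician_noise(array(100, c(10, 10)), snr = 1e9, seed = 2)
  expect_equal(as.vector(z), rep(100, 100), tolerance = 1e-6)
  # seeded reproducibility
  expect_identical(add_rician_noise(x, sigma = 1, seed = 9), y)
})

test_that("simulated datasets are deterministic per seed and noiseless-reproducible", {
  ph <- make_pvp_phantom(pvp_reference_series("m012"))
  a <- simulate_dwi(ph, wf_m012, snr = 25, seed = 5)
  b <- simulate_dwi(ph, wf_m012, snr = 25, seed = 5)
  expect_identical(a$volumes, b$volumes)
  c1 <- simulate_dwi(ph, wf_m012, snr = NULL)
  c2 <- simulate_dwi(ph, wf_m012, snr = NULL)
  expect_identical(c1$volumes, c2$volumes)
  d <- simulate_dwi(ph, wf_m012, snr = 25, seed = 6)
  expect_false(identical(a$volumes, d$volumes))
  # encoding table: exactly one b = 0, unit bvecs for b > 0
  expect_identical(sum(a$bvals == 0), 1L)
  expect_equal(rowSums(a$bvecs[a$bvals > 0, ]^2), rep(1, 6))
})

test_that("noiseless attenuation is monotone in b and in g'Dg", {
  ph <- make_pvp_phantom(pvp_reference_series("m012"))
  wf_low <- design_motion_compensated(encoding_spec(150, 2))
  hi <- simulate_dwi(ph, wf_m012, snr = NULL)
  lo <- simulate_dwi(ph, wf_low, snr = NULL)
  msk <- ph$region_map > 0
  for (k in 2:7) {
    expect_true(all(hi$volumes[, , , k][msk] < hi$volumes[, , , 1][msk]))
    expect_true(all(hi$volumes[, , , k][msk] < lo$volumes[, , , k][msk]))
  }
  # higher diffusivity vial attenuates more (vial 1 D > vial 6 D)
  v1 <- mean(hi$volumes[, , , 2][ph$region_map == 1])
  v6 <- mean(hi$volumes[, , , 2][ph$region_map == 6])
  expect_lt(v1, v6)
})

test_that("uncompensated encoding dephases the moving myocardium; M012 does not", {
  demo <- motion_demo(make_cardiac_phantom())
  expect_lt(demo$retention_m0, 0.1)      # > 90% myocardial signal lost
  expect_gt(demo$retention_m012, 0.99)   # fully retained
  expect_lt(demo$ratio_m0_over_m012, 0.1)
})
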