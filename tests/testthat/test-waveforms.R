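# Gradient waveform design, moments and b-value integration.

test_that("numerical b-value matches the Stejskal-Tanner closed form", {
  # rectangular idealization: G = 0.44 T/m, delta = 1 ms, Delta = 25.6 ms
  G <- 0.44; dt <- 1e-5
  samples <- c(rep(G, 100), rep(0, 2460), rep(G, 100))
  wf <- gradient_waveform(samples, dt, refocus_index = 1331)
  b_closed <- stejskal_tanner_bvalue(G, 1e-3, 25.6e-3)
  expect_equal(b_closed, 350.08, tolerance = 1e-4)       # hand-verified value
  expect_equal(numerical_bvalue(wf), b_closed, tolerance = 5e-3)
})

test_that("gradient moments reproduce analytic single-lobe and bipolar values", {
  G <- 0.44; dt <- 1e-5
  lobe <- gradient_waveform(rep(G, 100), dt)             # 1 ms rectangle
  m <- gradient_moments(lobe)
  expect_equal(m$m0, G * 1e-3)                           # G * delta
  expect_equal(m$m1, G * 1e-6 / 2)                       # G * delta^2 / 2
  bipolar <- gradient_waveform(c(rep(G, 50), rep(-G, 50)), dt)
  expect_equal(gradient_moments(bipolar)$m0, 0)
  zero <- gradient_waveform(rep(0, 10), dt)
  mz <- gradient_moments(zero)
  expect_identical(c(mz$m0, mz$m1, mz$m2), c(0, 0, 0))
  expect_equal(numerical_bvalue(zero), 0)
})

test_that("Stejskal-Tanner design hits the target b with nulled m0", {
  expect_equal(numerical_bvalue(wf_m0), 350, tolerance = 1e-9)
  m <- gradient_moments(wf_m0)
  expect_lt(abs(m$m0), 1e-9)
  expect_gt(abs(m$m1), 1e-7)                 # generically motion-sensitive
  expect_no_error(validate_waveform(wf_m0, hw_default))
  # b = 0 gives the null waveform
  wf0 <- design_stejskal_tanner(encoding_spec(0, 0), hw_default)
  expect_true(all(wf0$samples == 0))
  expect_equal(numerical_bvalue(wf0), 0)
})

test_that("infeasible b-value targets raise an informative error", {
  expect_error(
    design_stejskal_tanner(encoding_spec(350, 0), hw_default,
                           max_duration = 2e-3),
    "infeasible.*achievable b", ignore.case = TRUE)
  expect_error(
    design_motion_compensated(encoding_spec(5000, 2),
                              hardware_limits(g_max = 0.01),
                              max_duration = 0.01),
    "infeasible")
})

test_that("M012 design nulls m0, m1, m2 to tolerance at the target b", {
  m <- gradient_moments(wf_m012)
  expect_lt(abs(m$m0), 1e-9)      # T s/m
  expect_lt(abs(m$m1), 1e-12)     # T s^2/m
  expect_lt(abs(m$m2), 1e-15)     # T s^3/m
  expect_equal(numerical_bvalue(wf_m012), 350, tolerance = 1e-9)
  expect_no_error(validate_waveform(wf_m012, hw_default))
  # velocity-only compensation nulls m0 and m1 but not m2
  wf1 <- design_motion_compensated(encoding_spec(350, 1), hw_default)
  m1 <- gradient_moments(wf1)
  expect_lt(abs(m1$m0), 1e-9)
  expect_lt(abs(m1$m1), 1e-12)
  expect_gt(abs(m1$m2), 1e-9)
})

test_that("order-0 motion-compensated design delegates to Stejskal-Tanner", {
  wf <- design_motion_compensated(encoding_spec(350, 0), hw_default)
  expect_identical(wf$samples, wf_m0$samples)
  expect_identical(wf$refocus_index, wf_m0$refocus_index)
})

test_that("designs are deterministic and respect limits sample-wise", {
  for (order in 0:2) {
    a <- design_motion_compensated(encoding_spec(350, order), hw_default)
    b <- design_motion_compensated(encoding_spec(350, order), hw_default)
    expect_identical(a$samples, b$samples)
    expect_lte(max(abs(a$samples)), hw_default$g_max * (1 + 1e-12))
    expect_lte(max(abs(diff(a$samples))) / a$dt,
               hw_default$slew_max * (1 + 1e-12))
    expect_identical(a$samples[1], 0)
    expect_identical(a$samples[length(a$samples)], 0)
  }
})

test_that("b scales quadratically with amplitude", {
  wf <- wf_m0
  for (c_ in c(0.5, 2)) {
    scaled <- gradient_waveform(wf$samples * c_, wf$dt, wf$refocus_index)
    expect_equal(numerical_bvalue(scaled), c_^2 * numerical_bvalue(wf),
                 tolerance = 1e-12)
  }
})

test_that("time dilation scales moment n by alpha^(n+1)", {
  base <- gradient_moments(wf_m012)
  wf1 <- design_motion_compensated(encoding_spec(350, 1), hw_default)
  for (wf in list(wf_m0, wf1)) {
    m <- gradient_moments(wf)
    for (alpha in c(2, 3.5)) {
      dil <- gradient_waveform(wf$samples, wf$dt * alpha, wf$refocus_index)
      md <- gradient_moments(dil)
      expect_equal(md$m0, alpha * m$m0, tolerance = 1e-12)
      expect_equal(md$m1, alpha^2 * m$m1, tolerance = 1e-12)
      expect_equal(md$m2, alpha^3 * m$m2, tolerance = 1e-12)
    }
  }
})

test_that("waveform CSV round-trip preserves the design", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform(wf_m012, path)
  back <- read_waveform(path)
  expect_equal(back$samples, wf_m012$samples)
  expect_equal(back$dt, wf_m012$dt)
  expect_identical(back$refocus_index, wf_m012$refocus_index)
  expect_equal(numerical_bvalue(back), 350, tolerance = 1e-9)
})
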