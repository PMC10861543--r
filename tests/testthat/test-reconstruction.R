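# Tensor fitting, eigen-derived maps and ROI statistics.

test_that("noiseless isotropic round-trip recovers the tensor to float precision", {
  ph <- make_slab_phantom(c(1.578e-3, 1.578e-3, 1.578e-3, 0, 0, 0))
  dwi <- simulate_dwi(ph, wf_m012, snr = NULL)
  tf <- fit_tensor(dwi)
  Dm <- matrix(tf$D, ncol = 6)
  expect_equal(max(abs(Dm[, 1:3] - 1.578e-3)) / 1.578e-3, 0, tolerance = 1e-9)
  expect_lt(max(abs(Dm[, 4:6])), 1e-12)
  adc <- eigen_adc(tf)
  # reported in 1e-3 mm^2/s
  expect_equal(max(abs(adc$values - 1.578)), 0, tolerance = 1e-9)
})

test_that("noiseless anisotropic round-trip recovers diag(2,1,1)e-3 and MD", {
  ph <- make_slab_phantom(c(2e-3, 1e-3, 1e-3, 0, 0, 0))
  dwi <- simulate_dwi(ph, wf_m012, snr = NULL)
  tf <- fit_tensor(dwi)
  Dm <- matrix(tf$D, ncol = 6)
  expect_equal(Dm[1, ], c(2e-3, 1e-3, 1e-3, 0, 0, 0), tolerance = 1e-9)
  adc <- eigen_adc(tf)
  expect_equal(adc$values[1, 1, 1], 4 / 3, tolerance = 1e-9)
  ev <- tensor_eigen(tf)[1, 1, 1, ]
  expect_equal(ev, c(2e-3, 1e-3, 1e-3), tolerance = 1e-9)  # descending order
})

test_that("duplicating the encoding set leaves the least-squares fit unchanged", {
  ph <- make_slab_phantom(c(2e-3, 1.5e-3, 1e-3, 2e-4, -1e-4, 5e-5))
  dwi <- simulate_dwi(ph, wf_m012, snr = NULL)
  dup <- dwi
  dup$volumes <- array(dwi$volumes[, , , c(1:7, 2:7)],
                       c(dim(dwi$volumes)[1:3], 13L))
  dup$bvals <- dwi$bvals[c(1:7, 2:7)]
  dup$bvecs <- dwi$bvecs[c(1:7, 2:7), ]
  a <- fit_tensor(dwi); b <- fit_tensor(dup)
  expect_equal(a$D, b$D, tolerance = 1e-12)
})

test_that("tensor fit validates its inputs", {
  ph <- make_slab_phantom(c(1e-3, 1e-3, 1e-3, 0, 0, 0))
  dwi <- simulate_dwi(ph, wf_m012, snr = NULL)
  no_b0 <- dwi; no_b0$bvals[1] <- 350
  expect_error(fit_tensor(no_b0), "b = 0")
  few <- dwi
  few$volumes <- dwi$volumes[, , , 1:5, drop = FALSE]
  few$bvals <- dwi$bvals[1:5]; few$bvecs <- dwi$bvecs[1:5, ]
  expect_error(fit_tensor(few), "six")
  collinear <- dwi
  collinear$bvecs <- rbind(c(0, 0, 0), matrix(rep(c(1, 0, 0), 6), 6, 3,
                                              byrow = TRUE))
  expect_error(fit_tensor(collinear), "rank-deficient")
})

test_that("FA has the correct limits and hand-computed mid-range value", {
  mk <- function(l1, l2, l3) {
    dims <- c(1L, 1L, 1L)
    structure(list(D = array(c(l1, l2, l3, 0, 0, 0), c(dims, 6)),
                   valid = array(TRUE, dims), units = "mm^2/s"),
              class = "tensor_field")
  }
  expect_equal(fa_map(mk(1e-3, 1e-3, 1e-3))$values[1, 1, 1], 0)
  expect_equal(fa_map(mk(1e-3, 0, 0))$values[1, 1, 1], 1)
  expect_equal(fa_map(mk(2e-3, 1e-3, 1e-3))$values[1, 1, 1], 0.408248,
               tolerance = 1e-6)
  expect_true(is.na(fa_map(mk(0, 0, 0))$values[1, 1, 1]))
  # negative eigenvalue clamped to zero for FA
  expect_equal(fa_map(mk(1e-3, 1e-3, -1e-4))$values[1, 1, 1],
               fa_map(mk(1e-3, 1e-3, 0))$values[1, 1, 1])
})

test_that("ADC and FA maps are invariant when tensors and bvecs co-rotate", {
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  D0 <- diag(c(2e-3, 1.2e-3, 0.8e-3))
  D0[1, 2] <- D0[2, 1] <- 1e-4
  DR <- R %*% D0 %*% t(R)
  t6 <- function(M) c(M[1, 1], M[2, 2], M[3, 3], M[1, 2], M[1, 3], M[2, 3])
  ph0 <- make_slab_phantom(t6(D0))
  phR <- make_slab_phantom(t6(DR))
  dwi0 <- simulate_dwi(ph0, wf_m012, snr = NULL)
  dirR <- default_directions() %*% t(R)
  dwiR <- simulate_dwi(phR, wf_m012, directions = dirR, snr = NULL)
  tf0 <- fit_tensor(dwi0); tfR <- fit_tensor(dwiR)
  expect_equal(eigen_adc(tfR)$values, eigen_adc(tf0)$values,
               tolerance = 1e-9)
  expect_equal(fa_map(tfR)$values, fa_map(tf0)$values, tolerance = 1e-9)
})

test_that("Rician noise biases ADC by less than 2% at SNR 25", {
  # 800-voxel uniform slab, b = 350: Monte-Carlo bias check
  ph <- make_slab_phantom(c(1.578e-3, 1.578e-3, 1.578e-3, 0, 0, 0),
                          grid = c(40, 20))
  dwi <- simulate_dwi(ph, wf_m012, snr = 25, seed = 13)
  adc <- eigen_adc(fit_tensor(dwi))
  bias <- abs(mean(adc$values, na.rm = TRUE) - 1.578) / 1.578
  expect_lt(bias, 0.02)
})

test_that("weighted least squares agrees with OLS on noiseless data", {
  ph <- make_slab_phantom(c(2e-3, 1.5e-3, 1e-3, 2e-4, -1e-4, 5e-5),
                          grid = c(4, 4))
  dwi <- simulate_dwi(ph, wf_m012, snr = NULL)
  expect_equal(fit_tensor(dwi, weighted = TRUE)$D, fit_tensor(dwi)$D,
               tolerance = 1e-9)
})

test_that("ROI statistics summarize labelled regions correctly", {
  ph <- make_pvp_phantom(pvp_reference_series("m012"))
  dwi <- simulate_dwi(ph, wf_m012, snr = NULL)
  adc <- eigen_adc(fit_tensor(dwi))
  roi <- roi_stats(adc, ph$region_map, labels = 1:6,
                   names = ph$region_table$name)
  expect_identical(nrow(roi), 6L)
  # 50% PVP vial recovers exactly
  expect_equal(roi$mean[6], 1.37, tolerance = 1e-9)
  expect_equal(roi$sd, rep(0, 6), tolerance = 1e-8)
  expect_error(roi_stats(adc, ph$region_map, labels = 99), "no valid voxels")
  # constant synthetic map: mean c, sd 0
  cmap <- structure(list(values = array(7, dim(ph$region_map)), kind = "ADC",
                         units = "1e-3 mm^2/s"), class = "scalar_map")
  r <- roi_stats(cmap, ph$region_map, labels = c(2, 5))
  expect_equal(r$mean, c(7, 7))
  expect_equal(r$sd, c(0, 0))
})

test_that("voxels with non-positive signal are flagged invalid, not fitted", {
  ph <- make_slab_phantom(c(1e-3, 1e-3, 1e-3, 0, 0, 0), grid = c(4, 4))
  dwi <- simulate_dwi(ph, wf_m012, snr = NULL)
  dwi$volumes[1, 1, 1, 3] <- 0
  tf <- fit_tensor(dwi)
  expect_false(tf$valid[1, 1, 1])
  expect_true(is.na(eigen_adc(tf)$values[1, 1, 1]))
  expect_true(all(tf$valid[2:4, , 1]))
})
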