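# Forward simulation of diffusion-weighted voxel signals.
#
# The signal model is S = S0 * exp(-b * g' D g) for diffusion, multiplied by
# the motion response of the encoding waveform: a bulk phase
# gamma * (m0 r0 + m1 v + m2 a / 2) projected on the encoding axis, and an
# intravoxel dephasing magnitude factor exp(-gamma^2 m1^2 sigma_v^2 / 2) for
# a Gaussian spread of velocities inside the voxel. A moment-nulled (M012)
# waveform therefore returns the static signal for any rigid motion state.

#' Bulk-motion state of a voxel or phantom
#'
#' Rigid-body kinematics during the encoding: initial displacement, velocity
#' and acceleration, plus an isotropic intravoxel velocity spread that models
#' incoherent motion across the voxel (e.g. myocardial strain-rate dispersion
#' at end systole).
#'
#' @param r0 Displacement vector at encoding start (m).
#' @param v Velocity vector (m/s).
#' @param a Acceleration vector (m/s^2).
#' @param v_spread Standard deviation of the intravoxel velocity distribution
#'   (m/s), isotropic.
#' @return An object of class `motion_state`.
#' @export
motion_state <- function(r0 = c(0, 0, 0), v = c(0, 0, 0), a = c(0, 0, 0),
                         v_spread = 0) {
  stopifnot(length(r0) == 3, length(v) == 3, length(a) == 3, v_spread >= 0)
  structure(list(r0 = as.numeric(r0), v = as.numeric(v), a = as.numeric(a),
                 v_spread = v_spread),
            class = "motion_state")
}

as_tensor3 <- function(tensor) {
  if (length(tensor) == 1) return(diag(3) * as.numeric(tensor))
  tensor <- as.matrix(tensor)
  stopifnot(all(dim(tensor) == c(3, 3)))
  if (max(abs(tensor - t(tensor))) > 1e-12 * max(abs(tensor), 1e-300))
    stop("diffusion tensor must be symmetric")
  tensor
}

#' Encode one voxel
#'
#' Computes the complex diffusion-weighted signal of a voxel with diffusion
#' tensor `tensor` under encoding waveform `wf` played along `direction`,
#' while the voxel undergoes rigid motion `motion`.
#'
#' @param tensor Scalar diffusivity or symmetric 3x3 tensor (mm^2/s).
#' @param s0 Signal without diffusion weighting (arbitrary units, >= 0).
#' @param b Diffusion weighting (s/mm^2).
#' @param direction Unit encoding direction (length 3).
#' @param wf Optional [gradient_waveform()]; its moments drive the motion
#'   response. `NULL` means an idealized moment-free encoding (static case).
#' @param motion A [motion_state()].
#' @param gamma Gyromagnetic ratio (rad/s/T).
#' @return A list of class `voxel_signal` with `magnitude` and `phase` (rad).
#' @export
encode_voxel <- function(tensor, s0, b, direction, wf = NULL,
                         motion = motion_state(), gamma = GAMMA_PROTON) {
  stopifnot(s0 >= 0, b >= 0)
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-6) stop("encoding direction must be a unit vector")
  D <- as_tensor3(tensor)
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12 * max(abs(ev), 1e-300))
    stop("diffusion tensor must be positive semi-definite")
  d_eff <- drop(crossprod(direction, D %*% direction))
  mag <- s0 * exp(-b * d_eff)
  phase <- 0
  if (!is.null(wf)) {
    m <- gradient_moments(wf)
    phase <- gamma * (m$m0 * sum(motion$r0 * direction) +
                      m$m1 * sum(motion$v * direction) +
                      0.5 * m$m2 * sum(motion$a * direction))
    mag <- mag * exp(-0.5 * gamma^2 * m$m1^2 * motion$v_spread^2)
  }
  structure(list(magnitude = mag, phase = phase), class = "voxel_signal")
}

#' Encode one voxel with an explicit isochromat ensemble
#'
#' Validation oracle for the closed-form Gaussian dephasing model used by
#' [encode_voxel()]: draws `n_iso` isochromats with velocities
#' `motion$v + Normal(0, v_spread^2 I)`, accrues each one's moment phase, and
#' averages the complex signals.
#'
#' @inheritParams encode_voxel
#' @param n_iso Number of isochromats.
#' @param seed RNG seed for the velocity draws.
#' @return A `voxel_signal`.
#' @export
encode_voxel_ensemble <- function(tensor, s0, b, direction, wf,
                                  motion = motion_state(), n_iso = 10000,
                                  seed = 1, gamma = GAMMA_PROTON) {
  base <- encode_voxel(tensor, s0, b, direction, wf = NULL, gamma = gamma)
  m <- gradient_moments(wf)
  vg <- sum(motion$v * direction)
  dv <- withr_seed(seed, stats::rnorm(n_iso, 0, motion$v_spread))
  phases <- gamma * (m$m0 * sum(motion$r0 * direction) +
                     m$m1 * (vg + dv) +
                     0.5 * m$m2 * sum(motion$a * direction))
  z <- mean(exp(1i * phases))
  structure(list(magnitude = base$magnitude * Mod(z), phase = Arg(z)),
            class = "voxel_signal")
}

# evaluate `expr` under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Add Rician noise to a magnitude volume
#'
#' Standard MR magnitude noise: independent Gaussian noise of standard
#' deviation `sigma` on the real and imaginary channels, then the modulus.
#' `sigma` may be given directly or as `reference / snr`.
#'
#' @param x Magnitude array (any shape).
#' @param snr Signal-to-noise ratio defining `sigma = reference / snr`.
#' @param reference Reference signal level for the SNR definition; by
#'   convention the mean b = 0 signal over the object mask.
#' @param sigma Noise standard deviation (overrides `snr`).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return Array of the same shape with Rician-distributed values.
#' @export
add_rician_noise <- function(x, snr = NULL, reference = mean(x),
                             sigma = NULL, seed = NULL) {
  if (is.null(sigma)) {
    stopifnot(!is.null(snr), snr > 0)
    sigma <- reference / snr
  }
  noisify <- function() {
    n1 <- stats::rnorm(length(x), 0, sigma)
    n2 <- stats::rnorm(length(x), 0, sigma)
    out <- sqrt((as.vector(x) + n1)^2 + n2^2)
    array(out, dim = if (is.null(dim(x))) length(x) else dim(x))
  }
  if (is.null(seed)) noisify() else withr_seed(seed, noisify())
}

#' Default six-direction encoding scheme
#'
#' Dual-gradient scheme: (1,1,0), (1,-1,0), (1,0,1), (1,0,-1), (0,1,1),
#' (0,1,-1), each normalized to unit length. Rows are directions.
#'
#' @return A 6 x 3 matrix of unit vectors.
#' @export
default_directions <- function() {
  d <- rbind(c(1, 1, 0), c(1, -1, 0), c(1, 0, 1),
             c(1, 0, -1), c(0, 1, 1), c(0, 1, -1))
  d / sqrt(2)
}

#' Simulate a diffusion-weighted acquisition of a phantom
#'
#' Applies the voxel encoding model over the phantom grid for one b = 0
#' volume plus one diffusion-weighted volume per encoding direction, all with
#' the same designed waveform, then (optionally) adds Rician noise with
#' `sigma` defined by the noiseless mean b = 0 signal over the mask divided
#' by `snr`.
#'
#' @param phantom A [phantom_spec()].
#' @param wf The designed [gradient_waveform()]; its numerically integrated
#'   b-value sets the diffusion weighting of every encoded volume.
#' @param directions Encoding direction matrix (n x 3 unit rows).
#' @param snr Signal-to-noise ratio on the b = 0 mean; `Inf` or `NULL` for a
#'   noiseless, bit-reproducible simulation.
#' @param seed RNG seed for the noise draw.
#' @param motion Optional [motion_state()] overriding the phantom's own.
#' @param gamma Gyromagnetic ratio (rad/s/T).
#' @return A `dwi_dataset`: list with 4-D `volumes` (x, y, z, encoding),
#'   `bvals`, `bvecs` (n x 3), logical `mask`, and `voxel_size` (mm).
#' @export
simulate_dwi <- function(phantom, wf, directions = default_directions(),
                         snr = 25, seed = NULL, motion = NULL,
                         gamma = GAMMA_PROTON) {
  stopifnot(inherits(phantom, "phantom_spec"),
            inherits(wf, "gradient_waveform"))
  directions <- as.matrix(directions)
  stopifnot(ncol(directions) == 3)
  nenc <- nrow(directions) + 1L
  b <- numerical_bvalue(wf, gamma)
  if (is.null(motion)) motion <- phantom$motion
  m <- gradient_moments(wf)
  deph <- exp(-0.5 * gamma^2 * m$m1^2 * motion$v_spread^2)

  dims <- dim(phantom$region_map)
  Dm <- matrix(phantom$tensor_field, ncol = 6)     # voxels x 6 (mm^2/s)
  s0 <- as.vector(phantom$s0_map)
  vols <- array(0, dim = c(dims, nenc))
  vols[, , , 1] <- s0                              # b = 0: no encoding gradient
  for (k in seq_len(nrow(directions))) {
    g <- directions[k, ]
    g <- g / sqrt(sum(g^2))
    dg <- Dm %*% c(g[1]^2, g[2]^2, g[3]^2,
                   2 * g[1] * g[2], 2 * g[1] * g[3], 2 * g[2] * g[3])
    vols[, , , k + 1L] <- s0 * exp(-b * dg) * deph
  }
  bvals <- c(0, rep(b, nrow(directions)))
  bvecs <- rbind(c(0, 0, 0), directions)
  mask <- phantom$region_map > 0
  if (!is.null(snr) && is.finite(snr)) {
    ref <- mean(vols[, , , 1][mask])
    vols <- if (is.null(seed)) add_rician_noise(vols, sigma = ref / snr)
            else add_rician_noise(vols, sigma = ref / snr, seed = seed)
  }
  structure(list(volumes = vols, bvals = bvals, bvecs = bvecs, mask = mask,
                 voxel_size = phantom$voxel_size),
            class = "dwi_dataset")
}

#' @export
print.dwi_dataset <- function(x, ...) {
  d <- dim(x$volumes)
  cat(sprintf("<dwi_dataset> %d x %d x %d grid, %d encodings (b = %s s/mm^2)\n",
              d[1], d[2], d[3], d[4],
              paste(unique(round(x$bvals, 2)), collapse = ", ")))
  cat(sprintf("  voxel %s mm, %d voxels in mask\n",
              paste(signif(x$voxel_size, 3), collapse = " x "), sum(x$mask)))
  invisible(x)
}
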