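# Diffusion-encoding gradient waveform design and analysis.
#
# A waveform is a scalar gradient amplitude G(t) (T/m) sampled on a uniform
# raster, played along one spatial axis. The refocusing pulse of the spin echo
# is modelled as an instantaneous sign flip of the *effective* gradient at
# `refocus_index`: samples at or after that index count with sign -1 in every
# moment and b-value integral. Sample k is attributed the midpoint time
# t_k = (k - 1/2) * dt, which makes rectangle-rule moment sums exact for
# piecewise-constant lobes.

#' Proton gyromagnetic ratio (rad/s/T)
#'
#' Default gyromagnetic ratio used throughout the package; configurable in
#' every function that needs it.
#' @export
GAMMA_PROTON <- 2.675221874e8

#' Hardware gradient limits
#'
#' @param g_max Maximum gradient amplitude (T/m). Default 0.440 T/m
#'   (440 mT/m), a high-performance preclinical gradient insert.
#' @param slew_max Maximum slew rate (T/m/s). Default 3440 T/m/s.
#' @param dt Raster time (s). Default 10 us, giving >= 12 samples on a
#'   full-amplitude ramp at the default limits.
#' @return An object of class `hardware_limits`.
#' @export
hardware_limits <- function(g_max = 0.440, slew_max = 3440, dt = 1e-5) {
  stopifnot(g_max > 0, slew_max > 0, dt > 0)
  structure(list(g_max = g_max, slew_max = slew_max, dt = dt),
            class = "hardware_limits")
}

#' Diffusion encoding specification
#'
#' @param b_target Target diffusion weighting b (s/mm^2).
#' @param nulling_order Highest gradient-moment index forced to zero:
#'   0 (Stejskal-Tanner), 1 (velocity-compensated) or 2 (velocity- and
#'   acceleration-compensated, "M012").
#' @param gamma Gyromagnetic ratio (rad/s/T).
#' @return An object of class `encoding_spec`.
#' @export
encoding_spec <- function(b_target = 350, nulling_order = 2,
                          gamma = GAMMA_PROTON) {
  stopifnot(b_target >= 0, nulling_order %in% 0:2, gamma > 0)
  structure(list(b_target = b_target, nulling_order = as.integer(nulling_order),
                 gamma = gamma),
            class = "encoding_spec")
}

#' Construct a gradient waveform
#'
#' @param samples Gradient amplitudes (T/m) on a uniform raster.
#' @param dt Raster time (s).
#' @param refocus_index Index of the first sample *after* the instantaneous
#'   180 degree refocusing pulse (effective gradient sign is -1 from this
#'   sample on), or `NULL` for no refocusing.
#' @param axis Unit vector of the axis the scalar waveform is played along.
#' @return An object of class `gradient_waveform`.
#' @export
gradient_waveform <- function(samples, dt, refocus_index = NULL,
                              axis = c(1, 0, 0)) {
  samples <- as.numeric(samples)
  stopifnot(length(samples) >= 1, dt > 0, length(axis) == 3)
  if (!is.null(refocus_index)) {
    refocus_index <- as.integer(refocus_index)
    stopifnot(refocus_index >= 1, refocus_index <= length(samples) + 1L)
  }
  nrm <- sqrt(sum(axis^2))
  if (nrm > 0) axis <- axis / nrm
  structure(list(samples = samples, dt = dt, refocus_index = refocus_index,
                 axis = axis),
            class = "gradient_waveform")
}

#' @export
print.gradient_waveform <- function(x, ...) {
  m <- gradient_moments(x)
  cat(sprintf(
    "<gradient_waveform> %d samples, dt = %.3g us, duration = %.3f ms\n",
    length(x$samples), x$dt * 1e6, length(x$samples) * x$dt * 1e3))
  cat(sprintf("  peak |G| = %.1f mT/m, refocus at sample %s\n",
              max(abs(x$samples)) * 1e3,
              if (is.null(x$refocus_index)) "none" else x$refocus_index))
  cat(sprintf("  b = %.4g s/mm^2, m0 = %.3g T.s/m, m1 = %.3g T.s^2/m, m2 = %.3g T.s^3/m\n",
              numerical_bvalue(x), m$m0, m$m1, m$m2))
  invisible(x)
}

# effective (sign-flipped) sample vector
effective_samples <- function(wf) {
  s <- wf$samples
  if (!is.null(wf$refocus_index) && wf$refocus_index <= length(s)) {
    idx <- seq(wf$refocus_index, length(s))
    s[idx] <- -s[idx]
  }
  s
}

# midpoint times of the raster
sample_times <- function(wf) (seq_along(wf$samples) - 0.5) * wf$dt

#' Gradient moments of the effective waveform
#'
#' Computes m_n = sum G_eff(t_k) t_k^n dt for n = 0, 1, 2, with the effective
#' gradient sign flipped at the refocusing pulse. m0, m1 and m2 couple to
#' voxel position, velocity and acceleration respectively.
#'
#' @param wf A [gradient_waveform()].
#' @return A list of class `moment_vector` with elements `m0` (T s/m),
#'   `m1` (T s^2/m) and `m2` (T s^3/m).
#' @export
gradient_moments <- function(wf) {
  stopifnot(inherits(wf, "gradient_waveform"))
  g <- effective_samples(wf)
  t <- sample_times(wf)
  structure(list(m0 = sum(g) * wf$dt,
                 m1 = sum(g * t) * wf$dt,
                 m2 = sum(g * t^2) * wf$dt),
            class = "moment_vector")
}

#' Numerically integrated b-value
#'
#' Generalizes the rectangular-pulse closed form b = gamma^2 G^2 delta^2
#' (Delta - delta/3) to arbitrary shapes: b = integral of |q(t)|^2 dt with
#' q(t) = gamma * integral of G_eff, evaluated by cumulative summation on the
#' raster.
#'
#' @param wf A [gradient_waveform()].
#' @param gamma Gyromagnetic ratio (rad/s/T).
#' @return b-value in s/mm^2.
#' @export
numerical_bvalue <- function(wf, gamma = GAMMA_PROTON) {
  stopifnot(inherits(wf, "gradient_waveform"))
  q <- gamma * cumsum(effective_samples(wf)) * wf$dt   # rad/m
  sum(q^2) * wf$dt * 1e-6                              # s/m^2 -> s/mm^2
}

#' Check a waveform against hardware limits
#'
#' Asserts sample-wise amplitude and slew-rate compliance and zero first/last
#' samples.
#'
#' @param wf A [gradient_waveform()].
#' @param hw A [hardware_limits()].
#' @param tol Relative slack for floating-point comparisons.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_waveform <- function(wf, hw, tol = 1e-9) {
  s <- wf$samples
  if (max(abs(s)) > hw$g_max * (1 + tol))
    stop("waveform exceeds amplitude limit")
  if (length(s) > 1 && max(abs(diff(s))) / wf$dt > hw$slew_max * (1 + tol))
    stop("waveform exceeds slew-rate limit")
  if (s[1] != 0 || s[length(s)] != 0)
    stop("waveform must start and end at zero amplitude")
  invisible(TRUE)
}

# One trapezoidal lobe of unit amplitude: n_ramp rising samples, n_flat at 1,
# n_ramp - 1 falling samples plus the implicit zero that the next lobe (or the
# trailing pad) supplies. All lobes built from this shape have identical
# length n_flat + 2 * n_ramp and identical internal sample pattern, which is
# what makes the finite-difference amplitude patterns null the discrete
# moments identically.
unit_lobe <- function(n_ramp, n_flat) {
  c(seq_len(n_ramp) / n_ramp, rep(1, n_flat), seq(n_ramp - 1, 0) / n_ramp)
}

# Assemble a lobe-train waveform: contiguous identical trapezoids scaled by
# `coef`, zero-padded at both ends, refocus flip after `n_before` lobes.
lobe_train <- function(coef, n_before, amplitude, n_ramp, n_flat, dt) {
  lobe <- unit_lobe(n_ramp, n_flat)
  samples <- c(0, as.vector(vapply(coef, function(ck) ck * amplitude * lobe,
                                   numeric(length(lobe)))), 0)
  refocus <- 2L + n_before * length(lobe)  # first sample after the flip point
  gradient_waveform(samples, dt, refocus_index = refocus)
}

# Amplitude patterns on the *effective* gradient whose discrete moments 0..n
# vanish identically: finite-difference coefficients of order n + 1, scaled so
# the peak magnitude is 1. The played waveform flips the sign of the lobes
# after the refocusing pulse.
nulling_pattern <- function(order) {
  switch(as.character(order),
         "0" = list(eff = c(1, -1),        n_before = 1L),
         "1" = list(eff = c(1, -2, 1) / 2, n_before = 2L),
         "2" = list(eff = c(1, -3, 3, -1) / 3, n_before = 2L),
         stop("nulling_order must be 0, 1 or 2"))
}

# Shared design engine: fix the lobe topology for the requested nulling order,
# bisect the flat-top length until full-amplitude b >= b_target, then scale
# the amplitude by sqrt(b_target / b) for an exact match (b is quadratic in
# amplitude; scaling down never violates limits).
design_lobe_train <- function(spec, hw, order, max_duration) {
  if (spec$b_target == 0)
    return(gradient_waveform(c(0, 0), hw$dt))
  pat <- nulling_pattern(order)
  coef_play <- pat$eff
  idx <- seq(pat$n_before + 1L, length(coef_play))
  coef_play[idx] <- -coef_play[idx]
  n_ramp <- ceiling(hw$g_max / (hw$slew_max * hw$dt))
  n_lobes <- length(pat$eff)
  build <- function(n_flat)
    lobe_train(coef_play, pat$n_before, hw$g_max, n_ramp, n_flat, hw$dt)
  bval <- function(n_flat) numerical_bvalue(build(n_flat), spec$gamma)
  n_max <- floor((max_duration / hw$dt - 2) / n_lobes) - 2L * n_ramp
  if (n_max < 0 || bval(max(n_max, 0)) < spec$b_target) {
    achieved <- if (n_max >= 0) bval(n_max) else 0
    stop(sprintf(paste0(
      "target b = %g s/mm^2 infeasible within %.1f ms encoding duration ",
      "(best achievable b = %.4g s/mm^2)"),
      spec$b_target, max_duration * 1e3, achieved))
  }
  lo <- 0L; hi <- n_max
  while (lo < hi) {               # smallest n_flat with b >= b_target
    mid <- (lo + hi) %/% 2L
    if (bval(mid) >= spec$b_target) hi <- mid else lo <- mid + 1L
  }
  wf <- build(lo)
  scale <- sqrt(spec$b_target / numerical_bvalue(wf, spec$gamma))
  wf$samples <- wf$samples * scale
  validate_waveform(wf, hw)
  wf
}

#' Design a Stejskal-Tanner (M0-nulled) diffusion waveform
#'
#' Two identical trapezoidal lobes straddling the refocusing pulse. The paired
#' geometry nulls the zeroth effective moment by construction; the first and
#' second moments are generically nonzero, which is what makes this encoding
#' motion-sensitive.
#'
#' @param spec An [encoding_spec()] (its `nulling_order` is ignored here).
#' @param hw A [hardware_limits()].
#' @param max_duration Encoding-duration cap (s). Designs that cannot reach
#'   `b_target` within the cap raise an error reporting the achievable b.
#' @return A [gradient_waveform()] whose numerically integrated b-value equals
#'   `b_target` to floating-point precision.
#' @export
design_stejskal_tanner <- function(spec, hw = hardware_limits(),
                                   max_duration = 0.030) {
  stopifnot(inherits(spec, "encoding_spec"), inherits(hw, "hardware_limits"))
  design_lobe_train(spec, hw, 0L, max_duration)
}

#' Design a motion-compensated diffusion waveform
#'
#' Designs a gradient waveform whose effective moments up to
#' `spec$nulling_order` vanish: order 1 removes sensitivity to constant
#' velocity, order 2 ("M012") to velocity and acceleration, the regime needed
#' to image the beating heart. Order 0 delegates to
#' [design_stejskal_tanner()].
#'
#' The design uses a fixed train of identical trapezoidal lobes whose
#' amplitude pattern follows finite-difference coefficients (e.g.
#' (1, -3, 3, -1)/3 on the effective axis for order 2), so the discrete
#' moment sums cancel identically; the flat-top length sets b and the final
#' amplitude is scaled for an exact b match. The design is deterministic.
#'
#' @inheritParams design_stejskal_tanner
#' @return A [gradient_waveform()] with `|m0|`, `|m1|`, `|m2|` at
#'   floating-point cancellation level (far below 1e-9 T s/m, 1e-12 T s^2/m,
#'   1e-15 T s^3/m) and b equal to `b_target`.
#' @export
design_motion_compensated <- function(spec, hw = hardware_limits(),
                                      max_duration = 0.030) {
  stopifnot(inherits(spec, "encoding_spec"), inherits(hw, "hardware_limits"))
  if (spec$nulling_order == 0L)
    return(design_stejskal_tanner(spec, hw, max_duration))
  design_lobe_train(spec, hw, spec$nulling_order, max_duration)
}

#' Closed-form Stejskal-Tanner b-value
#'
#' b = gamma^2 G^2 delta^2 (Delta - delta/3) for a rectangular gradient pair
#' of amplitude G (T/m), duration delta (s) and leading-edge separation
#' Delta (s).
#'
#' @param G Gradient amplitude (T/m).
#' @param delta Gradient duration (s).
#' @param Delta Separation of the two gradient onsets (s).
#' @param gamma Gyromagnetic ratio (rad/s/T).
#' @return b-value in s/mm^2.
#' @export
stejskal_tanner_bvalue <- function(G, delta, Delta, gamma = GAMMA_PROTON) {
  gamma^2 * G^2 * delta^2 * (Delta - delta / 3) * 1e-6
}
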