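# Shared fixtures: designed waveforms are deterministic, so build them once.

hw_default <- hardware_limits()
wf_m0 <- design_stejskal_tanner(encoding_spec(350, 0), hw_default)
wf_m012 <- design_motion_compensated(encoding_spec(350, 2), hw_default)

# uniform-tensor slab phantom on a small grid (one region, label 1)
make_slab_phantom <- function(tensor6, grid = c(20, 10), s0 = 100,
                              md = mean(tensor6[1:3])) {
  dims <- c(grid, 1L)
  region <- array(1L, dims)
  tf <- array(rep(tensor6, each = prod(dims)), c(dims, 6))
  tb <- data.frame(label = 1L, name = "slab", md = md, s0 = s0)
  phantom_spec(region, tb, tf, voxel_size = c(0.39, 0.39, 2))
}

# brute-force phase oracle: gamma * integral G_eff(t) . x(t) dt for a
# polynomial trajectory projected on the encoding axis
phase_oracle <- function(wf, direction, r0, v, a, gamma = GAMMA_PROTON) {
  g <- cardiodti:::effective_samples(wf)
  t <- (seq_along(g) - 0.5) * wf$dt
  proj <- function(x) sum(x * direction)
  gamma * sum(g * (proj(r0) + proj(v) * t + 0.5 * proj(a) * t^2)) * wf$dt
}
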