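# Shared fixtures for the simulator-based tests.

# Measurement model with every noise source switched off: fl1 records the
# sampled reporter values exactly (gain 1).
noise_free_meas <- function(n_events = 1000L) {
  measurement_params(autofluorescence = 0, instrument_cv = 0,
                     maturation_fraction = 1, maturation_fraction2 = 1,
                     debris_fraction = 0, n_events = n_events)
}

# Constitutive-mode parameters in the deterministic limit (no intrinsic
# burst noise, no size variation, constant copy number).
det_constitutive <- function(...) {
  args <- utils::modifyList(
    list(mode = "constitutive_repressor", burst = 0, size_cv2 = 0,
         N_disp = 0),
    list(...))
  do.call(circuit_params, args)
}

# A population whose reporter is an exact Gamma(shape = k) law times an
# optional lognormal size factor: constant copy number, deterministic level
# G_det = N_mean * alpha, burst = G_det / k.
gamma_population <- function(k, mean_G = 10000, n_cells = 30000L, seed = 1L,
                             size_cv2 = 0) {
  p <- circuit_params(mode = "constitutive_repressor", R0 = 0,
                      alpha = mean_G / 10, N_mean = 10, N_disp = 0,
                      burst = mean_G / k, size_cv2 = size_cv2)
  simulate_population(p, inducer = 0, n_cells = n_cells, seed = seed)
}

# Independent bisection oracle for the autoregulation fixed point
# G = N * alpha * a(r * G * rho); used to cross-check the package solver.
bisect_fixed_point <- function(params, inducer, N, tol = 1e-12) {
  rho <- 1 / (1 + (inducer / params$Kd_I)^params$hill_I)
  f <- function(g) {
    a <- params$basal + (1 - params$basal) /
      (1 + (params$r_ratio * g * rho / params$K_R)^params$hill_R)
    g - N * params$alpha * a
  }
  lo <- 0
  hi <- N * params$alpha
  if (hi == 0) return(0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) <= tol * max(hi, 1)) break
  }
  (lo + hi) / 2
}
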