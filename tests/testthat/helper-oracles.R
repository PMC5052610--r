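# Independent closed-form and brute-force oracles used across tests.

# Trapezoid quadrature by explicit hand summation (independent of pracma).
trapz_manual <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1L))
    s <- s + (x[i + 1L] - x[i]) * (y[i + 1L] + y[i]) / 2
  s
}

# Closed-form effluent response of a linear tank chain to mass injected in
# one compartment: hypoexponential impulse response via partial fractions
# (requires distinct outflow rates along the occupied chain).
hypoexp_effluent <- function(config, inject_compartment, mass, t) {
  n <- config$n_compartments
  V <- config$compartment_volumes
  Q <- config$local_flow
  r <- Q / V
  j <- inject_compartment
  idx <- j:n
  gain <- mass / V[j]
  if (j < n) gain <- gain * prod(Q[j:(n - 1L)] / V[(j + 1L):n])
  vapply(t, function(tt) {
    gain * sum(vapply(idx, function(i) {
      denom <- prod(r[setdiff(idx, i)] - r[i])
      exp(-r[i] * tt) / denom
    }, numeric(1)))
  }, numeric(1))
}

# Per-path effluent response by matrix-exponential propagation of the tank
# chain (handles repeated rates; independent of the ODE integrator).
chain_effluent_response <- function(config, inject_compartment, mass, t) {
  n <- config$n_compartments
  V <- config$compartment_volumes
  Q <- config$local_flow
  A <- matrix(0, n, n)
  diag(A) <- -Q / V
  for (i in seq_len(n)[-1]) A[i, i - 1L] <- Q[i - 1L] / V[i]
  y0 <- rep(0, n)
  y0[inject_compartment] <- mass / V[inject_compartment]
  vapply(t, function(tt)
    (as.matrix(Matrix::expm(A * tt)) %*% y0)[n], numeric(1))
}

# Superposition oracle: route each feed fraction's share of the tracer mass
# through its downstream tank chain and sum the effluent contributions.
superposition_effluent <- function(config, mass, t) {
  out <- numeric(length(t))
  for (j in seq_len(config$n_compartments)) {
    fj <- config$feed_split[j]
    if (fj > 0)
      out <- out + chain_effluent_response(config, j, mass * fj, t)
  }
  out
}

# Dense noise-free tracer curve for RTD parameter-recovery checks.
dense_tracer_curve <- function(config, duration_multiple = 10,
                               points_per_hrt = 40) {
  ex <- tracer_experiment(
    injected_mass = 10,
    sampling_interval = config$nominal_hrt / points_per_hrt,
    duration_multiple = duration_multiple
  )
  simulate_tracer_pulse(config, ex)
}
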