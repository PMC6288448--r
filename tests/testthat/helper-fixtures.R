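# Shared fixtures: small communities and reference implementations used as
# independent oracles.

# Worked end-point experiments from published transfer studies.
transduction_example <- function() {
  endpoint_experiment(V0 = vector_conc_from_moi(6e8, 0.4), R0 = 6e8,
                      R1 = recipients_after_transfer(6e8, 876),
                      duration = 60, label = "transduction")
}

transformation_example <- function() {
  endpoint_experiment(V0 = fragments_from_mass(2.5), R0 = 2e6,
                      R1 = 1.9998e6, duration = 30, label = "transformation")
}

# A small all-ones single-mechanism community for dynamics tests.
uniform_mechanisms <- function(n, gamma = 1e-8) {
  list(mechanism_spec("conjugation", gamma, matrix(1, n, n)))
}

small_config <- function(n = 2, days = 30, n_steps = 2000, ...) {
  sim_config(n_species = n, total_time = as_minutes(days, "day"),
             n_steps = n_steps, ...)
}

# Closed-form replicator (logistic) carrier fraction under fitness m per
# minute, used as the growth-step oracle.
logistic_fraction <- function(f0, m_per_min, t_min) {
  f0 * exp(m_per_min * t_min) / (1 + f0 * (exp(m_per_min * t_min) - 1))
}

# Independent continuous-time integration of the two-process model
# (mass-action transfer + logistic selection) with full-spread root
# detection, via lsodar. Used to validate the discrete stepper.
continuous_oracle_spread_time <- function(n, alpha, gamma, m_per_min,
                                          density, f0, horizon_min,
                                          threshold = 0.99) {
  tot <- rep(density, n)
  deriv <- function(t, y, p) {
    Bp <- y
    Bn <- tot - Bp
    transfer <- gamma * Bn * as.vector(crossprod(alpha, Bp))
    growth <- m_per_min * Bp * Bn / tot
    list(transfer + growth)
  }
  root <- function(t, y, p) min(y / tot) - threshold
  y0 <- numeric(n)
  y0[1] <- f0 * density
  out <- deSolve::lsodar(y = y0, times = c(0, horizon_min), func = deriv,
                         parms = NULL, rootfunc = root,
                         rtol = 1e-10, atol = 1e-6)
  t_root <- attr(out, "troot")
  if (is.null(t_root) || length(t_root) == 0) NA_real_ else t_root[1]
}
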