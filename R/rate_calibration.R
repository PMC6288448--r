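# Calibration of per-vector transfer rate constants from end-point
# (initial/final concentration) batch transfer experiments, and the unit
# conversions needed to express published measurements as vector counts.

#' Describe a vector end-point transfer experiment
#'
#' A single batch experiment in which recipient cells are mixed with a gene
#' transfer vector (free DNA fragments, transducing phages, or extracellular
#' vesicles) and the recipient concentration is measured before and after a
#' fixed incubation. Under mass action the dynamics are
#' \deqn{dR/dt = -\gamma R V,\quad dV/dt = -\gamma R V,\quad dT/dt = \gamma R V}
#' with one vector consumed per converted recipient.
#'
#' @param V0 initial vector concentration (count/mL).
#' @param R0 initial recipient concentration (cells/mL).
#' @param R1 final recipient concentration (cells/mL); must satisfy
#'   `R1 <= R0` and `R0 - R1 <= V0`.
#' @param duration incubation time in minutes.
#' @param label optional free-text label.
#' @return An object of class `endpoint_experiment`.
#' @seealso [endpoint_rate()]
#' @examples
#' endpoint_experiment(V0 = 2.4e8, R0 = 6e8, R1 = 5.99999124e8, duration = 60)
#' @export
endpoint_experiment <- function(V0, R0, R1, duration, label = "") {
  check_scalar(V0, "V0", lower = 0)
  check_scalar(R0, "R0", lower = 0)
  check_scalar(R1, "R1", lower = 0)
  check_scalar(duration, "duration", lower = 0, strict_lower = TRUE)
  if (R1 > R0) {
    stop_invalid("R1 (", format(R1), ") exceeds R0 (", format(R0),
                 "): transfer only removes plasmid-free recipients")
  }
  if (R0 - R1 > V0) {
    stop_invalid("R0 - R1 (", format(R0 - R1), ") exceeds V0 (", format(V0),
                 "): one vector is consumed per converted recipient")
  }
  structure(list(V0 = V0, R0 = R0, R1 = R1, duration = duration,
                 label = as.character(label)[1]),
            class = "endpoint_experiment")
}

#' @export
print.endpoint_experiment <- function(x, ...) {
  cat("End-point transfer experiment",
      if (nzchar(x$label)) paste0(" '", x$label, "'"), "\n", sep = "")
  cat(sprintf("  V0 = %g /mL, R0 = %g cells/mL, R1 = %g cells/mL, dt = %g min\n",
              x$V0, x$R0, x$R1, x$duration))
  invisible(x)
}

as_endpoint_experiment <- function(x) {
  if (inherits(x, "endpoint_experiment")) return(x)
  if (is.list(x) && all(c("V0", "R0", "R1") %in% names(x))) {
    dur <- if (!is.null(x$duration)) x$duration else x$dt_min
    return(endpoint_experiment(x$V0, x$R0, x$R1, dur,
                               label = if (is.null(x$label)) "" else x$label))
  }
  stop_invalid("cannot interpret input as an end-point experiment")
}

#' End-point estimator of a per-vector transfer rate constant
#'
#' Inverts the mass-action vector-recipient model analytically from a single
#' pair of initial and final recipient concentrations:
#' \deqn{\gamma = \frac{\ln\left(\frac{V_0 - R_0 + R_1}{R_1}\right) -
#'   \ln\left(\frac{V_0}{R_0}\right)}{\Delta t\,(V_0 - R_0)}}
#' This is the exact inversion of the coupled ODEs (the quantity
#' \eqn{\ln(R/(R + V_0 - R_0))} decays linearly at rate
#' \eqn{\gamma(V_0 - R_0)}). `V0 < R0` is legal and common for phage and
#' vesicle experiments. At the removable singularity `V0 = R0` the analytic
#' limit \eqn{\gamma = (1/R_1 - 1/R_0)/\Delta t} is used.
#'
#' @param experiment an [endpoint_experiment()] (or a list/one-row data frame
#'   with fields `V0`, `R0`, `R1` and `duration` or `dt_min`).
#' @param rel_tol relative tolerance on `|V0 - R0|` below which the
#'   equal-concentration limit formula is used.
#' @return Rate constant in mL vector^-1 min^-1 (non-negative; zero iff
#'   `R1 == R0`).
#' @examples
#' # phage transduction at MOI 0.4:
#' endpoint_rate(endpoint_experiment(2.4e8, 6e8, 5.99999124e8, 60))
#' @export
endpoint_rate <- function(experiment, rel_tol = 1e-9) {
  x <- as_endpoint_experiment(experiment)
  if (x$V0 <= 0 || x$R0 <= 0 || x$R1 <= 0) {
    stop_invalid("endpoint_rate requires strictly positive V0, R0 and R1")
  }
  if (abs(x$V0 - x$R0) < rel_tol * max(x$V0, x$R0)) {
    return((1 / x$R1 - 1 / x$R0) / x$duration)
  }
  a_final <- (x$V0 - x$R0 + x$R1) / x$R1
  a_init <- x$V0 / x$R0
  if (a_final <= 0) {
    stop_infeasible("log argument (V0 - R0 + R1)/R1 is non-positive: ",
                    "data are inconsistent with the mass-action model")
  }
  (log(a_final) - log(a_init)) / (x$duration * (x$V0 - x$R0))
}

#' Numerical oracle for the vector-recipient mass-action ODEs
#'
#' Fixed-step Runge-Kutta integration (via \pkg{deSolve}) of
#' \eqn{dR/dt = -\gamma RV}, \eqn{dV/dt = -\gamma RV},
#' \eqn{dT/dt = \gamma RV}. Intended as an independent forward model for
#' validating [endpoint_rate()]; it conserves \eqn{R - V} and \eqn{R + T}
#' up to integration error.
#'
#' @param V0,R0 initial vector and recipient concentrations (per mL).
#' @param gamma rate constant (mL vector^-1 min^-1).
#' @param duration integration time (minutes).
#' @param steps number of RK4 steps (>= 1).
#' @return Named numeric vector `c(R = , V = , T = )` at `duration`.
#' @export
ode_oracle <- function(V0, R0, gamma, duration, steps = 1e5) {
  check_scalar(V0, "V0", lower = 0)
  check_scalar(R0, "R0", lower = 0)
  check_scalar(gamma, "gamma", lower = 0)
  check_scalar(duration, "duration", lower = 0)
  check_scalar(steps, "steps", lower = 1)
  deriv <- function(t, y, p) {
    flux <- p * y[1] * y[2]
    list(c(-flux, -flux, flux))
  }
  out <- deSolve::ode(y = c(R = R0, V = V0, T = 0),
                      times = seq(0, duration, length.out = steps + 1),
                      func = deriv, parms = gamma, method = "rk4")
  last <- out[nrow(out), c("R", "V", "T")]
  c(R = unname(last["R"]), V = unname(last["V"]), T = unname(last["T"]))
}

#' Convert a mass DNA concentration to a fragment count concentration
#'
#' Published transformation data report DNA by mass; the mass-action model
#' needs vector counts. With an average fragment size of 30 kb the default
#' fragment mass is 3.0e-17 g (about 600 g/mol per bp).
#'
#' @param mass_conc DNA concentration in micrograms/mL (>= 0).
#' @param fragment_mass mass of one fragment in grams (> 0).
#' @return Fragment concentration in count/mL.
#' @examples
#' fragments_from_mass(2.5)  # ~8.33e10 fragments/mL
#' @export
fragments_from_mass <- function(mass_conc, fragment_mass = 3.0e-17) {
  check_scalar(mass_conc, "mass_conc", lower = 0)
  check_scalar(fragment_mass, "fragment_mass", lower = 0, strict_lower = TRUE)
  mass_conc * 1e-6 / fragment_mass
}

#' Vector concentration from recipient concentration and MOI
#'
#' @param recipient_conc recipient concentration (cells/mL, >= 0).
#' @param moi multiplicity of infection (vectors per recipient, >= 0).
#' @return Vector concentration (count/mL).
#' @examples
#' vector_conc_from_moi(6e8, 0.4)
#' @export
vector_conc_from_moi <- function(recipient_conc, moi) {
  check_scalar(recipient_conc, "recipient_conc", lower = 0)
  check_scalar(moi, "moi", lower = 0)
  recipient_conc * moi
}

#' Final recipient concentration after a known number of conversions
#'
#' @param recipient_conc_initial initial recipient concentration (cells/mL).
#' @param converted_conc concentration of converted cells (transformants,
#'   transductants, ...); must not exceed the initial concentration.
#' @return `recipient_conc_initial - converted_conc` (cells/mL).
#' @examples
#' recipients_after_transfer(6e8, 876)
#' @export
recipients_after_transfer <- function(recipient_conc_initial, converted_conc) {
  check_scalar(recipient_conc_initial, "recipient_conc_initial", lower = 0)
  check_scalar(converted_conc, "converted_conc", lower = 0)
  if (converted_conc > recipient_conc_initial) {
    stop_invalid("converted_conc exceeds recipient_conc_initial")
  }
  recipient_conc_initial - converted_conc
}

#' Scaling from a per-vector to a per-donor rate constant
#'
#' The end-point estimator yields a rate per vector concentration; the
#' community model is written per donor cell concentration. The conversion
#' multiplies by the environmental ratio of vectors to donor cells and, where
#' applicable, a recipient efficiency (e.g. the natural competence rate for
#' transformation).
#'
#' @param vector_per_donor vectors per donor cell (> 0).
#' @param recipient_efficiency dimensionless efficiency in \[0, 1\]; 1 when
#'   inapplicable.
#' @return An object of class `calibration_scaling`.
#' @export
calibration_scaling <- function(vector_per_donor = 1, recipient_efficiency = 1) {
  check_scalar(vector_per_donor, "vector_per_donor", lower = 0, strict_lower = TRUE)
  check_scalar(recipient_efficiency, "recipient_efficiency", lower = 0, upper = 1)
  structure(list(vector_per_donor = vector_per_donor,
                 recipient_efficiency = recipient_efficiency),
            class = "calibration_scaling")
}

#' @rdname calibration_scaling
#' @param rate_per_vector rate constant in mL vector^-1 min^-1 (>= 0).
#' @param scaling a [calibration_scaling()].
#' @return `scale_to_donor_rate()` returns the rate in mL cell^-1 min^-1.
#' @examples
#' scale_to_donor_rate(4.35e-17, calibration_scaling(333, 0.01))
#' @export
scale_to_donor_rate <- function(rate_per_vector, scaling = calibration_scaling()) {
  check_scalar(rate_per_vector, "rate_per_vector", lower = 0)
  if (!inherits(scaling, "calibration_scaling")) {
    scaling <- do.call(calibration_scaling, as.list(scaling))
  }
  rate_per_vector * scaling$vector_per_donor * scaling$recipient_efficiency
}

#' Round a rate constant to the nearest power of ten
#'
#' Order-of-magnitude reporting for calibrated rate constants: returns
#' `10^round(log10(rate))` with the exponent rounded half-away-from-zero.
#'
#' @param rate a positive rate constant.
#' @return The nearest power of ten.
#' @examples
#' nearest_power_of_ten(1.449e-16)
#' @export
nearest_power_of_ten <- function(rate) {
  check_scalar(rate, "rate", lower = 0, strict_lower = TRUE)
  e <- log10(rate)
  10^(sign(e) * floor(abs(e) + 0.5))
}

#' Default calibration pipeline for the four mechanism rate constants
#'
#' Assembles the maximal per-donor rate constants used by the community
#' model. Conjugation is fixed at the top of the empirically measured range
#' (1e-8 mL cell^-1 min^-1, measured directly per donor). The other three are
#' per-vector constants scaled by environmental vector:donor ratios:
#' transformation uses the study-mean per-fragment constant, an ocean
#' DNA:cell ratio derived from 0.01 ug/mL DNA over 1e6 cells/mL, and a
#' natural competence rate; transduction re-derives its per-phage constant
#' from the most efficient published experiment via [endpoint_rate()] and
#' scales by phages-per-cell; vesicle transfer uses the study-mean
#' per-vesicle constant and vesicles-per-cell ratio.
#'
#' @param fragment_mass grams per 30 kb DNA fragment.
#' @param competence_rate natural competence rate applied to transformation.
#' @param dna_fragments_per_donor ocean free-DNA fragments per donor cell.
#' @param phages_per_donor ocean phages per donor cell.
#' @param vesicles_per_donor extracellular vesicles per donor cell.
#' @param mean_gamma_transformation study-mean per-fragment rate constant.
#' @param mean_gamma_vesicle study-mean per-vesicle rate constant.
#' @param gamma_conjugation fixed per-donor conjugation constant.
#' @return A data frame with one row per mechanism and columns `mechanism`,
#'   `gamma_per_vector`, `gamma_per_donor`, `gamma_rounded`.
#' @examples
#' calibrate_mechanisms()
#' @export
calibrate_mechanisms <- function(fragment_mass = 3.0e-17,
                                 competence_rate = 0.01,
                                 dna_fragments_per_donor = 333,
                                 phages_per_donor = 10,
                                 vesicles_per_donor = 0.4,
                                 mean_gamma_transformation = 4.35e-17,
                                 mean_gamma_vesicle = 4.76e-22,
                                 gamma_conjugation = 1e-8) {
  # transduction: most efficient published experiment (R0 = 6e8 cells/mL,
  # MOI 0.4, 876 transductants/mL after 60 min)
  td_exp <- endpoint_experiment(
    V0 = vector_conc_from_moi(6e8, 0.4),
    R0 = 6e8,
    R1 = recipients_after_transfer(6e8, 876),
    duration = 60,
    label = "transduction (optimal pair)")
  gamma_td_vec <- endpoint_rate(td_exp)

  per_vector <- c(conjugation = NA_real_,
                  transformation = mean_gamma_transformation,
                  transduction = gamma_td_vec,
                  vesicle = mean_gamma_vesicle)
  per_donor <- c(
    conjugation = gamma_conjugation,
    transformation = scale_to_donor_rate(
      mean_gamma_transformation,
      calibration_scaling(dna_fragments_per_donor, competence_rate)),
    transduction = scale_to_donor_rate(
      gamma_td_vec, calibration_scaling(phages_per_donor, 1)),
    vesicle = scale_to_donor_rate(
      mean_gamma_vesicle, calibration_scaling(vesicles_per_donor, 1)))
  data.frame(mechanism = names(per_donor),
             gamma_per_vector = unname(per_vector),
             gamma_per_donor = unname(per_donor),
             gamma_rounded = vapply(per_donor, nearest_power_of_ten, 0),
             row.names = NULL)
}

#' Calibrate rate constants from a table of end-point experiments
#'
#' Applies [endpoint_rate()] and [scale_to_donor_rate()] row-wise to a table
#' with columns `label`, `V0`, `R0`, `R1`, `dt_min` and optional scaling
#' columns `vector_per_donor`, `recipient_efficiency` (defaulting to 1).
#'
#' @param experiments a data frame (or path handled by
#'   [read_calibration_csv()]).
#' @return The input with appended columns `gamma_per_vector`,
#'   `gamma_per_donor`, `gamma_rounded`.
#' @export
calibrate_experiments <- function(experiments) {
  df <- experiments
  required <- c("label", "V0", "R0", "R1", "dt_min")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_invalid("experiment table lacks columns: ",
                 paste(missing, collapse = ", "))
  }
  if (is.null(df$vector_per_donor)) df$vector_per_donor <- 1
  if (is.null(df$recipient_efficiency)) df$recipient_efficiency <- 1
  df$vector_per_donor[is.na(df$vector_per_donor)] <- 1
  df$recipient_efficiency[is.na(df$recipient_efficiency)] <- 1
  gv <- gd <- gr <- numeric(nrow(df))
  for (i in seq_len(nrow(df))) {
    gv[i] <- endpoint_rate(endpoint_experiment(
      df$V0[i], df$R0[i], df$R1[i], df$dt_min[i], label = df$label[i]))
    gd[i] <- scale_to_donor_rate(
      gv[i], calibration_scaling(df$vector_per_donor[i],
                                 df$recipient_efficiency[i]))
    gr[i] <- if (gd[i] > 0) nearest_power_of_ten(gd[i]) else 0
  }
  df$gamma_per_vector <- gv
  df$gamma_per_donor <- gd
  df$gamma_rounded <- gr
  df
}
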