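# Community dynamics: mass-action horizontal transfer across the enabled
# mechanisms followed by within-species selection-driven vertical spread.
# All rates are per minute; concentrations are cells/mL.

#' Community state
#'
#' Per-species plasmid-positive and plasmid-negative concentrations. The
#' model conserves every per-species total: transfer converts cells in place
#' and the replicator growth step redistributes the fixed total between
#' carriers and non-carriers.
#'
#' @param plasmid_pos length-N vector of plasmid-carrying concentrations
#'   (cells/mL).
#' @param plasmid_neg length-N vector of plasmid-free concentrations.
#' @param time simulation time in minutes.
#' @return An object of class `community_state`.
#' @export
community_state <- function(plasmid_pos, plasmid_neg, time = 0) {
  if (length(plasmid_pos) != length(plasmid_neg)) {
    stop_invalid("plasmid_pos and plasmid_neg differ in length")
  }
  if (any(!is.finite(plasmid_pos)) || any(!is.finite(plasmid_neg)) ||
      any(plasmid_pos < 0) || any(plasmid_neg < 0)) {
    stop_invalid("concentrations must be finite and non-negative")
  }
  check_scalar(time, "time", lower = 0)
  structure(list(plasmid_pos = as.numeric(plasmid_pos),
                 plasmid_neg = as.numeric(plasmid_neg),
                 time = time),
            class = "community_state")
}

#' @export
print.community_state <- function(x, ...) {
  f <- plasmid_fraction(x)
  cat(sprintf("<community_state> %d species at t = %g min\n",
              length(x$plasmid_pos), x$time))
  cat(sprintf("  plasmid fraction: min %.3g, median %.3g, max %.3g\n",
              min(f), stats::median(f), max(f)))
  invisible(x)
}

#' @rdname community_state
#' @param state a `community_state`.
#' @return `plasmid_fraction()` returns the per-species carrier fraction
#'   B+/(B+ + B-) (0 for empty species).
#' @export
plasmid_fraction <- function(state) {
  tot <- state$plasmid_pos + state$plasmid_neg
  ifelse(tot > 0, state$plasmid_pos / tot, 0)
}

#' Mechanism specification
#'
#' One horizontal transfer mechanism: its maximal per-donor rate constant,
#' its compatibility matrix and an on/off flag.
#'
#' @param name one of `"conjugation"`, `"transformation"`, `"transduction"`,
#'   `"vesicle"`.
#' @param gamma maximal rate constant (mL cell^-1 min^-1, >= 0).
#' @param alpha an `hgt_alpha` (or plain N x N matrix with entries in
#'   \[0, 1\]).
#' @param enabled logical flag.
#' @return An object of class `mechanism_spec`.
#' @seealso [default_gammas()]
#' @export
mechanism_spec <- function(name, gamma, alpha, enabled = TRUE) {
  name <- match.arg(name, c("conjugation", "transformation", "transduction",
                            "vesicle"))
  check_scalar(gamma, "gamma", lower = 0)
  entries <- if (inherits(alpha, "hgt_alpha")) alpha$entries else as.matrix(alpha)
  if (nrow(entries) != ncol(entries)) stop_invalid("alpha must be square")
  structure(list(name = name, gamma = gamma, alpha = alpha,
                 enabled = isTRUE(enabled)),
            class = "mechanism_spec")
}

#' Default calibrated maximal rate constants
#'
#' Order-of-magnitude per-donor rate constants from the calibration
#' pipeline: 1e-8 (conjugation), 1e-16 (transformation), 1e-15
#' (transduction), 1e-22 (vesicle), all in mL cell^-1 min^-1.
#'
#' @return A named numeric vector.
#' @export
default_gammas <- function() {
  c(conjugation = 1e-8, transformation = 1e-16, transduction = 1e-15,
    vesicle = 1e-22)
}

mechanism_entries <- function(mech) {
  if (inherits(mech$alpha, "hgt_alpha")) mech$alpha$entries
  else as.matrix(mech$alpha)
}

# Sum of gamma * alpha over enabled mechanisms (transfer is linear in the
# per-mechanism rates, so a single combined matrix drives the step).
combined_transfer_matrix <- function(mechanisms, n) {
  A <- matrix(0, n, n)
  for (mech in mechanisms) {
    if (!inherits(mech, "mechanism_spec")) {
      stop_invalid("mechanisms must be a list of mechanism_spec objects")
    }
    if (!mech$enabled) next
    e <- mechanism_entries(mech)
    if (nrow(e) != n) {
      stop_invalid("alpha for '", mech$name, "' is ", nrow(e), " x ",
                   ncol(e), " but the community has ", n, " species")
    }
    A <- A + mech$gamma * e
  }
  A
}

#' One horizontal transfer step
#'
#' Forward-Euler update of the mass-action transfer term: for each recipient
#' species i,
#' \deqn{\Delta B_i^+ = \Delta t \; B_i^- \sum_{mech} \gamma_{mech}
#'   \sum_j \alpha_{mech}(j, i)\, B_j^+}
#' with the same amount removed from \eqn{B_i^-}. The increment is capped at
#' the available plasmid-free pool; a binding cap indicates too coarse a
#' timestep and raises a warning of class `hgtflow_cap_warning`.
#'
#' @param state a [community_state()].
#' @param mechanisms list of [mechanism_spec()] objects.
#' @param dt timestep in minutes (> 0).
#' @return The updated `community_state` (time unchanged; the caller owns
#'   the clock).
#' @export
hgt_step <- function(state, mechanisms, dt) {
  check_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  n <- length(state$plasmid_pos)
  A <- combined_transfer_matrix(mechanisms, n)
  inflow <- as.vector(crossprod(A, state$plasmid_pos))
  delta <- dt * state$plasmid_neg * inflow
  if (any(delta > state$plasmid_neg)) {
    warn_cap("hgt_step: transfer increment exceeded the plasmid-free pool and was capped; reduce dt")
    delta <- pmin(delta, state$plasmid_neg)
  }
  community_state(state$plasmid_pos + delta, state$plasmid_neg - delta,
                  time = state$time)
}

#' One vertical (selection) growth step
#'
#' Within-species spread of the plasmid under a Malthusian fitness advantage
#' m of the carriers. The carrier fraction follows the exact replicator
#' (logistic) update
#' \deqn{f' = \frac{f e^{m\Delta t}}{1 + f\,(e^{m\Delta t} - 1)}}
#' and the per-species total is redistributed accordingly, so the step is
#' exact for any dt, preserves totals, and fixes f = 0 and f = 1.
#'
#' @param state a [community_state()].
#' @param fitness_per_min Malthusian fitness advantage per minute (>= 0).
#' @param dt timestep in minutes (> 0).
#' @return The updated `community_state`.
#' @export
growth_step <- function(state, fitness_per_min, dt) {
  check_scalar(fitness_per_min, "fitness_per_min", lower = 0)
  check_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  tot <- state$plasmid_pos + state$plasmid_neg
  f <- plasmid_fraction(state)
  g <- exp(fitness_per_min * dt)
  f2 <- f * g / (1 + f * (g - 1))
  community_state(f2 * tot, (1 - f2) * tot, time = state$time)
}

#' Simulation configuration
#'
#' Defaults reflect an ocean-like community: 100 species at 1e4 cells/mL
#' each (1e6 cells/mL total), a Malthusian fitness advantage of 0.02 per day
#' for plasmid carriers, 1e4 Euler steps over the simulation horizon, and a
#' single seeded species starting at carrier fraction 1e-4. Full spread
#' means every species at >= 99% carriers.
#'
#' @param n_species community size N.
#' @param total_time simulation horizon in minutes (default 60 days; use
#'   [as_minutes()] for other units).
#' @param n_steps number of timesteps (dt = total_time / n_steps).
#' @param fitness Malthusian fitness advantage m, in units of
#'   `fitness_unit`.
#' @param fitness_unit `"day"`, `"hour"` or `"minute"`; m is converted to
#'   per-minute internally. The default per-day reading of m = 0.02 is the
#'   interpretation consistent with multi-year spread of non-conjugative
#'   plasmids.
#' @param per_species_density cells/mL per species.
#' @param initial_species index of the seeded species.
#' @param initial_fraction initial carrier fraction in the seeded species.
#' @param threshold full-spread detection threshold on every species'
#'   carrier fraction.
#' @param record_every record the state every this many steps.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_species = 100,
                       total_time = as_minutes(60, "day"),
                       n_steps = 1e4,
                       fitness = 0.02,
                       fitness_unit = c("day", "hour", "minute"),
                       per_species_density = 1e4,
                       initial_species = 1,
                       initial_fraction = 1e-4,
                       threshold = 0.99,
                       record_every = 1) {
  fitness_unit <- match.arg(fitness_unit)
  check_scalar(n_species, "n_species", lower = 1)
  check_scalar(total_time, "total_time", lower = 0, strict_lower = TRUE)
  check_scalar(n_steps, "n_steps", lower = 1)
  check_scalar(fitness, "fitness", lower = 0)
  check_scalar(per_species_density, "per_species_density", lower = 0,
               strict_lower = TRUE)
  check_scalar(initial_species, "initial_species", lower = 1,
               upper = n_species)
  check_scalar(initial_fraction, "initial_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_scalar(threshold, "threshold", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_scalar(record_every, "record_every", lower = 1, upper = n_steps)
  structure(list(n_species = as.integer(n_species),
                 total_time = total_time,
                 n_steps = as.integer(n_steps),
                 fitness = fitness,
                 fitness_unit = fitness_unit,
                 per_species_density = per_species_density,
                 initial_species = as.integer(initial_species),
                 initial_fraction = initial_fraction,
                 threshold = threshold,
                 record_every = as.integer(record_every)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  N = %d species at %g cells/mL; horizon %g min (%.3g days)\n",
              x$n_species, x$per_species_density, x$total_time,
              minutes_to(x$total_time, "day")))
  cat(sprintf("  %d steps (dt = %.4g min); m = %g per %s; f0 = %g in species %d\n",
              x$n_steps, x$total_time / x$n_steps, x$fitness, x$fitness_unit,
              x$initial_fraction, x$initial_species))
  invisible(x)
}

fitness_per_min <- function(config) {
  config$fitness / switch(config$fitness_unit,
                          day = 1440, hour = 60, minute = 1)
}

#' Run a community gene-transfer simulation
#'
#' Initializes every species at `per_species_density` with the plasmid
#' present (at `initial_fraction`) in `initial_species` only, then iterates
#' `n_steps` times: the mass-action transfer step ([hgt_step()]) followed by
#' the exact replicator growth step ([growth_step()]). The recorded
#' trajectory is deterministic given the configuration and matrices; all
#' stochasticity lives in the matrix draws.
#'
#' @param config a [sim_config()].
#' @param mechanisms list of [mechanism_spec()] objects; every enabled
#'   mechanism must carry an N x N matrix.
#' @return An object of class `hgt_trajectory`: recorded `times` (minutes),
#'   a `fractions` matrix (recorded times x species), `full_spread_time`
#'   (minutes, or `NA` if the threshold is never reached by all species),
#'   the configuration, and a per-mechanism summary.
#' @examples
#' cfg <- sim_config(n_species = 5, total_time = as_minutes(30, "day"),
#'                   n_steps = 2000)
#' mech <- list(mechanism_spec("conjugation", 1e-8,
#'                             conjugation_alpha(5, seed = 1)))
#' traj <- run_simulation(cfg, mech)
#' @export
run_simulation <- function(config, mechanisms) {
  if (!inherits(config, "sim_config")) stop_config("config must be a sim_config")
  n <- config$n_species
  enabled <- Filter(function(m) m$enabled, mechanisms)
  for (mech in enabled) {
    e <- mechanism_entries(mech)
    if (nrow(e) != n || ncol(e) != n) {
      stop_config("enabled mechanism '", mech$name,
                  "' has a matrix of dimension ", nrow(e), " x ", ncol(e),
                  " but n_species = ", n)
    }
  }
  At <- t(combined_transfer_matrix(mechanisms, n))
  dt <- config$total_time / config$n_steps
  m_min <- fitness_per_min(config)
  g <- exp(m_min * dt)

  tot <- rep(config$per_species_density, n)
  Bp <- numeric(n)
  Bp[config$initial_species] <- config$initial_fraction * tot[config$initial_species]
  Bn <- tot - Bp

  n_rec <- config$n_steps %/% config$record_every
  times <- numeric(n_rec + 1)
  fractions <- matrix(NA_real_, n_rec + 1, n)
  colnames(fractions) <- paste0("sp", seq_len(n))
  fractions[1, ] <- Bp / tot
  rec <- 1L
  cap_events <- 0L

  for (s in seq_len(config$n_steps)) {
    delta <- dt * Bn * as.vector(At %*% Bp)
    over <- delta > Bn
    if (any(over)) {
      cap_events <- cap_events + sum(over)
      delta <- pmin(delta, Bn)
    }
    Bp <- Bp + delta
    f <- Bp / tot
    f <- f * g / (1 + f * (g - 1))
    Bp <- f * tot
    Bn <- tot - Bp
    if (s %% config$record_every == 0L) {
      rec <- rec + 1L
      times[rec] <- s * dt
      fractions[rec, ] <- f
    }
  }
  if (cap_events > 0) {
    warn_cap(sprintf(
      "run_simulation: transfer increment capped at the plasmid-free pool in %d species-steps; dt is too coarse",
      cap_events))
  }

  traj <- structure(list(times = times,
                         fractions = fractions,
                         full_spread_time = NA_real_,
                         threshold = config$threshold,
                         config = config,
                         mechanisms = data.frame(
                           name = vapply(mechanisms, `[[`, "", "name"),
                           gamma = vapply(mechanisms, `[[`, 0, "gamma"),
                           enabled = vapply(mechanisms, `[[`, TRUE, "enabled")),
                         cap_events = cap_events),
                    class = "hgt_trajectory")
  traj$full_spread_time <- full_spread_time(traj, config$threshold)
  traj
}

#' First time of community-wide plasmid spread
#'
#' @param trajectory an `hgt_trajectory`.
#' @param threshold carrier-fraction threshold in (0, 1\] (default the
#'   trajectory's own, normally 0.99).
#' @return First recorded time (minutes) at which every species' carrier
#'   fraction is at or above the threshold, or `NA_real_` if never reached.
#' @export
full_spread_time <- function(trajectory, threshold = NULL) {
  if (is.null(threshold)) threshold <- trajectory$threshold
  check_scalar(threshold, "threshold", lower = 0, upper = 1)
  reached <- apply(trajectory$fractions, 1, min) >= threshold
  if (!any(reached)) return(NA_real_)
  trajectory$times[which(reached)[1]]
}

#' @export
print.hgt_trajectory <- function(x, ...) {
  cat(sprintf("<hgt_trajectory> %d species, %d recorded times over %.4g days\n",
              ncol(x$fractions), length(x$times),
              minutes_to(max(x$times), "day")))
  on <- x$mechanisms$name[x$mechanisms$enabled]
  cat("  mechanisms:", if (length(on)) paste(on, collapse = ", ") else "none", "\n")
  if (is.na(x$full_spread_time)) {
    cat(sprintf("  full spread (>= %g%% in every species): not reached\n",
                100 * x$threshold))
  } else {
    cat(sprintf("  full spread (>= %g%%) at %.4g days (%.3g years)\n",
                100 * x$threshold, minutes_to(x$full_spread_time, "day"),
                minutes_to(x$full_spread_time, "year")))
  }
  invisible(x)
}

#' @export
summary.hgt_trajectory <- function(object, ...) {
  f_end <- object$fractions[nrow(object$fractions), ]
  out <- list(n_species = ncol(object$fractions),
              full_spread_time_min = object$full_spread_time,
              threshold = object$threshold,
              final_fraction_min = min(f_end),
              final_fraction_median = stats::median(f_end),
              final_fraction_max = max(f_end),
              cap_events = object$cap_events)
  class(out) <- "summary.hgt_trajectory"
  out
}

#' @export
print.summary.hgt_trajectory <- function(x, ...) {
  cat(sprintf("%d species; final carrier fraction min/median/max = %.4g / %.4g / %.4g\n",
              x$n_species, x$final_fraction_min, x$final_fraction_median,
              x$final_fraction_max))
  if (is.na(x$full_spread_time_min)) cat("full spread: not reached\n")
  else cat(sprintf("full spread at %.5g min (%.4g days)\n",
                   x$full_spread_time_min,
                   minutes_to(x$full_spread_time_min, "day")))
  invisible(x)
}

#' @export
as.data.frame.hgt_trajectory <- function(x, ...) {
  n <- ncol(x$fractions)
  data.frame(time_min = rep(x$times, n),
             species_id = rep(colnames(x$fractions), each = length(x$times)),
             plasmid_fraction = as.vector(x$fractions))
}

#' @export
plot.hgt_trajectory <- function(x, time_unit = c("day", "year", "hour", "minute"),
                                ...) {
  time_unit <- match.arg(time_unit)
  t <- minutes_to(x$times, time_unit)
  graphics::matplot(t, x$fractions, type = "l", lty = 1,
                    col = grDevices::hcl.colors(ncol(x$fractions), "viridis"),
                    xlab = paste0("time (", time_unit, "s)"),
                    ylab = "plasmid-carrier fraction", ylim = c(0, 1), ...)
  if (!is.na(x$full_spread_time)) {
    graphics::abline(v = minutes_to(x$full_spread_time, time_unit),
                     lty = 2, col = "darkgreen")
  }
  invisible(x)
}

#' Timestep convergence check for the Euler transfer step
#'
#' Reruns a simulation with the step count doubled per refinement and
#' reports the relative change in the full-spread time, flagging
#' non-convergence when the last refinement still moves the result by more
#' than `tol` (or when the transfer cap binds).
#'
#' @param config a [sim_config()].
#' @param mechanisms list of [mechanism_spec()] objects.
#' @param refinements number of doublings (>= 1).
#' @param tol relative-change tolerance for the converged verdict.
#' @return A list with the step counts, full-spread times, successive
#'   relative changes, cap counts and a `converged` flag.
#' @export
convergence_check <- function(config, mechanisms, refinements = 3, tol = 0.01) {
  check_scalar(refinements, "refinements", lower = 1)
  steps <- config$n_steps * 2^(0:refinements)
  times <- numeric(length(steps))
  caps <- integer(length(steps))
  for (i in seq_along(steps)) {
    cfg <- config
    cfg$n_steps <- as.integer(steps[i])
    cfg$record_every <- 1L
    traj <- withCallingHandlers(
      run_simulation(cfg, mechanisms),
      hgtflow_cap_warning = function(w) invokeRestart("muffleWarning"))
    times[i] <- traj$full_spread_time
    caps[i] <- traj$cap_events
  }
  rel_change <- abs(diff(times)) / abs(times[-1])
  last <- rel_change[length(rel_change)]
  list(n_steps = steps,
       full_spread_time_min = times,
       rel_change = rel_change,
       cap_events = caps,
       converged = is.finite(last) && last <= tol && caps[length(caps)] == 0)
}
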