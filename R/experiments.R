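# Replicated in-silico experiments: mechanism-knockout scenarios, the
# conjugative vs non-conjugative timescale ratio, and rate-constant sweeps.
# Replicate k draws all four matrices under seed base_seed + k regardless of
# which mechanisms are enabled, so scenarios sharing a base seed are paired
# (matched matrices) and knockout effects are isolated from matrix noise.

MECHANISM_NAMES <- c("conjugation", "transformation", "transduction", "vesicle")

#' Scenario specification
#'
#' A named scenario: which mechanisms are enabled, how many replicate matrix
#' draws to run, the base simulation configuration and the replicate seeds
#' (`base_seed + 1:n_replicates`).
#'
#' @param name scenario label.
#' @param mechanisms character subset of
#'   `c("conjugation", "transformation", "transduction", "vesicle")`.
#' @param config a [sim_config()].
#' @param n_replicates number of replicate matrix draws (>= 1).
#' @param base_seed integer; replicate k is seeded with `base_seed + k`.
#' @param gammas named vector overriding [default_gammas()] entries.
#' @param matrix_params list of optional generator parameters:
#'   `spc_fraction`, `attenuation`, `p_transformable`, `n_modules`,
#'   `vesicle_participation`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, mechanisms = MECHANISM_NAMES,
                          config = sim_config(), n_replicates = 5,
                          base_seed = 1, gammas = NULL,
                          matrix_params = list()) {
  mechanisms <- match.arg(mechanisms, MECHANISM_NAMES, several.ok = TRUE)
  check_scalar(n_replicates, "n_replicates", lower = 1)
  check_scalar(base_seed, "base_seed")
  if (!inherits(config, "sim_config")) stop_config("config must be a sim_config")
  g <- default_gammas()
  if (!is.null(gammas)) {
    unknown <- setdiff(names(gammas), MECHANISM_NAMES)
    if (length(unknown)) stop_config("unknown gamma names: ",
                                     paste(unknown, collapse = ", "))
    g[names(gammas)] <- gammas
  }
  structure(list(name = name, mechanisms = mechanisms, config = config,
                 n_replicates = as.integer(n_replicates),
                 base_seed = as.integer(base_seed), gammas = g,
                 matrix_params = matrix_params),
            class = "scenario_spec")
}

#' Draw the four-mechanism set for one community
#'
#' Draws all four compatibility matrices from a single seeded stream (in the
#' fixed order conjugation, transformation, transduction, vesicle) and wraps
#' them with the calibrated rate constants as [mechanism_spec()] objects.
#' All four matrices are always drawn — disabled mechanisms are carried with
#' their flag off — so scenarios sharing a seed share matrices regardless of
#' which mechanisms they enable.
#'
#' @param n community size.
#' @param seed RNG seed for the draw (`NULL` uses the current stream).
#' @param enabled character subset of mechanisms to switch on.
#' @param gammas named per-donor rate constants (defaults
#'   [default_gammas()]).
#' @param matrix_params optional generator parameters (`spc_fraction`,
#'   `attenuation`, `p_transformable`, `n_modules`,
#'   `vesicle_participation`).
#' @return A list of four [mechanism_spec()] objects.
#' @export
draw_mechanism_set <- function(n, seed, enabled = MECHANISM_NAMES,
                               gammas = default_gammas(),
                               matrix_params = list()) {
  p <- matrix_params
  with_seed(seed, {
    alphas <- list(
      conjugation = conjugation_alpha(
        n,
        spc_fraction = if (is.null(p$spc_fraction)) 0.15 else p$spc_fraction,
        attenuation = if (is.null(p$attenuation)) 25 else p$attenuation),
      transformation = transformation_alpha(
        n,
        p_transformable = if (is.null(p$p_transformable)) 0.01 else p$p_transformable),
      transduction = transduction_alpha(phage_host_network(
        n,
        n_modules = if (is.null(p$n_modules)) min(13L, n) else p$n_modules)),
      vesicle = vesicle_alpha(
        n,
        participation = if (is.null(p$vesicle_participation)) 1 else p$vesicle_participation))
    lapply(MECHANISM_NAMES, function(nm) {
      mechanism_spec(nm, gammas[[nm]], alphas[[nm]],
                     enabled = nm %in% enabled)
    })
  })
}

#' Run a replicated scenario
#'
#' For each replicate, draws all four compatibility matrices under seed
#' `base_seed + k`, runs the simulation with the scenario's enabled
#' mechanism set, and collects full-spread times. Mean and standard
#' deviation are computed only over replicates that reached full spread
#' within the horizon; the reaching fraction is reported alongside.
#'
#' @param spec a [scenario_spec()].
#' @param keep_trajectories keep the per-replicate `hgt_trajectory` objects.
#' @return An object of class `hgt_replicates` with fields `times_min`
#'   (NA for replicates that never reached full spread), `reached`,
#'   `mean_min`, `sd_min`, `frac_reached` and `seeds`.
#' @export
run_scenario <- function(spec, keep_trajectories = FALSE) {
  if (!inherits(spec, "scenario_spec")) stop_config("spec must be a scenario_spec")
  seeds <- spec$base_seed + seq_len(spec$n_replicates)
  times <- rep(NA_real_, spec$n_replicates)
  trajs <- if (keep_trajectories) vector("list", spec$n_replicates) else NULL
  for (k in seq_len(spec$n_replicates)) {
    mechs <- draw_mechanism_set(spec$config$n_species, seeds[k],
                                enabled = spec$mechanisms,
                                gammas = spec$gammas,
                                matrix_params = spec$matrix_params)
    traj <- run_simulation(spec$config, mechs)
    times[k] <- traj$full_spread_time
    if (keep_trajectories) trajs[[k]] <- traj
  }
  reached <- !is.na(times)
  structure(list(name = spec$name,
                 mechanisms = spec$mechanisms,
                 times_min = times,
                 reached = reached,
                 mean_min = if (any(reached)) mean(times[reached]) else NA_real_,
                 sd_min = if (sum(reached) > 1) stats::sd(times[reached]) else NA_real_,
                 frac_reached = mean(reached),
                 seeds = seeds,
                 config = spec$config,
                 trajectories = trajs),
            class = "hgt_replicates")
}

#' @export
print.hgt_replicates <- function(x, ...) {
  cat(sprintf("<hgt_replicates> '%s' (%s), %d replicates\n", x$name,
              paste(x$mechanisms, collapse = " + "), length(x$times_min)))
  if (x$frac_reached == 0) {
    cat("  no replicate reached full spread within the horizon\n")
  } else {
    d <- minutes_to(x$mean_min, "day")
    if (d > 365) {
      cat(sprintf("  full spread: %.2f +/- %.2f years (%.0f%% of replicates)\n",
                  minutes_to(x$mean_min, "year"),
                  minutes_to(x$sd_min, "year"), 100 * x$frac_reached))
    } else {
      cat(sprintf("  full spread: %.1f +/- %.1f days (%.0f%% of replicates)\n",
                  d, minutes_to(x$sd_min, "day"), 100 * x$frac_reached))
    }
  }
  invisible(x)
}

#' @export
as.data.frame.hgt_replicates <- function(x, ...) {
  data.frame(scenario = x$name,
             replicate = seq_along(x$times_min),
             seed = x$seeds,
             full_spread_min = x$times_min,
             reached = x$reached)
}

#' Mechanism-knockout panel for a non-conjugative plasmid
#'
#' Runs the four standard panels for a plasmid that cannot conjugate: all
#' three remaining mechanisms, then each of transformation, transduction and
#' vesicle transfer removed in turn. Panels share replicate seeds, so the
#' same matrices underlie each comparison.
#'
#' @param config a [sim_config()]; the default horizon is 7 years.
#' @param n_replicates replicates per panel.
#' @param base_seed base replicate seed shared by all panels.
#' @param gammas,matrix_params passed to [scenario_spec()].
#' @return A named list of `hgt_replicates` (class `hgt_knockout_panel`):
#'   `non_conjugative`, `minus_transformation`, `minus_transduction`,
#'   `minus_vesicle`.
#' @export
knockout_panel <- function(config = sim_config(total_time = as_minutes(7, "year")),
                           n_replicates = 5, base_seed = 1, gammas = NULL,
                           matrix_params = list()) {
  panels <- list(
    non_conjugative = c("transformation", "transduction", "vesicle"),
    minus_transformation = c("transduction", "vesicle"),
    minus_transduction = c("transformation", "vesicle"),
    minus_vesicle = c("transformation", "transduction"))
  out <- lapply(names(panels), function(nm) {
    run_scenario(scenario_spec(nm, panels[[nm]], config = config,
                               n_replicates = n_replicates,
                               base_seed = base_seed, gammas = gammas,
                               matrix_params = matrix_params))
  })
  names(out) <- names(panels)
  class(out) <- c("hgt_knockout_panel", "list")
  out
}

#' @export
print.hgt_knockout_panel <- function(x, ...) {
  for (r in x) print(r)
  invisible(x)
}

#' Ratio of non-conjugative to conjugative spread timescales
#'
#' @param conjugative an `hgt_replicates` result for a scenario in which
#'   conjugation operates.
#' @param nonconjugative an `hgt_replicates` result without conjugation.
#' @return `mean(nonconjugative) / mean(conjugative)` over replicates that
#'   reached full spread (dimensionless).
#' @export
conjugative_ratio <- function(conjugative, nonconjugative) {
  if (!inherits(conjugative, "hgt_replicates") ||
      !inherits(nonconjugative, "hgt_replicates")) {
    stop_invalid("both arguments must be hgt_replicates results")
  }
  if (!any(conjugative$reached)) {
    stop_invalid("conjugative scenario never reached full spread; ratio undefined")
  }
  if (!any(nonconjugative$reached)) {
    stop_invalid("non-conjugative scenario never reached full spread; ratio undefined")
  }
  nonconjugative$mean_min / conjugative$mean_min
}

#' Compare two replicated scenarios
#'
#' Difference of mean full-spread times with a pooled-variance two-tailed
#' unpaired t-test over the replicates that reached full spread, plus
#' whether the +/- 1 SD intervals overlap.
#'
#' @param result_a,result_b `hgt_replicates` objects with at least two
#'   successful replicates each.
#' @return A list of class `hgt_comparison`: `diff_min`, `t`, `df`, `p`,
#'   `sd_overlap`.
#' @export
compare_scenarios <- function(result_a, result_b) {
  a <- result_a$times_min[result_a$reached]
  b <- result_b$times_min[result_b$reached]
  if (length(a) < 2 || length(b) < 2) {
    stop_invalid("each scenario needs >= 2 successful replicates to compare")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b)) {
    tt <- list(statistic = c(t = 0), parameter = c(df = length(a) + length(b) - 2),
               p.value = 1)
  } else {
    tt <- stats::t.test(a, b, var.equal = TRUE)
  }
  overlap <- (mean(a) + stats::sd(a) >= mean(b) - stats::sd(b)) &&
    (mean(b) + stats::sd(b) >= mean(a) - stats::sd(a))
  structure(list(names = c(result_a$name, result_b$name),
                 diff_min = mean(a) - mean(b),
                 t = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p = tt$p.value,
                 sd_overlap = overlap),
            class = "hgt_comparison")
}

#' @export
print.hgt_comparison <- function(x, ...) {
  cat(sprintf("'%s' vs '%s': diff = %.4g days, t = %.3g (df %g), p = %.3g, +/-1 SD %s\n",
              x$names[1], x$names[2], minutes_to(x$diff_min, "day"), x$t, x$df,
              x$p, if (x$sd_overlap) "overlap" else "disjoint"))
  invisible(x)
}

#' Sensitivity sweep over a calibration parameter
#'
#' Reruns a scenario with one parameter scaled by each multiplier, reusing
#' the scenario's replicate seeds so results are paired across multipliers.
#' `"competence_rate"` scales the transformation rate constant (to which it
#' is directly proportional); `"vesicle_participation"` interprets the
#' multiplier as the fraction of species able to produce and take up
#' vesicles.
#'
#' @param spec a [scenario_spec()].
#' @param parameter one of `"gamma_conjugation"`, `"gamma_transformation"`,
#'   `"gamma_transduction"`, `"gamma_vesicle"`, `"competence_rate"`,
#'   `"vesicle_participation"`.
#' @param multipliers positive multipliers (participation fractions in
#'   \[0, 1\] for `"vesicle_participation"`).
#' @return A data frame with one row per multiplier (`multiplier`,
#'   `mean_min`, `sd_min`, `frac_reached`), with the per-multiplier
#'   `hgt_replicates` attached as attribute `"results"`.
#' @export
parameter_sweep <- function(spec, parameter, multipliers) {
  allowed <- c("gamma_conjugation", "gamma_transformation",
               "gamma_transduction", "gamma_vesicle",
               "competence_rate", "vesicle_participation")
  if (!is.character(parameter) || length(parameter) != 1 ||
      !parameter %in% allowed) {
    stop_invalid("unknown sweep parameter; use one of: ",
                 paste(allowed, collapse = ", "))
  }
  if (!is.numeric(multipliers) || !length(multipliers) ||
      any(!is.finite(multipliers))) {
    stop_invalid("multipliers must be finite numbers")
  }
  if (parameter == "vesicle_participation") {
    if (any(multipliers < 0 | multipliers > 1)) {
      stop_invalid("vesicle participation fractions must lie in [0, 1]")
    }
  } else if (any(multipliers <= 0)) {
    stop_invalid("multipliers must be > 0")
  }
  results <- lapply(multipliers, function(mult) {
    s <- spec
    if (parameter == "vesicle_participation") {
      s$matrix_params$vesicle_participation <- mult
    } else if (parameter == "competence_rate") {
      s$gammas[["transformation"]] <- s$gammas[["transformation"]] * mult
    } else {
      nm <- sub("^gamma_", "", parameter)
      s$gammas[[nm]] <- s$gammas[[nm]] * mult
    }
    run_scenario(s)
  })
  out <- data.frame(multiplier = multipliers,
                    mean_min = vapply(results, `[[`, 0, "mean_min"),
                    sd_min = vapply(results, `[[`, 0, "sd_min"),
                    frac_reached = vapply(results, `[[`, 0, "frac_reached"))
  attr(out, "results") <- results
  out
}
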