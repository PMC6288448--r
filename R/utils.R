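# Internal helpers: classed conditions, seeded evaluation, time units.

stop_invalid <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...),
                      class = c("hgtflow_invalid_input", "hgtflow_error")))
}

stop_infeasible <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...),
                      class = c("hgtflow_infeasible", "hgtflow_error")))
}

stop_config <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...),
                      class = c("hgtflow_config_error", "hgtflow_error")))
}

warn_cap <- function(msg) {
  warning(warningCondition(msg, class = "hgtflow_cap_warning"))
}

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream. seed = NULL evaluates in the current stream (used when a caller has
# already seeded a replicate-level stream).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_invalid("'seed' must be a single finite number or NULL")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("'", name, "' must be a single finite number")
  }
  if (x < lower || (strict_lower && x <= lower)) {
    stop_invalid("'", name, "' must be ", if (strict_lower) "> " else ">= ",
                 lower, " (got ", format(x), ")")
  }
  if (x > upper || (strict_upper && x >= upper)) {
    stop_invalid("'", name, "' must be ", if (strict_upper) "< " else "<= ",
                 upper, " (got ", format(x), ")")
  }
  invisible(x)
}

#' Time-unit conversion
#'
#' All internal quantities are in minutes (rate constants are
#' mL cell^-1 min^-1). These helpers convert between minutes and the units
#' used for reporting (hours, days, 365-day years).
#'
#' @param x numeric vector of time values.
#' @param unit one of `"minute"`, `"hour"`, `"day"`, `"year"`.
#' @return `as_minutes()` returns `x` converted to minutes; `minutes_to()`
#'   converts a value in minutes to `unit`.
#' @examples
#' as_minutes(7, "year")
#' minutes_to(40320, "day")
#' @export
as_minutes <- function(x, unit = c("minute", "hour", "day", "year")) {
  unit <- match.arg(unit)
  x * switch(unit, minute = 1, hour = 60, day = 1440, year = 525600)
}

#' @rdname as_minutes
#' @export
minutes_to <- function(x, unit = c("minute", "hour", "day", "year")) {
  unit <- match.arg(unit)
  x / switch(unit, minute = 1, hour = 60, day = 1440, year = 525600)
}

# Parse "60 days" / "7 years" / plain minutes into minutes.
parse_time_value <- function(x, field = "time") {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.character(x) && length(x) == 1L) {
    parts <- strsplit(trimws(x), "\\s+")[[1]]
    if (length(parts) == 2L) {
      val <- suppressWarnings(as.numeric(parts[1]))
      unit <- sub("s$", "", tolower(parts[2]))
      if (!is.na(val) && unit %in% c("minute", "min", "hour", "day", "year")) {
        if (unit == "min") unit <- "minute"
        return(as_minutes(val, unit))
      }
    }
  }
  stop_config("cannot parse '", field, "': expected minutes or \"<value> <unit>\"")
}
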