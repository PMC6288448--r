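# Serialization and configuration: YAML run configuration, CSV matrix and
# trajectory files with JSON sidecars, and reproducibility manifests.
# All writes are atomic (temp file in the target directory, then rename).

atomic_write <- function(path, writer) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(pattern = ".tmp_", tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

write_json_atomic <- function(x, path) {
  atomic_write(path, function(tmp) {
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
  })
}

config_defaults <- function() {
  list(n_species = 100,
       total_time = "60 days",
       n_steps = 1e4,
       fitness = 0.02,
       fitness_unit = "day",
       per_species_density = 1e4,
       initial_species = 1,
       initial_fraction = 1e-4,
       threshold = 0.99,
       record_every = 1,
       mechanisms = MECHANISM_NAMES,
       gamma_conjugation = 1e-8,
       gamma_transformation = 1e-16,
       gamma_transduction = 1e-15,
       gamma_vesicle = 1e-22,
       n_modules = 13,
       spc_fraction = 0.15,
       attenuation = 25,
       p_transformable = 0.01,
       vesicle_participation = 1,
       seed = 1)
}

#' Load a simulation configuration file
#'
#' Reads a YAML key/value file, fills defaults, rejects unknown keys and
#' validates every field. Time fields (`total_time`) accept plain minutes or
#' strings with a unit suffix (`"60 days"`, `"7 years"`). An empty file
#' yields the full default configuration.
#'
#' @param path path to a YAML file.
#' @return A list with elements `config` (a [sim_config()]), `mechanisms`
#'   (enabled mechanism names), `gammas` (named vector), `matrix_params`
#'   and `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  user <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop_config("cannot parse config file '", path, "': ", conditionMessage(e))
  })
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop_config("config file must be a key/value mapping")
  resolve_config(user)
}

resolve_config <- function(user = list()) {
  defaults <- config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop_config("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  full <- utils::modifyList(defaults, user)
  # YAML 1.1 leaves exponent-style scalars like "1e-10" as strings
  numeric_keys <- c("n_species", "n_steps", "fitness", "per_species_density",
                    "initial_species", "initial_fraction", "threshold",
                    "record_every", "gamma_conjugation",
                    "gamma_transformation", "gamma_transduction",
                    "gamma_vesicle", "n_modules", "spc_fraction",
                    "attenuation", "p_transformable", "vesicle_participation",
                    "seed")
  for (key in numeric_keys) {
    if (is.character(full[[key]])) {
      val <- suppressWarnings(as.numeric(full[[key]]))
      if (is.na(val)) stop_config("'", key, "' is not numeric: ", full[[key]])
      full[[key]] <- val
    }
  }
  # default 13 phage-host modules, capped for small communities
  full$n_modules <- min(full$n_modules, full$n_species)
  total_min <- parse_time_value(full$total_time, "total_time")
  config <- sim_config(n_species = full$n_species,
                       total_time = total_min,
                       n_steps = full$n_steps,
                       fitness = full$fitness,
                       fitness_unit = full$fitness_unit,
                       per_species_density = full$per_species_density,
                       initial_species = full$initial_species,
                       initial_fraction = full$initial_fraction,
                       threshold = full$threshold,
                       record_every = full$record_every)
  mechanisms <- match.arg(unlist(full$mechanisms), MECHANISM_NAMES,
                          several.ok = TRUE)
  gammas <- c(conjugation = full$gamma_conjugation,
              transformation = full$gamma_transformation,
              transduction = full$gamma_transduction,
              vesicle = full$gamma_vesicle)
  if (any(gammas < 0)) stop_config("rate constants must be >= 0")
  list(config = config,
       mechanisms = mechanisms,
       gammas = gammas,
       matrix_params = list(n_modules = full$n_modules,
                            spc_fraction = full$spc_fraction,
                            attenuation = full$attenuation,
                            p_transformable = full$p_transformable,
                            vesicle_participation = full$vesicle_participation),
       seed = full$seed)
}

#' Write / read a compatibility matrix as CSV
#'
#' The CSV carries species identifiers as a header row and first column and
#' entries at full double precision, so a write/read round trip is lossless.
#' A JSON sidecar (`<path>.json`) stores the mechanism, seed, generator
#' parameters and, for transduction, the module partition and phage-set
#' sizes.
#'
#' @param matrix an `hgt_alpha` (or plain square matrix with entries in
#'   \[0, 1\]).
#' @param path CSV file path.
#' @return `write_matrix()` returns `path` invisibly; `read_matrix()`
#'   returns an `hgt_alpha`.
#' @export
write_matrix <- function(matrix, path) {
  x <- if (inherits(matrix, "hgt_alpha")) matrix else
    new_alpha("unspecified", as.matrix(matrix))
  entries <- x$entries
  atomic_write(path, function(tmp) {
    header <- paste(c("species", x$species_ids), collapse = ",")
    rows <- vapply(seq_len(nrow(entries)), function(i) {
      paste(c(x$species_ids[i],
              formatC(entries[i, ], format = "g", digits = 17)),
            collapse = ",")
    }, "")
    writeLines(c(header, rows), tmp)
  })
  sidecar <- list(mechanism = x$mechanism,
                  n = nrow(entries),
                  seed = x$seed,
                  species_ids = x$species_ids,
                  params = x$params[setdiff(names(x$params),
                                            c("spc", "transformable",
                                              "donor_eff", "recipient_eff"))])
  if (!is.null(x$network)) {
    sidecar$network <- list(n_modules = x$network$n_modules,
                            module = x$network$module,
                            n_phages = x$network$n_phages,
                            module_sizes = x$network$module_sizes)
  }
  write_json_atomic(sidecar, paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop_invalid("matrix file not found: ", path)
  lines <- readLines(path)
  fields <- strsplit(lines, ",", fixed = TRUE)
  width <- unique(lengths(fields))
  if (length(width) != 1) stop_invalid("ragged rows in matrix file: ", path)
  ids <- fields[[1]][-1]
  n <- length(ids)
  if (length(fields) - 1 != n) {
    stop_invalid("matrix file is not square: ", n, " columns but ",
                 length(fields) - 1, " rows")
  }
  entries <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    vals <- suppressWarnings(as.numeric(fields[[i + 1]][-1]))
    if (any(is.na(vals))) stop_invalid("non-numeric entry in row ", i)
    entries[i, ] <- vals
  }
  if (any(entries < 0 | entries > 1)) {
    bad <- which(entries < 0 | entries > 1, arr.ind = TRUE)[1, ]
    stop_invalid("entry [", bad[1], ", ", bad[2], "] = ",
                 entries[bad[1], bad[2]], " outside [0, 1]")
  }
  mechanism <- "unspecified"
  seed <- NULL
  params <- list()
  network <- NULL
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    mechanism <- sc$mechanism %||% "unspecified"
    seed <- sc$seed
    params <- as.list(sc$params)
    if (!is.null(sc$network)) {
      network <- structure(list(n = n,
                                n_modules = sc$network$n_modules,
                                module = sc$network$module,
                                n_phages = sc$network$n_phages,
                                module_sizes = sc$network$module_sizes,
                                seed = seed),
                           class = "phage_host_network")
    }
  }
  new_alpha(mechanism, entries, params = params, seed = seed,
            network = network, species_ids = ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a trajectory
#'
#' The trajectory is stored as a long-format CSV (`time_min`, `species_id`,
#' `plasmid_fraction`) with a JSON summary (`<path>.json`) carrying the
#' full-spread time (`null` when never reached), threshold and
#' configuration.
#'
#' @param trajectory an `hgt_trajectory` with at least one recorded point.
#' @param path CSV file path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns an `hgt_trajectory` rebuilt from the files.
#' @export
write_trajectory <- function(trajectory, path) {
  if (!inherits(trajectory, "hgt_trajectory")) {
    stop_invalid("'trajectory' must be an hgt_trajectory")
  }
  if (length(trajectory$times) == 0 || nrow(trajectory$fractions) == 0) {
    stop_invalid("trajectory has no recorded points")
  }
  df <- as.data.frame(trajectory)
  df$time_min <- formatC(df$time_min, format = "g", digits = 17)
  df$plasmid_fraction <- formatC(df$plasmid_fraction, format = "g", digits = 17)
  atomic_write(path, function(tmp) {
    utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  })
  fs <- trajectory$full_spread_time
  write_json_atomic(list(
    full_spread_time_min = if (is.na(fs)) NULL else fs,
    threshold = trajectory$threshold,
    config = unclass(trajectory$config),
    mechanisms = trajectory$mechanisms,
    cap_events = trajectory$cap_events), paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop_invalid("trajectory file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "species_id", "plasmid_fraction")
  if (!all(need %in% names(df))) {
    stop_invalid("trajectory CSV lacks columns: ",
                 paste(setdiff(need, names(df)), collapse = ", "))
  }
  species <- unique(df$species_id)
  times <- unique(df$time_min)
  fractions <- matrix(df$plasmid_fraction, nrow = length(times),
                      ncol = length(species))
  colnames(fractions) <- species
  summary_path <- paste0(path, ".json")
  threshold <- 0.99
  fs <- NA_real_
  config <- NULL
  if (file.exists(summary_path)) {
    sc <- jsonlite::read_json(summary_path, simplifyVector = TRUE)
    threshold <- sc$threshold %||% 0.99
    fs <- if (is.null(sc$full_spread_time_min)) NA_real_ else sc$full_spread_time_min
    config <- sc$config
  }
  structure(list(times = times, fractions = fractions,
                 full_spread_time = fs, threshold = threshold,
                 config = config,
                 mechanisms = data.frame(name = character(0),
                                         gamma = numeric(0),
                                         enabled = logical(0)),
                 cap_events = NA_integer_),
            class = "hgt_trajectory")
}

#' Build and write a run manifest
#'
#' Everything needed to reproduce a run byte-for-byte: package version,
#' timestamp, the fully resolved configuration, all RNG seeds and MD5
#' digests of the files the run wrote.
#'
#' @param config resolved configuration (any list-like object).
#' @param seeds named or unnamed vector of RNG seeds used.
#' @param files character vector of output file paths to digest.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config, seeds, files = character(0)) {
  files <- files[file.exists(files)]
  structure(list(tool = "hgtflow",
                 version = as.character(utils::packageVersion("hgtflow")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 config = if (inherits(config, "sim_config")) unclass(config) else config,
                 seeds = if (is.null(names(seeds))) seeds else as.list(seeds),
                 files = lapply(files, function(f) {
                   list(path = f, md5 = unname(tools::md5sum(f)))
                 })),
            class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path JSON output path.
#' @export
write_manifest <- function(manifest, path) {
  write_json_atomic(unclass(manifest), path)
  invisible(path)
}

#' Read a calibration experiment table
#'
#' CSV columns: `label`, `V0`, `R0`, `R1`, `dt_min` and optionally
#' `vector_per_donor`, `recipient_efficiency` (defaulting to 1 when absent).
#'
#' @param path CSV file path.
#' @return A data frame suitable for [calibrate_experiments()].
#' @export
read_calibration_csv <- function(path) {
  if (!file.exists(path)) stop_invalid("calibration file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("label", "V0", "R0", "R1", "dt_min")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_invalid("calibration CSV lacks columns: ",
                 paste(missing, collapse = ", "))
  }
  df
}

#' Calibrate rate constants from a CSV and write a JSON report
#'
#' @param experiments_path input CSV (see [read_calibration_csv()]).
#' @param out_path output JSON mapping each experiment label to
#'   `gamma_per_vector`, `gamma_per_donor`, `gamma_rounded`.
#' @return The calibration table, invisibly.
#' @export
calibrate_file <- function(experiments_path, out_path) {
  df <- calibrate_experiments(read_calibration_csv(experiments_path))
  out <- stats::setNames(lapply(seq_len(nrow(df)), function(i) {
    list(gamma_per_vector = df$gamma_per_vector[i],
         gamma_per_donor = df$gamma_per_donor[i],
         gamma_rounded = df$gamma_rounded[i])
  }), df$label)
  write_json_atomic(out, out_path)
  invisible(df)
}
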