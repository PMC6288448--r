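# Generators for the four donor -> recipient compatibility matrices (alpha).
# Orientation everywhere: rows are donor species j, columns are recipient
# species i; entries lie in [0, 1] and scale the mechanism's maximal rate
# constant for that pair.

new_alpha <- function(mechanism, entries, params = list(), seed = NULL,
                      network = NULL, species_ids = NULL) {
  n <- nrow(entries)
  if (is.null(species_ids)) species_ids <- paste0("sp", seq_len(n))
  dimnames(entries) <- list(donor = species_ids, recipient = species_ids)
  structure(list(mechanism = mechanism, entries = entries,
                 species_ids = species_ids, params = params, seed = seed,
                 network = network),
            class = "hgt_alpha")
}

#' @export
print.hgt_alpha <- function(x, ...) {
  n <- nrow(x$entries)
  cat(sprintf("<hgt_alpha> %s compatibility matrix, %d x %d\n",
              x$mechanism, n, n))
  cat(sprintf("  entries in [%.3g, %.3g], mean %.3g\n",
              min(x$entries), max(x$entries), mean(x$entries)))
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' @export
as.matrix.hgt_alpha <- function(x, ...) x$entries

#' @export
dim.hgt_alpha <- function(x) dim(x$entries)

alpha_n <- function(x) {
  if (inherits(x, "hgt_alpha")) nrow(x$entries) else nrow(x)
}

#' Conjugation compatibility matrix
#'
#' Pairwise conjugation efficiencies with a "super-permissive core" (SPC) of
#' recipient species. Exactly `round(spc_fraction * n)` recipient columns are
#' chosen uniformly without replacement; their entries are i.i.d. uniform on
#' \[0, 1\], while all other columns are uniform on \[0, 1/attenuation\]
#' (default 25-fold slower uptake outside the core).
#'
#' @param n community size (number of species).
#' @param spc_fraction fraction of species in the super-permissive core.
#' @param attenuation fold reduction of uptake outside the core (>= 1).
#' @param seed optional RNG seed; `NULL` draws from the current stream.
#' @return An object of class `hgt_alpha` with `params$spc` holding the core
#'   column indices.
#' @examples
#' a <- conjugation_alpha(9, seed = 1)
#' @export
conjugation_alpha <- function(n, spc_fraction = 0.15, attenuation = 25,
                              seed = NULL) {
  check_scalar(n, "n", lower = 1)
  check_scalar(spc_fraction, "spc_fraction", lower = 0, upper = 1)
  check_scalar(attenuation, "attenuation", lower = 1)
  n <- as.integer(n)
  with_seed(seed, {
    n_spc <- round(spc_fraction * n)
    spc <- if (n_spc > 0) sort(sample.int(n, n_spc)) else integer(0)
    m <- matrix(runif(n * n, 0, 1 / attenuation), n, n)
    if (n_spc > 0) m[, spc] <- runif(n * n_spc)
    new_alpha("conjugation", m,
              params = list(spc_fraction = spc_fraction,
                            attenuation = attenuation, spc = spc),
              seed = seed)
  })
}

#' Transformation compatibility matrix
#'
#' Each species is independently naturally transformable with probability
#' `p_transformable` (about 1% of species in nature). Columns of
#' transformable recipients are filled with 1 (any donor's free DNA can be
#' taken up), all other columns with 0. Because a community of 100 species
#' has a ~37% chance of containing no transformable species at p = 0.01,
#' `ensure_nonempty = TRUE` (the default) redraws until at least one species
#' is transformable.
#'
#' @inheritParams conjugation_alpha
#' @param p_transformable per-species transformability probability.
#' @param ensure_nonempty redraw until >= 1 transformable species.
#' @return An `hgt_alpha` with `params$transformable` holding the
#'   transformable column indices.
#' @export
transformation_alpha <- function(n, p_transformable = 0.01, seed = NULL,
                                 ensure_nonempty = TRUE) {
  check_scalar(n, "n", lower = 1)
  check_scalar(p_transformable, "p_transformable", lower = 0, upper = 1)
  if (ensure_nonempty && p_transformable == 0) {
    stop_config("ensure_nonempty = TRUE is impossible with p_transformable = 0")
  }
  n <- as.integer(n)
  with_seed(seed, {
    repeat {
      transformable <- which(stats::runif(n) < p_transformable)
      if (length(transformable) > 0 || !ensure_nonempty) break
    }
    m <- matrix(0, n, n)
    if (length(transformable)) m[, transformable] <- 1
    new_alpha("transformation", m,
              params = list(p_transformable = p_transformable,
                            ensure_nonempty = ensure_nonempty,
                            transformable = transformable),
              seed = seed)
  })
}

# Module sizes proportional to 1..n_modules, largest-remainder rounded to sum
# to n, every module >= 1 species. Deterministic.
linear_module_sizes <- function(n, n_modules) {
  raw <- seq_len(n_modules) / sum(seq_len(n_modules)) * n
  sizes <- floor(raw)
  remainder <- raw - sizes
  extra <- n - sum(sizes)
  if (extra > 0) {
    ord <- order(remainder, seq_along(remainder), decreasing = c(TRUE, FALSE),
                 method = "radix")
    sizes[ord[seq_len(extra)]] <- sizes[ord[seq_len(extra)]] + 1
  }
  while (any(sizes == 0)) {
    sizes[which.max(sizes == 0)] <- 1L
    sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
  }
  as.integer(sizes)
}

#' Modular-nested phage-host network
#'
#' Builds the host-side structure from which the transduction compatibility
#' matrix is derived. Species are partitioned into `n_modules` disjoint
#' phage-host modules whose sizes grow linearly (proportional to
#' 1, 2, ..., n_modules, largest-remainder rounded to sum to `n`, each
#' module >= 1). A module of size s carries s module-local phages; hosts in
#' the module are ranked by a uniform random permutation, and the host of
#' rank r is infected by phages 1..r, so phage sets within a module are
#' perfectly nested (phage 1 is the module generalist, phage s the most
#' specialist).
#'
#' @inheritParams conjugation_alpha
#' @param n_modules number of phage-host modules (1..n); the default 13 gives
#'   linear sizes summing near 100 for the standard community size.
#' @return An object of class `phage_host_network` with fields `module`
#'   (module id per species), `n_phages` (phage-set size per species) and
#'   `module_sizes`.
#' @examples
#' net <- phage_host_network(100, seed = 1)
#' table(net$module)
#' @export
phage_host_network <- function(n, n_modules = 13, seed = NULL) {
  check_scalar(n, "n", lower = 1)
  check_scalar(n_modules, "n_modules", lower = 1)
  n <- as.integer(n); n_modules <- as.integer(n_modules)
  if (n_modules > n) stop_invalid("n_modules exceeds community size")
  sizes <- linear_module_sizes(n, n_modules)
  with_seed(seed, {
    perm <- sample.int(n)
    module <- integer(n)
    n_phages <- integer(n)
    pos <- 1L
    for (m in seq_len(n_modules)) {
      sp <- perm[pos:(pos + sizes[m] - 1L)]
      pos <- pos + sizes[m]
      module[sp] <- m
      n_phages[sp] <- sample.int(sizes[m])
    }
    structure(list(n = n, n_modules = n_modules, module = module,
                   n_phages = n_phages, module_sizes = sizes, seed = seed),
              class = "phage_host_network")
  })
}

#' @export
print.phage_host_network <- function(x, ...) {
  cat(sprintf("<phage_host_network> %d species in %d modules (sizes: %s)\n",
              x$n, x$n_modules, paste(x$module_sizes, collapse = ", ")))
  invisible(x)
}

#' Phage sets hosted by each species
#'
#' @param network a [phage_host_network()].
#' @return A list, per species, of module-qualified phage identifiers.
#' @export
phage_sets <- function(network) {
  lapply(seq_len(network$n), function(i) {
    paste0("m", network$module[i], ".p", seq_len(network$n_phages[i]))
  })
}

#' Transduction compatibility matrix from a phage-host network
#'
#' The compatibility of donor d with recipient r is the fraction of the
#' donor's hosted phages that also infect the recipient: with nested
#' phage sets of sizes k this is `min(k_d, k_r) / k_d` within a module, and
#' 0 across modules. Diagonal entries are 1.
#'
#' @param network a [phage_host_network()].
#' @return An `hgt_alpha` with the generating network attached.
#' @export
transduction_alpha <- function(network) {
  if (!inherits(network, "phage_host_network")) {
    stop_invalid("'network' must be a phage_host_network")
  }
  n <- network$n
  kd <- matrix(network$n_phages, n, n)        # kd[d, r] = k_d
  kr <- t(kd)
  m <- pmin(kd, kr) / kd
  m[outer(network$module, network$module, "!=")] <- 0
  new_alpha("transduction", m,
            params = list(n_modules = network$n_modules),
            seed = network$seed, network = network)
}

#' Vesicle-mediated transfer compatibility matrix
#'
#' Every species participates as both donor and recipient: each species gets
#' independent uniform \[0, 1\] donor and recipient efficiencies, and the
#' pairwise compatibility is their product (a rank-1 outer-product matrix).
#'
#' @inheritParams conjugation_alpha
#' @param participation fraction of species able to produce and take up
#'   vesicles (default 1); non-participating species, chosen at random, get
#'   zero donor and recipient efficiency.
#' @return An `hgt_alpha` with `params$donor_eff` and `params$recipient_eff`.
#' @export
vesicle_alpha <- function(n, seed = NULL, participation = 1) {
  check_scalar(n, "n", lower = 1)
  check_scalar(participation, "participation", lower = 0, upper = 1)
  n <- as.integer(n)
  with_seed(seed, {
    e <- stats::runif(n)
    u <- stats::runif(n)
    if (participation < 1) {
      n_out <- n - round(participation * n)
      out <- sample.int(n, n_out)
      e[out] <- 0
      u[out] <- 0
    }
    new_alpha("vesicle", outer(e, u),
              params = list(donor_eff = e, recipient_eff = u,
                            participation = participation),
              seed = seed)
  })
}

#' Validate a compatibility matrix
#'
#' Checks squareness, finiteness, the \[0, 1\] entry range and, for
#' transduction matrices carrying their generating network, the block-zero
#' structure across modules. Reports rather than raises.
#'
#' @param matrix an `hgt_alpha` or plain numeric matrix.
#' @return A list with elements `pass` (logical) and `violations`
#'   (character vector locating each failure).
#' @export
validate_alpha <- function(matrix) {
  x <- if (inherits(matrix, "hgt_alpha")) matrix$entries else as.matrix(matrix)
  network <- if (inherits(matrix, "hgt_alpha")) matrix$network else NULL
  violations <- character(0)
  if (nrow(x) != ncol(x)) {
    violations <- c(violations,
                    sprintf("not square: %d x %d", nrow(x), ncol(x)))
  }
  bad <- which(!is.finite(x) | x < 0 | x > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    violations <- c(violations, apply(bad, 1, function(ij) {
      sprintf("entry [%d, %d] = %g outside [0, 1]", ij[1], ij[2],
              x[ij[1], ij[2]])
    }))
  }
  if (!is.null(network) && nrow(x) == ncol(x) && nrow(x) == network$n) {
    cross <- outer(network$module, network$module, "!=") & x != 0
    bad <- which(cross, arr.ind = TRUE)
    if (nrow(bad)) {
      violations <- c(violations, apply(bad, 1, function(ij) {
        sprintf("cross-module entry [%d, %d] = %g is nonzero",
                ij[1], ij[2], x[ij[1], ij[2]])
      }))
    }
  }
  list(pass = length(violations) == 0, violations = violations)
}
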