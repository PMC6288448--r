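# Generators for the four compatibility-matrix rulesets.

test_that("conjugation matrix has an exact super-permissive core quota", {
  a <- conjugation_alpha(100, seed = 11)
  spc <- a$params$spc
  expect_length(spc, 15)
  # non-core columns never exceed 1/25
  expect_true(all(a$entries[, -spc] <= 0.04))
  expect_true(all(a$entries >= 0 & a$entries <= 1))
  # core columns are plain uniforms: with 1500 draws some must exceed 1/25
  expect_true(any(a$entries[, spc] > 0.04))
  # degenerate ruleset: no core, no attenuation
  b <- conjugation_alpha(50, spc_fraction = 0, attenuation = 1, seed = 2)
  expect_length(b$params$spc, 0)
  expect_true(max(b$entries) > 0.9)  # full-range uniforms
})

test_that("conjugation entry distributions match the ruleset over many seeds", {
  spc_vals <- numeric(0)
  non_vals <- numeric(0)
  n_spc <- integer(1000)
  for (s in seq_len(1000)) {
    a <- conjugation_alpha(100, seed = s)
    spc <- a$params$spc
    n_spc[s] <- length(spc)
    spc_vals <- c(spc_vals, a$entries[, spc][seq(1, 1500, by = 100)])
    non_vals <- c(non_vals, a$entries[, -spc][seq(1, 8500, by = 100)])
  }
  expect_true(all(n_spc == 15))
  expect_equal(mean(spc_vals), 0.5, tolerance = 0.01 / 0.5)
  expect_equal(mean(non_vals), 0.02, tolerance = 0.001 / 0.02)
})

test_that("transformation matrix fills transformable columns with ones", {
  a <- transformation_alpha(9, p_transformable = 0.25, seed = 4)
  tf <- a$params$transformable
  expect_gt(length(tf), 0)
  expect_true(all(a$entries[, tf] == 1))
  if (length(tf) < 9) expect_true(all(a$entries[, -tf] == 0))
  # p = 0 without the redraw guard gives the zero matrix
  z <- transformation_alpha(9, p_transformable = 0, ensure_nonempty = FALSE,
                            seed = 1)
  expect_true(all(z$entries == 0))
  expect_error(transformation_alpha(9, p_transformable = 0),
               class = "hgtflow_config_error")
})

test_that("transformable count is binomial with mean p * n", {
  counts <- vapply(seq_len(10000), function(s) {
    length(transformation_alpha(20, p_transformable = 0.01, seed = s,
                                ensure_nonempty = FALSE)$params$transformable)
  }, 0L)
  # binomial(20, 0.01): mean 0.2, SE of the mean over 1e4 draws ~ 0.0045
  expect_equal(mean(counts), 0.2, tolerance = 0.02 / 0.2)
})

test_that("ensure_nonempty guarantees at least one transformable species", {
  for (s in 1:50) {
    a <- transformation_alpha(100, seed = s)
    expect_gt(length(a$params$transformable), 0)
  }
})

test_that("linear module sizes sum to n with every module non-empty", {
  expect_equal(hgtflow:::linear_module_sizes(6, 2), c(2L, 4L))
  expect_equal(hgtflow:::linear_module_sizes(91, 13), 1:13)
  for (n in c(7, 13, 50, 100)) {
    for (m in c(1, 2, 5, min(13, n))) {
      sizes <- hgtflow:::linear_module_sizes(n, m)
      expect_equal(sum(sizes), n)
      expect_true(all(sizes >= 1))
    }
  }
})

test_that("phage-host networks are modular with nested phage sets", {
  net <- phage_host_network(100, n_modules = 13, seed = 21)
  expect_equal(sort(as.integer(table(net$module))),
               sort(hgtflow:::linear_module_sizes(100, 13)))
  sets <- phage_sets(net)
  for (m in seq_len(net$n_modules)) {
    members <- which(net$module == m)
    s <- length(members)
    # ranks are a permutation: one full generalist host, one specialist
    expect_setequal(net$n_phages[members], seq_len(s))
    # nestedness: any two phage sets in a module are contained one in the
    # other (brute-force containment check)
    for (i in members) for (j in members) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      expect_true(inter == length(sets[[i]]) || inter == length(sets[[j]]))
    }
  }
  # phages are module-local
  all_phages <- unlist(sets)
  mod_of_phage <- sub("\\.p\\d+$", "", all_phages)
  expect_equal(length(unique(paste(mod_of_phage, all_phages))),
               length(unique(all_phages)))
})

test_that("transduction compatibility equals shared-phage fractions", {
  net <- phage_host_network(12, n_modules = 3, seed = 5)
  a <- transduction_alpha(net)
  sets <- phage_sets(net)
  brute <- outer(seq_len(12), seq_len(12), Vectorize(function(d, r) {
    length(intersect(sets[[d]], sets[[r]])) / length(sets[[d]])
  }))
  expect_equal(unname(a$entries), brute)
  expect_true(all(diag(a$entries) == 1))
  # cross-module pairs are zero
  cross <- outer(net$module, net$module, "!=")
  expect_true(all(a$entries[cross] == 0))
  # reciprocity: alpha(d,r) * k_d == alpha(r,d) * k_r within a module
  k <- net$n_phages
  lhs <- a$entries * matrix(k, 12, 12)
  expect_equal(lhs, t(lhs), ignore_attr = TRUE)
})

test_that("vesicle matrix is the outer product of uniform efficiencies", {
  a <- vesicle_alpha(30, seed = 9)
  e <- a$params$donor_eff
  u <- a$params$recipient_eff
  expect_equal(a$entries, outer(e, u), ignore_attr = TRUE)
  expect_true(all(a$entries >= 0 & a$entries <= 1))
  # rank-1 multiplicative structure
  expect_equal(a$entries[2, 3] * a$entries[5, 7],
               a$entries[2, 7] * a$entries[5, 3])
  # participation < 1 zeroes whole donor rows and recipient columns
  b <- vesicle_alpha(20, seed = 9, participation = 0.5)
  out <- which(b$params$donor_eff == 0)
  expect_length(out, 10)
  expect_true(all(b$entries[out, ] == 0) && all(b$entries[, out] == 0))
})

test_that("mean vesicle compatibility approaches E[U]^2 = 0.25", {
  means <- vapply(seq_len(500), function(s) {
    mean(vesicle_alpha(50, seed = s)$entries)
  }, 0)
  expect_equal(mean(means), 0.25, tolerance = 0.01 / 0.25)
})

test_that("generators are reproducible from their seeds", {
  for (gen in list(function(s) conjugation_alpha(40, seed = s),
                   function(s) transformation_alpha(40, seed = s),
                   function(s) transduction_alpha(phage_host_network(40, 5, seed = s)),
                   function(s) vesicle_alpha(40, seed = s))) {
    expect_identical(gen(123)$entries, gen(123)$entries)
  }
  # and seeded generation does not disturb the caller's RNG stream
  set.seed(77)
  before <- runif(1)
  set.seed(77)
  invisible(conjugation_alpha(10, seed = 5))
  expect_identical(runif(1), before)
})

test_that("validate_alpha reports violations with locations", {
  good <- conjugation_alpha(10, seed = 1)
  expect_true(validate_alpha(good)$pass)
  bad <- matrix(runif(16), 4, 4)
  bad[2, 3] <- 1.5
  rep <- validate_alpha(bad)
  expect_false(rep$pass)
  expect_match(rep$violations, "\\[2, 3\\]", all = FALSE)
  # constructed cross-module leak in a transduction matrix
  net <- phage_host_network(10, 2, seed = 3)
  a <- transduction_alpha(net)
  cross <- which(outer(net$module, net$module, "!="), arr.ind = TRUE)[1, ]
  a$entries[cross[1], cross[2]] <- 0.5
  leak <- validate_alpha(a)
  expect_false(leak$pass)
  expect_match(leak$violations, "cross-module", all = FALSE)
})
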