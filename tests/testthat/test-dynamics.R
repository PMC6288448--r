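# Transfer and growth steps, trajectory recording, full-spread detection.

test_that("hgt_step moves mass from recipients to carriers and conserves totals", {
  st <- community_state(c(100, 0), c(9900, 10000))
  mech <- uniform_mechanisms(2, gamma = 1e-8)
  out <- hgt_step(st, mech, dt = 1)
  expect_equal(out$plasmid_pos + out$plasmid_neg,
               st$plasmid_pos + st$plasmid_neg)
  expect_true(all(out$plasmid_pos >= st$plasmid_pos))
  # expected Euler increment: dt * Bn_i * gamma * sum_j alpha(j,i) Bp_j
  expect_equal(out$plasmid_pos - st$plasmid_pos,
               1 * st$plasmid_neg * 1e-8 * sum(st$plasmid_pos))
  # no donors, no transfer
  none <- community_state(c(0, 0), c(1e4, 1e4))
  expect_equal(hgt_step(none, mech, 10)$plasmid_pos, c(0, 0))
})

test_that("hgt_step matches fine-grained integration over one coarse step", {
  st <- community_state(c(100, 50), c(9900, 9950))
  mech <- uniform_mechanisms(2, gamma = 1e-8)
  coarse <- hgt_step(st, mech, dt = 100)
  fine <- st
  for (i in 1:1000) fine <- hgt_step(fine, mech, dt = 0.1)
  expect_equal(coarse$plasmid_pos, fine$plasmid_pos, tolerance = 1e-3)
})

test_that("transfer is additive across enabled mechanisms", {
  st <- community_state(c(100, 0, 10), c(9900, 1e4, 9990))
  a1 <- matrix(runif(9, max = 0.5), 3, 3)
  a2 <- matrix(runif(9, max = 0.5), 3, 3)
  m1 <- mechanism_spec("conjugation", 1e-8, a1)
  m2 <- mechanism_spec("transduction", 1e-9, a2)
  both <- hgt_step(st, list(m1, m2), dt = 1)
  only1 <- hgt_step(st, list(m1), dt = 1)
  only2 <- hgt_step(st, list(m2), dt = 1)
  expect_equal(both$plasmid_pos - st$plasmid_pos,
               (only1$plasmid_pos - st$plasmid_pos) +
                 (only2$plasmid_pos - st$plasmid_pos))
  # disabled mechanisms contribute nothing
  m2off <- mechanism_spec("transduction", 1e-9, a2, enabled = FALSE)
  expect_equal(hgt_step(st, list(m1, m2off), dt = 1)$plasmid_pos,
               only1$plasmid_pos)
})

test_that("hgt_step caps the increment at the plasmid-free pool with a warning", {
  st <- community_state(c(1e4, 0), c(0.01, 1e4))
  mech <- uniform_mechanisms(2, gamma = 1e-4)
  expect_warning(out <- hgt_step(st, mech, dt = 100),
                 class = "hgtflow_cap_warning")
  expect_equal(out$plasmid_neg[1], 0)
  expect_equal(out$plasmid_pos[1] + out$plasmid_neg[1], 1e4 + 0.01)
})

test_that("hgt_step rejects dimension mismatches", {
  st <- community_state(c(1, 2, 3), c(4, 5, 6))
  expect_error(hgt_step(st, uniform_mechanisms(2), dt = 1),
               class = "hgtflow_invalid_input")
})

test_that("growth_step is the exact replicator map", {
  st <- community_state(c(5000, 0, 1e4), c(5000, 1e4, 0))
  m <- log(2)  # per minute, so m * dt = ln 2 at dt = 1
  out <- growth_step(st, m, dt = 1)
  f <- plasmid_fraction(out)
  expect_equal(f[1], 2 / 3)   # f = 1/2 doubles its odds
  expect_equal(f[2], 0)       # extinction is a fixed point
  expect_equal(f[3], 1)       # fixation is a fixed point
  # m = 0 is the identity
  expect_equal(growth_step(st, 0, 5)$plasmid_pos, st$plasmid_pos)
  # totals preserved exactly
  expect_equal(out$plasmid_pos + out$plasmid_neg,
               st$plasmid_pos + st$plasmid_neg)
  # group property: two half steps equal one full step
  two <- growth_step(growth_step(st, m, 0.5), m, 0.5)
  one <- growth_step(st, m, 1)
  expect_equal(two$plasmid_pos, one$plasmid_pos, tolerance = 1e-12)
})

test_that("with transfer off the trajectory follows the logistic closed form", {
  cfg <- small_config(n = 3, days = 200, n_steps = 1000,
                      initial_fraction = 1e-4, record_every = 10)
  mech <- list(mechanism_spec("conjugation", 0, matrix(1, 3, 3)))
  traj <- run_simulation(cfg, mech)
  m_min <- 0.02 / 1440
  expect_equal(traj$fractions[, 1],
               logistic_fraction(1e-4, m_min, traj$times),
               tolerance = 1e-9)
  # unseeded species never acquire the plasmid, so no full spread at N > 1
  expect_true(all(traj$fractions[, 2:3] == 0))
  expect_true(is.na(traj$full_spread_time))
})

test_that("per-species totals are conserved and fractions are monotone", {
  cfg <- small_config(n = 8, days = 60, n_steps = 10000)
  mechs <- draw_mechanism_set(8, 13)
  traj <- run_simulation(cfg, mechs)
  # fractions bounded and non-decreasing for every species
  expect_true(all(traj$fractions >= 0 & traj$fractions <= 1))
  expect_true(all(apply(traj$fractions, 2, function(x) all(diff(x) >= 0))))
  # conservation is structural: fractions are defined against fixed totals;
  # verify through the step functions over a long chain
  st <- community_state(rep(1, 8) * 500, rep(1, 8) * 9500)
  tot0 <- st$plasmid_pos + st$plasmid_neg
  for (i in 1:200) {
    st <- growth_step(hgt_step(st, mechs, dt = 10), 0.02 / 1440, 10)
  }
  expect_equal(st$plasmid_pos + st$plasmid_neg, tot0, tolerance = 1e-9)
})

test_that("trajectory is constant when all rates vanish", {
  cfg <- small_config(n = 2, days = 10, n_steps = 100, fitness = 0)
  mech <- list(mechanism_spec("conjugation", 0, matrix(1, 2, 2)))
  traj <- run_simulation(cfg, mech)
  expect_true(all(traj$fractions[, 1] == traj$fractions[1, 1]))
  expect_true(all(traj$fractions[, 2] == 0))
})

test_that("discrete stepper matches a continuous-time oracle on spread time", {
  n <- 2
  cfg <- small_config(n = n, days = 60, n_steps = 10000)
  mech <- uniform_mechanisms(n, gamma = 1e-8)
  traj <- run_simulation(cfg, mech)
  oracle <- continuous_oracle_spread_time(
    n, alpha = matrix(1, n, n), gamma = 1e-8, m_per_min = 0.02 / 1440,
    density = 1e4, f0 = 1e-4, horizon_min = as_minutes(60, "day"))
  expect_false(is.na(traj$full_spread_time))
  expect_equal(traj$full_spread_time, oracle, tolerance = 5e-3)
})

test_that("full_spread_time respects thresholds and recording resolution", {
  cfg <- small_config(n = 2, days = 60, n_steps = 5000)
  mech <- uniform_mechanisms(2, gamma = 1e-8)
  traj <- run_simulation(cfg, mech)
  t99 <- full_spread_time(traj, 0.99)
  t50 <- full_spread_time(traj, 0.5)
  expect_true(t50 < t99)               # monotone trajectories order thresholds
  expect_true(t99 %in% traj$times)     # detection at recorded times
  # threshold ~0 is satisfied from the first recorded time of full coverage
  expect_true(is.na(full_spread_time(traj, 1)) ||
                full_spread_time(traj, 1) >= t99)
  # a trajectory ending below threshold reports absence
  short <- run_simulation(small_config(n = 2, days = 1, n_steps = 100), mech)
  expect_true(is.na(short$full_spread_time))
})

test_that("simulations are bitwise reproducible from config plus matrices", {
  cfg <- small_config(n = 6, days = 40, n_steps = 3000)
  mechs <- draw_mechanism_set(6, 99)
  t1 <- run_simulation(cfg, mechs)
  t2 <- run_simulation(cfg, mechs)
  expect_identical(t1$fractions, t2$fractions)
  expect_identical(t1$full_spread_time, t2$full_spread_time)
  # and the matrix draw itself is seed-reproducible end to end
  t3 <- run_simulation(cfg, draw_mechanism_set(6, 99))
  expect_identical(t1$fractions, t3$fractions)
})

test_that("convergence check flags coarse timesteps and passes smooth runs", {
  cfg <- small_config(n = 2, days = 60, n_steps = 2500)
  mech <- uniform_mechanisms(2, gamma = 1e-8)
  rep <- convergence_check(cfg, mech, refinements = 2, tol = 0.01)
  expect_length(rep$full_spread_time_min, 3)
  expect_true(rep$converged)
  # changes stay small under refinement (full-spread detection happens at
  # recording resolution, so quantization keeps them from shrinking exactly
  # linearly)
  expect_true(all(rep$rel_change < 0.01))
  # a deliberately coarse, fast scenario trips the cap and is flagged
  fast <- small_config(n = 2, days = 60, n_steps = 2, fitness = 0)
  hot <- uniform_mechanisms(2, gamma = 1e-5)
  out <- convergence_check(fast, hot, refinements = 1)
  expect_false(out$converged)
  expect_true(any(out$cap_events > 0))
})

test_that("simulation rejects an enabled mechanism without a matching matrix", {
  cfg <- small_config(n = 4)
  expect_error(run_simulation(cfg, uniform_mechanisms(3)),
               class = "hgtflow_config_error")
})
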