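test_that("Bell rate and detachment-time draws follow their closed forms", {
  b <- head_bond()
  expect_equal(dissociation_rate(b, 0), 0.0027)
  ## hand-evaluated: 0.0027 * exp(1.23 * 20 / 4.114)
  expect_equal(dissociation_rate(b, 20), 0.0027 * exp(24.6 / 4.114),
               tolerance = 1e-12)
  expect_equal(dissociation_rate(b, 20), 1.067, tolerance = 1e-3)
  expect_equal(dissociation_rate(strong_bond(), 70),
               2.7e-5 * exp(56 / 4.114), tolerance = 1e-12)
  expect_equal(dissociation_rate(strong_bond(), 70), 22.05, tolerance = 1e-3)
  f <- seq(0, 60, by = 5)
  expect_true(all(diff(dissociation_rate(b, f)) > 0))
  expect_warning(dissociation_rate(bond_model(1, 100), 1e4), "capped")

  expect_equal(detachment_time(5, 0), 0)
  expect_equal(detachment_time(1, 1 - exp(-1)), 1, tolerance = 1e-12)
  expect_error(detachment_time(0, 0.5), ">")
  expect_error(detachment_time(1, 1), "\\[0, 1\\)")
  expect_error(detachment_time(1, -0.1), "\\[0, 1\\)")
  ## exponential oracle: mean of many draws is 1/rate
  set.seed(1)
  r <- runif(1e5)
  t <- detachment_time(2, r)
  expect_lt(abs(mean(t) - 0.5), 3 * 0.5 / sqrt(1e5))
})

test_that("rupture simulation is bit-for-bit reproducible given a seed", {
  wlc <- lambda_wlc()
  a <- simulate_rupture_distribution(exp_protocol(seed = 5), head_bond(), wlc, 200)
  b <- simulate_rupture_distribution(exp_protocol(seed = 5), head_bond(), wlc, 200)
  expect_identical(a$forces, b$forces)
  expect_identical(a$events, b$events)
  c <- simulate_rupture_distribution(exp_protocol(seed = 6), head_bond(), wlc, 200)
  expect_false(identical(a$forces, c$forces))
})

test_that("an extremely weak bond ruptures immediately at near-zero force", {
  ev <- simulate_single_pull(exp_protocol(seed = 1), bond_model(1000, 1.23),
                             lambda_wlc())
  expect_false(ev$censored)
  expect_equal(ev$rupture_time_s, 0.01)
  expect_lt(ev$rupture_force_pN, 0.01)
  expect_gt(ev$rupture_time_s, 0)
})

test_that("with delta = 0 rupture times follow the zero-force exponential", {
  ## force-independent limit: a homogeneous process at rate k0, discretised
  ## to the time grid; mean time is 1/k0 + dt/2 up to O(k0 dt^2).  k0 is
  ## fast enough that no pull reaches the extensibility limit, so the
  ## sample is a complete (uncensored) exponential draw.
  k0 <- 0.5
  dt <- 0.01
  s <- quiet(simulate_rupture_distribution(exp_protocol(seed = 3, dt_s = dt),
                                           bond_model(k0, 0), lambda_wlc(),
                                           1e4))
  expect_equal(s$censored, 0L)
  times <- s$events$time_s[s$events$censored == 0]
  se <- (1 / k0) / sqrt(length(times))
  expect_lt(abs(mean(times) - (1 / k0 + dt / 2)), 3 * se)
  ## exponential shape: sd of an exponential equals its mean
  expect_lt(abs(sd(times) / mean(times) - 1), 0.05)
})

test_that("pulls that never rupture are censored, counted and excluded", {
  ## essentially unbreakable bond: every pull reaches the extensibility limit
  expect_message(
    s <- simulate_rupture_distribution(exp_protocol(seed = 2),
                                       bond_model(1e-12, 0), lambda_wlc(), 5),
    "censored"
  )
  expect_equal(s$censored, 5L)
  expect_equal(s$n, 0L)
  expect_equal(sum(s$events$censored), 5L)
  expect_true(all(is.na(s$events$force_pN)))
})

test_that("rupture forces fall with k0, with delta, and rise with velocity", {
  wlc <- lambda_wlc()
  n <- 1500
  mean_at <- function(k0, delta, v = 0.16) {
    quiet(simulate_rupture_distribution(
      pulling_protocol(velocity_um_per_s = v, seed = 9),
      bond_model(k0, delta), wlc, n
    ))$mean
  }
  expect_gt(mean_at(0.0005, 1.23), mean_at(0.0027, 1.23))
  expect_gt(mean_at(0.0027, 1.23), mean_at(0.015, 1.23))
  expect_gt(mean_at(0.0027, 0.9), mean_at(0.0027, 1.23))
  expect_gt(mean_at(0.0027, 1.23), mean_at(0.0027, 1.7))
  expect_gt(mean_at(0.0027, 1.23, v = 0.8), mean_at(0.0027, 1.23, v = 0.16))
})

test_that("two-DNA pulls record per-event orientation and rupture lower than direct pulls", {
  wlc <- lambda_wlc()
  two <- quiet(simulate_two_dna_pull(exp_protocol(seed = 21), 2e-3,
                                     delta_nm = c(1.23, 1.61),
                                     wlc1 = plasmid_wlc(), wlc2 = wlc,
                                     n = 1500))
  expect_setequal(unique(two$events$delta_nm), c(1.23, 1.61))
  ## both orientations drawn with roughly equal frequency
  expect_gt(mean(two$events$delta_nm == 1.23), 0.4)
  expect_lt(mean(two$events$delta_nm == 1.23), 0.6)

  ## matched single-DNA mixture at the same k0 and deltas
  s1 <- quiet(simulate_rupture_distribution(exp_protocol(seed = 22),
                                            bond_model(2e-3, 1.23), wlc, 750))
  s2 <- quiet(simulate_rupture_distribution(exp_protocol(seed = 23),
                                            bond_model(2e-3, 1.61), wlc, 750))
  expect_lt(two$mean, mean(c(s1$forces, s2$forces)))
})

test_that("two-DNA simulation degenerates to the single-DNA law as chain 1 vanishes", {
  wlc <- lambda_wlc()
  two <- quiet(simulate_two_dna_pull(exp_protocol(seed = 31), 0.0027,
                                     delta_nm = 1.23, prob = 1,
                                     wlc1 = wlc_params(50, 1), wlc2 = wlc,
                                     n = 2000))
  one <- quiet(simulate_rupture_distribution(exp_protocol(seed = 32),
                                             head_bond(), wlc, 2000))
  ks <- ks_two_sample(two, one)
  expect_gt(ks$p_value, 0.01)
})

test_that("constant-ramp mode matches the Bell-Evans most probable force", {
  b <- head_bond()
  kBT <- 4.114
  for (fdot in c(0.5, 2)) {
    s <- simulate_constant_ramp(b, fdot, n = 8000, dt_s = 0.005, seed = 17)
    f_star <- (kBT / b$delta_nm) *
      log(b$delta_nm * fdot / (b$k0_per_s * kBT))
    dens <- density(s$forces)
    mode_hat <- dens$x[which.max(dens$y)]
    expect_lt(abs(mode_hat - f_star) / f_star, 0.05)
  }
})
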