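test_that("scenario generation is reproducible and validates its inputs", {
  a <- generate_scenario("head", n_events = 60, seed = 12)
  b <- generate_scenario("head", n_events = 60, seed = 12)
  expect_identical(a$forces, b$forces)
  expect_identical(a$events, b$events)
  expect_equal(a$n + a$censored, 60L)
  expect_error(generate_scenario("nope"), "head")

  ## default event counts mirror the experimental samples
  expect_equal(generate_scenario("hinge", seed = 1)$metadata$n_events, 21L)
  expect_setequal(scenario_names(),
                  c("head", "hinge", "head_crosslinked",
                    "hinge_crosslinked_mixture", "two_dna"))
})

test_that("sidecar provenance regenerates the identical sample", {
  dir <- withr::local_tempdir()
  smp <- generate_scenario("head", n_events = 40, seed = 31, dir = dir)
  expect_true(file.exists(file.path(dir, "head.csv")))
  meta <- jsonlite::read_json(file.path(dir, "head.json"),
                              simplifyVector = TRUE)
  regen <- generate_scenario(meta$scenario, n_events = meta$n_events,
                             seed = meta$seed)
  expect_identical(regen$forces, smp$forces)
  roundtrip <- read_rupture_csv(file.path(dir, "head.csv"))
  expect_equal(roundtrip$forces, smp$forces, tolerance = 1e-12)
})

test_that("the crosslinked-hinge mixture is bimodal around 20 and 70 pN", {
  smp <- generate_scenario("hinge_crosslinked_mixture", n_events = 4000,
                           seed = 5)
  h <- hist(smp$forces, breaks = seq(0, 100, by = 2), plot = FALSE)
  low <- h$mids < 40
  mode_low <- h$mids[low][which.max(h$counts[low])]
  mode_high <- h$mids[!low][which.max(h$counts[!low])]
  expect_gt(mode_low, 14)
  expect_lt(mode_low, 30)
  expect_gt(mode_high, 60)
  expect_lt(mode_high, 78)
  ## roughly half the events in each subpopulation
  expect_gt(mean(smp$forces < 40), 0.45)
  expect_lt(mean(smp$forces < 40), 0.55)
  ## per-event bond parameters recorded for the two subpopulations
  expect_setequal(unique(smp$events$delta_nm), c(1.23, 0.8))
})

test_that("optional measurement noise perturbs forces without changing the count", {
  clean <- generate_scenario("head", n_events = 50, seed = 8)
  noisy <- generate_scenario("head", n_events = 50, seed = 8, noise_sd_pN = 2)
  expect_equal(noisy$n, clean$n)
  expect_false(identical(noisy$forces, clean$forces))
  expect_lt(abs(mean(noisy$forces) - mean(clean$forces)), 1.5)
  expect_true(all(noisy$forces >= 0))
})

test_that("force-distance traces agree with the event simulator and the geometry", {
  proto <- exp_protocol()
  trace <- generate_fd_trace(proto, head_bond(), lambda_wlc(), seed = 91)
  expect_true(all(trace$force_pN >= 0))
  expect_true(all(diff(trace$displacement_um) > 0))
  ## rupture row keeps the peak force; later rows read zero
  i_rupt <- which(trace$ruptured == 1L)[1]
  expect_false(is.na(i_rupt))
  expect_true(all(trace$force_pN[seq(i_rupt + 1L, nrow(trace))] == 0))

  ## same seed, same draw order: the trace ends at the simulator's event
  pr <- proto
  pr$seed <- 91L
  ev <- simulate_single_pull(pr, head_bond(), lambda_wlc())
  expect_equal(trace$force_pN[i_rupt], ev$rupture_force_pN, tolerance = 1e-12)
  expect_equal(trace$time_s[i_rupt], ev$rupture_time_s, tolerance = 1e-12)

  ## pre-rupture forces reproduce the tether geometry exactly
  idx <- seq_len(i_rupt)
  f_geom <- vapply(trace$displacement_um[idx], function(x) {
    tether_geometry(ev$anchor_distance_um, x, lambda_wlc())$F_cohesin_pN
  }, numeric(1))
  expect_equal(trace$force_pN[idx], f_geom, tolerance = 1e-12)
})

test_that("occupancy generator matches its Poisson/uniform law", {
  empty <- generate_occupancy(50, 0, seed = 2)
  expect_true(all(lengths(empty$positions) == 0))

  occ <- generate_occupancy(10000, mean_cohesins = 1.5, seed = 3)
  counts <- lengths(occ$positions)
  se <- sqrt(1.5 / 10000)
  expect_lt(abs(mean(counts) - 1.5), 3 * se)
  pos <- unlist(occ$positions)
  expect_gte(min(pos), 0)
  expect_lte(max(pos), 16.32)
  expect_identical(generate_occupancy(20, 1, seed = 9)$positions,
                   generate_occupancy(20, 1, seed = 9)$positions)
})
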