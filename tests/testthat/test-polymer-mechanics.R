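test_that("wlc_force reproduces the Marko-Siggia interpolation", {
  wlc <- lambda_wlc()
  expect_equal(wlc_force(wlc, 0), 0)
  ## half extension: interpolation factor 1/(4 * 0.25) - 1/4 + 1/2 = 1.25
  expect_equal(wlc_force(wlc, 8160), 4.114 / 50 * 1.25, tolerance = 1e-12)
  ## agrees with an independently written evaluation across extensions
  L <- seq(0, 16000, by = 500)
  expect_equal(wlc_force(wlc, L), ms_force(L, 50, 16320), tolerance = 1e-12)
})

test_that("wlc_force rejects overstretched and negative extensions", {
  wlc <- lambda_wlc()
  expect_error(wlc_force(wlc, 16320), "overstretched")
  expect_error(wlc_force(wlc, 16320 * (1 - 1e-9)), "overstretched")
  expect_error(wlc_force(wlc, -1), "non-negative")
})

test_that("wlc_force is strictly increasing and linear in thermal energy", {
  set.seed(42)
  for (i in 1:20) {
    P <- runif(1, 5, 100)
    L0 <- runif(1, 1000, 50000)
    wlc <- wlc_params(P, L0)
    L <- seq(0, 0.999 * L0, length.out = 200)
    f <- wlc_force(wlc, L)
    expect_true(all(diff(f) > 0))
    kBT2 <- 2 * 4.114
    expect_equal(wlc_force(wlc, L, kBT = kBT2), 2 * f, tolerance = 1e-12)
  }
})

test_that("tether geometry satisfies the V-geometry relations", {
  wlc <- lambda_wlc()
  ## slack symmetric case
  g0 <- tether_geometry(8.8, 0, wlc)
  expect_equal(g0$alpha, 0)
  expect_equal(g0$L_dna_um, 8.8)
  expect_equal(g0$F_cohesin_pN, 0)

  ## hand-computed configuration: D = 8.8 um, x = 4 um
  g <- tether_geometry(8.8, 4.0, wlc)
  L_exp <- 2 * sqrt(4.4^2 + 4^2)              # 11.8929... um
  sin_exp <- (2 * 4) / sqrt(8.8^2 + 4 * 16)   # sin(atan(2x/D))
  F_dna_exp <- ms_force(L_exp * 1000, 50, 16320)
  expect_equal(g$L_dna_um, L_exp, tolerance = 1e-10)
  expect_equal(sin(g$alpha), sin_exp, tolerance = 1e-10)
  expect_equal(g$F_dna_pN, F_dna_exp, tolerance = 1e-10)
  expect_equal(g$F_cohesin_pN, 2 * F_dna_exp * sin_exp, tolerance = 1e-10)
  ## frozen magnitudes of the same configuration
  expect_equal(g$L_dna_um, 11.893, tolerance = 1e-4)
  expect_equal(g$F_dna_pN, 0.319, tolerance = 2e-3)
  expect_equal(g$F_cohesin_pN, 0.429, tolerance = 2e-3)

  ## mirror symmetry in x, and the ring force vanishes only at x = 0
  gm <- tether_geometry(8.8, -4.0, wlc)
  expect_equal(gm$F_cohesin_pN, g$F_cohesin_pN)
  expect_gt(tether_geometry(8.8, 1e-6, wlc)$F_cohesin_pN, 0)
})

test_that("ring force increases strictly with displacement", {
  wlc <- lambda_wlc()
  for (D in c(5, 8.8, 12)) {
    ## displacement grid kept inside the inextensibility limit for this D
    x_lim <- 0.95 * sqrt((16.32 / 2 * 0.999)^2 - (D / 2)^2)
    x <- seq(0, x_lim, length.out = 80)
    f <- vapply(x, function(xi) tether_geometry(D, xi, wlc)$F_cohesin_pN,
                numeric(1))
    expect_true(all(diff(f) > 0))
  }
  expect_error(tether_geometry(8.8, 8.0, wlc), "contour")
})

test_that("two-DNA solver satisfies all five relations to tolerance", {
  wlc1 <- plasmid_wlc()
  wlc2 <- lambda_wlc()
  for (x in c(0.5, 2, 5, 7.5, 8.2)) {
    st <- solve_two_dna(8.8, x, wlc1, wlc2, tol = 1e-8)
    res <- two_dna_residuals(st, 8.8, wlc1, wlc2)
    expect_lt(max(abs(res)), 1e-8)
    expect_gte(st$F1_pN, 0)
    expect_gte(st$F2_pN, 0)
    expect_lt(st$L1_um, 2.448)
    expect_lt(st$L2_um, 16.32)
  }
})

test_that("two-DNA solution is continuous in displacement and handles x = 0", {
  wlc <- lambda_wlc()
  st0 <- solve_two_dna(8.8, 0, wlc, wlc)
  expect_equal(st0$F1_pN, 0)
  expect_equal(st0$L1_um, 0)
  expect_equal(st0$alpha, 0)
  x <- seq(0.1, 7, length.out = 60)
  f1 <- vapply(x, function(xi) solve_two_dna(8.8, xi, wlc, wlc)$F1_pN,
               numeric(1))
  expect_true(all(diff(f1) > 0))
  expect_lt(max(abs(diff(f1))), 0.75) # no jumps on a 0.12 um grid
})

test_that("two-DNA system degenerates to the single tether as chain 1 vanishes", {
  wlc2 <- lambda_wlc()
  tiny <- wlc_params(50, 1) # 1 nm contour: chain 1 is effectively a point
  for (x in c(2, 4, 6)) {
    st <- solve_two_dna(8.8, x, tiny, wlc2)
    single <- tether_geometry(8.8, x, wlc2)
    expect_equal(st$F1_pN, single$F_cohesin_pN,
                 tolerance = 0.01)
  }
})

test_that("two-DNA solver reports unphysical displacements as domain errors", {
  wlc <- lambda_wlc()
  ## x so large that both chains would need to exceed their contours
  expect_error(solve_two_dna(8.8, 30, wlc, wlc), class = "ringpull_domain_error")
})

test_that("compiled two-DNA path agrees with the R-level solver", {
  wlc1 <- plasmid_wlc()
  wlc2 <- lambda_wlc()
  x_um <- seq(0.5, 8.5, by = 0.5)
  f_cpp <- ringpull:::two_dna_force_cpp(x_um * 1000, 8800, 50, 2448, 50,
                                        16320, 4.114)
  f_r <- vapply(x_um, function(xi) solve_two_dna(8.8, xi, wlc1, wlc2)$F1_pN,
                numeric(1))
  expect_equal(f_cpp, f_r, tolerance = 1e-7)
})
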