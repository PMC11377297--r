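## Monte-Carlo rupture simulation: R wrappers around the compiled engines.
##
## Scheme per event: draw the anchor separation D once, then advance the
## perpendicular displacement x by velocity * dt each step, evaluate the
## tether geometry and WLC tension, the Bell rate k(F), draw a uniform r
## and the candidate detachment time t = -ln(1 - r)/k; the ring disengages
## at the first step with t <= dt, and the force at that step is recorded.
## Events that reach the chain extensibility limit without rupturing are
## censored: excluded from the force vector, counted in `censored`.

mc_metadata <- function(protocol, extra = list()) {
  c(list(protocol = unclass(protocol),
         package_version = as.character(utils::packageVersion("ringpull"))),
    extra)
}

#' Simulate one constant-velocity pulling event
#'
#' Runs a single pull of the single-DNA geometry to rupture (or censoring)
#' and returns the event record.  Uses the protocol's seed if set.
#'
#' @param protocol a [pulling_protocol()].
#' @param bond a [bond_model()].
#' @param wlc a [wlc_params()] for the tether.
#' @return a list of class `rupture_event`: `rupture_force_pN`,
#'   `rupture_time_s`, `displacement_at_rupture_um`, `anchor_distance_um`,
#'   `censored`.
#' @examples
#' simulate_single_pull(pulling_protocol(seed = 1), bond_model(0.0027, 1.23),
#'                      wlc_params())
#' @export
simulate_single_pull <- function(protocol, bond, wlc) {
  protocol <- as_protocol(protocol)
  bond <- as_bond(bond)
  wlc <- as_wlc(wlc)
  res <- with_seed(protocol$seed, mc_single_cpp(
    1L, bond$k0_per_s, bond$delta_nm, wlc$persistence_nm, wlc$contour_nm,
    protocol$kBT_pN_nm, um_to_nm(protocol$velocity_um_per_s), protocol$dt_s,
    um_to_nm(protocol$anchor_mean_um), um_to_nm(protocol$anchor_sd_um),
    um_to_nm(protocol$x0_um)
  ))
  structure(
    list(
      rupture_force_pN = res$force_pN[1],
      rupture_time_s = res$time_s[1],
      displacement_at_rupture_um = nm_to_um(res$x_nm[1]),
      anchor_distance_um = nm_to_um(res$D_nm[1]),
      censored = res$censored[1] == 1L
    ),
    class = "rupture_event"
  )
}

#' @export
print.rupture_event <- function(x, ...) {
  if (x$censored) {
    cat(sprintf(
      "<rupture_event> censored at the extensibility limit after %.4g s (D = %.3g um)\n",
      x$rupture_time_s, x$anchor_distance_um
    ))
  } else {
    cat(sprintf(
      "<rupture_event> %.4g pN at t = %.4g s (x = %.4g um, D = %.3g um)\n",
      x$rupture_force_pN, x$rupture_time_s, x$displacement_at_rupture_um,
      x$anchor_distance_um
    ))
  }
  invisible(x)
}

#' Simulate a rupture-force distribution (single-DNA geometry)
#'
#' Repeats the single-pull Monte Carlo `n` times under a seeded stream and
#' collects the rupture forces.
#'
#' @inheritParams simulate_single_pull
#' @param n number of pulling events (>= 1).
#' @return a [rupture_sample()]; censored events are excluded from the
#'   forces and counted in `$censored` (a message reports them).
#' @examples
#' simulate_rupture_distribution(pulling_protocol(seed = 1),
#'                               bond_model(0.0027, 1.23), wlc_params(),
#'                               n = 100)
#' @export
simulate_rupture_distribution <- function(protocol, bond, wlc, n) {
  protocol <- as_protocol(protocol)
  bond <- as_bond(bond)
  wlc <- as_wlc(wlc)
  n <- as.integer(n)
  stopifnot(n >= 1L)
  res <- with_seed(protocol$seed, mc_single_cpp(
    n, bond$k0_per_s, bond$delta_nm, wlc$persistence_nm, wlc$contour_nm,
    protocol$kBT_pN_nm, um_to_nm(protocol$velocity_um_per_s), protocol$dt_s,
    um_to_nm(protocol$anchor_mean_um), um_to_nm(protocol$anchor_sd_um),
    um_to_nm(protocol$x0_um)
  ))
  keep <- res$censored == 0L
  n_cens <- sum(!keep)
  if (n_cens > 0) {
    message(sprintf("%d of %d events censored at the WLC extensibility limit",
                    n_cens, n))
  }
  ev <- events_frame(res$force_pN, res$time_s, nm_to_um(res$D_nm),
                     rep(bond$delta_nm, n), res$censored)
  rupture_sample(
    res$force_pN[keep], events = ev, censored = n_cens,
    metadata = mc_metadata(protocol, list(bond = unclass(bond),
                                          wlc = unclass(wlc), n = n,
                                          geometry = "single_dna"))
  )
}

#' Simulate rupture forces in the two-DNA capture geometry
#'
#' The ring links a straight bead-proximal chain (DNA-1) to the middle of
#' a surface-tethered chain (DNA-2); at every time step the coupled
#' nonlinear system (see [solve_two_dna()]) is solved for the tensions and
#' the Bell rate is evaluated at the tension transmitted through the ring
#' (`F1`, which is also what the trap measures and what is recorded at
#' rupture).  The ring's orientation is randomized per event by drawing
#' `delta` from `delta_nm` with probabilities `prob`.
#'
#' @inheritParams simulate_rupture_distribution
#' @param k0_per_s zero-force disengagement rate in 1/s.
#' @param delta_nm vector of candidate mechanical displacements in nm.
#' @param prob mixture probabilities (same length, sums to 1); default
#'   equiprobable.
#' @param wlc1,wlc2 [wlc_params()] for DNA-1 (straight) and DNA-2 (V).
#' @return a [rupture_sample()] whose `events` record the per-event delta.
#' @examples
#' simulate_two_dna_pull(pulling_protocol(seed = 1), 2e-3,
#'                       delta_nm = c(1.23, 1.61), wlc1 = wlc_params(),
#'                       wlc2 = wlc_params(), n = 20)
#' @export
simulate_two_dna_pull <- function(protocol, k0_per_s, delta_nm,
                                  prob = NULL, wlc1, wlc2, n) {
  protocol <- as_protocol(protocol)
  wlc1 <- as_wlc(wlc1)
  wlc2 <- as_wlc(wlc2)
  check_number(k0_per_s, "k0_per_s", lower = 0, strict_lower = TRUE)
  if (!is.numeric(delta_nm) || length(delta_nm) < 1 || any(delta_nm < 0)) {
    stop("`delta_nm` must be non-negative numeric", call. = FALSE)
  }
  if (is.null(prob)) prob <- rep(1 / length(delta_nm), length(delta_nm))
  if (length(prob) != length(delta_nm) || any(prob < 0) ||
      abs(sum(prob) - 1) > 1e-8) {
    stop("`prob` must match `delta_nm` and sum to 1", call. = FALSE)
  }
  n <- as.integer(n)
  stopifnot(n >= 1L)
  res <- with_seed(protocol$seed, mc_two_cpp(
    n, k0_per_s, delta_nm, cumsum(prob),
    wlc1$persistence_nm, wlc1$contour_nm,
    wlc2$persistence_nm, wlc2$contour_nm,
    protocol$kBT_pN_nm, um_to_nm(protocol$velocity_um_per_s), protocol$dt_s,
    um_to_nm(protocol$anchor_mean_um), um_to_nm(protocol$anchor_sd_um),
    um_to_nm(protocol$x0_um)
  ))
  keep <- res$censored == 0L
  n_cens <- sum(!keep)
  if (n_cens > 0) {
    message(sprintf("%d of %d events censored at the WLC extensibility limit",
                    n_cens, n))
  }
  ev <- events_frame(res$force_pN, res$time_s, nm_to_um(res$D_nm),
                     res$delta_nm, res$censored)
  rupture_sample(
    res$force_pN[keep], events = ev, censored = n_cens,
    metadata = mc_metadata(protocol, list(
      k0_per_s = k0_per_s, delta_nm = delta_nm, prob = prob,
      wlc1 = unclass(wlc1), wlc2 = unclass(wlc2), n = n,
      geometry = "two_dna"
    ))
  )
}

## moments-only fast path for the fitter: same engine and event law as
## simulate_rupture_distribution, without building the per-event frame
sim_moments <- function(protocol, bond, wlc, n, seed) {
  res <- with_seed(seed, mc_single_cpp(
    as.integer(n), bond$k0_per_s, bond$delta_nm, wlc$persistence_nm,
    wlc$contour_nm, protocol$kBT_pN_nm, um_to_nm(protocol$velocity_um_per_s),
    protocol$dt_s, um_to_nm(protocol$anchor_mean_um),
    um_to_nm(protocol$anchor_sd_um), um_to_nm(protocol$x0_um)
  ))
  f <- res$force_pN[res$censored == 0L]
  c(mean = mean(f), sd = stats::sd(f), n = length(f))
}

#' Simulate rupture under a linear force ramp (no tether geometry)
#'
#' Diagnostic mode in which the force grows linearly in time,
#' `F(t) = ramp * t`, bypassing the WLC geometry.  In this mode the most
#' probable rupture force has the Bell-Evans closed form
#' \eqn{F^* = (k_B T/\delta)\,\ln(\delta \dot F / (k_0 k_B T))}, which
#' provides an independent oracle for the engine's rupture kinetics.
#'
#' @param bond a [bond_model()] with `delta > 0`.
#' @param ramp_pN_per_s force loading rate in pN/s (> 0).
#' @param n number of events.
#' @param dt_s time step in s.
#' @param kBT thermal energy in pN nm.
#' @param seed optional integer seed.
#' @param fmax_pN safety cap on the ramp (events reaching it are censored).
#' @return a [rupture_sample()].
#' @export
simulate_constant_ramp <- function(bond, ramp_pN_per_s, n, dt_s = 0.01,
                                   kBT = DEFAULT_KBT, seed = NULL,
                                   fmax_pN = 500) {
  bond <- as_bond(bond)
  check_number(ramp_pN_per_s, "ramp_pN_per_s", lower = 0, strict_lower = TRUE)
  check_number(dt_s, "dt_s", lower = 0, strict_lower = TRUE)
  n <- as.integer(n)
  stopifnot(n >= 1L)
  f <- with_seed(seed, mc_ramp_cpp(n, bond$k0_per_s, bond$delta_nm, kBT,
                                   ramp_pN_per_s, dt_s, fmax_pN))
  keep <- !is.na(f)
  rupture_sample(
    f[keep], censored = sum(!keep),
    metadata = list(bond = unclass(bond), ramp_pN_per_s = ramp_pN_per_s,
                    dt_s = dt_s, kBT = kBT, n = n, geometry = "constant_ramp")
  )
}
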