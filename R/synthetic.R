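## Synthetic-data generators standing in for the study's unreleased raw
## data.  Each generator is a pure function of its arguments and seed and
## records full provenance, so every downstream module is testable with no
## download.

## fitted parameter pairs and experimental sample sizes per scenario
SCENARIOS <- list(
  head = list(
    bonds = list(c(k0 = 0.0027, delta = 1.23)), weights = 1, n_default = 89
  ),
  hinge = list(
    bonds = list(c(k0 = 0.0025, delta = 1.61)), weights = 1, n_default = 21
  ),
  head_crosslinked = list(
    bonds = list(c(k0 = 0.0022, delta = 1.22)), weights = 1, n_default = 24
  ),
  ## roughly half the loaded rings fail to crosslink at the hinge and
  ## rupture like wild type (~20 pN); the crosslinked half ruptures at the
  ## second-weakest interface (~70 pN)
  hinge_crosslinked_mixture = list(
    bonds = list(c(k0 = 0.0021, delta = 1.23), c(k0 = 2.7e-5, delta = 0.8)),
    weights = c(0.5, 0.5), n_default = 25
  ),
  two_dna = list(
    k0 = 2e-3, delta = c(1.23, 1.61), prob = c(0.5, 0.5), n_default = 41
  )
)

#' Scenario names for the synthetic-data generator
#' @return character vector of valid scenario names.
#' @export
scenario_names <- function() names(SCENARIOS)

#' Generate a synthetic rupture-force scenario
#'
#' Produces a rupture-force sample for one of the named experimental
#' scenarios at its fitted parameters: `head`, `hinge`,
#' `head_crosslinked` (single-population pulls at the head/hinge, and at
#' the head with the Smc3-kleisin interface crosslinked),
#' `hinge_crosslinked_mixture` (50/50 mixture of ~20 pN and ~70 pN
#' subpopulations) and `two_dna` (force applied through a second captured
#' DNA; bead-proximal chain defaults to the 7.2 kb plasmid contour).
#' Default event counts mirror the experimental sample sizes.
#'
#' @param scenario scenario name (see [scenario_names()]).
#' @param n_events number of pulling events; `NULL` for the scenario's
#'   experimental default.
#' @param seed integer seed.
#' @param protocol a [pulling_protocol()]; its seed field is overridden by
#'   `seed`.
#' @param wlc [wlc_params()] of the pulled lambda-DNA tether.
#' @param wlc1_two_dna [wlc_params()] of the bead-proximal chain in the
#'   `two_dna` scenario (default: 7.2 kb plasmid, contour 2448 nm).
#' @param noise_sd_pN optional Gaussian measurement noise added to the
#'   recorded forces (default 0: the generative model has none; nonzero
#'   values support robustness tests of the fitter), truncated at zero.
#' @param dir optional directory; when given, writes `<scenario>.csv` (the
#'   package CSV dialect) and a JSON sidecar `<scenario>.json` recording
#'   all parameters and the seed.
#' @return a [rupture_sample()] whose `metadata` holds the provenance.
#' @examples
#' generate_scenario("head", n_events = 50, seed = 1)
#' @export
generate_scenario <- function(scenario, n_events = NULL, seed = 1,
                              protocol = pulling_protocol(),
                              wlc = wlc_params(),
                              wlc1_two_dna = wlc_params(50, 2448),
                              noise_sd_pN = 0, dir = NULL) {
  if (!is.character(scenario) || length(scenario) != 1 ||
      !scenario %in% names(SCENARIOS)) {
    stop(sprintf("unknown scenario %s; valid scenarios: %s",
                 deparse(substitute(scenario)),
                 paste(names(SCENARIOS), collapse = ", ")), call. = FALSE)
  }
  spec <- SCENARIOS[[scenario]]
  n <- if (is.null(n_events)) spec$n_default else as.integer(n_events)
  stopifnot(n >= 1L)
  proto <- as_protocol(protocol)
  proto$seed <- as.integer(seed)

  if (scenario == "two_dna") {
    smp <- suppressMessages(simulate_two_dna_pull(
      proto, spec$k0, spec$delta, spec$prob, wlc1 = wlc1_two_dna, wlc2 = wlc,
      n = n
    ))
  } else if (length(spec$bonds) == 1L) {
    b <- spec$bonds[[1]]
    smp <- suppressMessages(simulate_rupture_distribution(
      proto, bond_model(b[["k0"]], b[["delta"]]), wlc, n
    ))
  } else {
    ## mixture: draw each event's bond pair, then simulate per component
    smp <- with_seed(seed, {
      comp <- sample.int(length(spec$bonds), n, replace = TRUE,
                         prob = spec$weights)
      parts <- lapply(seq_along(spec$bonds), function(j) {
        nj <- sum(comp == j)
        if (nj == 0L) return(NULL)
        b <- spec$bonds[[j]]
        pj <- proto
        pj$seed <- NULL # events continue the stream seeded above
        suppressMessages(simulate_rupture_distribution(
          pj, bond_model(b[["k0"]], b[["delta"]]), wlc, nj
        ))
      })
      keep <- !vapply(parts, is.null, logical(1))
      parts <- parts[keep]
      ev <- do.call(rbind, lapply(parts, function(p) p$events))
      ev$event_id <- seq_len(nrow(ev))
      rupture_sample(
        unlist(lapply(parts, function(p) p$forces)),
        events = ev, censored = sum(vapply(parts, function(p) p$censored,
                                           integer(1)))
      )
    })
  }

  if (noise_sd_pN > 0) {
    noisy <- with_seed(seed + 10000L,
                       pmax(0, smp$forces + rnorm(smp$n, 0, noise_sd_pN)))
    ev <- smp$events
    if (!is.null(ev)) ev$force_pN[ev$censored == 0L] <- noisy
    smp <- rupture_sample(noisy, events = ev, censored = smp$censored)
  }

  smp$metadata <- list(
    scenario = scenario, n_events = n, seed = as.integer(seed),
    parameters = spec, protocol = unclass(proto), wlc = unclass(wlc),
    wlc1_two_dna = if (scenario == "two_dna") unclass(wlc1_two_dna),
    noise_sd_pN = noise_sd_pN,
    package_version = as.character(utils::packageVersion("ringpull"))
  )

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_rupture_csv(smp, file.path(dir, paste0(scenario, ".csv")))
    jsonlite::write_json(smp$metadata,
                         file.path(dir, paste0(scenario, ".json")),
                         auto_unbox = TRUE, pretty = TRUE, null = "null",
                         digits = NA)
  }
  smp
}

#' Generate a force-distance trace
#'
#' Replays one seeded pulling event step by step and records the full
#' force-distance record: the WLC stretching ramp up to the rupture step,
#' then a force drop to zero (the trace continues for a short tail so the
#' drop is visible).  With the same seed, the rupture force and time equal
#' those of [simulate_single_pull()] exactly.
#'
#' @inheritParams simulate_single_pull
#' @param seed integer seed (overrides the protocol's seed field).
#' @param tail_fraction extra post-rupture steps, as a fraction of the
#'   pre-rupture trace length.
#' @return data frame with columns `time_s`, `displacement_um`,
#'   `force_pN`, `ruptured` (0 before the rupture row, 1 from it on).
#' @export
generate_fd_trace <- function(protocol, bond, wlc, seed = 1,
                              tail_fraction = 0.1) {
  proto <- as_protocol(protocol)
  bond <- as_bond(bond)
  wlc <- as_wlc(wlc)
  with_seed(seed, {
    ## same draw order as the Monte-Carlo engine: anchor distance first
    ## (truncated normal by rejection), then one uniform per step
    lo <- 0.1 * wlc$contour_nm
    hi <- 0.95 * wlc$contour_nm
    D_nm <- um_to_nm(proto$anchor_mean_um)
    if (proto$anchor_sd_um > 0) {
      repeat {
        D_nm <- rnorm(1, um_to_nm(proto$anchor_mean_um),
                      um_to_nm(proto$anchor_sd_um))
        if (D_nm > lo && D_nm < hi) break
      }
    }
    v <- um_to_nm(proto$velocity_um_per_s)
    dt <- proto$dt_s
    kBT <- proto$kBT_pN_nm
    Lc <- wlc$contour_nm * (1 - OVERSTRETCH_FRACTION)
    xmax <- 0.5 * sqrt(Lc^2 - D_nm^2)
    x <- um_to_nm(proto$x0_um)
    t <- 0
    rows_t <- numeric(0); rows_x <- numeric(0); rows_f <- numeric(0)
    ruptured <- FALSE
    while (!ruptured) {
      x <- x + v * dt
      t <- t + dt
      if (x >= xmax) break # censored: trace ends at the extensibility limit
      g <- tether_geometry(nm_to_um(D_nm), nm_to_um(x), wlc, kBT)
      Fc <- g$F_cohesin_pN
      k <- dissociation_rate(bond, Fc, kBT)
      if (detachment_time(k, runif(1)) <= dt) ruptured <- TRUE
      rows_t <- c(rows_t, t); rows_x <- c(rows_x, x); rows_f <- c(rows_f, Fc)
    }
    n_pre <- length(rows_t)
    n_tail <- ceiling(tail_fraction * n_pre)
    tail_t <- t + dt * seq_len(n_tail)
    tail_x <- x + v * dt * seq_len(n_tail)
    ## the rupture row keeps the peak force; rows after it read zero
    data.frame(
      time_s = c(rows_t, tail_t),
      displacement_um = nm_to_um(c(rows_x, tail_x)),
      force_pN = c(rows_f, rep(0, n_tail)),
      ruptured = c(rep(0L, n_pre - 1L), as.integer(ruptured),
                   rep(as.integer(ruptured), n_tail))
    )
  })
}

#' Generate a synthetic per-DNA ring occupancy table
#'
#' Stand-in for the unpublished experimental occupancy distribution:
#' Poisson ring counts per DNA with uniform positions along the molecule.
#'
#' @param n_dna number of DNA molecules.
#' @param mean_cohesins Poisson mean ring count per DNA (>= 0).
#' @param dna_length_um DNA length in um.
#' @param seed integer seed.
#' @return a [dna_occupancy()].
#' @export
generate_occupancy <- function(n_dna, mean_cohesins, dna_length_um = 16.32,
                               seed = 1) {
  n_dna <- as.integer(n_dna)
  stopifnot(n_dna >= 1L)
  check_number(mean_cohesins, "mean_cohesins", lower = 0)
  with_seed(seed, {
    counts <- stats::rpois(n_dna, mean_cohesins)
    dna_occupancy(
      lapply(counts, function(k) runif(k, 0, dna_length_um)),
      dna_length_um = dna_length_um
    )
  })
}
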