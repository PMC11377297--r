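#' Bell-model bond parameters
#'
#' The ring's disengagement kinetics are described by two parameters: the
#' spontaneous (zero-force) opening rate `k0` and the mechanical
#' displacement `delta` that couples force to the rate,
#' \eqn{k(F) = k_0 \exp(\delta F / k_B T)}.
#'
#' @param k0_per_s zero-force disengagement rate in 1/s (> 0).
#' @param delta_nm mechanical displacement parameter in nm (>= 0).
#' @return an object of class `bond_model`.
#' @examples
#' head_bond <- bond_model(0.0027, 1.23)
#' dissociation_rate(head_bond, force_pN = 20)
#' @export
bond_model <- function(k0_per_s, delta_nm) {
  check_number(k0_per_s, "k0_per_s", lower = 0, strict_lower = TRUE)
  check_number(delta_nm, "delta_nm", lower = 0)
  structure(
    list(k0_per_s = k0_per_s, delta_nm = delta_nm),
    class = "bond_model"
  )
}

#' @export
print.bond_model <- function(x, ...) {
  cat(sprintf("<bond_model> k0 = %g /s, delta = %g nm\n",
              x$k0_per_s, x$delta_nm))
  invisible(x)
}

as_bond <- function(x) {
  if (!inherits(x, "bond_model")) stop("expected a `bond_model` object", call. = FALSE)
  x
}

## Exponent beyond which exp() would overflow well before double limits;
## the rate is capped with a warning, making rupture certain within one
## time step of any practical protocol.
RATE_EXPONENT_CAP <- 500

#' Force-dependent disengagement rate
#'
#' Bell-model rate \eqn{k(F) = k_0 \exp(\delta F / k_B T)}.  At `F = 0` it
#' equals `k0`; for `delta > 0` it is strictly increasing in force.  If the
#' exponent exceeds 500 the rate is capped at `k0 * exp(500)` with a
#' warning (rupture is then certain within any one time step).
#'
#' @param bond a [bond_model()].
#' @param force_pN tension transmitted through the ring, pN (vectorised,
#'   >= 0).
#' @param kBT thermal energy in pN nm.
#' @return rate(s) in 1/s.
#' @export
dissociation_rate <- function(bond, force_pN, kBT = DEFAULT_KBT) {
  bond <- as_bond(bond)
  check_number(kBT, "kBT", lower = 0, strict_lower = TRUE)
  if (!is.numeric(force_pN) || any(!is.finite(force_pN)) || any(force_pN < 0)) {
    stop("`force_pN` must be finite and non-negative", call. = FALSE)
  }
  expo <- bond$delta_nm * force_pN / kBT
  if (any(expo > RATE_EXPONENT_CAP)) {
    warning("disengagement-rate exponent overflow: rate capped, rupture certain within one step")
    expo <- pmin(expo, RATE_EXPONENT_CAP)
  }
  bond$k0_per_s * exp(expo)
}

#' Stochastic detachment time from a uniform draw
#'
#' Inverse-CDF draw of an exponential waiting time,
#' \eqn{t = -\ln(1 - r)/k}: given the current rate and a uniform variate
#' `r` in `[0, 1)`, returns the candidate detachment time.  In the
#' time-stepping scheme the ring disengages in the current step iff
#' `t <= dt`.
#'
#' @param rate_per_s disengagement rate in 1/s (> 0).
#' @param r uniform variate(s) in `[0, 1)`.
#' @return time(s) in s.
#' @export
detachment_time <- function(rate_per_s, r) {
  if (!is.numeric(rate_per_s) || any(rate_per_s <= 0)) {
    stop("`rate_per_s` must be > 0", call. = FALSE)
  }
  if (!is.numeric(r) || any(r < 0) || any(r >= 1)) {
    stop("`r` must lie in [0, 1)", call. = FALSE)
  }
  -log1p(-r) / rate_per_s
}
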