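#' Worm-like-chain parameters
#'
#' Bundles the persistence length and contour length of a DNA tether.  The
#' defaults describe the lambda-DNA used throughout: persistence length
#' 50 nm, contour length 16.32 um.
#'
#' @param persistence_nm persistence length P in nm (> 0).
#' @param contour_nm contour length L0 in nm (> 0).
#' @return an object of class `wlc_params`.
#' @examples
#' wlc <- wlc_params()
#' wlc_force(wlc, length_nm = 8160)
#' @export
wlc_params <- function(persistence_nm = 50, contour_nm = 16320) {
  check_number(persistence_nm, "persistence_nm", lower = 0, strict_lower = TRUE)
  check_number(contour_nm, "contour_nm", lower = 0, strict_lower = TRUE)
  structure(
    list(persistence_nm = persistence_nm, contour_nm = contour_nm),
    class = "wlc_params"
  )
}

#' @export
print.wlc_params <- function(x, ...) {
  cat(sprintf("<wlc_params> P = %g nm, L0 = %g nm (%.3g um)\n",
              x$persistence_nm, x$contour_nm, nm_to_um(x$contour_nm)))
  invisible(x)
}

as_wlc <- function(x) {
  if (!inherits(x, "wlc_params")) stop("expected a `wlc_params` object", call. = FALSE)
  x
}

#' Marko-Siggia worm-like-chain force
#'
#' Entropic tension of a worm-like chain at end-to-end extension
#' `length_nm`, using the Marko-Siggia interpolation
#' \deqn{F = (k_B T / P)\,[1/(4(1-L/L_0)^2) - 1/4 + L/L_0].}
#' The force is strictly increasing in extension and diverges as the
#' extension approaches the contour length; extensions within a factor
#' `1e-6` of the contour length (or beyond) are outside the model's
#' validity and raise a domain error rather than being clamped.
#'
#' @param wlc a [wlc_params()] object.
#' @param length_nm end-to-end extension in nm (vectorised; `0 <= L < L0`).
#' @param kBT thermal energy in pN nm (default 4.114, i.e. 298 K).
#' @return force(s) in pN.
#' @examples
#' wlc_force(wlc_params(), 8160)  # half extension: ~0.103 pN
#' @export
wlc_force <- function(wlc, length_nm, kBT = DEFAULT_KBT) {
  wlc <- as_wlc(wlc)
  check_number(kBT, "kBT", lower = 0, strict_lower = TRUE)
  if (!is.numeric(length_nm) || any(!is.finite(length_nm))) {
    stop("`length_nm` must be finite numeric", call. = FALSE)
  }
  if (any(length_nm < 0)) {
    stop("`length_nm` must be non-negative", call. = FALSE)
  }
  L0 <- wlc$contour_nm
  if (any(length_nm >= L0 * (1 - OVERSTRETCH_FRACTION))) {
    stop_domain(
      "extension %g nm at or beyond the contour length %g nm: overstretched beyond WLC validity",
      max(length_nm), L0
    )
  }
  l <- length_nm / L0
  (kBT / wlc$persistence_nm) * (0.25 / (1 - l)^2 - 0.25 + l)
}

#' Single-tether V geometry
#'
#' A DNA molecule is tethered to the surface at both ends, `D_um` apart,
#' with the ring bound at its centre and displaced a distance `x_um`
#' perpendicular to the anchor line.  The chain then forms a V of total
#' length \eqn{L = 2\sqrt{(D/2)^2 + x^2}}, each arm carries the WLC tension
#' at that length, and the ring feels
#' \eqn{F_{ring} = 2 F_{DNA} \sin\alpha} with \eqn{\tan\alpha = 2x/D}.
#'
#' @param D_um anchor separation in um (> 0).
#' @param x_um perpendicular displacement of the ring in um; a signed value
#'   is accepted and only its magnitude enters (mirror symmetry).
#' @param wlc a [wlc_params()] object for the tether.
#' @param kBT thermal energy in pN nm.
#' @return an object of class `tether_geometry`: fields `D_um`, `x_um`,
#'   `L_dna_um`, `alpha` (radians), `F_dna_pN`, `F_cohesin_pN`.
#' @examples
#' tether_geometry(8.8, 4.0, wlc_params())
#' @export
tether_geometry <- function(D_um, x_um, wlc, kBT = DEFAULT_KBT) {
  wlc <- as_wlc(wlc)
  check_number(D_um, "D_um", lower = 0, strict_lower = TRUE)
  check_number(x_um, "x_um")
  x_um <- abs(x_um)
  D <- um_to_nm(D_um)
  x <- um_to_nm(x_um)
  L <- 2 * sqrt((D / 2)^2 + x^2)
  if (L >= wlc$contour_nm * (1 - OVERSTRETCH_FRACTION)) {
    stop_domain(
      "tether length %.4g um reaches the contour length %.4g um: pull exceeds the inextensible-chain limit",
      nm_to_um(L), nm_to_um(wlc$contour_nm)
    )
  }
  F_dna <- wlc_force(wlc, L, kBT)
  alpha <- atan2(2 * x, D)
  F_ring <- 2 * F_dna * sin(alpha)
  structure(
    list(
      D_um = D_um, x_um = x_um, L_dna_um = nm_to_um(L), alpha = alpha,
      F_dna_pN = F_dna, F_cohesin_pN = F_ring
    ),
    class = "tether_geometry"
  )
}

#' @export
print.tether_geometry <- function(x, ...) {
  cat(sprintf(
    "<tether_geometry> D = %g um, x = %g um, L = %.4g um, alpha = %.4g rad\n  F_dna = %.4g pN, F_cohesin = %.4g pN\n",
    x$D_um, x$x_um, x$L_dna_um, x$alpha, x$F_dna_pN, x$F_cohesin_pN
  ))
  invisible(x)
}

#' Residuals of the coupled two-DNA system
#'
#' Evaluates the five relations of the two-tether force balance at a given
#' state, independently of any solver: (1) `F1 = WLC1(L1)`, (2)
#' `F2 = WLC2(L2)`, (3) `F1 = 2 F2 sin(alpha)`, (4)
#' `(L2/2) sin(alpha) + L1 = x`, (5) `tan(alpha) = 2 (x - L1) / D`.
#' Forces are scaled by `max(1, |F|)` and lengths by the larger contour
#' length, so the returned residuals are relative.
#'
#' @param state a list or `two_dna_state` with `F1_pN`, `L1_um`, `F2_pN`,
#'   `L2_um`, `alpha`, `x_um`.
#' @param D_um anchor separation of the surface-tethered chain, um.
#' @param wlc1,wlc2 [wlc_params()] for the bead-proximal straight chain
#'   (1) and the surface-tethered V chain (2).
#' @param kBT thermal energy in pN nm.
#' @return named numeric vector of five relative residuals.
#' @export
two_dna_residuals <- function(state, D_um, wlc1, wlc2, kBT = DEFAULT_KBT) {
  wlc1 <- as_wlc(wlc1)
  wlc2 <- as_wlc(wlc2)
  D <- um_to_nm(D_um)
  x <- um_to_nm(state$x_um)
  L1 <- um_to_nm(state$L1_um)
  L2 <- um_to_nm(state$L2_um)
  a <- state$alpha
  Lref <- max(wlc1$contour_nm, wlc2$contour_nm)
  c(
    wlc1 = (state$F1_pN - wlc_force(wlc1, L1, kBT)) / max(1, abs(state$F1_pN)),
    wlc2 = (state$F2_pN - wlc_force(wlc2, L2, kBT)) / max(1, abs(state$F2_pN)),
    balance = (state$F1_pN - 2 * state$F2_pN * sin(a)) / max(1, abs(state$F1_pN)),
    closure = ((L2 / 2) * sin(a) + L1 - x) / Lref,
    angle = (tan(a) - 2 * (x - L1) / D) / max(1, abs(tan(a)))
  )
}

#' Solve the coupled two-DNA pulling geometry
#'
#' In the two-DNA capture experiment the ring links a straight
#' bead-proximal chain (DNA-1, extension `L1`, tension `F1`) to the middle
#' of a surface-tethered chain (DNA-2) that forms a V with anchor
#' separation `D`.  Pulling the bead a distance `x` from the anchor line
#' couples the two chains through the force balance `F1 = 2 F2 sin(alpha)`.
#' The five-equation system (see [two_dna_residuals()]) reduces to a single
#' strictly increasing equation in `L1`, which is bracketed and solved with
#' [stats::uniroot()].
#'
#' @inheritParams tether_geometry
#' @param wlc1,wlc2 [wlc_params()] for DNA-1 (straight) and DNA-2 (V).
#' @param tol relative residual tolerance (default `1e-8`).
#' @return an object of class `two_dna_state`: `F1_pN`, `L1_um`, `F2_pN`,
#'   `L2_um`, `alpha`, `x_um`, `residual_norm`.
#' @examples
#' solve_two_dna(8.8, 5, wlc_params(), wlc_params())
#' @export
solve_two_dna <- function(D_um, x_um, wlc1, wlc2, kBT = DEFAULT_KBT,
                          tol = 1e-8) {
  wlc1 <- as_wlc(wlc1)
  wlc2 <- as_wlc(wlc2)
  check_number(D_um, "D_um", lower = 0, strict_lower = TRUE)
  check_number(x_um, "x_um", lower = 0)
  check_number(tol, "tol", lower = 0, strict_lower = TRUE)
  D <- um_to_nm(D_um)
  x <- um_to_nm(x_um)
  ## bracket strictly inside the overstretch guard so the WLC force stays
  ## evaluable at the bracket endpoints
  Lc1 <- wlc1$contour_nm * (1 - 2 * OVERSTRETCH_FRACTION)
  Lc2 <- wlc2$contour_nm * (1 - 2 * OVERSTRETCH_FRACTION)
  if (D >= Lc2) {
    stop_domain("anchor separation %g um exceeds the contour of DNA-2", D_um)
  }

  finish <- function(L1) {
    y <- x - L1
    L2 <- 2 * sqrt((D / 2)^2 + y^2)
    alpha <- atan2(2 * y, D)
    F1 <- wlc_force(wlc1, L1, kBT)
    F2 <- wlc_force(wlc2, L2, kBT)
    st <- structure(
      list(
        F1_pN = F1, L1_um = nm_to_um(L1), F2_pN = F2, L2_um = nm_to_um(L2),
        alpha = alpha, x_um = x_um, residual_norm = NA_real_
      ),
      class = "two_dna_state"
    )
    st$residual_norm <- max(abs(two_dna_residuals(st, D_um, wlc1, wlc2, kBT)))
    if (st$residual_norm > tol) {
      stop(sprintf(
        "two-DNA solve did not reach tolerance: residual %.3g > %.3g",
        st$residual_norm, tol
      ), call. = FALSE)
    }
    st
  }

  if (x == 0) {
    return(finish(0))
  }

  ## physical bracket for L1: chain 2 must stay below contour, chain 1 too
  ymax <- sqrt(max((Lc2 / 2)^2 - (D / 2)^2, 0))
  lo <- max(0, x - ymax)
  hi <- min(x, Lc1)
  if (lo >= hi) {
    stop_domain(
      "no physical solution at x = %g um: one chain is at its contour length",
      x_um
    )
  }

  g <- function(L1) {
    y <- x - L1
    L2 <- 2 * sqrt((D / 2)^2 + y^2)
    wlc_force(wlc1, L1, kBT) - 2 * wlc_force(wlc2, L2, kBT) * (2 * y / L2)
  }
  glo <- g(lo)
  if (glo >= 0) {
    return(finish(lo))
  }
  root <- tryCatch(
    stats::uniroot(g, lower = lo, upper = hi, f.lower = glo,
                   tol = 1e-10 * max(1, hi), maxiter = 2000L),
    error = function(e) {
      stop(sprintf("two-DNA solve failed to converge: %s", conditionMessage(e)),
           call. = FALSE)
    }
  )
  finish(root$root)
}

#' @export
print.two_dna_state <- function(x, ...) {
  cat(sprintf(
    "<two_dna_state> x = %g um\n  DNA-1: L1 = %.4g um, F1 = %.4g pN\n  DNA-2: L2 = %.4g um, F2 = %.4g pN\n  alpha = %.4g rad, residual_norm = %.2g\n",
    x$x_um, x$L1_um, x$F1_pN, x$L2_um, x$F2_pN, x$alpha, x$residual_norm
  ))
  invisible(x)
}
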