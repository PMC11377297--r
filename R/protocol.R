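#' Constant-velocity pulling protocol
#'
#' Describes how the bead is moved and how the anchor geometry is drawn:
#' the bead advances perpendicular to the anchor line by `velocity * dt`
#' each step, and the anchor separation `D` is drawn once per event from a
#' normal distribution truncated to `(0.1, 0.95)` of the contour length.
#' Defaults reproduce the experimental protocol: 0.16 um/s, dt = 0.01 s,
#' D ~ Normal(8.8, 0.5) um.
#'
#' @param velocity_um_per_s pulling speed in um/s (> 0).
#' @param dt_s time step in s (> 0); 0.01 s default, with 0.1 s the coarse
#'   setting used for convergence checks.
#' @param anchor_mean_um,anchor_sd_um mean and sd of the anchor
#'   separation D in um (`anchor_sd_um >= 0`).
#' @param kBT_pN_nm thermal energy in pN nm.
#' @param x0_um initial perpendicular displacement in um (default 0: the
#'   bead starts on the anchor line; forces are negligible until the chain
#'   is taut, so this only shifts rupture times, not forces).
#' @param seed integer seed for the event stream, or `NULL` to use the
#'   current RNG state.
#' @return an object of class `pulling_protocol`.
#' @examples
#' pulling_protocol(seed = 1)
#' @export
pulling_protocol <- function(velocity_um_per_s = 0.16, dt_s = 0.01,
                             anchor_mean_um = 8.8, anchor_sd_um = 0.5,
                             kBT_pN_nm = DEFAULT_KBT, x0_um = 0,
                             seed = NULL) {
  check_number(velocity_um_per_s, "velocity_um_per_s", lower = 0, strict_lower = TRUE)
  check_number(dt_s, "dt_s", lower = 0, strict_lower = TRUE)
  check_number(anchor_mean_um, "anchor_mean_um", lower = 0, strict_lower = TRUE)
  check_number(anchor_sd_um, "anchor_sd_um", lower = 0)
  check_number(kBT_pN_nm, "kBT_pN_nm", lower = 0, strict_lower = TRUE)
  check_number(x0_um, "x0_um", lower = 0)
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    stopifnot(is.finite(seed))
  }
  structure(
    list(
      velocity_um_per_s = velocity_um_per_s, dt_s = dt_s,
      anchor_mean_um = anchor_mean_um, anchor_sd_um = anchor_sd_um,
      kBT_pN_nm = kBT_pN_nm, x0_um = x0_um, seed = seed
    ),
    class = "pulling_protocol"
  )
}

#' @export
print.pulling_protocol <- function(x, ...) {
  cat(sprintf(
    "<pulling_protocol> v = %g um/s, dt = %g s, D ~ N(%g, %g) um\n  kBT = %g pN nm, x0 = %g um, seed = %s\n",
    x$velocity_um_per_s, x$dt_s, x$anchor_mean_um, x$anchor_sd_um,
    x$kBT_pN_nm, x$x0_um, if (is.null(x$seed)) "<none>" else x$seed
  ))
  invisible(x)
}

as_protocol <- function(x) {
  if (!inherits(x, "pulling_protocol")) {
    stop("expected a `pulling_protocol` object", call. = FALSE)
  }
  x
}
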