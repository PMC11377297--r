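#' Rupture-force sample
#'
#' A collection of rupture forces from repeated pulling events, with
#' summary statistics.  Censored events (pulls that reached the chain's
#' extensibility limit without rupturing) are excluded from `forces` but
#' their count is kept, so the bookkeeping stays visible.
#'
#' @param forces_pN numeric vector of rupture forces in pN (uncensored
#'   events only).
#' @param events optional per-event data frame in the package CSV dialect
#'   (`event_id`, `force_pN`, `time_s`, `D_um`, `delta_nm`, `censored`),
#'   including censored rows.
#' @param censored number of censored events.
#' @param metadata named list of provenance (parameters, seed, ...).
#' @return an object of class `rupture_sample` with fields `forces`, `n`,
#'   `mean`, `sd`, `median`, `censored`, `events`, `metadata`.
#' @export
rupture_sample <- function(forces_pN, events = NULL, censored = 0L,
                           metadata = list()) {
  if (!is.numeric(forces_pN)) stop("`forces_pN` must be numeric", call. = FALSE)
  forces_pN <- as.numeric(forces_pN)
  if (any(!is.finite(forces_pN)) || any(forces_pN < 0)) {
    stop("rupture forces must be finite and non-negative", call. = FALSE)
  }
  structure(
    list(
      forces = forces_pN,
      n = length(forces_pN),
      mean = if (length(forces_pN)) mean(forces_pN) else NA_real_,
      sd = if (length(forces_pN) > 1) stats::sd(forces_pN) else NA_real_,
      median = if (length(forces_pN)) stats::median(forces_pN) else NA_real_,
      censored = as.integer(censored),
      events = events,
      metadata = metadata
    ),
    class = "rupture_sample"
  )
}

as_rupture_sample <- function(x) {
  if (inherits(x, "rupture_sample")) return(x)
  if (is.numeric(x)) return(rupture_sample(x))
  stop("expected a `rupture_sample` or a numeric force vector", call. = FALSE)
}

#' @export
print.rupture_sample <- function(x, ...) {
  cat(sprintf(
    "<rupture_sample> n = %d events (%d censored)\n  mean = %.3g pN, sd = %.3g pN, median = %.3g pN\n",
    x$n, x$censored, x$mean, x$sd, x$median
  ))
  invisible(x)
}

#' @export
summary.rupture_sample <- function(object, ...) {
  c(
    n = object$n, censored = object$censored, mean_pN = object$mean,
    sd_pN = object$sd, median_pN = object$median,
    min_pN = if (object$n) min(object$forces) else NA_real_,
    max_pN = if (object$n) max(object$forces) else NA_real_
  )
}

## per-event data frame in the canonical column order
events_frame <- function(force, time, D_um, delta_nm, censored) {
  data.frame(
    event_id = seq_along(force),
    force_pN = force,
    time_s = time,
    D_um = D_um,
    delta_nm = delta_nm,
    censored = as.integer(censored)
  )
}
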