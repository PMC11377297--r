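## Bead-attachment sampling model.
##
## Beads report on single rings only if most beads carry one ring.  The
## model infers the distribution of rings per bead from per-DNA occupancy
## (ring positions along each DNA) and a single efficiency parameter
## lambda: each ring nucleates a bead with probability lambda; other rings
## on the same DNA join that bead with probability 1 if within the
## proximity threshold of the nucleating ring, else with probability
## lambda.  Rings already captured are unavailable to later beads.

#' Bead-attachment model parameters
#'
#' @param lambda per-ring probability of nucleating a bead (in `[0, 1]`).
#' @param proximity_threshold_um distance below which co-capture is
#'   certain (default 1 um).
#' @param n_steps sampling draws (default 10000).
#' @param seed optional integer seed.
#' @return an object of class `bead_model`.
#' @export
bead_model <- function(lambda, proximity_threshold_um = 1, n_steps = 10000,
                       seed = NULL) {
  check_number(lambda, "lambda", lower = 0, upper = 1)
  check_number(proximity_threshold_um, "proximity_threshold_um", lower = 0,
               strict_lower = TRUE)
  n_steps <- as.integer(n_steps)
  stopifnot(n_steps >= 1L)
  structure(
    list(lambda = lambda, proximity_threshold_um = proximity_threshold_um,
         n_steps = n_steps, seed = seed),
    class = "bead_model"
  )
}

#' Per-DNA ring occupancy
#'
#' A list of ring positions (um along the DNA) for each of `n_dna`
#' molecules; DNAs with no rings are kept as empty entries so the
#' beads-per-DNA statistic is unbiased.
#'
#' @param positions list of numeric vectors (one per DNA) of ring
#'   positions in um, each within `[0, dna_length_um]`.
#' @param dna_length_um length of the DNA in um.
#' @return an object of class `dna_occupancy`.
#' @export
dna_occupancy <- function(positions, dna_length_um = 16.32) {
  if (!is.list(positions) || length(positions) == 0) {
    stop("`positions` must be a non-empty list of numeric vectors", call. = FALSE)
  }
  check_number(dna_length_um, "dna_length_um", lower = 0, strict_lower = TRUE)
  for (p in positions) {
    if (length(p) && (!is.numeric(p) || any(p < 0) || any(p > dna_length_um))) {
      stop("ring positions must lie within [0, dna_length_um]", call. = FALSE)
    }
  }
  structure(
    list(positions = positions, dna_length_um = dna_length_um,
         n_dna = length(positions)),
    class = "dna_occupancy"
  )
}

#' @export
print.dna_occupancy <- function(x, ...) {
  counts <- lengths(x$positions)
  cat(sprintf(
    "<dna_occupancy> %d DNAs of %g um, %.3g rings per DNA (range %d-%d)\n",
    x$n_dna, x$dna_length_um, mean(counts), min(counts), max(counts)
  ))
  invisible(x)
}

as_occupancy <- function(x) {
  if (inherits(x, "dna_occupancy")) return(x)
  if (is.data.frame(x)) {
    if (!all(c("dna_id", "position_um") %in% names(x))) {
      stop("occupancy data frame needs columns `dna_id`, `position_um`",
           call. = FALSE)
    }
    ids <- sort(unique(x$dna_id))
    return(dna_occupancy(lapply(ids, function(i) x$position_um[x$dna_id == i]),
                         dna_length_um = max(16.32, max(x$position_um, 0))))
  }
  stop("expected a `dna_occupancy` or an occupancy data frame", call. = FALSE)
}

#' @export
as.data.frame.dna_occupancy <- function(x, ...) {
  counts <- lengths(x$positions)
  data.frame(
    dna_id = rep(seq_along(x$positions), counts),
    position_um = unlist(x$positions)
  )
}

#' Write an occupancy table as CSV (`dna_id`, `position_um`)
#'
#' DNAs without rings produce no rows, so the DNA count is not recoverable
#' from the file alone; keep it alongside if empty molecules matter.
#'
#' @param occupancy a [dna_occupancy()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_occupancy_csv <- function(occupancy, path) {
  occupancy <- as_occupancy(occupancy)
  utils::write.csv(as.data.frame(occupancy), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

## bead assignment on one DNA: returns the ring count of each bead formed
assign_beads <- function(pos, lambda, threshold_um) {
  k <- length(pos)
  if (k == 0 || lambda == 0) return(integer(0))
  order_idx <- sample.int(k)
  free <- rep(TRUE, k)
  beads <- integer(0)
  for (i in order_idx) {
    if (!free[i]) next
    if (runif(1) >= lambda) next
    free[i] <- FALSE
    size <- 1L
    for (j in order_idx) {
      if (!free[j]) next
      near <- abs(pos[j] - pos[i]) < threshold_um
      if (near || runif(1) < lambda) {
        free[j] <- FALSE
        size <- size + 1L
      }
    }
    beads <- c(beads, size)
  }
  beads
}

#' Sample the joint (rings per bead, beads per DNA) distribution
#'
#' Draws `n_steps` DNAs (with replacement) from the occupancy source and
#' applies the bead-nucleation/co-capture rule at the model's lambda.
#'
#' @param occupancy a [dna_occupancy()] (or occupancy data frame).
#' @param model a [bead_model()].
#' @return list with `cohesins_per_bead` (named probability table),
#'   `beads_per_dna` (named probability table), `mean_beads_per_dna`,
#'   `single_ring_fraction`, `lambda`, `n_steps`.
#' @examples
#' occ <- generate_occupancy(200, mean_cohesins = 1.5, seed = 1)
#' sample_attachment(occ, bead_model(0.3, seed = 1))
#' @export
sample_attachment <- function(occupancy, model) {
  occupancy <- as_occupancy(occupancy)
  if (!inherits(model, "bead_model")) stop("expected a `bead_model`", call. = FALSE)
  if (all(lengths(occupancy$positions) == 0)) {
    stop("occupancy source is empty: no rings on any DNA", call. = FALSE)
  }
  res <- with_seed(model$seed, {
    beads_per_dna <- integer(model$n_steps)
    sizes <- vector("list", model$n_steps)
    which_dna <- sample.int(occupancy$n_dna, model$n_steps, replace = TRUE)
    for (s in seq_len(model$n_steps)) {
      b <- assign_beads(occupancy$positions[[which_dna[s]]], model$lambda,
                        model$proximity_threshold_um)
      beads_per_dna[s] <- length(b)
      sizes[[s]] <- b
    }
    list(beads_per_dna = beads_per_dna, sizes = unlist(sizes))
  })
  size_tab <- if (length(res$sizes)) {
    prop.table(table(res$sizes))
  } else {
    table(integer(0))
  }
  list(
    cohesins_per_bead = size_tab,
    beads_per_dna = prop.table(table(res$beads_per_dna)),
    mean_beads_per_dna = mean(res$beads_per_dna),
    single_ring_fraction = if (length(res$sizes)) mean(res$sizes == 1L) else NA_real_,
    lambda = model$lambda,
    n_steps = model$n_steps
  )
}

#' Calibrate lambda against an observed beads-per-DNA statistic
#'
#' The mean number of beads per DNA is non-decreasing in lambda, so a
#' monotone bisection (with common random numbers across evaluations)
#' recovers the lambda that reproduces the observed value; the
#' rings-per-bead distribution at that lambda is returned alongside.
#'
#' @param occupancy a [dna_occupancy()] (or occupancy data frame).
#' @param observed_beads_per_dna target mean beads per DNA (>= 0).
#' @param model a [bead_model()] template supplying the threshold,
#'   `n_steps` and seed; its lambda is ignored.
#' @param tol absolute tolerance on the matched statistic.
#' @param max_iter bisection iterations.
#' @return list with `lambda`, `achieved_beads_per_dna`,
#'   `cohesins_per_bead`, `single_ring_fraction`.
#' @export
calibrate_lambda <- function(occupancy, observed_beads_per_dna,
                             model = bead_model(0.5), tol = 0.01,
                             max_iter = 30) {
  occupancy <- as_occupancy(occupancy)
  check_number(observed_beads_per_dna, "observed_beads_per_dna", lower = 0)
  seed <- if (is.null(model$seed)) 1L else model$seed
  eval_at <- function(lambda) {
    m <- model
    m$lambda <- lambda
    m$seed <- seed  # common random numbers across bisection evaluations
    sample_attachment(occupancy, m)
  }
  if (observed_beads_per_dna == 0) {
    res <- eval_at(0)
    return(list(lambda = 0, achieved_beads_per_dna = 0,
                cohesins_per_bead = res$cohesins_per_bead,
                single_ring_fraction = res$single_ring_fraction))
  }
  top <- eval_at(1)
  if (observed_beads_per_dna > top$mean_beads_per_dna + tol) {
    stop(sprintf(
      "target %.3g beads per DNA unattainable: attainable range is [0, %.3g]",
      observed_beads_per_dna, top$mean_beads_per_dna
    ), call. = FALSE)
  }
  lo <- 0
  hi <- 1
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    val <- eval_at(mid)$mean_beads_per_dna
    if (abs(val - observed_beads_per_dna) <= tol) break
    if (val < observed_beads_per_dna) lo <- mid else hi <- mid
  }
  res <- eval_at(mid)
  list(lambda = mid, achieved_beads_per_dna = res$mean_beads_per_dna,
       cohesins_per_bead = res$cohesins_per_bead,
       single_ring_fraction = res$single_ring_fraction)
}
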