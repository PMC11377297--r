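## Parameter estimation by moment matching.
##
## The fitted statistic is the pair (mean, sd) of the rupture-force
## distribution; both are monotone in k0 and in delta, which is what makes
## the coordinate-wise golden-section search well posed.  Every objective
## evaluation re-simulates with the same seed (common random numbers), so
## the objective surface is a deterministic function of the parameters.

## asymptotic sampling variances of the observed mean and sd under
## approximate normality: var(mean) = s^2/n, var(sd) = s^2/(2n)
observed_variances <- function(observed) {
  s2 <- observed$sd^2
  list(var_mean = s2 / observed$n, var_std = s2 / (2 * observed$n))
}

#' Moment-matching objective for a candidate bond model
#'
#' Simulates a rupture-force distribution under `candidate` and measures
#' its distance from the observed sample.  Two forms are available:
#' `"weighted"` (default) scales the squared mean and sd mismatches by the
#' observed sampling variances `var_mean = s^2/n` and `var_std = s^2/(2n)`
#' (the negative log of the likelihood weight used for confidence
#' intervals); `"raw"` is the unscaled least-squares distance between the
#' means and variances.  Deterministic given `seed`.
#'
#' @param candidate a [bond_model()] to score.
#' @param observed a [rupture_sample()] (or numeric force vector) with at
#'   least 2 events and nonzero spread.
#' @param protocol a [pulling_protocol()] (its own seed field is ignored
#'   here; `seed` controls the simulation).
#' @param wlc a [wlc_params()].
#' @param n_sim simulated events per evaluation.
#' @param seed integer seed shared across evaluations (common random
#'   numbers).
#' @param form `"weighted"` or `"raw"`.
#' @param var_mean,var_std optional overrides of the observed sampling
#'   variances used by the weighted form.
#' @return non-negative scalar objective.
#' @export
summary_objective <- function(candidate, observed, protocol, wlc,
                              n_sim = 2000, seed = 1,
                              form = c("weighted", "raw"),
                              var_mean = NULL, var_std = NULL) {
  candidate <- as_bond(candidate)
  observed <- as_rupture_sample(observed)
  form <- match.arg(form)
  if (observed$n < 2) stop("observed sample needs at least 2 events", call. = FALSE)
  if (!is.finite(observed$sd) || observed$sd <= 0) {
    stop("observed sample is degenerate: zero spread", call. = FALSE)
  }
  proto <- as_protocol(protocol)
  proto$seed <- NULL
  sim <- sim_moments(proto, candidate, wlc, n_sim, seed)
  if (sim[["n"]] < 2) {
    stop("candidate produced fewer than 2 uncensored events", call. = FALSE)
  }
  if (form == "weighted") {
    v <- observed_variances(observed)
    if (is.null(var_mean)) var_mean <- v$var_mean
    if (is.null(var_std)) var_std <- v$var_std
    (sim[["mean"]] - observed$mean)^2 / var_mean +
      (sim[["sd"]] - observed$sd)^2 / var_std
  } else {
    (sim[["mean"]] - observed$mean)^2 + (sim[["sd"]]^2 - observed$sd^2)^2
  }
}

## 1-D golden-section minimisation.  Degenerate brackets return the point
## itself, so shrinking the bounds to a point pins the parameter.
golden_section <- function(f, lo, hi, tol) {
  if (hi < lo) stop("empty bracket", call. = FALSE)
  if (hi - lo <= tol) {
    x <- (lo + hi) / 2
    return(list(x = x, fx = f(x)))
  }
  gr <- (sqrt(5) - 1) / 2
  c1 <- hi - gr * (hi - lo)
  c2 <- lo + gr * (hi - lo)
  f1 <- f(c1)
  f2 <- f(c2)
  while (hi - lo > tol) {
    if (f1 < f2) {
      hi <- c2
      c2 <- c1; f2 <- f1
      c1 <- hi - gr * (hi - lo)
      f1 <- f(c1)
    } else {
      lo <- c1
      c1 <- c2; f1 <- f2
      c2 <- lo + gr * (hi - lo)
      f2 <- f(c2)
    }
  }
  x <- (lo + hi) / 2
  list(x = x, fx = f(x))
}

#' Fit (k0, delta) by two-dimensional golden-section search
#'
#' Nested (profiled) golden-section minimisation of
#' [summary_objective()]: an outer golden-section contraction on `delta`
#' evaluates, at every trial `delta`, an inner golden-section minimisation
#' over `log(k0)`; the outer objective is thus the profile
#' `min_k0 f(k0, delta)`, which the monotone dependence of both moments on
#' both parameters renders unimodal.  (The two moments trade off along a
#' narrow diagonal valley in `(log k0, delta)`, where alternating
#' single-coordinate contractions stall; profiling out `log(k0)` removes
#' the valley.)  Common random numbers (a fixed `seed` for every
#' evaluation) make the objective surface deterministic, so the bracketing
#' comparisons are well posed.
#'
#' @inheritParams summary_objective
#' @param bounds_k0 search interval for `k0` in 1/s (positive; searched on
#'   the log scale).
#' @param bounds_delta search interval for `delta` in nm.
#' @param tol_log_k0,tol_delta final bracket widths of the inner
#'   (`log(k0)`) and outer (`delta`, nm) golden sections.
#' @param dt_sim_s optional coarser time step for the objective's
#'   simulations only (the observed data keep their own); the moment bias
#'   between dt = 0.01 and 0.02 s is below Monte-Carlo noise at
#'   `n_sim <= 2e4`, so 0.02 s halves the cost of a fit at no practical
#'   accuracy loss.  `NULL` uses the protocol's `dt_s`.
#' @param n_sim_refine optional larger simulation count for a second,
#'   narrowed golden pass around the first optimum (box of 0.75 log units
#'   in `k0` by 0.1 nm in `delta`); concentrates simulation effort where
#'   the objective's Monte-Carlo noise limits precision.
#' @return an object of class `ringpull_fit`: `k0_hat`, `delta_hat`,
#'   `objective_value`, `ci90_k0`, `ci90_delta` (NA until
#'   [likelihood_ci()] is run; see [fit_bond_model()]), `at_bound` flag,
#'   `n_simulations_per_eval`, `n_evaluations`, `seed`, `form`.
#' @examples
#' \donttest{
#' obs <- simulate_rupture_distribution(pulling_protocol(seed = 2),
#'                                      bond_model(0.0027, 1.23),
#'                                      wlc_params(), n = 500)
#' golden_search_fit(obs, pulling_protocol(), wlc_params(), n_sim = 300)
#' }
#' @export
golden_search_fit <- function(observed, protocol, wlc,
                              bounds_k0 = c(1e-6, 1),
                              bounds_delta = c(0.2, 3),
                              tol_log_k0 = 0.01, tol_delta = 0.004,
                              n_sim = 2000, seed = 1,
                              form = c("weighted", "raw"),
                              dt_sim_s = NULL, n_sim_refine = NULL) {
  observed <- as_rupture_sample(observed)
  form <- match.arg(form)
  stopifnot(length(bounds_k0) == 2, all(bounds_k0 > 0),
            bounds_k0[1] <= bounds_k0[2],
            length(bounds_delta) == 2, all(bounds_delta > 0),
            bounds_delta[1] <= bounds_delta[2])
  lb <- log(bounds_k0)
  sim_protocol <- as_protocol(protocol)
  if (!is.null(dt_sim_s)) sim_protocol$dt_s <- dt_sim_s

  n_eval <- 0L
  ## one nested golden search over a given box at a given simulation budget
  run_nested <- function(lk_range, d_range, n_sim_use, seed_use,
                         tol_lk_use = tol_log_k0, tol_d_use = tol_delta) {
    cache <- new.env(parent = emptyenv())
    obj <- function(lk, d) {
      key <- paste(format(lk, digits = 17), format(d, digits = 17))
      if (!is.null(cache[[key]])) return(cache[[key]])
      val <- summary_objective(bond_model(exp(lk), d), observed, sim_protocol,
                               wlc, n_sim = n_sim_use, seed = seed_use,
                               form = form)
      if (!is.finite(val)) stop("non-finite objective", call. = FALSE)
      n_eval <<- n_eval + 1L
      cache[[key]] <- val
      val
    }
    ## inner golden section: profile out log(k0) at a fixed delta
    profile_cache <- new.env(parent = emptyenv())
    profile_k0 <- function(d) {
      key <- format(d, digits = 17)
      if (!is.null(profile_cache[[key]])) return(profile_cache[[key]])
      res <- golden_section(function(lk) obj(lk, d), lk_range[1], lk_range[2],
                            tol_lk_use)
      profile_cache[[key]] <- res
      res
    }
    outer_res <- golden_section(function(d) profile_k0(d)$fx,
                                d_range[1], d_range[2], tol_d_use)
    inner_res <- profile_k0(outer_res$x)
    list(lk = inner_res$x, d = outer_res$x, fx = inner_res$fx)
  }

  refine <- !is.null(n_sim_refine) && n_sim_refine > n_sim
  ## when a refinement pass follows, the first pass only needs to localise
  ## the optimum inside the refinement box, so its brackets stop earlier
  stage1 <- run_nested(lb, bounds_delta, n_sim, seed,
                       tol_lk_use = if (refine) max(tol_log_k0, 0.05) else tol_log_k0,
                       tol_d_use = if (refine) max(tol_delta, 0.012) else tol_delta)
  cur_lk <- stage1$lk
  cur_d <- stage1$d
  cur_f <- stage1$fx
  if (refine) {
    ## the attainable precision is set by the simulation noise of the
    ## objective; a second golden pass over a narrow box around the
    ## stage-one optimum buys a larger n_sim only where it matters
    lk2 <- c(max(lb[1], cur_lk - 0.6), min(lb[2], cur_lk + 0.6))
    d2 <- c(max(bounds_delta[1], cur_d - 0.08),
            min(bounds_delta[2], cur_d + 0.08))
    stage2 <- run_nested(lk2, d2, n_sim_refine, seed + 1L)
    cur_lk <- stage2$lk
    cur_d <- stage2$d
    cur_f <- stage2$fx
  }

  at_bound <- (cur_lk - lb[1] < 2 * tol_log_k0) ||
    (lb[2] - cur_lk < 2 * tol_log_k0) ||
    (cur_d - bounds_delta[1] < 2 * tol_delta) ||
    (bounds_delta[2] - cur_d < 2 * tol_delta)
  if (at_bound && diff(lb) > 2 * tol_log_k0 &&
      diff(bounds_delta) > 2 * tol_delta) {
    warning("optimum lies at a search bound; widen `bounds_k0`/`bounds_delta`")
  }

  structure(
    list(
      k0_hat = exp(cur_lk), delta_hat = cur_d, objective_value = cur_f,
      ci90_k0 = c(NA_real_, NA_real_), ci90_delta = c(NA_real_, NA_real_),
      at_bound = at_bound, n_simulations_per_eval = n_sim,
      n_evaluations = n_eval, seed = seed, form = form,
      bounds_k0 = bounds_k0, bounds_delta = bounds_delta
    ),
    class = "ringpull_fit"
  )
}

#' @export
print.ringpull_fit <- function(x, ...) {
  fmt_ci <- function(ci) {
    if (all(is.na(ci))) "(not computed)" else sprintf("(%.4g, %.4g)", ci[1], ci[2])
  }
  cat(sprintf(
    "<ringpull_fit> k0 = %.4g /s %s, delta = %.4g nm %s\n  objective = %.4g (%s), %d evaluations x %d simulated events, seed %d\n",
    x$k0_hat, fmt_ci(x$ci90_k0), x$delta_hat, fmt_ci(x$ci90_delta),
    x$objective_value, x$form, x$n_evaluations, x$n_simulations_per_eval,
    x$seed
  ))
  if (isTRUE(x$at_bound)) cat("  ! optimum at a search bound\n")
  invisible(x)
}

#' Monte-Carlo likelihood confidence interval for one parameter
#'
#' Scans one parameter over a window around its optimum while the other is
#' held fixed, re-simulating at each scanned value and converting the
#' moment mismatch into a likelihood weight
#' \deqn{P_i = \exp\{-(\mu_i - \bar F)^2/\mathrm{var}_{mean}
#'              - (\sigma_i - s_F)^2/\mathrm{var}_{std}\},}
#' then reports the central region covering 90% of the normalised area.
#' `k0` is scanned on a uniform log grid, `delta` on a uniform linear
#' grid; the window is widened automatically until the endpoint weights
#' are negligible.
#'
#' @inheritParams summary_objective
#' @param optimum a `ringpull_fit` from [golden_search_fit()].
#' @param which_parameter `"k0"` or `"delta"`.
#' @param n_samples number of scanned parameter values (>= 11).
#' @param half_width initial half width of the scan window, in log units
#'   for `k0` and in nm for `delta`.
#' @param dt_sim_s optional coarser simulation time step for the scan (see
#'   [golden_search_fit()]).
#' @return length-2 numeric interval (5th and 95th percentile of the
#'   likelihood mass), with the scan grid and weights attached as
#'   attributes `grid` and `weights`.
#' @export
likelihood_ci <- function(observed, optimum, which_parameter = c("k0", "delta"),
                          protocol, wlc, n_samples = 1001, n_sim = 2000,
                          seed = 1, half_width = NULL,
                          var_mean = NULL, var_std = NULL, dt_sim_s = NULL) {
  observed <- as_rupture_sample(observed)
  which_parameter <- match.arg(which_parameter)
  if (!inherits(optimum, "ringpull_fit")) {
    stop("`optimum` must be a `ringpull_fit`", call. = FALSE)
  }
  n_samples <- as.integer(n_samples)
  if (n_samples < 11L) stop("`n_samples` must be at least 11", call. = FALSE)
  v <- observed_variances(observed)
  if (is.null(var_mean)) var_mean <- v$var_mean
  if (is.null(var_std)) var_std <- v$var_std
  if (is.null(half_width)) {
    half_width <- if (which_parameter == "k0") 0.5 else 0.15
  }

  moments_at <- function(value, idx) {
    bond <- if (which_parameter == "k0") {
      bond_model(value, optimum$delta_hat)
    } else {
      bond_model(optimum$k0_hat, value)
    }
    proto <- as_protocol(protocol)
    proto$seed <- NULL
    if (!is.null(dt_sim_s)) proto$dt_s <- dt_sim_s
    ## fresh stream per scanned value, reproducible given `seed`
    sim <- sim_moments(proto, bond, wlc, n_sim, seed + idx)
    sim[c("mean", "sd")]
  }

  for (attempt in 1:6) {
    grid <- if (which_parameter == "k0") {
      exp(seq(log(optimum$k0_hat) - half_width,
              log(optimum$k0_hat) + half_width, length.out = n_samples))
    } else {
      seq(max(1e-4, optimum$delta_hat - half_width),
          optimum$delta_hat + half_width, length.out = n_samples)
    }
    mom <- vapply(seq_along(grid), function(i) moments_at(grid[i], i),
                  numeric(2))
    logw <- -(mom[1, ] - observed$mean)^2 / var_mean -
      (mom[2, ] - observed$sd)^2 / var_std
    w <- exp(logw - max(logw))
    if (sum(w) <= .Machine$double.eps) {
      stop("all likelihood weights are zero over the scan window", call. = FALSE)
    }
    edge <- max(w[1], w[n_samples]) / max(w)
    if (edge < 1e-3) break
    half_width <- half_width * 1.6
    if (attempt == 6) {
      warning("likelihood mass still touches the scan window edge; CI may be wide")
    }
  }

  w <- w / sum(w)
  cdf <- cumsum(w)
  qfun <- function(p) {
    i <- which(cdf >= p)[1]
    if (i <= 1) return(grid[1])
    ## linear interpolation on the CDF between neighbouring grid points
    p0 <- cdf[i - 1]
    grid[i - 1] + (grid[i] - grid[i - 1]) * (p - p0) / (cdf[i] - p0)
  }
  ci <- c(qfun(0.05), qfun(0.95))
  attr(ci, "grid") <- grid
  attr(ci, "weights") <- w
  ci
}

#' Full fit: golden-section optimum plus 90% confidence intervals
#'
#' Convenience wrapper running [golden_search_fit()] and then
#' [likelihood_ci()] for both parameters, returning a complete
#' `ringpull_fit`.
#'
#' @inheritParams golden_search_fit
#' @param n_samples_ci,n_sim_ci grid size and per-point simulation count
#'   for the confidence intervals.
#' @param dt_sim_s optional coarser simulation time step (see
#'   [golden_search_fit()]).
#' @return a `ringpull_fit` with `ci90_k0` and `ci90_delta` filled in.
#' @export
fit_bond_model <- function(observed, protocol, wlc,
                           bounds_k0 = c(1e-6, 1), bounds_delta = c(0.2, 3),
                           n_sim = 2000, seed = 1,
                           form = c("weighted", "raw"),
                           n_samples_ci = 201, n_sim_ci = 1000,
                           dt_sim_s = NULL, ...) {
  observed <- as_rupture_sample(observed)
  form <- match.arg(form)
  fit <- golden_search_fit(observed, protocol, wlc, bounds_k0 = bounds_k0,
                           bounds_delta = bounds_delta, n_sim = n_sim,
                           seed = seed, form = form, dt_sim_s = dt_sim_s, ...)
  fit$ci90_k0 <- as.numeric(likelihood_ci(
    observed, fit, "k0", protocol, wlc,
    n_samples = n_samples_ci, n_sim = n_sim_ci, seed = seed,
    dt_sim_s = dt_sim_s
  ))
  fit$ci90_delta <- as.numeric(likelihood_ci(
    observed, fit, "delta", protocol, wlc,
    n_samples = n_samples_ci, n_sim = n_sim_ci, seed = seed,
    dt_sim_s = dt_sim_s
  ))
  ## the point estimate should sit inside its own intervals; clip against
  ## grid-edge effects would hide a defect, so assert instead
  stopifnot(fit$k0_hat >= fit$ci90_k0[1], fit$k0_hat <= fit$ci90_k0[2],
            fit$delta_hat >= fit$ci90_delta[1],
            fit$delta_hat <= fit$ci90_delta[2])
  fit
}

#' Bootstrap stability of the fitted parameters
#'
#' Refits random subsamples of the observed forces (without replacement)
#' and reports the spread of the recovered parameters, as a check that the
#' sample size, not the fitting machinery, limits the precision.
#'
#' @inheritParams golden_search_fit
#' @param n_subsamples number of subsamples to fit.
#' @param subsample_fraction fraction of the observed events per subsample
#'   (in `(0, 1]`; `1` reuses the full sample and gives zero dispersion).
#' @return data frame with one row per subsample (`k0_hat`, `delta_hat`,
#'   `objective_value`, `n_obs`), with standard deviations in
#'   `attr(, "sd")`.
#' @export
bootstrap_stability <- function(observed, protocol, wlc, n_subsamples = 10,
                                subsample_fraction = 0.5, n_sim = 1000,
                                seed = 1, ...) {
  observed <- as_rupture_sample(observed)
  if (observed$n < 10) stop("need at least 10 observed events", call. = FALSE)
  stopifnot(subsample_fraction > 0, subsample_fraction <= 1)
  m <- max(2L, floor(subsample_fraction * observed$n))
  idx <- with_seed(seed, replicate(n_subsamples,
                                   sample.int(observed$n, m), simplify = FALSE))
  rows <- lapply(seq_along(idx), function(i) {
    sub <- rupture_sample(observed$forces[idx[[i]]])
    if (!is.finite(sub$sd) || sub$sd <= 0) {
      message(sprintf("subsample %d skipped: zero spread", i))
      return(NULL)
    }
    ## same CRN seed for every subsample: dispersion reflects the data only
    fit <- golden_search_fit(sub, protocol, wlc, n_sim = n_sim, seed = seed,
                             ...)
    data.frame(k0_hat = fit$k0_hat, delta_hat = fit$delta_hat,
               objective_value = fit$objective_value, n_obs = m)
  })
  out <- do.call(rbind, rows)
  attr(out, "sd") <- c(k0 = stats::sd(out$k0_hat),
                       delta = stats::sd(out$delta_hat))
  out
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Standard two-sample KS statistic with the asymptotic p-value, used to
#' compare rupture-force distributions (e.g. head- versus hinge-pulled
#' samples).
#'
#' @param a,b [rupture_sample()] objects or numeric force vectors.
#' @return list with `statistic` and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  a <- as_rupture_sample(a)
  b <- as_rupture_sample(b)
  if (a$n < 1 || b$n < 1) stop("both samples must be non-empty", call. = FALSE)
  ## ties are expected between discretised simulated samples; the asymptotic
  ## statistic is still well defined, so the tie warning is suppressed
  res <- suppressWarnings(stats::ks.test(a$forces, b$forces, exact = FALSE))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}
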