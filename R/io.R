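## File I/O and run configuration.
##
## All tabular I/O uses one CSV dialect (header row, decimal point, no
## locale variants); fit reports are JSON; run configurations are YAML or
## JSON with explicit units in every key (the experiment mixes um, nm and
## pN, so bare numbers are the dominant source of bugs).

RUPTURE_CSV_COLUMNS <- c("event_id", "force_pN", "time_s", "D_um",
                         "delta_nm", "censored")

#' Write a rupture sample to CSV
#'
#' Columns: `event_id`, `force_pN`, `time_s`, `D_um`, `delta_nm`,
#' `censored`.  Censored events appear as rows with an empty force and
#' `censored = 1`.
#'
#' @param sample a [rupture_sample()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rupture_csv <- function(sample, path) {
  sample <- as_rupture_sample(sample)
  ev <- sample$events
  if (is.null(ev)) {
    ev <- events_frame(sample$forces, NA_real_, NA_real_, NA_real_,
                       rep(0L, sample$n))
  }
  utils::write.csv(ev[, RUPTURE_CSV_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a rupture sample from CSV
#'
#' Reads the dialect written by [write_rupture_csv()], validating the
#' header and every numeric cell; malformed input is reported with the
#' offending column (and row where known).
#'
#' @param path CSV file path.
#' @return a [rupture_sample()] (censored rows excluded from the forces,
#'   counted in `$censored`).
#' @export
read_rupture_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop(sprintf("%s: no events in file", path), call. = FALSE)
  missing_cols <- setdiff(RUPTURE_CSV_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in c("force_pN", "time_s", "D_um", "delta_nm", "censored")) {
    if (!is.numeric(df[[col]]) && !all(is.na(df[[col]]))) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))) &
                     !is.na(df[[col]]))[1]
      stop(sprintf("%s: non-numeric value in column `%s`, row %d",
                   path, col, bad), call. = FALSE)
    }
  }
  cens <- df$censored == 1L
  bad_force <- which(!cens & (is.na(df$force_pN) | df$force_pN < 0))
  if (length(bad_force)) {
    stop(sprintf("%s: invalid force in column `force_pN`, row %d",
                 path, bad_force[1]), call. = FALSE)
  }
  rupture_sample(df$force_pN[!cens], events = df, censored = sum(cens),
                 metadata = list(source = path))
}

#' Write a fit report as JSON
#'
#' Records the fitted parameters, confidence intervals, objective, seeds
#' and simulation sizes so the fit is fully reproducible.
#'
#' @param fit a `ringpull_fit`.
#' @param path output path.
#' @param extra optional named list merged into the report (e.g. censoring
#'   counts, input provenance).
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, extra = list()) {
  if (!inherits(fit, "ringpull_fit")) stop("expected a `ringpull_fit`", call. = FALSE)
  report <- c(
    list(
      k0_hat_per_s = fit$k0_hat, delta_hat_nm = fit$delta_hat,
      objective_value = fit$objective_value,
      ci90_k0_per_s = fit$ci90_k0, ci90_delta_nm = fit$ci90_delta,
      at_bound = fit$at_bound, objective_form = fit$form,
      n_simulations_per_eval = fit$n_simulations_per_eval,
      n_evaluations = fit$n_evaluations, seed = fit$seed,
      package_version = as.character(utils::packageVersion("ringpull"))
    ),
    extra
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read and validate a run configuration
#'
#' Configurations are YAML or JSON (by extension).  Every physical
#' quantity carries its unit in the key (`velocity_um_per_s`, `k0_per_s`,
#' `delta_nm`, ...); unknown keys inside the known blocks are rejected so
#' typos fail loudly.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("configuration must be a .yaml/.yml or .json file", call. = FALSE)
  }
  validate_run_config(cfg)
}

known_keys <- list(
  protocol = c("velocity_um_per_s", "dt_s", "anchor_mean_um", "anchor_sd_um",
               "kBT_pN_nm", "x0_um", "seed"),
  wlc = c("persistence_nm", "contour_nm"),
  wlc1 = c("persistence_nm", "contour_nm"),
  wlc2 = c("persistence_nm", "contour_nm"),
  bond = c("k0_per_s", "delta_nm"),
  two_dna = c("k0_per_s", "delta_nm", "prob"),
  fit = c("bounds_k0_per_s", "bounds_delta_nm", "n_sim", "form",
          "n_samples_ci", "n_sim_ci", "bootstrap_subsamples",
          "bootstrap_fraction"),
  beads = c("lambda", "proximity_threshold_um", "n_steps",
            "target_beads_per_dna", "occupancy_csv", "n_dna",
            "mean_cohesins", "dna_length_um"),
  scenario = c("name", "n_events", "noise_sd_pN")
)

#' Validate a run configuration list
#'
#' @param cfg a named list (as from [read_run_config()]).
#' @return `cfg` with class `run_config`, or an error naming the offending
#'   block/key.
#' @export
validate_run_config <- function(cfg) {
  if (!is.list(cfg)) stop("configuration must be a named list", call. = FALSE)
  top <- c(names(known_keys), "seed", "n_events", "output_dir", "input_csv",
           "log_level")
  bad <- setdiff(names(cfg), top)
  if (length(bad)) {
    stop(sprintf("unknown configuration block(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  for (blk in intersect(names(cfg), names(known_keys))) {
    if (!is.list(cfg[[blk]])) {
      stop(sprintf("block `%s` must be a mapping", blk), call. = FALSE)
    }
    unknown <- setdiff(names(cfg[[blk]]), known_keys[[blk]])
    if (length(unknown)) {
      stop(sprintf("unknown key(s) in block `%s`: %s", blk,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    for (key in setdiff(names(cfg[[blk]]), c("form", "occupancy_csv", "name"))) {
      val <- cfg[[blk]][[key]]
      if (!is.numeric(val) || any(!is.finite(val))) {
        stop(sprintf("key `%s.%s` must be finite numeric", blk, key),
             call. = FALSE)
      }
    }
  }
  structure(cfg, class = c("run_config", "list"))
}

config_protocol <- function(cfg) {
  p <- cfg$protocol
  if (is.null(p)) p <- list()
  if (is.null(p$seed) && !is.null(cfg$seed)) p$seed <- cfg$seed
  do.call(pulling_protocol, p)
}

config_wlc <- function(cfg, block = "wlc") {
  w <- cfg[[block]]
  if (is.null(w)) w <- list()
  do.call(wlc_params, w)
}

run_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf(...))
}

#' Run a simulation from a configuration
#'
#' Executes the single-DNA simulation (block `bond`) or the two-DNA
#' simulation (block `two_dna`) described by the configuration, writing
#' the rupture CSV and a JSON summary (resolved configuration, package
#' version, seed, censoring counts) into `output_dir`.
#'
#' @param cfg a `run_config` (or path to one).
#' @return the [rupture_sample()], invisibly; side effect: files in
#'   `cfg$output_dir` (`ruptures.csv`, `summary.json`) when set.
#' @export
run_simulate <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  cfg <- validate_run_config(cfg)
  proto <- config_protocol(cfg)
  n <- if (!is.null(cfg$n_events)) as.integer(cfg$n_events) else 1000L
  if (!is.null(cfg$two_dna)) {
    smp <- simulate_two_dna_pull(
      proto, cfg$two_dna$k0_per_s, cfg$two_dna$delta_nm,
      prob = cfg$two_dna$prob,
      wlc1 = config_wlc(cfg, "wlc1"), wlc2 = config_wlc(cfg, "wlc2"), n = n
    )
  } else if (!is.null(cfg$bond)) {
    smp <- simulate_rupture_distribution(
      proto, do.call(bond_model, cfg$bond), config_wlc(cfg), n
    )
  } else {
    stop("configuration needs a `bond` or `two_dna` block", call. = FALSE)
  }
  run_log(cfg, "ringpull %s: simulated %d events (%d censored), seed %s",
          utils::packageVersion("ringpull"), n, smp$censored,
          if (is.null(proto$seed)) "<none>" else proto$seed)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_rupture_csv(smp, file.path(cfg$output_dir, "ruptures.csv"))
    jsonlite::write_json(
      list(config = unclass(cfg), summary = as.list(summary(smp)),
           censored = smp$censored,
           package_version = as.character(utils::packageVersion("ringpull"))),
      file.path(cfg$output_dir, "summary.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null"
    )
  }
  invisible(smp)
}

#' Run a fit from a configuration
#'
#' Reads the observed forces from `cfg$input_csv`, fits the bond model
#' (with confidence intervals, and bootstrap stability when the `fit`
#' block requests it) and writes `fit_report.json` into `output_dir`.
#'
#' @param cfg a `run_config` (or path to one).
#' @param input_csv overrides `cfg$input_csv`.
#' @return the `ringpull_fit`, invisibly.
#' @export
run_fit <- function(cfg, input_csv = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  cfg <- validate_run_config(cfg)
  path <- if (!is.null(input_csv)) input_csv else cfg$input_csv
  if (is.null(path)) stop("no input CSV given", call. = FALSE)
  observed <- read_rupture_csv(path)
  proto <- config_protocol(cfg)
  wlc <- config_wlc(cfg)
  fb <- cfg$fit
  if (is.null(fb)) fb <- list()
  seed <- if (!is.null(cfg$seed)) as.integer(cfg$seed) else 1L
  fit <- fit_bond_model(
    observed, proto, wlc,
    bounds_k0 = fb$bounds_k0_per_s %||% c(1e-6, 1),
    bounds_delta = fb$bounds_delta_nm %||% c(0.2, 3),
    n_sim = fb$n_sim %||% 2000, seed = seed,
    form = fb$form %||% "weighted",
    n_samples_ci = fb$n_samples_ci %||% 201,
    n_sim_ci = fb$n_sim_ci %||% 1000
  )
  extra <- list(input_csv = path, n_observed = observed$n,
                censored_in_input = observed$censored)
  if (!is.null(fb$bootstrap_subsamples)) {
    bs <- bootstrap_stability(
      observed, proto, wlc, n_subsamples = fb$bootstrap_subsamples,
      subsample_fraction = fb$bootstrap_fraction %||% 0.5,
      n_sim = fb$n_sim %||% 1000, seed = seed
    )
    extra$bootstrap_sd <- as.list(attr(bs, "sd"))
  }
  run_log(cfg, "ringpull %s: fit k0 = %.4g /s, delta = %.4g nm (seed %d)",
          utils::packageVersion("ringpull"), fit$k0_hat, fit$delta_hat, seed)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_fit_report(fit, file.path(cfg$output_dir, "fit_report.json"), extra)
  }
  invisible(fit)
}

#' Run the bead-attachment model from a configuration
#'
#' Loads (or generates) the occupancy table, runs [sample_attachment()] at
#' a fixed lambda or [calibrate_lambda()] against a target beads-per-DNA
#' value, and writes the distributions as CSV and JSON into `output_dir`.
#'
#' @param cfg a `run_config` (or path to one).
#' @return the attachment/calibration result list, invisibly.
#' @export
run_beads <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  cfg <- validate_run_config(cfg)
  bb <- cfg$beads
  if (is.null(bb)) stop("configuration needs a `beads` block", call. = FALSE)
  seed <- if (!is.null(cfg$seed)) as.integer(cfg$seed) else 1L
  occ <- if (!is.null(bb$occupancy_csv)) {
    as_occupancy(utils::read.csv(bb$occupancy_csv))
  } else {
    generate_occupancy(bb$n_dna %||% 1000, bb$mean_cohesins %||% 1.5,
                       bb$dna_length_um %||% 16.32, seed = seed)
  }
  model <- bead_model(bb$lambda %||% 0.5,
                      bb$proximity_threshold_um %||% 1,
                      bb$n_steps %||% 10000, seed = seed)
  res <- if (!is.null(bb$target_beads_per_dna)) {
    calibrate_lambda(occ, bb$target_beads_per_dna, model)
  } else {
    sample_attachment(occ, model)
  }
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    tab <- data.frame(
      cohesins_per_bead = as.integer(names(res$cohesins_per_bead)),
      probability = as.numeric(res$cohesins_per_bead)
    )
    utils::write.csv(tab, file.path(cfg$output_dir, "cohesins_per_bead.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(lambda = res$lambda,
           single_ring_fraction = res$single_ring_fraction,
           cohesins_per_bead = as.list(setNames(
             as.numeric(res$cohesins_per_bead),
             names(res$cohesins_per_bead))),
           config = unclass(cfg), seed = seed,
           package_version = as.character(utils::packageVersion("ringpull"))),
      file.path(cfg$output_dir, "beads.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null"
    )
  }
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
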