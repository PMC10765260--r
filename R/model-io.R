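#' Load a model configuration file
#'
#' Reads and validates the YAML configuration that is the single source of
#' truth for a run: all model inputs (2021 US dollars, months, ages in
#' years), the per-arm calibration targets, the life-table path (resolved
#' relative to the config file; the token `"bundled"` selects the packaged
#' table) and the sensitivity-analysis block. Unknown keys and out-of-range
#' values are rejected with the offending field path.
#'
#' @param path Path to a YAML config (see the bundled
#'   `inst/extdata/base_case.yaml` for the schema).
#' @return A `run_config`: list with `scenario`, `life_table` (loaded),
#'   `params` (arguments for [model_params()]), `schedule_tail` (post-year-4
#'   annual probabilities), `targets` (list of two [calibration_targets()]),
#'   `sensitivity` (ranges data frame, `n_draws`, `seed`, `wtp_grid`) and
#'   `hash` (MD5 of the file).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  allowed <- c("scenario", "life_table", "starting_age", "horizon_age",
               "annual_discount_rate", "treatment_duration",
               "imaging_fraction", "costs", "utilities", "transitions",
               "targets", "sensitivity")
  .reject_unknown(cfg, allowed, "")
  need <- function(x, field, where) {
    if (is.null(x)) stop("config missing `", where, field, "`", call. = FALSE)
    x
  }
  costs <- need(cfg$costs, "costs", "")
  .reject_unknown(costs, c("monthly_drug_cost", "oncologist_visit_cost",
                           "imaging_cost", "monthly_metastatic_cost"),
                  "costs.")
  utilities <- need(cfg$utilities, "utilities", "")
  .reject_unknown(utilities, c("utility_no_recurrence", "utility_metastatic",
                               "olaparib_utility_multiplier"), "utilities.")
  trans <- need(cfg$transitions, "transitions", "")
  .reject_unknown(trans, c("hazard_ratio", "annual_prob_y5_9",
                           "annual_prob_y10p",
                           "monthly_metastatic_death_rate"), "transitions.")
  hr_raw <- need(trans$hazard_ratio, "hazard_ratio", "transitions.")
  hr <- hazard_ratio(hr_raw$point, hr_raw$ci_low, hr_raw$ci_high)

  lt_path <- need(cfg$life_table, "life_table", "")
  if (identical(lt_path, "bundled")) {
    lt <- us_life_table_2018_female()
  } else {
    if (!file.exists(lt_path)) {
      lt_path <- file.path(dirname(normalizePath(path)), lt_path)
    }
    lt <- read_life_table(lt_path)
  }

  tg <- need(cfg$targets, "targets", "")
  .reject_unknown(tg, c("placebo", "olaparib"), "targets.")
  targets <- lapply(names(tg), function(arm) {
    calibration_targets(arm, ddfs = unlist(tg[[arm]]$ddfs),
                        os = unlist(tg[[arm]]$os))
  })
  names(targets) <- names(tg)

  params <- c(
    list(starting_age = need(cfg$starting_age, "starting_age", ""),
         horizon_age = cfg$horizon_age %||% 110,
         annual_discount_rate = need(cfg$annual_discount_rate,
                                     "annual_discount_rate", ""),
         treatment_duration = cfg$treatment_duration %||% 12,
         imaging_fraction = need(cfg$imaging_fraction, "imaging_fraction", ""),
         hr = hr,
         monthly_metastatic_death_rate =
           need(trans$monthly_metastatic_death_rate,
                "monthly_metastatic_death_rate", "transitions.")),
    costs, utilities
  )
  # validate value ranges early via the constructor
  probe <- recurrence_schedule(rep(0, 4),
                               annual_prob_y5_9 = trans$annual_prob_y5_9 %||% 0.0156,
                               annual_prob_y10p = trans$annual_prob_y10p %||% 0.0078)
  do.call(model_params, c(list(olaparib = TRUE, schedule = probe), params))

  sens <- NULL
  if (!is.null(cfg$sensitivity)) {
    s <- cfg$sensitivity
    .reject_unknown(s, c("n_draws", "seed", "wtp_max", "wtp_step", "ranges"),
                    "sensitivity.")
    ranges <- if (is.null(s$ranges)) {
      default_sa_ranges()
    } else {
      do.call(rbind, lapply(s$ranges, function(r) {
        .reject_unknown(r, c("parameter", "base", "low", "high",
                             "distribution"), "sensitivity.ranges.")
        data.frame(parameter = r$parameter, base = r$base, low = r$low,
                   high = r$high,
                   distribution = r$distribution %||% NA_character_)
      }))
    }
    sens <- list(ranges = ranges,
                 n_draws = s$n_draws %||% 10000,
                 seed = s$seed %||% 1,
                 wtp_grid = seq(0, s$wtp_max %||% 300000,
                                by = s$wtp_step %||% 5000))
  }

  structure(list(
    scenario = cfg$scenario %||% "unnamed",
    life_table = lt,
    params = params,
    schedule_tail = list(annual_prob_y5_9 = probe$annual_prob_y5_9,
                         annual_prob_y10p = probe$annual_prob_y10p),
    targets = targets,
    sensitivity = sens,
    hash = unname(tools::md5sum(path)),
    path = normalizePath(path)
  ), class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.reject_unknown <- function(x, allowed, prefix) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop("unknown config key `", prefix, extra[1], "`", call. = FALSE)
  }
  invisible(x)
}

#' Bundled base-case configuration path
#'
#' @return Path to the packaged `base_case.yaml`.
#' @export
base_case_config <- function() {
  system.file("extdata", "base_case.yaml", package = "olaparibCEA")
}

# build the calibrated strategy pair from a run_config
.config_strategies <- function(config, mode = "grid") {
  seed_sched <- recurrence_schedule(
    rep(0, 4),
    annual_prob_y5_9 = config$schedule_tail$annual_prob_y5_9,
    annual_prob_y10p = config$schedule_tail$annual_prob_y10p
  )
  lt <- config$life_table
  pn <- do.call(model_params,
                c(list(olaparib = FALSE, schedule = seed_sched),
                  config$params))
  rep_n <- calibrate_arm(config$targets$placebo, pn, lt, mode = mode)
  pn <- structure(modifyList(unclass(pn), list(schedule = rep_n$schedule)),
                  class = "model_params")
  po <- do.call(model_params,
                c(list(olaparib = TRUE, schedule = seed_sched),
                  config$params))
  rep_o <- calibrate_arm(config$targets$olaparib, po, lt, mode = mode)
  po <- structure(modifyList(unclass(po), list(schedule = rep_o$schedule)),
                  class = "model_params")
  list(olaparib = po, no_olaparib = pn,
       report_olaparib = rep_o, report_no_olaparib = rep_n)
}

.write_manifest <- function(out_dir, config, task, seed = NULL, extra = list()) {
  manifest <- c(list(
    task = task,
    scenario = config$scenario,
    config_hash = config$hash,
    package = "olaparibCEA",
    version = as.character(utils::packageVersion("olaparibCEA")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(task, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Calibrate both arms from a configuration and write reports
#'
#' @param config A `run_config` from [load_config()].
#' @param out_dir Output directory (created if needed).
#' @param mode Calibration mode, `"grid"` or `"bisect"`.
#' @return Invisibly, the strategy list from the calibration.
#' @export
cea_calibrate <- function(config, out_dir, mode = "grid") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- .config_strategies(config, mode = mode)
  write_calibration_report(st$report_no_olaparib,
                           file.path(out_dir, "calibration_no_olaparib.json"))
  write_calibration_report(st$report_olaparib,
                           file.path(out_dir, "calibration_olaparib.json"))
  .write_manifest(out_dir, config, "calibrate")
  invisible(st)
}

#' Run the configured base-case comparison and write the summary
#'
#' Writes `summary.json` (per-strategy totals and ICERs) and the two
#' per-cycle trace CSVs.
#'
#' @inheritParams cea_calibrate
#' @return The `ce_result`, invisibly.
#' @export
cea_run <- function(config, out_dir, mode = "grid") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- .config_strategies(config, mode = mode)
  ta <- run_cohort(st$olaparib, config$life_table)
  tb <- run_cohort(st$no_olaparib, config$life_table)
  res <- compare_strategies(ta, tb)
  write_trace(ta, file.path(out_dir, "trace_olaparib.csv"))
  write_trace(tb, file.path(out_dir, "trace_no_olaparib.csv"))
  jsonlite::write_json(list(
    strategies = res$summary,
    incremental = list(cost = res$d_cost, ly = res$d_ly, qaly = res$d_qaly),
    icer_per_ly = res$icer_ly, icer_per_qaly = res$icer_qaly,
    status = res$status
  ), file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  .write_manifest(out_dir, config, "run")
  invisible(res)
}

#' One-way sensitivity analysis from a configuration
#'
#' @inheritParams cea_calibrate
#' @return The `tornado` data frame, invisibly.
#' @export
cea_owsa <- function(config, out_dir, mode = "grid") {
  if (is.null(config$sensitivity)) {
    stop("config has no `sensitivity` block: add one (or use the bundled ",
         "base_case.yaml) to run one-way sensitivity analysis",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- .config_strategies(config, mode = mode)
  torn <- one_way_sa(st, config$life_table, config$sensitivity$ranges)
  write_tornado(torn, file.path(out_dir, "tornado.csv"))
  .write_manifest(out_dir, config, "owsa")
  invisible(torn)
}

#' Threshold analysis from a configuration
#'
#' @inheritParams cea_calibrate
#' @param parameter Parameter to vary.
#' @param wtp Willingness-to-pay threshold, dollars per QALY.
#' @param bounds Length-2 search interval (defaults to the parameter's
#'   sensitivity range).
#' @return The crossing value, invisibly.
#' @export
cea_threshold <- function(config, out_dir, parameter, wtp = 150000,
                          bounds = NULL, mode = "grid") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- .config_strategies(config, mode = mode)
  if (is.null(bounds)) {
    rg <- config$sensitivity$ranges
    row <- rg[rg$parameter == parameter, ]
    if (nrow(row) != 1L) {
      stop("no sensitivity range for `", parameter,
           "`; pass `bounds` explicitly", call. = FALSE)
    }
    bounds <- c(row$low, row$high)
  }
  value <- threshold_search(parameter, wtp, bounds, st, config$life_table)
  jsonlite::write_json(list(parameter = parameter, wtp = wtp,
                            bounds = bounds, value = value),
                       file.path(out_dir, "threshold.json"),
                       auto_unbox = TRUE, digits = NA)
  .write_manifest(out_dir, config, "threshold")
  invisible(value)
}

#' Probabilistic sensitivity analysis from a configuration
#'
#' Writes the draws CSV, the CEAC CSV and a manifest recording the seed.
#'
#' @inheritParams cea_calibrate
#' @param n,seed Override the config's draw count / seed.
#' @return The `psa_result`, invisibly.
#' @export
cea_psa <- function(config, out_dir, n = NULL, seed = NULL, mode = "grid") {
  if (is.null(config$sensitivity)) {
    stop("config has no `sensitivity` block", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- .config_strategies(config, mode = mode)
  rg <- config$sensitivity$ranges
  rg <- rg[!is.na(rg$distribution), ]
  specs <- stats::setNames(lapply(seq_len(nrow(rg)), function(i) {
    fit_distribution(rg$base[i], rg$low[i], rg$high[i], rg$distribution[i])
  }), rg$parameter)
  n <- n %||% config$sensitivity$n_draws
  seed <- seed %||% config$sensitivity$seed
  psa <- run_psa(st, config$life_table, specs = specs, n = n, seed = seed,
                 wtp_grid = config$sensitivity$wtp_grid)
  write_psa(psa, draws_path = file.path(out_dir, "psa_draws.csv"),
            ceac_path = file.path(out_dir, "ceac.csv"))
  .write_manifest(out_dir, config, "psa", seed = seed,
                  extra = list(n_draws = n))
  invisible(psa)
}
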