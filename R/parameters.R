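#' @title Model parameter containers and configuration I/O
#'
#' @description
#' All model inputs live in a `model_config` object: one `strategy_parameters`
#' block per reconstruction arm (costs in 2024 USD, trajectory-level expected
#' B-QALY targets, per-cycle transition parameters, demographics), a
#' `simulation_settings` block (horizon, cycle length, discounting, cohort
#' size, willingness-to-pay thresholds), and a life table. Configurations are
#' read from and written to YAML; the package bundles
#' `breast_recon_2024.yaml`, which carries the published cost, utility and
#' demographic tables together with prior (pre-calibration) transition rates.
#'
#' @name model_parameters
NULL

.cost_fields <- c("surgical_materials", "anesthesia", "hospital_stay",
                  "salvage", "loss", "revision", "pain_medication_monthly")
.utility_fields <- c("no_complication", "loss", "salvage", "revision")
.transition_fields <- c("p_complication_monthly", "p_salvage_given_complication",
                        "p_revision_monthly", "revision_window",
                        "anesthesia_mortality_multiplier")

#' Construct and validate a cost set (2024 USD)
#'
#' One-off costs are charged on state entry (salvage, loss, revision) or at
#' model entry (surgical + materials, anesthesia, hospital stay); the
#' pain-medication cost recurs every alive cycle. A zero hospital-stay cost is
#' allowed (outpatient implant surgery).
#'
#' @param x Named list with fields `surgical_materials`, `anesthesia`,
#'   `hospital_stay`, `salvage`, `loss`, `revision`,
#'   `pain_medication_monthly`. `pain_medication_monthly` defaults to 0 when
#'   absent.
#' @param prefix Field-path prefix used in validation messages.
#' @return A validated `cost_set` (named list).
#' @export
as_cost_set <- function(x, prefix = "costs") {
  x$pain_medication_monthly <- x$pain_medication_monthly %||% 0
  check_present(x, .cost_fields, prefix)
  for (f in .cost_fields) check_nonneg(x[[f]], paste0(prefix, ".", f))
  structure(x[.cost_fields], class = "cost_set")
}

#' Construct and validate trajectory-level utility targets (B-QALY)
#'
#' Targets are expected total discounted B-QALYs over the model horizon for a
#' patient following each canonical trajectory: never complicated, lost
#' reconstruction, salvaged reconstruction, or electively revised.
#' Complications deduct B-QALYs, so the uncomplicated trajectory must weakly
#' dominate salvage and revision, which in turn dominate loss.
#'
#' @param x Named list with fields `no_complication`, `loss`, `salvage`,
#'   `revision`.
#' @param horizon_years Optional horizon used to check that no target exceeds
#'   the perfect-health bound of one B-QALY per year.
#' @param prefix Field-path prefix for validation messages.
#' @return A validated `utility_targets` (named list).
#' @export
as_utility_targets <- function(x, horizon_years = NULL, prefix = "utilities") {
  check_present(x, .utility_fields, prefix)
  for (f in .utility_fields) check_nonneg(x[[f]], paste0(prefix, ".", f))
  u <- structure(x[.utility_fields], class = "utility_targets")
  rep_ <- validate_utility_ordering(u)
  if (!rep_$pass) {
    stop_config(prefix, paste("utility ordering violated:",
                              paste(rep_$violations, collapse = "; ")))
  }
  if (!is.null(horizon_years) && is.numeric(horizon_years)) {
    for (f in .utility_fields) {
      if (u[[f]] > horizon_years + 1e-9) {
        stop_config(paste0(prefix, ".", f),
                    sprintf("target %.4f exceeds horizon bound of %g B-QALYs",
                            u[[f]], horizon_years))
      }
    }
  }
  u
}

#' Check the complication-deduction ordering of utility targets
#'
#' Passes iff `no_complication >= salvage`, `no_complication >= revision`,
#' `salvage >= loss`, `revision >= loss`, and `loss >= 0`.
#'
#' @param u A `utility_targets` object or named list.
#' @return List with `pass` (logical) and `violations` (character vector
#'   naming each violated pair, e.g. `"salvage>no_complication"`).
#' @export
validate_utility_ordering <- function(u) {
  v <- character(0)
  if (u$salvage > u$no_complication) v <- c(v, "salvage>no_complication")
  if (u$revision > u$no_complication) v <- c(v, "revision>no_complication")
  if (u$loss > u$salvage) v <- c(v, "loss>salvage")
  if (u$loss > u$revision) v <- c(v, "loss>revision")
  if (u$loss < 0) v <- c(v, "loss<0")
  list(pass = length(v) == 0L, violations = v)
}

#' Construct and validate per-cycle transition parameters
#'
#' Monthly probabilities of a post-operative complication and of elective
#' revision (the latter restricted to a window of cycles), the split of
#' complications into salvage versus loss, and the peri-operative all-cause
#' mortality multiplier applied in cycles containing a surgical event.
#' The loss probability given a complication is the complement of
#' `p_salvage_given_complication`.
#'
#' @param x Named list with fields `p_complication_monthly`,
#'   `p_salvage_given_complication`, `p_revision_monthly`, `revision_window`
#'   (length-2 integer vector of first and last eligible cycle), and
#'   `anesthesia_mortality_multiplier` (>= 1).
#' @param horizon_cycles Optional horizon used to check the revision window.
#' @param prefix Field-path prefix for validation messages.
#' @return A validated `transition_parameters` (named list).
#' @export
as_transition_parameters <- function(x, horizon_cycles = NULL,
                                     prefix = "transitions") {
  x$anesthesia_mortality_multiplier <- x$anesthesia_mortality_multiplier %||% 1
  check_present(x, .transition_fields, prefix)
  check_probability(x$p_complication_monthly,
                    paste0(prefix, ".p_complication_monthly"))
  check_probability(x$p_salvage_given_complication,
                    paste0(prefix, ".p_salvage_given_complication"))
  check_probability(x$p_revision_monthly,
                    paste0(prefix, ".p_revision_monthly"))
  w <- as.integer(round(unlist(x$revision_window)))
  if (length(w) != 2L || any(is.na(w)) || w[1L] < 1L || w[2L] < w[1L]) {
    stop_config(paste0(prefix, ".revision_window"),
                "must be two cycle indices [first, last] with 1 <= first <= last")
  }
  if (!is.null(horizon_cycles) && w[2L] > horizon_cycles) {
    stop_config(paste0(prefix, ".revision_window"),
                sprintf("window end %d exceeds horizon of %d cycles",
                        w[2L], horizon_cycles))
  }
  if (x$p_complication_monthly + x$p_revision_monthly > 1) {
    stop_config(prefix,
                "p_complication_monthly + p_revision_monthly must not exceed 1")
  }
  m <- x$anesthesia_mortality_multiplier
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1) {
    stop_config(paste0(prefix, ".anesthesia_mortality_multiplier"),
                "must be a single number >= 1")
  }
  x$revision_window <- w
  structure(x[.transition_fields], class = "transition_parameters")
}

#' Construct and validate the parameter block of one strategy arm
#'
#' @param x Named list with `costs`, `utilities`, `transitions`, and
#'   optionally `inpatient_days` (defaults: 3 for flap arms, 0 for implant),
#'   demographics (`age_mean`, `age_sd`, `bmi_mean`, `bmi_sd`,
#'   `nipple_sparing_pct`, `followup_months_mean`, `followup_months_sd`), and
#'   `state_weights` (derived monthly utility weights; usually filled in by
#'   calibration).
#' @param name Strategy name, one of [strategy_names()].
#' @param horizon_years,horizon_cycles Optional horizon for cross-checks.
#' @return A validated `strategy_parameters` object.
#' @export
as_strategy_parameters <- function(x, name, horizon_years = NULL,
                                   horizon_cycles = NULL) {
  if (!name %in% strategy_names()) {
    stop_config(paste0("strategies.", name),
                sprintf("unknown strategy; expected one of %s",
                        paste(strategy_names(), collapse = ", ")))
  }
  prefix <- paste0("strategies.", name)
  check_present(x, c("costs", "utilities", "transitions"), prefix)
  out <- list(
    name = name,
    costs = as_cost_set(x$costs, paste0(prefix, ".costs")),
    utilities = as_utility_targets(x$utilities, horizon_years,
                                   paste0(prefix, ".utilities")),
    transitions = as_transition_parameters(x$transitions, horizon_cycles,
                                           paste0(prefix, ".transitions")),
    inpatient_days = x$inpatient_days %||% if (name == "IMPLANT") 0L else 3L
  )
  check_nonneg(out$inpatient_days, paste0(prefix, ".inpatient_days"))
  for (f in c("age_mean", "age_sd", "bmi_mean", "bmi_sd",
              "nipple_sparing_pct", "followup_months_mean",
              "followup_months_sd")) {
    if (!is.null(x[[f]])) {
      check_nonneg(x[[f]], paste0(prefix, ".", f))
      out[[f]] <- x[[f]]
    }
  }
  if (!is.null(x$state_weights)) {
    w <- unlist(x$state_weights)
    if (!all(health_states() %in% names(w))) {
      stop_config(paste0(prefix, ".state_weights"),
                  "must name every health state")
    }
    out$state_weights <- w[health_states()]
  }
  structure(out, class = "strategy_parameters")
}

#' Construct and validate simulation settings
#'
#' @param x Named list; recognised fields with defaults:
#'   `horizon_years` (5; 2 and `"lifetime"` are also supported),
#'   `cycle_length_months` (1, the only supported value),
#'   `annual_discount_rate` (0.03), `n_patients` (10000),
#'   `wtp_thresholds` (50000, 100000, 200000), `seed` (1),
#'   `cohort_age_mean` (52), `cohort_age_sd` (9), `cohort_sex` ("female"),
#'   `horizon_cycles` (optional override of the cycle count, used by
#'   horizon sweeps).
#' @return A validated `simulation_settings` object.
#' @export
as_simulation_settings <- function(x = list()) {
  s <- list(
    horizon_years = x$horizon_years %||% 5,
    cycle_length_months = x$cycle_length_months %||% 1,
    annual_discount_rate = x$annual_discount_rate %||% 0.03,
    n_patients = x$n_patients %||% 10000L,
    wtp_thresholds = unlist(x$wtp_thresholds %||% c(50000, 100000, 200000)),
    seed = x$seed %||% 1L,
    cohort_age_mean = x$cohort_age_mean %||% 52,
    cohort_age_sd = x$cohort_age_sd %||% 9,
    cohort_sex = x$cohort_sex %||% "female",
    horizon_cycles = x$horizon_cycles
  )
  if (!identical(as.numeric(s$cycle_length_months), 1)) {
    stop_config("settings.cycle_length_months", "only 1-month cycles are supported")
  }
  if (!(identical(s$horizon_years, "lifetime") ||
        (is.numeric(s$horizon_years) && s$horizon_years > 0))) {
    stop_config("settings.horizon_years",
                "must be a positive number of years or \"lifetime\"")
  }
  check_nonneg(s$annual_discount_rate, "settings.annual_discount_rate")
  if (s$n_patients < 0) stop_config("settings.n_patients", "must be >= 0")
  if (any(s$wtp_thresholds < 0)) {
    stop_config("settings.wtp_thresholds", "thresholds must be >= 0")
  }
  check_nonneg(s$cohort_age_mean, "settings.cohort_age_mean")
  check_nonneg(s$cohort_age_sd, "settings.cohort_age_sd")
  structure(s, class = "simulation_settings")
}

#' Number of monthly cycles implied by the settings
#'
#' The lifetime horizon caps age at 100 years; death probability is 1 beyond
#' the life-table range.
#'
#' @param settings A `simulation_settings` object.
#' @param age Entry age in years (needed for the lifetime horizon).
#' @return Integer cycle count.
#' @export
horizon_cycles <- function(settings, age = settings$cohort_age_mean) {
  if (!is.null(settings$horizon_cycles)) {
    return(as.integer(settings$horizon_cycles))
  }
  if (identical(settings$horizon_years, "lifetime")) {
    return(max(1L, as.integer(ceiling((100 - age) * 12))))
  }
  as.integer(round(settings$horizon_years * 12))
}

#' Load a model configuration from YAML
#'
#' Reads strategies, settings, and a life table (synthetic-parameter block,
#' inline rows, or a CSV path relative to the config file), validating every
#' field and reporting failures with their field path.
#'
#' @param path Path to a YAML configuration file.
#' @param strategies Optional character vector restricting which strategy
#'   blocks must be present and are loaded; default all blocks in the file.
#' @return A `model_config` list with elements `strategies` (named list of
#'   `strategy_parameters`), `settings`, and `life_table`.
#' @export
load_model_config <- function(path, strategies = NULL) {
  if (!file.exists(path)) {
    stop_config("path", sprintf("configuration file '%s' does not exist", path))
  }
  raw <- yaml::read_yaml(path)
  check_present(raw, c("strategies", "settings"), "config")
  settings <- as_simulation_settings(raw$settings)
  hy <- if (is.numeric(settings$horizon_years)) settings$horizon_years else NULL
  hc <- if (is.numeric(settings$horizon_years)) {
    horizon_cycles(settings)
  } else {
    NULL
  }
  names_wanted <- strategies %||% names(raw$strategies)
  missing <- setdiff(names_wanted, names(raw$strategies))
  if (length(missing)) {
    stop_config(paste0("strategies.", missing[1L]), "strategy block not found")
  }
  strat <- lapply(names_wanted, function(nm) {
    as_strategy_parameters(raw$strategies[[nm]], nm, hy, hc)
  })
  names(strat) <- names_wanted

  lt_spec <- raw$life_table
  life_table <- if (is.null(lt_spec)) {
    generate_life_table()
  } else if (identical(lt_spec$type, "synthetic") || is.null(lt_spec$type) &&
             !is.null(lt_spec$base_annual_mortality_at_50)) {
    generate_life_table(
      base_annual_mortality_at_50 = lt_spec$base_annual_mortality_at_50 %||% 0.004,
      doubling_time = lt_spec$doubling_time_years %||% 8,
      anesthesia_multiplier = lt_spec$anesthesia_multiplier %||% 1,
      ages = (lt_spec$age_min %||% 18):(lt_spec$age_max %||% 100),
      sex = lt_spec$sex %||% "female"
    )
  } else if (identical(lt_spec$type, "csv")) {
    read_life_table(file.path(dirname(path), lt_spec$path))
  } else {
    stop_config("life_table.type", "must be 'synthetic' or 'csv'")
  }

  structure(list(strategies = strat, settings = settings,
                 life_table = life_table, source_path = path),
            class = "model_config")
}

#' Write a model configuration to YAML
#'
#' A synthetic life table is written back as its generating parameters, so a
#' write/load round trip reproduces the configuration exactly.
#'
#' @param config A `model_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(config, path) {
  strat <- lapply(config$strategies, function(s) {
    out <- list(
      costs = lapply(unclass(s$costs), identity),
      utilities = lapply(unclass(s$utilities), identity),
      transitions = {
        tr <- unclass(s$transitions)
        tr$revision_window <- as.integer(tr$revision_window)
        tr
      },
      inpatient_days = s$inpatient_days
    )
    for (f in c("age_mean", "age_sd", "bmi_mean", "bmi_sd",
                "nipple_sparing_pct", "followup_months_mean",
                "followup_months_sd")) {
      if (!is.null(s[[f]])) out[[f]] <- s[[f]]
    }
    if (!is.null(s$state_weights)) {
      out$state_weights <- as.list(s$state_weights)
    }
    out
  })
  settings <- unclass(config$settings)
  settings$horizon_cycles <- NULL
  lt_params <- attr(config$life_table, "synthetic_params")
  lt_block <- if (!is.null(lt_params)) {
    c(list(type = "synthetic"), lt_params)
  } else {
    list(type = "csv", path = "life_table.csv")
  }
  yaml::write_yaml(list(strategies = strat, settings = settings,
                        life_table = lt_block),
                   path, precision = 15)
  if (is.null(lt_params)) {
    write_life_table(config$life_table, file.path(dirname(path), "life_table.csv"))
  }
  invisible(path)
}

#' Path to the bundled study configuration
#'
#' The bundled `breast_recon_2024.yaml` carries the published 2024-USD cost
#' table, the trajectory-level expected B-QALY table, and cohort demographics
#' for the three arms, together with prior (uncalibrated) transition rates
#' and a synthetic life-table block. Run [calibrate_model()] to obtain the
#' calibrated configuration used in the base-case analysis.
#'
#' @return File path of the bundled YAML.
#' @export
ofaff_config_path <- function() {
  system.file("extdata", "breast_recon_2024.yaml", package = "ofaffcea",
              mustWork = TRUE)
}

#' @export
print.model_config <- function(x, ...) {
  cat("model_config:", length(x$strategies), "strategies (",
      paste(names(x$strategies), collapse = ", "), ")\n")
  cat("  horizon:", format(x$settings$horizon_years), "years;",
      "discount:", x$settings$annual_discount_rate, "/yr;",
      "n_patients:", x$settings$n_patients, "\n")
  invisible(x)
}
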