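#' @title Deterministic and probabilistic sensitivity analyses
#'
#' @description
#' One-way deterministic sensitivity re-runs the full pairwise evaluation
#' with a single input swept +/-15% from base (tornado layout). Probabilistic
#' sensitivity draws every varied parameter from a moment-matched
#' distribution -- gamma for costs, beta for proportions -- and evaluates each
#' draw with the deterministic cohort engine, so parameter (second-order)
#' uncertainty is not confounded with patient-level (first-order) noise.
#' Acceptability curves count the fraction of draws in which the
#' intervention has the higher net monetary benefit at each
#' willingness-to-pay value; ties count one half.
#'
#' @name sensitivity_analysis
NULL

#' One-way deterministic sensitivity sweep of a single input
#'
#' Evaluates the pairwise comparisons at `low = (1 - sweep) x base` and
#' `high = (1 + sweep) x base` with every other input fixed, using the
#' deterministic cohort engine. A sweep of 0 reproduces the base case
#' bit-for-bit.
#'
#' @param config A `model_config` (calibrated for the study's base case).
#' @param parameter_path Dot-separated path to a scalar input, e.g.
#'   `"strategies.O-FAFF.costs.surgical_materials"` or
#'   `"settings.horizon_years"`.
#' @param sweep Fractional sweep width (default 0.15).
#' @param pairs Strategy pairs to evaluate (default the study's two).
#' @return A `tornado_entry` list: parameter, numeric inputs at
#'   low/base/high, and the `ce_result` list at each level.
#' @export
one_way_dsa <- function(config, parameter_path, sweep = 0.15,
                        pairs = default_pairs()) {
  base <- get_config_value(config, parameter_path)
  levels <- c(low = (1 - sweep) * base, base = base, high = (1 + sweep) * base)
  outcomes <- lapply(levels, function(v) {
    evaluate_strategies(set_config_value(config, parameter_path, v), pairs)$ce
  })
  structure(list(parameter = parameter_path, sweep = sweep,
                 low = levels[["low"]], base = levels[["base"]],
                 high = levels[["high"]],
                 outcome_low = outcomes$low, outcome_base = outcomes$base,
                 outcome_high = outcomes$high),
            class = "tornado_entry")
}

format_dsa_outcome <- function(ce) {
  switch(ce$classification,
         ICER_REPORTED = sprintf("%.2f", ce$icer),
         DOMINANT = "D",
         DOMINATED = "Dominated",
         COST_SAVING_LESS_EFFECTIVE = sprintf("%.2f", ce$icer),
         EQUIVALENT = "Equivalent")
}

#' Tornado table over several inputs
#'
#' @param config A calibrated `model_config`.
#' @param parameter_paths Character vector of inputs to sweep; default the
#'   intervention's surgical + materials cost and the time horizon.
#' @param sweep Fractional sweep (default 0.15).
#' @param pairs Strategy pairs.
#' @return Data frame with one row per (parameter, pair): input values at
#'   low/base/high and the comparison outcome at each level (ICER to two
#'   decimals, or `"D"` for dominance).
#' @export
tornado <- function(config,
                    parameter_paths = c(
                      "strategies.O-FAFF.costs.surgical_materials",
                      "settings.horizon_years"),
                    sweep = 0.15, pairs = default_pairs()) {
  rows <- list()
  for (path in parameter_paths) {
    entry <- one_way_dsa(config, path, sweep, pairs)
    for (j in seq_along(pairs)) {
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = path,
        pair = paste(pairs[[j]], collapse = " versus "),
        input_low = entry$low, input_base = entry$base,
        input_high = entry$high,
        outcome_low = format_dsa_outcome(entry$outcome_low[[j]]),
        outcome_base = format_dsa_outcome(entry$outcome_base[[j]]),
        outcome_high = format_dsa_outcome(entry$outcome_high[[j]]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Moment-matched gamma distribution for a cost parameter
#'
#' `shape = mean^2/sd^2`, `scale = sd^2/mean`, so `shape x scale = mean`
#' exactly and the sampled long-run moments reproduce the inputs.
#'
#' @param mean,sd Target mean (> 0) and standard deviation (> 0).
#' @return List with `shape` and `scale`.
#' @export
moment_matched_gamma <- function(mean, sd) {
  if (!is.numeric(mean) || mean <= 0) {
    stop("gamma moment matching requires mean > 0", call. = FALSE)
  }
  if (!is.numeric(sd) || sd <= 0) {
    stop("gamma moment matching requires sd > 0", call. = FALSE)
  }
  list(shape = mean^2 / sd^2, scale = sd^2 / mean)
}

#' Moment-matched beta distribution for a proportion
#'
#' `alpha = mean x nu`, `beta = (1 - mean) x nu` with
#' `nu = mean(1 - mean)/sd^2 - 1`; requires `sd^2 < mean(1 - mean)`.
#'
#' @param mean Target mean in (0, 1).
#' @param sd Target standard deviation (> 0).
#' @return List with `alpha` and `beta`.
#' @export
moment_matched_beta <- function(mean, sd) {
  if (!is.numeric(mean) || mean <= 0 || mean >= 1) {
    stop("beta moment matching requires 0 < mean < 1", call. = FALSE)
  }
  if (!is.numeric(sd) || sd <= 0) {
    stop("beta moment matching requires sd > 0", call. = FALSE)
  }
  bound <- mean * (1 - mean)
  if (sd^2 >= bound) {
    stop(sprintf(
      "infeasible beta variance: sd^2 = %.6g must be < mean(1-mean) = %.6g",
      sd^2, bound), call. = FALSE)
  }
  nu <- bound / sd^2 - 1
  list(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Table of parameters varied in the probabilistic analysis
#'
#' Costs (every strictly positive cost entry of every arm) are assigned a
#' gamma distribution; transition proportions (monthly complication and
#' revision probabilities and the salvage split, when strictly inside
#' (0, 1)) a beta distribution. Standard deviations default to a fixed
#' fraction of the base value, mirroring the +/-15% deterministic sweep.
#'
#' @param config A `model_config`.
#' @param rel_sd Standard deviation as a fraction of base (default 0.15).
#' @return Data frame with columns `path`, `type` (`cost`/`proportion`),
#'   `base`, `sd`.
#' @export
psa_parameter_table <- function(config, rel_sd = 0.15) {
  rows <- list()
  for (nm in names(config$strategies)) {
    s <- config$strategies[[nm]]
    for (f in .cost_fields) {
      v <- s$costs[[f]]
      if (v > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          path = sprintf("strategies.%s.costs.%s", nm, f),
          type = "cost", base = v, sd = rel_sd * v,
          stringsAsFactors = FALSE)
      }
    }
    for (f in c("p_complication_monthly", "p_salvage_given_complication",
                "p_revision_monthly")) {
      v <- s$transitions[[f]]
      if (v > 0 && v < 1) {
        rows[[length(rows) + 1L]] <- data.frame(
          path = sprintf("strategies.%s.transitions.%s", nm, f),
          type = "proportion", base = v, sd = rel_sd * v,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Probabilistic sensitivity analysis
#'
#' Second-order Monte Carlo: samples `n_draws` independent parameter sets
#' from the moment-matched distributions and evaluates each with the
#' deterministic cohort engine. Reproducible by seed. A zero `rel_sd`
#' degenerates every draw to the base case.
#'
#' @param config A calibrated `model_config`.
#' @param n_draws Number of parameter draws (the study ran 5000).
#' @param seed Integer seed (default from settings).
#' @param rel_sd Relative standard deviation for every varied parameter
#'   (default 0.15); may also be overridden per parameter via `param_table`.
#' @param param_table Optional pre-built table from
#'   [psa_parameter_table()].
#' @param arms Strategy arms to evaluate (default all in the config).
#' @return A `psa_result`: `draws` data frame with per-arm discounted cost
#'   and B-QALY columns (`cost_<arm>`, `bqaly_<arm>`) plus the sampled
#'   parameter matrix, `n_draws`, and metadata.
#' @export
run_psa <- function(config, n_draws = 5000, seed = config$settings$seed,
                    rel_sd = 0.15, param_table = NULL,
                    arms = names(config$strategies)) {
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  pt <- param_table %||% psa_parameter_table(config, rel_sd)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  samples <- matrix(NA_real_, n_draws, nrow(pt),
                    dimnames = list(NULL, pt$path))
  for (j in seq_len(nrow(pt))) {
    base <- pt$base[j]; sd <- pt$sd[j]
    samples[, j] <- if (sd == 0) {
      rep(base, n_draws)
    } else if (pt$type[j] == "cost") {
      g <- moment_matched_gamma(base, sd)
      stats::rgamma(n_draws, shape = g$shape, scale = g$scale)
    } else {
      b <- moment_matched_beta(base, sd)
      stats::rbeta(n_draws, b$alpha, b$beta)
    }
  }

  cost <- matrix(NA_real_, n_draws, length(arms),
                 dimnames = list(NULL, arms))
  bqaly <- cost
  for (i in seq_len(n_draws)) {
    cfg <- config
    for (j in seq_len(ncol(samples))) {
      cfg <- set_config_value(cfg, pt$path[j], samples[i, j])
    }
    for (arm in arms) {
      res <- run_cohort(cfg$strategies[[arm]], cfg$settings, cfg$life_table)
      cost[i, arm] <- res$mean_cost
      bqaly[i, arm] <- res$mean_bqaly
    }
  }
  draws <- data.frame(draw = seq_len(n_draws))
  for (arm in arms) {
    draws[[paste0("cost_", arm)]] <- cost[, arm]
    draws[[paste0("bqaly_", arm)]] <- bqaly[, arm]
  }
  structure(list(draws = draws, samples = samples, n_draws = n_draws,
                 seed = seed, rel_sd = rel_sd, arms = arms,
                 param_table = pt),
            class = "psa_result")
}

psa_deltas <- function(psa, intervention, comparator) {
  d <- psa$draws
  list(
    delta_cost = d[[paste0("cost_", intervention)]] -
      d[[paste0("cost_", comparator)]],
    delta_effect = d[[paste0("bqaly_", intervention)]] -
      d[[paste0("bqaly_", comparator)]]
  )
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability that the intervention
#' is cost-effective is the fraction of draws in which its net monetary
#' benefit exceeds the comparator's; exact ties count one half.
#'
#' @param psa A `psa_result`.
#' @param intervention,comparator Arm names.
#' @param wtp_grid Increasing willingness-to-pay grid in USD per B-QALY
#'   (default 0 to 200,000 in 2,000-USD steps, covering the study's
#'   50k/100k/200k thresholds).
#' @return A `ceac_curve` data frame with columns `wtp`, `probability`.
#' @export
ceac <- function(psa, intervention = "O-FAFF", comparator = "IMPLANT",
                 wtp_grid = seq(0, 200000, by = 2000)) {
  if (psa$n_draws < 1 || !nrow(psa$draws)) {
    stop("evaluation error: no draws to summarise", call. = FALSE)
  }
  if (is.unsorted(wtp_grid, strictly = TRUE)) {
    stop("wtp_grid must be strictly increasing", call. = FALSE)
  }
  dd <- psa_deltas(psa, intervention, comparator)
  prob <- vapply(wtp_grid, function(w) {
    nmb <- w * dd$delta_effect - dd$delta_cost
    mean((nmb > 0) + 0.5 * (nmb == 0))
  }, 0)
  structure(data.frame(wtp = wtp_grid, probability = prob),
            class = c("ceac_curve", "data.frame"),
            intervention = intervention, comparator = comparator)
}

#' Incremental cost-effectiveness scatter
#'
#' One `(delta_effect, delta_cost)` point per draw, with quadrant counts
#' (NE: more effective & more costly; SE: more effective & cost-saving;
#' NW/SW their mirrors) attached as the `quadrants` attribute.
#'
#' @param psa A `psa_result`.
#' @param intervention,comparator Arm names.
#' @return Data frame with columns `draw`, `delta_effect`, `delta_cost`.
#' @export
incremental_scatter <- function(psa, intervention = "O-FAFF",
                                comparator = "IMPLANT") {
  dd <- psa_deltas(psa, intervention, comparator)
  out <- data.frame(draw = seq_len(psa$n_draws),
                    delta_effect = dd$delta_effect,
                    delta_cost = dd$delta_cost)
  e <- dd$delta_effect >= 0
  c_ <- dd$delta_cost >= 0
  attr(out, "quadrants") <- c(NE = sum(e & c_), NW = sum(!e & c_),
                              SE = sum(e & !c_), SW = sum(!e & !c_))
  attr(out, "intervention") <- intervention
  attr(out, "comparator") <- comparator
  out
}

#' Fraction of draws cost-effective at given thresholds
#'
#' @param psa A `psa_result`.
#' @param intervention,comparator Arm names.
#' @param wtp Vector of thresholds (default the study's 50k/100k/200k).
#' @return Named numeric vector of probabilities.
#' @export
psa_percent_cost_effective <- function(psa, intervention = "O-FAFF",
                                       comparator = "IMPLANT",
                                       wtp = c(50000, 100000, 200000)) {
  dd <- psa_deltas(psa, intervention, comparator)
  out <- vapply(wtp, function(w) {
    nmb <- w * dd$delta_effect - dd$delta_cost
    mean((nmb > 0) + 0.5 * (nmb == 0))
  }, 0)
  names(out) <- format(wtp, scientific = FALSE, trim = TRUE)
  out
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param curve A `ceac_curve`.
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$wtp, y = .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (USD per B-QALY)",
                  y = "Probability cost-effective",
                  title = sprintf("%s versus %s", attr(curve, "intervention"),
                                  attr(curve, "comparator")))
}

#' Plot the incremental cost-effectiveness scatter
#'
#' @param scatter Output of [incremental_scatter()].
#' @param wtp Willingness-to-pay line to overlay (default 50,000).
#' @return A ggplot object.
#' @export
plot_scatter <- function(scatter, wtp = 50000) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(scatter,
                  ggplot2::aes(x = .data$delta_effect, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_abline(intercept = 0, slope = wtp, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Incremental B-QALYs", y = "Incremental cost (USD)",
                  title = sprintf("%s versus %s",
                                  attr(scatter, "intervention"),
                                  attr(scatter, "comparator")))
}
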