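#' @title Incremental cost-effectiveness and dominance
#'
#' @description
#' Pairwise comparison of strategy results: incremental cost, incremental
#' effectiveness, and either an incremental cost-effectiveness ratio (ICER,
#' USD per B-QALY gained) or a dominance label. A strategy is *dominant*
#' when it costs less and is more effective than its comparator (no ICER is
#' reported), *dominated* in the mirror case. In the cost-saving but
#' less-effective quadrant a ratio is still computed (savings per B-QALY
#' forgone) but is flagged with its own classification, since a bare ICER is
#' sign-ambiguous there.
#'
#' @name economic_evaluation
NULL

#' Compare two strategy results
#'
#' @param intervention,comparator `cohort_result` objects sharing horizon
#'   and discount settings.
#' @param effect_tol Absolute B-QALY difference below which the strategies
#'   are classified EQUIVALENT (default 1e-9, guarding against division
#'   blow-ups in probabilistic draws).
#' @return A `ce_result` with `delta_cost`, `delta_effect`, `icer` (NA
#'   unless a ratio is meaningful) and `classification` in
#'   `ICER_REPORTED`, `DOMINANT`, `DOMINATED`, `COST_SAVING_LESS_EFFECTIVE`,
#'   `EQUIVALENT`.
#' @export
compute_icer <- function(intervention, comparator, effect_tol = 1e-9) {
  if (!identical(intervention$horizon_cycles, comparator$horizon_cycles) ||
      !identical(intervention$annual_discount_rate,
                 comparator$annual_discount_rate)) {
    stop("comparison error: results differ in horizon or discount settings",
         call. = FALSE)
  }
  dc <- intervention$mean_cost - comparator$mean_cost
  de <- intervention$mean_bqaly - comparator$mean_bqaly
  icer <- NA_real_
  cls <- if (abs(de) < effect_tol) {
    "EQUIVALENT"
  } else if (de > 0 && dc < 0) {
    "DOMINANT"
  } else if (de < 0 && dc > 0) {
    "DOMINATED"
  } else if (de > 0 && dc >= 0) {
    icer <- dc / de
    "ICER_REPORTED"
  } else {
    icer <- dc / de
    "COST_SAVING_LESS_EFFECTIVE"
  }
  structure(list(intervention = intervention$strategy,
                 comparator = comparator$strategy,
                 delta_cost = dc, delta_effect = de,
                 icer = icer, classification = cls),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  lab <- if (x$classification == "ICER_REPORTED") {
    sprintf("ICER %.2f USD/B-QALY", x$icer)
  } else {
    x$classification
  }
  cat(sprintf("%s vs %s: dCost %+.2f USD, dB-QALY %+.4f -> %s\n",
              x$intervention, x$comparator, x$delta_cost, x$delta_effect, lab))
  invisible(x)
}

#' Net monetary benefit
#'
#' `NMB = wtp x effectiveness - cost`, linearising the threshold decision
#' rule; used to build acceptability curves from probabilistic draws.
#'
#' @param result A `cohort_result` (or any list with `mean_cost` and
#'   `mean_bqaly`).
#' @param wtp Willingness-to-pay threshold in USD per B-QALY (>= 0).
#' @return NMB in USD.
#' @export
net_monetary_benefit <- function(result, wtp) {
  if (!is.numeric(wtp) || any(wtp < 0)) {
    stop("wtp must be non-negative", call. = FALSE)
  }
  wtp * result$mean_bqaly - result$mean_cost
}

#' Cost-effectiveness verdict at a willingness-to-pay threshold
#'
#' TRUE when the intervention is dominant; when an ICER is reported with
#' positive deltas and does not exceed the threshold; or when the
#' intervention saves money at an acceptable effectiveness loss (ratio at or
#' above the threshold in the cost-saving, less-effective quadrant). FALSE
#' when dominated. EQUIVALENT comparisons are cost-effective iff they do
#' not cost more.
#'
#' @param ce A `ce_result`.
#' @param wtp Willingness-to-pay in USD per B-QALY.
#' @return Logical flag.
#' @export
threshold_verdict <- function(ce, wtp) {
  switch(ce$classification,
         DOMINANT = TRUE,
         DOMINATED = FALSE,
         ICER_REPORTED = ce$icer <= wtp,
         COST_SAVING_LESS_EFFECTIVE = ce$icer >= wtp,
         EQUIVALENT = ce$delta_cost <= 0)
}

#' Tabulate pairwise results in the published layout
#'
#' One row per comparison with incremental cost, incremental B-QALY, and the
#' ICER formatted to two decimals (or `"Dominant"`/`"Dominated"` labels).
#'
#' @param ce_list List of `ce_result` objects.
#' @return Data frame with columns `comparison`, `incremental_cost_usd`,
#'   `incremental_bqaly`, `icer`.
#' @export
ce_table <- function(ce_list) {
  rows <- lapply(ce_list, function(ce) {
    icer_lab <- switch(ce$classification,
                       ICER_REPORTED = sprintf("%.2f", ce$icer),
                       DOMINANT = "Dominant",
                       DOMINATED = "Dominated",
                       COST_SAVING_LESS_EFFECTIVE =
                         sprintf("%.2f (cost-saving, less effective)", ce$icer),
                       EQUIVALENT = "Equivalent")
    data.frame(comparison = paste(ce$intervention, "versus", ce$comparator),
               incremental_cost_usd = round(ce$delta_cost, 2),
               incremental_bqaly = round(ce$delta_effect, 4),
               icer = icer_lab, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Evaluate both base-case comparisons of a configuration
#'
#' Runs the cohort engine for every strategy in the configuration and
#' returns the pairwise comparisons (intervention listed first in each
#' pair).
#'
#' @param config A `model_config`.
#' @param pairs List of 2-vectors `c(intervention, comparator)`; default the
#'   study's two comparisons of O-FAFF against implant and abdominal flap.
#' @return List with `results` (named list of `cohort_result`) and `ce`
#'   (list of `ce_result`).
#' @export
evaluate_strategies <- function(config, pairs = default_pairs()) {
  arms <- unique(unlist(pairs))
  missing <- setdiff(arms, names(config$strategies))
  if (length(missing)) {
    stop_config(paste0("strategies.", missing[1L]), "strategy block not found")
  }
  results <- lapply(config$strategies[arms], run_cohort,
                    settings = config$settings,
                    life_table = config$life_table)
  ce <- lapply(pairs, function(p) compute_icer(results[[p[1L]]],
                                               results[[p[2L]]]))
  names(ce) <- vapply(pairs, paste, "", collapse = "_vs_")
  list(results = results, ce = ce)
}
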