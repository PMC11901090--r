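#' @title Monthly-cycle Markov engine
#'
#' @description
#' Patients enter the model in the uncomplicated post-operative state after
#' the index reconstruction and move monthly among the five health states.
#' The same transition kernel drives two engines: [run_cohort()] propagates
#' the state-occupancy vector deterministically, and [run_microsim()] samples
#' individual patient trajectories from identical per-cycle probabilities, so
#' microsimulation means converge to the cohort expectations by construction.
#'
#' Accrual conventions: utilities and the recurring medication cost accrue at
#' end of cycle for the state occupied after that cycle's transition
#' (discount exponent `t` for cycle `t`); one-off complication/revision costs
#' are charged on the entry cycle; the index surgery bundle (surgical +
#' materials, anesthesia, hospital stay) is charged at cycle 0 undiscounted.
#' No half-cycle correction is applied, keeping the cohort engine exactly
#' comparable to the microsimulation.
#'
#' @name markov_engine
NULL

#' Per-cycle discount factor
#'
#' Twelve consecutive cycle factors compound to exactly one year of
#' discounting: `d^12 = 1/(1 + annual_rate)`.
#'
#' @param annual_rate Annual discount rate (fraction/year, >= 0).
#' @return The multiplicative monthly factor `(1 + annual_rate)^(-1/12)`.
#' @export
monthly_discount_factor <- function(annual_rate) {
  if (!is.numeric(annual_rate) || length(annual_rate) != 1L ||
      is.na(annual_rate) || annual_rate < 0) {
    stop("annual_rate must be a single non-negative number", call. = FALSE)
  }
  (1 + annual_rate)^(-1 / 12)
}

#' Discounted annuity factor over a cycle range
#'
#' Sum of `d^t` for `t` in `from:to` with `d` the monthly factor; 0 when
#' `from > to`.
#'
#' @param annual_rate Annual discount rate.
#' @param from,to First and last cycle index (1-based).
#' @return Numeric annuity factor.
#' @export
discount_annuity <- function(annual_rate, from = 1L, to) {
  if (from > to) return(0)
  d <- monthly_discount_factor(annual_rate)
  n <- to - from + 1L
  if (d == 1) return(n)
  d^from * (1 - d^n) / (1 - d)
}

# Transition kernel shared by both engines and by build_transition_matrix().
#
# Competing risks within a cycle: complications split into salvage vs loss,
# elective revision is possible only inside the revision window, and death
# takes the life-table monthly probability. The anesthesia mortality
# multiplier applies to patients undergoing surgery that cycle: everyone in
# cycle 1 (index surgery) and, afterwards, the sub-masses transitioning to
# SALVAGED (salvage surgery) or REVISED (revision surgery). Residual mass
# stays in the current state; rows are never renormalised.
#
# `q` may be a vector (per-patient mortality); all outputs follow its length.
transition_components <- function(transitions, cycle, q) {
  p_c <- transitions$p_complication_monthly
  p_sg <- transitions$p_salvage_given_complication
  w <- transitions$revision_window
  p_r <- if (cycle >= w[1L] && cycle <= w[2L]) transitions$p_revision_monthly else 0
  m <- transitions$anesthesia_mortality_multiplier

  ps_ <- p_c * p_sg
  pl_ <- p_c * (1 - p_sg)
  qs <- pmin(1, q * m)
  if (cycle == 1L) {
    # index surgery: the whole entering mass is peri-operative
    p12 <- ps_ * (1 - qs)
    p13 <- pl_ * (1 - qs)
    p14 <- p_r * (1 - qs)
    p15 <- qs
    p11 <- (1 - ps_ - pl_ - p_r) * (1 - qs)
  } else {
    p12 <- ps_ * (1 - qs)
    p13 <- pl_ * (1 - q)
    p14 <- p_r * (1 - qs)
    p15 <- (ps_ + p_r) * qs + (1 - ps_ - p_r) * q
    p11 <- (1 - ps_ - pl_ - p_r) * (1 - q)
  }
  list(p11 = p11, p12 = p12, p13 = p13, p14 = p14, p15 = p15, q_other = q)
}

#' Build the monthly transition matrix for one cycle
#'
#' Row-stochastic 5x5 matrix over [health_states()] at the given cycle and
#' patient age. The death column uses the life-table monthly probability,
#' multiplied by the strategy's anesthesia mortality multiplier in cycles
#' containing a surgical event (index surgery at cycle 1; the salvage and
#' revision sub-masses thereafter) and capped at 1. Complication mass is
#' split between SALVAGED and LOSS by `p_salvage_given_complication`;
#' elective revision is possible only from POSTOP_UNCOMPLICATED inside the
#' revision window. Residual mass stays put; rows are never renormalised.
#'
#' @param strategy A `strategy_parameters` object.
#' @param cycle Cycle index (1-based).
#' @param age Patient age in years during this cycle.
#' @param sex Sex label for the life-table lookup.
#' @param life_table A `life_table`.
#' @param cap Cap mortality at 1 beyond the life-table range (lifetime
#'   horizon) instead of raising a range error.
#' @return 5x5 numeric matrix with state dimnames; rows sum to 1 within
#'   1e-12.
#' @export
build_transition_matrix <- function(strategy, cycle, age, sex = "female",
                                    life_table, cap = FALSE) {
  q <- lookup_mortality(life_table, age, sex, cap = cap)
  k <- transition_components(strategy$transitions, cycle, q)
  states <- health_states()
  M <- matrix(0, 5L, 5L, dimnames = list(states, states))
  M[.S_POSTOP, ] <- c(k$p11, k$p12, k$p13, k$p14, k$p15)
  for (s in c(.S_SALVAGED, .S_LOSS, .S_REVISED)) {
    M[s, s] <- 1 - k$q_other
    M[s, .S_DEAD] <- k$q_other
  }
  M[.S_DEAD, .S_DEAD] <- 1
  M
}

# Resolve the per-state monthly utility weights for a strategy, deriving
# them from the trajectory targets when calibration has not stored them.
resolve_state_weights <- function(strategy, settings) {
  if (!is.null(strategy$state_weights)) {
    return(strategy$state_weights)
  }
  derive_state_utility_weights(strategy$utilities, settings,
                               strategy$transitions)
}

entry_age <- function(strategy, settings) {
  strategy$age_mean %||% settings$cohort_age_mean
}

upfront_cost <- function(strategy) {
  strategy$costs$surgical_materials + strategy$costs$anesthesia +
    strategy$costs$hospital_stay
}

#' Deterministic cohort evaluation
#'
#' Propagates the state-occupancy vector through the monthly transition
#' kernel and accumulates discounted cost and B-QALY expectations per
#' patient. The result is deterministic (independent of any seed).
#'
#' @param strategy A `strategy_parameters` object.
#' @param settings A `simulation_settings` object.
#' @param life_table A `life_table`.
#' @param keep_trace Also return the per-cycle occupancy matrix.
#' @return A `cohort_result`: strategy name, mean discounted cost (USD) and
#'   B-QALY per patient, engine tag `"cohort"`, horizon and discount
#'   metadata; with `keep_trace`, an occupancy matrix whose rows sum to 1.
#' @export
run_cohort <- function(strategy, settings, life_table, keep_trace = FALSE) {
  age0 <- entry_age(strategy, settings)
  H <- horizon_cycles(settings, age0)
  cap <- identical(settings$horizon_years, "lifetime")
  d <- monthly_discount_factor(settings$annual_discount_rate)
  w <- resolve_state_weights(strategy, settings)
  qvec <- lookup_mortality(life_table, age0 + (seq_len(H) - 1) / 12,
                           settings$cohort_sex, cap = cap)
  cs <- strategy$costs
  pain <- cs$pain_medication_monthly

  occ <- c(1, 0, 0, 0, 0)
  trace <- if (keep_trace) matrix(NA_real_, H + 1L, 5L,
                                  dimnames = list(NULL, health_states()))
  if (keep_trace) trace[1L, ] <- occ
  cost <- upfront_cost(strategy)  # cycle 0, undiscounted
  bqaly <- 0
  dt <- 1
  for (t in seq_len(H)) {
    k <- transition_components(strategy$transitions, t, qvec[t])
    o <- occ[1L]
    in_s <- o * k$p12
    in_l <- o * k$p13
    in_r <- o * k$p14
    surv <- 1 - k$q_other
    occ <- c(o * k$p11,
             occ[2L] * surv + in_s,
             occ[3L] * surv + in_l,
             occ[4L] * surv + in_r,
             occ[5L] + o * k$p15 + (occ[2L] + occ[3L] + occ[4L]) * k$q_other)
    dt <- dt * d
    alive <- 1 - occ[5L]
    cost <- cost + dt * (in_s * cs$salvage + in_l * cs$loss +
                           in_r * cs$revision + alive * pain)
    bqaly <- bqaly + dt * sum(occ[1:4] * w[1:4])
    if (keep_trace) trace[t + 1L, ] <- occ
  }
  structure(list(strategy = strategy$name, mean_cost = cost,
                 mean_bqaly = bqaly, se_cost = NA_real_, se_bqaly = NA_real_,
                 n_patients = NA_integer_, engine = "cohort",
                 horizon_cycles = H,
                 annual_discount_rate = settings$annual_discount_rate,
                 age_entry = age0,
                 trace = if (keep_trace) trace),
            class = "cohort_result")
}

#' Expected B-QALY of the never-complicated trajectory
#'
#' Evaluates the strategy through the cohort engine with all event rates and
#' mortality set to zero, so every patient remains in the uncomplicated
#' state for the whole horizon. By construction of the derived state weights
#' this reproduces the strategy's `no_complication` utility target.
#'
#' @param strategy A `strategy_parameters` object.
#' @param settings A `simulation_settings` object.
#' @return Discounted B-QALY of the uncomplicated trajectory.
#' @export
uncomplicated_bqaly <- function(strategy, settings) {
  s0 <- strategy
  s0$transitions$p_complication_monthly <- 0
  s0$transitions$p_revision_monthly <- 0
  if (is.null(s0$state_weights)) {
    # weights must reflect the *actual* rates' event timing, not the zeroed ones
    s0$state_weights <- derive_state_utility_weights(strategy$utilities,
                                                     settings,
                                                     strategy$transitions)
  }
  ages <- 18:100
  lt0 <- data.frame(age = ages, sex = "female",
                    monthly_death_probability = 0)
  class(lt0) <- c("life_table", "data.frame")
  run_cohort(s0, settings, lt0)$mean_bqaly
}

# Deterministic per-patient substream seed below 2^31, independent of
# execution order.
substream_seed <- function(seed, patient_id) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(patient_id)
  as.integer(s %% 2147483647 + 1)
}

patient_uniforms <- function(seed, patient_id, n_cycles) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(substream_seed(seed, patient_id))
  stats::runif(n_cycles)
}

# shared categorical draw: next state j is the smallest j with u < cumsum[j]
sample_from_cum <- function(cum4, u) {
  as.integer(unname(1L + (u >= cum4[1L]) + (u >= cum4[2L]) +
                      (u >= cum4[3L]) + (u >= cum4[4L])))
}

#' Simulate a single patient trajectory
#'
#' Samples one stochastic trajectory cycle-by-cycle from the same transition
#' kernel as the cohort engine, using a per-patient random substream derived
#' from `(seed, patient_id)` so results are reproducible and independent of
#' execution order.
#'
#' @param strategy A `strategy_parameters` object.
#' @param settings A `simulation_settings` object.
#' @param life_table A `life_table`.
#' @param seed Master seed.
#' @param patient_id Patient index (1-based) selecting the substream.
#' @param age Entry age; defaults to the strategy's (or cohort's) mean age.
#' @return A `trajectory_record`: integer state sequence (ending at the
#'   first DEAD entry or the horizon), an event log, and discounted cost and
#'   B-QALY totals.
#' @export
simulate_patient <- function(strategy, settings, life_table,
                             seed = settings$seed, patient_id = 1L,
                             age = NULL) {
  age0 <- age %||% entry_age(strategy, settings)
  H <- horizon_cycles(settings, age0)
  cap <- identical(settings$horizon_years, "lifetime")
  d <- monthly_discount_factor(settings$annual_discount_rate)
  w <- unname(c(resolve_state_weights(strategy, settings)))
  cs <- strategy$costs
  u <- patient_uniforms(seed, patient_id, H)

  state <- .S_POSTOP
  states <- integer(0)
  events <- list()
  cost <- upfront_cost(strategy)
  bqaly <- 0
  dt <- 1
  for (t in seq_len(H)) {
    M <- build_transition_matrix(strategy, t, age0 + (t - 1) / 12,
                                 settings$cohort_sex, life_table, cap = cap)
    cum <- cumsum(M[state, ])[1:4]
    nxt <- sample_from_cum(cum, u[t])
    dt <- dt * d
    if (nxt != state) {
      ev <- switch(nxt,
                   NULL,
                   {cost <- cost + dt * cs$salvage; c("complication", "salvage")},
                   {cost <- cost + dt * cs$loss; c("complication", "loss")},
                   {cost <- cost + dt * cs$revision; "revision"},
                   "death")
      for (e in ev) events[[length(events) + 1L]] <- list(event = e, cycle = t)
    }
    if (nxt != .S_DEAD) {
      cost <- cost + dt * cs$pain_medication_monthly
      bqaly <- bqaly + dt * w[nxt]
    }
    state <- nxt
    states <- c(states, state)
    if (state == .S_DEAD) break
  }
  event_log <- if (length(events)) {
    data.frame(event = vapply(events, `[[`, "", "event"),
               cycle = vapply(events, `[[`, 1L, "cycle"))
  } else {
    data.frame(event = character(0), cycle = integer(0))
  }
  structure(list(states = states, events = event_log,
                 discounted_cost = cost, discounted_bqaly = bqaly,
                 age_entry = age0, horizon_cycles = H),
            class = "trajectory_record")
}

#' Monte Carlo microsimulation of a patient cohort
#'
#' Runs `n_patients` independent trajectories through the transition kernel
#' (vectorised across patients, but drawing each patient's uniforms from the
#' same per-patient substream as [simulate_patient()], so a single patient's
#' trajectory is identical under either entry point) and summarises the
#' discounted outcomes.
#'
#' @param strategy A `strategy_parameters` object.
#' @param settings A `simulation_settings` object.
#' @param life_table A `life_table`.
#' @param seed Master seed (default from settings).
#' @param n_patients Cohort size (default from settings).
#' @param ages Optional vector of entry ages (length 1 or `n_patients`);
#'   default is the strategy's mean entry age for every patient, matching
#'   the cohort engine's expectation.
#' @param keep_trajectories Also return the per-patient state matrix and
#'   outcome vectors.
#' @return A `cohort_result` with engine tag `"microsim"`, means and
#'   standard errors of discounted cost and B-QALY; `se_undefined` is TRUE
#'   when `n_patients < 2`.
#' @export
run_microsim <- function(strategy, settings, life_table,
                         seed = settings$seed,
                         n_patients = settings$n_patients,
                         ages = NULL, keep_trajectories = FALSE) {
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  n <- as.integer(n_patients)
  age0 <- ages %||% entry_age(strategy, settings)
  if (length(age0) == 1L) age0 <- rep(age0, n)
  if (length(age0) != n) stop("ages must have length 1 or n_patients",
                              call. = FALSE)
  H <- horizon_cycles(settings, min(age0))
  cap <- identical(settings$horizon_years, "lifetime")
  d <- monthly_discount_factor(settings$annual_discount_rate)
  w <- unname(c(resolve_state_weights(strategy, settings)))
  cs <- strategy$costs
  pain <- cs$pain_medication_monthly

  U <- matrix(NA_real_, n, H)
  for (i in seq_len(n)) U[i, ] <- patient_uniforms(seed, i, H)

  state <- rep(.S_POSTOP, n)
  cost <- rep(upfront_cost(strategy), n)
  bqaly <- numeric(n)
  traj <- if (keep_trajectories) matrix(NA_integer_, n, H)
  cost_cycle <- if (keep_trajectories) matrix(0, n, H)
  qaly_cycle <- if (keep_trajectories) matrix(0, n, H)
  dt <- 1
  for (t in seq_len(H)) {
    q <- lookup_mortality(life_table, age0 + (t - 1) / 12,
                          settings$cohort_sex, cap = cap)
    k <- transition_components(strategy$transitions, t, q)
    dt <- dt * d
    u <- U[, t]
    nxt <- state
    ip <- state == .S_POSTOP
    if (any(ip)) {
      c1 <- k$p11; c2 <- c1 + k$p12; c3 <- c2 + k$p13; c4 <- c3 + k$p14
      pick <- function(x, idx) if (length(x) > 1L) x[idx] else x
      ui <- u[ip]
      nxt[ip] <- 1L + (ui >= pick(c1, ip)) + (ui >= pick(c2, ip)) +
        (ui >= pick(c3, ip)) + (ui >= pick(c4, ip))
    }
    io <- state %in% c(.S_SALVAGED, .S_LOSS, .S_REVISED)
    if (any(io)) {
      qo <- if (length(k$q_other) > 1L) k$q_other[io] else k$q_other
      die <- u[io] >= 1 - qo
      nxt[io] <- ifelse(die, .S_DEAD, state[io])
    }
    entered <- nxt != state
    alive <- nxt != .S_DEAD
    dcost_t <- dt * ((entered & nxt == .S_SALVAGED) * cs$salvage +
                       (entered & nxt == .S_LOSS) * cs$loss +
                       (entered & nxt == .S_REVISED) * cs$revision +
                       alive * pain)
    dqaly_t <- dt * w[nxt] * alive
    cost <- cost + dcost_t
    bqaly <- bqaly + dqaly_t
    state <- nxt
    if (keep_trajectories) {
      traj[, t] <- state
      cost_cycle[, t] <- dcost_t
      qaly_cycle[, t] <- dqaly_t
    }
  }
  se_undef <- n < 2L
  structure(list(strategy = strategy$name,
                 mean_cost = mean(cost), mean_bqaly = mean(bqaly),
                 se_cost = if (se_undef) NA_real_ else stats::sd(cost) / sqrt(n),
                 se_bqaly = if (se_undef) NA_real_ else stats::sd(bqaly) / sqrt(n),
                 se_undefined = se_undef,
                 n_patients = n, engine = "microsim",
                 horizon_cycles = H,
                 annual_discount_rate = settings$annual_discount_rate,
                 age_entry = age0[1L],
                 costs = if (keep_trajectories) cost,
                 bqalys = if (keep_trajectories) bqaly,
                 trajectories = if (keep_trajectories) traj,
                 cost_cycle = if (keep_trajectories) cost_cycle,
                 qaly_cycle = if (keep_trajectories) qaly_cycle),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("%s [%s]: cost %.2f USD, B-QALY %.4f", x$strategy, x$engine,
              x$mean_cost, x$mean_bqaly))
  if (!is.na(x$se_cost)) {
    cat(sprintf(" (SE %.2f / %.5f, n = %d)", x$se_cost, x$se_bqaly,
                x$n_patients))
  }
  cat("\n")
  invisible(x)
}

#' Export patient trajectories to CSV or JSONL
#'
#' Deterministic column order `(patient_id, cycle, state, event, cost_cycle,
#' qaly_cycle)`; events are the state-entry labels.
#'
#' @param microsim A `cohort_result` from [run_microsim()] with
#'   `keep_trajectories = TRUE`.
#' @param path Output path; format chosen by extension (`.csv` or `.jsonl`).
#' @return `path`, invisibly.
#' @export
export_trajectories <- function(microsim, path) {
  traj <- microsim$trajectories
  if (is.null(traj)) {
    stop("run_microsim must be called with keep_trajectories = TRUE",
         call. = FALSE)
  }
  states <- health_states()
  n <- nrow(traj); H <- ncol(traj)
  prev <- cbind(rep(.S_POSTOP, n), traj[, -H, drop = FALSE])
  event <- matrix("", n, H)
  event[traj != prev & traj == .S_SALVAGED] <- "salvage"
  event[traj != prev & traj == .S_LOSS] <- "loss"
  event[traj != prev & traj == .S_REVISED] <- "revision"
  event[traj != prev & traj == .S_DEAD] <- "death"
  df <- data.frame(patient_id = rep(seq_len(n), H),
                   cycle = rep(seq_len(H), each = n),
                   state = states[as.vector(traj)],
                   event = as.vector(event),
                   cost_cycle = as.vector(microsim$cost_cycle),
                   qaly_cycle = as.vector(microsim$qaly_cycle),
                   stringsAsFactors = FALSE)
  df <- df[order(df$patient_id, df$cycle), ]
  if (grepl("\\.jsonl$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(df))) {
      writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE), con)
    }
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
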