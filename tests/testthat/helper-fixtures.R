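# Fixtures built in code: small strategies, degenerate life tables, and a
# session-cached calibrated study configuration (calibration is
# deterministic, so caching only saves time).

.fixture_env <- new.env()

bundled_config <- function() {
  if (is.null(.fixture_env$bundled)) {
    .fixture_env$bundled <- load_model_config(ofaff_config_path())
  }
  .fixture_env$bundled
}

calibrated_config <- function() {
  if (is.null(.fixture_env$calibrated)) {
    .fixture_env$calibrated <- calibrate_model(bundled_config())
  }
  .fixture_env$calibrated
}

# life table with constant monthly mortality for every adult age
flat_life_table <- function(q = 0) {
  lt <- data.frame(age = 18:100, sex = "female",
                   monthly_death_probability = q)
  class(lt) <- c("life_table", "data.frame")
  lt
}

# minimal strategy: unit upfront cost components, configurable rates
toy_strategy <- function(name = "O-FAFF",
                         p_complication = 0, p_salvage = 0.7,
                         p_revision = 0, window = c(7L, 24L),
                         multiplier = 1,
                         pain = 0,
                         utilities = list(no_complication = 3.74, loss = 0.03,
                                          salvage = 3.48, revision = 3.49)) {
  as_strategy_parameters(list(
    costs = list(surgical_materials = 1000, anesthesia = 100,
                 hospital_stay = 500, salvage = 200, loss = 300,
                 revision = 400, pain_medication_monthly = pain),
    utilities = utilities,
    transitions = list(p_complication_monthly = p_complication,
                       p_salvage_given_complication = p_salvage,
                       p_revision_monthly = p_revision,
                       revision_window = window,
                       anesthesia_mortality_multiplier = multiplier),
    age_mean = 50, age_sd = 0
  ), name)
}

toy_settings <- function(horizon_years = 5, discount = 0.03, ...) {
  as_simulation_settings(c(list(horizon_years = horizon_years,
                                annual_discount_rate = discount,
                                cohort_age_mean = 50, cohort_age_sd = 0),
                           list(...)))
}

# small two-arm configuration over a 2-year horizon (utility targets scaled
# to stay feasible in 24 cycles), for cheap calibration round trips
toy_config <- function() {
  mk <- function(name, surgical, p_c, p_sg, p_rev, u) {
    as_strategy_parameters(list(
      costs = list(surgical_materials = surgical, anesthesia = 500,
                   hospital_stay = 2000, salvage = 1500, loss = 300,
                   revision = 1574, pain_medication_monthly = 0),
      utilities = u,
      transitions = list(p_complication_monthly = p_c,
                         p_salvage_given_complication = p_sg,
                         p_revision_monthly = p_rev,
                         revision_window = c(7L, 20L),
                         anesthesia_mortality_multiplier = 1.5),
      age_mean = 50, age_sd = 0
    ), name)
  }
  strategies <- list(
    "O-FAFF" = mk("O-FAFF", 8000, 0.002, 0.9, 0.005,
                  list(no_complication = 1.80, loss = 0.02,
                       salvage = 1.70, revision = 1.71)),
    "IMPLANT" = mk("IMPLANT", 5000, 0.010, 0.5, 0.020,
                   list(no_complication = 1.60, loss = 0.05,
                        salvage = 1.50, revision = 1.51))
  )
  settings <- toy_settings(horizon_years = 2)
  cfg <- structure(list(strategies = strategies, settings = settings,
                        life_table = flat_life_table(0.0005)),
                   class = "model_config")
  for (nm in names(cfg$strategies)) {
    s <- cfg$strategies[[nm]]
    cfg$strategies[[nm]]$state_weights <-
      derive_state_utility_weights(s$utilities, cfg$settings, s$transitions)
  }
  cfg
}

# independent brute-force discounted annuity (loop, no closed form)
annuity_oracle <- function(rate, from, to) {
  d <- (1 + rate)^(-1 / 12)
  total <- 0
  for (t in from:to) total <- total + d^t
  total
}
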