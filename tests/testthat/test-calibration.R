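test_that("derived weights reproduce trajectory targets and closed forms", {
  set_ <- toy_settings(5, 0.03)
  # null utility: all-zero weights
  u0 <- list(no_complication = 0, loss = 0, salvage = 0, revision = 0)
  w0 <- derive_state_utility_weights(u0, set_)
  expect_equal(unname(w0), rep(0, 5))

  # perfect health without discounting: monthly weight exactly 1/12
  set0 <- toy_settings(5, 0)
  u5 <- list(no_complication = 5, loss = 0, salvage = 5, revision = 5)
  w5 <- derive_state_utility_weights(u5, set0)
  expect_equal(unname(w5["POSTOP_UNCOMPLICATED"]), 1 / 12, tolerance = 1e-12)

  # infeasible target: more than 1 B-QALY per year cannot be accrued
  u_bad <- list(no_complication = 5.5, loss = 0, salvage = 5, revision = 5)
  expect_error(derive_state_utility_weights(u_bad, set0), "infeasible")

  # weights never leave [0, 1/12]
  cfg <- calibrated_config()$config
  for (nm in names(cfg$strategies)) {
    w <- cfg$strategies[[nm]]$state_weights
    expect_true(all(w >= 0 & w <= 1 / 12 + 1e-12))
    expect_equal(unname(w["DEAD"]), 0)
  }
})

test_that("uncomplicated trajectories accrue the published B-QALYs through the engine", {
  cfg <- calibrated_config()$config
  targets <- c("O-FAFF" = 3.74, "ABDOMINAL_FLAP" = 3.55, "IMPLANT" = 3.38)
  for (nm in names(targets)) {
    expect_equal(uncomplicated_bqaly(cfg$strategies[[nm]], cfg$settings),
                 unname(targets[nm]), tolerance = 1e-6)
  }
})

test_that("an empty target list leaves the configuration unchanged", {
  cfg <- bundled_config()
  fit <- calibrate_transition_rates(cfg, targets = list())
  expect_true(fit$converged)
  expect_identical(fit$config$strategies[["IMPLANT"]]$transitions,
                   cfg$strategies[["IMPLANT"]]$transitions)
})

test_that("a single monotone rate is recovered against a grid-search oracle", {
  cfg <- toy_config()
  target <- list(quantity = "incremental_bqaly",
                 pair = c("O-FAFF", "IMPLANT"), value = 0.35,
                 tolerance = 1e-4)
  path <- "strategies.IMPLANT.transitions.p_complication_monthly"

  # independent oracle: dense grid over the bounded range
  grid <- seq(1e-5, 0.05, length.out = 10000)
  ofaff <- run_cohort(cfg$strategies[["O-FAFF"]], cfg$settings, cfg$life_table)
  dev <- vapply(grid, function(p) {
    c2 <- set_config_value(cfg, path, p)
    imp <- run_cohort(c2$strategies[["IMPLANT"]], c2$settings, c2$life_table)
    abs(ofaff$mean_bqaly - imp$mean_bqaly - target$value)
  }, 0)
  oracle_root <- grid[which.min(dev)]

  fit <- calibrate_transition_rates(cfg, targets = list(target),
                                    free = list(list(path = path,
                                                     lower = 1e-5,
                                                     upper = 0.05)))
  expect_true(fit$converged)
  expect_lt(abs(unname(fit$rates[path]) - oracle_root), 1e-5)
})

test_that("the full study calibration reproduces the published incrementals", {
  fit <- calibrated_config()
  expect_true(fit$converged)
  rep_ <- fit$report
  get_res <- function(q, comp) {
    rep_$residual[rep_$quantity == q & grepl(comp, rep_$pair)]
  }
  expect_lt(abs(get_res("incremental_cost", "IMPLANT")), 100)
  expect_lt(abs(get_res("incremental_bqaly", "IMPLANT")), 0.02)
  expect_lt(abs(get_res("incremental_cost", "ABDOMINAL")), 100)
  expect_lt(abs(get_res("incremental_bqaly", "ABDOMINAL")), 0.02)

  ev <- evaluate_strategies(fit$config)
  expect_equal(ev$ce[[1]]$icer, 9712.64, tolerance = 5e-3)
  expect_equal(ev$ce[[2]]$classification, "DOMINANT")

  # calibrated rates respect the documented qualitative ordering
  p_c <- vapply(fit$config$strategies,
                function(s) s$transitions$p_complication_monthly, 0)
  expect_lt(p_c[["O-FAFF"]], p_c[["ABDOMINAL_FLAP"]])
  expect_lt(p_c[["ABDOMINAL_FLAP"]], p_c[["IMPLANT"]])
})

test_that("calibration recovers deltas generated by random ground-truth rates", {
  base <- toy_config()
  free <- list(
    list(path = "strategies.IMPLANT.transitions.p_complication_monthly",
         lower = 1e-5, upper = 0.05),
    list(path = "strategies.IMPLANT.costs.pain_medication_monthly",
         lower = 0, upper = 300)
  )
  set.seed(12345)
  for (rep_i in 1:20) {
    truth <- base
    truth <- set_config_value(truth, free[[1]]$path, runif(1, 0.001, 0.04))
    truth <- set_config_value(truth, free[[2]]$path, runif(1, 5, 250))
    ev <- evaluate_strategies(truth, pairs = list(c("O-FAFF", "IMPLANT")))$ce[[1]]
    targets <- list(
      list(quantity = "incremental_cost", pair = c("O-FAFF", "IMPLANT"),
           value = ev$delta_cost, tolerance = 1e-3),
      list(quantity = "incremental_bqaly", pair = c("O-FAFF", "IMPLANT"),
           value = ev$delta_effect, tolerance = 1e-3)
    )
    fit <- calibrate_transition_rates(base, targets = targets, free = free,
                                      max_sweeps = 100, objective_tol = 1e-16)
    expect_true(all(abs(fit$report$residual) <= 1e-3))
  }
})

test_that("synthetic cohorts match their specification", {
  coh <- generate_synthetic_cohort(49, 8, n = 10000, seed = 99)
  expect_equal(nrow(coh), 10000)
  expect_lt(abs(mean(coh$age) - 49), 0.5)
  expect_true(all(coh$age >= 18 & coh$age <= 100))
  expect_true(all(coh$sex == "female"))

  degenerate <- generate_synthetic_cohort(49, 0, n = 5, seed = 1)
  expect_equal(degenerate$age, rep(49, 5))

  empty <- generate_synthetic_cohort(49, 8, n = 0, seed = 1)
  expect_equal(nrow(empty), 0)

  # reproducible by seed
  a <- generate_synthetic_cohort(51, 9, n = 50, seed = 7)
  b <- generate_synthetic_cohort(51, 9, n = 50, seed = 7)
  expect_identical(a, b)
})

test_that("calibration reports serialise to JSON", {
  fit <- calibrated_config()
  path <- file.path(tempdir(), "calibration_report.json")
  write_calibration_report(fit, path)
  rep_ <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_true(rep_$converged)
  expect_equal(nrow(rep_$report), 4)
  expect_equal(rep_$report$achieved, fit$report$achieved, tolerance = 1e-9)
})
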