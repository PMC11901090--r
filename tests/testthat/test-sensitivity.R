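test_that("moment matching recovers closed forms and rejects infeasible inputs", {
  g <- moment_matched_gamma(1, 1)
  expect_equal(g$shape, 1)
  expect_equal(g$scale, 1)
  # shape x scale = mean algebraically for arbitrary inputs
  g2 <- moment_matched_gamma(7974.48, 0.15 * 7974.48)
  expect_equal(g2$shape * g2$scale, 7974.48, tolerance = 1e-12)
  expect_error(moment_matched_gamma(0, 1), "mean > 0")
  expect_error(moment_matched_gamma(1, 0), "sd > 0")

  # sd^2 = 1/12 at mean 0.5 gives the uniform distribution
  b <- moment_matched_beta(0.5, sqrt(1 / 12) * (1 - 1e-9))
  expect_equal(b$alpha, 1, tolerance = 1e-6)
  expect_equal(b$beta, 1, tolerance = 1e-6)
  expect_error(moment_matched_beta(0.5, 0.5), "infeasible beta variance")
  expect_error(moment_matched_beta(1.2, 0.1), "0 < mean < 1")
})

test_that("gamma and beta samplers recover their target moments", {
  n <- 1e5
  set.seed(101)
  g <- moment_matched_gamma(7974.48, 0.15 * 7974.48)
  x <- rgamma(n, shape = g$shape, scale = g$scale)
  expect_equal(mean(x), 7974.48, tolerance = 0.01)
  expect_equal(sd(x), 0.15 * 7974.48, tolerance = 0.01)

  b <- moment_matched_beta(0.1, 0.015)
  y <- rbeta(n, b$alpha, b$beta)
  expect_equal(mean(y), 0.1, tolerance = 0.01)
  expect_equal(sd(y), 0.015, tolerance = 0.01)
  # smoke test that the sample is consistent with the intended family
  ks <- suppressWarnings(ks.test(y, pbeta, b$alpha, b$beta))
  expect_gt(ks$p.value, 0.01)
})

test_that("a zero-width sweep reproduces the base case bit-for-bit", {
  cfg <- calibrated_config()$config
  entry <- one_way_dsa(cfg, "strategies.O-FAFF.costs.surgical_materials",
                       sweep = 0)
  expect_identical(entry$low, entry$base)
  expect_identical(entry$outcome_low, entry$outcome_base)
  expect_identical(entry$outcome_high, entry$outcome_base)
  base_ce <- evaluate_strategies(cfg)$ce
  expect_identical(entry$outcome_base[[1]]$icer, base_ce[[1]]$icer)
  expect_identical(entry$outcome_base[[2]]$classification,
                   base_ce[[2]]$classification)
})

test_that("ICER responds monotonically to the intervention's surgical cost", {
  cfg <- calibrated_config()$config
  path <- "strategies.O-FAFF.costs.surgical_materials"
  base <- get_config_value(cfg, path)
  icers <- vapply(seq(0.85, 1.15, length.out = 5), function(f) {
    ce <- evaluate_strategies(set_config_value(cfg, path, f * base),
                              pairs = list(c("O-FAFF", "IMPLANT")))$ce[[1]]
    ce$icer
  }, 0)
  expect_false(is.unsorted(icers))
})

test_that("dominance over the abdominal flap survives the +/-15% sweeps", {
  cfg <- calibrated_config()$config
  tor <- tornado(cfg, sweep = 0.15)
  abd <- tor[tor$pair == "O-FAFF versus ABDOMINAL_FLAP", ]
  expect_equal(nrow(abd), 2)  # surgical cost and time horizon rows
  expect_true(all(abd$outcome_low == "D" & abd$outcome_base == "D" &
                    abd$outcome_high == "D"))
  # horizon sweep of +/-15% of 5 years lands on 51 and 69 cycles
  hz <- tor[tor$parameter == "settings.horizon_years", ][1, ]
  expect_equal(round(hz$input_low * 12), 51)
  expect_equal(round(hz$input_high * 12), 69)
  expect_error(one_way_dsa(cfg, "strategies.O-FAFF.costs.nonexistent"),
               "does not resolve")
})

test_that("degenerate and repeated probabilistic analyses are deterministic", {
  cfg <- calibrated_config()$config
  base <- evaluate_strategies(cfg)
  # all sds zero: every draw equals the base case
  psa0 <- run_psa(cfg, n_draws = 4, seed = 5, rel_sd = 0)
  for (arm in names(cfg$strategies)) {
    expect_equal(psa0$draws[[paste0("cost_", arm)]],
                 rep(base$results[[arm]]$mean_cost, 4), tolerance = 1e-12)
  }
  # same seed twice: identical outputs
  a <- run_psa(cfg, n_draws = 40, seed = 9)
  b <- run_psa(cfg, n_draws = 40, seed = 9)
  expect_identical(a$draws, b$draws)
  expect_error(run_psa(cfg, n_draws = 0), "n_draws")
})

test_that("PSA draws centre on the base case deltas", {
  cfg <- calibrated_config()$config
  base <- evaluate_strategies(cfg)$ce
  psa <- run_psa(cfg, n_draws = 400, seed = 31)
  for (i in 1:2) {
    pair <- default_pairs()[[i]]
    sc <- incremental_scatter(psa, pair[1], pair[2])
    for (f in c("delta_cost", "delta_effect")) {
      se <- sd(sc[[f]]) / sqrt(nrow(sc))
      expect_lt(abs(mean(sc[[f]]) - base[[i]][[f]]), 3 * se + 1e-9)
    }
  }
})

test_that("acceptability curves match a hand-enumerated four-draw set", {
  # four draws, all with delta effect +1 and delta costs 10, 20, 30, 40:
  # at wtp w the intervention wins when w > delta cost
  draws <- data.frame(draw = 1:4,
                      cost_A = c(10, 20, 30, 40), bqaly_A = 2,
                      cost_B = 0, bqaly_B = 1)
  psa <- structure(list(draws = draws, n_draws = 4L, arms = c("A", "B")),
                   class = "psa_result")
  cc <- ceac(psa, "A", "B", wtp_grid = c(5, 15, 35, 45))
  expect_equal(cc$probability, c(0, 0.25, 0.75, 1))
  # exact ties count one half
  cc_tie <- ceac(psa, "A", "B", wtp_grid = c(10, 20))
  expect_equal(cc_tie$probability, c(0.125, 0.375))
  expect_error(ceac(psa, "A", "B", wtp_grid = c(2, 1)), "increasing")
})

test_that("CEAC is monotone and limits to the positive-effect fraction", {
  cfg <- calibrated_config()$config
  psa <- run_psa(cfg, n_draws = 300, seed = 17)
  cc <- ceac(psa, "O-FAFF", "IMPLANT")
  expect_false(is.unsorted(cc$probability))
  sc <- incremental_scatter(psa, "O-FAFF", "IMPLANT")
  frac_pos <- mean(sc$delta_effect > 0)
  big <- ceac(psa, "O-FAFF", "IMPLANT", wtp_grid = 1e12)
  expect_equal(big$probability, frac_pos)
})

test_that("scatter quadrants partition the draws", {
  cfg <- calibrated_config()$config
  psa <- run_psa(cfg, n_draws = 200, seed = 23)
  for (pair in default_pairs()) {
    sc <- incremental_scatter(psa, pair[1], pair[2])
    q <- attr(sc, "quadrants")
    expect_equal(sum(q), 200)
    expect_equal(nrow(sc), 200)
  }
  # a draw set that is dominant everywhere sits entirely in the SE quadrant
  draws <- data.frame(draw = 1:3, cost_A = -c(1, 2, 3), bqaly_A = 2,
                      cost_B = 0, bqaly_B = 1)
  psa_d <- structure(list(draws = draws, n_draws = 3L, arms = c("A", "B")),
                     class = "psa_result")
  sc_d <- incremental_scatter(psa_d, "A", "B")
  expect_equal(unname(attr(sc_d, "quadrants")["SE"]), 3)
  cc_d <- ceac(psa_d, "A", "B", wtp_grid = c(0, 50000))
  expect_equal(cc_d$probability, c(1, 1))
})
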