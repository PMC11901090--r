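#' Generate a synthetic Gompertz-style life table
#'
#' Stands in for national all-cause mortality statistics, which cannot be
#' redistributed with the package: annual mortality doubles every
#' `doubling_time` years around an anchor value at age 50, which is the
#' classical Gompertz shape of adult all-cause mortality. Annual
#' probabilities are converted to monthly ones via
#' `q_m = 1 - (1 - q_a)^(1/12)` and capped just below 1.
#'
#' @param base_annual_mortality_at_50 Annual death probability at age 50
#'   (default 0.004, in the range of published all-cause rates for women in
#'   mid-life).
#' @param doubling_time Years per doubling of annual mortality (default 8).
#' @param anesthesia_multiplier Peri-operative mortality multiplier carried
#'   as metadata (a configuration may reference it as the default for the
#'   per-arm `anesthesia_mortality_multiplier`); it is not applied to the
#'   table rows themselves.
#' @param ages Integer ages covered (default 18 to 100).
#' @param sex Sex label for the rows (default "female"; the modelled cohort
#'   is post-mastectomy and entirely female).
#' @return A `life_table` data frame with columns `age`, `sex`,
#'   `monthly_death_probability`, carrying its generating parameters as the
#'   `synthetic_params` attribute.
#' @export
generate_life_table <- function(base_annual_mortality_at_50 = 0.004,
                                doubling_time = 8,
                                anesthesia_multiplier = 1,
                                ages = 18:100,
                                sex = "female") {
  if (!is.numeric(base_annual_mortality_at_50) ||
      base_annual_mortality_at_50 <= 0 || base_annual_mortality_at_50 >= 1) {
    stop("base_annual_mortality_at_50 must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(doubling_time) || doubling_time <= 0) {
    stop("doubling_time must be > 0", call. = FALSE)
  }
  q_annual <- base_annual_mortality_at_50 * 2^((ages - 50) / doubling_time)
  if (any(q_annual >= 1)) {
    warning("annual mortality reaches 1 within the age range; capping",
            call. = FALSE)
    q_annual <- pmin(q_annual, 1 - 1e-12)
  }
  q_monthly <- 1 - (1 - q_annual)^(1 / 12)
  out <- data.frame(age = as.integer(ages), sex = sex,
                    monthly_death_probability = q_monthly,
                    stringsAsFactors = FALSE)
  attr(out, "synthetic_params") <- list(
    base_annual_mortality_at_50 = base_annual_mortality_at_50,
    doubling_time_years = doubling_time,
    anesthesia_multiplier = anesthesia_multiplier,
    age_min = min(ages), age_max = max(ages), sex = sex
  )
  class(out) <- c("life_table", "data.frame")
  out
}

#' Read a life table from CSV
#'
#' Expects the header `age,sex,monthly_death_probability`.
#'
#' @param path CSV path.
#' @return A validated `life_table` data frame.
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_life_table(df)
}

#' Write a life table to CSV
#'
#' @param life_table A `life_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(life_table, path) {
  utils::write.csv(
    life_table[, c("age", "sex", "monthly_death_probability")],
    path, row.names = FALSE)
  invisible(path)
}

#' Validate a life table
#'
#' Checks column presence, probability range `[0, 1)`, and monotone
#' non-decreasing mortality in age beyond 30 within each sex.
#'
#' @param df Data frame with columns `age`, `sex`,
#'   `monthly_death_probability`.
#' @return The validated `life_table`.
#' @export
validate_life_table <- function(df) {
  check_present(df, c("age", "sex", "monthly_death_probability"), "life_table")
  q <- df$monthly_death_probability
  if (any(!is.finite(q)) || any(q < 0) || any(q >= 1)) {
    stop_config("life_table.monthly_death_probability",
                "probabilities must lie in [0, 1)")
  }
  for (s in unique(df$sex)) {
    sub <- df[df$sex == s & df$age >= 30, ]
    sub <- sub[order(sub$age), ]
    if (is.unsorted(sub$monthly_death_probability)) {
      stop_config("life_table",
                  sprintf("mortality not monotone in age beyond 30 for sex '%s'", s))
    }
  }
  if (!inherits(df, "life_table")) class(df) <- c("life_table", "data.frame")
  df
}

#' Monthly all-cause death probability at given ages
#'
#' Ages are floored to the table's integer grid. Ages beyond the table range
#' raise an error unless `cap = TRUE`, in which case the probability is 1
#' (the lifetime-horizon convention of capping survival at the table's last
#' age).
#'
#' @param life_table A `life_table`.
#' @param age Numeric vector of ages in years.
#' @param sex Sex label (default "female").
#' @param cap Return probability 1 beyond the table instead of erroring.
#' @return Numeric vector of monthly death probabilities.
#' @export
lookup_mortality <- function(life_table, age, sex = "female", cap = FALSE) {
  sub <- life_table[life_table$sex == sex, ]
  if (!nrow(sub)) {
    stop(sprintf("life table has no rows for sex '%s'", sex), call. = FALSE)
  }
  a <- floor(age)
  idx <- match(pmax(a, min(sub$age)), sub$age)
  over <- a > max(sub$age)
  if (any(is.na(idx) & !over)) {
    stop("age below life-table range", call. = FALSE)
  }
  q <- sub$monthly_death_probability[idx]
  if (any(over)) {
    if (!cap) {
      stop(sprintf("age %g beyond life-table range (max %d) with no lifetime cap",
                   max(a), max(sub$age)), call. = FALSE)
    }
    q[over] <- 1
  }
  q
}
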