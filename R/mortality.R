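# Background mortality from an annual life table plus condition-specific
# excess mortality applied on the hazard scale.

#' Read an annual life table
#'
#' The CSV dialect has a header `age,qx_male,qx_female` and one row per
#' integer age.  Ages must be contiguous; annual death probabilities must
#' lie in `[0, 1]`.
#'
#' @param path CSV file path.
#' @return A `life_table` object (data.frame with columns `age`, `qx_male`,
#'   `qx_female`).
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life table not found: ", path)
  lt <- utils::read.csv(path)
  as_life_table(lt)
}

#' Coerce a data.frame to a validated life table
#'
#' @param lt Data.frame with columns `age`, `qx_male`, `qx_female`.
#' @return A `life_table` object.
#' @export
as_life_table <- function(lt) {
  need <- c("age", "qx_male", "qx_female")
  if (!all(need %in% names(lt))) {
    stop("life table must have columns: ", paste(need, collapse = ", "))
  }
  lt <- lt[order(lt$age), need]
  if (any(diff(lt$age) != 1)) stop("life table has gaps in age")
  q <- c(lt$qx_male, lt$qx_female)
  if (any(q < 0 | q > 1)) stop("life table probabilities must lie in [0, 1]")
  if (any(diff(lt$qx_male[lt$age >= 40]) < 0) ||
      any(diff(lt$qx_female[lt$age >= 40]) < 0)) {
    warning("life table mortality is not monotone beyond age 40")
  }
  rownames(lt) <- NULL
  structure(lt, class = c("life_table", "data.frame"))
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("<life_table: ages %d-%d>\n", min(x$age), max(x$age)))
  invisible(as.data.frame(x))
}

# sex-weighted annual death probability at completed age
annual_death_prob <- function(table, age, male_fraction) {
  a <- pmin(floor(age), max(table$age))
  i <- match(a, table$age)
  if (any(is.na(i))) stop("age ", age[which(is.na(i))[1]], " outside life table")
  male_fraction * table$qx_male[i] + (1 - male_fraction) * table$qx_female[i]
}

#' Background per-cycle death probability
#'
#' The sex-weighted annual probability at the completed age is rescaled to
#' the cycle length under a constant within-year hazard.
#'
#' @param table A `life_table`.
#' @param age Age in years (indexed by completed years).
#' @param male_fraction Male fraction of the cohort.
#' @param cycle_years Cycle length in years.
#' @return Per-cycle death probability.
#' @export
background_death_prob <- function(table, age, male_fraction,
                                  cycle_years = 0.25) {
  q <- annual_death_prob(table, age, male_fraction)
  rescale_prob(q, from = 1, to = cycle_years)
}

#' Apply excess-mortality hazard ratios to a baseline death probability
#'
#' Applicable hazard ratios multiply on the hazard scale:
#' `1 - (1 - base)^prod(hr)`.
#'
#' @param base Baseline per-period death probability in `[0, 1)`.
#' @param hr Vector of applicable hazard ratios (all > 0).
#' @return Adjusted death probability.
#' @export
excess_death_prob <- function(base, hr = 1) {
  apply_relative_risk(base, prod(hr))
}

#' Life-table expected remaining lifetime
#'
#' Analytic life-table expectation computed by yearly survival products with
#' the within-year person-time approximated as a half year in the year of
#' death (the standard `ax = 0.5` convention), optionally discounted.
#' Used as an independent check on the cohort engine run with mortality
#' alone.
#'
#' @param table A `life_table`.
#' @param age Starting age (integer years).
#' @param male_fraction Male fraction of the cohort.
#' @param hr Hazard ratio applied to all ages (default 1).
#' @param discount_rate Annual discount rate (default 0, undiscounted).
#' @return Expected (discounted) remaining life-years.
#' @export
life_expectancy <- function(table, age, male_fraction, hr = 1,
                            discount_rate = 0) {
  ages <- seq(floor(age), max(table$age))
  q <- vapply(ages, annual_death_prob, numeric(1), table = table,
              male_fraction = male_fraction)
  q <- apply_relative_risk(pmin(q, 1 - 1e-12), hr)
  surv <- cumprod(1 - q)
  s_start <- c(1, surv[-length(surv)])
  v <- (1 + discount_rate)^-(ages - floor(age) + 0.5)
  # person-years in each year of age: survivors the full year, deaths half
  sum(v * (surv + 0.5 * (s_start - surv)))
}
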