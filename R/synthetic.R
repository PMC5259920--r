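# Synthetic inputs: a deterministic Gompertz-Makeham life table emulating a
# modern high-income population, the packaged parameter fixture, and toy
# models with closed-form answers used to verify the engine.

#' Gompertz-Makeham mortality specification
#'
#' Annual death probability at age `a`:
#' `q(a) = 1 - exp(-(A + B * exp(theta * a)))`.
#'
#' @param A Makeham (age-independent) hazard component, per year.
#' @param B Gompertz scale, per year.
#' @param theta Gompertz shape, per year of age.
#' @param max_age Last tabulated age.
#' @return A `gm_spec` object.
#' @export
gm_spec <- function(A, B, theta, max_age = 105) {
  stopifnot(A >= 0, B > 0, theta > 0, max_age > 60)
  structure(list(A = A, B = B, theta = theta, max_age = max_age),
            class = "gm_spec")
}

#' Default male and female mortality specifications
#'
#' Constants calibrated (once, by least squares on the life-table
#' expectation) so that period life expectancy matches published UK 2011-13
#' values: 79.0 at birth / 18.3 at 65 (male) and 82.8 / 20.8 (female).
#' The table is synthetic: it reproduces the longevity level of the target
#' population, not any specific national release.
#'
#' @return Named list with `male` and `female` `gm_spec` objects.
#' @export
default_gm_specs <- function() {
  list(male   = gm_spec(A = 5.1396e-04, B = 1.03663e-05, theta = 0.108219),
       female = gm_spec(A = 6.5220e-04, B = 3.54861e-07, theta = 0.145909))
}

gm_annual_q <- function(spec, ages) {
  -expm1(-(spec$A + spec$B * exp(spec$theta * ages)))
}

#' Generate a synthetic annual life table
#'
#' Deterministic (no randomness): annual death probabilities follow the
#' Gompertz-Makeham law for each sex over ages 0 to `max_age`.
#'
#' @param male,female `gm_spec` objects (defaults: [default_gm_specs()]).
#' @return A `life_table` object.
#' @export
#' @examples
#' lt <- generate_life_table()
#' life_expectancy(lt, 0, male_fraction = 0.5)
generate_life_table <- function(male = default_gm_specs()$male,
                                female = default_gm_specs()$female) {
  max_age <- min(male$max_age, female$max_age)
  ages <- 0:max_age
  qm <- gm_annual_q(male, ages)
  qf <- gm_annual_q(female, ages)
  if (any(qm[ages < 60] >= 1) || any(qf[ages < 60] >= 1)) {
    stop("gm_spec implies certain death before age 60")
  }
  as_life_table(data.frame(age = ages, qx_male = qm, qx_female = qf))
}

#' Write the packaged fixture: parameter file, life table and manifest
#'
#' Writes `parameters.yaml` (the full default parameter set),
#' `life_table.csv` (the synthetic table) and `manifest.csv` (the flattened
#' parameter table whose `source` column distinguishes published values
#' from package assumptions) into `dir`.
#'
#' @param dir Output directory (created if needed).
#' @return Named list of the written paths, invisibly.
#' @export
packaged_fixture <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- default_parameters()
  paths <- list(parameters = file.path(dir, "parameters.yaml"),
                life_table = file.path(dir, "life_table.csv"),
                manifest = file.path(dir, "manifest.csv"))
  write_parameters(p, paths$parameters)
  lt <- generate_life_table()
  utils::write.csv(as.data.frame(lt), paths$life_table, row.names = FALSE)
  export_parameter_table(p, paths$manifest)
  invisible(paths)
}

# strip a default parameter set down to an inert skeleton: no events, no
# index-event accrual, no decrements, zero costs, no discounting
blank_toy_parameters <- function() {
  p <- default_parameters()
  p$risks$value <- 0; p$risks$lo <- 0; p$risks$hi <- 0
  p$absolute_overrides$value <- 0
  p$absolute_overrides$lo <- 0; p$absolute_overrides$hi <- 0
  p$long_term$cteph_probability <- 0
  p$long_term$cteph_lo <- 0; p$long_term$cteph_hi <- 0
  p$long_term$pts_cumulative_probability <- 0
  p$long_term$pts_lo <- 0; p$long_term$pts_hi <- 0
  p$long_term$late_recurrence$annual_prob <- 0
  p$long_term$bleed_age_multiplier_per_decade <- 1
  p$costs$value <- 0
  p$costs$lo <- NA; p$costs$hi <- NA
  p$utilities$value <- c(1, 1, 1, rep(0, 7))
  p$utilities$lo <- p$utilities$value
  p$utilities$hi <- p$utilities$value
  p$mortality <- list(hr_vte_history = 1, hr_cteph = 1, hr_post_ic = 1)
  p$settings$discount_rate <- 0
  p$settings$include_index_event <- FALSE
  p
}

#' Toy models with closed-form expected outputs
#'
#' Three tiny configurations used to verify the engine against arithmetic:
#' \describe{
#'   \item{pure_mortality}{Background death only, 0.25 per cycle:
#'     undiscounted life-years are a geometric series summing to 1.0 under
#'     start-of-cycle accrual.}
#'   \item{event_pulse}{No mortality; a CRNM bleed risk of 0.2 in the first
#'     cycle only: expected cost and QALY decrement are the event pulse
#'     times 0.2.}
#'   \item{analytic_icer}{Two deathless arms over a fixed 1-year horizon;
#'     drug pricing and treatment disutility chosen so the incremental cost
#'     is exactly £100 and the incremental QALY 0.01: ICER £10,000.}
#' }
#'
#' @return Named list; each element has `parameters`, `life_table`, `arms`
#'   and `expected` (closed-form values).
#' @export
toy_models <- function() {
  flat_table <- function(q) {
    as_life_table(data.frame(age = 0:120, qx_male = q, qx_female = q))
  }
  out <- list()

  # (a) geometric decay: per-cycle death 0.25 <=> annual q = 1 - 0.75^4
  pa <- blank_toy_parameters()
  pa$population$start_age <- 20
  pa$settings$max_age <- 120
  out$pure_mortality <- list(
    parameters = pa,
    life_table = flat_table(1 - 0.75^4),
    arms = list(arm_schedule("apixaban", 18)),
    expected = list(ly = 1.0, p_cycle = 0.25))

  # (b) one-event pulse: CRNM risk 0.2 in cycle 0, zero afterwards
  pb <- blank_toy_parameters()
  pb$risks$value[pb$risks$event == "crnm_bleed" &
                   pb$risks$start_month == 0] <- 0.2
  pb$costs$value[pb$costs$item == "crnm_bleed"] <- 133.56
  pb$utilities$value[pb$utilities$item == "dec_crnm"] <- 0.0054
  pb$population$start_age <- 99
  pb$settings$max_age <- 100
  out$event_pulse <- list(
    parameters = pb,
    life_table = flat_table(0),
    arms = list(arm_schedule("apixaban", 18)),
    expected = list(crnm_events = 0.2, cost = 0.2 * 133.56,
                    qaly_lost = 0.2 * 0.0054 * 2 / 365.25))

  # (c) analytic ICER: 1-year horizon, apixaban costs £100/year more and
  # avoids a 0.01 utility decrement carried by the comparator
  pc <- blank_toy_parameters()
  pc$costs$value[pc$costs$item == "apix_daily_initial"] <- 100 / 365.25
  pc$costs$value[pc$costs$item == "apix_daily_extended"] <- 100 / 365.25
  pc$utilities$value[pc$utilities$item == "dec_lmwh_vka"] <- 0.01
  pc$population$start_age <- 99
  pc$settings$max_age <- 100
  out$analytic_icer <- list(
    parameters = pc,
    life_table = flat_table(0),
    arms = list(arm_schedule("apixaban", 12), arm_schedule("lmwh_vka", 12)),
    expected = list(d_cost = 100, d_qaly = 0.01, icer = 10000))

  out
}
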