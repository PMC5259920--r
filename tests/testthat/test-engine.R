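test_that("arm schedules encode the trial regimens", {
  a <- arm_schedule("apixaban", 18)
  expect_equal(a$name, "apixaban-18m")
  v <- arm_schedule("lmwh_vka", Inf)
  expect_equal(v$name, "lmwh_vka-lifelong")
  expect_error(arm_schedule("apixaban", 0))
  arms <- base_arms()
  expect_equal(vapply(arms, function(x) x$duration_months, numeric(1)),
               c(apixaban_18m = 18, lmwh_vka_6m = 6, lmwh_vka_18m = 18))
})

test_that("occupancy mass is conserved and dead states absorb", {
  for (arm in base_arms()) {
    tr <- run_model(arm, pkg_params(), syn_lt())
    expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-9))
    expect_true(all(tr$occupancy >= -1e-15))
    # deaths never decrease
    for (j in 15:17) expect_true(all(diff(tr$occupancy[, j]) >= -1e-15))
  }
  # an all-dead cohort is a fixed point of the step
  ctx <- engine_context(arm_schedule("apixaban", 18), pkg_params(), syn_lt())
  occ <- numeric(17); occ[17] <- 1
  stp <- transition_step(ctx, occ, 5)
  expect_equal(stp$occupancy, occ)
  expect_true(all(stp$events == 0))
})

test_that("a lone per-cycle risk yields exactly its marginal in expected events", {
  toys <- toy_models()
  p <- toys$pure_mortality$parameters
  p$risks$value[p$risks$event == "recurrent_vte" & p$risks$start_month == 0] <-
    0.0171
  p$population$start_age <- 20
  lt <- toys$event_pulse$life_table  # zero mortality
  tr <- run_model(arm_schedule("apixaban", 18), p, lt)
  ev <- count_events(tr, 1000)
  # only the first cycle carries risk 0.0171 under no competition: 17.1
  expect_equal(unname(tr$events[1, c("recurrent_dvt", "recurrent_pe",
                                     "vte_death")] %*% c(1, 1, 1))[1] * 1000,
               17.1, tolerance = 1e-9)
  # composite additivity over the whole horizon
  expect_equal(unname(ev["recurrent_vte"]),
               unname(ev["recurrent_dvt"] + ev["recurrent_pe"] +
                        ev["vte_death"]), tolerance = 1e-12)
})

test_that("the engine is deterministic and symmetric arms give zero increments", {
  p <- pkg_params(); lt <- syn_lt()
  arm <- arm_schedule("apixaban", 18)
  t1 <- run_model(arm, p, lt)
  t2 <- run_model(arm, p, lt)
  expect_identical(t1, t2)
  o1 <- accrue_outcomes(t1, arm, p)
  o2 <- accrue_outcomes(t2, arm, p)
  inc <- incremental(o1, o2)
  expect_identical(inc$d_cost, 0)
  expect_identical(inc$d_qaly, 0)
  expect_equal(inc$dominance, "undefined")
})

test_that("equalising relative effects and prices makes the comparator match", {
  p <- pkg_params()
  p$relative_effects$rr[!is.na(p$relative_effects$rr)] <- 1
  p$relative_effects$lo <- NA; p$relative_effects$hi <- NA
  # off-treatment major-bleed override equal to the apixaban extended rate
  p$absolute_overrides$value <- 0.0024
  # placebo effects = 1 as well, so off-treatment equals on-treatment risks
  cost_eq <- function(p, from, to) {
    p$costs$value[p$costs$item == to] <-
      p$costs$value[p$costs$item == from]
    p
  }
  p <- cost_eq(p, "apix_daily_initial", "lmwh_vka_daily_initial")
  p <- cost_eq(p, "apix_daily_extended", "vka_daily")
  p$costs$value[p$costs$item %in% c("monitor_first_cycle",
                                    "monitor_subsequent_cycle",
                                    "lmwh_education", "lmwh_admin_daily")] <- 0
  p$utilities$value[p$utilities$item == "dec_lmwh_vka"] <-
    p$utilities$value[p$utilities$item == "dec_apixaban"]
  lt <- syn_lt()
  oa <- run_arm(arm_schedule("apixaban", 18), p, lt)
  ov <- run_arm(arm_schedule("lmwh_vka", 18), p, lt)
  expect_equal(ov$trace$events, oa$trace$events, tolerance = 1e-12)
  inc <- incremental(oa, ov)
  expect_equal(inc$d_cost, 0, tolerance = 1e-9)
  expect_equal(inc$d_qaly, 0, tolerance = 1e-12)
  expect_equal(inc$d_ly, 0, tolerance = 1e-12)
})

test_that("accruals follow the published cost and utility arithmetic", {
  # state utility: one undiscounted cycle fully on apixaban
  toys <- toy_models()
  p <- toys$pure_mortality$parameters
  p$utilities$value[p$utilities$item == "baseline"] <- 0.825
  p$utilities$value[p$utilities$item == "dec_apixaban"] <- 0.002
  lt <- toys$event_pulse$life_table
  o <- run_arm(arm_schedule("apixaban", 18), p, lt)
  expect_equal(o$per_cycle$qaly[1], 0.25 * (0.825 - 0.002), tolerance = 1e-12)

  # an incident PE pulse: cost and 30-day utility decrement
  p2 <- toys$pure_mortality$parameters
  p2$risks$value[p2$risks$event == "recurrent_vte" &
                   p2$risks$start_month == 0] <- 0.1
  p2$splits$value[p2$splits$context == "on"] <- c(0, 1, 0)  # all PE
  p2$costs$value[p2$costs$item == "pe"] <- 1340.41
  p2$utilities$value[p2$utilities$item == "dec_pe"] <- 0.32
  o2 <- run_arm(arm_schedule("apixaban", 18), p2, lt)
  expect_equal(o2$per_cycle$cost_event[1], 0.1 * 1340.41, tolerance = 1e-10)
  expect_equal(o2$per_cycle$qaly[1],
               0.25 * 1 - 0.1 * 0.32 * 30 / 365.25, tolerance = 1e-10)
})

test_that("discounting, QALY bounds and dominance directions hold", {
  p <- pkg_params(); lt <- syn_lt()
  o <- run_arm(arm_schedule("apixaban", 18), p, lt)
  expect_lte(o$qaly, o$ly)
  expect_lt(o$ly, o$ly_undiscounted)
  expect_lt(o$cost_total, o$cost_total_undiscounted)

  # raising an event cost weakly raises total cost
  p2 <- set_parameter(p, "cost.crnm_bleed", 300)
  o2 <- run_arm(arm_schedule("apixaban", 18), p2, lt)
  expect_gt(o2$cost_total, o$cost_total)
  # raising a decrement weakly lowers QALYs
  p3 <- set_parameter(p, "util.dec_pts", 0.2)
  o3 <- run_arm(arm_schedule("apixaban", 18), p3, lt)
  expect_lt(o3$qaly, o$qaly)
})

test_that("half-cycle correction averages adjacent occupancies", {
  toys <- toy_models()
  p <- toys$pure_mortality$parameters
  p$settings$half_cycle_correction <- TRUE
  o <- run_arm(toys$pure_mortality$arms[[1]], p, toys$pure_mortality$life_table)
  # geometric: 0.25 * sum (S_k + S_{k+1})/2 = (1 + 0.75)/2 = 0.875
  expect_equal(o$ly_undiscounted, 0.875, tolerance = 1e-10)
})

test_that("trace exports include occupancy, events and accruals", {
  toys <- toy_models()
  o <- run_arm(toys$pure_mortality$arms[[1]], toys$pure_mortality$parameters,
               toys$pure_mortality$life_table)
  f <- withr::local_tempfile(fileext = ".csv")
  export_trace(o, f)
  df <- utils::read.csv(f)
  expect_true(all(c("cycle", "qaly", "on_dvt", "crnm_bleed",
                    "pts_prevalence") %in% names(df)))
  expect_equal(nrow(df), o$trace$K)
})
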