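fake_outcome <- function(name, cost, qaly, ly = qaly + 1) {
  structure(list(arm = list(name = name), cost_total = cost, qaly = qaly,
                 ly = ly,
                 cost_anticoagulant = cost, cost_monitoring = 0,
                 cost_event = 0,
                 events_per_cohort = c(recurrent_vte = 0)),
            class = "vte_outcomes")
}

test_that("incremental arithmetic, ICERs and dominance tags", {
  a <- fake_outcome("a", 1000, 1)
  expect_equal(incremental(a, a)$d_cost, 0)
  expect_equal(incremental(a, a)$dominance, "undefined")

  # published-style rounded components: (1023 - 385 - 101)/0.063
  i2 <- incremental(fake_outcome("a", 1537, 8.488),
                    fake_outcome("b", 1000, 8.425))
  expect_equal(i2$icer, 537 / 0.063, tolerance = 1e-9)
  expect_equal(round(i2$icer), 8524)

  expect_equal(incremental(fake_outcome("a", 990, 1.01),
                           fake_outcome("b", 1000, 1.00))$dominance,
               "dominant")
  expect_equal(incremental(fake_outcome("a", 1010, 0.99),
                           fake_outcome("b", 1000, 1.00))$dominance,
               "dominated")
})

test_that("the deterministic base case runs both comparisons", {
  bc <- base_case_cached()
  expect_length(bc$outcomes, 3)
  expect_s3_class(bc$vs_6m, "vte_incremental")
  # direction checks published in the result table: apixaban has higher
  # drug costs and lower monitoring costs than both comparators
  o <- bc$outcomes
  expect_gt(o[[1]]$cost_anticoagulant, o[[2]]$cost_anticoagulant)
  expect_gt(o[[1]]$cost_anticoagulant, o[[3]]$cost_anticoagulant)
  expect_lt(o[[1]]$cost_monitoring, o[[2]]$cost_monitoring)
  expect_lt(o[[1]]$cost_monitoring, o[[3]]$cost_monitoring)
  # fewer bleeds on apixaban than on either comparator
  expect_lt(bc$vs_6m$d_events[["major_bleed"]], 0)
  expect_lt(bc$vs_18m$d_events[["crnm_bleed"]], 0)
  expect_true(all(c("qaly", "ly") %in% bc$table$quantity))
})

test_that("parity parameters collapse both ICERs to undefined", {
  p <- pkg_params()
  p$relative_effects$rr[!is.na(p$relative_effects$rr)] <- 1
  p$absolute_overrides$value <- 0.0024
  for (pair in list(c("apix_daily_initial", "lmwh_vka_daily_initial"),
                    c("apix_daily_extended", "vka_daily"))) {
    p$costs$value[p$costs$item == pair[2]] <-
      p$costs$value[p$costs$item == pair[1]]
  }
  p$costs$value[p$costs$item %in% c("monitor_first_cycle",
                                    "monitor_subsequent_cycle",
                                    "lmwh_education", "lmwh_admin_daily")] <- 0
  p$utilities$value[p$utilities$item == "dec_lmwh_vka"] <-
    p$utilities$value[p$utilities$item == "dec_apixaban"]
  bc <- run_base_case(p, syn_lt())
  expect_equal(bc$vs_18m$d_cost, 0, tolerance = 1e-9)
  expect_equal(bc$vs_18m$d_qaly, 0, tolerance = 1e-12)
  expect_equal(bc$vs_18m$dominance, "undefined")
})

test_that("tornado entries bracket the base ICER and sort by spread", {
  ow <- memo("owsa", run_owsa(pkg_params(), syn_lt(), comparison = "vka6"))
  bc <- base_case_cached()
  expect_equal(ow$base_icer, bc$vs_6m$icer, tolerance = 1e-12)
  expect_true(all(diff(ow$table$spread) <= 1e-9))
  expect_equal(sum(ow$table$top15), 15)
  # setting a parameter to its own mean reproduces the base ICER
  p1 <- set_parameter(pkg_params(), "cost.dvt",
                      parameter_table(pkg_params())$value[
                        parameter_table(pkg_params())$name == "cost.dvt"])
  o <- lapply(base_arms()[1:2], run_arm, p = p1, life_table = syn_lt())
  expect_equal(incremental(o[[1]], o[[2]])$icer, ow$base_icer,
               tolerance = 1e-12)
  # every varied bound stays in-domain, so no entry is NA
  expect_false(any(is.na(ow$table$icer_low) | any(is.na(ow$table$icer_high))))
})

test_that("PSA is seed-reproducible and its acceptability curve is coherent", {
  p <- pkg_params(); lt <- syn_lt()
  ps1 <- run_psa(p, lt, n_draws = 30, seed = 7)
  ps2 <- run_psa(p, lt, n_draws = 30, seed = 7)
  expect_identical(ps1$ceac, ps2$ceac)
  expect_identical(ps1$draws, ps2$draws)
  expect_false(identical(ps1$draws,
                         run_psa(p, lt, n_draws = 30, seed = 8)$draws))
  probs <- as.matrix(ps1$ceac[, -1])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-12))
  expect_true(all(probs >= 0 & probs <= 1))
  # mean sampled increment consistent with the deterministic one
  bc <- base_case_cached()
  se <- stats::sd(ps1$draws$d_qaly_vs_6m) / sqrt(nrow(ps1$draws))
  expect_lt(abs(mean(ps1$draws$d_qaly_vs_6m) - bc$vs_6m$d_qaly), 4 * se)
})

test_that("a degenerate PSA reduces to the deterministic ranking", {
  p <- all_fixed_params()
  ps <- run_psa(p, syn_lt(), n_draws = 5, seed = 1)
  probs <- as.matrix(ps$ceac[, -1])
  expect_true(all(probs %in% c(0, 1)))
  bc <- run_base_case(p, syn_lt())
  nmb <- vapply(bc$outcomes, function(o) 20000 * o$qaly - o$cost_total,
                numeric(1))
  expect_equal(unname(probs[ps$ceac$wtp == 20000, which.max(nmb)]), 1)
})

test_that("net monetary benefit ties out at the ICER threshold", {
  bc <- base_case_cached()
  w <- bc$vs_6m$icer
  nmb_diff <- w * bc$vs_6m$d_qaly - bc$vs_6m$d_cost
  expect_equal(nmb_diff / abs(bc$vs_6m$d_cost), 0, tolerance = 1e-9)
})

test_that("duration scenarios reduce to the base case and extend to lifelong", {
  p <- pkg_params(); lt <- syn_lt()
  sc <- run_scenario_durations(p, lt, 18, 6)
  bc <- base_case_cached()
  expect_equal(sc$icer, bc$vs_6m$icer, tolerance = 1e-12)
  ll <- memo("lifelong", run_scenario_durations(p, lt, Inf, Inf))
  # lifelong treatment accrues more drug cost than the 18-month course
  expect_gt(ll$outcomes[[1]]$cost_anticoagulant,
            bc$outcomes[[1]]$cost_anticoagulant)
  # and fewer late recurrences than its own 18-month course arm
  expect_lt(ll$outcomes[[1]]$events_per_cohort[["recurrent_vte"]],
            bc$outcomes[[1]]$events_per_cohort[["recurrent_vte"]])
})

test_that("the simplified-mortality variant lengthens survival", {
  p <- pkg_params()
  bs <- memo("simplified", run_base_case(simplified_mortality(p), syn_lt()))
  bc <- base_case_cached()
  expect_gt(bs$outcomes[[1]]$ly, bc$outcomes[[1]]$ly)
  expect_gt(bs$vs_6m$d_qaly, bc$vs_6m$d_qaly)
})

test_that("auxiliary-default sensitivity reports both ICERs over ranges", {
  aux <- memo("aux", auxiliary_sensitivity(
    pkg_params(), syn_lt(),
    ranges = list(hr_vte_history = c(1, 2.5),
                  late_recurrence_scale = c(0.5, 1.5))))
  expect_equal(nrow(aux), 2)
  expect_true(all(is.finite(aux$icer_vs_6m_low)))
  # the late-recurrence level has a visible effect on both headline ICERs
  lr <- aux[aux$parameter == "late_recurrence_scale", ]
  expect_gt(abs(lr$icer_vs_6m_high - lr$icer_vs_6m_low), 1)
  expect_gt(abs(lr$icer_vs_18m_high - lr$icer_vs_18m_low), 1)
})
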