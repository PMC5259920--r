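test_that("the synthetic life table matches modern high-income longevity", {
  lt <- syn_lt()
  # independent expectation: yearly survival products straight off the table
  e0 <- function(q) {
    surv <- cumprod(1 - q)
    s0 <- c(1, surv[-length(surv)])
    sum(surv + 0.5 * (s0 - surv))
  }
  le <- 0.5 * e0(lt$qx_male) + 0.5 * e0(lt$qx_female)
  expect_gt(le, 78)
  expect_lt(le, 84)
  # monotone non-decreasing mortality from age 30
  expect_true(all(diff(lt$qx_male[lt$age >= 30]) >= 0))
  expect_true(all(diff(lt$qx_female[lt$age >= 30]) >= 0))
  # the table is deterministic
  expect_identical(as.data.frame(lt), as.data.frame(generate_life_table()))
})

test_that("degenerate mortality specifications are caught", {
  expect_error(gm_spec(A = -1, B = 1e-5, theta = 0.1))
  expect_error(generate_life_table(male = gm_spec(A = 2, B = 1, theta = 0.2)),
               "before age 60")
  # vanishing hazard: everyone survives
  tiny <- generate_life_table(male = gm_spec(0, 1e-300, 1e-3),
                              female = gm_spec(0, 1e-300, 1e-3))
  expect_lt(max(tiny$qx_male), 1e-10)
})

test_that("the installed extdata fixture matches a freshly generated one", {
  ext <- system.file("extdata", "parameters.yaml", package = "apixcea")
  p <- load_parameters(ext)
  expect_equal(p, pkg_params(), tolerance = 1e-9)
  lt <- read_life_table(system.file("extdata", "life_table.csv",
                                    package = "apixcea"))
  expect_equal(as.data.frame(lt), as.data.frame(syn_lt()), tolerance = 1e-9)
})

test_that("the packaged fixture reproduces the defaults and flags assumptions", {
  dir <- withr::local_tempdir()
  paths <- packaged_fixture(dir)
  expect_true(all(file.exists(unlist(paths))))
  p <- load_parameters(paths$parameters)
  expect_length(validate_parameters(p), 0)
  expect_equal(p, pkg_params(), tolerance = 1e-9)
  r <- p$risks
  expect_equal(r$value[r$event == "crnm_bleed" & r$start_month == 0], 0.0265)
  man <- utils::read.csv(paths$manifest)
  expect_true(all(man$source[grepl("^mortality\\.", man$name)] ==
                    "assumption"))
  expect_true(any(man$source == "published"))
})

test_that("toy models reproduce their closed forms through the engine", {
  toys <- toy_models()

  # (a) geometric decay: LY = 0.25 * sum 0.75^k = 1, occupancy 0.75^k
  ta <- toys$pure_mortality
  out <- run_arm(ta$arms[[1]], ta$parameters, ta$life_table)
  expect_equal(out$ly_undiscounted, ta$expected$ly, tolerance = 1e-10)
  alive <- 1 - rowSums(out$trace$occupancy[, 15:17])
  expect_equal(alive[1:10], 0.75^(0:9), tolerance = 1e-10)
  expect_equal(out$qaly_undiscounted, out$ly_undiscounted, tolerance = 1e-10)

  # (b) one CRNM pulse in cycle 0
  tb <- toys$event_pulse
  ob <- run_arm(tb$arms[[1]], tb$parameters, tb$life_table)
  expect_equal(unname(count_events(ob$trace, 1)["crnm_bleed"]),
               tb$expected$crnm_events, tolerance = 1e-10)
  expect_equal(ob$cost_total_undiscounted, tb$expected$cost,
               tolerance = 1e-10)
  expect_equal(ob$ly_undiscounted - ob$qaly_undiscounted,
               tb$expected$qaly_lost, tolerance = 1e-10)

  # (c) analytic ICER
  tc <- toys$analytic_icer
  o1 <- run_arm(tc$arms[[1]], tc$parameters, tc$life_table)
  o2 <- run_arm(tc$arms[[2]], tc$parameters, tc$life_table)
  inc <- incremental(o1, o2)
  expect_equal(inc$d_cost, tc$expected$d_cost, tolerance = 1e-10)
  expect_equal(inc$d_qaly, tc$expected$d_qaly, tolerance = 1e-10)
  expect_equal(inc$icer, tc$expected$icer, tolerance = 1e-10)
})
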