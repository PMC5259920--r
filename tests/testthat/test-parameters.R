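test_that("default parameter set carries the published values", {
  p <- pkg_params()
  expect_length(validate_parameters(p), 0)
  r <- p$risks
  expect_equal(r$value[r$event == "recurrent_vte" & r$start_month == 0], 0.0171)
  expect_equal(r$value[r$event == "crnm_bleed" & r$start_month == 0], 0.0265)
  expect_equal(r$value[r$event == "major_bleed" & r$start_month == 6], 0.0024)
  re <- p$relative_effects
  expect_equal(re$rr[re$comparator == "extended_vka" &
                       re$event == "major_bleed"], 7.7)
  expect_equal(re$rr[re$comparator == "extended_placebo" &
                       re$event == "recurrent_vte"], 5.33)
  expect_equal(p$utilities$value[p$utilities$item == "baseline"], 0.825)
  expect_equal(p$costs$value[p$costs$item == "apix_daily_initial"], 4.39)
  expect_equal(p$absolute_overrides$value, 0.0048)
  s <- p$splits
  expect_equal(sum(s$value[s$context == "on"]), 1, tolerance = 1e-9)
  expect_equal(sum(s$value[s$context == "off"]), 1, tolerance = 1e-9)
  expect_equal(p$population$start_age, 56.9)
  expect_equal(p$policy$disc_after_non_ic, 0.527)
})

test_that("validation reports violations as data, naming the parameter", {
  p <- pkg_params()
  p$splits$value[p$splits$context == "on" &
                   p$splits$component == "dvt"] <- 0.3077
  v <- validate_parameters(p)
  expect_length(v, 1)
  expect_match(v, "splits\\[on\\]")

  p2 <- pkg_params()
  p2$risks$start_month[p2$risks$event == "crnm_bleed" &
                         p2$risks$start_month == 6] <- 9
  v2 <- validate_parameters(p2)
  expect_true(any(grepl("crnm_bleed.*gap", v2)))

  p3 <- pkg_params()
  p3$costs$value[3] <- -5
  expect_match(validate_parameters(p3), "negative", all = FALSE)
})

test_that("parameter files round-trip and merge strictly", {
  p <- pkg_params()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, f)
  p2 <- load_parameters(f)
  expect_equal(p2, p, tolerance = 1e-9)

  # partial override of a single scalar leaves everything else unchanged
  f2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("settings:\n  wtp: 30000\n", f2)
  p3 <- load_parameters(f2)
  expect_equal(p3$settings$wtp, 30000)
  p3$settings$wtp <- p$settings$wtp
  expect_equal(p3, p, tolerance = 1e-9)

  # unknown keys are rejected by name
  f3 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("settings:\n  wtppp: 1\n", f3)
  expect_error(load_parameters(f3), "wtppp")
  f4 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("nonsense:\n  a: 1\n", f4)
  expect_error(load_parameters(f4), "nonsense")

  # domain violations surface with the offending table named
  bad <- p
  bad$relative_effects$rr[2] <- -1
  f5 <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(bad, f5)
  expect_error(load_parameters(f5), "relative_effects")

  expect_error(load_parameters("no/such/file.yaml"), "not found")
})

test_that("the uncertain-parameter registry addresses write back correctly", {
  p <- pkg_params()
  tab <- parameter_table(p)
  expect_true(all(c("name", "value", "lo", "hi", "family", "source") %in%
                    names(tab)))
  # auxiliary defaults are flagged as assumptions and not sampled
  hrs <- tab[grepl("^mortality\\.", tab$name), ]
  expect_true(all(hrs$source == "assumption"))
  expect_true(all(hrs$family == "fixed"))
  p2 <- set_parameter(p, "cost.dvt", 500)
  expect_equal(p2$costs$value[p2$costs$item == "dvt"], 500)
  p3 <- set_parameter(p, "rr.extended_vka.major_bleed", 1.62)
  expect_equal(p3$relative_effects$rr[p3$relative_effects$comparator ==
    "extended_vka" & p3$relative_effects$event == "major_bleed"], 1.62)
  expect_error(set_parameter(p, "no.such.param", 1), "unknown parameter")
})

test_that("distributions are moment-matched to the mean and 95% interval", {
  d <- build_distribution(0.0171, 0.012, 0.022, "beta")
  expect_equal(dist_mean(d), 0.0171, tolerance = 1e-6)
  # percentiles approximate the interval (moment matching, so loosely)
  expect_equal(dist_quantile(d, c(0.025, 0.975)), c(0.012, 0.022),
               tolerance = 0.05)

  g <- build_distribution(389.72, 272.80, 506.64, "gamma")
  expect_equal(dist_mean(g), 389.72, tolerance = 1e-6)

  ln <- build_distribution(3.26, 1.84, 5.79, "lognormal")
  expect_equal(ln$sdlog, 0.292440489787, tolerance = 1e-9)
  expect_equal(dist_mean(ln), 3.26, tolerance = 1e-9)

  fx <- build_distribution(5, 5, 5, "gamma")
  expect_equal(fx$family, "fixed")
  expect_equal(dist_sample(fx, 3), rep(5, 3))

  expect_error(build_distribution(3, 1, 5, "beta"), "mean in \\[0, 1\\]")
  expect_error(build_distribution(0.5, -3, 4, "beta"), "too wide")
  expect_error(build_distribution(0.2, 0.4, 0.5, "beta"), "bracket")
})

test_that("parameter sampling is seed-deterministic and domain-respecting", {
  p <- pkg_params()
  a <- sample_parameters(p, seed = 11)
  b <- sample_parameters(p, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, sample_parameters(p, seed = 12)))
  # every draw passes validation (simplex renormalisation included)
  for (s in 1:15) {
    expect_length(validate_parameters(sample_parameters(p, seed = s)), 0)
  }
  # all-point-mass parameter set: the draw is the input
  pf <- all_fixed_params()
  expect_equal(sample_parameters(pf, seed = 3), pf, tolerance = 1e-12)
})

test_that("sampled means converge on the point estimates", {
  p <- pkg_params()
  d <- build_distribution(0.0171, 0.012, 0.022, "beta")
  set.seed(99)
  x <- dist_sample(d, 10000)
  se <- stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 0.0171), 3 * se)
})

test_that("the flattened table exports as CSV", {
  f <- withr::local_tempfile(fileext = ".csv")
  export_parameter_table(pkg_params(), f)
  tab <- utils::read.csv(f)
  expect_true(all(c("name", "value", "ci_low", "ci_high", "family",
                    "source") %in% names(tab)))
  expect_gt(nrow(tab), 50)
})
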