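# Shared fixtures, computed once per test run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

pkg_params <- function() memo("p", default_parameters())
syn_lt <- function() memo("lt", generate_life_table())
base_case_cached <- function() {
  memo("bc", run_base_case(pkg_params(), syn_lt()))
}

# a parameter set whose every sampling distribution is a point mass
all_fixed_params <- function() {
  p <- pkg_params()
  p$risks$lo <- p$risks$value; p$risks$hi <- p$risks$value
  p$relative_effects$lo <- p$relative_effects$rr
  p$relative_effects$hi <- p$relative_effects$rr
  p$absolute_overrides$lo <- p$absolute_overrides$value
  p$absolute_overrides$hi <- p$absolute_overrides$value
  p$splits$lo <- p$splits$value; p$splits$hi <- p$splits$value
  p$costs$lo <- p$costs$value; p$costs$hi <- p$costs$value
  p$utilities$lo <- p$utilities$value; p$utilities$hi <- p$utilities$value
  p$long_term$cteph_lo <- p$long_term$cteph_probability
  p$long_term$cteph_hi <- p$long_term$cteph_probability
  p$long_term$pts_lo <- p$long_term$pts_cumulative_probability
  p$long_term$pts_hi <- p$long_term$pts_cumulative_probability
  p$policy$disc_after_non_ic_lo <- p$policy$disc_after_non_ic
  p$policy$disc_after_non_ic_hi <- p$policy$disc_after_non_ic
  p$policy$self_inject_lo <- p$policy$self_inject
  p$policy$self_inject_hi <- p$policy$self_inject
  p$settings$ci_less_cost_fraction <- 0
  p
}
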