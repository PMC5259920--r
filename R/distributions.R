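# Probability distributions for probabilistic sensitivity analysis.
# Each uncertain input is assigned a distribution from its mean and 95% CI:
# beta for probabilities/fractions/utilities (method of moments, the CI
# width supplying the standard deviation), gamma for costs (method of
# moments), lognormal for relative risks and other ratio parameters
# (log-scale sigma from the CI ratio, mu chosen so the analytic mean equals
# the point value).

#' Build a sampling distribution from a mean and 95\% interval
#'
#' The constructed distribution has analytic mean equal to `mean` (to
#' machine precision for all families) and 2.5/97.5 percentiles
#' approximating the supplied interval.  The interval is converted to a
#' standard deviation as `(hi - lo)/(2 * 1.96)` for the beta and gamma
#' families, and to a log-scale sigma as `(log(hi) - log(lo))/(2 * 1.96)`
#' for the lognormal family.  A degenerate interval (or the `fixed` family)
#' yields a point mass.
#'
#' @param mean Point value (must satisfy `lo <= mean <= hi`).
#' @param lo,hi 95\% interval bounds.
#' @param family One of `"beta"`, `"gamma"`, `"lognormal"`, `"fixed"`.
#' @return An object of class `param_dist`.
#' @seealso [dist_mean()], [dist_sample()], [dist_quantile()]
#' @export
#' @examples
#' d <- build_distribution(0.0171, 0.012, 0.022, "beta")
#' dist_mean(d)
build_distribution <- function(mean, lo = NA, hi = NA,
                               family = c("beta", "gamma", "lognormal",
                                          "fixed")) {
  family <- match.arg(family)
  point <- function() {
    structure(list(family = "fixed", value = mean), class = "param_dist")
  }
  if (family == "fixed" || is.na(lo) || is.na(hi) ||
      (lo == mean && hi == mean)) {
    return(point())
  }
  if (!(lo <= mean && mean <= hi)) {
    stop(sprintf("build_distribution: interval (%g, %g) does not bracket mean %g",
                 lo, hi, mean))
  }
  if (family == "beta") {
    if (mean <= 0 || mean >= 1) {
      if (mean == 0 || mean == 1) return(point())
      stop("build_distribution: beta requires mean in [0, 1]")
    }
    sd <- (hi - lo) / (2 * 1.96)
    if (sd == 0) return(point())
    v <- sd^2
    if (v >= mean * (1 - mean)) {
      stop(sprintf(
        "build_distribution: interval too wide for a beta with mean %g", mean))
    }
    k <- mean * (1 - mean) / v - 1
    return(structure(list(family = "beta", shape1 = mean * k,
                          shape2 = (1 - mean) * k), class = "param_dist"))
  }
  if (family == "gamma") {
    if (mean <= 0) {
      if (mean == 0) return(point())
      stop("build_distribution: gamma requires mean >= 0")
    }
    sd <- (hi - lo) / (2 * 1.96)
    if (sd == 0) return(point())
    return(structure(list(family = "gamma", shape = (mean / sd)^2,
                          rate = mean / sd^2), class = "param_dist"))
  }
  # lognormal
  if (mean <= 0 || lo <= 0)
    stop("build_distribution: lognormal requires positive mean and bounds")
  sigma <- (log(hi) - log(lo)) / (2 * 1.96)
  if (sigma == 0) return(point())
  structure(list(family = "lognormal", meanlog = log(mean) - sigma^2 / 2,
                 sdlog = sigma), class = "param_dist")
}

#' @export
print.param_dist <- function(x, ...) {
  pars <- x[setdiff(names(x), "family")]
  cat(sprintf("<param_dist %s: %s>\n", x$family,
              paste(sprintf("%s=%.6g", names(pars), unlist(pars)),
                    collapse = ", ")))
  invisible(x)
}

#' Analytic mean of a sampling distribution
#' @param d A `param_dist` object.
#' @return The distribution's mean.
#' @export
dist_mean <- function(d) {
  switch(d$family,
         fixed = d$value,
         beta = d$shape1 / (d$shape1 + d$shape2),
         gamma = d$shape / d$rate,
         lognormal = exp(d$meanlog + d$sdlog^2 / 2))
}

#' Draw from a sampling distribution
#' @param d A `param_dist` object.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
dist_sample <- function(d, n = 1) {
  switch(d$family,
         fixed = rep(d$value, n),
         beta = stats::rbeta(n, d$shape1, d$shape2),
         gamma = stats::rgamma(n, shape = d$shape, rate = d$rate),
         lognormal = stats::rlnorm(n, d$meanlog, d$sdlog))
}

#' Quantile of a sampling distribution
#' @param d A `param_dist` object.
#' @param q Probabilities.
#' @return Quantiles.
#' @export
dist_quantile <- function(d, q) {
  switch(d$family,
         fixed = rep(d$value, length(q)),
         beta = stats::qbeta(q, d$shape1, d$shape2),
         gamma = stats::qgamma(q, shape = d$shape, rate = d$rate),
         lognormal = stats::qlnorm(q, d$meanlog, d$sdlog))
}

# family-appropriate distribution for one registry row
row_distribution <- function(row) {
  build_distribution(row$value, row$lo, row$hi, row$family)
}

#' Precompute the sampling machinery for [sample_parameters()]
#'
#' @param p A `vte_parameters` object.
#' @return A list with the registry addresses and built distributions.
#' @export
sampling_spec <- function(p) {
  tab <- parameter_table(p)
  list(addr = attr(tab, "address"),
       dists = lapply(seq_len(nrow(tab)),
                      function(i) row_distribution(tab[i, ])))
}

#' Draw one coherent parameter set for probabilistic sensitivity analysis
#'
#' Every uncertain parameter in [parameter_table()] is drawn independently
#' from its distribution; recurrent-event split fractions are then
#' renormalised to the unit simplex.  Auxiliary `assumption` inputs carry no
#' interval evidence and stay at their point values.  Deterministic given
#' the seed.
#'
#' @param p A `vte_parameters` object.
#' @param seed Integer seed (optional; when missing, the current RNG stream
#'   is used, so bulk callers can seed once).
#' @param spec Precomputed sampling spec from [sampling_spec()]; bulk
#'   callers (the PSA loop) pass one to avoid rebuilding the registry per
#'   draw.
#' @return A `vte_parameters` object holding one draw.
#' @export
sample_parameters <- function(p, seed = NULL, spec = sampling_spec(p)) {
  if (!is.null(seed)) set.seed(seed)
  out <- p
  for (i in seq_along(spec$dists)) {
    out <- set_param_at(out, spec$addr[[i]], dist_sample(spec$dists[[i]], 1))
  }
  # renormalise the recurrent-event splits drawn independently
  for (ctx in c("on", "off")) {
    idx <- out$splits$context == ctx
    out$splits$value[idx] <- out$splits$value[idx] / sum(out$splits$value[idx])
  }
  # guard the rare draw that exceeds the probability domain (lognormal
  # override on an absolute probability)
  out$absolute_overrides$value <- pmin(out$absolute_overrides$value, 0.999)
  # retained intervals are provenance; widen them to bracket the draw so
  # the sampled set satisfies the structural invariants
  widen <- function(df, value_col = "value") {
    df$lo <- pmin(df$lo, df[[value_col]])
    df$hi <- pmax(df$hi, df[[value_col]])
    df
  }
  out$risks <- widen(out$risks)
  out$splits <- widen(out$splits)
  out$costs <- widen(out$costs)
  out$utilities <- widen(out$utilities)
  out$absolute_overrides <- widen(out$absolute_overrides)
  re <- out$relative_effects
  re$lo <- pmin(re$lo, re$rr); re$hi <- pmax(re$hi, re$rr)
  out$relative_effects <- re
  out
}
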