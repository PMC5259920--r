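# Decision analyses: incremental cost-effectiveness, one-way (tornado)
# sensitivity, probabilistic sensitivity with acceptability curves, and
# treatment-duration scenarios.

#' Incremental cost-effectiveness of one arm over another
#'
#' @param intervention,comparator `vte_outcomes` objects from the same
#'   parameter set.
#' @return A `vte_incremental` object: cost/QALY/LY deltas, per-category
#'   cost deltas, per-event count deltas per cohort, and the ICER or a
#'   dominance tag (`"dominant"`, `"dominated"`, `"undefined"`).
#' @export
incremental <- function(intervention, comparator) {
  d_cost <- intervention$cost_total - comparator$cost_total
  d_qaly <- intervention$qaly - comparator$qaly
  d_ly <- intervention$ly - comparator$ly
  icer <- NA_real_
  tag <- NA_character_
  if (d_qaly > 0 && d_cost <= 0) {
    tag <- "dominant"
  } else if (d_qaly < 0 && d_cost >= 0) {
    tag <- "dominated"
  } else if (d_qaly == 0) {
    tag <- if (d_cost == 0) "undefined" else
      if (d_cost < 0) "dominant" else "dominated"
  } else {
    icer <- d_cost / d_qaly
  }
  structure(list(
    intervention = intervention$arm$name, comparator = comparator$arm$name,
    d_cost = d_cost, d_qaly = d_qaly, d_ly = d_ly,
    icer = icer, dominance = tag,
    d_cost_by_category = c(
      anticoagulant = intervention$cost_anticoagulant -
        comparator$cost_anticoagulant,
      monitoring = intervention$cost_monitoring - comparator$cost_monitoring,
      event = intervention$cost_event - comparator$cost_event),
    d_events = intervention$events_per_cohort - comparator$events_per_cohort
  ), class = "vte_incremental")
}

#' @export
print.vte_incremental <- function(x, ...) {
  cat(sprintf("<vte_incremental %s vs %s>\n", x$intervention, x$comparator))
  cat(sprintf("  dCost £%.0f  dQALY %.4f  dLY %.4f  %s\n",
              x$d_cost, x$d_qaly, x$d_ly,
              if (is.na(x$icer)) x$dominance
              else sprintf("ICER £%.0f/QALY", x$icer)))
  invisible(x)
}

#' Deterministic base-case analysis
#'
#' Runs the three base-case arms once and reports both comparisons
#' (18-month apixaban vs 6-month LMWH/VKA; vs 18-month LMWH/VKA) with
#' lifetime event counts per cohort, discounted cost categories, LYs,
#' QALYs and ICERs.
#'
#' @param p A `vte_parameters` object.
#' @param life_table A `life_table` (default: the synthetic table).
#' @param arms List of three arms (default [base_arms()]), the first being
#'   the intervention.
#' @return A `vte_base_case` object with `$outcomes` (per arm),
#'   `$vs_6m` and `$vs_18m` (`vte_incremental`), and `$table`
#'   (a result table shaped like the deterministic-results report).
#' @export
run_base_case <- function(p, life_table = generate_life_table(),
                          arms = base_arms()) {
  outs <- lapply(arms, run_arm, p = p, life_table = life_table)
  inc1 <- incremental(outs[[1]], outs[[2]])
  inc2 <- incremental(outs[[1]], outs[[3]])
  rows <- c("recurrent_vte", "vte_death", "recurrent_pe", "recurrent_dvt",
            "major_bleed", "crnm_bleed", "ae_disc")
  tab <- data.frame(
    quantity = c(paste0("events_", rows), "cost_anticoagulant",
                 "cost_monitoring", "cost_event", "qaly", "ly"),
    check.names = FALSE)
  for (i in seq_along(outs)) {
    o <- outs[[i]]
    tab[[o$arm$name]] <- c(o$events_per_cohort[rows], o$cost_anticoagulant,
                           o$cost_monitoring, o$cost_event, o$qaly, o$ly)
  }
  structure(list(outcomes = outs, vs_6m = inc1, vs_18m = inc2, table = tab),
            class = "vte_base_case")
}

#' @export
print.vte_base_case <- function(x, ...) {
  cat("<vte_base_case>\n")
  for (o in x$outcomes) {
    cat(sprintf("  %-14s £%7.0f  %.3f QALY  %.3f LY\n",
                o$arm$name, o$cost_total, o$qaly, o$ly))
  }
  print(x$vs_6m); print(x$vs_18m)
  invisible(x)
}

icer_of <- function(inc) if (is.na(inc$icer)) NA_real_ else inc$icer

#' One-way (tornado) sensitivity analysis
#'
#' Every uncertain parameter with interval evidence (printed CI,
#' count-derived CI, or the documented \eqn{\pm}30\% rule for unpriced
#' costs) plus the cohort starting age (varied \eqn{\pm}10 years) is set to
#' each bound in turn with everything else at base value, the deterministic
#' model re-run, and the ICER recorded.  Entries are sorted by ICER spread.
#'
#' @param p A `vte_parameters` object.
#' @param life_table A `life_table`.
#' @param comparison `"vka6"` or `"vka18"`: comparator arm for the ICER.
#' @param top Number of entries to flag as most influential (default 15).
#' @return A `vte_owsa` object; `$table` has one row per parameter with
#'   `low`, `high`, `icer_low`, `icer_high`, `spread`, `top15`.
#' @export
run_owsa <- function(p, life_table = generate_life_table(),
                     comparison = c("vka6", "vka18"), top = 15) {
  comparison <- match.arg(comparison)
  arms <- base_arms()
  pair <- list(arms$apixaban_18m,
               if (comparison == "vka6") arms$lmwh_vka_6m else arms$lmwh_vka_18m)
  icer_for <- function(pp) {
    outs <- lapply(pair, run_arm, p = pp, life_table = life_table)
    icer_of(incremental(outs[[1]], outs[[2]]))
  }
  base_icer <- icer_for(p)

  tab <- parameter_table(p)
  addr <- attr(tab, "address")
  vary <- which(!is.na(tab$lo) & tab$hi > tab$lo)
  # varying one recurrent-split fraction rescales its complements so the
  # split stays on the simplex
  renorm_splits <- function(pp, name) {
    m <- regmatches(name, regexec("^split\\.(on|off)\\.(.+)$", name))[[1]]
    if (length(m) == 0) return(pp)
    idx <- pp$splits$context == m[2]
    keep <- idx & pp$splits$component == m[3]
    oth <- idx & !keep
    pp$splits$value[oth] <- pp$splits$value[oth] *
      (1 - pp$splits$value[keep]) / sum(pp$splits$value[oth])
    pp
  }
  entries <- list()
  for (i in vary) {
    lo <- tab$lo[i]; hi <- tab$hi[i]
    pl <- renorm_splits(set_param_at(p, addr[[i]], lo), tab$name[i])
    ph <- renorm_splits(set_param_at(p, addr[[i]], hi), tab$name[i])
    if (length(validate_parameters(pl)) || length(validate_parameters(ph))) {
      warning("skipping ", tab$name[i], ": bound outside domain")
      next
    }
    entries[[length(entries) + 1]] <- data.frame(
      parameter = tab$name[i], low = lo, high = hi,
      icer_low = icer_for(pl), icer_high = icer_for(ph))
  }
  # starting age, varied +/- 10 years around the trial mean
  pa_lo <- p; pa_lo$population$start_age <- p$population$start_age - 10
  pa_hi <- p; pa_hi$population$start_age <- p$population$start_age + 10
  entries[[length(entries) + 1]] <- data.frame(
    parameter = "population.start_age",
    low = pa_lo$population$start_age, high = pa_hi$population$start_age,
    icer_low = icer_for(pa_lo), icer_high = icer_for(pa_hi))

  out <- do.call(rbind, entries)
  out$spread <- abs(out$icer_high - out$icer_low)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  out$top15 <- seq_len(nrow(out)) <= top
  structure(list(comparison = comparison, base_icer = base_icer, table = out),
            class = "vte_owsa")
}

#' @export
print.vte_owsa <- function(x, ...) {
  cat(sprintf("<vte_owsa vs %s: base ICER £%.0f/QALY, %d parameters>\n",
              x$comparison, x$base_icer, nrow(x$table)))
  print(utils::head(x$table[, c("parameter", "icer_low", "icer_high",
                                "spread")], 10))
  invisible(x)
}

#' Probabilistic sensitivity analysis with acceptability curves
#'
#' Draws `n_draws` full parameter sets from their distributions, re-runs
#' all three arms for each, and summarises the draws as a
#' cost-effectiveness acceptability curve: the fraction of draws in which
#' each arm has the highest net monetary benefit (NMB = WTP x QALYs -
#' costs) at each willingness-to-pay value.
#'
#' @param p A `vte_parameters` object.
#' @param life_table A `life_table`.
#' @param n_draws Number of simulations (default from settings, 2000).
#' @param seed Integer seed; the analysis is reproducible given the seed.
#' @param wtp_grid Willingness-to-pay grid (default from settings).
#' @return A `vte_psa` object: `$draws` (per-draw costs/QALYs by arm and
#'   increments), `$ceac` (grid with per-arm probabilities),
#'   `$p_ce_at_wtp` (probability the intervention is optimal at the
#'   base-case threshold).
#' @export
run_psa <- function(p, life_table = generate_life_table(),
                    n_draws = p$settings$psa_draws, seed = 1,
                    wtp_grid = p$settings$wtp_grid) {
  arms <- base_arms()
  set.seed(seed)
  spec <- sampling_spec(p)
  res <- matrix(NA_real_, n_draws, 6,
                dimnames = list(NULL, c("cost_apix", "qaly_apix",
                                        "cost_vka6", "qaly_vka6",
                                        "cost_vka18", "qaly_vka18")))
  for (j in seq_len(n_draws)) {
    pj <- sample_parameters(p, spec = spec)
    outs <- lapply(arms, run_arm, p = pj, life_table = life_table)
    res[j, ] <- c(outs[[1]]$cost_total, outs[[1]]$qaly,
                  outs[[2]]$cost_total, outs[[2]]$qaly,
                  outs[[3]]$cost_total, outs[[3]]$qaly)
  }
  draws <- data.frame(draw = seq_len(n_draws), res)
  draws$d_cost_vs_6m <- draws$cost_apix - draws$cost_vka6
  draws$d_qaly_vs_6m <- draws$qaly_apix - draws$qaly_vka6
  draws$d_cost_vs_18m <- draws$cost_apix - draws$cost_vka18
  draws$d_qaly_vs_18m <- draws$qaly_apix - draws$qaly_vka18

  costs <- as.matrix(draws[, c("cost_apix", "cost_vka6", "cost_vka18")])
  qalys <- as.matrix(draws[, c("qaly_apix", "qaly_vka6", "qaly_vka18")])
  arm_names <- vapply(arms, function(a) a$name, character(1))
  ceac <- t(vapply(wtp_grid, function(w) {
    nmb <- w * qalys - costs
    best <- max.col(nmb, ties.method = "first")
    tabulate(best, 3) / nrow(nmb)
  }, numeric(3)))
  colnames(ceac) <- arm_names
  ceac <- data.frame(wtp = wtp_grid, ceac, check.names = FALSE)

  nmb0 <- p$settings$wtp * qalys - costs
  p_ce <- mean(max.col(nmb0, ties.method = "first") == 1)

  structure(list(n_draws = n_draws, seed = seed, wtp = p$settings$wtp,
                 draws = draws, ceac = ceac, p_ce_at_wtp = p_ce,
                 p_beats_6m = mean(nmb0[, 1] > nmb0[, 2]),
                 p_beats_18m = mean(nmb0[, 1] > nmb0[, 3]),
                 arm_names = arm_names),
            class = "vte_psa")
}

#' @export
print.vte_psa <- function(x, ...) {
  cat(sprintf("<vte_psa: %d draws (seed %d)>\n", x$n_draws, x$seed))
  cat(sprintf("  P(%s most cost-effective at £%s/QALY) = %.1f%%\n",
              x$arm_names[1], format(x$wtp, big.mark = ","),
              100 * x$p_ce_at_wtp))
  cat(sprintf("  mean dQALY vs 6m %.4f, mean dCost vs 6m £%.0f\n",
              mean(x$draws$d_qaly_vs_6m), mean(x$draws$d_cost_vs_6m)))
  invisible(x)
}

#' Treatment-duration scenario analysis
#'
#' Rebuilds the arm schedules with the requested durations (months; `Inf`
#' for lifelong treatment, in which case extended-period risk and cost
#' parameters and the ageing bleed adjustment apply until death) and
#' re-runs the comparison.
#'
#' @param p A `vte_parameters` object.
#' @param life_table A `life_table`.
#' @param apixaban_months Apixaban treatment duration (months or `Inf`).
#' @param comparator_months LMWH/VKA treatment duration (months or `Inf`).
#' @return A `vte_incremental` object (outcomes attached as
#'   `$outcomes`).
#' @export
run_scenario_durations <- function(p, life_table = generate_life_table(),
                                   apixaban_months = 18,
                                   comparator_months = 6) {
  a1 <- arm_schedule("apixaban", apixaban_months)
  a2 <- arm_schedule("lmwh_vka", comparator_months)
  o1 <- run_arm(a1, p, life_table)
  o2 <- run_arm(a2, p, life_table)
  inc <- incremental(o1, o2)
  inc$outcomes <- list(o1, o2)
  inc
}

#' Simplified-mortality variant of a parameter set
#'
#' Mirrors the simpler mortality structure of earlier models in the field:
#' event-free patients follow general-population mortality (no post-VTE
#' excess hazard), bleeding has no long-term mortality effect, and bleeding
#' risks do not rise with ageing.  The CTEPH excess hazard is retained.
#'
#' @param p A `vte_parameters` object.
#' @return The modified parameter set.
#' @export
simplified_mortality <- function(p) {
  p$mortality$hr_vte_history <- 1
  p$mortality$hr_post_ic <- 1
  p$long_term$bleed_age_multiplier_per_decade <- 1
  p
}

#' Sensitivity of headline results to the non-published auxiliary defaults
#'
#' The excess-mortality hazard ratios and the late off-treatment recurrence
#' schedule are consumed as configuration (their sources do not print
#' values).  This report varies each over a plausibility range, holding
#' everything else at base value, and records both base-case ICERs.
#'
#' @param p A `vte_parameters` object.
#' @param life_table A `life_table`.
#' @param ranges Named list of length-2 ranges; defaults cover
#'   `hr_vte_history` 1-2.5, `hr_cteph` 2-8, `hr_post_ic` 1-5 and a
#'   0.5x-1.5x scaling of the late-recurrence schedule.
#' @return Data.frame: parameter, bound values, ICER vs each comparator at
#'   each bound.
#' @export
auxiliary_sensitivity <- function(p, life_table = generate_life_table(),
                                  ranges = list(
                                    hr_vte_history = c(1, 2.5),
                                    hr_cteph = c(2, 8),
                                    hr_post_ic = c(1, 5),
                                    late_recurrence_scale = c(0.5, 1.5))) {
  both_icers <- function(pp) {
    bc <- run_base_case(pp, life_table)
    c(icer_of(bc$vs_6m), icer_of(bc$vs_18m))
  }
  rows <- lapply(names(ranges), function(nm) {
    vals <- vapply(ranges[[nm]], function(b) {
      pp <- p
      if (nm == "late_recurrence_scale") {
        pp$long_term$late_recurrence$annual_prob <-
          pmin(1, b * pp$long_term$late_recurrence$annual_prob)
      } else {
        pp$mortality[[nm]] <- b
      }
      both_icers(pp)
    }, numeric(2))
    data.frame(parameter = nm, low = ranges[[nm]][1], high = ranges[[nm]][2],
               icer_vs_6m_low = vals[1, 1], icer_vs_6m_high = vals[1, 2],
               icer_vs_18m_low = vals[2, 1], icer_vs_18m_high = vals[2, 2])
  })
  do.call(rbind, rows)
}
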