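# Markov cohort engine.
#
# State space (17 states):
#   1 on_dvt, 2 on_pe          on arm treatment, by index-event history
#   3 off_dvt, 4 off_pe        off treatment
#   5-8   rt_a_{dvt,pe}_{1,2}  6-month re-treatment tunnel, apixaban
#   9-12  rt_v_{dvt,pe}_{1,2}  6-month re-treatment tunnel, LMWH/VKA
#   13 post_ic                 semi-absorbing after non-fatal IC bleed
#   14 cteph                   semi-absorbing CTEPH
#   15 dead_vte, 16 dead_bleed, 17 dead_other
#
# Transient events (recurrent DVT/PE start a tunnel; CRNM and continuing
# non-IC major bleeds return to the originating state) are expected-value
# pulses for costs/utilities.  Severe PTS is a background attribute, not a
# state.  PE history is monotone: once a patient has had a PE (index or
# recurrent), they stay in PE-history states and remain at CTEPH risk.

STATE_NAMES <- c("on_dvt", "on_pe", "off_dvt", "off_pe",
                 "rt_a_dvt_1", "rt_a_dvt_2", "rt_a_pe_1", "rt_a_pe_2",
                 "rt_v_dvt_1", "rt_v_dvt_2", "rt_v_pe_1", "rt_v_pe_2",
                 "post_ic", "cteph", "dead_vte", "dead_bleed", "dead_other")

EVENT_NAMES <- c("recurrent_dvt", "recurrent_pe", "vte_death",
                 "fatal_bleed", "ic_bleed", "non_ic_bleed", "crnm_bleed",
                 "ae_disc", "cteph_onset", "pts_onset", "other_death")

#' Define a treatment arm
#'
#' The apixaban arm follows the trial regimen (10 mg BID for 7 days, 5 mg
#' BID to month 6, 2.5 mg BID thereafter); the LMWH/VKA arm bridges with
#' LMWH for the first days of a course with dose-adjusted VKA continuing,
#' under INR monitoring.  On-treatment risks are the apixaban absolute
#' schedule with the arm's relative effects applied (initial-period
#' LMWH/VKA effects to month 6, extended-VKA effects afterwards).
#'
#' @param drug `"apixaban"` or `"lmwh_vka"`.
#' @param duration_months Intended total treatment duration in months
#'   (`Inf` for lifelong treatment).
#' @param name Optional arm label.
#' @return A `vte_arm` object.
#' @export
#' @examples
#' arm_schedule("apixaban", 18)
arm_schedule <- function(drug = c("apixaban", "lmwh_vka"),
                         duration_months = 18, name = NULL) {
  drug <- match.arg(drug)
  stopifnot(duration_months > 0)
  if (is.null(name)) {
    dur <- if (is.finite(duration_months)) {
      paste0(duration_months, "m")
    } else "lifelong"
    name <- paste0(if (drug == "apixaban") "apixaban-" else "lmwh_vka-", dur)
  }
  structure(list(name = name, drug = drug,
                 duration_months = duration_months),
            class = "vte_arm")
}

#' @export
print.vte_arm <- function(x, ...) {
  cat(sprintf("<vte_arm %s: %s for %s>\n", x$name, x$drug,
              if (is.finite(x$duration_months))
                paste0(x$duration_months, " months") else "life"))
  invisible(x)
}

#' The three base-case treatment arms
#'
#' @return Named list: 18-month apixaban, 6-month LMWH/VKA, 18-month
#'   LMWH/VKA.
#' @export
base_arms <- function() {
  list(apixaban_18m = arm_schedule("apixaban", 18),
       lmwh_vka_6m  = arm_schedule("lmwh_vka", 6),
       lmwh_vka_18m = arm_schedule("lmwh_vka", 18))
}

# per-cycle apixaban base probability for one event's risk schedule;
# `months` is the cycle start month.  Beyond the schedule a recurrent-VTE
# entry continues at the mean extended-period per-cycle risk.
base_cycle_prob <- function(segments, months, cycle_years) {
  out <- numeric(length(months))
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, ]
    idx <- months >= seg$start_month & months < seg$end_month
    p_cycle <- switch(seg$scale,
      cycle  = seg$value,
      annual = rescale_prob(seg$value, 1, cycle_years),
      period = rescale_prob(seg$value,
                            (seg$end_month - seg$start_month) / 12,
                            cycle_years))
    out[idx] <- p_cycle
  }
  last_end <- max(segments$end_month)
  if (is.finite(last_end) && any(months >= last_end)) {
    ext <- segments[segments$start_month >= 6, ]
    out[months >= last_end] <- mean(ext$value)
  }
  out
}

rr_for <- function(p, comparator, event) {
  re <- p$relative_effects
  re$rr[re$comparator == comparator & re$event == event]
}

# per-cycle late off-treatment recurrence probability by years since
# cessation (cessation approximated by the end of the trial-informed
# 18-month window)
late_recurrence_prob <- function(schedule, years_since, cycle_years) {
  out <- numeric(length(years_since))
  for (i in seq_len(nrow(schedule))) {
    idx <- years_since >= schedule$years_from[i] &
      years_since < schedule$years_to[i]
    out[idx] <- rescale_prob(schedule$annual_prob[i], 1, cycle_years)
  }
  out
}

#' Prepare the cycle-indexed engine context for one arm
#'
#' Precomputes, for every cycle: on-treatment, off-treatment and
#' re-treatment risk marginals (relative effects, the absolute off-treatment
#' major-bleed override, and the post-18-month ageing multiplier on bleeding
#' applied), background and excess mortality, the competing-risk effective
#' probabilities, and the cost/utility schedules.  [transition_step()] and
#' [run_model()] consume this context.
#'
#' @param arm A `vte_arm`.
#' @param p A `vte_parameters` object.
#' @param life_table A `life_table`.
#' @return An `engine_context` list.
#' @export
engine_context <- function(arm, p, life_table) {
  st <- p$settings
  cyc <- st$cycle_years
  start_age <- p$population$start_age
  K <- ceiling((st$max_age - start_age) / cyc) + 8L
  k <- 0:(K - 1)
  months <- k * cyc * 12
  age <- start_age + k * cyc

  # apixaban absolute per-cycle base risks
  b <- sapply(c("recurrent_vte", "major_bleed", "crnm_bleed", "ae_disc"),
              function(ev) base_cycle_prob(p$risks[p$risks$event == ev, ],
                                           months, cyc))

  # ageing multiplier on bleeding hazards after month 18
  age_mult <- rep(1, K)
  late <- months >= 18
  age_mult[late] <- age_bleed_multiplier(
    age[late], start_age + 1.5, p$long_term$bleed_age_multiplier_per_decade)

  # on-treatment risks under the arm's relative effects
  on <- matrix(0, K, 4, dimnames = list(NULL, colnames(b)))
  if (arm$drug == "apixaban") {
    on[] <- b
  } else {
    initial <- months < 6
    for (ev in colnames(b)) {
      rr_i <- rr_for(p, "initial_lmwh_vka", ev)
      rr_e <- rr_for(p, "extended_vka", ev)
      on[, ev] <- apply_relative_risk(b[, ev],
                                      ifelse(initial, rr_i, rr_e))
    }
  }
  on[, "major_bleed"] <- apply_relative_risk(on[, "major_bleed"], age_mult)
  on[, "crnm_bleed"]  <- apply_relative_risk(on[, "crnm_bleed"], age_mult)

  # off-treatment risks: extended-placebo effects over the contemporaneous
  # apixaban schedule; absolute override for major bleeding; late-recurrence
  # schedule beyond month 18
  off_recur <- apply_relative_risk(b[, "recurrent_vte"],
                                   rr_for(p, "extended_placebo",
                                          "recurrent_vte"))
  off_recur[late] <- late_recurrence_prob(
    p$long_term$late_recurrence, (months[late] - 18) / 12, cyc)
  ao <- p$absolute_overrides
  ov <- ao[ao$comparator == "extended_placebo" & ao$event == "major_bleed", ]
  off_major <- rep(rescale_prob(ov$value, ov$period_years, cyc), K)
  off_crnm <- apply_relative_risk(b[, "crnm_bleed"],
                                  rr_for(p, "extended_placebo", "crnm_bleed"))
  if (isTRUE(st$age_bleeds_off_treatment)) {
    off_major <- apply_relative_risk(off_major, age_mult)
    off_crnm  <- apply_relative_risk(off_crnm, age_mult)
  }

  # re-treatment tunnels: a fresh course runs through the acute (0-3 m) and
  # post-acute (3-6 m) schedule under the course drug's effects
  tun_base <- rbind(tc1 = sapply(colnames(b), function(ev)
                      base_cycle_prob(p$risks[p$risks$event == ev, ], 0, cyc)),
                    tc2 = sapply(colnames(b), function(ev)
                      base_cycle_prob(p$risks[p$risks$event == ev, ], 3, cyc)))
  tun <- list()
  for (d in c("a", "v")) {
    for (tc in 1:2) {
      v <- tun_base[tc, ]
      if (d == "v") {
        for (ev in colnames(b)) {
          v[ev] <- apply_relative_risk(v[ev], rr_for(p, "initial_lmwh_vka", ev))
        }
      }
      m <- matrix(rep(v, each = K), K, 4, dimnames = list(NULL, colnames(b)))
      m[, "major_bleed"] <- apply_relative_risk(m[, "major_bleed"], age_mult)
      m[, "crnm_bleed"]  <- apply_relative_risk(m[, "crnm_bleed"], age_mult)
      tun[[paste0(d, tc)]] <- m
    }
  }

  # CTEPH onset (PE history, treatment-independent)
  p_cteph <- rescale_prob(p$long_term$cteph_probability,
                          p$long_term$cteph_period_years, cyc)

  # background death, capped at the maximum age, with excess hazard ratios
  q_annual <- vapply(pmin(age, st$max_age), annual_death_prob, numeric(1),
                     table = life_table,
                     male_fraction = p$population$male_fraction)
  q_annual[age >= st$max_age] <- 1 - 1e-12
  q_bg <- rescale_prob(q_annual, 1, cyc)
  hr <- p$mortality
  q_base  <- excess_death_prob(q_bg, hr$hr_vte_history)
  q_ic    <- excess_death_prob(q_bg, c(hr$hr_vte_history, hr$hr_post_ic))
  q_cteph <- excess_death_prob(q_bg, c(hr$hr_vte_history, hr$hr_cteph))

  # marginal risk array M[k, state, event-type]; types:
  # recur, major, crnm, ae, cteph, death
  M <- array(0, dim = c(K, 14, 6))
  pe_states <- c(2, 4, 7, 8, 11, 12)
  for (s in 1:2)  M[, s, 1:4] <- on
  for (s in 3:4)  M[, s, 1:3] <- cbind(off_recur, off_major, off_crnm)
  M[, 5, 1:4] <- tun$a1; M[, 6, 1:4] <- tun$a2
  M[, 7, 1:4] <- tun$a1; M[, 8, 1:4] <- tun$a2
  M[, 9, 1:4] <- tun$v1; M[, 10, 1:4] <- tun$v2
  M[, 11, 1:4] <- tun$v1; M[, 12, 1:4] <- tun$v2
  M[, pe_states, 5] <- p_cteph
  M[, 1:12, 6] <- q_base
  M[, 13, 6] <- q_ic
  M[, 14, 6] <- q_cteph

  # competing-risk allocation, vectorised over cycles and states; marginals
  # are kept strictly below 1 so hazards stay finite at the age cap
  M <- pmin(M, 1 - 1e-12)
  R <- -log1p(-M)
  rtot <- R[, , 1] + R[, , 2] + R[, , 3] + R[, , 4] + R[, , 5] + R[, , 6]
  total <- -expm1(-rtot)
  scale <- ifelse(rtot > 0, total / rtot, 0)
  EFF <- array(0, dim = dim(M))
  for (j in 1:6) EFF[, , j] <- R[, , j] * scale
  STAY <- 1 - (EFF[, , 1] + EFF[, , 2] + EFF[, , 3] +
               EFF[, , 4] + EFF[, , 5] + EFF[, , 6])

  # policy / split constants; per-state context weights
  sp <- p$splits
  spv <- function(ctx, comp) sp$value[sp$context == ctx & sp$component == comp]
  is_on_tx <- c(TRUE, TRUE, FALSE, FALSE, rep(TRUE, 8), FALSE, FALSE)
  w_death <- ifelse(is_on_tx, spv("on", "vte_death"), spv("off", "vte_death"))
  w_pe    <- ifelse(is_on_tx, spv("on", "pe"),        spv("off", "pe"))
  w_dvt   <- ifelse(is_on_tx, spv("on", "dvt"),       spv("off", "dvt"))

  arm_d <- if (arm$drug == "apixaban") "a" else "v"
  src_a_pe  <- c(if (arm_d == "a") 2, 7, 8)
  src_a_dvt <- c(if (arm_d == "a") 1, 5, 6)
  src_v_pe  <- c(if (arm_d == "v") 2, 4, 11, 12)
  src_v_dvt <- c(if (arm_d == "v") 1, 3, 9, 10)

  on_active <- months < arm$duration_months
  days <- 365.25 * cyc

  # cost schedules (per unit occupancy per cycle)
  cost <- function(item) p$costs$value[p$costs$item == item]
  si <- p$policy$self_inject; lmwh_d <- p$policy$lmwh_days
  edu_admin <- cost("lmwh_education") +
    cost("lmwh_admin_daily") * (1 - si) * lmwh_d
  if (arm$drug == "apixaban") {
    dcost_on <- ifelse(k == 0,
                       cost("apix_daily_initial") * 7 +
                         cost("apix_daily_extended") * (days - 7),
                       cost("apix_daily_extended") * days)
    mcost_on <- rep(0, K)
    start_course_cost <- 0
  } else {
    dcost_on <- ifelse(k == 0,
                       cost("lmwh_vka_daily_initial") * lmwh_d +
                         cost("vka_daily") * (days - lmwh_d),
                       cost("vka_daily") * days)
    mcost_on <- ifelse(k == 0, cost("monitor_first_cycle"),
                       cost("monitor_subsequent_cycle"))
    start_course_cost <- edu_admin
  }
  dcost_on[!on_active] <- 0
  mcost_on[!on_active] <- 0
  tun_cost <- list(
    a1 = c(drug = cost("apix_daily_initial") * 7 +
             cost("apix_daily_extended") * (days - 7), monitor = 0),
    a2 = c(drug = cost("apix_daily_extended") * days, monitor = 0),
    v1 = c(drug = cost("lmwh_vka_daily_initial") * lmwh_d +
             cost("vka_daily") * (days - lmwh_d),
           monitor = cost("monitor_first_cycle") + edu_admin),
    v2 = c(drug = cost("vka_daily") * days,
           monitor = cost("monitor_subsequent_cycle")))

  # utilities
  util <- function(item) p$utilities$value[p$utilities$item == item]
  udur <- function(item) {
    p$utilities$duration_days[p$utilities$item == item]
  }
  dec_a <- util("dec_apixaban"); dec_v <- util("dec_lmwh_vka")
  dec_arm <- if (arm$drug == "apixaban") dec_a else dec_v
  u_state <- c(rep(util("baseline") - dec_arm, 2),
               rep(util("baseline"), 2),
               rep(util("baseline") - dec_a, 4),
               rep(util("baseline") - dec_v, 4),
               util("ic_state"), util("cteph_state"))
  pulse_dec <- c(
    dvt = util("dec_dvt") * udur("dec_dvt") / 365.25,
    pe = util("dec_pe") * udur("dec_pe") / 365.25,
    non_ic = util("dec_non_ic_bleed") * udur("dec_non_ic_bleed") / 365.25,
    crnm = util("dec_crnm") * udur("dec_crnm") / 365.25)

  h_pts <- if (p$long_term$pts_interpretation == "cumulative") {
    1 - (1 - p$long_term$pts_cumulative_probability)^
      (cyc / p$long_term$pts_horizon_years)
  } else {
    p$long_term$pts_cumulative_probability
  }
  pts_window <- if (p$long_term$pts_interpretation == "cumulative") {
    round(p$long_term$pts_horizon_years / cyc)
  } else Inf

  structure(list(
    arm = arm, K = K, cyc = cyc, days = days, months = months, age = age,
    EFF = EFF, STAY = STAY,
    is_on_tx = is_on_tx, w_death = w_death, w_pe = w_pe, w_dvt = w_dvt,
    mb_fatal = spv("major_bleed", "fatal"),
    mb_ic = spv("major_bleed", "ic_of_nonfatal"),
    disc_non_ic = p$policy$disc_after_non_ic,
    int_non_ic = p$policy$interrupt_non_ic_days,
    int_crnm = p$policy$interrupt_crnm_days,
    src_a_pe = src_a_pe, src_a_dvt = src_a_dvt,
    src_v_pe = src_v_pe, src_v_dvt = src_v_dvt,
    cont_factor = ifelse(is_on_tx, 1 - p$policy$disc_after_non_ic, 1),
    on_active = on_active,
    dcost_on = dcost_on, mcost_on = mcost_on,
    start_course_cost = start_course_cost, tun_cost = tun_cost,
    u_state = u_state, pulse_dec = pulse_dec,
    dec_by_class = c(on = dec_arm, tun_a = dec_a, tun_v = dec_v),
    h_pts = h_pts, pts_window = pts_window,
    stop_alive = 1e-13
  ), class = "engine_context")
}

#' One cohort transition step
#'
#' Applies cycle `k`'s competing-risk effective probabilities to an
#' occupancy vector, routes each event to its destination state (VTE death,
#' re-treatment tunnels, permanent/temporary discontinuation, post-IC-bleed
#' and CTEPH states, death), and advances tunnel and scheduled-treatment
#' positions.
#'
#' @param ctx An [engine_context()].
#' @param occ Occupancy vector over the 17 states (sums to 1).
#' @param k Cycle index (0-based).
#' @return List with `occupancy` (next cycle), `events` (named expected
#'   incident events) and `interrupt_days` (expected treatment-interruption
#'   days by drug class).
#' @export
transition_step <- function(ctx, occ, k) {
  ki <- k + 1L
  a <- occ[1:14]
  E <- ctx$EFF[ki, , ]
  e <- a * E
  stay <- a * ctx$STAY[ki, ]

  rec <- e[, 1]; mb <- e[, 2]; crnm <- e[, 3]
  ae <- e[, 4]; ct <- e[, 5]; dth <- e[, 6]

  f <- ctx$mb_fatal; ici <- ctx$mb_ic
  nonfatal <- mb * (1 - f)
  ic <- nonfatal * ici
  nonic <- nonfatal * (1 - ici)
  cont <- nonic * ctx$cont_factor
  to_off_bleed <- nonic - cont

  vdeath <- rec * ctx$w_death
  rpe <- rec * ctx$w_pe
  rdvt <- rec * ctx$w_dvt
  nd <- rec - vdeath                      # non-fatal recurrences

  tostay <- stay + crnm + cont
  act <- if (ki + 1L <= ctx$K) ctx$on_active[ki + 1L] else FALSE

  new <- numeric(17)
  dvt_ontx <- c(1, 5, 6, 9, 10); pe_ontx <- c(2, 7, 8, 11, 12)
  new[1] <- tostay[1] + (if (act) tostay[6] + tostay[10] else 0)
  new[2] <- tostay[2] + (if (act) tostay[8] + tostay[12] else 0)
  new[3] <- tostay[3] + sum(ae[dvt_ontx]) + sum(to_off_bleed[dvt_ontx]) +
    (if (act) 0 else tostay[6] + tostay[10])
  new[4] <- tostay[4] + sum(ae[pe_ontx]) + sum(to_off_bleed[pe_ontx]) +
    (if (act) 0 else tostay[8] + tostay[12])
  new[5] <- sum(rdvt[ctx$src_a_dvt])
  new[7] <- sum(nd[ctx$src_a_pe]) + sum(rpe[ctx$src_a_dvt])
  new[9] <- sum(rdvt[ctx$src_v_dvt])
  new[11] <- sum(nd[ctx$src_v_pe]) + sum(rpe[ctx$src_v_dvt])
  new[6] <- tostay[5]; new[8] <- tostay[7]
  new[10] <- tostay[9]; new[12] <- tostay[11]
  new[13] <- tostay[13] + sum(ic)
  new[14] <- tostay[14] + sum(ct)
  new[15] <- occ[15] + sum(vdeath)
  new[16] <- occ[16] + sum(mb) * f
  new[17] <- occ[17] + sum(dth)

  if (abs(sum(new) - sum(occ)) > 1e-9) {
    stop("internal error: occupancy mass not conserved at cycle ", k)
  }

  on_idx <- 1:2; ta_idx <- 5:8; tv_idx <- 9:12
  interrupt <- c(
    on    = ctx$int_non_ic * sum(cont[on_idx]) + ctx$int_crnm * sum(crnm[on_idx]),
    tun_a = ctx$int_non_ic * sum(cont[ta_idx]) + ctx$int_crnm * sum(crnm[ta_idx]),
    tun_v = ctx$int_non_ic * sum(cont[tv_idx]) + ctx$int_crnm * sum(crnm[tv_idx]))

  events <- c(recurrent_dvt = sum(rdvt), recurrent_pe = sum(rpe),
              vte_death = sum(vdeath), fatal_bleed = sum(mb) * f,
              ic_bleed = sum(ic), non_ic_bleed = sum(nonic),
              crnm_bleed = sum(crnm), ae_disc = sum(ae),
              cteph_onset = sum(ct), pts_onset = 0,
              other_death = sum(dth))

  list(occupancy = new, events = events, interrupt_days = interrupt)
}

#' Run the cohort model for one arm
#'
#' The cohort starts in the on-treatment states split by index event
#' (DVT/PE), is stepped through 3-month cycles until it is extinct or the
#' maximum age is reached, and the state-occupancy trace, incident-event
#' ledger, severe-PTS background prevalence and treatment-interruption days
#' are recorded.
#'
#' @param arm A `vte_arm` (or a prepared [engine_context()]).
#' @param p A `vte_parameters` object.
#' @param life_table A `life_table`.
#' @return A `vte_trace` object.
#' @export
run_model <- function(arm, p, life_table) {
  ctx <- if (inherits(arm, "engine_context")) arm
         else engine_context(arm, p, life_table)
  K <- ctx$K
  OCC <- matrix(0, K + 1, 17, dimnames = list(NULL, STATE_NAMES))
  EVT <- matrix(0, K, 11, dimnames = list(NULL, EVENT_NAMES))
  INT <- matrix(0, K, 3, dimnames = list(NULL, c("on", "tun_a", "tun_v")))
  pts_prev <- numeric(K)

  occ <- numeric(17)
  occ[1] <- p$population$dvt_fraction
  occ[2] <- p$population$pe_fraction

  # severe-PTS eligibility queue: mass by cycles since latest DVT
  W <- ctx$pts_window
  finiteW <- is.finite(W)
  q <- if (finiteW) c(p$population$dvt_fraction, numeric(W - 1)) else NULL
  pool <- 0
  dvt_states <- c(1, 3, 5, 6, 9, 10)

  used <- K
  for (k in 0:(K - 1)) {
    ki <- k + 1L
    if (!ctx$on_active[ki] && (occ[1] + occ[2]) > 0) {
      occ[3] <- occ[3] + occ[1]; occ[4] <- occ[4] + occ[2]
      occ[1] <- 0; occ[2] <- 0
    }
    OCC[ki, ] <- occ
    alive <- 1 - sum(occ[15:17])
    if (alive < ctx$stop_alive) { used <- k; break }
    pts_prev[ki] <- pool

    stp <- transition_step(ctx, occ, k)
    new <- stp$occupancy
    EVT[ki, ] <- stp$events
    INT[ki, ] <- stp$interrupt_days

    # PTS background attribute
    if (finiteW) {
      onset <- ctx$h_pts * sum(q)
      q <- q * (1 - ctx$h_pts)
      q <- c(stp$events[["recurrent_dvt"]], q[-W])
    } else {
      eligible <- max(0, sum(occ[dvt_states]) - pool)
      onset <- ctx$h_pts * eligible
    }
    EVT[ki, "pts_onset"] <- onset
    pool <- pool + onset
    alive_new <- 1 - sum(new[15:17])
    ratio <- if (alive > 0) alive_new / alive else 0
    pool <- min(pool * ratio, alive_new)
    if (finiteW) q <- q * ratio

    occ <- new
  }
  if (used == K) OCC[K + 1, ] <- occ

  keep <- seq_len(used)
  structure(list(
    arm = ctx$arm, K = used,
    occupancy = OCC[keep, , drop = FALSE],
    events = EVT[keep, , drop = FALSE],
    interrupt_days = INT[keep, , drop = FALSE],
    pts_prevalence = pts_prev[keep],
    month = ctx$months[keep], age = ctx$age[keep],
    cycle_years = ctx$cyc
  ), class = "vte_trace")
}

#' @export
print.vte_trace <- function(x, ...) {
  cat(sprintf("<vte_trace %s: %d cycles (to age %.1f)>\n", x$arm$name, x$K,
              max(x$age) + x$cycle_years))
  cat(sprintf("  final occupancy: %.4f dead (%.4f VTE, %.4f bleed, %.4f other)\n",
              sum(x$occupancy[x$K, 15:17]), x$occupancy[x$K, 15],
              x$occupancy[x$K, 16], x$occupancy[x$K, 17]))
  invisible(x)
}

#' Accrue discounted life-years, QALYs and costs over a cohort trace
#'
#' Per cycle `k` (3 months), with discount factor `(1 + r)^(-0.25 k)`:
#' life-years and state utilities accrue on start-of-cycle occupancy;
#' transient events contribute duration-weighted utility decrements and
#' acute costs at incidence; semi-absorbing states and background severe
#' PTS contribute per-cycle maintenance costs; drug, monitoring and
#' administration costs follow the arm schedule and any re-treatment
#' courses, net of bleeding-related interruption days.
#'
#' @param trace A `vte_trace` from [run_model()].
#' @param arm The `vte_arm` the trace was run with.
#' @param p The `vte_parameters` used.
#' @return A `vte_outcomes` object.
#' @export
accrue_outcomes <- function(trace, arm, p) {
  st <- p$settings
  cyc <- trace$cycle_years
  K <- trace$K
  k <- 0:(K - 1)
  v <- (1 + st$discount_rate)^(-cyc * k)
  days <- 365.25 * cyc
  OCC <- trace$occupancy
  EVT <- trace$events

  cost <- function(item) p$costs$value[p$costs$item == item]
  util <- function(item) p$utilities$value[p$utilities$item == item]
  udur <- function(item) p$utilities$duration_days[p$utilities$item == item]

  dec_a <- util("dec_apixaban"); dec_v <- util("dec_lmwh_vka")
  dec_arm <- if (arm$drug == "apixaban") dec_a else dec_v
  u_state <- c(rep(util("baseline") - dec_arm, 2), rep(util("baseline"), 2),
               rep(util("baseline") - dec_a, 4),
               rep(util("baseline") - dec_v, 4),
               util("ic_state"), util("cteph_state"))

  alive <- 1 - rowSums(OCC[, 15:17, drop = FALSE])
  occ_mid <- OCC[, 1:14, drop = FALSE]
  if (isTRUE(st$half_cycle_correction)) {
    nxt <- rbind(occ_mid[-1, , drop = FALSE], occ_mid[K, ] * 0)
    occ_mid <- (occ_mid + nxt) / 2
    alive <- rowSums(occ_mid)
  }

  ly_cycle <- cyc * alive
  u_occ <- cyc * as.vector(occ_mid %*% u_state)
  pts_dec <- cyc * util("dec_pts") * trace$pts_prevalence

  pulse <- EVT[, "recurrent_dvt"] * util("dec_dvt") * udur("dec_dvt") / 365.25 +
    EVT[, "recurrent_pe"] * util("dec_pe") * udur("dec_pe") / 365.25 +
    EVT[, "non_ic_bleed"] * util("dec_non_ic_bleed") *
      udur("dec_non_ic_bleed") / 365.25 +
    EVT[, "crnm_bleed"] * util("dec_crnm") * udur("dec_crnm") / 365.25
  giveback <- (trace$interrupt_days[, "on"] * dec_arm +
               trace$interrupt_days[, "tun_a"] * dec_a +
               trace$interrupt_days[, "tun_v"] * dec_v) / 365.25
  qaly_cycle <- u_occ - pts_dec - pulse + giveback

  # drug / monitoring cost schedules (mirrors engine_context)
  si <- p$policy$self_inject; lmwh_d <- p$policy$lmwh_days
  edu_admin <- cost("lmwh_education") +
    cost("lmwh_admin_daily") * (1 - si) * lmwh_d
  on_active <- trace$month < arm$duration_months
  if (arm$drug == "apixaban") {
    dcost_on <- ifelse(k == 0, cost("apix_daily_initial") * 7 +
                         cost("apix_daily_extended") * (days - 7),
                       cost("apix_daily_extended") * days)
    mcost_on <- rep(0, K); course0 <- 0
  } else {
    dcost_on <- ifelse(k == 0, cost("lmwh_vka_daily_initial") * lmwh_d +
                         cost("vka_daily") * (days - lmwh_d),
                       cost("vka_daily") * days)
    mcost_on <- ifelse(k == 0, cost("monitor_first_cycle"),
                       cost("monitor_subsequent_cycle"))
    course0 <- edu_admin
  }
  dcost_on[!on_active] <- 0; mcost_on[!on_active] <- 0
  tun_drug <- cbind(
    a1 = cost("apix_daily_initial") * 7 + cost("apix_daily_extended") * (days - 7),
    a2 = cost("apix_daily_extended") * days,
    v1 = cost("lmwh_vka_daily_initial") * lmwh_d +
      cost("vka_daily") * (days - lmwh_d),
    v2 = cost("vka_daily") * days)
  tun_mon <- cbind(a1 = 0, a2 = 0,
                   v1 = cost("monitor_first_cycle") + edu_admin,
                   v2 = cost("monitor_subsequent_cycle"))

  on_occ <- rowSums(OCC[, 1:2, drop = FALSE])
  tun_occ <- OCC[, 5:12, drop = FALSE]
  tun_cols <- c("a1", "a2", "a1", "a2", "v1", "v2", "v1", "v2")
  drug_cost <- dcost_on * on_occ +
    as.vector(tun_occ %*% as.numeric(tun_drug[, tun_cols]))
  daily_on <- dcost_on / days
  drug_cost <- drug_cost - trace$interrupt_days[, "on"] * daily_on -
    trace$interrupt_days[, "tun_a"] * cost("apix_daily_extended") -
    trace$interrupt_days[, "tun_v"] * cost("vka_daily")
  monitor_cost <- mcost_on * on_occ +
    as.vector(tun_occ %*% as.numeric(tun_mon[, tun_cols]))
  monitor_cost[1] <- monitor_cost[1] + course0 * on_occ[1]

  event_cost <- EVT[, "recurrent_dvt"] * cost("dvt") +
    (EVT[, "recurrent_pe"] + EVT[, "vte_death"]) * cost("pe") +
    EVT[, "ic_bleed"] * (cost("ic_acute") + cost("ic_maintenance")) +
    OCC[, "post_ic"] * cost("ic_long_term_cycle") +
    EVT[, "cteph_onset"] * cost("cteph_acute") +
    OCC[, "cteph"] * cost("cteph_long_term_cycle") +
    EVT[, "non_ic_bleed"] * cost("non_ic_bleed") +
    EVT[, "crnm_bleed"] * cost("crnm_bleed") +
    trace$pts_prevalence * cost("pts_cycle")

  if (isTRUE(st$include_index_event)) {
    fr <- p$population
    event_cost[1] <- event_cost[1] + fr$dvt_fraction * cost("dvt") +
      fr$pe_fraction * cost("pe")
    qaly_cycle[1] <- qaly_cycle[1] -
      fr$dvt_fraction * util("dec_dvt") * udur("dec_dvt") / 365.25 -
      fr$pe_fraction * util("dec_pe") * udur("dec_pe") / 365.25
  }

  per_cycle <- data.frame(
    cycle = k, month = trace$month, age = trace$age, alive = alive,
    ly = ly_cycle, qaly = qaly_cycle, cost_anticoagulant = drug_cost,
    cost_monitoring = monitor_cost, cost_event = event_cost,
    discount = v)

  total <- function(x, disc = TRUE) sum(x * if (disc) v else 1)
  cohort <- p$population$cohort_size
  ev_tot <- colSums(EVT) * cohort
  ev_tot <- c(ev_tot,
              recurrent_vte = unname(ev_tot["recurrent_dvt"] +
                ev_tot["recurrent_pe"] + ev_tot["vte_death"]),
              major_bleed = unname(ev_tot["fatal_bleed"] +
                ev_tot["ic_bleed"] + ev_tot["non_ic_bleed"]))

  structure(list(
    arm = arm,
    ly = total(ly_cycle), qaly = total(qaly_cycle),
    cost_anticoagulant = total(drug_cost),
    cost_monitoring = total(monitor_cost),
    cost_event = total(event_cost),
    cost_total = total(drug_cost + monitor_cost + event_cost),
    ly_undiscounted = total(ly_cycle, FALSE),
    qaly_undiscounted = total(qaly_cycle, FALSE),
    cost_total_undiscounted = total(drug_cost + monitor_cost + event_cost,
                                    FALSE),
    events_per_cohort = ev_tot, cohort_size = cohort,
    per_cycle = per_cycle
  ), class = "vte_outcomes")
}

#' @export
print.vte_outcomes <- function(x, ...) {
  cat(sprintf("<vte_outcomes %s>\n", x$arm$name))
  cat(sprintf("  discounted per patient: %.3f LY, %.3f QALY, £%.0f total\n",
              x$ly, x$qaly, x$cost_total))
  cat(sprintf("    anticoagulant £%.0f, monitoring/admin £%.0f, events £%.0f\n",
              x$cost_anticoagulant, x$cost_monitoring, x$cost_event))
  cat(sprintf("  events per %d: %.0f recurrent VTE, %.0f major bleed, %.0f CRNM\n",
              x$cohort_size, x$events_per_cohort["recurrent_vte"],
              x$events_per_cohort["major_bleed"],
              x$events_per_cohort["crnm_bleed"]))
  invisible(x)
}

#' Lifetime expected event counts per cohort
#'
#' @param trace A `vte_trace`.
#' @param cohort_size Cohort size for scaling (default 1000).
#' @return Named vector of undiscounted expected lifetime event counts,
#'   including the recurrent-VTE and major-bleed composites.
#' @export
count_events <- function(trace, cohort_size = 1000) {
  ev <- colSums(trace$events) * cohort_size
  c(ev,
    recurrent_vte = unname(ev["recurrent_dvt"] + ev["recurrent_pe"] +
      ev["vte_death"]),
    major_bleed = unname(ev["fatal_bleed"] + ev["ic_bleed"] +
      ev["non_ic_bleed"]))
}

#' Run one arm end to end
#'
#' @param arm A `vte_arm`.
#' @param p A `vte_parameters`.
#' @param life_table A `life_table`.
#' @return A `vte_outcomes` object (the trace is in `$trace`).
#' @export
run_arm <- function(arm, p, life_table) {
  trace <- run_model(arm, p, life_table)
  out <- accrue_outcomes(trace, arm, p)
  out$trace <- trace
  out
}

#' Export a cohort trace and its accruals as CSV
#'
#' One row per cycle: occupancy, incident events, PTS prevalence and
#' per-cycle accruals.
#'
#' @param outcomes A `vte_outcomes` with `$trace` (from [run_arm()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_trace <- function(outcomes, path) {
  trace <- outcomes$trace
  stopifnot(!is.null(trace))
  df <- cbind(outcomes$per_cycle,
              as.data.frame(trace$occupancy),
              as.data.frame(trace$events),
              pts_prevalence = trace$pts_prevalence)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
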