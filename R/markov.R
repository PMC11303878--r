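# Cohort engine: runs the state-occupancy trace over the horizon and accrues
# discounted costs and DALYs per arm.

#' Discount factor for an annual cycle
#'
#' Costs and benefits are discounted beyond the first year: cycle 1 is
#' undiscounted and cycle `k` carries `(1 + rate)^-(k - 1)`.
#'
#' @param cycle 1-based cycle index (vectorized).
#' @param rate annual discount rate, `>= 0`.
#' @return discount factor(s).
#' @export
discount_factor <- function(cycle, rate) {
  if (any(cycle < 1)) stop_domain("cycle index must be >= 1")
  if (rate < 0) stop_domain("discount rate must be >= 0")
  (1 + rate)^(-(cycle - 1))
}

# event-probability block: 6 living states x 4 event outcomes, constant over
# cycles because the arm's QRISK3 score is held fixed over the horizon
event_prob_block <- function(q_arm, params) {
  live <- setdiff(health_states(), "DEAD")
  t(vapply(live, function(s) {
    if (s == "HTN") first_event_probs(q_arm, params$epi)
    else subsequent_event_probs(s, q_arm, params$epi, params$hazard_ratios)
  }, numeric(4)))
}

#' Run the cohort trace for one arm
#'
#' All mass starts in the hypertensive state at cycle 0 (the intervention
#' year, during which no cardiovascular events occur). Each subsequent annual
#' cycle applies the transition row of every living state at the cohort's
#' current age and records the four event flows.
#'
#' @param arm_name one of `"usual_care"`, `"group_medical_visits"`,
#'   `"microfinance"`, `"gmv_mf"`.
#' @param params a `cea_parameters` object.
#' @param stratum `"population"`, `"men"`, or `"women"`; default from settings.
#' @return an object of class `cohort_trace`: occupancy matrix
#'   `(horizon + 1) x 7` (rows are cycles 0..horizon), event-flow matrix
#'   `horizon x 4`, and run metadata.
#' @export
run_cohort <- function(arm_name, params, stratum = NULL) {
  stopifnot(inherits(params, "cea_parameters"))
  stratum <- stratum %||% params$settings$stratum
  if (!arm_name %in% names(params$arms)) stop_domain("unknown arm '", arm_name, "'")
  s <- params$settings
  H <- as.integer(s$horizon)
  q <- qrisk_for_arm(params, arm_name, stratum)
  states <- health_states()
  live <- setdiff(states, "DEAD")

  E <- event_prob_block(q, params)   # rows: live states; cols: 4 event outcomes
  occ <- matrix(0, H + 1, 7, dimnames = list(0:H, states))
  occ[1, "HTN"] <- 1
  flows <- matrix(0, H, 4, dimnames = list(
    1:H, c("nonfatal_mi", "fatal_mi", "nonfatal_stroke", "fatal_stroke")))

  for (k in seq_len(H)) {
    age <- s$start_age + k - 1
    prev <- occ[k, ]
    nxt <- numeric(7); names(nxt) <- states
    nxt["DEAD"] <- prev["DEAD"]
    for (i in seq_along(live)) {
      st <- live[i]
      m <- prev[st]
      if (m == 0) next
      pd <- background_mortality(age, params$life_table, st != "HTN",
                                 params$hazard_ratios)
      ev <- E[i, ] * (1 - pd)
      stay <- 1 - pd - sum(ev)
      nxt[st] <- nxt[st] + m * stay
      nxt["DEAD"] <- nxt["DEAD"] + m * (pd + ev["fatal_mi"] + ev["fatal_stroke"])
      if (st %in% names(NONFATAL_DEST)) {
        d <- NONFATAL_DEST[[st]]
        nxt[d[1]] <- nxt[d[1]] + m * ev["nonfatal_mi"]
        nxt[d[2]] <- nxt[d[2]] + m * ev["nonfatal_stroke"]
      }
      flows[k, ] <- flows[k, ] + m * ev
    }
    occ[k + 1, ] <- nxt
  }
  stopifnot(all(abs(rowSums(occ) - 1) < 1e-10))
  structure(list(arm = arm_name, stratum = stratum, occupancy = occ,
                 flows = flows, qrisk = q, settings = s),
            class = "cohort_trace")
}

#' Accrue discounted costs and DALYs over a cohort trace
#'
#' Per cycle, state-occupancy accruals (hypertension-management cost and
#' no-CVD disability weight in the hypertensive state; chronic-management
#' cost and state weight in chronic states; a DALY of 1 and zero cost in the
#' death state) are half-cycle corrected by the trapezoidal rule when
#' enabled, one-off hospitalisation costs and acute disutilities attach to
#' the cycle's event flows, and every cycle accrual is discounted. Cycle 0
#' carries the intervention's first-year cost undiscounted and, when
#' `cycle0_accrual` is on, the hypertensive-state cost and weight; in the
#' recurrent-cost scenario the subsequent-year intervention cost is added,
#' discounted, in cycles 1-9 (ten delivery years in total).
#'
#' By default only non-fatal events accrue the one-off hospitalisation cost
#' and acute disutility; set `settings$fatal_event_accrual` to `TRUE` to
#' attach them to fatal events as well.
#'
#' @param trace a `cohort_trace` from [run_cohort()].
#' @param params the same `cea_parameters` object the trace was run with.
#' @return an object of class `arm_result` with `total_cost`, `total_dalys`
#'   (discounted, per person), and per-cycle accrual vectors.
#' @export
accrue_outcomes <- function(trace, params) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(params, "cea_parameters"))
  s <- params$settings
  if (!identical(trace$settings$horizon, s$horizon)) {
    stop("trace/parameter mismatch: horizon differs")
  }
  H <- as.integer(s$horizon)
  occ <- trace$occupancy
  flows <- trace$flows
  cc <- params$clinical_costs
  w <- params$disability_weights
  state_cost <- c(cc$htn_management, rep(cc$chronic_cvd_management, 5), 0)
  state_daly <- c(w$no_cvd, w$chronic_one_mi, w$chronic_one_stroke,
                  w$chronic_two_mi, w$chronic_two_stroke,
                  w$chronic_mi_and_stroke, 1)

  arm <- params$arms[[trace$arm]]
  cycle_cost <- numeric(H + 1)
  cycle_daly <- numeric(H + 1)
  cycle_cost[1] <- arm$year1_cost +
    if (isTRUE(s$cycle0_accrual)) cc$htn_management else 0
  cycle_daly[1] <- if (isTRUE(s$cycle0_accrual)) w$no_cvd else 0

  for (k in seq_len(H)) {
    so <- if (isTRUE(s$half_cycle_correction)) (occ[k, ] + occ[k + 1, ]) / 2
          else occ[k + 1, ]
    if (isTRUE(s$fatal_event_accrual)) {
      n_mi <- flows[k, "nonfatal_mi"] + flows[k, "fatal_mi"]
      n_st <- flows[k, "nonfatal_stroke"] + flows[k, "fatal_stroke"]
    } else {
      n_mi <- flows[k, "nonfatal_mi"]
      n_st <- flows[k, "nonfatal_stroke"]
    }
    ck <- sum(so * state_cost) + n_mi * cc$mi_hospitalisation +
      n_st * cc$stroke_hospitalisation
    if (isTRUE(s$recurrent_intervention_costs) && k <= 9) {
      ck <- ck + arm$subsequent_year_cost
    }
    dk <- sum(so * state_daly) + n_mi * w$acute_mi_disutility +
      n_st * w$acute_stroke_disutility
    d <- discount_factor(k, s$discount_rate)
    cycle_cost[k + 1] <- d * ck
    cycle_daly[k + 1] <- d * dk
  }
  structure(list(arm = trace$arm, stratum = trace$stratum,
                 total_cost = sum(cycle_cost), total_dalys = sum(cycle_daly),
                 cycle_cost = cycle_cost, cycle_daly = cycle_daly,
                 horizon = H),
            class = "arm_result")
}

#' Run one arm end to end
#'
#' Convenience wrapper: [run_cohort()] then [accrue_outcomes()].
#'
#' @inheritParams run_cohort
#' @return an `arm_result`.
#' @export
run_arm <- function(arm_name, params, stratum = NULL) {
  accrue_outcomes(run_cohort(arm_name, params, stratum), params)
}

#' @export
print.cohort_trace <- function(x, ...) {
  H <- nrow(x$occupancy) - 1
  cat(sprintf("cohort trace: %s / %s, %d cycles, QRISK3 %.2f%%\n",
              x$arm, x$stratum, H, x$qrisk))
  cat(sprintf("  dead by end of horizon: %.1f%%\n",
              100 * x$occupancy[H + 1, "DEAD"]))
  invisible(x)
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("%s (%s): total cost $%.2f, total DALYs %.4f per person over %d cycles\n",
              x$arm, x$stratum, x$total_cost, x$total_dalys, x$horizon))
  invisible(x)
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  H <- nrow(x$occupancy) - 1
  cbind(data.frame(cycle = 0:H), as.data.frame(x$occupancy),
        rbind(NA, as.data.frame(x$flows)))
}

#' Export a cohort trace (occupancy, flows, discounted accruals) to CSV
#'
#' @param trace a `cohort_trace`.
#' @param params the matching `cea_parameters`.
#' @param file CSV path.
#' @return the exported data frame, invisibly.
#' @export
write_trace_csv <- function(trace, params, file) {
  res <- accrue_outcomes(trace, params)
  out <- as.data.frame(trace)
  out$discounted_cost <- res$cycle_cost
  out$discounted_daly <- res$cycle_daly
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}
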