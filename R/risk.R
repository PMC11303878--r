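# Risk engine: converts ten-year QRISK3 risk into per-cycle transition
# probabilities over the seven health states.

#' Health state labels
#'
#' Seven mutually exclusive states: hypertensive (no CVD history), five
#' chronic cardiovascular-disease states keyed by event history, and death
#' (absorbing).
#' @export
health_states <- function() {
  c("HTN", "POST_MI", "POST_STROKE", "POST_2MI", "POST_2STROKE",
    "POST_MI_STROKE", "DEAD")
}

CHRONIC_STATES <- c("POST_MI", "POST_STROKE", "POST_2MI", "POST_2STROKE",
                    "POST_MI_STROKE")
TWO_EVENT_STATES <- c("POST_2MI", "POST_2STROKE", "POST_MI_STROKE")
OUTCOMES <- c("no_event", "nonfatal_mi", "fatal_mi", "nonfatal_stroke",
              "fatal_stroke", "noncvd_death")

#' Annualize a ten-year risk under a constant hazard
#'
#' Converts a QRISK3 ten-year risk (percent) to the annual event probability
#' `1 - (1 - q/100)^(1/10)`: compounding the annual probability ten times
#' recovers the ten-year risk exactly.
#'
#' @param q ten-year risk in percent, in `[0, 100)`.
#' @return annual event probability.
#' @examples
#' ten_year_risk_to_annual_prob(11.5)
#' @export
ten_year_risk_to_annual_prob <- function(q) {
  if (any(q < 0 | q >= 100)) stop_domain("ten-year risk must be in [0, 100)")
  1 - (1 - q / 100)^(1 / 10)
}

#' Convert an annual probability to a hazard rate
#' @param p probability in `[0, 1)`.
#' @return hazard rate per year, `-log(1 - p)`.
#' @export
prob_to_rate <- function(p) {
  if (any(p < 0 | p >= 1)) stop_domain("probability must be in [0, 1)")
  -log(1 - p)
}

#' Convert a hazard rate to an annual probability
#' @param r non-negative hazard rate per year.
#' @return probability `1 - exp(-r)`.
#' @export
rate_to_prob <- function(r) {
  if (any(r < 0)) stop_domain("rate must be >= 0")
  1 - exp(-r)
}

#' Apply a hazard ratio to a probability on the rate scale
#'
#' The probability is converted to a hazard rate, multiplied by the hazard
#' ratio, and converted back: `1 - (1 - p)^hr`.
#'
#' @param p probability in `[0, 1)`.
#' @param hr hazard ratio, `> 0`.
#' @return adjusted probability.
#' @export
adjust_prob_by_hr <- function(p, hr) {
  if (any(hr <= 0)) stop_domain("hazard ratio must be > 0")
  rate_to_prob(hr * prob_to_rate(p))
}

#' First cardiovascular-event probabilities by type and fatality
#'
#' Annualizes the arm's QRISK3 score, splits the annual event probability
#' into strokes and heart attacks by the stroke fraction, and splits each
#' type into fatal and non-fatal by the case-fatality proportions.
#'
#' @param q_arm arm-specific QRISK3 ten-year risk, percent.
#' @param epi list with `stroke_fraction`, `fatal_mi_fraction`,
#'   `fatal_stroke_fraction` (as in `params$epi`).
#' @return named vector with `nonfatal_mi`, `fatal_mi`, `nonfatal_stroke`,
#'   `fatal_stroke`; the four entries sum to the annual event probability.
#' @export
first_event_probs <- function(q_arm, epi) {
  p_event <- ten_year_risk_to_annual_prob(q_arm)
  p_stroke <- epi$stroke_fraction * p_event
  p_mi <- (1 - epi$stroke_fraction) * p_event
  c(nonfatal_mi = p_mi * (1 - epi$fatal_mi_fraction),
    fatal_mi = p_mi * epi$fatal_mi_fraction,
    nonfatal_stroke = p_stroke * (1 - epi$fatal_stroke_fraction),
    fatal_stroke = p_stroke * epi$fatal_stroke_fraction)
}

# (event HR for MI, event HR for stroke, fatal-MI HR, fatal-stroke HR) by history
history_hrs <- function(source, hrs) {
  switch(source,
    POST_MI = c(hrs$mi_after_mi, hrs$stroke_after_mi,
                hrs$fatal_mi_after_mi, hrs$fatal_stroke_after_mi),
    POST_STROKE = c(hrs$mi_after_stroke, hrs$stroke_after_stroke,
                    hrs$fatal_mi_after_stroke, hrs$fatal_stroke_after_stroke),
    POST_2MI = c(hrs$mi_after_mi, hrs$stroke_after_mi, NA, NA),
    POST_2STROKE = c(hrs$mi_after_stroke, hrs$stroke_after_stroke, NA, NA),
    POST_MI_STROKE = c(hrs$mi_after_both, hrs$stroke_after_both, NA, NA),
    stop_domain("'", source, "' has no event history")
  )
}

#' Subsequent cardiovascular-event probabilities from a chronic state
#'
#' Type-specific first-event probabilities are adjusted on the hazard scale
#' with the hazard ratio matching the state's event history; case-fatality
#' proportions are adjusted the same way with the fatal-event hazard ratios.
#' From the two-event states any further event is fatal (the model caps
#' non-fatal events at two).
#'
#' @param source a chronic state name (see [health_states()]).
#' @inheritParams first_event_probs
#' @param hrs hazard-ratio list (as in `params$hazard_ratios`).
#' @return named vector as in [first_event_probs()].
#' @export
subsequent_event_probs <- function(source, q_arm, epi, hrs) {
  if (!source %in% CHRONIC_STATES) {
    stop_domain("source state must be a chronic CVD state, got '", source, "'")
  }
  p_event <- ten_year_risk_to_annual_prob(q_arm)
  h <- history_hrs(source, hrs)
  p_mi <- adjust_prob_by_hr((1 - epi$stroke_fraction) * p_event, h[1])
  p_stroke <- adjust_prob_by_hr(epi$stroke_fraction * p_event, h[2])
  if (source %in% TWO_EVENT_STATES) {
    f_mi <- 1
    f_stroke <- 1
  } else {
    f_mi <- min(1, adjust_prob_by_hr(epi$fatal_mi_fraction, h[3]))
    f_stroke <- min(1, adjust_prob_by_hr(epi$fatal_stroke_fraction, h[4]))
  }
  c(nonfatal_mi = p_mi * (1 - f_mi),
    fatal_mi = p_mi * f_mi,
    nonfatal_stroke = p_stroke * (1 - f_stroke),
    fatal_stroke = p_stroke * f_stroke)
}

#' Annual probability of non-cardiovascular death
#'
#' Age-band lookup in the life table, multiplied on the hazard scale by the
#' all-cause hazard ratio for people with an event history.
#'
#' @param age age in years.
#' @param life_table data frame with `lower`, `upper`, `prob`.
#' @param has_event_history logical.
#' @param hrs hazard-ratio list (uses `allcause_after_event`).
#' @return annual probability of dying from non-CVD causes.
#' @export
background_mortality <- function(age, life_table, has_event_history = FALSE,
                                 hrs = list(allcause_after_event = 1)) {
  i <- which(age >= life_table$lower & age <= life_table$upper)
  if (!length(i)) stop_domain("age ", age, " outside life-table coverage")
  p <- life_table$prob[i[1]]
  if (has_event_history && hrs$allcause_after_event != 1) {
    p <- adjust_prob_by_hr(p, hrs$allcause_after_event)
  }
  p
}

# destinations of non-fatal events: list(source) -> c(mi_dest, stroke_dest)
NONFATAL_DEST <- list(
  HTN = c("POST_MI", "POST_STROKE"),
  POST_MI = c("POST_2MI", "POST_MI_STROKE"),
  POST_STROKE = c("POST_MI_STROKE", "POST_2STROKE")
)

#' One row of the annual transition model
#'
#' Combines non-CVD mortality and cardiovascular-event risk as competing
#' risks: background death is applied first and event probabilities are
#' scaled by the probability of surviving it, so the six outcome
#' probabilities sum to one.
#'
#' @param source a living state name.
#' @param age age in years during the cycle.
#' @param q_arm arm-specific QRISK3 score, percent.
#' @param params a `cea_parameters` object.
#' @return list with `source`, `age`, `probs` (named over `no_event`,
#'   `nonfatal_mi`, `fatal_mi`, `nonfatal_stroke`, `fatal_stroke`,
#'   `noncvd_death`), and `destinations` mapping each outcome to its state.
#' @export
build_transition_row <- function(source, age, q_arm, params) {
  if (source == "DEAD") stop_domain("DEAD is absorbing; no transition row")
  if (!source %in% health_states()) stop_domain("unknown state '", source, "'")
  p_death <- background_mortality(age, params$life_table,
                                  has_event_history = source != "HTN",
                                  hrs = params$hazard_ratios)
  ev <- if (source == "HTN") {
    first_event_probs(q_arm, params$epi)
  } else {
    subsequent_event_probs(source, q_arm, params$epi, params$hazard_ratios)
  }
  ev <- ev * (1 - p_death)
  probs <- c(no_event = unname(1 - p_death - sum(ev)), ev,
             noncvd_death = p_death)
  dest <- c(no_event = source,
            nonfatal_mi = if (source %in% names(NONFATAL_DEST)) NONFATAL_DEST[[source]][1] else NA,
            fatal_mi = "DEAD",
            nonfatal_stroke = if (source %in% names(NONFATAL_DEST)) NONFATAL_DEST[[source]][2] else NA,
            fatal_stroke = "DEAD",
            noncvd_death = "DEAD")
  stopifnot(abs(sum(probs) - 1) < 1e-12)
  list(source = source, age = age, probs = probs, destinations = dest)
}

#' Tabulate all transition rows for an arm
#'
#' Writes (or returns) one row per living state and model cycle, for
#' inspection of the assembled transition probabilities.
#'
#' @param arm_name one of the four arm names.
#' @param params a `cea_parameters` object.
#' @param stratum `"population"`, `"men"`, or `"women"`; default from settings.
#' @param file optional CSV path.
#' @return data frame of transition probabilities, invisibly if written.
#' @export
transition_table <- function(arm_name, params, stratum = NULL, file = NULL) {
  stratum <- stratum %||% params$settings$stratum
  q <- qrisk_for_arm(params, arm_name, stratum)
  s <- params$settings
  rows <- list()
  for (k in seq_len(s$horizon)) {
    age <- s$start_age + k - 1
    for (st in setdiff(health_states(), "DEAD")) {
      tr <- build_transition_row(st, age, q, params)
      rows[[length(rows) + 1]] <- data.frame(
        arm = arm_name, stratum = stratum, cycle = k, age = age, source = st,
        t(tr$probs))
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}
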