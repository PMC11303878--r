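test_that("constant-hazard annualization matches the closed form", {
  expect_equal(ten_year_risk_to_annual_prob(11.5), 1 - 0.885^0.1, tolerance = 1e-12)
  expect_lt(abs(ten_year_risk_to_annual_prob(11.5) - 0.0121424), 1e-7)
  expect_equal(ten_year_risk_to_annual_prob(0), 0)
  expect_error(ten_year_risk_to_annual_prob(100), "100")
  # compounding the annual no-event probability ten times recovers the
  # ten-year risk
  for (q in c(0.5, 5, 11.5, 40, 90)) {
    pa <- ten_year_risk_to_annual_prob(q)
    expect_equal(1 - (1 - pa)^10, q / 100, tolerance = 1e-12)
  }
})

test_that("probability/rate conversions are exact inverses", {
  expect_equal(prob_to_rate(0.012147), -log(1 - 0.012147), tolerance = 1e-12)
  expect_lt(abs(prob_to_rate(0.012147) - 0.012222), 1e-6)
  expect_lt(abs(rate_to_prob(0.035321) - 0.034705), 1e-6)
  expect_equal(prob_to_rate(0), 0)
  expect_equal(rate_to_prob(0), 0)
  p <- seq(0, 0.99, by = 0.01)
  expect_equal(rate_to_prob(prob_to_rate(p)), p, tolerance = 1e-12)
  r <- c(0.001, 0.1, 1, 5)
  expect_true(all(rate_to_prob(r) < r))   # concavity bound
  expect_error(prob_to_rate(1), "probability")
  expect_error(rate_to_prob(-0.1), "rate")
})

test_that("hazard-ratio adjustment works on the rate scale", {
  p <- ten_year_risk_to_annual_prob(11.5)
  expect_equal(adjust_prob_by_hr(p, 2.89), 1 - exp(-2.89 * -log(1 - p)),
               tolerance = 1e-12)
  expect_lt(abs(adjust_prob_by_hr(p, 2.89) - 0.0346904), 1e-6)
  expect_lt(abs(adjust_prob_by_hr(p, 1.42) - 0.0171982), 1e-6)
  expect_equal(adjust_prob_by_hr(p, 1.0), p, tolerance = 1e-15)
  expect_error(adjust_prob_by_hr(p, 0), "hazard ratio")
})

test_that("first-event probabilities split by type and fatality", {
  epi <- list(stroke_fraction = 0.6, fatal_mi_fraction = 0.45,
              fatal_stroke_fraction = 0.45)
  ev <- first_event_probs(11.5, epi)
  expect_lt(abs(ev[["fatal_stroke"]] - 0.003280), 2e-6)
  expect_lt(abs(ev[["nonfatal_stroke"]] - 0.004009), 2e-6)
  expect_lt(abs(ev[["fatal_mi"]] - 0.002187), 2e-6)
  expect_lt(abs(ev[["nonfatal_mi"]] - 0.002672), 2e-6)
  # conservation: the four entries sum to the annual event probability
  expect_equal(sum(ev), ten_year_risk_to_annual_prob(11.5), tolerance = 1e-15)

  only_strokes <- first_event_probs(11.5, modifyList(epi, list(stroke_fraction = 1)))
  expect_equal(unname(only_strokes[c("nonfatal_mi", "fatal_mi")]), c(0, 0))

  no_deaths <- first_event_probs(11.5, modifyList(
    epi, list(fatal_mi_fraction = 0, fatal_stroke_fraction = 0)))
  expect_equal(unname(no_deaths[c("fatal_mi", "fatal_stroke")]), c(0, 0))
  expect_equal(sum(no_deaths), ten_year_risk_to_annual_prob(11.5), tolerance = 1e-15)
})

test_that("subsequent-event probabilities use history-matched hazard ratios", {
  p <- default_params()
  ev <- subsequent_event_probs("POST_STROKE", 11.5, p$epi, p$hazard_ratios)
  base <- first_event_probs(11.5, p$epi)
  # stroke risk scales by HR 2.89 on the rate scale; MI HR is 1.00
  expect_equal(sum(ev[c("nonfatal_stroke", "fatal_stroke")]),
               adjust_prob_by_hr(sum(base[c("nonfatal_stroke", "fatal_stroke")]), 2.89),
               tolerance = 1e-12)
  expect_equal(sum(ev[c("nonfatal_mi", "fatal_mi")]),
               sum(base[c("nonfatal_mi", "fatal_mi")]), tolerance = 1e-12)

  # with all hazard ratios at 1 the chronic single-event states reduce to
  # the first-event probabilities
  hr1 <- p$hazard_ratios
  hr1[] <- 1
  for (s in c("POST_MI", "POST_STROKE")) {
    expect_equal(subsequent_event_probs(s, 11.5, p$epi, hr1), base,
                 tolerance = 1e-12, info = s)
  }

  # a third event is always fatal
  for (s in c("POST_2MI", "POST_2STROKE", "POST_MI_STROKE")) {
    ev2 <- subsequent_event_probs(s, 11.5, p$epi, p$hazard_ratios)
    expect_equal(unname(ev2[c("nonfatal_mi", "nonfatal_stroke")]), c(0, 0),
                 info = s)
  }
  expect_error(subsequent_event_probs("HTN", 11.5, p$epi, p$hazard_ratios),
               "chronic")
})

test_that("background mortality is an age-band lookup with a history HR", {
  p <- default_params()
  expect_equal(background_mortality(61, p$life_table), 0.02)
  expect_equal(background_mortality(83, p$life_table), 0.11)
  expect_equal(background_mortality(90, p$life_table), 0.20)
  expect_error(background_mortality(40, p$life_table), "coverage")
  # base-case all-cause HR is 1: history makes no difference
  expect_equal(background_mortality(61, p$life_table, TRUE, p$hazard_ratios),
               background_mortality(61, p$life_table, FALSE, p$hazard_ratios))
  hrs <- modifyList(p$hazard_ratios, list(allcause_after_event = 1.5))
  expect_equal(background_mortality(61, p$life_table, TRUE, hrs),
               adjust_prob_by_hr(0.02, 1.5))
})

test_that("transition rows are proper distributions following the state chart", {
  p <- default_params()
  for (s in setdiff(health_states(), "DEAD")) {
    for (age in c(61, 70, 80)) {
      tr <- build_transition_row(s, age, 11.17, p)
      expect_equal(sum(tr$probs), 1, tolerance = 1e-12)
      expect_true(all(tr$probs >= 0))
    }
  }
  tr <- build_transition_row("POST_MI", 61, 11.5, p)
  expect_equal(unname(tr$destinations["nonfatal_mi"]), "POST_2MI")
  expect_equal(unname(tr$destinations["nonfatal_stroke"]), "POST_MI_STROKE")
  expect_error(build_transition_row("DEAD", 61, 11.5, p), "absorbing")

  # vanishing risk leaves only no-event and background death
  tr0 <- build_transition_row("HTN", 61, 1e-9, p)
  expect_equal(unname(tr0$probs["no_event"] + tr0$probs["noncvd_death"]), 1,
               tolerance = 1e-9)

  # monotonicity: higher risk score weakly raises every event probability
  qs <- seq(2, 60, by = 2)
  rows <- sapply(qs, function(q) build_transition_row("HTN", 61, q, p)$probs)
  for (o in c("nonfatal_mi", "fatal_mi", "nonfatal_stroke", "fatal_stroke")) {
    expect_true(all(diff(rows[o, ]) > 0), info = o)
  }
  expect_true(all(diff(rows["no_event", ]) < 0))
})

test_that("the transition tabulation covers every cycle and living state", {
  p <- default_params()
  tab <- transition_table("usual_care", p)
  expect_equal(nrow(tab), p$settings$horizon * 6)
  psum <- rowSums(tab[, c("no_event", "nonfatal_mi", "fatal_mi",
                          "nonfatal_stroke", "fatal_stroke", "noncvd_death")])
  expect_equal(unname(psum), rep(1, nrow(tab)), tolerance = 1e-12)
  f <- tempfile(fileext = ".csv")
  transition_table("gmv_mf", p, stratum = "men", file = f)
  expect_true(file.exists(f))
  unlink(f)
})
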