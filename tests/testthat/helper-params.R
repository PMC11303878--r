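# shared fixtures: parameters are loaded once per test run

default_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_cea_parameters(quiet = TRUE)
    cache
  }
})

# a parameter set whose event and death probabilities are (numerically) zero
null_risk_params <- function(horizon = 1) {
  p <- default_params()
  p$life_table$prob[] <- 0
  p$epi$baseline_qrisk_population <- 1e-9
  p$epi$baseline_qrisk_men <- 1e-9
  p$epi$baseline_qrisk_women <- 1e-9
  for (a in names(p$arms)) {
    p$arms[[a]][c("qrisk_change_population", "qrisk_change_men",
                  "qrisk_change_women")] <- 0
  }
  p$settings$horizon <- horizon
  validate_cea_parameters(p, quiet = TRUE)
}

# brute-force frontier oracle: exact pairwise segment test, independent of
# compute_frontier's iterative algorithm
frontier_oracle <- function(costs, dalys) {
  n <- length(costs)
  status <- rep("frontier", n)
  for (a in seq_len(n)) {
    # strict (single-arm) dominance
    for (j in seq_len(n)) {
      if (j != a && costs[j] <= costs[a] && dalys[j] <= dalys[a] &&
          (costs[j] < costs[a] || dalys[j] < dalys[a])) {
        status[a] <- "dominated"
      }
    }
  }
  for (a in seq_len(n)) {
    if (status[a] != "frontier") next
    # extended dominance: a convex combination of two other arms achieves
    # the same DALYs at lower cost
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == a || j == a || i == j) next
      if (status[i] == "dominated" || status[j] == "dominated") next
      lo <- min(dalys[i], dalys[j]); hi <- max(dalys[i], dalys[j])
      if (dalys[a] < lo || dalys[a] > hi || hi == lo) next
      lam <- (dalys[a] - dalys[j]) / (dalys[i] - dalys[j])
      comb_cost <- lam * costs[i] + (1 - lam) * costs[j]
      if (comb_cost < costs[a] - 1e-12) status[a] <- "extended_dominated"
    }
  }
  status
}
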