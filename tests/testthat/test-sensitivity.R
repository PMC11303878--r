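test_that("one-way sensitivity re-runs the model at the published bounds", {
  p <- default_params()
  e <- one_way_dsa("cost_gmv_mf", p, arm = "gmv_mf")
  expect_equal(e$low, 125.1)
  expect_equal(e$high, 152.9)
  # raising the arm's own cost lowers its INMB dollar for dollar
  expect_equal(e$inmb_low - e$inmb_high, 152.9 - 125.1, tolerance = 1e-9)
  expect_error(one_way_dsa("cost_htn", p), "no sensitivity range")

  # a degenerate range yields a zero-width bar
  pd <- p
  pd$dsa_ranges$cost_gmv_mf <- c(139, 139)
  ed <- one_way_dsa("cost_gmv_mf", pd, arm = "gmv_mf")
  expect_equal(ed$inmb_low, ed$inmb_high)
  expect_equal(ed$inmb_low, ed$inmb_base)

  # the discount rate has a non-degenerate effect on the combined arm
  er <- one_way_dsa("discount_rate", p, arm = "gmv_mf")
  expect_gt(abs(er$inmb_high - er$inmb_low), 0)
})

test_that("the tornado ranks the intervention effect sizes as most influential", {
  p <- default_params()
  tor_gmv <- tornado_analysis(p, arm = "group_medical_visits")
  expect_s3_class(tor_gmv, "cea_tornado")
  expect_equal(nrow(tor_gmv), length(p$dsa_ranges))
  expect_equal(tor_gmv$id[1], "qrisk_change_group_medical_visits")
  widths <- abs(tor_gmv$inmb_high - tor_gmv$inmb_low)
  expect_true(all(diff(widths) <= 1e-9))   # sorted, widest first

  tor_cmb <- tornado_analysis(p, arm = "gmv_mf")
  expect_equal(tor_cmb$id[1], "qrisk_change_gmv_mf")

  pe <- p
  pe$dsa_ranges <- list()
  expect_warning(tornado_analysis(pe), "empty tornado")
})

test_that("threshold analysis finds the effect size where INMB crosses zero", {
  p <- default_params()
  th <- threshold_effect("group_medical_visits", p)
  expect_equal(th$comparator, "usual_care")
  expect_lt(abs(th$inmb_at_threshold), 0.01)
  expect_gt(th$threshold, -0.33)
  expect_lt(th$threshold, 0)

  # independent root-finder agrees to 1e-4
  inmb_at <- function(chg) {
    q <- p
    q$arms$group_medical_visits$qrisk_change_population <- chg
    nmb(run_arm("group_medical_visits", q, "population"),
        run_arm("usual_care", q, "population"), p$settings$wtp)
  }
  root <- stats::uniroot(inmb_at, c(-0.33, 0), tol = 1e-10)$root
  expect_lt(abs(th$threshold - root), 1e-4)

  # INMB strictly decreases as the risk reduction shrinks toward zero
  vals <- vapply(c(-0.33, -0.25, -0.15, -0.05), inmb_at, numeric(1))
  expect_true(all(diff(vals) < 0))

  # the combined arm's threshold is against group medical visits
  th2 <- threshold_effect("gmv_mf", p)
  expect_equal(th2$comparator, "group_medical_visits")
  expect_lt(th2$threshold, 0)

  # no sign change over a degenerate interval
  none <- threshold_effect("group_medical_visits", p, interval = c(-0.33, -0.32))
  expect_null(none$threshold)
})

test_that("PSA draws are deterministic under the seed and support-respecting", {
  p <- default_params()
  d1 <- sample_psa(p, seed = 123)
  d2 <- sample_psa(p, seed = 123)
  expect_identical(d1$values, d2$values)
  expect_identical(vapply(d1$results, `[[`, numeric(1), "total_cost"),
                   vapply(d2$results, `[[`, numeric(1), "total_cost"))
  d3 <- sample_psa(p, seed = 124)
  expect_false(identical(d1$values, d3$values))

  specs <- psa_specs(p)
  expect_setequal(specs$family, c("normal", "gamma", "beta", "lognormal"))
  set.seed(99)
  for (i in 1:50) {
    v <- sample_psa(p, seed = sample.int(1e6, 1))$values
    expect_true(all(v[grepl("^cost_", names(v))] > 0))
    expect_true(all(v[grepl("^dw_", names(v))] >= 0 & v[grepl("^dw_", names(v))] <= 1))
    expect_true(all(v[grepl("^hr_", names(v))] > 0))
    expect_true(all(v[c("stroke_fraction", "fatal_mi_fraction",
                        "fatal_stroke_fraction")] <= 1))
  }
})

test_that("PSA sample means recover the base values", {
  p <- default_params()
  psa <- run_psa(p, n = 400, seed = 2024)
  specs <- psa$specs
  for (i in seq_len(nrow(specs))) {
    if (specs$sd[i] == 0) next
    m <- mean(psa$values[, specs$id[i]])
    se <- specs$sd[i] / sqrt(psa$n)
    expect_lt(abs(m - specs$mean[i]) / se, 4, label = specs$id[i])
  }
})

test_that("zero-SD PSA reproduces the base case exactly", {
  p <- default_params()
  specs <- psa_specs(p)
  specs$sd[] <- 0
  d <- sample_psa(p, seed = 5, specs = specs)
  base <- lapply(names(p$arms), run_arm, params = p, stratum = "population")
  names(base) <- names(p$arms)
  for (a in names(base)) {
    expect_equal(d$results[[a]]$total_cost, base[[a]]$total_cost, info = a)
    expect_equal(d$results[[a]]$total_dalys, base[[a]]$total_dalys, info = a)
  }
})

test_that("acceptability curves are normalized probabilities with sane limits", {
  p <- default_params()
  psa <- run_psa(p, n = 60, seed = 11)
  grid <- c(0, 500, 1500, 3360, 8000)
  cc <- ceac(psa, grid)
  probs <- as.matrix(cc[setdiff(names(cc), "wtp")])
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(unname(rowSums(probs)), rep(1, length(grid)), tolerance = 1e-9)
  expect_error(ceac(psa, numeric(0)), "empty")

  # a single draw gives 0/1 indicators
  one <- run_psa(p, n = 1, seed = 3)
  c1 <- ceac(one, grid)
  expect_true(all(as.matrix(c1[setdiff(names(c1), "wtp")]) %in% c(0, 1)))

  # at negligible willingness-to-pay the cheapest arm (usual care) wins
  expect_equal(names(which.max(probs[1, ])), "usual_care")
})

test_that("with SDs at zero the CEAC degenerates to the deterministic ranking", {
  p <- default_params()
  specs <- psa_specs(p)
  specs$sd[] <- 0
  set.seed(1)
  draws <- sample_psa(p, seed = 1, specs = specs)
  costs <- t(vapply(draws$results, `[[`, numeric(1), "total_cost"))
  dalys <- t(vapply(draws$results, `[[`, numeric(1), "total_dalys"))
  psa0 <- structure(list(costs = costs, dalys = dalys, arms = names(p$arms),
                         n = 1, seed = 1), class = "cea_psa")
  grid <- c(0, 1000, 2000, 3000, 5000, 10000)
  cc <- ceac(psa0, grid)
  base <- lapply(names(p$arms), run_arm, params = p, stratum = "population")
  names(base) <- names(p$arms)
  ref <- base$usual_care
  for (g in seq_along(grid)) {
    nmbs <- vapply(base, nmb, numeric(1), reference = ref, wtp = grid[g])
    det_best <- names(base)[which.max(nmbs)]
    row <- as.matrix(cc[g, setdiff(names(cc), "wtp")])
    expect_equal(colnames(row)[which.max(row)], det_best,
                 info = paste("wtp", grid[g]))
  }
})

test_that("deterministic NMB crossovers sit exactly at the frontier ICERs", {
  p <- default_params()
  res <- run_cea(p, "population")
  fr <- as.data.frame(res$frontier)
  gmv_icer <- fr$icer[fr$arm == "group_medical_visits"]
  cmb_icer <- fr$icer[fr$arm == "gmv_mf"]
  uc <- res$arms$usual_care
  gmv <- res$arms$group_medical_visits
  cmb <- res$arms$gmv_mf
  expect_equal(nmb(gmv, uc, gmv_icer), 0, tolerance = 1e-9)
  # at the upper frontier ICER, the combined arm ties group medical visits
  expect_equal(nmb(cmb, uc, cmb_icer) - nmb(gmv, uc, cmb_icer), 0,
               tolerance = 1e-9)
})
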