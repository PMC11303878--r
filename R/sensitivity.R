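# Deterministic and probabilistic sensitivity analysis.

#' One-way deterministic sensitivity entry for a single parameter
#'
#' Re-runs the full model twice with the parameter at the low and high bound
#' of its published range (all else at base) and records the incremental net
#' monetary benefit of `arm` versus usual care at the willingness-to-pay
#' threshold.
#'
#' @param id flat parameter id (must have an entry in `params$dsa_ranges`).
#' @param params a `cea_parameters` object.
#' @param arm comparison arm (INMB is versus usual care).
#' @param wtp willingness-to-pay, US$ per DALY averted; default from settings.
#' @param stratum stratum for the runs; default from settings.
#' @return a one-row data frame: id, low/high input, INMB at low/high/base.
#' @export
one_way_dsa <- function(id, params, arm = "gmv_mf", wtp = NULL, stratum = NULL) {
  if (!id %in% names(params$dsa_ranges)) {
    stop_domain("parameter '", id, "' has no sensitivity range")
  }
  wtp <- wtp %||% params$settings$wtp
  r <- params$dsa_ranges[[id]]
  inmb_at <- function(p) {
    nmb(run_arm(arm, p, stratum), run_arm("usual_care", p, stratum), wtp)
  }
  data.frame(id = id, low = r[1], high = r[2],
             inmb_low = inmb_at(set_parameter(params, id, r[1])),
             inmb_high = inmb_at(set_parameter(params, id, r[2])),
             inmb_base = inmb_at(params),
             stringsAsFactors = FALSE)
}

#' Tornado analysis over all ranged parameters
#'
#' @inheritParams one_way_dsa
#' @param ids parameter ids to vary; default all of `params$dsa_ranges`.
#' @return an object of class `cea_tornado`: a data frame of
#'   [one_way_dsa()] entries sorted by decreasing INMB bar width.
#' @export
tornado_analysis <- function(params, arm = "gmv_mf", wtp = NULL,
                             ids = NULL, stratum = NULL) {
  ids <- ids %||% names(params$dsa_ranges)
  if (!length(ids)) {
    warning("no parameters with sensitivity ranges; empty tornado", call. = FALSE)
    out <- data.frame(id = character(), low = numeric(), high = numeric(),
                      inmb_low = numeric(), inmb_high = numeric(),
                      inmb_base = numeric())
  } else {
    out <- do.call(rbind, lapply(ids, one_way_dsa, params = params, arm = arm,
                                 wtp = wtp, stratum = stratum))
    out <- out[order(-abs(out$inmb_high - out$inmb_low), out$id), ]
    rownames(out) <- NULL
  }
  structure(out, class = c("cea_tornado", "data.frame"),
            arm = arm, wtp = wtp %||% params$settings$wtp)
}

#' @export
print.cea_tornado <- function(x, n = 10, ...) {
  cat(sprintf("Tornado: INMB of %s vs usual care at WTP $%.0f (top %d of %d)\n",
              attr(x, "arm"), attr(x, "wtp"), min(n, nrow(x)), nrow(x)))
  print(utils::head(as.data.frame(x), n), row.names = FALSE)
  invisible(x)
}

#' Tornado diagram
#'
#' Horizontal INMB bars for the most influential parameters, widest on top.
#'
#' @param x a `cea_tornado`.
#' @param n number of parameters to draw.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.cea_tornado <- function(x, n = 10, ...) {
  d <- utils::head(as.data.frame(x), n)
  d <- d[rev(seq_len(nrow(d))), ]
  base <- d$inmb_base[1]
  lo <- pmin(d$inmb_low, d$inmb_high) - base
  hi <- pmax(d$inmb_low, d$inmb_high) - base
  op <- graphics::par(mar = c(4, 12, 2, 1)); on.exit(graphics::par(op))
  graphics::plot(NULL, xlim = range(c(lo, hi, 0)), ylim = c(0.5, nrow(d) + 0.5),
                 yaxt = "n", xlab = "INMB - base INMB (US$)", ylab = "", ...)
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$id, las = 1, cex.axis = 0.7)
  graphics::rect(lo, seq_len(nrow(d)) - 0.35, hi, seq_len(nrow(d)) + 0.35,
                 col = "steelblue")
  graphics::abline(v = 0, col = "grey40")
  invisible(x)
}

#' Threshold analysis on an arm's QRISK3 effect
#'
#' Finds the signed QRISK3 change at which the arm's incremental net monetary
#' benefit versus the next-cheapest frontier arm crosses zero, by bisection
#' to within $0.01 of INMB.
#'
#' @param arm arm whose population QRISK3 change is varied.
#' @param params a `cea_parameters` object.
#' @param wtp willingness-to-pay; default from settings.
#' @param interval search interval for the change; defaults to
#'   `c(base change, 0)`.
#' @return list with `threshold` (signed QRISK3 change), `comparator`, and
#'   `inmb_at_threshold`; or `NULL` threshold when INMB does not change sign
#'   over the interval.
#' @export
threshold_effect <- function(arm, params, wtp = NULL, interval = NULL) {
  wtp <- wtp %||% params$settings$wtp
  base_change <- params$arms[[arm]]$qrisk_change_population
  interval <- interval %||% sort(c(base_change, 0))

  base_res <- run_cea(params, stratum = "population")
  fr <- as.data.frame(base_res$frontier)
  on_fr <- fr[fr$status == "frontier", ]
  pos <- match(arm, on_fr$arm)
  if (is.na(pos) || pos == 1) {
    stop_domain("arm '", arm, "' is not a non-reference frontier arm in the base case")
  }
  comparator <- on_fr$arm[pos - 1]

  id <- paste0("qrisk_change_", arm)
  inmb_at <- function(chg) {
    p <- params
    p$arms[[arm]]$qrisk_change_population <- chg
    nmb(run_arm(arm, p, "population"), run_arm(comparator, p, "population"), wtp)
  }
  f_lo <- inmb_at(interval[1]); f_hi <- inmb_at(interval[2])
  if (sign(f_lo) == sign(f_hi)) {
    return(list(threshold = NULL, comparator = comparator,
                inmb_range = c(f_lo, f_hi)))
  }
  lo <- interval[1]; hi <- interval[2]
  repeat {
    mid <- (lo + hi) / 2
    f_mid <- inmb_at(mid)
    if (abs(f_mid) < 0.01 || (hi - lo) < 1e-10) break
    if (sign(f_mid) == sign(f_lo)) { lo <- mid; f_lo <- f_mid } else hi <- mid
  }
  list(threshold = mid, comparator = comparator, inmb_at_threshold = f_mid)
}

# ---- probabilistic sensitivity analysis -------------------------------------

# moment-matched distribution samplers on the natural scale
rgamma_mm <- function(n, mean, sd) {
  stats::rgamma(n, shape = (mean / sd)^2, rate = mean / sd^2)
}
rbeta_mm <- function(n, mean, sd) {
  v_max <- mean * (1 - mean)
  if (sd^2 >= v_max) {
    warning("beta moment match infeasible for mean ", mean, "; sd clamped",
            call. = FALSE)
    sd <- sqrt(v_max) * 0.99
  }
  nu <- mean * (1 - mean) / sd^2 - 1
  stats::rbeta(n, mean * nu, (1 - mean) * nu)
}
rlnorm_mm <- function(n, mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Sampling specification for the probabilistic sensitivity analysis
#'
#' One row per sampled parameter: distribution family (normal for QRISK3
#' effect differences, gamma for costs, beta for disability weights,
#' log-normal for hazard ratios and event proportions), mean equal to the
#' base-case value, and SD taken from the published 95% CI-derived SE where
#' one exists (range width / 3.92) or 10% of the base value otherwise.
#'
#' @param params a `cea_parameters` object.
#' @return data frame with columns `id`, `family`, `mean`, `sd`.
#' @export
psa_specs <- function(params) {
  rng <- params$dsa_ranges
  se_from_range <- function(id) (rng[[id]][2] - rng[[id]][1]) / (2 * 1.96)
  spec <- function(id, family, se) {
    data.frame(id = id, family = family, mean = dsa_base_value(params, id),
               sd = se, stringsAsFactors = FALSE)
  }
  rows <- list()
  for (a in c("microfinance", "group_medical_visits", "gmv_mf")) {
    id <- paste0("qrisk_change_", a)
    rows[[id]] <- spec(id, "normal", se_from_range(id))
  }
  for (id in c("cost_usual_care", "cost_microfinance",
               "cost_group_medical_visits", "cost_gmv_mf",
               "cost_htn_management", "cost_chronic_cvd_management",
               "cost_mi_hospitalisation", "cost_stroke_hospitalisation")) {
    rows[[id]] <- spec(id, "gamma", 0.1 * dsa_base_value(params, id))
  }
  for (f in c("no_cvd", "chronic_one_mi", "chronic_one_stroke", "chronic_two_mi",
              "chronic_two_stroke", "chronic_mi_and_stroke",
              "acute_mi_disutility", "acute_stroke_disutility")) {
    id <- paste0("dw_", f)
    rows[[id]] <- spec(id, "beta", 0.1 * dsa_base_value(params, id))
  }
  for (f in c("mi_after_mi", "stroke_after_stroke", "mi_after_stroke",
              "stroke_after_mi", "mi_after_both", "stroke_after_both",
              "fatal_mi_after_mi", "fatal_mi_after_stroke",
              "fatal_stroke_after_mi", "fatal_stroke_after_stroke",
              "allcause_after_event")) {
    id <- paste0("hr_", f)
    rows[[id]] <- spec(id, "lognormal", se_from_range(id))
  }
  rows[["stroke_fraction"]] <- spec("stroke_fraction", "lognormal",
                                    se_from_range("stroke_fraction"))
  for (id in c("fatal_mi_fraction", "fatal_stroke_fraction")) {
    rows[[id]] <- spec(id, "lognormal", 0.1 * dsa_base_value(params, id))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# draw one parameter realization; proportions from log-normal are truncated
# at 1 (unbounded support); truncation counted by the caller via attribute
sample_parameter_values <- function(specs) {
  vals <- numeric(nrow(specs))
  truncated <- FALSE
  for (i in seq_len(nrow(specs))) {
    m <- specs$mean[i]; s <- specs$sd[i]
    if (s == 0 || m == 0) { vals[i] <- m; next }
    v <- switch(specs$family[i],
      normal = stats::rnorm(1, m, s),
      gamma = rgamma_mm(1, m, s),
      beta = rbeta_mm(1, m, s),
      lognormal = rlnorm_mm(1, m, s))
    if (specs$family[i] == "lognormal" &&
        specs$id[i] %in% c("stroke_fraction", "fatal_mi_fraction",
                           "fatal_stroke_fraction") && v > 1) {
      v <- 1
      truncated <- TRUE
    }
    vals[i] <- v
  }
  structure(vals, truncated = truncated)
}

#' Draw one probabilistic sensitivity realization
#'
#' Samples every parameter in [psa_specs()] from its family (seeded), writes
#' the values into a copy of the parameter set, and runs all four arms.
#'
#' @param params a `cea_parameters` object.
#' @param seed integer seed for this draw.
#' @param specs optional precomputed [psa_specs()].
#' @return list with `params` (the realized `cea_parameters`), `values`
#'   (named sampled values), and `results` (named list of `arm_result`).
#' @export
sample_psa <- function(params, seed, specs = NULL) {
  specs <- specs %||% psa_specs(params)
  set.seed(seed)
  vals <- sample_parameter_values(specs)
  p <- params
  for (i in seq_len(nrow(specs))) {
    path <- dsa_path(specs$id[i])
    p[[path]] <- vals[i]
  }
  # support constraints hold by construction of the sampling families, so the
  # full validator (which also enforces base-case orderings) is not re-run
  results <- lapply(names(p$arms), run_arm, params = p, stratum = "population")
  names(results) <- names(p$arms)
  list(params = p, values = stats::setNames(as.numeric(vals), specs$id),
       results = results, truncated = attr(vals, "truncated"))
}

#' Run the probabilistic sensitivity analysis
#'
#' A master seed spawns one substream seed per draw, so any subset of draws
#' is reproducible independently of execution order. Each draw samples all
#' parameters and re-runs the four-arm model for the population stratum.
#'
#' @param params a `cea_parameters` object.
#' @param n number of iterations (the published analysis used 10000).
#' @param seed master seed.
#' @param progress print a dot every 1000 draws.
#' @return an object of class `cea_psa`: per-draw cost and DALY matrices
#'   (`n x 4`), the sampled parameter matrix, arm names, and the seed.
#' @export
run_psa <- function(params, n = 10000, seed = 1, progress = FALSE) {
  stopifnot(n >= 1)
  specs <- psa_specs(params)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  arm_names <- names(params$arms)
  costs <- matrix(NA_real_, n, 4, dimnames = list(NULL, arm_names))
  dalys <- matrix(NA_real_, n, 4, dimnames = list(NULL, arm_names))
  values <- matrix(NA_real_, n, nrow(specs), dimnames = list(NULL, specs$id))
  n_trunc <- 0L
  for (i in seq_len(n)) {
    d <- sample_psa(params, sub_seeds[i], specs = specs)
    costs[i, ] <- vapply(d$results, function(r) r$total_cost, numeric(1))
    dalys[i, ] <- vapply(d$results, function(r) r$total_dalys, numeric(1))
    values[i, ] <- d$values
    if (isTRUE(d$truncated)) n_trunc <- n_trunc + 1L
    if (progress && i %% 1000 == 0) cat(".")
  }
  if (progress) cat("\n")
  if (n_trunc > 0) {
    warning(n_trunc, " draw(s) had a log-normal proportion truncated at 1",
            call. = FALSE)
  }
  structure(list(costs = costs, dalys = dalys, values = values,
                 arms = arm_names, n = n, seed = seed, specs = specs),
            class = "cea_psa")
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf("PSA: %d draws (seed %d), %d sampled parameters\n",
              x$n, x$seed, ncol(x$values)))
  cat("mean total cost: ",
      paste(sprintf("%s $%.0f", x$arms, colMeans(x$costs)), collapse = ", "), "\n")
  invisible(x)
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the fraction of PSA draws in which each
#' arm attains the highest net monetary benefit (ties split equally).
#'
#' @param psa a `cea_psa` from [run_psa()].
#' @param wtp_grid vector of willingness-to-pay values; default from the grid
#'   used at `run_psa` time is not stored, so pass the settings grid.
#' @return an object of class `cea_ceac`: data frame with `wtp` and one
#'   probability column per arm (rows sum to 1).
#' @export
ceac <- function(psa, wtp_grid) {
  stopifnot(inherits(psa, "cea_psa"))
  if (!length(wtp_grid)) stop_domain("empty willingness-to-pay grid")
  out <- matrix(0, length(wtp_grid), length(psa$arms),
                dimnames = list(NULL, psa$arms))
  for (g in seq_along(wtp_grid)) {
    # NMB relative to a zero-cost, zero-DALY origin; the argmax is what matters
    benefit <- -wtp_grid[g] * psa$dalys - psa$costs
    best <- benefit == apply(benefit, 1, max)
    out[g, ] <- colMeans(best / rowSums(best))
  }
  structure(data.frame(wtp = wtp_grid, out, check.names = FALSE),
            class = c("cea_ceac", "data.frame"), seed = psa$seed, n = psa$n)
}

#' @export
print.cea_ceac <- function(x, ...) {
  cat(sprintf("CEAC over %d WTP values (%d PSA draws, seed %d)\n",
              nrow(x), attr(x, "n"), attr(x, "seed")))
  print(as.data.frame(x), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Plot cost-effectiveness acceptability curves
#'
#' @param x a `cea_ceac`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cea_ceac <- function(x, ...) {
  arms <- setdiff(names(x), "wtp")
  graphics::matplot(x$wtp, as.matrix(x[arms]), type = "l", lty = 1, lwd = 2,
                    xlab = "Willingness-to-pay (US$ per DALY averted)",
                    ylab = "Probability optimal", ylim = c(0, 1), ...)
  graphics::legend("right", legend = arms, col = seq_along(arms), lty = 1, lwd = 2,
                   cex = 0.8, bty = "n")
  invisible(x)
}
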