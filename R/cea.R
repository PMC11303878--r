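# Cost-effectiveness ranking: ICERs, strict and extended dominance, net
# monetary benefit, and the top-level analysis runner.

#' Incremental cost-effectiveness ratio between two arms
#'
#' Incremental cost divided by DALYs averted moving from the less to the more
#' expensive arm. A zero DALY difference yields `NaN` (undefined ICER) rather
#' than an error; a negative value means the costlier arm is also worse
#' (dominated).
#'
#' @param higher,lower `arm_result` objects (or lists with `total_cost` and
#'   `total_dalys`), with `higher$total_cost >= lower$total_cost`.
#' @return US$ per DALY averted.
#' @export
icer <- function(higher, lower) {
  dc <- higher$total_cost - lower$total_cost
  if (dc < 0) stop_domain("'higher' must be the costlier arm")
  dd <- lower$total_dalys - higher$total_dalys
  if (dd == 0) {
    if (dc == 0) return(0)
    return(NaN)
  }
  dc / dd
}

#' Net monetary benefit of an arm relative to a reference
#'
#' `wtp x (DALYs averted) - incremental cost`; zero exactly when the
#' willingness-to-pay equals the pairwise ICER.
#'
#' @param result,reference `arm_result` objects.
#' @param wtp willingness-to-pay threshold, US$ per DALY averted.
#' @return incremental net monetary benefit in US$.
#' @export
nmb <- function(result, reference, wtp) {
  if (wtp < 0) stop_domain("wtp must be >= 0")
  wtp * (reference$total_dalys - result$total_dalys) -
    (result$total_cost - reference$total_cost)
}

#' Cost-effectiveness frontier with strict and extended dominance
#'
#' Arms are ordered by total cost (ties broken by total DALYs ascending, then
#' by name). An arm is dominated when a single alternative has lower-or-equal
#' cost and lower-or-equal DALYs with at least one strict (an arm identical
#' in both is reported dominated, deterministically by name order). Extended
#' dominance then iteratively removes arms whose adjacent ICER is not lower
#' than the next one along the frontier, until frontier ICERs strictly
#' increase.
#'
#' @param results list of `arm_result` objects (at least two).
#' @return an object of class `cea_frontier`: a data frame with per-arm cost,
#'   DALYs, status (`frontier`, `dominated`, `extended_dominated`), the
#'   adjacent frontier ICER, and the dominating arm(s) for excluded arms.
#' @export
compute_frontier <- function(results) {
  if (length(results) < 2) stop_domain("need at least 2 arms")
  tab <- data.frame(
    arm = vapply(results, function(r) r$arm %||% "?", character(1)),
    cost = vapply(results, function(r) r$total_cost, numeric(1)),
    dalys = vapply(results, function(r) r$total_dalys, numeric(1)),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$cost, tab$dalys, tab$arm), ]
  rownames(tab) <- NULL
  n <- nrow(tab)
  tab$status <- "frontier"
  tab$dominated_by <- NA_character_

  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cheaper <- tab$cost[j] <= tab$cost[i]
      better <- tab$dalys[j] <= tab$dalys[i]
      strict <- tab$cost[j] < tab$cost[i] || tab$dalys[j] < tab$dalys[i]
      tie_both <- tab$cost[j] == tab$cost[i] && tab$dalys[j] == tab$dalys[i]
      if (cheaper && better && (strict || (tie_both && tab$arm[j] < tab$arm[i]))) {
        tab$status[i] <- "dominated"
        tab$dominated_by[i] <- tab$arm[j]
        break
      }
    }
  }

  repeat {
    idx <- which(tab$status == "frontier")
    if (length(idx) < 3) break
    ic <- diff(tab$cost[idx]) / -diff(tab$dalys[idx])
    bad <- which(diff(ic) <= 0)
    if (!length(bad)) break
    drop <- idx[bad[1] + 1]   # middle arm of the first non-increasing pair
    tab$status[drop] <- "extended_dominated"
    tab$dominated_by[drop] <- paste(tab$arm[idx[bad[1]]], tab$arm[idx[bad[1] + 2]],
                                    sep = " + ")
  }

  tab$icer <- NA_real_
  idx <- which(tab$status == "frontier")
  if (length(idx) > 1) {
    for (m in seq_along(idx)[-1]) {
      i <- idx[m]; j <- idx[m - 1]
      tab$icer[i] <- (tab$cost[i] - tab$cost[j]) / (tab$dalys[j] - tab$dalys[i])
    }
  }
  structure(tab, class = c("cea_frontier", "data.frame"))
}

#' @export
print.cea_frontier <- function(x, ...) {
  cat("Cost-effectiveness frontier (arms ordered by total cost)\n")
  out <- as.data.frame(x)
  out$cost <- sprintf("$%.2f", out$cost)
  out$dalys <- sprintf("%.4f", out$dalys)
  out$icer <- ifelse(is.na(out$icer), "..", sprintf("$%.0f", out$icer))
  print(out, row.names = FALSE)
  invisible(x)
}

#' Run the full cost-effectiveness analysis for one stratum
#'
#' Runs the cohort model for all four arms, computes the dominance-aware
#' frontier, and reports pairwise ICERs against the usual-care reference.
#'
#' @param params a `cea_parameters` object.
#' @param stratum `"population"`, `"men"`, or `"women"`; default from settings.
#' @return an object of class `cea_result` with components `arms` (named list
#'   of `arm_result`), `frontier` (`cea_frontier`), `reference_icers`
#'   (pairwise vs usual care), `stratum`, and `settings`.
#' @examples
#' p <- read_cea_parameters(quiet = TRUE)
#' res <- run_cea(p)
#' summary(res)
#' @export
run_cea <- function(params, stratum = NULL) {
  stopifnot(inherits(params, "cea_parameters"))
  stratum <- stratum %||% params$settings$stratum
  arms <- lapply(names(params$arms), run_arm, params = params, stratum = stratum)
  names(arms) <- names(params$arms)
  frontier <- compute_frontier(arms)
  ref <- arms$usual_care
  reference_icers <- vapply(arms, function(a) {
    if (identical(a$arm, "usual_care")) return(NA_real_)
    (a$total_cost - ref$total_cost) / (ref$total_dalys - a$total_dalys)
  }, numeric(1))
  structure(list(arms = arms, frontier = frontier,
                 reference_icers = reference_icers, stratum = stratum,
                 settings = params$settings,
                 fingerprint = config_fingerprint(params)),
            class = "cea_result")
}

#' Extract a Table-2-style ICER table
#'
#' One row per arm in cost order: total cost, incremental cost and DALYs
#' averted versus the previous arm, dominance status, frontier ICER, and the
#' pairwise ICER against usual care. Full-precision columns are kept
#' alongside display rounding (costs to $1, DALYs to 0.001, ICERs to $1).
#'
#' @param result a `cea_result`.
#' @return a data frame.
#' @export
icer_table <- function(result) {
  stopifnot(inherits(result, "cea_result"))
  fr <- as.data.frame(result$frontier)
  fr$incr_cost <- c(NA, diff(fr$cost))
  fr$incr_dalys_averted <- c(NA, -diff(fr$dalys))
  fr$icer_vs_usual_care <- result$reference_icers[fr$arm]
  fr$cost_display <- round(fr$cost)
  fr$dalys_display <- round(fr$dalys, 3)
  fr$icer_display <- ifelse(fr$status == "frontier",
                            round(fr$icer), NA)
  fr
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("Markov cost-effectiveness analysis: stratum %s, horizon %d, config %s\n",
              x$stratum, as.integer(x$settings$horizon), x$fingerprint))
  print(x$frontier)
  invisible(x)
}

#' @export
summary.cea_result <- function(object, ...) {
  tab <- icer_table(object)
  cat(sprintf("Stratum: %s | horizon %d cycles | discount %.0f%% | config %s\n\n",
              object$stratum, as.integer(object$settings$horizon),
              100 * object$settings$discount_rate, object$fingerprint))
  disp <- data.frame(
    arm = tab$arm,
    total_cost = sprintf("$%d", tab$cost_display),
    incr_cost = ifelse(is.na(tab$incr_cost), "..", sprintf("$%.0f", tab$incr_cost)),
    total_DALYs = sprintf("%.3f", tab$dalys_display),
    DALYs_averted = ifelse(is.na(tab$incr_dalys_averted), "..",
                           sprintf("%.3f", tab$incr_dalys_averted)),
    ICER = ifelse(tab$status == "frontier",
                  ifelse(is.na(tab$icer), "..", sprintf("$%.0f", tab$icer)),
                  tab$status))
  print(disp, row.names = FALSE)
  cat("\nPairwise ICER vs usual care:",
      paste(sprintf("%s $%.0f", names(object$reference_icers)[-1],
                    object$reference_icers[-1]), collapse = ", "), "\n")
  invisible(tab)
}

#' Plot the cost-effectiveness plane
#'
#' Total cost against total DALYs for each arm, with the efficiency frontier
#' drawn through the non-dominated arms.
#'
#' @param x a `cea_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cea_result <- function(x, ...) {
  fr <- as.data.frame(x$frontier)
  graphics::plot(fr$dalys, fr$cost, pch = 19,
                 xlab = "Total DALYs per person (lower is better)",
                 ylab = "Total discounted cost per person (US$)", ...)
  on_fr <- fr$status == "frontier"
  graphics::lines(fr$dalys[on_fr], fr$cost[on_fr], col = "grey40")
  graphics::text(fr$dalys, fr$cost, labels = fr$arm, pos = 3, cex = 0.8)
  invisible(x)
}

#' Write the ICER table to CSV or JSON
#'
#' @param result a `cea_result`.
#' @param file path ending in `.csv` or `.json`.
#' @return the table, invisibly.
#' @export
write_icer_table <- function(result, file) {
  tab <- icer_table(result)
  tab$config <- result$fingerprint
  ext <- tolower(tools::file_ext(file))
  if (ext == "csv") {
    utils::write.csv(tab, file, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(tab, file, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    stop("unsupported output format '", ext, "'")
  }
  invisible(tab)
}
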