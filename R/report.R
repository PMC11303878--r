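# Scenario runners and publication-style outputs: thin wrappers over the
# analysis functions that write CSV/JSON artifacts stamped with the config
# fingerprint and seed.

#' Run the base-case analysis and write the ICER table
#'
#' @param params a `cea_parameters` object (or a path handed to
#'   [read_cea_parameters()]).
#' @param stratum stratum; default from settings.
#' @param out_dir directory for outputs; `NULL` writes nothing.
#' @return the `cea_result`, invisibly.
#' @export
run_base_case <- function(params, stratum = NULL, out_dir = NULL) {
  if (is.character(params)) params <- read_cea_parameters(params)
  res <- run_cea(params, stratum = stratum)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tag <- paste0(res$stratum, "_h", res$settings$horizon)
    write_icer_table(res, file.path(out_dir, paste0("icer_table_", tag, ".csv")))
    arm_json <- lapply(res$arms, function(a) {
      list(arm = a$arm, stratum = a$stratum, total_cost = a$total_cost,
           total_dalys = a$total_dalys)
    })
    jsonlite::write_json(
      list(config = res$fingerprint, arms = arm_json),
      file.path(out_dir, paste0("arm_results_", tag, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}

#' Run the tornado analysis and write it to CSV
#'
#' @param params a `cea_parameters` object.
#' @param arm comparison arm for the INMB (vs usual care).
#' @param wtp willingness-to-pay; default from settings.
#' @param out_dir directory for outputs; `NULL` writes nothing.
#' @return the `cea_tornado`, invisibly.
#' @export
run_dsa_report <- function(params, arm = "gmv_mf", wtp = NULL, out_dir = NULL) {
  if (is.character(params)) params <- read_cea_parameters(params)
  tor <- tornado_analysis(params, arm = arm, wtp = wtp)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- as.data.frame(tor)
    out$rank <- seq_len(nrow(out))
    out$top10 <- out$rank <= 10
    out$config <- config_fingerprint(params)
    utils::write.csv(out, file.path(out_dir, paste0("tornado_", arm, ".csv")),
                     row.names = FALSE)
  }
  invisible(tor)
}

#' Run the PSA and write cost-effectiveness acceptability curves to CSV
#'
#' @param params a `cea_parameters` object.
#' @param n PSA iterations.
#' @param seed master seed (logged in the output).
#' @param wtp_grid willingness-to-pay grid; default from settings.
#' @param out_dir directory for outputs; `NULL` writes nothing.
#' @return the `cea_ceac`, invisibly.
#' @export
run_psa_report <- function(params, n = 10000, seed = 1, wtp_grid = NULL,
                           out_dir = NULL) {
  if (is.character(params)) params <- read_cea_parameters(params)
  wtp_grid <- wtp_grid %||% unlist(params$settings$wtp_grid)
  psa <- run_psa(params, n = n, seed = seed)
  cc <- ceac(psa, wtp_grid)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- as.data.frame(cc)
    out$seed <- seed
    out$config <- config_fingerprint(params)
    utils::write.csv(out, file.path(out_dir, "ceac.csv"), row.names = FALSE)
  }
  invisible(cc)
}

#' Cross-validate the cohort engine against the microsimulation oracle
#'
#' Runs every arm through both the deterministic cohort trace (half-cycle
#' correction off, to match the oracle's end-of-cycle accrual) and the
#' individual-level microsimulation, and reports the gap in Monte Carlo
#' standard errors.
#'
#' @param params a `cea_parameters` object.
#' @param stratum stratum; default from settings.
#' @param n microsimulation size per arm.
#' @param seed integer seed.
#' @return data frame with per-arm cohort and microsimulation totals, SEs,
#'   and z-scores of the gaps.
#' @export
oracle_check <- function(params, stratum = NULL, n = 50000, seed = 1) {
  if (is.character(params)) params <- read_cea_parameters(params)
  params$settings$half_cycle_correction <- FALSE
  rows <- lapply(seq_along(names(params$arms)), function(i) {
    a <- names(params$arms)[i]
    coh <- run_arm(a, params, stratum)
    mc <- microsim_oracle(a, params, stratum, n = n, seed = seed + i)
    data.frame(arm = a,
               cohort_cost = coh$total_cost, microsim_cost = mc$mean_cost,
               se_cost = mc$se_cost,
               z_cost = (coh$total_cost - mc$mean_cost) / mc$se_cost,
               cohort_dalys = coh$total_dalys, microsim_dalys = mc$mean_dalys,
               se_dalys = mc$se_dalys,
               z_dalys = (coh$total_dalys - mc$mean_dalys) / mc$se_dalys)
  })
  do.call(rbind, rows)
}
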