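# Parameter registry: every model input lives in a validated `cea_parameters`
# object so all downstream computation is a pure function of it.

ARM_NAMES <- c("usual_care", "group_medical_visits", "microfinance", "gmv_mf")
STRATA <- c("population", "men", "women")

#' Load a model parameter set from a YAML or JSON document
#'
#' Reads the full model input registry — per-arm costs and QRISK3 effects,
#' clinical costs, disability weights, recurrent-event hazard ratios, the
#' Kenyan life table, epidemiological proportions, scenario settings, and
#' one-way sensitivity ranges — and validates every invariant. The packaged
#' default document (`system.file("extdata", "default_inputs.yaml",
#' package = "htncea")`) encodes the published base-case inputs.
#'
#' The default life table contains an annual all-cause mortality probability
#' of 0 for the 70-74-year band, as published. This is inconsistent with the
#' neighbouring bands (0.03 and 0.07) and is flagged with a warning at load
#' time; pass `fix_70_74 = TRUE` to replace it with the midpoint of the
#' adjacent bands (0.05).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` document; `NULL` (default)
#'   loads the packaged base-case inputs.
#' @param fix_70_74 replace a zero 70-74-year mortality band with the midpoint
#'   of its neighbours.
#' @param quiet suppress the life-table warning.
#' @return an object of class `cea_parameters`.
#' @seealso [cea_parameters()], [write_cea_parameters()]
#' @examples
#' p <- read_cea_parameters(quiet = TRUE)
#' p$arms$gmv_mf$year1_cost
#' @export
read_cea_parameters <- function(path = NULL, fix_70_74 = FALSE, quiet = FALSE) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_inputs.yaml", package = "htncea")
  }
  if (!file.exists(path)) stop("parameter document not found: ", path)
  ext <- tolower(tools::file_ext(path))
  doc <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE),
    stop("unsupported config format '", ext, "' (use YAML or JSON)")
  )
  cea_parameters(doc, fix_70_74 = fix_70_74, quiet = quiet)
}

#' Construct and validate a parameter set from a list
#'
#' @param doc a list with components `arms`, `clinical_costs`,
#'   `disability_weights`, `hazard_ratios`, `life_table`, `epi`, `settings`,
#'   and optionally `dsa_ranges`, as in the packaged YAML document.
#' @inheritParams read_cea_parameters
#' @return an object of class `cea_parameters`.
#' @export
cea_parameters <- function(doc, fix_70_74 = FALSE, quiet = FALSE) {
  required <- c("arms", "clinical_costs", "disability_weights",
                "hazard_ratios", "life_table", "epi", "settings")
  missing <- setdiff(required, names(doc))
  if (length(missing)) {
    stop("configuration error: missing key(s): ", paste(missing, collapse = ", "))
  }

  lt <- do.call(rbind, lapply(doc$life_table, function(b) {
    # a missing/null upper bound marks the open-ended oldest band
    data.frame(lower = as.numeric(b$lower %||% NA),
               upper = as.numeric(b$upper %||% Inf),
               prob  = as.numeric(b$prob  %||% NA))
  }))
  if (is.data.frame(doc$life_table)) lt <- doc$life_table
  lt$upper[is.na(lt$upper)] <- Inf

  p <- structure(list(
    arms = doc$arms,
    clinical_costs = doc$clinical_costs,
    disability_weights = doc$disability_weights,
    hazard_ratios = doc$hazard_ratios,
    life_table = lt,
    epi = doc$epi,
    settings = doc$settings,
    dsa_ranges = doc$dsa_ranges %||% list()
  ), class = "cea_parameters")

  zero_band <- which(p$life_table$prob == 0)
  if (length(zero_band)) {
    if (fix_70_74) {
      for (i in zero_band) {
        lo <- if (i > 1) p$life_table$prob[i - 1] else NA
        hi <- if (i < nrow(p$life_table)) p$life_table$prob[i + 1] else NA
        p$life_table$prob[i] <- mean(c(lo, hi), na.rm = TRUE)
      }
      if (!quiet) {
        warning("life table: zero mortality band(s) replaced by the midpoint ",
                "of adjacent bands", call. = FALSE)
      }
    } else if (!quiet) {
      warning("life table: band(s) ",
              paste(p$life_table$lower[zero_band], p$life_table$upper[zero_band],
                    sep = "-", collapse = ", "),
              " have zero annual mortality, as published; pass fix_70_74 = TRUE ",
              "to repair", call. = FALSE)
    }
  }

  validate_cea_parameters(p, quiet = quiet)
  p
}

#' Validate a parameter set
#'
#' Exhaustive invariant checks over every field; errors name the offending
#' field and bound. Called by [cea_parameters()] and after [set_parameter()];
#' exported so modified parameter sets can be re-checked explicitly.
#'
#' @param p a `cea_parameters` object.
#' @param quiet suppress non-fatal warnings (e.g. a published sensitivity
#'   range that does not bracket its base value).
#' @return `p`, invisibly, when valid.
#' @export
validate_cea_parameters <- function(p, quiet = FALSE) {
  num1 <- function(x, field) {
    if (is.null(x) || !is.numeric(x) || length(x) != 1 || is.na(x)) {
      stop_validation(field, "must be a single number")
    }
    x
  }
  if (!setequal(names(p$arms), ARM_NAMES)) {
    stop_validation("arms", "need exactly the four arms ",
                    paste(ARM_NAMES, collapse = ", "))
  }
  for (a in names(p$arms)) {
    arm <- p$arms[[a]]
    for (f in c("year1_cost", "subsequent_year_cost")) {
      v <- num1(arm[[f]], paste0("arms$", a, "$", f))
      if (v <= 0) stop_validation(paste0("arms$", a, "$", f), "must be > 0, got ", v)
    }
    for (f in paste0("qrisk_change_", STRATA)) {
      v <- num1(arm[[f]], paste0("arms$", a, "$", f))
      if (a == "usual_care" && v != 0) {
        stop_validation(paste0("arms$usual_care$", f), "must be 0 (reference arm)")
      }
    }
  }
  for (f in c("htn_management", "chronic_cvd_management",
              "mi_hospitalisation", "stroke_hospitalisation")) {
    v <- num1(p$clinical_costs[[f]], paste0("clinical_costs$", f))
    if (v <= 0) stop_validation(paste0("clinical_costs$", f), "must be > 0, got ", v)
  }
  w <- p$disability_weights
  for (f in c("no_cvd", "chronic_one_mi", "chronic_one_stroke", "chronic_two_mi",
              "chronic_two_stroke", "chronic_mi_and_stroke",
              "acute_mi_disutility", "acute_stroke_disutility")) {
    v <- num1(w[[f]], paste0("disability_weights$", f))
    if (v < 0 || v > 1) {
      stop_validation(paste0("disability_weights$", f), "must be in [0,1], got ", v)
    }
  }
  for (f in c("chronic_one_mi", "chronic_one_stroke", "chronic_two_mi",
              "chronic_two_stroke", "chronic_mi_and_stroke")) {
    if (w[[f]] < w$no_cvd) {
      stop_validation(paste0("disability_weights$", f),
                      "chronic weight below the no-CVD weight")
    }
  }
  for (f in c("mi_after_mi", "stroke_after_stroke", "mi_after_stroke",
              "stroke_after_mi", "mi_after_both", "stroke_after_both",
              "fatal_mi_after_mi", "fatal_mi_after_stroke", "fatal_stroke_after_mi",
              "fatal_stroke_after_stroke", "allcause_after_event")) {
    v <- num1(p$hazard_ratios[[f]], paste0("hazard_ratios$", f))
    if (v <= 0) stop_validation(paste0("hazard_ratios$", f), "must be > 0, got ", v)
  }
  lt <- p$life_table
  if (!is.data.frame(lt) || !all(c("lower", "upper", "prob") %in% names(lt))) {
    stop_validation("life_table", "must have columns lower, upper, prob")
  }
  if (any(lt$prob < 0 | lt$prob > 1)) {
    stop_validation("life_table$prob", "probabilities must be in [0,1]")
  }
  if (is.unsorted(lt$lower, strictly = TRUE)) {
    stop_validation("life_table", "bands must be ordered by age")
  }
  if (nrow(lt) > 1) {
    gaps <- lt$lower[-1] != lt$upper[-nrow(lt)] + 1
    if (any(gaps)) {
      stop_validation("life_table",
                      "bands must be contiguous; gap after band ending at age ",
                      lt$upper[which(gaps)[1]])
    }
  }
  e <- p$epi
  for (f in c("stroke_fraction", "fatal_mi_fraction", "fatal_stroke_fraction")) {
    v <- num1(e[[f]], paste0("epi$", f))
    if (v < 0 || v > 1) stop_validation(paste0("epi$", f), "must be in [0,1], got ", v)
  }
  for (f in paste0("baseline_qrisk_", STRATA)) {
    v <- num1(e[[f]], paste0("epi$", f))
    if (v <= 0 || v >= 100) {
      stop_validation(paste0("epi$", f), "must be in (0,100), got ", v)
    }
  }
  s <- p$settings
  if (num1(s$horizon, "settings$horizon") < 1) {
    stop_validation("settings$horizon", "must be >= 1")
  }
  if (num1(s$discount_rate, "settings$discount_rate") < 0) {
    stop_validation("settings$discount_rate", "must be >= 0")
  }
  if (num1(s$wtp, "settings$wtp") < 0) stop_validation("settings$wtp", "must be >= 0")
  if (!s$stratum %in% STRATA) {
    stop_validation("settings$stratum", "must be one of ", paste(STRATA, collapse = ", "))
  }
  ages <- s$start_age + seq_len(s$horizon) - 1
  covered <- vapply(ages, function(a) any(a >= lt$lower & a <= lt$upper), logical(1))
  if (!all(covered)) {
    stop_validation("life_table", "no band covers age ", ages[which(!covered)[1]],
                    " reachable within the horizon")
  }
  for (id in names(p$dsa_ranges)) {
    r <- p$dsa_ranges[[id]]
    if (!is.numeric(r) || length(r) != 2 || r[1] > r[2]) {
      stop_validation(paste0("dsa_ranges$", id), "must be numeric c(low, high)")
    }
    base <- dsa_base_value(p, id)
    if (!quiet && (base < r[1] - 1e-9 || base > r[2] + 1e-9)) {
      # one published range excludes its base value; kept as printed
      warning("dsa_ranges$", id, ": base value ", base,
              " lies outside [", r[1], ", ", r[2], "]", call. = FALSE)
    }
  }
  invisible(p)
}

#' Serialize a parameter set back to YAML or JSON
#'
#' Round-trips with [read_cea_parameters()]: the numeric content of the
#' written document equals the loaded one exactly.
#'
#' @param params a `cea_parameters` object.
#' @param path output path ending in `.yaml`, `.yml`, or `.json`.
#' @return `path`, invisibly.
#' @export
write_cea_parameters <- function(params, path) {
  stopifnot(inherits(params, "cea_parameters"))
  doc <- unclass_deep(params)
  doc$life_table <- lapply(seq_len(nrow(params$life_table)), function(i) {
    b <- as.list(params$life_table[i, c("lower", "upper", "prob")])
    if (is.infinite(b$upper)) b$upper <- NULL   # open-ended oldest band
    b
  })
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(doc, path, precision = 15)
  } else if (ext == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported config format '", ext, "'")
  }
  invisible(path)
}

#' Post-intervention QRISK3 score for an arm
#'
#' The arm-specific ten-year risk is the baseline score plus the tabulated
#' signed change (negative values lower risk, so the difference-in-differences
#' estimate is effectively subtracted from baseline).
#'
#' @param baseline baseline QRISK3 ten-year risk, in percent.
#' @param change signed change in QRISK3 percentage points.
#' @return the arm QRISK3 score, in percent.
#' @examples
#' arm_qrisk(11.5, -0.93)  # 10.57
#' @export
arm_qrisk <- function(baseline, change) {
  q <- baseline + change
  if (any(q <= 0 | q >= 100)) {
    stop_domain("arm QRISK3 score must lie in (0, 100), got ", q[which(q <= 0 | q >= 100)[1]])
  }
  q
}

# resolve the arm-specific QRISK3 score for a stratum
qrisk_for_arm <- function(params, arm_name, stratum = NULL) {
  stratum <- stratum %||% params$settings$stratum
  stopifnot(arm_name %in% ARM_NAMES, stratum %in% STRATA)
  arm_qrisk(params$epi[[paste0("baseline_qrisk_", stratum)]],
            params$arms[[arm_name]][[paste0("qrisk_change_", stratum)]])
}

# ---- one-way sensitivity addressing -----------------------------------------
# flat parameter ids map onto fields of the nested parameter list

dsa_path <- function(id) {
  if (grepl("^qrisk_change_", id)) {
    arm <- sub("^qrisk_change_", "", id)
    return(c("arms", arm, "qrisk_change_population"))
  }
  if (grepl("^cost_", id)) {
    f <- sub("^cost_", "", id)
    if (f %in% ARM_NAMES) return(c("arms", f, "year1_cost"))
    return(c("clinical_costs", f))
  }
  if (grepl("^dw_", id)) return(c("disability_weights", sub("^dw_", "", id)))
  if (grepl("^hr_", id)) return(c("hazard_ratios", sub("^hr_", "", id)))
  if (id %in% c("stroke_fraction", "fatal_mi_fraction", "fatal_stroke_fraction")) {
    return(c("epi", id))
  }
  if (id == "discount_rate") return(c("settings", "discount_rate"))
  stop_domain("unknown parameter id '", id, "'")
}

dsa_base_value <- function(params, id) {
  path <- dsa_path(id)
  params[[path]]
}

#' Set a single scalar parameter by its flat id
#'
#' Used by the deterministic and probabilistic sensitivity machinery. Ids
#' follow the `dsa_ranges` naming of the parameter document, e.g.
#' `"cost_gmv_mf"`, `"qrisk_change_group_medical_visits"`, `"dw_no_cvd"`,
#' `"hr_stroke_after_stroke"`, `"stroke_fraction"`, `"discount_rate"`.
#'
#' @param params a `cea_parameters` object.
#' @param id flat parameter id.
#' @param value replacement value.
#' @return the modified `cea_parameters` object (re-validated).
#' @export
set_parameter <- function(params, id, value) {
  path <- dsa_path(id)
  params[[path]] <- value
  # anomalies in the shipped ranges were already surfaced at load time
  validate_cea_parameters(params, quiet = TRUE)
}

#' @export
print.cea_parameters <- function(x, ...) {
  s <- x$settings
  cat("Markov CEA parameter set\n")
  cat(sprintf("  arms: %s\n", paste(names(x$arms), collapse = ", ")))
  cat(sprintf("  stratum %s, start age %d, horizon %d cycles, discount %.0f%%\n",
              s$stratum, as.integer(s$start_age), as.integer(s$horizon),
              100 * s$discount_rate))
  cat(sprintf("  half-cycle correction %s, cycle-0 accrual %s, fatal-event accrual %s\n",
              s$half_cycle_correction, s$cycle0_accrual, s$fatal_event_accrual))
  cat(sprintf("  baseline QRISK3: population %.1f, men %.1f, women %.1f\n",
              x$epi$baseline_qrisk_population, x$epi$baseline_qrisk_men,
              x$epi$baseline_qrisk_women))
  cat(sprintf("  %d parameters with one-way sensitivity ranges\n",
              length(x$dsa_ranges)))
  invisible(x)
}
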