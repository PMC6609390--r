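#' Build a single test result
#'
#' @param analyte analyte code (PT, APTT, TT, FBG or INR).
#' @param value measured value in the analyte's unit; must be finite and > 0.
#' @param flags character vector of instrument analytical flag codes
#'   (empty when the run was clean). Any flag — including codes unknown to
#'   this package — holds the result for manual verification.
#' @param analysis_complete_at time the instrument completed the analysis.
#' @return a `coag_test_result` list.
#' @export
test_result <- function(analyte, value, flags = character(),
                        analysis_complete_at = NULL) {
  check_analyte(analyte, allow_inr = TRUE)
  if (!is_scalar_number(value) || value <= 0) {
    stop_input(analyte, ": result value must be a finite number > 0, got ",
               deparse(value))
  }
  flags <- as.character(flags)
  flags <- flags[nzchar(flags)]
  structure(list(analyte = analyte, value = as.numeric(value), flags = flags,
                 analysis_complete_at =
                   if (is.null(analysis_complete_at)) NULL
                   else parse_timestamp(analysis_complete_at)),
            class = "coag_test_result")
}

#' Build a panel record
#'
#' One sample's coagulation panel: the four core results (PT, APTT, TT, FBG;
#' INR optional), collection/receipt timestamps, the patient context profile
#' and the per-analyte result history used by the delta check.
#'
#' @param sample_id,patient_id identifiers.
#' @param results named list of [test_result()]s; must cover PT, APTT, TT and
#'   FBG for whole-sample verification.
#' @param collected_at,received_at sample collection and laboratory receipt
#'   times.
#' @param context patient context profile id (see [resolve_context()]).
#' @param warfarin_indication indication under the warfarin context.
#' @param history named list (by analyte) of data frames with columns
#'   `timestamp` and `value`: the patient's prior results, all strictly
#'   before the current analysis time.
#' @return a `coag_panel` list.
#' @export
panel_record <- function(sample_id, patient_id, results,
                         collected_at = NULL, received_at = NULL,
                         context = "none", warfarin_indication = NULL,
                         history = list()) {
  if (!is.list(results) || is.null(names(results))) {
    stop_input("results must be a named list of test_result objects")
  }
  for (nm in names(results)) {
    r <- results[[nm]]
    if (!inherits(r, "coag_test_result") || !identical(r$analyte, nm)) {
      stop_input("results[['", nm, "']] must be a test_result for that analyte")
    }
  }
  for (nm in names(history)) {
    h <- history[[nm]]
    if (!is.data.frame(h) || !all(c("timestamp", "value") %in% names(h))) {
      stop_input("history[['", nm, "']] must have columns timestamp, value")
    }
  }
  structure(list(sample_id = as.character(sample_id),
                 patient_id = as.character(patient_id),
                 results = results,
                 collected_at = if (is.null(collected_at)) NULL else parse_timestamp(collected_at),
                 received_at = if (is.null(received_at)) NULL else parse_timestamp(received_at),
                 context = context,
                 warfarin_indication = warfarin_indication,
                 history = history),
            class = "coag_panel")
}

reason_row <- function(stage, code) data.frame(stage = stage, code = code,
                                               stringsAsFactors = FALSE)

#' Verify a single test result
#'
#' Runs the per-test screening stages in their fixed order — QC gate,
#' analytical error flags, critical value, limited range, delta check — with
#' short-circuit semantics: the first failing stage determines the status and
#' the leading reason code.
#'
#' A result outside its (context-effective) limited range is not held
#' immediately: if the patient has a prior result for the same analyte within
#' the delta window and the absolute change is strictly below the rule's
#' maximum, the result is *rescued* and passes with reason `delta_rescued`.
#' TT has no delta rule in the default rulebook, so an out-of-range TT is
#' always held.
#'
#' @param result a [test_result()].
#' @param effective_limits `[lower, upper]` limited range for this analyte,
#'   normally from [resolve_context()]; bounds inclusive.
#' @param rb the `coag_rulebook`.
#' @param history data frame of prior results (`timestamp`, `value`) or NULL.
#' @param qc a `coag_qc_gate` for this analyte; `NULL` (no QC information)
#'   is treated as halted — the gate fails closed.
#' @param now verification attempt time; used for the delta window when the
#'   result carries no analysis timestamp.
#' @param delta_window_days optional override of the delta rule's window (the
#'   anticoagulated 30-day window when INR is in band).
#' @return list with `status` (`"PASS"`, `"HOLD"` or `"CRITICAL"`) and
#'   `reasons` (data frame `stage`, `code` in stage order).
#' @examples
#' rb <- default_rulebook()
#' r <- test_result("PT", 13.1)
#' verify_test(r, rb$limited$PT, rb, qc = qc_open(),
#'             now = as.POSIXct("2021-03-01", tz = "UTC"))$status
#' @export
verify_test <- function(result, effective_limits, rb, history = NULL,
                        qc = NULL, now = Sys.time(), delta_window_days = NULL) {
  stopifnot(inherits(result, "coag_test_result"), inherits(rb, "coag_rulebook"))
  a <- result$analyte
  now <- parse_timestamp(now)

  # stage 1: QC gate (absence of QC information fails closed)
  if (is.null(qc) || !inherits(qc, "coag_qc_gate") || qc$status != "open") {
    code <- if (is.null(qc)) "qc_missing" else if (qc$stale) "qc_stale" else "qc_violation"
    return(list(status = "HOLD", reasons = reason_row("qc", code)))
  }

  # stage 2: instrument analytical error flags
  if (length(result$flags)) {
    return(list(status = "HOLD",
                reasons = reason_row("flag", paste0("flag:", result$flags))))
  }

  # stage 3: critical value
  cr <- rb$critical[[a]]
  if (!is.null(cr) && is_critical_value(result$value, cr)) {
    side <- if (!is.null(cr$low) &&
                (if (isTRUE(cr$low_inclusive)) result$value <= cr$low
                 else result$value < cr$low)) "critical_low" else "critical_high"
    return(list(status = "CRITICAL", reasons = reason_row("critical", side)))
  }

  # stage 4: limited range (bounds inclusive)
  if (is.null(effective_limits) || length(effective_limits) != 2L) {
    stop_config("no limited range configured for analyte ", a)
  }
  if (result$value >= effective_limits[1] && result$value <= effective_limits[2]) {
    return(list(status = "PASS", reasons = reason_row("range", "in_range")))
  }

  # stage 5: delta check against patient history
  dr <- rb$delta[[a]]
  if (is.null(dr)) {
    return(list(status = "HOLD", reasons = reason_row("range", "out_of_range:no_delta_rule")))
  }
  if (is.null(history) || nrow(history) == 0L) {
    return(list(status = "HOLD", reasons = reason_row("range", "out_of_range:no_history")))
  }
  ref_time <- result$analysis_complete_at %||% now
  ts <- parse_timestamp(history$timestamp)
  window <- delta_window_days %||% dr$max_interval_days
  age_days <- days_between(ts, ref_time)
  in_window <- which(age_days > 0 & age_days < window)  # strict, as written
  if (!length(in_window)) {
    return(list(status = "HOLD",
                reasons = reason_row("range", "out_of_range:history_outside_window")))
  }
  prev <- history$value[in_window[which.min(age_days[in_window])]]
  if (abs(result$value - prev) < dr$max_abs_delta) {
    return(list(status = "PASS", reasons = reason_row("delta", "delta_rescued")))
  }
  list(status = "HOLD", reasons = reason_row("range", "out_of_range:delta_exceeded"))
}

#' Whole-sample logical (clot-pattern) rules
#'
#' Cross-analyte consistency predicates run only after all four single tests
#' have passed. The default set detects the signature of an undetected clot
#' in the specimen — prolonged clotting times with depleted fibrinogen:
#' * `L1`: (PT >= 14.00 s or APTT >= 43.00 s) and FBG <= 2.00 g/L
#' * `L2`: PT >= 14.00 s and APTT >= 43.00 s
#' * `L3`: APTT <= 43.00 s and PT <= 14.00 s and TT >= 21.00 s
#'
#' Rules are ordered; the sample is held on the first rule that fires.
#'
#' @param values named numeric vector or list of panel values (must contain
#'   every analyte a rule references).
#' @param ruleset the rulebook's logical rule list (default: shipped rules).
#' @return list with `pass` (logical) and, when a rule fired, `rule` (its id).
#' @examples
#' logical_check(c(PT = 15, APTT = 44, TT = 18, FBG = 2.5))$rule  # "L2"
#' @export
logical_check <- function(values, ruleset = default_rulebook()$logical) {
  vals <- as.list(values)
  exprs <- lapply(ruleset, function(rule) rule$parsed %||% str2lang(rule$expr))
  for (i in seq_along(ruleset)) {
    needed <- intersect(all.names(exprs[[i]]), ALL_CODES)
    missing <- setdiff(needed, names(vals))
    if (length(missing)) {
      stop_config("logical rule ", ruleset[[i]]$id,
                  " references analyte(s) absent from the panel: ",
                  paste(missing, collapse = ", "))
    }
  }
  for (i in seq_along(ruleset)) {
    if (isTRUE(eval(exprs[[i]], envir = vals, enclos = baseenv()))) {
      return(list(pass = FALSE, rule = ruleset[[i]]$id))
    }
  }
  list(pass = TRUE)
}

#' Verify a whole coagulation panel
#'
#' Runs [verify_test()] for each analyte of the panel under the patient's
#' context-effective limits, then — only if every single test passed — the
#' whole-sample [logical_check()]. Any critical result anywhere yields
#' `CRITICAL_ALERT`; any hold yields `HOLD_MANUAL`; only a fully clean panel
#' is `AUTO_RELEASE`d. Configuration problems and invalid inputs never pass
#' silently: the sample is held with reason `engine_error`.
#'
#' Under an anticoagulant context (warfarin, heparin) the panel's INR is
#' additionally checked against the indication's allowable band, and — when
#' the INR lies in the rulebook's override band (default 2.00-3.00) — the
#' PT/APTT delta windows widen to the override interval (default 30 days).
#'
#' @param panel a [panel_record()].
#' @param rb a `coag_rulebook`.
#' @param qc either one `coag_qc_gate` applied to every analyte or a named
#'   list of gates by analyte; analytes without a gate are held (fail
#'   closed).
#' @param now verification attempt time.
#' @return a `coag_verdict` list: `sample_id`, `sample_status`
#'   (`"AUTO_RELEASE"`, `"HOLD_MANUAL"` or `"CRITICAL_ALERT"`), `per_test`
#'   (per-analyte `status` + `reasons`), `logical` (id of a fired rule or
#'   NA), `released_at` (the verification time for auto-released samples,
#'   otherwise NULL) and `rulebook_hash`.
#' @export
verify_sample <- function(panel, rb, qc = NULL, now = Sys.time()) {
  stopifnot(inherits(panel, "coag_panel"), inherits(rb, "coag_rulebook"))
  now <- parse_timestamp(now)

  engine_hold <- function(code) {
    structure(list(sample_id = panel$sample_id, sample_status = "HOLD_MANUAL",
                   per_test = list(), logical = NA_character_, released_at = NULL,
                   rulebook_hash = rulebook_hash(rb),
                   engine_error = code),
              class = "coag_verdict")
  }

  eff <- tryCatch(resolve_context(rb, panel$context %||% "none", panel$warfarin_indication),
                  coag_config_error = function(e) e)
  if (inherits(eff, "error")) return(engine_hold(conditionMessage(eff)))

  core <- analytes()
  if (!all(core %in% names(panel$results))) {
    return(engine_hold(paste0("missing core analyte(s): ",
                              paste(setdiff(core, names(panel$results)), collapse = ", "))))
  }

  inr_value <- if ("INR" %in% names(panel$results)) panel$results$INR$value else NULL

  # anticoagulated delta-window override (PT/APTT only)
  ov <- rb$anticoagulated_override
  override_active <- eff$anticoagulated && !is.null(inr_value) &&
    inr_value >= ov$inr_low && inr_value <= ov$inr_high

  qc_for <- function(a) {
    if (inherits(qc, "coag_qc_gate")) qc else qc[[a]]
  }

  per_test <- list()
  for (a in core) {
    window <- if (override_active && a %in% c("PT", "APTT")) ov$max_interval_days else NULL
    vt <- tryCatch(
      verify_test(panel$results[[a]], eff$limited[[a]], rb,
                  history = panel$history[[a]], qc = qc_for(a), now = now,
                  delta_window_days = window),
      error = function(e) e
    )
    if (inherits(vt, "error")) return(engine_hold(conditionMessage(vt)))
    per_test[[a]] <- vt
  }

  # INR allowable band (anticoagulant monitoring contexts only)
  if (!is.null(eff$inr_allowable)) {
    per_test$INR <- if (is.null(inr_value)) {
      list(status = "HOLD", reasons = reason_row("inr", "inr_missing"))
    } else if (inr_value >= eff$inr_allowable[1] && inr_value <= eff$inr_allowable[2]) {
      list(status = "PASS", reasons = reason_row("inr", "inr_in_allowable_range"))
    } else {
      list(status = "HOLD", reasons = reason_row("inr", "inr_outside_allowable_range"))
    }
  }

  statuses <- vapply(per_test, `[[`, "", "status")
  logical_rule <- NA_character_
  if (any(statuses == "CRITICAL")) {
    sample_status <- "CRITICAL_ALERT"
  } else if (any(statuses == "HOLD")) {
    sample_status <- "HOLD_MANUAL"
  } else {
    vals <- lapply(panel$results, `[[`, "value")
    lc <- tryCatch(logical_check(vals, rb$logical), error = function(e) e)
    if (inherits(lc, "error")) return(engine_hold(conditionMessage(lc)))
    if (lc$pass) {
      sample_status <- "AUTO_RELEASE"
    } else {
      sample_status <- "HOLD_MANUAL"
      logical_rule <- lc$rule
    }
  }

  structure(list(sample_id = panel$sample_id,
                 sample_status = sample_status,
                 per_test = per_test,
                 logical = logical_rule,
                 released_at = if (sample_status == "AUTO_RELEASE") now else NULL,
                 rulebook_hash = rulebook_hash(rb),
                 engine_error = NULL),
            class = "coag_verdict")
}

#' @export
print.coag_verdict <- function(x, ...) {
  cat("<verdict>", x$sample_id, "->", x$sample_status)
  if (!is.na(x$logical)) cat(" [logical:", x$logical, "]")
  cat("\n")
  for (a in names(x$per_test)) {
    pt <- x$per_test[[a]]
    cat(sprintf("  %-4s %-8s %s\n", a, pt$status,
                paste(pt$reasons$code, collapse = ", ")))
  }
  if (!is.null(x$engine_error)) cat("  engine_error:", x$engine_error, "\n")
  invisible(x)
}
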