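#' Brute-force decision-table verdict (independent oracle)
#'
#' A deliberately plain, flat re-derivation of the whole-panel verdict as one
#' explicit decision table, written independently of [verify_sample()] /
#' [verify_test()] and sharing no decision logic with them. It exists for two
#' purposes: the synthetic-data generator uses it to produce ground-truth
#' labels that are *not* circular with the engine under test, and the test
#' suite compares the engine against it on exhaustive value grids.
#'
#' Thresholds (critical rules, limited ranges, delta rules, context
#' replacements/scalings, the anticoagulated delta override and INR bands)
#' are read directly from the rulebook's fields; the whole-sample logical
#' rules are hard-coded to the default clot-pattern set L1-L3, so the oracle
#' only applies to rulebooks using that logical rule set.
#'
#' @param panel a [panel_record()].
#' @param rb a `coag_rulebook`.
#' @param qc_open named logical vector by analyte (or single logical): is the
#'   QC gate open for that analyte? Missing analytes count as closed.
#' @param now verification attempt time.
#' @return list with `sample_status`, `per_test` (named status vector) and
#'   `lead` (named leading reason-stage vector: `qc`, `flag`, `critical`,
#'   `range`, `delta`, `inr` or `pass`), `logical_rule`.
#' @export
decision_table_verdict <- function(panel, rb, qc_open = TRUE, now = Sys.time()) {
  now <- parse_timestamp(now)
  core <- c("PT", "APTT", "TT", "FBG")

  open_for <- function(a) {
    if (length(qc_open) == 1L && is.null(names(qc_open))) return(isTRUE(qc_open[[1]]))
    isTRUE(qc_open[[a]])
  }

  # --- effective limits, derived straight from the config fields ------------
  lim <- rb$limited
  ctx <- panel$context %||% "none"
  inr_band <- NULL
  if (ctx != "none") {
    prof <- rb$contexts[[ctx]]
    if (is.null(prof)) stop_config("oracle: unknown context ", ctx)
    for (a in names(prof$replace %||% list())) {
      if (!is.null(prof$replace[[a]]$lower)) lim[[a]][1] <- prof$replace[[a]]$lower
      if (!is.null(prof$replace[[a]]$upper)) lim[[a]][2] <- prof$replace[[a]]$upper
    }
    for (a in names(prof$scale %||% list())) {
      if (!is.null(prof$scale[[a]]$lower)) {
        lim[[a]][1] <- round_half_up(lim[[a]][1] * prof$scale[[a]]$lower, 2)
      }
      if (!is.null(prof$scale[[a]]$upper)) {
        lim[[a]][2] <- round_half_up(lim[[a]][2] * prof$scale[[a]]$upper, 2)
      }
    }
    if (!is.null(prof$inr_allowable)) {
      ind <- panel$warfarin_indication
      if (is.null(ind) || is.null(prof$inr_allowable[[ind]])) {
        return(list(sample_status = "HOLD_MANUAL",
                    per_test = stats::setNames(character(), character()),
                    lead = stats::setNames(character(), character()),
                    logical_rule = NA_character_))
      }
      inr_band <- prof$inr_allowable[[ind]]
    }
  }

  inr <- if ("INR" %in% names(panel$results)) panel$results$INR$value else NULL
  ov <- rb$anticoagulated_override
  widened <- ctx %in% c("warfarin", "heparin") && !is.null(inr) &&
    inr >= ov$inr_low && inr <= ov$inr_high

  status <- character()
  lead <- character()
  for (a in core) {
    res <- panel$results[[a]]
    if (is.null(res)) {
      return(list(sample_status = "HOLD_MANUAL", per_test = status, lead = lead,
                  logical_rule = NA_character_))
    }
    v <- res$value
    cr <- rb$critical[[a]]

    st <- NULL
    if (!open_for(a)) {
      st <- c("HOLD", "qc")
    } else if (length(res$flags)) {
      st <- c("HOLD", "flag")
    } else if (!is.null(cr$low) &&
               ((isTRUE(cr$low_inclusive) && v <= cr$low) ||
                (!isTRUE(cr$low_inclusive) && v < cr$low))) {
      st <- c("CRITICAL", "critical")
    } else if (!is.null(cr$high) &&
               ((isTRUE(cr$high_inclusive) && v >= cr$high) ||
                (!isTRUE(cr$high_inclusive) && v > cr$high))) {
      st <- c("CRITICAL", "critical")
    } else if (v >= lim[[a]][1] && v <= lim[[a]][2]) {
      st <- c("PASS", "pass")
    } else {
      dr <- rb$delta[[a]]
      rescued <- FALSE
      if (!is.null(dr)) {
        h <- panel$history[[a]]
        if (!is.null(h) && nrow(h)) {
          win <- if (widened && a %in% c("PT", "APTT")) ov$max_interval_days
                 else dr$max_interval_days
          ref <- res$analysis_complete_at %||% now
          age <- days_between(parse_timestamp(h$timestamp), ref)
          ok <- age > 0 & age < win
          if (any(ok)) {
            prev <- h$value[ok][which.min(age[ok])]
            rescued <- abs(v - prev) < dr$max_abs_delta
          }
        }
      }
      st <- if (rescued) c("PASS", "delta") else c("HOLD", "range")
    }
    status[a] <- st[1]
    lead[a] <- st[2]
  }

  if (!is.null(inr_band)) {
    if (is.null(inr)) {
      status["INR"] <- "HOLD"; lead["INR"] <- "inr"
    } else if (inr >= inr_band[1] && inr <= inr_band[2]) {
      status["INR"] <- "PASS"; lead["INR"] <- "pass"
    } else {
      status["INR"] <- "HOLD"; lead["INR"] <- "inr"
    }
  }

  logical_rule <- NA_character_
  if (any(status == "CRITICAL")) {
    sample_status <- "CRITICAL_ALERT"
  } else if (any(status == "HOLD")) {
    sample_status <- "HOLD_MANUAL"
  } else {
    pt <- panel$results$PT$value
    aptt <- panel$results$APTT$value
    tt <- panel$results$TT$value
    fbg <- panel$results$FBG$value
    # default clot-pattern rules, spelled out
    if ((pt >= 14.00 || aptt >= 43.00) && fbg <= 2.00) {
      logical_rule <- "L1"
    } else if (pt >= 14.00 && aptt >= 43.00) {
      logical_rule <- "L2"
    } else if (aptt <= 43.00 && pt <= 14.00 && tt >= 21.00) {
      logical_rule <- "L3"
    }
    sample_status <- if (is.na(logical_rule)) "AUTO_RELEASE" else "HOLD_MANUAL"
  }

  list(sample_status = sample_status, per_test = status, lead = lead,
       logical_rule = logical_rule)
}
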