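#' Read panel results from CSV
#'
#' One row per analyte result. Required columns: `sample_id`, `patient_id`,
#' `analyte`, `value`. Optional columns: `flags` (multiple flags separated by
#' `;`), `collected_at`, `received_at`, `analysis_complete_at`, `context`,
#' `warfarin_indication`.
#'
#' @param path CSV file path.
#' @return list of [panel_record()]s (without history; attach via
#'   [read_history_csv()] / `history` argument of [verify_panels()]).
#' @export
read_panels_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "analyte", "value")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop_input("panels csv lacks column(s): ", paste(missing, collapse = ", "))
  panels_from_df(df)
}

panels_from_df <- function(df) {
  opt <- function(row, col) {
    if (!col %in% names(df)) return(NULL)
    v <- row[[col]]
    if (is.na(v) || identical(v, "")) NULL else v
  }
  lapply(split(df, df$sample_id), function(sub) {
    results <- list()
    for (i in seq_len(nrow(sub))) {
      a <- sub$analyte[i]
      flags <- opt(sub[i, ], "flags")
      flags <- if (is.null(flags)) character() else strsplit(flags, ";", fixed = TRUE)[[1]]
      results[[a]] <- test_result(a, sub$value[i], flags = flags,
                                  analysis_complete_at = opt(sub[i, ], "analysis_complete_at"))
    }
    first <- sub[1, ]
    panel_record(sample_id = first$sample_id, patient_id = first$patient_id,
                 results = results,
                 collected_at = opt(first, "collected_at"),
                 received_at = opt(first, "received_at"),
                 context = opt(first, "context") %||% "none",
                 warfarin_indication = opt(first, "warfarin_indication"))
  })
}

#' Read patient result history from CSV
#'
#' Required columns: `patient_id`, `analyte`, `timestamp`, `value`.
#'
#' @param path CSV file path.
#' @return nested list: `history[[patient_id]][[analyte]]` is a data frame
#'   with `timestamp` and `value`, ready for [panel_record()].
#' @export
read_history_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "analyte", "timestamp", "value")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop_input("history csv lacks column(s): ", paste(missing, collapse = ", "))
  lapply(split(df, df$patient_id), function(sub) {
    lapply(split(sub, sub$analyte), function(s) {
      data.frame(timestamp = s$timestamp, value = s$value, stringsAsFactors = FALSE)
    })
  })
}

#' Verify a batch of panels
#'
#' Applies [verify_sample()] to each panel, attaching each patient's history
#' first. Verification of one sample is independent of all others; a sample
#' that errors is held (fail closed), never dropped.
#'
#' @param panels list of [panel_record()]s (e.g. from [read_panels_csv()]).
#' @param rb a `coag_rulebook`.
#' @param qc a single `coag_qc_gate`, or a named list of gates by analyte
#'   (e.g. from [qc_gate_all()]).
#' @param now verification attempt time.
#' @param history nested list `history[[patient_id]][[analyte]]` (from
#'   [read_history_csv()]); panels that already carry history keep it.
#' @return list of `coag_verdict`s, in input order.
#' @export
verify_panels <- function(panels, rb, qc = NULL, now = Sys.time(), history = NULL) {
  now <- parse_timestamp(now)
  lapply(panels, function(p) {
    if (!length(p$history) && !is.null(history)) {
      h <- history[[p$patient_id]]
      if (!is.null(h)) p$history <- h
    }
    verify_sample(p, rb, qc = qc, now = now)
  })
}

#' Tabulate verdicts
#'
#' @param verdicts list of `coag_verdict`s.
#' @return data frame with one row per sample: `sample_id`, `sample_status`,
#'   per-analyte statuses, the leading hold/critical reason, the fired
#'   logical rule (if any) and `released_at`.
#' @export
verdicts_table <- function(verdicts) {
  rows <- lapply(verdicts, function(v) {
    lead <- NA_character_
    for (a in names(v$per_test)) {
      pt <- v$per_test[[a]]
      if (pt$status != "PASS") {
        lead <- paste0(a, ":", pt$reasons$code[1])
        break
      }
    }
    if (is.na(lead) && !is.na(v$logical)) lead <- paste0("logical:", v$logical)
    if (is.na(lead) && !is.null(v$engine_error)) lead <- paste0("engine:", v$engine_error)
    status_of <- function(a) {
      if (a %in% names(v$per_test)) v$per_test[[a]]$status else NA_character_
    }
    data.frame(sample_id = v$sample_id, sample_status = v$sample_status,
               PT = status_of("PT"), APTT = status_of("APTT"),
               TT = status_of("TT"), FBG = status_of("FBG"),
               lead_reason = lead, logical_rule = v$logical,
               released_at = if (is.null(v$released_at)) NA_character_
                             else format(v$released_at, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write verdicts as a JSONL audit stream
#'
#' One JSON object per line per sample, carrying the sample status, the full
#' ordered per-test reason trail, the fired logical rule and the rulebook
#' version hash, so a release decision can be audited after the fact.
#'
#' @param verdicts list of `coag_verdict`s.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_verdicts_jsonl <- function(verdicts, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (v in verdicts) {
    obj <- list(
      sample_id = v$sample_id,
      sample_status = v$sample_status,
      per_test = lapply(v$per_test, function(pt) {
        list(status = pt$status,
             reasons = lapply(seq_len(nrow(pt$reasons)), function(i) {
               list(stage = pt$reasons$stage[i], code = pt$reasons$code[i])
             }))
      }),
      logical_rule = if (is.na(v$logical)) NULL else v$logical,
      released_at = if (is.null(v$released_at)) NULL
                    else format(v$released_at, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      engine_error = v$engine_error,
      rulebook_hash = v$rulebook_hash
    )
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}
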