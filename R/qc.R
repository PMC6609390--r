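#' Control series for statistical quality control
#'
#' A time-ordered series of control-material measurements for one analyte and
#' one control level, together with the target mean and SD against which
#' Westgard rules are evaluated (in z-score units, z = (x - mean) / sd).
#'
#' @param analyte analyte code (PT, APTT, TT, FBG).
#' @param level control level label (e.g. `"L1"`, `"normal"`, `"abnormal"`).
#' @param target_mean,target_sd target mean and standard deviation of the
#'   control material; `target_sd` must be > 0.
#' @param timestamps measurement times (POSIXct or parseable strings),
#'   strictly increasing.
#' @param values measured control values, same length as `timestamps`.
#' @return a `coag_control_series` object.
#' @examples
#' cs <- control_series("PT", "normal", 13, 0.5,
#'                      timestamps = as.POSIXct("2021-03-01", tz = "UTC") + 3600 * (0:5),
#'                      values = c(13.1, 12.9, 13.0, 13.2, 12.8, 13.0))
#' evaluate_westgard(cs)
#' @export
control_series <- function(analyte, level, target_mean, target_sd, timestamps, values) {
  check_analyte(analyte)
  if (!is_scalar_number(target_sd) || target_sd <= 0) {
    stop_input("target_sd must be a positive number")
  }
  if (!is_scalar_number(target_mean)) stop_input("target_mean must be a finite number")
  timestamps <- parse_timestamp(timestamps)
  values <- as.numeric(values)
  if (length(values) < 1L || length(values) != length(timestamps)) {
    stop_input("need >= 1 point with matching timestamps and values")
  }
  if (anyNA(values) || !all(is.finite(values))) stop_input("control values must be finite")
  if (is.unsorted(timestamps, strictly = TRUE)) {
    stop_input("control timestamps must be strictly increasing")
  }
  structure(list(analyte = analyte, level = as.character(level),
                 target_mean = as.numeric(target_mean), target_sd = as.numeric(target_sd),
                 timestamps = timestamps, values = values),
            class = "coag_control_series")
}

#' @export
print.coag_control_series <- function(x, ...) {
  cat(sprintf("<control series> %s / %s: %d points, target %.2f (SD %.2f)\n",
              x$analyte, x$level, length(x$values), x$target_mean, x$target_sd))
  invisible(x)
}

#' Evaluate Westgard multirules on a control series
#'
#' Checks the standard multirule set in z-score space:
#' * `1_3s` — any point beyond 3 SD;
#' * `2_2s` — two consecutive points beyond 2 SD on the same side;
#' * `R_4s` — two consecutive points on opposite sides spanning more than
#'   4 SD;
#' * `4_1s` — four consecutive points beyond 1 SD on the same side;
#' * `10_x` — ten consecutive points on the same side of the mean;
#' * `1_2s` — any point beyond 2 SD, reported as a *warning* only (it is a
#'   screening rule, never a rejection by itself).
#'
#' @param series a [control_series()].
#' @return a list with `violations` (data frame: `rule`, `index` of the last
#'   point of each triggering window) and `warnings` (indices of `1_2s`
#'   warning points).
#' @export
evaluate_westgard <- function(series) {
  stopifnot(inherits(series, "coag_control_series"))
  z <- (series$values - series$target_mean) / series$target_sd
  n <- length(z)
  rule <- character()
  index <- integer()
  add <- function(r, i) {
    rule <<- c(rule, r)
    index <<- c(index, i)
  }
  for (i in seq_len(n)) {
    if (abs(z[i]) > 3) add("1_3s", i)
    if (i >= 2L) {
      if (z[i] > 2 && z[i - 1] > 2) add("2_2s", i)
      if (z[i] < -2 && z[i - 1] < -2) add("2_2s", i)
      if (sign(z[i]) * sign(z[i - 1]) < 0 && abs(z[i] - z[i - 1]) > 4) add("R_4s", i)
    }
    if (i >= 4L) {
      w <- z[(i - 3):i]
      if (all(w > 1) || all(w < -1)) add("4_1s", i)
    }
    if (i >= 10L) {
      w <- z[(i - 9):i]
      if (all(w > 0) || all(w < 0)) add("10_x", i)
    }
  }
  list(
    violations = data.frame(rule = rule, index = index, stringsAsFactors = FALSE),
    warnings = which(abs(z) > 2)
  )
}

#' QC gate: may autoverification run for an analyte?
#'
#' Fail-closed gate combining control freshness with Westgard evaluation.
#' The gate is `halted` when there is no control series at all, when any
#' level's newest control measurement is older than `max_qc_age_hours`
#' relative to `now` (exactly that age still counts as fresh), or when any
#' rejection rule in the policy fires on any series. While halted, no sample
#' for that analyte may be auto-released.
#'
#' @param series_set a list of [control_series()] objects for one analyte
#'   (one per control level in use).
#' @param now the verification attempt time (POSIXct or parseable string).
#' @param policy QC policy list with `max_qc_age_hours` and
#'   `rejection_rules`; defaults to the shipped rulebook's policy.
#' @return a `coag_qc_gate` list: `status` (`"open"` or `"halted"`), `stale`
#'   (logical), `violated_rules` (data frame with `level`, `rule`, `index`)
#'   and `warnings` (count of 1_2s warning points).
#' @examples
#' now <- as.POSIXct("2021-03-02 08:00:00", tz = "UTC")
#' cs <- control_series("PT", "normal", 13, 0.5, now - 3600, 13.1)
#' qc_gate(list(cs), now)$status
#' @export
qc_gate <- function(series_set, now, policy = default_rulebook()$qc_policy) {
  now <- parse_timestamp(now)
  if (!is_scalar_number(policy$max_qc_age_hours) || policy$max_qc_age_hours <= 0) {
    stop_input("policy$max_qc_age_hours must be > 0")
  }
  if (inherits(series_set, "coag_control_series")) series_set <- list(series_set)
  if (length(series_set) == 0L) {
    return(structure(list(status = "halted", stale = TRUE,
                          violated_rules = data.frame(level = character(),
                                                      rule = character(),
                                                      index = integer()),
                          warnings = 0L),
                     class = "coag_qc_gate"))
  }
  stale <- FALSE
  viol <- list()
  warn <- 0L
  for (cs in series_set) {
    stopifnot(inherits(cs, "coag_control_series"))
    age_h <- hours_between(max(cs$timestamps), now)
    if (age_h > policy$max_qc_age_hours) stale <- TRUE
    ev <- evaluate_westgard(cs)
    warn <- warn + length(ev$warnings)
    v <- ev$violations[ev$violations$rule %in% policy$rejection_rules, , drop = FALSE]
    if (nrow(v)) viol[[length(viol) + 1L]] <- data.frame(level = cs$level, v)
  }
  violated <- if (length(viol)) do.call(rbind, viol) else
    data.frame(level = character(), rule = character(), index = integer())
  structure(list(status = if (stale || nrow(violated)) "halted" else "open",
                 stale = stale, violated_rules = violated, warnings = warn),
            class = "coag_qc_gate")
}

#' @rdname qc_gate
#' @details `qc_open()` builds an explicitly open gate, for workflows where
#'   QC is managed outside this package; absence of a gate is always treated
#'   as halted.
#' @export
qc_open <- function() {
  structure(list(status = "open", stale = FALSE,
                 violated_rules = data.frame(level = character(), rule = character(),
                                             index = integer()),
                 warnings = 0L),
            class = "coag_qc_gate")
}

#' @export
print.coag_qc_gate <- function(x, ...) {
  cat("<qc gate>", x$status,
      if (x$stale) "(stale)" else "",
      if (nrow(x$violated_rules)) paste0("violations: ",
                                         paste(unique(x$violated_rules$rule), collapse = ", "))
      else "", "\n")
  invisible(x)
}

#' Read control series from a CSV file
#'
#' Expected columns: `analyte`, `level`, `timestamp`, `value`, `target_mean`,
#' `target_sd`. One [control_series()] is built per (analyte, level) pair;
#' rows are sorted by timestamp within each pair.
#'
#' @param path CSV file path.
#' @return named list of `coag_control_series`, names `"<analyte>/<level>"`.
#' @export
read_qc_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("analyte", "level", "timestamp", "value", "target_mean", "target_sd")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop_input("qc csv lacks column(s): ", paste(missing, collapse = ", "))
  out <- list()
  for (key in unique(paste(df$analyte, df$level, sep = "/"))) {
    sub <- df[paste(df$analyte, df$level, sep = "/") == key, , drop = FALSE]
    sub <- sub[order(parse_timestamp(sub$timestamp)), , drop = FALSE]
    out[[key]] <- control_series(sub$analyte[1], sub$level[1],
                                 sub$target_mean[1], sub$target_sd[1],
                                 sub$timestamp, sub$value)
  }
  out
}

#' Run the QC gate for every analyte in a control-series set
#'
#' @param series_list list of [control_series()] (e.g. from [read_qc_csv()]).
#' @param now verification attempt time.
#' @param policy QC policy (see [qc_gate()]).
#' @return named list of `coag_qc_gate`, one per analyte present; analytes
#'   with no series are absent (and therefore treated as halted downstream).
#' @export
qc_gate_all <- function(series_list, now, policy = default_rulebook()$qc_policy) {
  by_analyte <- split(series_list, vapply(series_list, `[[`, "", "analyte"))
  lapply(by_analyte, qc_gate, now = now, policy = policy)
}
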