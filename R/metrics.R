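#' Label verdicts against reviewer truth
#'
#' Joins an autoverification verdict stream with reviewer reference labels.
#' Every verdict maps to exactly one release status: `AUTO_RELEASE` ->
#' `released`; `HOLD_MANUAL` and `CRITICAL_ALERT` -> `intercepted`.
#'
#' @param verdicts list of `coag_verdict`s or a data frame with `sample_id`
#'   and `sample_status`.
#' @param truth data frame with `sample_id` and `truth` (values
#'   `"correct_report"` / `"problematic_report"`).
#' @return data frame with `sample_id`, `av_status`, `truth`.
#' @export
label_verdicts <- function(verdicts, truth) {
  vt <- if (is.data.frame(verdicts)) verdicts else verdicts_table(verdicts)
  if (!all(c("sample_id", "truth") %in% names(truth))) {
    stop_input("truth must have columns sample_id, truth")
  }
  bad <- setdiff(unique(truth$truth), c("correct_report", "problematic_report"))
  if (length(bad)) stop_input("unknown truth label(s): ", paste(bad, collapse = ", "))
  m <- merge(vt[, c("sample_id", "sample_status")], truth[, c("sample_id", "truth")],
             by = "sample_id")
  if (nrow(m) != nrow(vt)) stop_input("truth labels missing for some samples")
  data.frame(sample_id = m$sample_id,
             av_status = ifelse(m$sample_status == "AUTO_RELEASE", "released", "intercepted"),
             truth = m$truth, stringsAsFactors = FALSE)
}

#' Confusion-matrix validation metrics
#'
#' Scores autoverification decisions against reviewer reference labels, using
#' the interception convention of laboratory validation studies: a
#' *true positive* is an intercepted problematic report, a *true negative* an
#' auto-released correct report, a *false positive* an intercepted correct
#' report and a *false negative* an auto-released problematic report (the
#' patient-safety failure mode). The passing rate is the auto-released
#' fraction, `(tn + fn) / n`.
#'
#' @param labels data frame from [label_verdicts()] (columns `av_status`,
#'   `truth`), or a list/vector of counts `c(tp=, tn=, fp=, fn=)`.
#' @return a `coag_validation` list with counts (`n`, `pass`, `fail`, `tp`,
#'   `tn`, `fp`, `fn`) and proportions (`sensitivity`, `specificity`,
#'   `passing_rate`; `NA` when the denominator is zero, never silently 0),
#'   plus `*_pct` fields rounded half-up to 2 decimals for reporting.
#' @examples
#' confusion_metrics(c(tp = 892, tn = 11257, fp = 2146, fn = 0))$sensitivity_pct
#' @export
confusion_metrics <- function(labels) {
  if (is.data.frame(labels)) {
    if (nrow(labels) == 0L) stop_input("empty label set")
    tp <- sum(labels$av_status == "intercepted" & labels$truth == "problematic_report")
    tn <- sum(labels$av_status == "released" & labels$truth == "correct_report")
    fp <- sum(labels$av_status == "intercepted" & labels$truth == "correct_report")
    fn <- sum(labels$av_status == "released" & labels$truth == "problematic_report")
  } else {
    cnt <- unlist(labels)
    missing <- setdiff(c("tp", "tn", "fp", "fn"), names(cnt))
    if (length(missing)) stop_input("counts must name tp, tn, fp, fn")
    tp <- cnt[["tp"]]; tn <- cnt[["tn"]]; fp <- cnt[["fp"]]; fn <- cnt[["fn"]]
  }
  n <- tp + tn + fp + fn
  if (n < 1L) stop_input("empty label set")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  pass <- (tn + fn) / n
  structure(list(n = n, pass = tn + fn, fail = tp + fp,
                 tp = tp, tn = tn, fp = fp, fn = fn,
                 sensitivity = sens, specificity = spec, passing_rate = pass,
                 sensitivity_pct = round_half_up(100 * sens),
                 specificity_pct = round_half_up(100 * spec),
                 passing_rate_pct = round_half_up(100 * pass)),
            class = "coag_validation")
}

#' @export
print.coag_validation <- function(x, ...) {
  cat(sprintf("<validation> n=%d pass=%d fail=%d | tp=%d tn=%d fp=%d fn=%d\n",
              x$n, x$pass, x$fail, x$tp, x$tn, x$fp, x$fn))
  cat(sprintf("  sensitivity %s%%  specificity %s%%  passing rate %s%%\n",
              format(x$sensitivity_pct), format(x$specificity_pct),
              format(x$passing_rate_pct)))
  invisible(x)
}

#' Passing-rate series over reporting periods
#'
#' Per-period and aggregate auto-release rates for a monitored deployment.
#' The aggregate is reported two ways, which differ when period sizes differ:
#' the unweighted mean of the period rates and the pooled rate
#' `sum(pass)/sum(n)`. The confidence interval is, by default, a t-interval
#' over the period rates (matching the "average rate over months" framing);
#' a pooled Wilson score interval on `sum(pass)/sum(n)` is available via
#' `ci_method = "wilson"`.
#'
#' @param periods data frame with columns `period`, `pass`, `n`.
#' @param conf confidence level (default 0.95).
#' @param ci_method `"t"` (t-interval over period rates) or `"wilson"`
#'   (pooled score interval via [stats::prop.test()] without continuity
#'   correction).
#' @return list with `per_period` (data frame adding `rate` and `rate_pct`),
#'   `mean_rate`, `pooled_rate`, `pooled_n`, `ci` (`[low, high]` on the rate
#'   scale; `NULL` with a warning when fewer than 2 usable periods) and
#'   `ci_method`.
#' @examples
#' passing_rate_series(data.frame(period = c("a", "b"), pass = c(80, 90),
#'                                n = c(100, 100)))$pooled_rate
#' @export
passing_rate_series <- function(periods, conf = 0.95, ci_method = c("t", "wilson")) {
  ci_method <- match.arg(ci_method)
  need <- c("period", "pass", "n")
  missing <- setdiff(need, names(periods))
  if (length(missing)) stop_input("periods must have columns ", paste(need, collapse = ", "))
  drop <- periods$n == 0
  if (any(drop)) {
    warning("excluding ", sum(drop), " period(s) with n = 0")
    periods <- periods[!drop, , drop = FALSE]
  }
  if (nrow(periods) == 0L) stop_input("no usable periods")
  if (any(periods$pass > periods$n) || any(periods$pass < 0)) {
    stop_input("pass counts must lie in [0, n]")
  }
  rate <- periods$pass / periods$n
  per_period <- data.frame(periods, rate = rate, rate_pct = round_half_up(100 * rate))
  pooled_n <- sum(periods$n)
  pooled_rate <- sum(periods$pass) / pooled_n
  ci <- NULL
  if (ci_method == "t") {
    if (nrow(periods) >= 2L && stats::sd(rate) > 0) {
      ci <- as.numeric(stats::t.test(rate, conf.level = conf)$conf.int)
    } else if (nrow(periods) >= 2L) {
      ci <- c(rate[1], rate[1])  # identical periods: zero-width interval
    } else {
      warning("need >= 2 periods for a t-interval; returning NULL CI")
    }
  } else {
    ci <- as.numeric(stats::prop.test(sum(periods$pass), pooled_n,
                                      conf.level = conf, correct = FALSE)$conf.int)
  }
  list(per_period = per_period,
       mean_rate = mean(rate), pooled_rate = pooled_rate, pooled_n = pooled_n,
       ci = ci, ci_method = ci_method)
}

#' Mann-Whitney U test (exact for small groups, tie-corrected otherwise)
#'
#' Two-sided Mann-Whitney U comparing two independent samples. The statistic
#' is `U = #\{x_i > y_j\} + 0.5 #\{x_i = y_j\}`. When the smaller group has
#' at most `exact_max` observations (and full enumeration is tractable) the
#' p-value is computed by exact enumeration of all group assignments,
#' `P(|U - n1 n2 / 2| >= |u_obs - n1 n2 / 2|)` under the permutation null —
#' valid with ties. Larger samples use the tie-corrected normal approximation
#' with continuity correction.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param exact_max exact enumeration is used when `min(n1, n2) <= exact_max`
#'   and `choose(n1 + n2, n1) <= 5e5`.
#' @return list with `u` (statistic for `x`), `n1`, `n2`, `p_value`,
#'   `method` (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(10, 20, 30))$p_value
#' @export
mann_whitney_u <- function(x, y, exact_max = 8) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop_input("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) stop_input("NA values not allowed")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_from_idx <- function(idx) sum(r[idx]) - length(idx) * (length(idx) + 1) / 2
  u_obs <- u_from_idx(seq_len(n1))
  mu <- n1 * n2 / 2

  if (min(n1, n2) <= exact_max && choose(n1 + n2, n1) <= 5e5) {
    combs <- utils::combn(n1 + n2, n1)
    us <- apply(combs, 2, u_from_idx)
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
    return(list(u = u_obs, n1 = n1, n2 = n2, p_value = p, method = "exact"))
  }

  n <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    # all values tied: the statistic is degenerate
    return(list(u = u_obs, n1 = n1, n2 = n2, p_value = 1, method = "normal"))
  }
  z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(u = u_obs, n1 = n1, n2 = n2, p_value = p, method = "normal")
}

#' Turnaround times from timestamp records
#'
#' TAT 1 is the interval from laboratory receipt of the sample to release of
#' the result; TAT 2 is the interval from completion of the instrument
#' analysis to release. Records with disordered timestamps (negative TAT) are
#' rejected with a warning rather than silently kept.
#'
#' @param records data frame with `sample_id`, `received_at`,
#'   `analysis_complete_at`, `released_at`.
#' @return data frame adding `tat1_minutes` and `tat2_minutes`.
#' @export
tat_minutes <- function(records) {
  need <- c("sample_id", "received_at", "analysis_complete_at", "released_at")
  missing <- setdiff(need, names(records))
  if (length(missing)) stop_input("tat records lack column(s): ", paste(missing, collapse = ", "))
  rec <- parse_timestamp(records$received_at)
  ana <- parse_timestamp(records$analysis_complete_at)
  rel <- parse_timestamp(records$released_at)
  out <- data.frame(records,
                    tat1_minutes = as.numeric(difftime(rel, rec, units = "mins")),
                    tat2_minutes = as.numeric(difftime(rel, ana, units = "mins")))
  bad <- out$tat1_minutes < 0 | out$tat2_minutes < 0
  if (any(bad)) {
    warning("rejecting ", sum(bad), " record(s) with disordered timestamps (negative TAT)")
    out <- out[!bad, , drop = FALSE]
  }
  out
}

#' Compare turnaround times before vs after deployment
#'
#' Median TAT in both groups plus a two-sided Mann-Whitney U test of the
#' shift (see [mann_whitney_u()]).
#'
#' @param before,after TAT record data frames (see [tat_minutes()]), or data
#'   frames already carrying `tat1_minutes`/`tat2_minutes` columns.
#' @param which `"tat1"` (receipt to release) or `"tat2"` (analysis complete
#'   to release).
#' @return list with `median_before`, `median_after`, `u`, `p_value`,
#'   `method`, `n_before`, `n_after`.
#' @export
tat_compare <- function(before, after, which = c("tat1", "tat2")) {
  which <- match.arg(which)
  col <- paste0(which, "_minutes")
  get <- function(df) {
    if (!col %in% names(df)) df <- tat_minutes(df)
    df[[col]]
  }
  b <- get(before); a <- get(after)
  if (!length(b) || !length(a)) stop_input("both groups must be non-empty")
  mw <- mann_whitney_u(b, a)
  list(median_before = stats::median(b), median_after = stats::median(a),
       u = mw$u, p_value = mw$p_value, method = mw$method,
       n_before = length(b), n_after = length(a))
}
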