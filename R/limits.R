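#' Distribution summary of a historical results archive
#'
#' Computes the summary statistics used to calibrate autoverification limited
#' ranges from a large historical archive: n, mean, sample SD, median,
#' min/max and the 5th/95th percentiles. Percentiles use linear interpolation
#' between order statistics (`stats::quantile` type 7, the common
#' spreadsheet/statistics default); the estimator is exposed via `type` since
#' no single convention is universal.
#'
#' @param values numeric vector of historical results for one analyte, or a
#'   data frame with columns `analyte` and `value`.
#' @param analyte analyte code; required when `values` is a data frame.
#' @param probs the two percentile levels (default 5% and 95%).
#' @param type quantile estimator type passed to [stats::quantile()].
#' @return a `coag_dist_summary` list: `analyte`, `n`, `mean`, `sd`,
#'   `median`, `min`, `max`, `p_lo`, `p_hi` (full precision; rounding to the
#'   2-decimal reporting precision happens only at serialization, see
#'   [derive_limits()]).
#' @examples
#' summarize_archive(c(10, 20, 30), "PT")$mean  # 20
#' @export
summarize_archive <- function(values, analyte = NULL, probs = c(0.05, 0.95), type = 7) {
  if (is.data.frame(values)) {
    if (is.null(analyte)) stop_input("analyte is required with a data-frame archive")
    values <- values$value[values$analyte == analyte]
  }
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop_input("need >= 2 finite values to summarize an archive")
  q <- stats::quantile(values, probs = probs, type = type, names = FALSE)
  structure(list(analyte = analyte, n = length(values),
                 mean = mean(values), sd = stats::sd(values),
                 median = stats::median(values),
                 min = min(values), max = max(values),
                 p_lo = q[1], p_hi = q[2]),
            class = "coag_dist_summary")
}

#' @export
print.coag_dist_summary <- function(x, ...) {
  cat(sprintf("<archive summary> %s: n=%d mean=%.2f sd=%.2f median=%.2f range=[%.2f, %.2f] p5/p95=[%.2f, %.2f]\n",
              x$analyte %||% "?", x$n, x$mean, x$sd, x$median, x$min, x$max, x$p_lo, x$p_hi))
  invisible(x)
}

#' Merge a reference interval and a percentile interval into a limited range
#'
#' The autoverification limited range combines the clinical reference
#' interval with the population 5th/95th percentiles of historical results:
#' the merged range is the union span, `[min(ref_low, p5), max(ref_high,
#' p95)]` — the smallest interval containing both inputs. The result must lie
#' strictly inside the analyte's critical band; a merged range that reaches
#' critical territory is a consistency error requiring manual review of the
#' configuration.
#'
#' @param reference `[low, high]` clinical reference interval.
#' @param percentile `[p5, p95]` percentile interval.
#' @param critical the analyte's critical rule (from a rulebook), or NULL to
#'   skip the containment check.
#' @return numeric `[lower, upper]` limited range.
#' @examples
#' merge_limited_range(c(11.00, 14.30), c(11.80, 16.30))  # PT: 11.00-16.30
#' merge_limited_range(c(2.00, 4.00), c(2.21, 6.51))      # FBG: 2.00-6.51
#' @export
merge_limited_range <- function(reference, percentile, critical = NULL) {
  reference <- as.numeric(reference)
  percentile <- as.numeric(percentile)
  for (iv in list(reference, percentile)) {
    if (length(iv) != 2L || anyNA(iv) || !(iv[1] <= iv[2])) {
      stop_input("intervals must be [low, high] with low <= high")
    }
  }
  merged <- c(min(reference[1], percentile[1]), max(reference[2], percentile[2]))
  if (!is.null(critical)) {
    check_inside_critical(merged, critical, "merged limited range")
  }
  merged
}

#' Derive autoverification limits from a historical archive
#'
#' Full limit-derivation pipeline: summarize the archive per analyte
#' ([summarize_archive()]), then merge each analyte's clinical reference
#' interval with its observed 5th/95th percentile interval under the critical
#' rule ([merge_limited_range()]).
#'
#' @param archive data frame with columns `analyte` and `value` (the
#'   historical results).
#' @param rb a `coag_rulebook` supplying reference intervals and critical
#'   rules.
#' @param probs percentile levels (default 5% and 95%).
#' @return a list with `summary` (data frame, one row per analyte, values
#'   rounded to the 2-decimal reporting precision) and `limits` (data frame
#'   with reference interval, percentiles and derived limited range).
#' @export
derive_limits <- function(archive, rb = default_rulebook(), probs = c(0.05, 0.95)) {
  stopifnot(inherits(rb, "coag_rulebook"))
  if (!all(c("analyte", "value") %in% names(archive))) {
    stop_input("archive must have columns analyte, value")
  }
  summ <- list()
  lims <- list()
  for (a in analytes()) {
    s <- summarize_archive(archive, a, probs = probs)
    lr <- merge_limited_range(rb$reference_intervals[[a]], c(s$p_lo, s$p_hi),
                              rb$critical[[a]])
    summ[[a]] <- data.frame(analyte = a, n = s$n,
                            mean = round_half_up(s$mean), sd = round_half_up(s$sd),
                            median = round_half_up(s$median),
                            min = round_half_up(s$min), max = round_half_up(s$max),
                            p5 = round_half_up(s$p_lo), p95 = round_half_up(s$p_hi),
                            stringsAsFactors = FALSE)
    lims[[a]] <- data.frame(analyte = a,
                            reference_low = rb$reference_intervals[[a]][1],
                            reference_high = rb$reference_intervals[[a]][2],
                            p5 = round_half_up(s$p_lo), p95 = round_half_up(s$p_hi),
                            limited_low = round_half_up(lr[1]),
                            limited_high = round_half_up(lr[2]),
                            stringsAsFactors = FALSE)
  }
  out <- list(summary = do.call(rbind, summ), limits = do.call(rbind, lims))
  rownames(out$summary) <- rownames(out$limits) <- NULL
  out
}

#' Default calibration summary of the large historical coagulation archive
#'
#' The per-analyte distribution summary (n, mean, SD, median, range and
#' 5th/95th percentiles) of the year-long historical archive of routine
#' coagulation results used to calibrate the shipped rulebook's limited
#' ranges. PT/APTT/TT in seconds, FBG in g/L. These numbers serve two roles:
#' they are the percentile inputs from which the default limited ranges are
#' re-derivable via [merge_limited_range()], and they are the
#' moment-matching targets for the synthetic-data generator's marginal
#' distributions.
#'
#' @return data frame with columns `analyte`, `n`, `mean`, `sd`, `median`,
#'   `min`, `max`, `p5`, `p95`.
#' @export
default_archive_summary <- function() {
  data.frame(
    analyte = c("PT", "APTT", "TT", "FBG"),
    n = c(157097L, 157097L, 157097L, 157097L),
    mean = c(13.60, 36.97, 17.12, 3.80),
    sd = c(2.51, 5.76, 4.04, 1.35),
    median = c(13.10, 36.10, 16.80, 3.50),
    min = c(10.00, 20.80, 13.00, 0.60),
    max = c(119.20, 174.10, 229.30, 13.54),
    p5 = c(11.80, 30.40, 15.00, 2.21),
    p95 = c(16.30, 46.40, 19.40, 6.51),
    stringsAsFactors = FALSE
  )
}
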