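# shared fixtures and independent test oracles

NOW <- as.POSIXct("2021-03-29 00:00:00", tz = "UTC")

# quick panel builder: four core values (+ optional INR), flags, history
make_panel <- function(pt = 13, aptt = 36, tt = 17, fbg = 3, inr = NULL,
                       flags = list(), context = "none", indication = NULL,
                       history = list(), analyzed = NOW - 1800,
                       sample_id = "s1", patient_id = "p1") {
  vals <- c(PT = unname(pt), APTT = unname(aptt), TT = unname(tt), FBG = unname(fbg))
  results <- lapply(names(vals), function(a) {
    test_result(a, vals[[a]], flags = flags[[a]] %||% character(),
                analysis_complete_at = analyzed)
  })
  names(results) <- names(vals)
  if (!is.null(inr)) results$INR <- test_result("INR", inr, analysis_complete_at = analyzed)
  panel_record(sample_id, patient_id, results, context = context,
               warfarin_indication = indication, history = history,
               collected_at = analyzed - 3600, received_at = analyzed - 1800)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# independent Westgard oracle: explicit scan over every window per rule,
# written against the rule definitions, not the package evaluator
westgard_scan_oracle <- function(z) {
  n <- length(z)
  viol <- character()
  if (any(abs(z) > 3)) viol <- c(viol, "1_3s")
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      w <- z[i:(i + 1)]
      if (all(w > 2) || all(w < -2)) { viol <- c(viol, "2_2s"); break }
    }
    for (i in 1:(n - 1)) {
      if (sign(z[i]) != sign(z[i + 1]) && sign(z[i]) != 0 && sign(z[i + 1]) != 0 &&
          max(z[i:(i + 1)]) - min(z[i:(i + 1)]) > 4) { viol <- c(viol, "R_4s"); break }
    }
  }
  if (n >= 4) {
    for (i in 1:(n - 3)) {
      w <- z[i:(i + 3)]
      if (all(w > 1) || all(w < -1)) { viol <- c(viol, "4_1s"); break }
    }
  }
  if (n >= 10) {
    for (i in 1:(n - 9)) {
      w <- z[i:(i + 9)]
      if (all(w > 0) || all(w < 0)) { viol <- c(viol, "10_x"); break }
    }
  }
  sort(unique(viol))
}

# control series with given z-scores (target mean 10, sd 1), hourly, fresh at NOW
series_from_z <- function(z, analyte = "PT") {
  control_series(analyte, "normal", 10, 1,
                 timestamps = NOW - rev(seq_along(z)) * 3600,
                 values = 10 + z)
}

# independent percentile oracle: sort + linear interpolation between order
# statistics at h = (n-1)p + 1
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# independent exact Mann-Whitney oracle: enumerate every assignment of the
# pooled values to group 1 and count pairwise wins directly (no rank formula)
mw_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  n <- length(pooled)
  u_pairs <- function(g1, g2) {
    sum(outer(g1, g2, ">")) + 0.5 * sum(outer(g1, g2, "=="))
  }
  u_obs <- u_pairs(x, y)
  mu <- n1 * (n - n1) / 2
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, function(idx) u_pairs(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
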