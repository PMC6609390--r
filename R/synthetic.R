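#' Simulation configuration for synthetic coagulation data
#'
#' Builds the configuration driving the seeded synthetic-data generator. The
#' marginal result distributions default to log-normals moment-matched to the
#' historical archive summary ([default_archive_summary()]): coagulation
#' times are right-skewed (archive maxima far above the median), strictly
#' positive, and a log-normal with the archive's mean and SD reproduces that
#' shape. The class mix defaults to the deployment-scale composition: 78.89%
#' clean panels (the pooled auto-release rate observed over six months of
#' formal operation) and an abnormality mix dominated by out-of-range
#' results, with instrument flags at roughly the observed ~120 flagged
#' samples per ~13,400-sample month.
#'
#' @param seed integer RNG seed; identical configs generate identical data.
#' @param n_samples number of panels to generate.
#' @param class_mix named proportions over the eight sample classes
#'   `normal`, `out_of_range`, `critical`, `clot_pattern`, `flagged`,
#'   `anticoagulated`, `pregnant`, `thrombolytic`; must sum to 1.
#' @param marginals per-analyte list of log-normal parameters
#'   (`meanlog`, `sdlog`); default moment-matched to the archive summary.
#' @param history_fraction fraction of out-of-range samples that carry a
#'   prior result within the delta window (with a non-rescuing offset).
#' @param qc_spec list: `levels` (control level labels), `every_hours`
#'   (control cadence), `days` (span), `inject` (list of injections, each
#'   `list(analyte=, level=, rule=)` with rule one of `1_3s`, `2_2s`,
#'   `R_4s`, `4_1s`, `10_x`, `stale`).
#' @param tat_spec list: `n` per phase, `tat1_median` and `tat2_median`
#'   (named `before`/`after`, minutes), `sigma` (log-scale spread).
#' @param origin start of the synthetic calendar month.
#' @return a `coag_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 1000L,
                       class_mix = c(normal = 0.7889, out_of_range = 0.12,
                                     critical = 0.02, clot_pattern = 0.03,
                                     flagged = 0.009, anticoagulated = 0.02,
                                     pregnant = 0.007, thrombolytic = 0.0051),
                       marginals = NULL,
                       history_fraction = 0.5,
                       qc_spec = list(levels = c("normal", "pathological"),
                                      every_hours = 12, days = 28, inject = list()),
                       tat_spec = list(n = 300,
                                       tat1_median = c(before = 126, after = 101),
                                       tat2_median = c(before = 41, after = 15),
                                       sigma = 0.25),
                       origin = as.POSIXct("2021-03-01 00:00:00", tz = "UTC")) {
  classes <- c("normal", "out_of_range", "critical", "clot_pattern", "flagged",
               "anticoagulated", "pregnant", "thrombolytic")
  if (is.null(names(class_mix)) || !all(names(class_mix) %in% classes)) {
    stop_input("class_mix must be named with classes: ", paste(classes, collapse = ", "))
  }
  full_mix <- stats::setNames(numeric(length(classes)), classes)
  full_mix[names(class_mix)] <- class_mix
  if (abs(sum(full_mix) - 1) > 1e-8) stop_input("class_mix must sum to 1")
  if (any(full_mix < 0)) stop_input("class_mix proportions must be >= 0")
  if (!is_scalar_number(n_samples) || n_samples < 1) stop_input("n_samples must be > 0")
  if (is.null(marginals)) {
    arch <- default_archive_summary()
    marginals <- stats::setNames(
      lapply(seq_len(nrow(arch)), function(i) {
        lognormal_params(arch$mean[i], arch$sd[i])
      }),
      arch$analyte)
  }
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 class_mix = full_mix, marginals = marginals,
                 history_fraction = history_fraction,
                 qc_spec = qc_spec, tat_spec = tat_spec,
                 origin = parse_timestamp(origin)),
            class = "coag_sim_config")
}

#' Moment-matched log-normal parameters
#'
#' Solves for `meanlog`/`sdlog` such that the log-normal has the given
#' arithmetic mean and SD.
#'
#' @param mean,sd target arithmetic mean and standard deviation (> 0).
#' @return list with `meanlog`, `sdlog`.
#' @export
lognormal_params <- function(mean, sd) {
  if (!is_scalar_number(mean) || mean <= 0 || !is_scalar_number(sd) || sd <= 0) {
    stop_input("mean and sd must be > 0")
  }
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# inverse-CDF truncated log-normal draw (exact, no rejection); windows so far
# in the tail that the marginal has no numerical mass there fall back to a
# uniform draw on the window
rtrunc_lnorm <- function(n, meanlog, sdlog, lower, upper) {
  plo <- stats::plnorm(lower, meanlog, sdlog)
  phi <- stats::plnorm(upper, meanlog, sdlog)
  if (phi - plo < 1e-10) return(stats::runif(n, lower, upper))
  out <- stats::qlnorm(stats::runif(n, plo, phi), meanlog, sdlog)
  pmin(pmax(out, lower), upper)
}

#' Generate a historical results archive
#'
#' Draws raw (untruncated) log-normal results per analyte — the synthetic
#' stand-in for a laboratory's historical archive, used by the
#' limit-derivation pipeline.
#'
#' @param n draws per analyte.
#' @param marginals per-analyte log-normal parameters (default: the
#'   archive-matched marginals of [sim_config()]).
#' @param seed optional RNG seed.
#' @return data frame with columns `analyte`, `value`.
#' @export
generate_archive <- function(n, marginals = sim_config()$marginals, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  do.call(rbind, lapply(names(marginals), function(a) {
    m <- marginals[[a]]
    data.frame(analyte = a, value = stats::rlnorm(n, m$meanlog, m$sdlog),
               stringsAsFactors = FALSE)
  }))
}

# per-class value windows for the default rulebook: chosen so each class has a
# deterministic engine outcome (see the methods vignette)
SIM_WINDOWS <- list(
  normal = list(PT = c(11.20, 13.90), APTT = c(30.60, 42.90),
                TT = c(14.20, 20.90), FBG = c(2.10, 6.40)),
  out_low = list(PT = c(9.30, 10.90), APTT = c(16.00, 30.20),
                 TT = c(12.00, 13.90), FBG = c(1.05, 1.95)),
  out_high = list(PT = c(16.50, 60.00), APTT = c(47.00, 95.00),
                  TT = c(22.00, 140.00), FBG = c(6.60, 12.00)),
  critical_low = list(PT = c(5.00, 9.00), APTT = c(10.00, 15.00),
                      TT = NULL, FBG = c(0.30, 0.95)),
  critical_high = list(PT = c(70.00, 110.00), APTT = c(100.00, 150.00),
                       TT = c(150.50, 220.00), FBG = NULL)
)

FLAG_VOCAB <- c("CLOT_DETECTED", "REAGENT_LOW", "SAMPLE_SHORT", "BARCODE_ERROR",
                "CRYSTALLIZATION")

#' Generate labelled synthetic coagulation panels
#'
#' Generates `config$n_samples` panels on a synthetic calendar month, each
#' assigned to one of eight classes (see [sim_config()]) and constructed so
#' the class implies a deterministic verdict under the given rulebook:
#'
#' * `normal` — all four results comfortably inside limited ranges, no
#'   logical rule can fire: auto-released.
#' * `out_of_range` — one analyte outside its limited range but not
#'   critical; a `history_fraction` share carries an in-window prior whose
#'   delta exceeds the rule's maximum (so rescue never applies): held.
#' * `critical` — exactly one analyte breaches one critical threshold: alert.
#' * `clot_pattern` — every single test inside its limits but the panel
#'   satisfies one of the clot-pattern rules L1/L2/L3: held by logic.
#' * `flagged` — normal values, one instrument analytical flag: held.
#' * `anticoagulated` — warfarin context with PT above the routine limit but
#'   inside the relaxed 40 s warfarin limit, INR outside the indication's
#'   allowable band: held at the INR stage.
#' * `pregnant` — late-pregnancy context with APTT between the tightened and
#'   the routine upper limit: held.
#' * `thrombolytic` — thrombolytic context with FBG between the therapy
#'   range's 4.00 g/L ceiling and the routine 6.51 g/L limit: held.
#'
#' Ground-truth labels are computed with the independent
#' [decision_table_verdict()] oracle (assuming open QC), never with the
#' verification engine itself.
#'
#' @param config a [sim_config()].
#' @param rb rulebook the data should exercise (default shipped rulebook;
#'   the class constructions assume its thresholds).
#' @return list with `panels` (list of [panel_record()]s), `truth` (data
#'   frame: `sample_id`, `class`, `expected_status`, `expected_logical`),
#'   `panels_df` / `history_df` / `truth_df` (flat data frames ready for
#'   CSV), and `verify_at` (timestamp at which the batch is meant to be
#'   verified, after the last analysis).
#' @export
generate_panels <- function(config, rb = default_rulebook()) {
  stopifnot(inherits(config, "coag_sim_config"), inherits(rb, "coag_rulebook"))
  set.seed(config$seed)
  n <- config$n_samples
  classes <- sample(names(config$class_mix), n, replace = TRUE, prob = config$class_mix)
  origin <- config$origin

  draw_window <- function(a, win) {
    m <- config$marginals[[a]]
    rtrunc_lnorm(1L, m$meanlog, m$sdlog, win[1], win[2])
  }
  normal_values <- function() {
    vapply(analytes(), function(a) draw_window(a, SIM_WINDOWS$normal[[a]]), 0)
  }

  panels <- vector("list", n)
  truth_rows <- vector("list", n)
  hist_rows <- list()

  for (i in seq_len(n)) {
    cls <- classes[i]
    sid <- sprintf("S%05d", i)
    pid <- sprintf("P%05d", i)
    collected <- origin + stats::runif(1, 0, 27 * 86400)
    received <- collected + stats::runif(1, 20, 90) * 60
    analyzed <- received + stats::runif(1, 25, 70) * 60
    vals <- normal_values()
    flags <- stats::setNames(vector("list", 4L), analytes())
    context <- "none"
    indication <- NULL
    inr <- NULL
    history <- list()

    if (cls == "out_of_range") {
      a <- sample(analytes(), 1L)
      side <- if (is.null(SIM_WINDOWS$out_low[[a]])) "out_high"
              else sample(c("out_low", "out_high"), 1L)
      vals[a] <- draw_window(a, SIM_WINDOWS[[side]][[a]])
      dr <- rb$delta[[a]]
      if (!is.null(dr) && stats::runif(1) < config$history_fraction) {
        # in-window prior whose delta exceeds the rule maximum: no rescue
        offset <- dr$max_abs_delta * (1.2 + stats::rexp(1, 2)) * sample(c(-1, 1), 1L)
        prev <- max(vals[a] + offset, 0.2)
        if (abs(vals[a] - prev) < dr$max_abs_delta) prev <- vals[a] + dr$max_abs_delta * 1.5
        history[[a]] <- data.frame(
          timestamp = analyzed - stats::runif(1, 0.5, dr$max_interval_days - 0.5) * 86400,
          value = prev)
      }
    } else if (cls == "critical") {
      a <- sample(analytes(), 1L)
      side <- if (a == "TT") "critical_high"
              else if (a == "FBG") "critical_low"
              else sample(c("critical_low", "critical_high"), 1L)
      vals[a] <- draw_window(a, SIM_WINDOWS[[side]][[a]])
    } else if (cls == "clot_pattern") {
      pattern <- sample(c("L1", "L2", "L3"), 1L)
      if (pattern == "L1") {
        vals["FBG"] <- 2.00
        if (stats::runif(1) < 0.5) vals["PT"] <- stats::runif(1, 14.00, 16.30)
        else vals["APTT"] <- stats::runif(1, 43.00, 46.40)
      } else if (pattern == "L2") {
        vals["PT"] <- stats::runif(1, 14.00, 16.30)
        vals["APTT"] <- stats::runif(1, 43.00, 46.40)
      } else {
        vals["TT"] <- 21.00
      }
    } else if (cls == "flagged") {
      a <- sample(analytes(), 1L)
      flags[[a]] <- sample(FLAG_VOCAB, 1L)
    } else if (cls == "anticoagulated") {
      context <- "warfarin"
      indication <- sample(WARFARIN_INDICATIONS, 1L)
      vals["PT"] <- stats::runif(1, 17.00, 39.50)
      band <- rb$contexts$warfarin$inr_allowable[[indication]]
      inr <- if (stats::runif(1) < 0.5) stats::runif(1, band[2] + 0.3, band[2] + 1.5)
             else stats::runif(1, max(0.5, band[1] - 0.8), band[1] - 0.1)
    } else if (cls == "pregnant") {
      context <- "late_pregnancy"
      vals["APTT"] <- stats::runif(1, 42.00, 46.00)  # above 41.76, below 46.40
      vals["PT"] <- draw_window("PT", c(11.20, 13.90))  # also below 14.67
      vals["FBG"] <- draw_window("FBG", c(2.30, 6.40))  # above raised 2.20 floor
    } else if (cls == "thrombolytic") {
      context <- "thrombolytic"
      vals["FBG"] <- stats::runif(1, 4.30, 6.40)
    }

    results <- lapply(analytes(), function(a) {
      test_result(a, vals[[a]], flags = flags[[a]] %||% character(),
                  analysis_complete_at = analyzed)
    })
    names(results) <- analytes()
    if (!is.null(inr)) {
      results$INR <- test_result("INR", inr, analysis_complete_at = analyzed)
    }
    panel <- panel_record(sid, pid, results, collected_at = collected,
                          received_at = received, context = context,
                          warfarin_indication = indication, history = history)
    panels[[i]] <- panel

    oracle <- decision_table_verdict(panel, rb, qc_open = TRUE, now = analyzed + 600)
    truth_rows[[i]] <- data.frame(sample_id = sid, class = cls,
                                  expected_status = oracle$sample_status,
                                  expected_logical = oracle$logical_rule,
                                  stringsAsFactors = FALSE)
    for (a in names(history)) {
      hist_rows[[length(hist_rows) + 1L]] <- data.frame(
        patient_id = pid, analyte = a,
        timestamp = format(history[[a]]$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
        value = history[[a]]$value, stringsAsFactors = FALSE)
    }
  }

  truth <- do.call(rbind, truth_rows)
  panels_df <- do.call(rbind, lapply(panels, function(p) {
    do.call(rbind, lapply(names(p$results), function(a) {
      r <- p$results[[a]]
      data.frame(sample_id = p$sample_id, patient_id = p$patient_id, analyte = a,
                 value = r$value,
                 flags = paste(r$flags, collapse = ";"),
                 collected_at = format(p$collected_at, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
                 received_at = format(p$received_at, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
                 analysis_complete_at = format(r$analysis_complete_at,
                                               "%Y-%m-%d %H:%M:%S", tz = "UTC"),
                 context = p$context,
                 warfarin_indication = p$warfarin_indication %||% "",
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(panels_df) <- NULL
  history_df <- if (length(hist_rows)) do.call(rbind, hist_rows) else
    data.frame(patient_id = character(), analyte = character(),
               timestamp = character(), value = numeric())
  list(panels = panels, truth = truth, panels_df = panels_df,
       history_df = history_df, truth_df = truth,
       verify_at = origin + 28 * 86400)
}

# break same-side runs of 9+ so in-control stretches can never trip 10_x
enforce_in_control <- function(z) {
  run <- 0L
  side <- 0
  for (i in seq_along(z)) {
    s <- sign(z[i])
    if (s != 0 && s == side) run <- run + 1L else run <- 1L
    side <- s
    if (run >= 9L) {
      z[i] <- -z[i]
      side <- sign(z[i])
      run <- 1L
    }
  }
  z
}

#' Generate control series with labelled injected violations
#'
#' Builds, for every analyte and control level in `config$qc_spec`, a
#' time-ordered in-control series (z-scores truncated to |z| <= 0.9 with
#' same-side runs broken, so no Westgard rule can fire spuriously), then
#' applies the requested injections: a named Westgard rule pattern written
#' over the final points of the series, or `stale` (the series is cut so its
#' newest point is older than the freshness window).
#'
#' @param config a [sim_config()]; injections in `config$qc_spec$inject`.
#' @param rb rulebook (for target levels; means/SDs follow the archive
#'   summary).
#' @return list with `series` (named list of [control_series()],
#'   `"analyte/level"`), `truth` (data frame: `analyte`, `level`,
#'   `injected_rule`, `stale`), and `now` (the end of the covered window, to
#'   be used as the verification time).
#' @export
generate_qc <- function(config, rb = default_rulebook()) {
  stopifnot(inherits(config, "coag_sim_config"))
  set.seed(config$seed + 1L)
  spec <- config$qc_spec
  arch <- default_archive_summary()
  now <- config$origin + (spec$days %||% 28) * 86400
  n_pts <- floor((spec$days %||% 28) * 24 / (spec$every_hours %||% 12))
  series <- list()
  truth <- list()
  inject_for <- function(a, lv) {
    for (inj in spec$inject %||% list()) {
      if (identical(inj$analyte, a) && identical(inj$level, lv)) return(inj$rule)
    }
    "none"
  }
  for (a in analytes()) {
    row <- arch[arch$analyte == a, ]
    for (lv in spec$levels %||% "normal") {
      mean_t <- if (lv == "pathological") row$mean * 2 else row$median
      sd_t <- mean_t * 0.04
      z <- stats::qnorm(stats::runif(n_pts, stats::pnorm(-0.9, sd = 0.5),
                                     stats::pnorm(0.9, sd = 0.5)), sd = 0.5)
      z <- enforce_in_control(z)
      rule <- inject_for(a, lv)
      stale <- FALSE
      ts <- now - rev(seq_len(n_pts)) * (spec$every_hours %||% 12) * 3600 + 3600
      if (rule == "1_3s") z[n_pts] <- 3.5
      else if (rule == "2_2s") z[(n_pts - 1):n_pts] <- c(2.5, 2.6)
      else if (rule == "R_4s") z[(n_pts - 1):n_pts] <- c(2.5, -2.5)
      else if (rule == "4_1s") z[(n_pts - 3):n_pts] <- c(1.4, 1.5, 1.6, 1.5)
      else if (rule == "10_x") z[(n_pts - 9):n_pts] <- abs(z[(n_pts - 9):n_pts]) + 0.05
      else if (rule == "stale") {
        stale <- TRUE
        keep <- ts <= now - 25 * 3600
        ts <- ts[keep]; z <- z[keep]
      } else if (rule != "none") {
        stop_input("unknown injection rule: ", rule)
      }
      series[[paste(a, lv, sep = "/")]] <-
        control_series(a, lv, mean_t, sd_t, ts, mean_t + z * sd_t)
      truth[[length(truth) + 1L]] <- data.frame(
        analyte = a, level = lv,
        injected_rule = if (rule %in% c("none", "stale")) "none" else rule,
        stale = stale, stringsAsFactors = FALSE)
    }
  }
  list(series = series, truth = do.call(rbind, truth), now = now)
}

#' Generate before/after turnaround-time records
#'
#' Draws TAT 1 (receipt to release) from a log-normal with exactly the
#' configured median, and TAT 2 (analysis complete to release) as a
#' log-normal fraction of TAT 1 whose median equals the configured TAT 2
#' median (medians of products of independent log-symmetric factors
#' multiply). The ratio stays far below 1 for any realistic spread, so
#' record timestamps are always ordered. Two phases are generated: "before"
#' (manual verification, a year earlier) and "after" (autoverification).
#'
#' @param config a [sim_config()].
#' @return data frame with `sample_id`, `phase`, `received_at`,
#'   `analysis_complete_at`, `released_at`.
#' @export
generate_tat <- function(config) {
  stopifnot(inherits(config, "coag_sim_config"))
  set.seed(config$seed + 2L)
  spec <- config$tat_spec
  sigma <- spec$sigma %||% 0.25
  out <- list()
  for (phase in c("before", "after")) {
    n <- spec$n %||% 300
    t1 <- spec$tat1_median[[phase]] * exp(stats::rnorm(n, 0, sigma))
    ratio <- spec$tat2_median[[phase]] / spec$tat1_median[[phase]]
    t2 <- t1 * pmin(0.99, ratio * exp(stats::rnorm(n, 0, sigma / 2)))
    received <- config$origin + stats::runif(n, 0, 27 * 86400) -
      if (phase == "before") 365 * 86400 else 0
    released <- received + t1 * 60
    analyzed <- released - t2 * 60
    out[[phase]] <- data.frame(
      sample_id = sprintf("T%s%04d", toupper(substr(phase, 1, 1)), seq_len(n)),
      phase = phase,
      received_at = format(received, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
      analysis_complete_at = format(analyzed, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
      released_at = format(released, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
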