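rb <- default_rulebook()

test_that("per-test stages run in fixed order with short-circuit semantics", {
  lim <- rb$limited$PT

  # clean mid-range result passes at the range stage
  r <- test_result("PT", 13.10, analysis_complete_at = NOW)
  v <- verify_test(r, lim, rb, qc = qc_open(), now = NOW)
  expect_equal(v$status, "PASS")
  expect_equal(v$reasons$code, "in_range")

  # critical low
  v <- verify_test(test_result("PT", 8.50), lim, rb, qc = qc_open(), now = NOW)
  expect_equal(v$status, "CRITICAL")
  expect_equal(v$reasons$code, "critical_low")
  # boundary is inclusive for PT
  expect_equal(verify_test(test_result("PT", 9.00), lim, rb, qc = qc_open(),
                           now = NOW)$status, "CRITICAL")
  expect_equal(verify_test(test_result("PT", 70.00), lim, rb, qc = qc_open(),
                           now = NOW)$status, "CRITICAL")
  # ... but exclusive for TT and FBG as written
  expect_equal(verify_test(test_result("TT", 150.00), rb$limited$TT, rb,
                           qc = qc_open(), now = NOW)$status, "HOLD")
  expect_equal(verify_test(test_result("FBG", 1.00), rb$limited$FBG, rb,
                           qc = qc_open(), now = NOW)$status, "HOLD")

  # halted QC shadows everything, even a critical value
  v <- verify_test(test_result("PT", 8.50), lim, rb, qc = NULL, now = NOW)
  expect_equal(v$status, "HOLD")
  expect_equal(v$reasons$stage, "qc")

  # an error flag shadows a critical value
  v <- verify_test(test_result("PT", 8.50, flags = "CLOT_DETECTED"), lim, rb,
                   qc = qc_open(), now = NOW)
  expect_equal(v$status, "HOLD")
  expect_equal(v$reasons$code, "flag:CLOT_DETECTED")

  # unknown flags still hold
  v <- verify_test(test_result("PT", 13, flags = "WEIRD_NEW_FLAG"), lim, rb,
                   qc = qc_open(), now = NOW)
  expect_equal(v$status, "HOLD")

  # missing limits are a configuration error, never a silent pass
  expect_error(verify_test(test_result("PT", 13), NULL, rb, qc = qc_open(), now = NOW),
               class = "coag_config_error")
})

test_that("delta check rescues an out-of-range result only under its rule", {
  lim <- rb$limited$PT
  hist <- function(days_ago, value) data.frame(timestamp = NOW - days_ago * 86400,
                                               value = value)

  # |delta| = 1.00 < 10.00 within 5 < 10 days: rescued
  v <- verify_test(test_result("PT", 17.00, analysis_complete_at = NOW), lim, rb,
                   history = hist(5, 16.00), qc = qc_open(), now = NOW)
  expect_equal(v$status, "PASS")
  expect_equal(v$reasons$code, "delta_rescued")

  # same delta but 11 days ago: outside the 10-day window
  v <- verify_test(test_result("PT", 17.00, analysis_complete_at = NOW), lim, rb,
                   history = hist(11, 16.00), qc = qc_open(), now = NOW)
  expect_equal(v$status, "HOLD")
  expect_equal(v$reasons$code, "out_of_range:history_outside_window")

  # delta of exactly 10.00 is not rescued (strict <)
  v <- verify_test(test_result("PT", 27.00, analysis_complete_at = NOW), lim, rb,
                   history = hist(5, 17.00), qc = qc_open(), now = NOW)
  expect_equal(v$status, "HOLD")
  expect_equal(v$reasons$code, "out_of_range:delta_exceeded")

  # no history at all
  v <- verify_test(test_result("PT", 17.00, analysis_complete_at = NOW), lim, rb,
                   qc = qc_open(), now = NOW)
  expect_equal(v$reasons$code, "out_of_range:no_history")

  # the most recent in-window prior is the comparator when several exist
  h <- data.frame(timestamp = NOW - c(9, 2) * 86400, value = c(16.5, 40.0))
  v <- verify_test(test_result("PT", 17.00, analysis_complete_at = NOW), lim, rb,
                   history = h, qc = qc_open(), now = NOW)
  expect_equal(v$status, "HOLD")  # compared against 40.0 (2 days ago), not 16.5

  # TT has no delta rule: out-of-range TT is held whatever the history says
  v <- verify_test(test_result("TT", 22.00, analysis_complete_at = NOW),
                   rb$limited$TT, rb, history = hist(1, 21.9),
                   qc = qc_open(), now = NOW)
  expect_equal(v$status, "HOLD")
  expect_equal(v$reasons$code, "out_of_range:no_delta_rule")
})

test_that("logical rules fire in order on the documented clot patterns", {
  expect_equal(logical_check(c(PT = 15, APTT = 44, TT = 18, FBG = 2.5), rb$logical)$rule, "L2")
  expect_equal(logical_check(c(PT = 13, APTT = 42, TT = 21, FBG = 3), rb$logical)$rule, "L3")
  expect_true(logical_check(c(PT = 12, APTT = 36, TT = 17, FBG = 3), rb$logical)$pass)
  # L1 takes precedence when both L1 and L2 would fire
  expect_equal(logical_check(c(PT = 15, APTT = 44, TT = 18, FBG = 2.0), rb$logical)$rule, "L1")
  expect_error(logical_check(c(PT = 15, APTT = 44, FBG = 2.0), rb$logical),
               class = "coag_config_error")
})

test_that("whole-sample verdicts combine per-test and logical stages", {
  # all normal: auto-release, with the release time stamped
  v <- verify_sample(make_panel(), rb, qc = qc_open(), now = NOW)
  expect_equal(v$sample_status, "AUTO_RELEASE")
  expect_equal(v$released_at, NOW)

  # one critical result forces an alert
  v <- verify_sample(make_panel(fbg = 0.80), rb, qc = qc_open(), now = NOW)
  expect_equal(v$sample_status, "CRITICAL_ALERT")
  expect_null(v$released_at)

  # a clot pattern holds the sample even though every single test passed
  v <- verify_sample(make_panel(pt = 15, aptt = 44), rb, qc = qc_open(), now = NOW)
  expect_equal(v$sample_status, "HOLD_MANUAL")
  expect_equal(v$logical, "L2")
  expect_true(all(vapply(v$per_test, `[[`, "", "status") == "PASS"))

  # critical anywhere dominates holds elsewhere
  v <- verify_sample(make_panel(pt = 8.5, tt = 22), rb, qc = qc_open(), now = NOW)
  expect_equal(v$sample_status, "CRITICAL_ALERT")
})

test_that("warfarin monitoring requires both the relaxed PT limit and the INR band", {
  war <- function(pt, inr) make_panel(pt = pt, inr = inr, context = "warfarin",
                                      indication = "hip_surgery")
  # PT above routine limit but inside the 40 s warfarin limit, INR in band
  v <- verify_sample(war(25, 2.5), rb, qc = qc_open(), now = NOW)
  expect_equal(v$sample_status, "AUTO_RELEASE")
  expect_equal(v$per_test$INR$status, "PASS")

  # INR outside the indication band holds the sample
  v <- verify_sample(war(25, 4.5), rb, qc = qc_open(), now = NOW)
  expect_equal(v$sample_status, "HOLD_MANUAL")
  expect_equal(v$per_test$INR$reasons$code, "inr_outside_allowable_range")

  # INR missing under warfarin fails closed
  v <- verify_sample(make_panel(pt = 25, context = "warfarin",
                                indication = "hip_surgery"), rb,
                     qc = qc_open(), now = NOW)
  expect_equal(v$sample_status, "HOLD_MANUAL")
  expect_equal(v$per_test$INR$reasons$code, "inr_missing")

  # PT beyond even the warfarin limit is still held
  v <- verify_sample(war(45, 2.5), rb, qc = qc_open(), now = NOW)
  expect_equal(v$sample_status, "HOLD_MANUAL")

  # warfarin context without an indication is an engine error, held
  v <- verify_sample(make_panel(inr = 2.5, context = "warfarin"), rb,
                     qc = qc_open(), now = NOW)
  expect_equal(v$sample_status, "HOLD_MANUAL")
  expect_match(v$engine_error, "indication")
})

test_that("anticoagulated delta override widens the PT/APTT window when INR is 2-3", {
  hist20 <- list(PT = data.frame(timestamp = NOW - 20 * 86400, value = 24.5))
  base <- function(inr) make_panel(pt = 25, inr = inr, context = "heparin",
                                   history = hist20)
  # 20-day-old prior: outside the routine 10-day PT window...
  v <- verify_sample(make_panel(pt = 25, history = hist20), rb, qc = qc_open(), now = NOW)
  expect_equal(v$per_test$PT$reasons$code, "out_of_range:history_outside_window")
  # ...but inside the 30-day anticoagulated window when INR is in 2-3
  v <- verify_sample(base(2.5), rb, qc = qc_open(), now = NOW)
  expect_equal(v$per_test$PT$reasons$code, "delta_rescued")
  # INR outside 2-3: the override does not apply
  v <- verify_sample(base(3.5), rb, qc = qc_open(), now = NOW)
  expect_equal(v$per_test$PT$reasons$code, "out_of_range:history_outside_window")
})

test_that("no code path auto-releases under halted QC, flags, or engine errors", {
  p <- make_panel()

  # no QC information
  expect_equal(verify_sample(p, rb, qc = NULL, now = NOW)$sample_status, "HOLD_MANUAL")
  # stale QC
  stale <- qc_gate(list(control_series("PT", "n", 10, 1, NOW - 30 * 3600, 10)), NOW)
  expect_equal(verify_sample(p, rb, qc = stale, now = NOW)$sample_status, "HOLD_MANUAL")
  # QC open for three analytes but missing for the fourth
  part <- list(PT = qc_open(), APTT = qc_open(), TT = qc_open())
  expect_equal(verify_sample(p, rb, qc = part, now = NOW)$sample_status, "HOLD_MANUAL")
  # flags on an otherwise perfect panel
  v <- verify_sample(make_panel(flags = list(PT = "REAGENT_LOW")), rb,
                     qc = qc_open(), now = NOW)
  expect_equal(v$sample_status, "HOLD_MANUAL")
  # a missing core analyte aborts the sample as held, not as released
  p3 <- make_panel()
  p3$results$TT <- NULL
  expect_equal(verify_sample(p3, rb, qc = qc_open(), now = NOW)$sample_status,
               "HOLD_MANUAL")
})

test_that("widening a limited range never turns a release into a hold", {
  set.seed(11)
  wide <- rulebook_to_list(default_rulebook())
  wide$limited$PT <- c(10.5, 17.5)
  wide$limited$APTT <- c(25.0, 50.0)
  rb_wide <- load_rulebook(yaml::as.yaml(wide))
  for (i in 1:50) {
    p <- make_panel(pt = runif(1, 9.5, 30), aptt = runif(1, 16, 60),
                    tt = runif(1, 14.5, 20.5), fbg = runif(1, 2.1, 6.4))
    before <- verify_sample(p, rb, qc = qc_open(), now = NOW)$sample_status
    after <- verify_sample(p, rb_wide, qc = qc_open(), now = NOW)$sample_status
    if (before == "AUTO_RELEASE") expect_equal(after, "AUTO_RELEASE")
  }
})

test_that("removing history never converts a within-range pass into a hold", {
  set.seed(12)
  for (i in 1:30) {
    h <- list(PT = data.frame(timestamp = NOW - 86400, value = runif(1, 5, 60)))
    p_with <- make_panel(pt = runif(1, 11.0, 16.3), history = h)
    p_without <- p_with
    p_without$history <- list()
    expect_equal(verify_sample(p_with, rb, qc = qc_open(), now = NOW)$per_test$PT$status,
                 "PASS")
    expect_equal(verify_sample(p_without, rb, qc = qc_open(), now = NOW)$per_test$PT$status,
                 "PASS")
  }
})

test_that("batch verification attaches history by patient and writes an audit stream", {
  panels <- list(
    make_panel(sample_id = "a1", patient_id = "pat1"),
    make_panel(pt = 17.0, sample_id = "a2", patient_id = "pat2"),
    make_panel(fbg = 0.5, sample_id = "a3", patient_id = "pat3")
  )
  history <- list(pat2 = list(PT = data.frame(timestamp = NOW - 3 * 86400, value = 16.5)))
  verdicts <- verify_panels(panels, rb, qc = qc_open(), now = NOW, history = history)
  tab <- verdicts_table(verdicts)
  expect_equal(tab$sample_status, c("AUTO_RELEASE", "AUTO_RELEASE", "CRITICAL_ALERT"))
  expect_equal(verdicts[[2]]$per_test$PT$reasons$code, "delta_rescued")

  out <- tempfile(fileext = ".jsonl")
  write_verdicts_jsonl(verdicts, out)
  lines <- readLines(out)
  expect_length(lines, 3)
  rec <- jsonlite::fromJSON(lines[3], simplifyVector = FALSE)
  expect_equal(rec$sample_status, "CRITICAL_ALERT")
  expect_equal(rec$per_test$FBG$reasons[[1]]$stage, "critical")
  expect_equal(rec$rulebook_hash, rulebook_hash(rb))
})
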