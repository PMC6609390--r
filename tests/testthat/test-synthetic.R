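test_that("identical configurations generate identical datasets", {
  cfg <- sim_config(seed = 5, n_samples = 120)
  s1 <- generate_panels(cfg)
  s2 <- generate_panels(cfg)
  expect_identical(s1$panels_df, s2$panels_df)
  expect_identical(s1$history_df, s2$history_df)
  expect_identical(s1$truth, s2$truth)
  expect_identical(generate_tat(cfg), generate_tat(cfg))
  q1 <- generate_qc(cfg)
  q2 <- generate_qc(cfg)
  expect_identical(lapply(q1$series, `[[`, "values"), lapply(q2$series, `[[`, "values"))

  # a different seed produces different data
  s3 <- generate_panels(sim_config(seed = 6, n_samples = 120))
  expect_false(identical(s1$panels_df$value, s3$panels_df$value))
})

test_that("an all-normal batch is auto-released in full, by construction", {
  cfg <- sim_config(seed = 8, n_samples = 300, class_mix = c(normal = 1))
  sim <- generate_panels(cfg)
  expect_true(all(sim$truth$expected_status == "AUTO_RELEASE"))
  verdicts <- verify_panels(sim$panels, default_rulebook(), qc = qc_open(),
                            now = sim$verify_at)
  expect_true(all(vapply(verdicts, `[[`, "", "sample_status") == "AUTO_RELEASE"))
})

test_that("each abnormality class produces its intended verdict class", {
  cfg <- sim_config(seed = 13, n_samples = 800,
                    class_mix = c(out_of_range = 0.2, critical = 0.2,
                                  clot_pattern = 0.2, flagged = 0.1,
                                  anticoagulated = 0.1, pregnant = 0.1,
                                  thrombolytic = 0.1))
  sim <- generate_panels(cfg)
  by_class <- split(sim$truth$expected_status, sim$truth$class)
  expect_true(all(by_class$critical == "CRITICAL_ALERT"))
  for (cls in c("out_of_range", "clot_pattern", "flagged", "anticoagulated",
                "pregnant", "thrombolytic")) {
    expect_true(all(by_class[[cls]] == "HOLD_MANUAL"), label = cls)
  }
  # clot-pattern panels fail through the logical stage specifically
  clot <- sim$truth[sim$truth$class == "clot_pattern", ]
  expect_true(all(clot$expected_logical %in% c("L1", "L2", "L3")))
})

test_that("panel and history CSV round-trip preserves verdicts", {
  cfg <- sim_config(seed = 4, n_samples = 150)
  sim <- generate_panels(cfg)
  pf <- tempfile(fileext = ".csv")
  hf <- tempfile(fileext = ".csv")
  utils::write.csv(sim$panels_df, pf, row.names = FALSE)
  utils::write.csv(sim$history_df, hf, row.names = FALSE)
  panels <- read_panels_csv(pf)
  history <- read_history_csv(hf)
  verdicts <- verify_panels(panels, default_rulebook(), qc = qc_open(),
                            now = sim$verify_at, history = history)
  got <- vapply(verdicts, `[[`, "", "sample_status")
  truth <- sim$truth[match(names(got), sim$truth$sample_id), ]
  expect_equal(unname(got), truth$expected_status)
})

test_that("generated control series are clean unless a violation is injected", {
  cfg <- sim_config(seed = 2)
  q <- generate_qc(cfg)
  for (key in names(q$series)) {
    expect_equal(nrow(evaluate_westgard(q$series[[key]])$violations), 0, label = key)
  }
  gates <- qc_gate_all(q$series, q$now)
  expect_true(all(vapply(gates, `[[`, "", "status") == "open"))

  # one injected 2_2s event: exactly that series and rule flagged
  cfg2 <- sim_config(seed = 2, qc_spec = list(
    levels = c("normal", "pathological"), every_hours = 12, days = 28,
    inject = list(list(analyte = "APTT", level = "normal", rule = "2_2s"))))
  q2 <- generate_qc(cfg2)
  gates2 <- qc_gate_all(q2$series, q2$now)
  expect_equal(gates2$APTT$status, "halted")
  expect_setequal(unique(gates2$APTT$violated_rules$rule), "2_2s")
  for (a in c("PT", "TT", "FBG")) expect_equal(gates2[[a]]$status, "open")

  # an injected stale gap halts that analyte
  cfg3 <- sim_config(seed = 2, qc_spec = list(
    levels = "normal", every_hours = 12, days = 28,
    inject = list(list(analyte = "TT", level = "normal", rule = "stale"))))
  q3 <- generate_qc(cfg3)
  gates3 <- qc_gate_all(q3$series, q3$now)
  expect_true(gates3$TT$stale)
  expect_equal(gates3$TT$status, "halted")
})

test_that("normal-class marginals reproduce the configured distributions", {
  cfg <- sim_config(seed = 31)
  arch <- generate_archive(30000, cfg$marginals, seed = 31)
  for (a in analytes()) {
    m <- cfg$marginals[[a]]
    x <- arch$value[arch$analyte == a]
    expect_equal(median(x), stats::qlnorm(0.5, m$meanlog, m$sdlog),
                 tolerance = 0.02, label = a)
  }
})

test_that("synthetic TAT streams carry the configured medians and ordering", {
  cfg <- sim_config(seed = 17, tat_spec = list(n = 600,
                                               tat1_median = c(before = 126, after = 101),
                                               tat2_median = c(before = 41, after = 15),
                                               sigma = 0.25))
  tat <- generate_tat(cfg)
  tt <- tat_minutes(tat)
  expect_true(all(tt$tat1_minutes >= tt$tat2_minutes))
  before <- tt[tt$phase == "before", ]
  after <- tt[tt$phase == "after", ]
  expect_equal(median(before$tat1_minutes), 126, tolerance = 0.05)
  expect_equal(median(after$tat1_minutes), 101, tolerance = 0.05)
  expect_equal(median(before$tat2_minutes), 41, tolerance = 0.08)
  expect_equal(median(after$tat2_minutes), 15, tolerance = 0.08)
  cmp <- tat_compare(before, after, "tat1")
  expect_lt(cmp$p_value, 0.001)
  expect_equal(cmp$median_before - cmp$median_after, 25, tolerance = 0.2)
})
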