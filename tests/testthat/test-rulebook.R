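test_that("default rulebook carries the laboratory's printed thresholds field for field", {
  rb <- default_rulebook()

  expect_equal(rb$limited$PT, c(11.00, 16.30))
  expect_equal(rb$limited$APTT, c(30.40, 46.40))
  expect_equal(rb$limited$TT, c(14.00, 21.00))
  expect_equal(rb$limited$FBG, c(2.00, 6.51))

  expect_equal(rb$critical$PT[c("low", "high")], list(low = 9, high = 70))
  expect_true(rb$critical$PT$low_inclusive && rb$critical$PT$high_inclusive)
  expect_equal(rb$critical$APTT[c("low", "high")], list(low = 15, high = 100))
  expect_null(rb$critical$TT$low)
  expect_equal(rb$critical$TT$high, 150)
  expect_false(rb$critical$TT$high_inclusive)
  expect_equal(rb$critical$FBG$low, 1)
  expect_false(rb$critical$FBG$low_inclusive)
  expect_null(rb$critical$FBG$high)

  expect_equal(rb$delta$PT, list(max_abs_delta = 10, max_interval_days = 10L))
  expect_equal(rb$delta$APTT, list(max_abs_delta = 10, max_interval_days = 7L))
  expect_equal(rb$delta$FBG, list(max_abs_delta = 1, max_interval_days = 3L))
  expect_false("TT" %in% names(rb$delta))
  expect_equal(rb$anticoagulated_override,
               list(max_interval_days = 30L, inr_low = 2, inr_high = 3))

  expect_equal(vapply(rb$logical, `[[`, "", "id"), c("L1", "L2", "L3"))

  expect_equal(rb$reference_intervals$PT, c(11.00, 14.30))
  expect_equal(rb$reference_intervals$APTT, c(32.00, 43.00))
  expect_equal(rb$reference_intervals$TT, c(14.00, 21.00))
  expect_equal(rb$reference_intervals$FBG, c(2.00, 4.00))

  expect_equal(rb$qc_policy$max_qc_age_hours, 24)
  expect_setequal(rb$qc_policy$rejection_rules, c("1_3s", "2_2s", "R_4s", "4_1s", "10_x"))
})

test_that("the shipped YAML document loads to the default rulebook and round-trips", {
  path <- system.file("extdata", "rulebook-default.yaml", package = "coagverify")
  rb <- load_rulebook(path)
  expect_identical(rulebook_to_list(rb), rulebook_to_list(default_rulebook()))

  tmp <- tempfile(fileext = ".yaml")
  write_rulebook(rb, tmp)
  rb2 <- load_rulebook(tmp)
  expect_identical(rulebook_to_list(rb2), rulebook_to_list(rb))
  expect_identical(rulebook_hash(rb2), rulebook_hash(rb))
})

test_that("loading is fail-closed: bad documents never yield a partial rulebook", {
  base <- yaml::read_yaml(system.file("extdata", "rulebook-default.yaml",
                                      package = "coagverify"))
  reload <- function(x) load_rulebook(yaml::as.yaml(x))

  # limited range reaching into critical territory
  bad <- base
  bad$limited$PT <- c(11.00, 80.00)
  expect_error(reload(bad), "critical", class = "coag_config_error")

  # unknown keys are errors, not warnings
  bad <- base
  bad$typo_section <- list(a = 1)
  expect_error(reload(bad), "unknown key", class = "coag_config_error")
  bad <- base
  bad$critical$PT$lwo <- 9
  expect_error(reload(bad), "unknown key", class = "coag_config_error")

  # unknown analyte codes rejected at parse time
  bad <- base
  bad$limited$XX <- c(1, 2)
  expect_error(reload(bad), "unknown key", class = "coag_config_error")

  # inverted bounds
  bad <- base
  bad$limited$FBG <- c(6.51, 2.00)
  expect_error(reload(bad), "lower", class = "coag_config_error")

  # logical rule referencing anything outside the panel vocabulary
  bad <- base
  bad$logical[[1]]$expr <- "system('echo') | PT >= 14"
  expect_error(reload(bad), "disallowed", class = "coag_config_error")

  # wrong schema version
  bad <- base
  bad$schema_version <- 99
  expect_error(reload(bad), "schema_version", class = "coag_config_error")
})

test_that("context resolution applies replacements then scalings as documented", {
  rb <- default_rulebook()

  # identity for context = none, and idempotent
  eff <- resolve_context(rb, "none")
  expect_identical(eff$limited, rb$limited)
  expect_null(eff$inr_allowable)

  # late pregnancy: upper PT/APTT x 0.90, lower FBG x 1.10, 2-decimal rounding
  preg <- resolve_context(rb, "late_pregnancy")
  expect_equal(preg$limited$PT[2], 14.67)
  expect_equal(preg$limited$APTT[2], 41.76)
  expect_equal(preg$limited$FBG[1], 2.20)
  expect_equal(preg$limited$TT, rb$limited$TT)

  # warfarin: PT upper replaced by 40, INR band per indication
  war <- resolve_context(rb, "warfarin", "hip_surgery")
  expect_equal(war$limited$PT[2], 40.00)
  expect_equal(war$inr_allowable, c(2.00, 3.00))
  expect_true(war$anticoagulated)
  expect_equal(resolve_context(rb, "warfarin", "non_hip_surgery")$inr_allowable,
               c(1.50, 2.50))
  expect_equal(resolve_context(rb, "warfarin", "pulmonary_infarction")$inr_allowable,
               c(2.00, 4.00))
  expect_equal(resolve_context(rb, "warfarin", "valve_prosthesis")$inr_allowable,
               c(3.00, 4.00))

  # heparin and thrombolytic replacements
  expect_equal(resolve_context(rb, "heparin")$limited$APTT[2], 90.00)
  expect_equal(resolve_context(rb, "thrombolytic")$limited$FBG, c(1.20, 4.00))

  # warfarin without an indication is a configuration error
  expect_error(resolve_context(rb, "warfarin"), "indication", class = "coag_config_error")
  # combined contexts are not guessed
  expect_error(resolve_context(rb, "warfarin+heparin"), class = "coag_config_error")
})

test_that("context adjustments move bounds only in their documented direction", {
  rb <- default_rulebook()
  base <- rb$limited
  preg <- resolve_context(rb, "late_pregnancy")$limited
  for (a in analytes()) {
    expect_lte(preg[[a]][2], base[[a]][2])  # pregnancy never widens an upper bound
    expect_gte(preg[[a]][1], base[[a]][1])  # nor lowers a floor
  }
  expect_gt(resolve_context(rb, "warfarin", "hip_surgery")$limited$PT[2], base$PT[2])
  expect_gt(resolve_context(rb, "heparin")$limited$APTT[2], base$APTT[2])
  expect_lt(resolve_context(rb, "thrombolytic")$limited$FBG[1], base$FBG[1])
})
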