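# coagverify

Rule-based autoverification for routine coagulation panels.

Clinical laboratories verify every coagulation panel — prothrombin time
(PT), activated partial thromboplastin time (APTT), thrombin time (TT) and
fibrinogen (FBG), plus the INR for anticoagulated patients — before results
reach the patient record. Most panels are unremarkable, and reviewing them
by hand costs time on exactly the samples that need it least.
Autoverification encodes the review as rules: results that pass are released
automatically; anything suspicious is held for a technologist.

`coagverify` implements the full staged decision process used by laboratory
information systems, as configurable data rather than code:

1. **QC gate** — Westgard multirules (`1_3s`, `2_2s`, `R_4s`, `4_1s`,
   `10_x`; `1_2s` warns only) on control series in z-score units, plus a
   24-hour freshness requirement; no QC means no release.
2. **Analytical error flags** — any instrument flag holds the result.
3. **Critical values** — PT ≤ 9 / ≥ 70 s, APTT ≤ 15 / ≥ 100 s, TT > 150 s,
   FBG < 1 g/L trigger a clinician alert.
4. **Limited range** — the auto-releasable interval per analyte, derived as
   the union span of the clinical reference interval and the 5th/95th
   percentiles of a historical archive: `[min(ref_lo, P5), max(ref_hi, P95)]`.
5. **Delta check** — an out-of-range result is rescued when the patient has
   a recent prior within the analyte's window and |Δ| below the rule
   maximum (PT 10 s/10 d, APTT 10 s/7 d, FBG 1 g/L/3 d; no rule for TT;
   30-day window for PT/APTT under stable anticoagulation with INR 2–3).
6. **Logical (clot-pattern) rules** — whole-sample predicates that catch a
   partial specimen clot even when every single test is in range.

Patient contexts (warfarin with per-indication INR bands, heparin,
thrombolytic therapy, late pregnancy) adjust the limits per sample. Every
uncertain path fails closed: unknown flags, stale QC, malformed
configuration and internal errors all hold the sample.

The package also ships the machinery around the engine: limit derivation
from historical archives (`derive_limits()`), validation metrics
(sensitivity/specificity under the interception convention, passing-rate
series with confidence intervals, Mann-Whitney turnaround-time comparison),
and a seeded synthetic-data generator producing fully labelled panels,
histories, QC series and TAT records for testing deployments without
patient data.

## Worked example

```r
library(coagverify)
rb <- default_rulebook()   # the shipped thresholds; load_rulebook() for your own

now <- as.POSIXct("2021-03-29 09:00:00", tz = "UTC")
qc <- qc_gate(list(control_series("PT", "normal", 13.0, 0.5,
                                  timestamps = now - c(20, 8) * 3600,
                                  values = c(13.1, 12.9))), now)
qc
#> <qc gate> open

panel <- panel_record(
  sample_id = "S001", patient_id = "P123",
  results = list(
    PT   = test_result("PT",   17.2, analysis_complete_at = now - 1800),
    APTT = test_result("APTT", 38.5, analysis_complete_at = now - 1800),
    TT   = test_result("TT",   16.9, analysis_complete_at = now - 1800),
    FBG  = test_result("FBG",   3.1, analysis_complete_at = now - 1800)
  ),
  history = list(PT = data.frame(timestamp = now - 6 * 86400, value = 16.8))
)
verify_sample(panel, rb, qc = qc, now = now)
#> <verdict> S001 -> AUTO_RELEASE
#>   PT   PASS     delta_rescued
#>   APTT PASS     in_range
#>   TT   PASS     in_range
#>   FBG  PASS     in_range
```

The PT of 17.2 s is outside the 11.00–16.30 s limited range, but the patient
had 16.8 s six days ago: the change (0.4 s) is well under the 10 s delta
maximum inside the 10-day window, so the result is rescued and the sample
auto-releases. Without that prior it would be `HOLD_MANUAL`.

Scoring a month of verdicts against reviewer labels:

```r
confusion_metrics(c(tp = 858, tn = 10823, fp = 2263, fn = 5))
#> <validation> n=13949 pass=10828 fail=3121 | tp=858 tn=10823 fp=2263 fn=5
#>   sensitivity 99.42%  specificity 82.71%  passing rate 77.63%
```

Here a *true positive* is an intercepted problematic report; the passing
rate is the auto-released fraction `(tn + fn) / n`. The 5 false negatives
are auto-released problematic reports — the quantity a deployment tunes its
logical rules to drive to zero.

Synthetic data for end-to-end testing (seeded, fully labelled):

```r
sim <- generate_panels(sim_config(seed = 1, n_samples = 1000))
verdicts <- verify_panels(sim$panels, rb, qc = qc_open(), now = sim$verify_at)
table(vapply(verdicts, `[[`, "", "sample_status"))
```

A thin command-line wrapper over these functions (subcommands `verify`,
`derive-limits`, `evaluate`, `simulate`) is installed at
`system.file("cli", "coagverify.R", package = "coagverify")`.

See `vignettes/autoverification-methods.Rmd` for the full account of the
decision procedure, the limit-derivation rule, the metric conventions and
the generator's design.

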