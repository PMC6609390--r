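---
title: "Autoverification of coagulation panels: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autoverification of coagulation panels: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coagverify)
```

## The problem

A clinical laboratory releasing coagulation panels — prothrombin time (PT),
activated partial thromboplastin time (APTT), thrombin time (TT) and
fibrinogen (FBG), with the derived INR for anticoagulated patients — must
decide, for every sample, whether the results can go straight to the
electronic record or need a technologist's review. Autoverification encodes
that decision as rules: anything suspicious is held, anything clean is
released automatically. The safety requirement is asymmetric. A held correct
report costs minutes of manual review; an auto-released wrong report can
mislead treatment. Every design choice in this package therefore defaults to
*fail closed*: missing QC, unknown flags, configuration errors and internal
failures all hold the sample.

## The decision procedure

Verification of a single test runs five stages in a fixed order, stopping at
the first that fails:

1. **QC gate.** Statistical quality control must be current and in control
   for the analyte. Control series are evaluated against Westgard multirules
   in z-score units, $z = (x - \mu_{target})/\sigma_{target}$: `1_3s`
   ($|z|>3$), `2_2s` (two consecutive same-side $|z|>2$), `R_4s` (two
   consecutive opposite-side points spanning $>4$ SD), `4_1s` (four
   consecutive same-side $|z|>1$), `10_x` (ten consecutive points one side
   of the mean). `1_2s` is a screening warning only. A gate is also halted
   when the newest control for any level in use is older than 24 h at
   verification time; exactly 24.0 h still counts as fresh (inclusive
   boundary, chosen so a once-daily QC schedule does not flap). No QC data
   at all is treated as halted, never as open.
2. **Analytical error flags.** Any instrument flag — clot detection, short
   sample, reagent problems, or a code this package has never seen — holds
   the result.
3. **Critical values.** Life-threatening results trigger an alert for
   immediate clinician notification: PT $\le 9$ or $\ge 70$ s, APTT $\le 15$
   or $\ge 100$ s, TT $> 150$ s, FBG $< 1.00$ g/L. Inclusivity is encoded
   per rule exactly as the thresholds are written (`<=`/`>=` for PT and
   APTT, strict for TT and FBG); the shipped limited ranges sit strictly
   inside the critical bands, so a range-passing value can never be
   critical.
4. **Limited range.** The interval within which a result may be released
   without historical corroboration (bounds inclusive): PT 11.00–16.30 s,
   APTT 30.40–46.40 s, TT 14.00–21.00 s, FBG 2.00–6.51 g/L.
5. **Delta check.** An out-of-range result is rescued if the patient has a
   prior result close enough, recently enough: PT $|\Delta| < 10$ s within
   10 days, APTT $|\Delta| < 10$ s within 7 days, FBG $|\Delta| < 1$ g/L
   within 3 days — strict inequalities on both the change and the window,
   comparing against the most recent in-window prior. TT deliberately has no
   delta rule, so an out-of-range TT is always held. Under anticoagulant
   therapy with INR in 2.00–3.00 the PT and APTT windows widen to 30 days
   (a stably anticoagulated patient's old baseline is still informative).

If all four tests pass, whole-sample **logical rules** look for cross-analyte
patterns a single test cannot see — chiefly a partial clot in the specimen,
which consumes fibrinogen and prolongs clotting times without necessarily
pushing any single value out of range:

* `L1`: (PT $\ge 14.00$ or APTT $\ge 43.00$) and FBG $\le 2.00$
* `L2`: PT $\ge 14.00$ and APTT $\ge 43.00$
* `L3`: APTT $\le 43.00$ and PT $\le 14.00$ and TT $\ge 21.00$

Rules are data (safe, parsed predicate expressions in the rulebook document),
evaluated in order, holding on the first that fires. The source sentence
describing these rules is grammatically ambiguous about operator binding; the
L1–L3 reading is the one consistent with the stated purpose (clot detection:
prolonged PT/APTT with depleted fibrinogen, or an isolated TT prolongation).
Sites that read it differently can re-specify the rules in the config without
touching code.

A critical result anywhere makes the sample a `CRITICAL_ALERT`; any hold
makes it `HOLD_MANUAL`; only a fully clean panel is `AUTO_RELEASE`d. The
alert record is this package's interface boundary — calling the clinician is
workflow, not computation.

### Patient-context customization

One context profile applies per sample (combined contexts are rejected, not
guessed):

* **warfarin** — PT upper limit replaced by 40.00 s *and* the INR must lie
  in the indication's allowable band (1.50–2.50 before non-hip surgery,
  2.00–3.00 before hip surgery and for deep-vein thrombosis, 2.00–4.00 for
  pulmonary infarction, 3.00–4.00 for arterial-thrombosis prevention and
  valve prosthesis). The source text is ambiguous about whether the relaxed
  PT limit alone suffices; this package requires both checks to pass, the
  conservative reading, and holds the sample when the INR is missing.
* **heparin** — APTT upper limit replaced by 90.00 s.
* **thrombolytic** — FBG range replaced by 1.20–4.00 g/L.
* **late_pregnancy** — PT and APTT upper limits reduced by 10%, the FBG
  floor raised by 10%, applied multiplicatively after any replacement and
  rounded to 2 decimals (the reporting precision): effective PT upper
  14.67 s, APTT upper 41.76 s, FBG lower 2.20 g/L.

The INR-based 30-day delta override is applied to PT and APTT only; FBG
turnover is fast enough that its 3-day window stays authoritative under
anticoagulation as well.

## Deriving the limited ranges

Clinical reference intervals describe healthy subjects; a hospital's actual
result stream does not. The limited range is therefore the *union span* of
the clinical reference interval and the 5th/95th percentiles of a year-scale
historical archive:

$$[\,\min(\mathrm{ref}_{lo}, P_5),\ \max(\mathrm{ref}_{hi}, P_{95})\,]$$

subject to the result lying strictly inside the critical band. This merge
rule is inferred from the four shipped limited ranges, which it reproduces
exactly (for TT the reference interval already contains the percentile
interval and survives unchanged); it is exposed as `merge_limited_range()`
and overridable per analyte. Percentiles use linear interpolation between
order statistics (`stats::quantile` type 7) — the estimator behind the
shipped percentile values is unrecorded, and at archive scale
($n \approx 1.6 \times 10^5$) estimator choice moves the 5th/95th
percentiles by less than the 2-decimal reporting precision. All internal
computation is full precision; rounding (half-up, 2 decimals) happens only
at serialization.

## Validation metrics

Validation labels follow the interception convention: a *true positive* is an
intercepted problematic report and a *true negative* an auto-released correct
report, so sensitivity is the fraction of problematic reports caught and the
passing rate is $(tn + fn)/n$ — note that false negatives *raise* the
passing rate, which is why the identity matters. Zero-denominator metrics are
reported as undefined, never as 0. Aggregate passing rates over reporting
periods are emitted both as the unweighted mean of period rates and as the
pooled rate, with a t-interval over period rates by default (a pooled Wilson
interval is available); the two aggregates differ when months differ in size
and neither is privileged.

Turnaround time is compared with a two-sided Mann-Whitney U test. The
implementation is in-package because release-time data are heavily tied
(minute resolution) and the stock `wilcox.test` cannot compute exact
p-values under ties: for $\min(n_1,n_2) \le 8$ the permutation null is
enumerated exactly (valid with ties), larger samples use the tie-corrected
normal approximation with continuity correction. The test suite checks the
exact path against an independent pairwise-enumeration oracle for every
group-size split up to $n_1+n_2=12$ and the approximate path against
`wilcox.test`.

## The synthetic-data generator

No real patient data ship with (or were available to) this package, so the
generator produces fully labelled datasets that exercise every rule path.

**Marginals.** Per-analyte log-normals moment-matched to the historical
archive summary (`default_archive_summary()`): coagulation results are
strictly positive and right-skewed (the archive maxima sit 5–50 SDs above
the medians, which a normal cannot produce). Draws for specific classes are
taken from the marginal truncated to a class-specific window by inverse-CDF;
windows so deep in the tail that the marginal has no numerical mass there
(critical values) fall back to uniform draws on the window.

**Classes.** Eight classes, each constructed so its verdict is deterministic
under the shipped rulebook — `normal` draws live in a safe interior of every
limited range where no logical rule can fire; `out_of_range` breaches one
limited range without reaching critical territory, and any attached history
is in-window but with a delta exceeding the rule maximum; `critical`
breaches exactly one critical threshold; `clot_pattern` satisfies one of
L1–L3 while every single test stays in range; `flagged` carries one
instrument flag; `anticoagulated` is a warfarin patient whose PT passes only
the relaxed limit while the INR is outside the indication band; `pregnant`
and `thrombolytic` sit between their tightened context limit and the routine
limit. The default mix is 78.89% normal — the pooled auto-release rate
observed over six months of deployment of the reference system — with
instrument flags at their observed monthly frequency (~120 per ~13,400
samples) and the remaining abnormal mass split across the other classes
(12% out-of-range, 3% clot pattern, 2% critical, 2% anticoagulated, 0.7%
pregnant, 0.51% thrombolytic); true class prevalences are unpublished, so
these are fixed, config-exposed choices, not estimates.

**Ground truth.** Labels come from `decision_table_verdict()`, a flat
brute-force decision table written independently of the engine, so the
system-level fidelity test (engine verdict equals label for 100% of
samples) is adversarial rather than circular.

**What the generator does not emulate.** Inter-analyte physiological
correlation (beyond what the clot-pattern class injects), pre-analytical
error modes other than flags, drifting QC (violations are injected as
canonical patterns), class mixtures within one sample, and longitudinal
patient trajectories (history is one synthetic prior, placed relative to the
delta window). Passing tests on this data demonstrate that the engine
implements its rules exactly — not that the rules have any particular
sensitivity or specificity on real patients, which is a property of the
rules and the population, not of this software.

**QC series.** In-control stretches are drawn with $|z| \le 0.9$ and
same-side runs broken at length 8, so no Westgard rule can fire spuriously;
violations are injected as canonical patterns (e.g. $z = 2.5, 2.6$ for
`2_2s`) and recorded in ground truth. Staleness is injected by cutting the
series short of the freshness window.

**TAT records.** TAT 1 (receipt to release) is log-normal with exactly the
configured median; TAT 2 (analysis complete to release) is TAT 1 times an
independent log-normal ratio, so both medians are exact (medians of products
of independent log-symmetric factors multiply) and timestamps are always
ordered. Defaults: medians 126 → 101 min (TAT 1) and 41 → 15 min (TAT 2)
for the before/after phases.

## Numerical and engineering choices

* Timestamps are UTC `POSIXct`; a day is exactly 86 400 s; delta windows and
  QC freshness use strict/inclusive comparisons exactly as documented above.
* Percentage and limit rounding is half-up (half away from zero) at 2
  decimals, applied only at presentation; R's `round()` half-to-even would
  print 82.715 as 82.71 rather than the conventional 82.72.
* The rulebook document is YAML with an explicit `schema_version`; unknown
  keys, unknown analyte codes and inconsistent thresholds are fatal parse
  errors (fail closed — a typo in a safety config must not be ignored).
  Logical-rule expressions are validated against a whitelist of analyte
  names, comparison operators and logical connectives before evaluation.
* Verdicts carry the rulebook hash, so an audit stream records which
  configuration released each sample.

## Problem sizes used by the test suite

The suite verifies the engine against the independent decision table on an
exhaustive grid of 15 000 cases (5 values per analyte spanning both critical
sides, the limited range and its boundaries × 4 history variants × 6
context variants), checks 100% ground-truth fidelity on 10 000 seeded
synthetic panels, compares the Westgard evaluator with a window-scan oracle
on 1 000 random series, enumerates the Mann-Whitney permutation null for all
group sizes with $n_1+n_2 \le 12$, and checks quantile recovery on
$10^5$ archive draws against the generator's analytic quantiles within
3 standard errors of the order statistic.

## Known limitations

* One context per sample; a pregnant patient on heparin needs a site-defined
  combined profile.
* Westgard rules are evaluated within one (analyte, level) series;
  across-level variants (e.g. `2of3_2s`) are not implemented.
* No outlier pre-filtering or age/sex-partitioned reference intervals in the
  limit-derivation pipeline.
* The critical-alert record is the boundary: no paging, HL7, or
  instrument-protocol integration.
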