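---
title: "Methods: learning-curve labor estimation for digitization projects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: learning-curve labor estimation for digitization projects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herblabor)
```

## The problem

Herbarium digitization — applying barcodes, imaging sheets, transcribing
skeletal label data — is dominated by labor cost, and that labor is
typically supplied by short-tenure student technicians. Because manual
task throughput improves with practice, the hours needed to digitize a
collection depend not only on specimen count but on how long each
technician stays on a task before being replaced by a novice. This
package estimates that dependence from per-session self-reports
(minutes worked, specimens processed, free-text setbacks) and converts
it into labor projections under technician turnover.

## Rate curves

Each task's throughput in specimens per minute (SPM) is modelled as a
polynomial in cumulative task experience $x$ (hours):

$$y_{\text{imaging}} = 1.95170 + 0.02118\,x, \qquad
  y_{\text{databasing}} = 2.55659 + 0.02760\,x,$$
$$y_{\text{barcoding}} = 3.7216 + 0.09928\,x - 0.00175\,x^2.$$

Imaging and databasing improve roughly linearly; barcoding — the
simplest task — peaks near 28 hours and then declines, which is why it
gets a quadratic. Every curve carries a rate limit (4.00 and 6.50 SPM
ceilings for imaging and databasing, a 3.00 SPM floor for barcoding)
reflecting physical and technical extremes of real workflows, and a
64-hour experience limit beyond which the data thin out and the curve is
not extrapolated. These canonical coefficient sets ship with the package
(`canonical_rate_models()`) and are the projection defaults, so
projections never depend on refitting any particular data set.

## Cleaning procedure

Raw session reports are partitioned in a fixed five-stage order, each
entry landing in exactly one category:

1. **Non-representative reporters.** Supplied via configuration, never
   inferred: in practice such reporters (fraudulent or systematically
   inaccurate) are identified by project oversight, and no algorithmic
   rule can substitute for that investigation.
2. **Non-representative workflow entries.** Also configuration-supplied.
3. **Entry errors (swapped fields).** An entry is a suspected
   minutes/specimens swap when its rate falls below the task's 5th
   percentile *and* its inverse ratio (minutes per specimen) lies within
   2 SDs of the task's mean rate. The reference mean/SD describe the
   candidate-clean population: rates below the trigger quantile and
   obvious field outliers are left out of them, since those are exactly
   the corrupted values the statistics must not absorb. Both the
   quantile and the band width are configurable.
4. **Setbacks.** Free text is normalized (lowercase, punctuation to
   spaces, whitespace squished) and compared to a whitelist of
   "no setback" phrases (`no`, `none`, `no setbacks`). Any other
   non-empty text marks the session as a setback. A blank field counts
   as "nothing to report": the whitelist's own examples all mean "none",
   and an untouched box is the most common way of saying it.
5. **Extreme outliers.** Entries whose minutes or specimens deviate from
   the field mean by strictly more than 5 SDs, with mean and SD computed
   per task over the survivors of stages 1–4. Per-task statistics are
   used because the fields' scales differ by task; "exceeding" is read
   as a strict inequality.

Stages run in this listed order, so an entry that is both a setback and
a numeric outlier is recorded as a setback. Re-cleaning the kept
partition excludes nothing further in stages 1–4; stage 5 can in
principle move entries because its statistics are recomputed on the
smaller population (this is tested, not hidden).

## Experience model

Cumulative task hours are accumulated per (technician, task) in
ascending date order, ties keeping input order, and are attributed at
session end — a session's own minutes count toward the experience at
which its rate is recorded, matching a report filed at the end of a
shift. Rates are pooled into shared half-open 2-hour bins $[2k, 2k+2)$
below the 64-hour threshold, and each task's bin means are fit by
unweighted ordinary least squares against bin midpoints. Midpoints are
the symmetric abscissa choice; fitting bin means (rather than raw
entries) equalizes the influence of heavily and sparsely populated
experience levels, and the unweighted fit keeps late, sparse bins from
being ignored entirely. Linear fits need at least 3 bins, quadratic 4.

## Turnover simulation

The projection (`simulate_labor_hours()`) advances in whole hours —
session reports are minute-grained, but contract durations and the
printed estimates are whole hours, so the hour is the natural step. The
rate for a technician's $k$-th hour is the curve evaluated at
end-of-hour experience $\min(k, 65)$: the curve is followed through the
hour that ends one hour past the 64-hour bin threshold (experience
accrues *during* the hour, so the hour beginning at 64 is still within
the supported range) and frozen thereafter. The rate limit clamps every
hour. When a contract of $d$ hours completes, experience resets to zero
(a novice replaces the leaver) while cumulative production carries over.
The returned estimate is the first whole hour at which cumulative
production reaches the target, so all projections are integers and a
target equal to $m$ whole contracts' production returns exactly $md$
hours. Accumulation is evaluated by closed-form contract arithmetic
(full contracts plus a partial cumulative sum) with a $10^{-9}$ relative
guard for exact-boundary targets; the test suite checks it against an
independently coded power-sum oracle.

The "Combined" rows of `projection_table()` sum the three per-task
estimates at the same contract duration: contracts are per-task, so a
technician splitting time across tasks accrues experience separately in
each.

## Synthetic data generator

`generate_sessions()` emulates the statistical structure the analysis
assumes, with ground-truth labels for every entry:

- **Scale and session lengths.** Default 30 technicians with 8–40
  sessions each; session minutes are normal with mean 101 and SD 35,
  truncated to [15, mean + 2.5 SD] and reported to the nearest 5
  minutes, as technicians round their time. The 101-minute mean matches
  typical setback-free sessions; the SD and session counts are chosen as
  realistic for student shifts of one to three hours, since no
  particular distribution is asserted by the underlying analysis.
- **Clean throughput.** Specimens = minutes × noise × $f$(cumulative
  hours at session end), rounded to whole specimens, where $f$ is the
  task's rate curve with its limits applied. Rate noise is
  multiplicative lognormal (rates are positive and right-skewed) with
  configurable CV, default 0.25, truncated at two log-SDs. The
  truncation is what makes the generator's anomaly labels *separable by
  construction*: a clean session can be unlucky, but never so unlucky
  that it imitates an injected swap or outlier.
- **Setbacks** (default probability 0.15) inflate session minutes by
  1.32 — the ratio of mean setback to setback-free session durations
  (133/101 minutes) — and draw non-whitelisted free text from an
  equipment/connectivity/training phrase pool. Specimens follow the
  inflated minutes, so the setback's signature lives in the duration and
  the text, disjoint from the rate-based swap signature.
- **Swapped fields** (default 0.01) exchange minutes and specimens of an
  otherwise noise-free session, so the inverse ratio sits exactly on the
  task curve and the entry is unambiguously recoverable.
- **Extreme outliers** (default 0.01) corrupt the specimens field to
  40,000–60,000 (extra digits typed). Injections are capped at 2% of
  each task's entries: flagging is relative to a mean/SD that the
  outliers themselves inflate, and beyond roughly 1 in 26 entries no
  magnitude is detectable at 5 SDs, so a generator promising separable
  labels must bound the contamination share.
- **Fraudulent reporters** (default 1 technician) emit rates scattered
  far off-curve. They carry labels but are *not* algorithmically
  detected: the cleaning stage receives their ids via configuration,
  mirroring how real projects identify them.

What the generator does **not** emulate: per-collection workflow
differences, seasonal staffing patterns, motivational effects of
rate tracking, serially correlated technician ability, or the real
data's unknown anomaly structure. Perfect anomaly recovery on these
fixtures therefore demonstrates that the cleaning rules implement their
definitions — not that real session logs are this cleanly separable.

## Productivity reporting

Project-wide rates treat "specimens digitized" as the arithmetic mean of
the three per-task specimen totals (each specimen passes through all
three tasks) and differ in the hour denominator: all pre-cleaning hours
(method A), all post-cleaning hours (B), or post-cleaning hours on the
primary tasks only (C). On published project totals these compute 0.653,
0.691, and 0.98247 SPM; note that the computational layer returns
unrounded values and rounding happens only in the report writer, so
small discrepancies in externally printed figures (e.g. 0.983, 4.07)
remain visible rather than baked in.

## Problem sizes and runtime choices

The test suite exercises generator fixtures of roughly 600–3000 sessions
(up to 60 technicians × 60 sessions), parameter-recovery simulations
with 50 technicians at CV 0.1, and the full 6 × 13 projection grid;
these sizes give stable bin coverage through the 64-hour threshold while
keeping the whole suite comfortably fast. Curve-shape checks use
technicians with enough barcoding hours (~35) to span the quadratic's
inflection, without which the curvature sign is not identifiable.

## Known limitations

- The five-stage cleaning cannot discover non-representative reporters;
  garbage from an unflagged reporter flows into the fit.
- Stage-5 outlier statistics are contamination-sensitive by definition;
  above ~4% corrupted entries in a task field, 5-SD flagging breaks down
  regardless of magnitude.
- Projections assume every technician follows the mean curve; real
  heterogeneity widens the uncertainty but is not modelled, and the
  estimates exclude training time and setbacks, so they are best-case
  figures — planning budgets should add a setback buffer on the order of
  20–30%.
- The 64/65-hour freeze extrapolates the final supported rate to
  arbitrarily long contracts; for tasks with late-declining rates (like
  barcoding) this may be optimistic.
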