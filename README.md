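# herblabor

Labor estimation for natural-history-collections digitization projects
that accounts for the technician learning curve.

Herbaria digitize their collections with largely inexperienced, high-turnover
student workforces. Planning such an effort requires an answer to "how many
labor hours will N specimens take?" — and that answer depends on how long
each technician stays, because throughput improves with experience.
`herblabor` provides the full analysis pipeline for producing such
estimates from technician session reports:

1. **Session cleaning** — a five-stage, fully audited partition of raw
   work-session logs: manually flagged non-representative reporters and
   workflows, swapped minutes/specimens entry errors (suspiciously low
   rates whose inverse ratio is typical of the task), free-text setback
   reports matched against a whitelist of "no setback" phrases, and
   extreme numeric outliers (values more than five SDs from their field
   mean).
2. **Experience model** — per-technician cumulative hours on each task,
   rates pooled into shared 2-hour experience bins up to a 64-hour
   threshold, and least-squares rate curves fit to the bin means.
3. **Turnover labor simulation** — a discrete-time simulator that
   converts a rate curve into labor-hour projections under technician
   turnover, producing the projection grid across contract durations and
   specimen counts.
4. **Synthetic session generator** — seeded session tables with
   ground-truth anomaly labels, so every stage is testable without
   access to any project's raw reports.

## The model

For each digitization task, throughput in specimens per minute (SPM) is a
polynomial in the technician's cumulative hours *x* on that task:

- imaging: *y* = 1.95170 + 0.02118 *x*, capped at 4.00 SPM
- skeletal databasing: *y* = 2.55659 + 0.02760 *x*, capped at 6.50 SPM
- barcoding: *y* = 3.7216 + 0.09928 *x* − 0.00175 *x*², floored at 3.00 SPM

Curves are supported by data up to 64 cumulative hours; the simulation
advances in whole hours, evaluates each hour at end-of-hour experience,
freezes experience one hour past that limit, clamps every hourly rate at
the task's limit, and resets experience to zero whenever a technician's
contract ends (production carries over). The reported estimate is the
first hour at which cumulative production reaches the target.

## Worked example

```r
library(herblabor)

pt <- projection_table(durations = c(15, 135), counts = c(20000, 100000, 500000))
projection_wide(pt)
#> # A tibble: 8 × 5
#>   contract_duration task                `20000` `100000` `500000`
#>               <int> <chr>                 <int>    <int>    <int>
#> 1                15 barcoding                77      382     1907
#> 2                15 imaging                 158      787     3929
#> 3                15 skeletal_databasing     121      601     3001
#> 4                15 Combined                356     1770     8837
#> 5               135 barcoding                80      440     2233
#> 6               135 imaging                 114      561     2782
#> 7               135 skeletal_databasing      90      432     2127
#> 8               135 Combined                284     1433     7142

retention_savings(pt, 500000)
#> [1] 0.1918072
```

Each cell is the labor hours needed to finish that many specimens of that
task when every technician works the given number of hours (the contract
duration) before being replaced by a novice. Fully digitizing 500,000
specimens (all three tasks) takes 8837 h with 15-hour contracts but only
7142 h with 135-hour contracts — longer retention saves about 19.2%,
because experienced technicians image and database faster. Barcoding runs
against the trend (77 → 80 h at 20,000 specimens): its rate curve peaks
near 28 hours of experience and declines afterwards, so very long
barcoding contracts spend hours on the far side of the peak.

An end-to-end run on synthetic data — generate, clean, bin, fit, project,
report — is one call:

```r
manifest <- run_pipeline(pipeline_config(output_dir = "run1", seed = 7))
```

or, from a shell, via the thin CLI:

```sh
Rscript inst/cli/herblabor.R run --out run1 --seed 7
```

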