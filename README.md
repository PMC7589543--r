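# pabarcode

Multidimensional measurement of habitual physical activity from five
synchronized body-worn inertial measurement units (IMUs), built for the
capacity-vs-performance question in children with cerebral palsy: clinical
tests measure what a child *can* do (gross motor capacity, GMFM-66, 0–100);
a school day of trunk + thigh + shank IMU wear measures what the child
*actually does*. `pabarcode` turns the raw 100 Hz accelerometer/gyroscope
streams into

- an **activity barcode**: a per-second symbol sequence over 22 states
  combining activity type (lying/sitting, standing, walking/running), bout
  duration (short `[0,60)` / medium `[60,120)` / long `[120,360)` / very
  long `[360,∞)` s) and intensity (body acceleration for static states,
  cadence bands `<70 / 70–100 / 100–130 / >130` steps/min for walking);
- **pattern-complexity metrics** of that sequence — normalized information
  entropy `Hn`, symbolic sample entropy `SampEn`, Lempel-Ziv complexity
  `LZC` (all in [0,1]) — and the composites

  ```
  CC  = Hn + SampEn + LZC            (0..3)
  CDS = CC * %activity               (%activity = time in states 3-22, percent)
  ```

- **6 physical activity states (PAS)** with time fractions and
  achiever/non-achiever flags (achiever = any nonzero time in the PAS);
- the **cohort battery**: Spearman correlations of GMFM-66 with seven PAS
  variables and four complexity variables, Holm-corrected within each
  family separately; age-partialled rank correlations; ROC analyses with
  permutation-tested AUC and Youden-optimal GMFM-66 cut-offs separating
  achievers from non-achievers (positives = non-achievers).

Detection follows the field's conventions: walking bouts are mid-swing
peaks on band-passed shank pitch angular velocity with a hard minimum of
**4 consecutive steps**; postures come from the gravity orientation of
trunk and thigh acceleration; sensor axes are auto-calibrated from gait.
A seeded synthetic cohort generator (subjects, capacity-linked activity
timelines, rendered IMU signals) makes the whole chain testable without
clinical data; no subject data ship with the package.

## Worked example

Simulate a 25-subject cohort of 9.4 h school days, barcode it, and run the
capacity–performance battery:

```r
library(pabarcode)

cfg       <- generator_config(n_subjects = 25, seed = 42)
cohort    <- generate_cohort(cfg)
timelines <- lapply(seq_len(25), function(i)
  generate_timeline(cohort[i, ], cfg, seed = derive_seed(42, i)))
barcodes  <- lapply(timelines, to_barcode)
summaries <- setNames(lapply(barcodes, pa_summary), cohort$subject_id)
metrics   <- setNames(lapply(barcodes, complexity_metrics), cohort$subject_id)

summaries[[1]]
#> <pab_pasummary> subject S001 (33840 s monitored)
#>   PAS 1 lying/sitting     74.12%  achiever
#>   PAS 2 standing          20.21%  achiever
#>   PAS 3 active short       2.92%  achiever
#>   PAS 4 active medium      1.46%  achiever
#>   PAS 5 active long        1.29%  achiever
#>   PAS 6 active very long   0.00%  non-achiever
#>   PAS 3-6   5.67%   PAS 4-6   2.75%   %activity  25.88%

metrics[[1]]
#> <pab_complexity> subject S001
#>   Hn 0.2999  SampEn 0.0002  LZC 0.0110  ->  CC 0.3110
#>   %activity 25.88  ->  CDS 8.050
```

Subject S001 spent three quarters of the day sitting or lying and never
held a walking bout past 6 minutes; the low entropy/LZC values say the day
was not only inactive but also monotonous, and CDS combines both facets
into one score. The cohort stage relates all of this to capacity:

```r
tab <- build_cohort_table(cohort, summaries, metrics)
ana <- run_analysis(tab, seed = 42)
ana
#> <pab_correlations> Holm-adjusted within family
#>      family variable  n    rho    p_raw    p_adj                   band significant
#>         PAS     pas1 25 -0.668 2.66e-04 7.97e-04       moderate to good        TRUE
#>         PAS     pas2 25  0.202 3.32e-01 3.32e-01           no to little       FALSE
#>         PAS     pas5 25  0.758 1.13e-05 4.52e-05 very good to excellent        TRUE
#>  complexity       Hn 25  0.545 4.81e-03 9.62e-03       moderate to good        TRUE
#>  complexity   SampEn 25  0.161 4.43e-01 4.43e-01           no to little       FALSE
#>  ...
#>
#> ROC for PAS 5 achievement:
#> <pab_roc> AUC = 0.981 (p = 9.999e-05; 11 non-achievers vs 14 achievers)
#>   Youden-optimal cut-off 80.41 (sens 1.00, spec 0.93, J = 0.93)
```

Read: in this synthetic cohort, more time lying/sitting goes with lower
capacity (rho −0.668), long active bouts with higher capacity (rho 0.758),
and a GMFM-66 score around 80 separates children who ever reach a
2–6-minute walking bout from those who never do. `plot(barcodes[[1]])`
draws the day as a color stripe; `render_barcode_image()` writes it to a
PNG.

The same stages run from the shell over plain-text files:

```sh
Rscript inst/cli/pabarcode.R run-all --config cfg.yml --out out/ --seed 42
```

with subcommands `simulate | detect | barcode | complexity | analyze | viz`
composing through the documented delimited-text formats (see
`?pab_cli`). Every run writes a `run_metadata.yml` echoing the resolved
configuration, seeds and thresholds.

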