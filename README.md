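# poincareHRV

Continuous, non-invasive characterization of autonomic function from
heart-rate recordings, built for anesthesia monitoring research: a
real-time-capable Poincaré SD1/SD2 index of heart-rate variability (HRV),
plus the pre-induction versus maintenance stage comparison used to validate
it on patient and resting-control cohorts.

The Poincaré plot is the lag-1 return map of a uniformly sampled heart-rate
series: each value HR(t) is plotted against HR(t+1). With d = x − y and
s = x + y over the pair cloud,

    SD1 = sqrt(Var(d) / 2)     (dispersion ⟂ to the line of identity;
                                short-term, beat-to-beat variability)
    SD2 = sqrt(Var(s) / 2)     (dispersion along the identity line;
                                longer-term variability)

using the unbiased (n − 1) sample variance. The package standardizes any
input (heart-rate CSV or beat-annotation files, plain text or MIT/WFDB
format) onto a 1 Hz grid by linear interpolation, removes ectopic/noise
samples with the standard ±20% previous-accepted relative filter, computes
SD1/SD2 over a sliding window (default 20 s window, 5 s step) both in batch
and through an online streaming engine with identical emissions, and runs
the cohort stage comparison (mean/median/IQR per stage, two-sided unpaired
Mann–Whitney–Wilcoxon test). A seeded synthetic generator (AR(1) noise plus
a respiratory sinusoid, with closed-form expected descriptors) makes the
whole pipeline testable without clinical data.

## Worked example

A 25-minute synthetic subject with anesthetic induction at t = 300 s
(variability suppressed to 30% of baseline), filtered and analyzed per
stage:

```r
library(poincareHRV)

cfg <- synthetic_config(duration = 1500, seed = 11)
rec <- inject_transition(generate_hr(cfg),
                         transition_config(t0 = 300, suppression_factor = 0.3))
rec <- filter_ectopic(rec)

sd_descriptors(make_pairs(extract_stage(rec, c(0, 300))))     # pre-induction
#> <poincare_descriptors> n_pairs = 300
#>   SD1 = 1.9774 bpm   SD2 = 5.8659 bpm   SD1/SD2 = 0.3371
#>   centroid = (64.62, 64.66) bpm

sd_descriptors(make_pairs(extract_stage(rec, c(900, 1200))))  # maintenance
#> <poincare_descriptors> n_pairs = 300
#>   SD1 = 0.6347 bpm   SD2 = 1.4725 bpm   SD1/SD2 = 0.4310
#>   centroid = (65.12, 65.11) bpm
```

Both descriptors collapse after induction — the signature the real-time
index is built to display. The same contrast at cohort level, as a
stage-comparison table:

```r
cohort <- generate_cohort(18, cfg, transition_config(300, 0.3), seed = 1000)
ps <- cohort_stage_descriptors(cohort$recordings,
                               stage_spec(c(0, 300), c(900, 1200)))
compare_stages(ps)
#> Stage comparison (n = 18 subjects, alpha = 0.05)
#>                    Mean   Median      IQR          p
#> SD1 stage 1        2.11     2.09     0.09  3.23e-07*
#> SD1 stage 2        0.63     0.63     0.02
#> SD2 stage 1        5.67     5.54     0.52  3.23e-07*
#> SD2 stage 2        1.70     1.66     0.35
```

Mean, median and IQR are per-stage summaries of the 18 per-subject
descriptor values; `p` is the two-sided rank-sum p-value for the stage
difference (`*` = significant at alpha). The real-time view of the same
recording:

```r
tr <- sliding_trace(rec, window_spec(window_length = 20, step = 5))
head(as.data.frame(tr), 3)
#>   t_end      sd1      sd2 n_pairs
#> 1    20 1.936662 3.398197      20
#> 2    25 1.764941 3.632869      20
#> 3    30 1.869385 3.748783      20
plot(tr)   # SD1/SD2 trend lines over the surgery
```

The first emission appears at t = 20 s (one full window buffered); the
online engine `stream_engine()`/`stream_push()` produces exactly the same
sequence one sample at a time.

## Command line

A thin script over the same functions:

```sh
Rscript inst/cli/poincare-hrv.R simulate --n-subjects 18 --duration 1500 \
    --transition-t0 300 --suppression 0.3 --seed 42 --out cohort/
Rscript inst/cli/poincare-hrv.R compare --manifest cohort/manifest.csv --out report/
Rscript inst/cli/poincare-hrv.R stream --input cohort/S01.csv --window 20 --step 5 --out out/
```

Commands: `analyze`, `stream`, `sweep`, `compare`, `simulate`. Every run
writes a `provenance.txt` (config echo, version, seed) beside its outputs.

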