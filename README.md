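# myoasl

Regional myocardial blood flow (MBF) quantification from FAIR arterial spin
labeled cardiovascular MR (ASL-CMR), with a synthetic data generator for
validation.

ASL-CMR measures myocardial perfusion without gadolinium: arterial blood
water is magnetically labeled (here by FAIR — flow-sensitive alternating
inversion recovery) and the control-minus-label signal difference is
proportional to flow. Because that difference is a fraction of a percent of
the base signal, quality control (physiological noise, temporal SNR) and
regional averaging are as much a part of the method as the kinetic model
itself. `myoasl` is aimed at researchers analyzing single-delay myocardial
ASL series — e.g. rest/stress vasodilator studies or serial post-infarction
imaging — and at methodologists who need a ground-truth simulator to probe
the pipeline's accuracy and statistical power.

## The model

Each acquisition is one short-axis slice: a base image (no labeling pulse),
a noise image, and six control/label pairs, with the inversions applied two
cardiac RR intervals before imaging. For mean myocardial signals C, L and B
(control, label, base), MBF is obtained from the Buxton general kinetic
model at a single post-labeling delay T_D:

    F = (C − L) / (2 · B · T_D · exp(−T_D / T1_blood)),   T_D = n_RR · 60000 / HR  [ms]

with T1_blood = 1650 ms by default and F in ml/g/min. Per AHA convention the
LV myocardium is divided into six angular segments (anterior, anteroseptal,
inferoseptal, inferior, inferolateral, anterolateral). Per segment:

- **MBF** — mean of the six per-pair measurements;
- **physiological noise (PN)** — their sample standard deviation;
- **tSNR** = MBF / PN; segments with tSNR < 2 are flagged excluded for
  rest/stress analyses (no exclusion in post-infarction comparisons, where
  the infarcted anteroseptal segment is expected to fail tSNR);
- **region** — anteroseptal = infarct; inferior, inferolateral,
  anterolateral = remote.

Group statistics follow the study design the package emulates: paired t-test
for rest vs stress, per-segment myocardial perfusion reserve
(MPR = stress/rest), and cross-sectional one-way ANOVA across
post-infarction timepoints with Holm–Sidak-adjusted pairwise comparisons
against baseline.

## Worked example

Simulate a small resting cohort with known ground truth and quantify it:

```r
library(myoasl)

cfg    <- scenario_config("baseline", n_slices = 5, seed = 42)
cohort <- simulate_cohort(cfg)
results <- quantify_cohort(cohort, exclusion_enabled = TRUE)
results[1:6, c("slice", "segment_name", "region", "mbf", "pn", "tsnr", "included")]
#>   slice  segment_name  region   mbf     pn  tsnr included
#> 1     1      anterior   other 0.612 0.1493  4.10     TRUE
#> 2     1  anteroseptal infarct 0.763 0.0506 15.06     TRUE
#> 3     1  inferoseptal   other 3.032 0.1821 16.65     TRUE
#> 4     1      inferior  remote 0.946 0.1495  6.33     TRUE
#> 5     1 inferolateral  remote 2.799 0.1808 15.48     TRUE
#> 6     1 anterolateral  remote 0.713 0.2115  3.37     TRUE

included <- results[results$included, ]
sprintf("%d/%d segments included; MBF %.2f ± %.2f, PN %.3f ml/g/min",
        nrow(included), nrow(results), mean(included$mbf),
        sd(included$mbf), mean(included$pn))
#> "30/30 segments included; MBF 1.20 ± 0.81, PN 0.131 ml/g/min"
```

Each row is one AHA segment of one slice: `mbf` is the segment's perfusion
estimate, `pn` its repeat-to-repeat noise, and `included` whether it
survives the tSNR ≥ 2 quality gate (all do here; in a 41-slice cohort a few
percent of segments are flagged). The 5-slice cohort mean (1.20 ml/g/min)
scatters around the configured true mean of 1.08 with SE ≈ 0.15.

`run_study("out/", seed = 1)` drives the whole design — baseline, paired
rest/stress, and three post-AMI cohorts — and writes results tables, a
markdown report, MBF maps and summary figures. A command-line wrapper with
`simulate` / `segment` / `quantify` / `stats` / `run-study` subcommands is
installed at `inst/cli/myoasl.R`.

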