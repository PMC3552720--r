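# mpri — semi-quantitative myocardial perfusion reserve for first-pass cardiac MR

`mpri` implements the semi-quantitative up-slope analysis used to quantify
myocardial perfusion reserve from first-pass perfusion cardiac MR, together
with a ground-truth digital phantom for validating the whole chain.

## The problem and who it is for

First-pass perfusion MR acquires one short-axis frame per heartbeat while a
gadolinium bolus transits the heart. The maximum up-slope of a myocardial
time–intensity curve, normalized to the left-ventricular (LV) blood-pool
up-slope, is a standard flow surrogate. The **myocardial perfusion reserve
index** compares hyperemic (vasodilator stress) and baseline acquisitions:

- `MPRi-rest = S_stress / S_rest` — baseline imaged *before* the vasodilator,
- `MPRi-recov = S_stress / S_recov` — baseline imaged at *post-stress
  recovery*,

where `S` is the segment-averaged, cavity-normalized maximum up-slope
(`S = 100 · mean_k(slope_k) / slope_blood` over myocardial sectors `k`).
With long-acting vasodilators (e.g. regadenoson), hyperemia persists into
recovery, so `MPRi-recov` systematically underestimates the reserve; in some
subjects recovery flow even exceeds stress flow ("delayed maximal
hyperemia"), forcing `MPRi-recov < 1`. The package is aimed at imaging
researchers who need this analysis reproducible, testable, and separable
from any commercial workstation: curve extraction from image series + masks,
baseline/foot detection, sliding-window slope search, normalization, reserve
indices, delayed-hyperemia classification, cohort tables, and the
accompanying statistics (Welch and paired t-tests, Fisher's exact test,
two-group sample-size calculation).

Because raw clinical first-pass images are rarely shared, the package ships
a tracer-kinetic phantom — gamma-variate arterial input, one-compartment
(Kety-type) myocardium, annular short-axis geometry, per-pixel Gaussian
noise, per-state gain/dose effects, known per-state flows — so every claim
about the pipeline can be phrased as parameter recovery against ground
truth. See the methods vignette
(`vignettes/perfusion-reserve-methods.Rmd`) for the model, defaults, and
design rationale.

## Worked example

```r
library(mpri)

cfg <- phantom_config(noise_sd = 2, seed = 5)   # true stress/rest flow ratio = 2.0
sub <- simulate_subject(cfg)                    # renders rest/stress/recovery series
res <- analyze_subject(lapply(sub$states, `[[`, "curves"), id = "demo")
print(res)
#> <subject demo> group=NA up-slopes r/s/rec = 8.45/15.95/14.08  MPRi-rest=1.888 MPRi-recov=1.133 (40.0% lower) delayed=FALSE
```

Reading the output: the mean normalized up-slopes are 8.45 at rest, 15.95 at
stress and 14.08 at recovery (×100 scale). The recovered `MPRi-rest` (1.89)
is within 10% of the phantom's true flow ratio 2.0; `MPRi-recov` (1.13) is
40% lower because the phantom's recovery flow is still 1.68× rest —
the stress-recovery protocol's underestimate, reproduced from known truth.

The statistics are callable directly, e.g. the two-group sample size needed
to detect a 25% difference in reserve from a reference mean 1.78 (SD 0.60)
at 80% power and two-sided α = 0.05:

```r
sample_size_two_group(mean = 1.78, sd = 0.60, rel_diff = 0.25)
#> $n_per_group 29; $n_total 58
```

A file-based pipeline (`run_simulate`, `run_analyze`, `run_cohort`) reads and
writes NIfTI/CSV/YAML/JSON, and a thin subcommand CLI wraps it:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "mpri", package = "mpri"))')
Rscript $CLI simulate --out phantom_demo --seed 5
Rscript $CLI analyze  --in phantom_demo --id demo
Rscript $CLI stats samplesize 1.78 0.6 0.25
```

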