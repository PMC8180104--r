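# ratgait3d

Quantitative 3D gait and tactile-allodynia phenotyping for the
spinal-nerve-ligation (SNL) rat, the standard rodent model of neuropathic
pain. The SNL rat shows no gross motor deficit, so conventional scoring
misses its locomotor phenotype; what changes instead are fine-grained,
clinically relevant gait features — vertical joint instability, step
asymmetry, prolonged double support and disturbed left–right coordination.
`ratgait3d` turns already-reconstructed 3D joint-marker trajectories
(iliac, hip, knee, ankle, 5th metatarsophalangeal joint, both hind-limbs)
from treadmill walking at 12 m/min into those parameters, and pairs them
with a von Frey withdrawal-threshold summary.

## What it computes

For each animal, over a 10-stride analysis window:

- **Joint fluctuation** — per gait cycle, the top-minus-bottom height
  `max z − min z` of a joint marker (cm), averaged over cycles. Vertical
  instability of the operated hip/knee is the headline kinematic sign.
- **Heel step and stride length** — in the treadmill *belt frame*
  (`x_belt = x + v_belt · t`), stride = distance between consecutive
  same-limb contacts, step = distance from the preceding contralateral
  contact. The toe (mtp5) marker is the contact reference (no heel marker
  exists in this marker set).
- **Both-foot contact time** — cumulative overlap of left and right stance
  phases over the window (double support).
- **Circular times and R** — per-side swing duration (lift-off → next
  same-limb touchdown) and their ratio `R = w_R / w_L`; `R = 1` is
  symmetric coordination.
- **Ankle swing-slope ratio** — least-squares slopes of ankle height over
  the first 2/3 and last 1/3 of normalized swing phase; their ratio
  separates the SNL "late rapid rise" pattern (ratio > 2) from sham.
- **Allodynia** — von Frey ramp (1→50 g over 20 s, 3 trials/paw), percent
  decrease `100·(right − left)/right` of the withdrawal threshold time,
  weekly cohort means, overall mean with 95% CI, weekly paired t-tests.

Gait events (touchdown/lift-off) are detected from toe height against the
belt plane (threshold 0.15 cm with hysteresis and debouncing), or imported
from manually entered tables, which always take precedence. Group
comparisons use Mann–Whitney (SNL vs sham) and paired t (left vs right),
two-sided, α = 0.05.

Because the original animal recordings were never deposited, the package
ships a calibrated synthetic cohort generator (`gait_preset()`,
`simulate_cohort()`, `simulate_vonfrey_cohort()`) whose group means are the
published values (sham hip 1.0 cm vs SNL 1.47/1.30; knee 1.20/1.28 vs
1.80/1.88; both-foot contact 1.03 vs 1.9–2.0 s; R 1.0 vs 0.66/0.62; steps
8.1/4.7 cm on a 12.8 cm stride; 47% threshold decrease) and whose
between-animal SDs are the published SEs × √10. Every pipeline stage is
tested by parameter recovery against this generator's ground truth.

## Worked example

```r
library(ratgait3d)
sham <- simulate_cohort(gait_preset("sham",    n_animals = 10, seed = 101))
snl  <- simulate_cohort(gait_preset("snl_wk4", n_animals = 10, seed = 102))
gait_sham <- analyze_cohort(sham)   # detect events, segment 10 strides, all metrics
gait_snl  <- analyze_cohort(snl)
cmp <- compare_groups(gait_snl, gait_sham,
                      metrics = c("hip_left", "knee_left", "both_foot_contact", "r_raw"))
cmp[, c("metric", "mean_a", "se_a", "mean_b", "se_b", "p", "significant")]
#>              metric mean_a   se_a mean_b   se_b      p significant
#> 1          hip_left  1.431 0.1836  0.846 0.1372 0.0232        TRUE
#> 2         knee_left  1.993 0.3310  1.608 0.2089 0.4359       FALSE
#> 3 both_foot_contact  1.661 0.0878  1.212 0.1071 0.0052        TRUE
#> 4             r_raw  0.768 0.0754  0.980 0.0737 0.0524       FALSE

vf <- simulate_vonfrey_cohort(n_animals = 10, weeks = 1:8, seed = 103)
threshold_summary(vf)
#> <allodynia_summary> overall decrease 46.4% (95% CI 41.1-51.8), 8 weeks
```

Column `mean_a` is the SNL group, `mean_b` sham. In this draw the operated
hip fluctuation (1.43 vs 0.85 cm) and the cumulative both-foot contact time
(1.66 vs 1.21 s) separate the groups at α = 0.05; the knee and R
comparisons, with 10 animals and large between-animal SDs, do not reach
significance in every draw — which is the honest behaviour of this design.
The simulated allodynia cohort recovers the generative 47% decrease with a
CI of about the published width.

## Command line

```sh
Rscript inst/cli/ratgait3d.R simulate --preset snl_wk1 --n 10 --seed 1 --out sim/
Rscript inst/cli/ratgait3d.R detect   --in sim/snl_wk1_01_traj.csv --out ev.csv
Rscript inst/cli/ratgait3d.R gait     --in sim/snl_wk1_01_traj.csv --out summary.csv
Rscript inst/cli/ratgait3d.R run      --in sim/ --out report/
```

Trajectory files are long-form CSV (`t,marker,side,x,y,z` with
`#sample_rate_hz=` / `#belt_speed_cm_s=` metadata lines); event files are
`side,event,t`; von Frey files are
`animal_id,week,side,trial,threshold_time_s`.

## Vignette

`vignettes/gait-analysis-methods.Rmd` documents the model, the calibration
of the synthetic cohorts, numerical choices (event-detection thresholds,
per-cycle range normalization, windowing) and the known limitations of what
a green recovery test does and does not establish.
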