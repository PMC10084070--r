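# cartipart

Depth-resolved ioxaglate partition analysis for dual contrast-enhanced
micro-CT arthrography of articular cartilage.

## The problem

Post-traumatic cartilage degeneration begins with proteoglycan (PG) loss.
Because ioxaglate is anionic, its equilibrium uptake into cartilage is
inversely related to the PG-borne fixed charge density, so the **ioxaglate
partition** — the agent's concentration in cartilage relative to its
concentration in the joint-cavity bath, in percent — rises where the matrix
is degraded. Pairing ioxaglate with neutral bismuth nanoparticles (BiNPs),
which cannot enter cartilage, keeps the articulating surface visible at the
delayed time point in a single scan. `cartipart` is for researchers in
quantitative cartilage imaging who want this whole analysis — from
Hounsfield-unit volumes to partition profiles, location means, matched
Safranin-O optical densities, and nonparametric group comparisons — as
reproducible, tested code.

The core quantity, per depth position of a volume of interest (VOI), is

```
partition(z) = 100 · (A(z) − A_native) / A_iox      [%]
A_native = HU(1.05 µ_water) = water + 50 HU
A_iox    = A_cavity(t = 60 min) − A_BiNP-phantom
```

with profiles resampled onto a normalized depth axis (0 = articulating
surface, 1 = cartilage–bone interface) and averaged over the VOI.

Because the ex vivo scans behind the method are not public, the package
includes a first-class synthetic joint generator: curved cartilage on bone,
blunt/sharp 400 µm grooves with peri-lesion PG depletion, a 1667 HU dual
contrast bath, CT noise, partial-volume effects, air-bubble artifacts, and
matched synthetic histology sections with a neutral-density calibration
strip — all seeded and with exact ground truth.

## Worked example

The closed-form check from the reference attenuations (lesion
cartilage 1054 HU, joint cavity 1667 HU, water-based native baseline):

```r
library(cartipart)

cal <- phantom_calibration(water_hu = 0, binp_hu = 0, dual_bath_hu = 1667)
prof <- attenuation_to_partition(mean_profile(matrix(1054, 100, 1)), cal)
round(full_thickness_mean(prof))
#> [1] 60
```

— a 60 % full-thickness lesion partition. A full joint pair, from synthesis
through segmentation to partition:

```r
pair <- build_joint_pair(cartipart_scenario("blunt"), seed = 1)
res  <- analyze_joint_pair(pair)
res$results[, 1:5]
#> # A tibble: 3 × 5
#>   joint_id groove_kind role          mean_partition_pct n_columns
#>   <chr>    <chr>       <chr>                      <dbl>     <int>
#> 1 joint_1  blunt       lesion                      69.7         6
#> 2 joint_1  blunt       away_3mm                    50.2        12
#> 3 joint_1  blunt       contralateral               36.1        12
```

The lesion VOI (6 columns over the groove) shows strongly elevated uptake
relative to the ungrooved locations. A full two-arm cohort reproduces the
study-level table and statistics:

```r
library(dplyr)
voi <- bind_rows(
  simulate_cohort(cartipart_scenario("blunt"), 1:9),
  simulate_cohort(cartipart_scenario("sharp"), 10:17)
)
summarize_cohort(voi)
#> # A tibble: 6 × 5
#>   groove_kind role              n partition_mean partition_sd
#> 1 blunt       lesion            9           67.1         8.33
#> 2 blunt       away_3mm          9           45.6         5.18
#> 3 blunt       contralateral     9           41.2         4.82
#> 4 sharp       lesion            8           53.6         3.45
#> 5 sharp       away_3mm          8           42.6         2.56
#> 6 sharp       contralateral     8           40.5         6.03

cmp <- compare_locations(voi, mean_partition_pct)
glance(cmp)   # Kruskal–Wallis: H = 33.0, p = 6.9e-8
tidy(cmp)     # Bonferroni-adjusted pairwise tests, e.g.
#>   group_a  group_b        diff   p_adj
#> 1 lesion   away_3mm       16.5  1.2e-7
#> 2 lesion   contralateral  19.9  1.0e-8
#> 3 away_3mm contralateral   3.4  0.20
```

Lesion partition sits ~20 percentage points above the contralateral
control, and ~16 above tissue 3 mm away — the degeneration signal the
method exists to measure. `autoplot()` on any profile, and
`plot_voi_summary(voi)`, give the corresponding figures.
`run_pipeline(list(blunt_seeds = 1:9, sharp_seeds = 10:17, bubble_seed = 18))`
adds matched optical-density sections, air-bubble QC (the bubble joint is
reported and excluded), and writes CSV/JSON artifacts.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/cartipart.R simulate --scenario blunt --seed 1 --out out/
Rscript inst/cli/cartipart.R run --out out/
```

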