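---
title: "Dual-contrast CT cartilage partition profiling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-contrast CT cartilage partition profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartipart)
```

## The measurement problem

Contrast-enhanced CT arthrography quantifies the condition of articular
cartilage from how much of an anionic, iodinated contrast agent (ioxaglate)
diffuses into the tissue. Cartilage carries a high fixed charge density from
its proteoglycans (PGs); the negative agent is partially excluded, so its
equilibrium **partition** — concentration in cartilage relative to the
concentration in the joint-cavity bath, in percent — rises where PGs are
depleted, an early marker of post-traumatic degeneration. A second,
neutral agent (bismuth nanoparticles, BiNPs, ~0.2 µm) is too large to enter
cartilage and stays in the cavity, keeping the articulating surface sharply
delineated at the delayed imaging time point when ioxaglate has equilibrated.

On the Hounsfield scale the partition of a cartilage voxel with attenuation
$A$ is

$$
P \;=\; 100 \cdot \frac{A - A_\text{native}}{A_\text{iox}} ,
$$

where $A_\text{native}$ is the attenuation of native (non-enhanced)
cartilage, taken as $1.05\,\mu_w$, i.e. water + 50 HU, and
$A_\text{iox}$ is the attenuation of plain ioxaglate in the cavity: the
dual-bath (cavity) attenuation at $t = 60$ min minus the attenuation of the
BiNP suspension measured in a separate phantom. With the reference
values — cavity 1667 HU, lesion cartilage 1054 HU, ungrooved cartilage
747 HU — this formula gives the worked-example partitions of 60 % and 42 %
that `attenuation_to_partition()` reproduces.

The pipeline mirrors the study protocol: coronal slab averaging of six
consecutive 80 µm slices (0.48 mm), articulating-surface and cartilage–bone
interface detection, groove (surgical lesion) localisation, placement of
three volumes of interest (lesion 0.48 × 0.48 mm including the groove;
enlarged 1.04 × 0.48 mm VOIs 3 mm away and at the mirrored location in the
contralateral control joint), per-column depth normalization, and
conversion to partition. Group differences across the three locations use a
Kruskal–Wallis omnibus test with Bonferroni-corrected pairwise rank-sum
tests.

## The synthetic joint phantom

No scan data accompany the study, so the package ships a seeded generator
(`build_joint_phantom()`, `build_joint_pair()`) that renders the study
conditions with known ground truth:

* a cylindrically curved articular surface (radius 20 mm, axis
  lateromedial) about 1.1 mm below the volume top, on a
  30 × 96 × 24 voxel grid at 80 µm (2.4 × 7.68 × 1.92 mm);
* a cartilage layer of per-joint thickness drawn from 0.501 ± 0.101 mm,
  truncated to [0.45, 0.65] mm (below 0.45 mm a 400 µm groove leaves less
  than two voxels of analysable tissue under its floor — see *Degenerate
  inputs*);
* a blunt (500 µm wide) or sharp (150 µm) groove, 400 µm deep, running
  lateromedially, rasterised to the nearest voxel (6 / 2 columns wide,
  floor 5 voxels below the local surface);
* joint cavity and groove void filled with dual contrast agent at 1667 HU
  at $t = 60$; subchondral bone at 2500 HU; native cartilage at +50 HU at
  $t = 0$;
* additive Gaussian noise (SD 40 HU) and partial-volume emulation by
  rendering at 2× resolution and box-downsampling;
* optionally, an air bubble (air, −1000 HU) carved into the cavity.

The BiNP suspension offset defaults to 0 HU above water: the reference
attenuation triplet (1054, 747, 1667 HU) reproduces the reference partitions
(60 %, 42 %) only if the BiNP contribution to the cavity is ≈ 0, so that is
the calibrated default; the parameter stays configurable.

### Uptake model and calibration

Partition and PG density are coupled by the linear law
$P = P_\text{max} - k \cdot \mathrm{pg}$ (defaults $P_\text{max} = k =
150$), so the rendered partition and PG fields correlate at exactly −1.
Depth structure is a linear profile from 1.1× the column mean at the
articulating surface to 0.9× at the bone interface, a mild superficial
elevation consistent with depth-resolved partition profiles in layered
cartilage. Laterally, grooved joints carry a peri-lesion bump that decays
exponentially from the groove wall (length 0.5 mm — the gradient is shown
but not parameterised in the source material) on top of the far-field
(3 mm) level; the bump amplitude is scaled numerically so that the mean
over the lesion-VOI footprint equals the configured lesion truth. Control
joints are laterally homogeneous at the contralateral truth. Because each
column's full-thickness mean equals its local target by construction, the
generator's `voi_truth` table is an exact oracle for the pipeline.

Grooved joints additionally swell by +40 % thickness at the groove
(decaying with the same lateral length). This emulates the water-influx
swelling of degenerated cartilage and is also what makes the geometry
analysable: 400 µm grooves in ~0.5 mm cartilage would otherwise leave
barely one voxel of tissue under the floor.

### Cohort structure

Between-joint biological variation is injected at the level of the three
location means (and thickness) through a golden-ratio low-discrepancy
normal stream indexed by the seed. Consecutive seeds therefore realise the
configured cohort means with minimal sampling drift, which is what
"calibrated to the reference cohort table" should mean for sample statistics.
The injected between-joint SD is half the reference SD; the remainder of the
observed variance is attributed to scanner effects — notably beam
hardening, which the source material itself names as adding partition
variation regardless of tissue state and which the generator deliberately
omits (no polychromatic physics). The full reference SDs remain in the
scenario files and are used verbatim by the stats-module power and
separation simulations. The quantile stream is clamped to [0.02, 0.98] so
single joints stay within ~2 SD and remain physically renderable
(partition never approaches the bath).

### What the generator does not emulate

No beam hardening or scatter, no time-resolved diffusion between 0 and
60 min, no anatomical variation beyond a cylindrical condyle, no
histology wet-lab artefacts beyond grey-level noise and an optional
section tilt. Passing tests therefore demonstrate that the *analysis
chain* is correct and unbiased under the stated imaging model — not that
it is robust to every artefact of real arthrography data.

## Segmentation choices

* **Surface**: per depth column, first crossing below the midpoint
  threshold $(A_\text{bath} + A_\text{cart})/2$ after light smoothing
  (window 3), with two consecutive sub-threshold samples required and the
  crossing refined against the raw profile (smoothing otherwise drags the
  crossing one voxel into the cavity). The expected superficial cartilage
  attenuation defaults to $A_\text{native} + 0.85\,A_\text{iox}$, an upper
  bound for near-equilibrated surface tissue that keeps ~5 noise SDs of
  margin to the bath after slab averaging.
* **Interface**: the null point of the first derivative — the local
  minimum preceding the rise into bone — searched below the surface, ties
  broken by the greatest subsequent rise. The derivative is taken on the
  raw profile: slab averaging has already cut the noise by √6, and any
  depth smoothing displaces the minimum on groove-floor columns whose
  remnant is only 2–3 samples. The returned index is one past the minimum,
  so the half-open span excludes the bone-contaminated boundary voxel.
* **Partial-volume guard**: leading profile samples more than 150 HU
  (~9 post-averaging noise SDs) above their successor are cavity-mixture
  boundary voxels and are trimmed before resampling.
* **Groove**: per lateromedial slab, surface depression against a
  running-median reference; the centre is the rounded centroid of columns
  within one voxel of the peak depression (surface maps are quantized, so
  a fractional band would collapse to a single column). A median
  depression of ≥ 2 voxels is required — grooves are ~5 voxels deep, and
  a 1-voxel cut would false-alarm on noise-jittered control surfaces.
* **Bubble QC**: 6-connected components of cavity voxels below −300 HU;
  a joint is excluded for components over 5 mm³ or touching a VOI
  footprint. Exclusion happens before analysis, mirroring the study's
  handling of its bubble-afflicted joint, and is reported, never silent.

Manual segmentation in the original workflow is replaced by these
detectors; externally drawn maps can be injected wherever a `surface_maps`
object is accepted.

## Numerical choices

* Depth profiles are resampled to **N = 100** equally spaced positions on
  [0, 1] by linear interpolation (endpoint-preserving); the source
  material states only "the same length".
* The full-thickness mean is the **unweighted mean** over the resampled
  positions (equal depth weighting, matching the normalized-profile
  representation), not a voxel-count-weighted mean.
* Partition values are reported unclipped; values outside [0, 100] % are
  flagged with a message.
* The bath is re-measured per joint over the detected cavity at least
  0.3 mm above the surface (and the ground-truth cavity ROI used in
  calibration tests is eroded by the same margin): boundary voxels are
  partial-volume mixtures and would bias the bath ~15 HU low.
* Coordinates are 1-based voxel indices with half-open extents; the depth
  axis runs cavity → bone.
* Slab averaging runs along the lateromedial (along-groove) axis so the
  averaged slabs are coronal; the averaging plane is not named in the
  source material.

## Densitometry

Safranin-O digital densitometry is simulated as transmitted-light imaging:
grey level = full scale × $10^{-\mathrm{OD}}$, OD proportional to local PG
and scaled to the configured section mean, with a 10-step neutral-density
strip at the filter ODs 0.0–3.0 embedded in every section. Calibration
interpolates OD against log grey level — piecewise-linear in
log-transmittance — which reproduces the filter nodes exactly by
construction and is clamped to [0, 3]; a parametric Beer–Lambert fit would
add assumptions without improving the node fit. OD columns then reuse the
CT depth-normalization machinery, and CT/OD results are matched by
`(joint, location)`, i.e. by distance from the groove. Sections are
rendered co-planar with the CT slabs by default; a `tilt_deg` parameter
emulates the imperfect parallelism conceded for the real sections.

## Statistics

`stats::kruskal.test` and `stats::wilcox.test` supply the test engines.
The package adds a full-enumeration exact permutation p-value for the
omnibus test at total n ≤ 12, Bonferroni adjustment with m = 3 (the three
location pairs), and a Monte-Carlo retrospective power estimate for the
Bonferroni-adjusted pairwise test under normal sampling. Pairwise
comparisons are independent (not paired): contralateral joints are distinct
limbs and the two arms have unequal sizes after QC exclusion (9 and 8).
Combined-arm analyses pool the joints of both groove types. Reference
retrospective-power figures for this design do not name their test family,
so `retrospective_power()` reports its Monte-Carlo estimate for the stated
test without asserting agreement with any external range.

## Problem sizes

Default analyses use 30 × 96 × 24 voxel volumes (≈ 6 mm³-scale tissue
regions at 80 µm), cohorts of 9 + 8 joint pairs, 100-point profiles,
2000-replicate null calibrations and 400-replicate separation
simulations — sizes chosen so a full cohort reproduction, including
matched histology, completes in seconds on one CPU while keeping every
Monte-Carlo standard error well under the tolerance it supports.

## Known limitations

* The groove cross-section is rectangular for both groove types; blade and
  probe grooves differ only in width here, whereas real sharp grooves are
  V-shaped.
* Swelling magnitude (+40 %) and the peri-lesion decay length (0.5 mm) are
  plausibility choices; only their existence, not their size, is supported
  by the source imagery.
* The contralateral VOI is placed by mirroring the groove centre across
  the dorsopalmar midline; how locations were transferred between joints
  in the original workflow is not described.
* Cross-scan HU drift is out of scope: phantoms and joints are assumed on
  a common scale, as in the original acquisitions.
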