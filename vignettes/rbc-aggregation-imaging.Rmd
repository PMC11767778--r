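---
title: "Quantifying red blood cell aggregation from microfluidic flow images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying red blood cell aggregation from microfluidic flow images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbcflow)
```

## The measurement problem

At low shear, red blood cells (RBCs) reversibly stack into rouleaux —
coin-stack chains that may branch and, with strong aggregation stimuli,
collapse into compact three-dimensional clusters and cluster networks.
The degree and *morphology* of aggregation carries rheological and clinical
information: a suspension whose aggregate mass sits in a few large networks
behaves very differently from one with many small linear rouleaux, even at
the same total aggregated area.

`rbcflow` quantifies this from phase-contrast snapshots of RBC suspensions
in microfluidic channels. Each field is segmented into aggregates, each
aggregate is classified by projected area into one of six populations, and
two families of indices are reported per population:

* the **Aggregation-Area Indicator**, \(AAI_i = S_i / S_V\), where
  \(S_i\) is the summed pixel area of population-\(i\) aggregates and
  \(S_V\) the pixel area of the visual field (dimensionless, in \([0,1]\));
* the **aggregate count** \(NA_i\), the number of population-\(i\)
  aggregates in the field.

The populations are fixed intervals of projected area in µm²:

| population | area (µm²) | morphology | overlay color |
|---|---|---|---|
| P0 | [50, 100) | unaggregated single cells | white |
| P1 | [100, 331) | small linear rouleaux | green |
| P2 | [331, 661) | branched rouleaux | blue |
| P3 | [661, 1321) | small 3-D clusters | cyan |
| P4 | [1321, 2701) | large 3-D clusters | magenta |
| P5 | [2701, ∞) | aggregate networks | yellow |

Bins are half-open and jointly partition \([50, \infty)\): every detected
particle belongs to exactly one population, and the per-population pixel
areas always sum to the total detected foreground. The published
descriptions of these bands use slightly inconsistent boundaries
(330/331, 660/661/666, 2700/2701); we adopt the integer-consistent
half-open convention above, which preserves the partition property, and the
boundaries are configurable via `population_binning()`. The 1 µm² gap
between a "<99 µm²" description of P0 and a P1 starting at 100 µm² is below
measurement resolution and is closed by extending P0 to [50, 100).

Particles below **50 µm²** are not detected at all — the particle analysis
runs on the area interval [50 µm², ∞). A resting biconcave RBC projects
roughly \(\pi (3.9)^2 \approx 48\) µm², so isolated resting cells sit just
below the gate; the P0 population captures single cells whose projected
image (halo, tilt, swelling) reaches 50 µm², and doublets.

## The pipeline and its assumptions

`analyze_image()` chains the stages; each is exported separately.

1. **Thresholding** (`binarize`). One global threshold separates
   aggregates from background, as in ImageJ's make-binary step. `otsu`
   (default) and `isodata` (the iterative-intermeans scheme behind
   ImageJ's default) are offered, plus `fixed`. Aggregates may be darker
   or brighter than background depending on phase-contrast focus;
   `polarity = "auto"` takes the minority pixel class as foreground, which
   is correct whenever aggregates cover less than half the field — true of
   all channel images this design targets. A constant (contrast-free)
   image yields an empty mask with a warning, not an error, so batch runs
   survive blank frames.

2. **Boundary refinement** (`refine`). Interior holes are filled and one
   binary opening with a 3×3 box removes single-pixel salt noise; a final
   hole fill keeps the operation idempotent. This is the minimal
   morphology that makes each aggregate a single solid region: it never
   splits the overlapping-disc geometry of rouleaux, and its only area
   cost is single-pixel protrusions on rasterized boundaries — which is
   why downstream accuracy statements are phrased as "within one
   boundary-pixel ring per object".

3. **Particle analysis** (`label_components`, `measure_particles`).
   Connected components at 8-connectivity (ImageJ's particle-analysis
   convention; 4-connectivity available), labeled in raster-scan order.
   Areas are exact pixel counts, converted by
   \(\mathrm{area}_{\mu m^2} = \mathrm{area}_{px} \cdot s^2\) with \(s\)
   the µm-per-pixel calibration. The calibration must be supplied by the
   user: it is instrument metadata, and inferring it from scale bars would
   be fragile. Touching aggregates are deliberately *not* split by
   watershed: an aggregate that touches another is, physically, one
   aggregate under this protocol.

4. **Gate, classify, index** (`classify_records`,
   `compute_field_result`). The ≥50 µm² gate is inclusive. Classification
   happens on µm² (so results are resolution-invariant); AAI is computed
   on pixel counts (the ratio is unit-free). \(S_V\) is the full frame
   area — channel-wall masking is left to cropping at acquisition.

5. **Group statistics** (`summarize_group`, `compare_groups`,
   `shapiro_wilk`, `rank_sum_test`). Summaries are mean and sample SD
   (n−1). Comparison uses the two-sided Wilcoxon rank-sum test for
   independent groups — the "Wilcoxon test between independent groups" of
   hemorheology practice — with significance at \(p \le \alpha\),
   \(\alpha = 0.05\) by default, and no multiple-testing correction (the
   reference workflow applies none). The exact null distribution of the
   rank sum is computed by a subset-sum recursion over doubled midranks,
   so tied data are handled exactly; `mode = "auto"` uses it for
   \(n_a + n_b \le 20\) without ties and otherwise a normal approximation
   with tie-variance and continuity corrections. Summaries are per image;
   when several fields per subject are acquired, average within subject
   before comparing if subject-level inference is wanted — the package
   does not silently pool.

## Physical conversions

The flow protocol is specified in wall shear stress (dyn/cm²); the
rheological literature reports shear rates (s⁻¹). For a Newtonian
suspension these are related by the viscosity:
\(\dot\gamma = \tau/\mu\). With the dilute-suspension viscosity
µ = 1.12 mPa·s, the working points 5 and 0.1 dyn/cm² map to 446 s⁻¹ and
8.9 s⁻¹ (`shear_rate_from_stress`; `format_shear_rate` applies the
reporting convention of integers above 100 s⁻¹ and one decimal below).
`final_hematocrit` implements the volume-balance dilution: 10 µL of a 40 %
suspension into 200 µL of aggregant gives 1.9 %, i.e. 2 % to the nearest
percent — the dilute regime in which individual aggregates are optically
separable.

## The synthetic benchmark: what it emulates, and what not

Real channel images of this protocol have no deposited ground truth, so
validation rests on `generate_field()`: seeded synthetic fields whose
per-object pixel sets are known exactly.

* **Single cells** are filled discs of diameter 7.8 µm (typical RBC).
* **Rouleaux** are chains of discs overlapping by half a diameter —
  `render_rouleau(n, theta)`; the union area grows affinely with `n`, so
  chain length selects the population (a doublet lands in P0 at
  ~77 µm², a 5-chain in P1, a 12-chain in P2, ...).
* **Clusters** are dilated random walks of discs, hole-filled —
  `render_cluster(area)`; the realized area is within 10 % of target.

Geometry, placement and the cluster growth process all live in continuous
µm coordinates (growth is metered on a fixed 0.25 µm/px internal reference
raster), so the same seed produces the *same physical scene* at any output
resolution — the property behind the resolution-invariance guarantee that
population assignments are identical and AAI agrees within 2 % between
0.5 and 0.25 µm/px renderings. Objects are placed with ≥2 µm clearance
(≥2 px at the default calibration) so the ground-truth object count and
8-connected labeling can never disagree. Defaults: 300×1600 px fields at
0.5 µm/px (the nominal frame geometry; the pixel size is a user-supplied
calibration in real use), dark cells (intensity 70) on bright background
(190), 8-bit, Gaussian noise of selectable SD.

What the generator does **not** emulate: phase-contrast halos and texture,
uneven illumination (a linear shading stressor can be added by the user on
the returned image), touching objects, out-of-focus blur, and the shear
physics of aggregation itself. Passing the synthetic suite therefore
demonstrates that the *measurement chain* — threshold, refine, label,
gate, classify, index — is exact on known geometry and robust to additive
noise; it does not validate thresholding against real phase-contrast
artifacts, which is why the threshold method and polarity remain exposed,
recorded parameters rather than hard-coded choices.

## Numerical choices and edge cases

* Noise-free recovery is exact in counts and within one boundary-pixel
  ring per object in area; the synthetic content used in the validation
  suite keeps every object's area at least 10 % away from a bin edge so
  this ring cannot flip a population.
* At SNR 5 (the contract's floor), isolated salt/pepper noise is removed
  by the opening and interior speckle by hole-filling; recovered \(NA\)
  vectors match truth in ≥ 95 % of replicates.
* Problem sizes in the validation suite: 50 noise-free 300×1600 fields
  for end-to-end equivalence; 1000 random 32×32 masks at both
  connectivities against an independent label-propagation oracle; 10⁴
  random areas for partition/conservation; exhaustive rank-assignment
  enumeration for all group sizes ≤ 6 and 1000 null replicates at
  n = 10 + 10 for the type-I calibration ([0.03, 0.07] at α = 0.05).
* Degenerate inputs: constant images warn and return empty masks;
  single-field groups report SD 0 with a warning; `rank_sum_test` on
  identical multisets returns p = 1 exactly; empty record lists produce
  all-zero indices rather than errors.
* The exact rank-sum statistic reported is the rank sum of the smaller
  group (ties toward the first), a convention chosen so the statistic is
  comparable across unequal group sizes.

## Worked example

```{r example}
spec <- synthetic_spec(
  field_shape = c(300L, 1600L), um_per_px = 0.5, n_singles = 3L,
  rouleaux = list(c(2, 0.3), c(5, 1.0), c(12, 0.7), c(16, 1.9)),
  clusters = c(900, 3500), seed = 7)
gf <- generate_field(spec)
res <- analyze_image(gf$image, method = "fixed", fixed_threshold = 130,
                     polarity = "dark_foreground")
res$result[, c("AAI_1", "AAI_2", "AAI_5", "NA_1", "NA_2", "NA_5", "n_p0")]
gf$truth$totals
```

The recovered counts equal the generator's truth; the color overlay
(`colorize(res$labeled, res$records)`) reproduces the per-population areas
as a color histogram.

## Known limitations

Touching aggregates are one aggregate by design; densely aggregated fields
(foreground above ~50 %) would defeat the auto-polarity heuristic and
should set `polarity` explicitly; the global threshold assumes roughly
uniform illumination; and the six-bin partition, while configurable, is
calibrated to 2 % hematocrit suspensions in Dextran 70 — other aggregation
protocols may need different bin edges.
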