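# rbcflow

Image flow analysis of red blood cell (RBC) aggregation in microfluidic
channels.

At low shear, RBCs stack into rouleaux — linear and branched "coin-stack"
chains — and, under strong aggregation stimuli or in disease, collapse into
compact 3-D clusters and cluster networks. `rbcflow` is for hemorheology
labs that image diluted RBC suspensions (typically ~2 % hematocrit in
Dextran 70) in microfluidic flow channels by phase-contrast microscopy and
need the aggregation state quantified per field, stratified by aggregate
size, and compared across study groups.

## What it computes

Each grayscale field is thresholded, boundary-refined, and run through
connected-component particle analysis on the area interval [50 µm², ∞).
Every detected particle is assigned by projected area *A* (µm²) to one of
six populations:

    P0 [50, 100)      single cells          (white)
    P1 [100, 331)     linear rouleaux       (green)
    P2 [331, 661)     branched rouleaux     (blue)
    P3 [661, 1321)    small 3-D clusters    (cyan)
    P4 [1321, 2701)   large 3-D clusters    (magenta)
    P5 [2701, ∞)      aggregate networks    (yellow)

and two indices are reported per population *i* = 1..5 (plus the P0
analogues):

* **AAI_i = S_i / S_V** — the Aggregation-Area Indicator: summed pixel
  area of population-*i* aggregates over the pixel area of the visual
  field;
* **NA_i** — the number of population-*i* aggregates in the field.

Group tables are summarized as mean ± SD and compared with two-sided
Wilcoxon rank-sum tests (exact null distribution with midrank ties for
small samples) at p ≤ 0.05, after Shapiro–Wilk normality screening.
Closed-form hemorheology conversions are included: wall shear stress ↔
shear rate via suspension viscosity (5 dyn/cm² at 1.12 mPa·s ↔ 446 s⁻¹)
and dilution hematocrit.

A seeded synthetic-field generator (`generate_field`) renders single
cells, rouleaux chains and random-walk cluster blobs with exact per-object
ground truth, in continuous µm coordinates so the same seed yields the
same physical scene at any pixel size — this is the package's validation
backbone.

## Worked example

```r
library(rbcflow)

spec <- synthetic_spec(
  field_shape = c(300L, 1600L), um_per_px = 0.5, n_singles = 3L,
  rouleaux = list(c(2, 0.3), c(5, 1.0), c(12, 0.7), c(16, 1.9)),
  clusters = c(900, 3500), seed = 7)
gf  <- generate_field(spec)
res <- analyze_image(gf$image, method = "fixed", fixed_threshold = 130,
                     polarity = "dark_foreground")

res$result[, c("AAI_1", "AAI_2", "AAI_3", "AAI_5",
               "NA_1", "NA_2", "NA_5", "n_p0")]
#>      AAI_1    AAI_2    AAI_3   AAI_5 NA_1 NA_2 NA_5 n_p0
#> 1 0.001371 0.007092 0.007602 0.02926    1    2    1    1

gf$truth$totals
#>   population n area_px area_um2
#> 1         P0 1     302    75.50
#> 2         P1 1     658   164.50
#> 3         P2 2    3409   852.25
#> 4         P3 1    3654   913.50
#> 5         P4 0       0     0.00
#> 6         P5 1   14057  3514.25
```

Reading: the 300×1600 px field (S_V = 480,000 px) holds one P5 network of
~3514 µm², so AAI_5 ≈ 14057/480000 ≈ 0.029; the doublet (two overlapping
7.8 µm cells, ~77 µm²) lands in P0; the three isolated single cells
(~48 µm² each) sit below the 50 µm² detection gate and are not counted.
Every recovered count `NA_i` matches the generator's ground truth; areas
agree within a one-pixel boundary ring per object (the morphological
refinement may shave single-pixel protrusions).

```r
format_shear_rate(shear_rate_from_stress(c(5, 0.1), 1.12))
#> [1] 446.0   8.9
round(final_hematocrit(10, 0.40, 200) * 100, 1)
#> [1] 1.9
```

`colorize(res$labeled, res$records)` renders the Fig.-style overlay
(P1 green … P5 yellow, P0 white on black); `run_pipeline()` batches whole
directories and writes `results.csv`, per-field particle tables and
overlay PNGs; `compare_groups()` produces the per-index test reports.

A command-line front end is installed at `inst/cli/rbcflow`:

```sh
Rscript inst/cli/rbcflow simulate --seed 3 --shape 300x1600 \
    --rouleaux "2:0.4,5:1.1,12:2" --clusters 900 --out sim/
Rscript inst/cli/rbcflow analyze sim/field.tif --um-per-px 0.5 \
    --threshold otsu --group control --out results/
Rscript inst/cli/rbcflow rheology stress-to-rate --tau 5
#> 5 dyn/cm^2 at 1.12 mPa.s -> 446 1/s
```

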