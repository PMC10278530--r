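# tsrzone

Multiperspective quantification of the **tumor–stroma ratio (TSR)** in
zoned histology images, with the cohort statistics needed to evaluate it
as a prognostic marker.

## The problem

In oral squamous cell carcinoma (and many solid tumors), the proportion
of tumor cells relative to stroma carries prognostic information — but it
differs systematically between histological regions. `tsrzone`
quantifies the TSR separately in two 1-mm bands of a
pancytokeratin-style (brown tumor / blue stroma) stained section:

- the **inner tumor** — the band extending 1 mm inward from the origin
  of the epithelial tumor tissue, and
- the **invasive tumor front (ITF)** — the band extending 1 mm inward
  from the invasive edge (tumor side only).

For each band, the pipeline selects the three 1.15 × 0.68 mm
(0.78 mm²) image fields with the *lowest* tumor area fraction such that
tumor is present at all four field borders (overlap between fields
allowed), then computes

```
TSR = tumor cell area / image field area × 100%
```

per field, averages the three values, and dichotomizes at 50%:
`tumor_high` (TSR ≥ 50%) vs `tumor_low` (TSR < 50%). The joint
inner/ITF grouping yields the slide pattern (`high_high`, `high_low`,
`low_low`, plus the rarely seen `low_high`).

The package covers the whole workflow:

| stage | functions |
|---|---|
| synthetic ground truth | `generate_phantom()`, `simulate_cohort()`, `table1_fixtures()` |
| tumor/stroma segmentation | `rgb_to_optical_density()`, `deconvolve_hdab()`, `threshold_classify()`, `train_pixel_classifier()`, `refine_classifier()`, `predict_mask()` |
| zonation | `boundary_curve()`, `distance_to_curve()`, `extract_band()` |
| field selection | `enumerate_windows()`, `border_has_tumor()`, `select_fields()` |
| TSR | `field_tsr()`, `region_tsr()`, `slide_pattern()`, `run_pipeline()` |
| cohort statistics | `chi_square_test()`, `paired_t_test()`, `spearman_association()`, `km_logrank()`, `cox_fit()`, `logistic_pni()`, `proportion_summary()` |
| I/O + CLI | `read_calibrated_image()`, `read_curves()`, `write_mask()`, `run_cli()` |

Because no patient imaging data are distributable, the package ships a
**phantom generator** (pseudo-IHC slides with exact per-band
ground-truth tumor fractions) and a **proportional-hazards cohort
simulator** (exponential event times at specified hazard ratios, the
study population's covariate prevalences, independent censoring), so
every stage is testable against known truth.

## Worked example

```r
library(tsrzone)

# a 2.56 x 2.0 mm phantom at 4 um/px: dense inner tumor (0.9),
# stroma-rich invasive front (0.3)
ph <- generate_phantom(phantom_config(seed = 7))
ph$truth
#> <phantom_truth> inner fraction 0.900, front fraction 0.300

report <- run_pipeline(ph$image, list(ph$truth$epithelial_origin,
                                      ph$truth$invasive_edge))
report
#> <slide_report> pattern high_low | inner 68.03% (tumor_high) | ITF 29.73% (tumor_low)
report$fields$itf
#>   zone   x    y   w    h  fraction border_ok
#> 1  itf 200 1300 680 1150 0.2910981      TRUE
#> 2  itf 250 1300 680 1150 0.2952206      TRUE
#> 3  itf 150 1300 680 1150 0.3056373      TRUE
```

The slide is classified `high_low`: tumor-high in the inner band,
tumor-low at the front. The three ITF fields (here in portrait
orientation, coordinates in µm) sit in the stroma-richest part of the
band — their mean TSR (29.7%) tracks the band's true 30% fraction, and
the inner mean (68%) is *below* the 90% band fraction because the
selection deliberately seeks the stroma-richest fields.

Cohort-level statistics, on the published baseline tables and on a
simulated cohort:

```r
chi_square_test(table1_fixtures()$poi_itf)
#> <tsr_test> chi_square_yates: statistic 9.528 (df 1), p = 0.002024

co <- simulate_cohort(cohort_config(n = 2000, group_prevalence = 0.45,
        censor_rate = 0.3,
        event_type_probs = c(death = 1, relapse = 0, metastasis = 0),
        seed = 1))
cox_fit(co, "group_itf", "os")
#> <tsr_fit> cox (os)
#>                 term effect ci_lower ci_upper    p_value
#> 1 group_itftumor_low  4.167    3.671    4.729 3.709e-108
```

The pattern-of-invasion × ITF-group association reproduces the
published p = 0.002 exactly, and the Cox fit recovers the generative
hazard ratio (truth 4.34) within its confidence interval.

## Command line

```sh
Rscript -e 'tsrzone::run_cli(commandArgs(TRUE))' \
    simulate phantom --out phantom/ --seed 7
Rscript -e 'tsrzone::run_cli(commandArgs(TRUE))' \
    pipeline phantom/image.ppm phantom/curves.geojson --out run/
```

Subcommands: `simulate`, `segment`, `zones`, `fields`, `tsr`, `stats`,
`pipeline`. Rasters are plain-text NetPBM with a JSON calibration
sidecar; curves are GeoJSON LineStrings; cohorts and fields are CSV.

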