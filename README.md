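# myofuse

Automated quantification of myoblast differentiation and muscle fiber
phenotype from micrographs, for muscle biologists running C2C12-style
differentiation assays and histochemical fiber typing.

The package implements four readouts:

* **Fusion index (FI).** For a two-channel field (DAPI nuclei, myosin
  heavy chain), nuclei are segmented by a fixed chain — 5th-percentile
  background subtraction, Gaussian smoothing (σ = 1.2 px), Otsu or
  adaptive thresholding, morphological cleaning, distance-transform
  watershed splitting of touching nuclei, and a 30–5000 px size gate.
  Myotubes come from the MHC channel, and a tube is *qualified* when it
  contains ≥ 3 nuclei. Then

  FI = (nuclei inside qualified myotubes) / (all nuclei in the field),

  averaged unweighted over the (conventionally four) fields of a well.
* **Myotube diameter.** Mean medial-axis diameter of long, multinucleated
  tubes: at each skeleton pixel the local diameter is 2 × the Euclidean
  distance to background, with end-cap trimming and exclusion of
  clustered-nuclei regions (≥ 2 nucleus centroids within a radius).
* **SDH fiber typing.** Per-fiber mean optical density OD = log₁₀(I₀/I)
  on a brightfield SDH stain, split into oxidative (high OD) vs
  glycolytic fibers at an Otsu or fixed threshold.
* **Group statistics.** Percent change between group means (rounded half
  away from zero for headline figures), two-tailed Student's t, and an
  F-test variance check that switches to Welch's t.

A synthetic image generator (`generate_field()`, `generate_well()`,
`generate_sdh_section()`) produces fields with exact ground truth —
nucleus positions, tube membership, true FI, true widths, true fiber
classes — so every stage is verifiable without original micrographs.

## Worked example

Simulate a well with a true fusion index of 0.45 and recover it:

```r
library(myofuse)

w   <- generate_well(synth_params(true_fi = 0.45, seed = 42))
res <- fusion_index(w$well)
tidy(res)
#> # A tibble: 4 × 8
#>   well_id field_id total_nuclei fused_nuclei n_myotubes n_qualified    fi
#> 1 well1   field1            100           45          6           6  0.45
#> 2 well1   field2            100           45          6           6  0.45
#> 3 well1   field3            100           45          6           6  0.45
#> 4 well1   field4            100           45          6           6  0.45
glance(res)
#>   well_id    fi n_fields fi_percent
#> 1 well1    0.45        4         45
```

Each row is one field: 100 nuclei detected, 45 of them inside qualified
tubes, so FI = 0.45 per field and 0.45 for the well — the generator's
ground truth, recovered exactly here. `autoplot(res)` draws the per-field
points with the well mean.

Type a synthetic SDH section and compare two FI groups:

```r
sec <- generate_sdh_section(n_fibers = 120, oxidative_fraction = 0.7,
                            seed = 42)
classify_fibers(sec$fiber_labels,
                optical_density(sec$brightfield, sec$i0))
#> <fiber_type_result> 120 fibers: 70.0% oxidative / 30.0% glycolytic
#>   (OD threshold 0.508)

compare_groups(data.frame(
  group = rep(c("control", "treated"), each = 4),
  value = c(0.44, 0.47, 0.42, 0.45, 0.26, 0.24, 0.27, 0.25)),
  control = "control")
#> 1 treated control 4 4 0.255 0.445 student -42.7  (t, df, p, ...)
```

The treated wells show a −42.7% change in mean FI (rounds to −43%),
flagged by a pooled-variance Student's t after the F-test found no
variance difference.

For real data, point `load_wells()` at a manifest CSV (`well_id`,
`field_id`, `path`, optional `pixel_size` and per-row channel overrides);
`read_config()`/`write_config()` persist the full parameter set as YAML. A
command-line front end for shell pipelines lives at `inst/cli/myofuse.R`
(subcommands `simulate`, `segment`, `fusion-index`, `sdh`, `compare`).

A methods vignette (`vignettes/myofuse-methods.Rmd`) documents the model,
every tunable parameter, the degenerate-input conventions, and what
passing synthetic-recovery tests does and does not show about real data.

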