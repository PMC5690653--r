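# tubulometry

Tubule histomorphometry for micro-CT volumes of the renal
medullo-papillary complex.

Early kidney-stone research needs quantitative geometry from 3D scans:
mineralized tubules in an unstained scan, iodine-stained vasculature in a
post-stain scan of the same specimen, and patent (open) tubules appearing
as voids inside stained tissue. Because different renal tubule types have
characteristically different calibers — vasa recta around 10–50 µm,
uriniferous tubules roughly an order of magnitude wider — the **diameter
distribution** identifies what a segmented structure is, and two-channel
**co-localization** says whether a mineralized tubule and a stained vessel
are the same structure.

## What the package computes

For a label volume *L* with common tubule direction **n** (the average
principal direction of all components), the package reslices *L*
perpendicular to **n** and measures every cross-section *S* as

> d(S) = minor-axis length of the minimum-area (Löwner–John) ellipse
> enclosing the pixel centers of *S*,

the tubule summary being the median of d over usable slices. An oblique
cut of a circular cylinder is an ellipse whose *minor* axis equals the
true diameter, so the estimate is tilt-invariant. The ellipse is computed
with Khachiyan's algorithm (Todd–Yıldırım away-steps, tolerance 1e-4).

Around that core: Otsu/fixed density thresholding, digital void inversion
(`organ & !tissue`), 3D connected-component labeling (6/26-connectivity,
speckle filter), rigid translation registration and per-tubule overlap /
Dice statistics, zone assignment along the organ axis (equal thirds:
proximal I, mid II, papillary tip III), normalized 10 µm-bin diameter
histograms with mode detection, and a synthetic two-channel phantom
generator with exact per-tubule ground truth. I/O is multi-page TIFF with
a JSON spacing sidecar, plus CSV measurement tables.

## Worked example

```r
library(tubulometry)

spec <- phantom_spec(grid_shape = c(96, 96, 96), n_tubules = 20, seed = 3)
ph   <- generate_phantom(spec)

lab  <- label_components(threshold_segment(ph$channel_a), spacing_um = 5)
m    <- measure_tubules(lab)
h    <- build_histogram(m$summary_diameter_um)
find_modes(h)
#>   bin bin_lo_um bin_hi_um count
#> 1   3        20        30    13
#> 2   5        40        50     7

# segmentation labels are matched back to ground-truth tubules by
# majority voxel overlap before comparing diameters
mt <- match_labels_to_truth(lab, ph)
truth_d <- ph$truth$true_diameter_um[match(mt$tubule_id, ph$truth$tubule_id)]
mean(abs(m$summary_diameter_um[match(mt$label, m$tubule_id)] - truth_d))
#> [1] 0.7624811
```

The two detected modes sit in the 20–30 µm and 40–50 µm bins — the two
populations the default phantom mixture 0.5·N(25, 2²) + 0.5·N(45, 4²)
plants — and per-tubule diameters are recovered to well under one voxel
(0.76 µm) on this small noisy phantom.

A thin command-line front end over the same functions ships in
`inst/cli/tubulometry.R` with subcommands `phantom`, `segment`, `measure`,
`coloc` and `histo`.

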