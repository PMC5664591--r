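# hyperrow

Automated segmentation and per-plant trait extraction for lateral-view
push-broom hyperspectral images of row crops.

Ground-based hyperspectral phenotyping platforms tow a pair of line-scan
scanners (VNIR, 400–896 nm; SWIR, 895–2506 nm) along a crop row and build
2-D image cubes line by line. Before the spectra are of any use, each row
image has to be segmented — target plants separated from the cardboard
backdrop, the grass strip, support posts and the white reflectance
standard kept in frame for calibration — converted to reflectance, and
cut into the individual plants, which in a mapping population are
distinct genotypes. `hyperrow` does all of that without manual
intervention beyond a one-off crop of the row ends, and includes a
seeded synthetic-scene simulator with full ground truth so the whole
pipeline is testable without field data.

## Methods at a glance

* **VNIR plant detection** — fixed threshold on
  NDVI = (I<sub>IR</sub> − I<sub>red</sub>)/(I<sub>IR</sub> + I<sub>red</sub>)
  (red 650–680 nm, IR 710–740 nm), 3×3 cross erosion, then removal of the
  grass strip below a minimum-cost seam traced over the NDVI image with
  cost C = e<sup>−I(x)</sup>(1 − g<sub>y</sub>).
* **SWIR plant detection** — water-absorption index
  N<sub>dif</sub> = (I<sub>1375</sub> − I<sub>1411</sub>)/(I<sub>1375</sub> + I<sub>1411</sub>)
  thresholded by Otsu's method, plus a fixed bottom crop.
* **Minimum-cost seams** — dynamic programming over
  t(x, y) = min(t(x−1, y−1) + C + λ<sub>ver</sub>, t(x−1, y) + C,
  t(x−1, y+1) + C + λ<sub>ver</sub>), verified against exhaustive
  shortest-path search in the tests.
* **White-reference detection** — VNIR: two seams (tile bottom with
  C = 1 − g<sub>y</sub>, tile top with C = 1 − g<sub>y</sub> + λ<sub>dist</sub>·d
  for a V-shaped distance penalty d), then variance and darkness rules
  flag occluded columns. SWIR: 1620/1537 nm index, histogram
  local-minimum threshold seeded at the 10% pixel quantile, cross
  erosion.
* **Reflectance** — the image is divided into fixed-width column
  sections and every pixel spectrum is divided by its section's mean
  white-reference spectrum.
* **Plant splitting** — peaks of the per-column plant-pixel profile
  (minimum separation 80% of the expected pitch), midpoint boundaries,
  gap subdivision, merge/split to the known plant count, local-minimum
  refinement, and a 10% margin crop per side.
* **Traits** — per-plant height (pixels and metres via the 1.2 m swath
  calibration), density (mean plant pixels per column) and mean
  reflectance spectrum.

See `vignettes/hyperrow-methods.Rmd` for the full account, including
every tunable and the design decisions behind the defaults.

## Worked example

```r
library(hyperrow)

cfg <- scene_config(n_plants = 12, seed = 42)   # a 12-plant simulated row
scene <- generate_scene(cfg)
scene$vnir
#> <hypercube> 402 rows x 480 cols x 178 bands (raw), 400.0-896.0 nm

det <- detect_plants_vnir(scene$vnir)            # NDVI + erosion + grass seam
panel <- detect_whiteref_vnir(scene$vnir, expected_width = 40)
panel
#> <whiteref_panel> 472/480 valid columns, 18720 mask pixels

refl <- normalize_reflectance(scene$vnir, panel)
regions <- split_row(column_profile(det$mask), n_expected = 12,
                     expected_spacing_px = 40)
out <- extract_plant_data(refl, det$mask, regions)
head(out$traits, 4)
#>   plant_id height_px height_m density n_pixels
#> 1        1       145    0.433    77.7     2564
#> 2        2       194    0.579   122.0     3781
#> 3        3       170    0.507   134.2     4293
#> 4        4       211    0.630   143.5     4737

mean(out$spectra[1, scene$vnir$wavelengths_nm > 740])
#> [1] 0.514
```

The eight invalid white-reference columns are the ones occluded by the
scene's two posts; heights are the mask's vertical extent converted at
1.2 m / 402 rows; the NIR plateau reflectance of ~0.51 matches the
simulated leaf endmember. `run_row()` wraps the same steps (for both
scanners, with dark-current correction and ENVI/CSV/PNG outputs plus a
JSON run manifest), and `inst/cli/hyperrow.R` exposes everything as a
command line:

```sh
Rscript inst/cli/hyperrow.R simulate --out scene --n-plants 12 --seed 42
Rscript inst/cli/hyperrow.R run --vnir scene/vnir.bsq --swir scene/swir.bsq --out results
```

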