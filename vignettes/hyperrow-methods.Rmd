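---
title: "Methods: segmenting and splitting push-broom hyperspectral row images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmenting and splitting push-broom hyperspectral row images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Field phenotyping platforms that drive push-broom hyperspectral scanners
along a crop row produce lateral-view cubes in which the plants of
interest are mixed with grass, sky-replacement backgrounds, support posts
and a white reflectance standard, all under illumination that drifts as
the platform moves. Before any spectral analysis can happen, each row
image must be (i) reduced to a binary mask of target plant material,
(ii) calibrated to reflectance against the in-frame white standard, and
(iii) cut into the individual plants, which in a mapping population are
distinct genotypes. `hyperrow` implements that front end for a two-scanner
set-up (VNIR, 400–896 nm; SWIR, 895–2506 nm) imaging raspberry rows
against a suspended cardboard background, and ships a synthetic-scene
simulator so every stage can be tested quantitatively without field data.

The two scanners are processed independently throughout; no image
registration between them is attempted.

## Plant detection

**VNIR.** Leaf material is separated from the background with the
normalised difference vegetation index,
$\mathrm{NDVI} = (I_{IR} - I_{red}) / (I_{IR} + I_{red})$, where
$I_{red}$ is the per-pixel mean intensity over 650–680 nm and $I_{IR}$
over 710–740 nm (band centres, endpoints inclusive). A fixed threshold
(default 0.3, the conventional green-vegetation cut-off; results are
stable over roughly 0.2–0.5 on simulated scenes) gives a provisional
mask, which is eroded with a 3×3 cross-shaped structuring element: a
pixel survives only if its four 4-connected neighbours are also plant.
This removes stray single-pixel detections and the mixed pixels on leaf
edges. Off-image neighbours count as non-plant, so border pixels are
dropped unless fully supported — the conservative choice.

**Grass removal.** The strip of grass below the cardboard background
scores high NDVI and must be cut away. The bottom edge of the cardboard
is traced as a minimum-cost seam across the NDVI image with per-pixel
cost

$$C(x, y) = e^{-I(x)}\,\bigl(1 - g_y(x, y)\bigr),$$

where $g_y$ is the vertical gradient of the NDVI image and $I(x)$ the
column mean. The brightness factor $e^{-I(x)}$ weakens the cost in
columns where overhanging plants hide the cardboard–grass edge, so the
seam is not dragged off course there. Everything below the seam is
removed from the mask.

**SWIR.** Pigment contrast is unavailable beyond 1000 nm, so detection
exploits the different shape of the water-absorption region in leaves:
$N_{dif} = (I_{1375} - I_{1411}) / (I_{1375} + I_{1411})$, each term the
mean of 3 bands centred on the named wavelength. Leaf water absorption
depresses 1411 nm relative to 1375 nm, giving vegetation a high index
while dry materials sit near zero. The index image is thresholded with
Otsu's method (256-bin histogram over the image range, between-class
variance maximised; the returned threshold is the selected bin edge, used
with a strict `>`). Horizontal striping noise in the SWIR scanner makes a
seam-based grass boundary unreliable there, so a fixed fraction of bottom
rows (default 0.15) is cleared instead — a larger cut than the VNIR seam
makes, but a dependable one.

## The minimum-cost seam

Both the grass boundary and the white-reference edges are instances of
one primitive: the continuous left-to-right path $y(x)$ with
$|y(x{+}1) - y(x)| \le 1$ minimising the summed per-pixel cost. The
dynamic programme is

$$t(x, y) = \begin{cases}
C(x, y) & x = 1\\
\min\bigl(t(x{-}1, y{-}1) + C(x, y) + \lambda_{ver},\;
          t(x{-}1, y) + C(x, y),\;
          t(x{-}1, y{+}1) + C(x, y) + \lambda_{ver}\bigr) & \text{else,}
\end{cases}$$

with off-image rows at infinite cost; the seam backtracks from the
minimum of the last column. $\lambda_{ver}$ penalises each diagonal move
and favours seams with limited vertical movement; with an all-zero cost
matrix the optimum is exactly horizontal. The test suite checks the
implementation against an independent Dijkstra search over the explicit
move graph on hundreds of random instances.

Numerical conventions, chosen for determinism:

* the gradient is a central finite difference (one-sided at the top and
  bottom rows), rescaled so the maximum absolute value is 1; this makes
  every cost scale-invariant to image brightness;
* ties in the minimum prefer the horizontal move, then the upward, then
  the downward one, and the smallest row wins the final argmin;
* `lambda_ver` defaults to 0.05 and the tile-edge distance weight
  `lambda_dist` to 0.01. Both are dimensionless and config-overridable;
  the defaults are small enough that a full-contrast edge (a cost drop of
  1 after gradient normalisation) always dominates a one-pixel vertical
  move, while flat regions still iron out to near-horizontal paths.

**Edge polarity.** The cost $1 - g_y$ is minimised along edges where the
chosen image *brightens* downward; an edge that darkens downward needs
$1 + g_y$. The two edges of the white tile have opposite polarity, so the
edge costs take a `polarity` argument: the tile's bottom edge
(bright-above/dark-below) is traced with the falling polarity, the tile's
top edge and the cardboard–grass boundary (dark-above/bright-below) with
the rising one. A single signed convention cannot serve both, and the
choice is made explicit rather than hidden in a gradient sign.

## White-reference detection

**VNIR.** The mean image over 455–480 nm offers the strongest contrast
between the bright tile and its surroundings. The tile's bottom edge is
traced first with the plain edge cost $C = 1 - g_y$ (falling polarity).
From it and the tile's expected width $w$ (known a priori from the
imaging geometry) a shape function
$d(x, y) = \lvert (y_{bottom}(x) - w) - y \rvert$ — a per-column V with
its vertex at the expected top-edge position — steers the second seam:
$C = 1 - g_y + \lambda_{dist}\, d$. Pixels strictly between the two seams
form the initial mask.

**Occlusion filtering.** The tile is nominally uniform down each column,
so two rules flag columns occluded by leaves or posts: columns whose
mask-pixel intensity variance exceeds twice the mean column variance
(partial, mixed occlusions), then columns whose mean intensity falls
below 80% of the median of the survivors (full, dark occlusions). The
80%-of-median darkness cut is this package's operationalisation of
"remove the darkest columns"; being median-relative it is robust to
global illumination drift. The variance is computed over the mask rows of
the detection image; computing it over wavelengths instead would be the
main alternative reading, and is deliberately not used because a
uniformly grey occluder could pass a spectral-variance test while
corrupting the reference level.

**SWIR.** The normalised difference of 3 bands centred at 1620 nm versus
1537 nm makes the tile the *lowest* mode of the image histogram, with
background and plants above it. The 256-bin histogram is smoothed with a
5-bin moving average and searched for a local minimum starting from the
bin containing the 10% pixel quantile, walking outward to the nearest
qualifying bin. A "local minimum" is a maximal run of equal smoothed
counts flanked on both sides by strictly greater values (the run's centre
bin is used); treating plateaus as single minima keeps the rule
well-defined when empty bins separate well-spaced modes. The image is
thresholded below that minimum and eroded with the 3×3 cross; column
validity follows mask occupancy.

## Reflectance normalisation

Illumination changes along the travel direction, so the image is divided
into consecutive column sections of fixed width (default 100 columns) and
every pixel spectrum in a section is divided by the mean white-reference
spectrum over the section's valid columns. Sections left with no valid
reference column — a post can occlude an entire section — borrow the
nearest section's spectrum (ties to the left). Reflectance is not clipped
at 1, since specular pixels legitimately exceed the tile. A zero in any
reference band aborts with the band named, rather than silently dividing
by zero.

## Splitting the row into plants

The number of plant-mask pixels in each column gives a profile whose
peaks are plants and whose minima are gaps. The splitter:

1. smooths the profile with a moving average of width 10% of the expected
   plant pitch (stabilises peaks against cane-level texture) and finds
   local maxima, kept greedily in decreasing height order subject to a
   minimum separation of 80% of the expected pitch;
2. places provisional boundaries midway between consecutive peaks, plus
   the image ends;
3. subdivides any inter-peak gap wider than 1.5× the pitch into
   `round(gap / pitch)` equal parts, catching plants the peak finder
   missed entirely;
4. matches the region count to the known number of plants per row by
   merging the region with the fewest plant pixels into its lower-profile
   neighbour, or splitting the widest region at its internal profile
   minimum (ties resolved toward the region centre, so a missing plant
   gets its own region rather than a sliver at one edge);
5. moves each internal boundary to the profile's local minimum within
   ±25% of the pitch (ties toward the provisional boundary) — the optimum
   cutting point;
6. finally shaves 10% of each region's width from both sides to form the
   analysis span, excluding areas where neighbouring bushes intermingle.

The regions always tile the image exactly and are numbered by position.
The 1.5× gap threshold, the merge/split selection rules and the ±25%
search window are this package's choices — symmetric around one plant
pitch — where the procedure itself leaves them open.

## Traits

Per plant, within the analysis span of the binary mask: height is the
vertical extent (lowest minus highest plant row + 1), converted to metres
with the scanner swath calibration (1.2 m over 402 rows for the VNIR
scanner, 378 for the SWIR); density is the mean number of plant pixels
per column — the image counterpart of a visual cane-density score; and
the mean reflectance spectrum averages the masked pixels per band. Height
uses the mask's vertical extent rather than a distance to the grass
boundary; the two coincide for plants that reach their own base and the
extent is robust when the boundary seam is locally imperfect.

## The synthetic scene simulator

`generate_scene()` renders seeded VNIR and SWIR cubes of one row plus
complete ground truth (per-material masks, the cardboard-bottom row,
plant centres and spans, endmember spectra, the injected illumination and
dark-current fields). The scene is a cardboard background, a grass strip
along the bottom (14% of image height), a horizontal tile strip at height
fractions 0.10–0.20, vertical posts occluding it, and plants built as
unions of overlapping ellipses standing just above the grass, one per
pitch with jittered centres and random sizes. Pixel values are
`reflectance × illumination × gain + dark + Gaussian noise`; the
illumination drift is a smooth low-order polynomial in the column index
shared by every material — precisely the nuisance the sectioned
normalisation must cancel — and the SWIR dark current varies smoothly
with detector row and band.

The endmembers are hand-built piecewise-linear curves, not measured
spectra: a leaf with red absorption, a red edge, an NIR plateau and
water-absorption features that depress 1411 nm against 1375 nm; grass as
a dimmer leaf; flat cardboard; a bright tile with a mild 1620 nm dip that
makes it the low mode of the 1620/1537 index; and dark posts. They carry
exactly the spectral structure the pipeline's indices rely on and nothing
more.

Scanner geometry defaults to the field set-up this package was built
around: 178 bands over 400–896 nm with 402 rows (VNIR) and 278 bands over
895–2506 nm with 378 rows (SWIR), 12 plants per default scene at a 40 px
pitch (the full trial rows hold 48 plants, available via configuration).
Other free parameters — gain 1000 DN, noise 5 DN, SWIR dark ~40 DN, 20%
illumination drift — were fixed once at values representative of a
line-scan camera at mid-range exposure.

What the simulator does **not** emulate: measured reflectance libraries,
specular/BRDF effects, wind-induced motion blur, scanner misalignment
between VNIR and SWIR, atmospheric-absorption noise bands, or intertwined
canopies beyond what overlapping ellipses produce. Passing the recovery
tests therefore demonstrates the algorithms' correctness under controlled
conditions, not field-grade robustness.

## Problem sizes used by the checks

The test suite exercises unit behaviour on miniature scenes (4 plants,
~90-row cubes) and the quantitative recovery checks on 20 seeded scenes
at the default scanner geometry. The 48-plant splitting sweep runs at a
reduced spectral/vertical sampling (60 bands, 240 rows, 32 px pitch),
since splitting depends only on the mask profile; the acceptance script
regenerates the 48-plant row at the full VNIR geometry. These sizes are
the package's choices for routine runs; all of them can be scaled up
through `scene_config()`.

## Known limitations

* The NDVI threshold and SWIR bottom-crop fraction are fixed, not
  adaptive; scenes with very different backgrounds need retuning.
* The seam model allows at most one row of vertical movement per column,
  so a cardboard bottom with steps steeper than 45° would be smoothed
  over.
* Column-wise occlusion filtering discards whole columns; a leaf touching
  only the tile's lowest row still invalidates its column.
* Splitting assumes an approximately known, constant plant pitch and a
  known plant count per image.
* With heavily overlapping canopies the 10% analysis-span margin reduces,
  but does not eliminate, cross-plant contamination.
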