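---
title: "Stereoscopic soma census: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stereoscopic soma census: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

braincensus counts fluorescently labeled neuronal somas in whole-brain
optical volumes and summarizes how they are distributed across anatomical
regions. This vignette explains the underlying models and procedures, the
parameters that matter, what the synthetic generator does and does not
emulate, and the design decisions taken where more than one reasonable
choice existed.

## The problem

Whole-brain sectioning tomography produces continuous image stacks at
sub-micrometre lateral resolution and micrometre-scale section thickness —
the package's default geometry is 0.32 μm × 0.32 μm laterally and 2 μm
axially, so a voxel is six times longer along z than along x or y. A single
channel of such a dataset runs to terabytes. Counting labeled somas
stereoscopically (in 3D, rather than in sampled 2D sections) avoids both
double-counting of cells that span adjacent sections and missed counts of
axially overlapping cells, but requires (i) detection that works blockwise
because the volume cannot be held in memory, (ii) exactly-once accounting
of somas that straddle block boundaries, and (iii) all distances computed
in physical micrometres, never in voxel units.

## Guard-zone block processing and the exactly-once merge

`plan_blocks()` tiles the voxel grid into non-overlapping *core* blocks
(default edge 512 voxels) and expands each by a *guard zone* (default 50
voxels) into a padded extent. Detection runs independently on padded
extents; a soma near a core boundary is fully visible to at least one
block.

The merge rule is ownership by center voxel: a detection survives iff the
voxel containing its center lies in its source block's core. Cores
partition the volume, so every soma is counted exactly once — no pairwise
distance-based deduplication is needed, and the result is provably
independent of block processing order. Somas whose diameter exceeds the
physical guard width are flagged (`oversize`) rather than silently
mis-merged; at the default geometry the 50-voxel guard is 16 μm laterally,
far above any plausible soma diameter.

For the tiled result to equal whole-volume detection *exactly*, every
block must apply identical thresholds. `calibrate_detection()` therefore
estimates the background level (median), robust noise SD (MAD of a
deterministic voxel subsample) and peak intensity once per dataset, and
`run_blocks()`/`count_neurons()` pass this calibration to every block.
The guard must also cover the detector's influence radius
(growth reach plus smoothing support); `run_blocks()` warns when it does
not. The package's tests verify bit-identical center sets between
whole-volume and tiled detection on multi-block plans.

## Soma detection

Detection internals are the package's own design; the contract they
satisfy is: one detection per sufficiently bright compact blob in the
expected radius range, none for thin elongated structures (dendritic
trunks), and splitting of touching somas whose centers are at least one
expected radius apart.

The stages, with tunables from `detection_params()`:

1. **Calibration.** Background = the `background_percentile` (default
   median) of raw intensities; noise SD = MAD around it; peak = maximum.
   All three scale with the data, so thresholds are invariant to a global
   intensity rescaling.
2. **Smoothing** at soma scale: separable Gaussian with `sigma_um`
   (default half the minimum expected radius, i.e. 1.25 μm), converted to
   per-axis voxel sigmas so the anisotropy is respected.
3. **Seeding.** 26-neighborhood regional maxima of the smoothed volume
   above `background + max(noise_k × σ_smoothed, rel_floor × dynamic
   range)`, where σ_smoothed is the raw noise SD times the exact
   white-noise attenuation of the smoothing kernel. `noise_k = 8` places
   the threshold above the expected maximum of ~10⁶–10⁸ smoothed noise
   variates (~5–6 σ), so pure-noise blocks yield no seeds. Seeds closer
   than `min_separation_um` (default the mean expected radius) are
   suppressed greedily by descending intensity; equal-intensity neighbors
   merge to one seed at their centroid, which makes tie-breaking
   deterministic.
4. **Region growing on the raw volume.** Each seed claims 26-connected
   voxels with raw intensity ≥ background + `boundary_frac` (default
   0.25) of the seed's height above background, within
   `max_reach_factor × max radius` of the seed. Contested voxels go to
   the physically nearest seed — this deterministic partition is what
   splits touching cells. Growing on the *raw* rather than smoothed
   volume matters: smoothing inflates a 1 μm trunk to ~2.3 μm apparent
   half-width, which would defeat the trunk gate below.
5. **Trunk removal.** Each claimed mask is opened with an ellipsoidal
   structuring element of physical radius 0.6 × `trunk_cutoff_um`
   (default cutoff 2 μm). Structures thinner than the cutoff — dendritic
   trunk cylinders — do not survive the erosion. A seed whose own voxel
   does not survive the opening sat on a trunk, not a soma, and is
   rejected outright; for genuine somas the opening merely strips any
   attached trunk stub from the mask.
6. **Shape and size gates.** Remaining components are rejected if their
   minor principal extent (4√λ_min of the physical-coordinate covariance)
   is below the trunk cutoff, or their equivalent-sphere radius is far
   outside the expected range.
7. **Center.** Intensity-weighted centroid of the mask (background
   subtracted), in physical μm. On rendered ellipsoids this recovers
   centers to ~0.05 μm.

## Morphology features

`measure_morphology()` computes the six per-soma features used by the
similarity analysis: volume (voxel count × voxel volume), surface area,
the longest/shortest/average radii (centroid to surface-voxel centers, in
μm), and the longest-to-shortest ratio.

Surface area is the area of a triangulated isosurface: marching tetrahedra
at level 0.5 on the mask's indicator field after a light Gaussian
mollification (σ = 0.8 voxels). The mollification matters — the exposed
voxel-face area of a digitized sphere overestimates the true area by a
factor approaching 1.5, and marching tetrahedra on the raw binary field
still carry a ~10% staircase bias, while on the mollified field the
estimate lands within ~2% for spheres of radius ≥ 3 μm at 0.5 μm
sampling. A single-voxel mask cannot support a triangulation and is
flagged degenerate; its features come from the voxel half-edges.

Because somas only a few μm across span very few 2 μm sections, morphology
recovery is validated at a finer 0.5 μm isotropic geometry; this separates
algorithmic correctness from axial-sampling artifacts, which no algorithm
can undo.

## Regional statistics

Counting is center-based: a neuron belongs to the region whose label its
center voxel carries (`floor(coordinate/edge)`, boundary points to the
higher voxel). Region volume is voxel count × voxel volume (μm³ → mm³,
×10⁻⁹); density is count/volume; group roll-ups aggregate counts and
volumes over catalog parent groups *before* dividing. Detections whose
centers fall in background (label 0) are reported separately, never
dropped.

The nuclei distance of a region is the mean, over its neurons, of each
neuron's Euclidean distance to its nearest same-region neighbor. It is
computed with a uniform-grid spatial index required to agree with the
all-pairs brute force to 10⁻⁹ μm (both compute squared distances in
double precision; ties cannot affect the statistic since only the
distance, not the neighbor's identity, enters).

## Detection evaluation

Recall and precision follow the standard definitions R = B/B1 and
P = B/B2, with B1 ground-truth neurons, B2 detections, and B correct
detections. Which detections are "correct" requires a matching rule: the
package uses optimal one-to-one bipartite assignment that maximizes the
number of pairs within `tolerance_um` and, among those, minimizes total
distance (Hungarian algorithm on a padded cost matrix). Greedy matching
mis-handles crossed configurations; optimal matching is deterministic and
exact. The default tolerance of 5 μm is about one soma radius — a
detection farther than that from every truth center is not the same cell.

`evaluate_cubes()` implements the randomized evaluation protocol: 12
cubes of 300 μm edge placed uniformly inside the volume, per-cube matching
restricted to centers inside the cube (half-open bounds), and the
highest/lowest/mean of R and P reported. Whether somas straddling cube
faces should count is ambiguous; centers-inside is used.

## Soma-shape similarity workflow

One 200 μm cube is sampled uniformly at random fully inside each region;
the six features of the neurons inside form the pooled feature matrix.
Regions with fewer than `min_cells = 3` neurons in their cube are excluded
(the dispersion and test statistics are undefined below that; this
generalizes the exclusion of a cube containing only 2 neurons).

The order of operations is: standardize features (zero mean, unit
variance, pooled) → PCA → min-max normalize the top-2 scores to [0, 1].
The alternative reading — min-max the raw features before PCA — would let
the feature with the largest numeric range (surface area) dominate the
decomposition; standardization is the conventional choice. PCA is pooled
across regions (one shared score space), matching the analysis of all
regions in common axes. Loading signs are fixed (largest-magnitude entry
positive) so the orientation is deterministic.

Concentration keeps, per region, the `floor(0.8 n)` points nearest the
region's mean in the normalized score plane (ties broken by stable row
order), trimming deviation points before dispersion is measured. Region
similarity is the sample SD (n−1) of each component on the concentrated
subset. Pairwise region differences use a two-group one-way ANOVA F test
per component at α = 0.05, uncorrected by default (an optional
`p_adjust` is available); a pair is "not different" iff both components
are non-significant. A two-group one-way ANOVA is equivalent to the
squared pooled-variance t test, and the suite verifies both this identity
and the test's type-I error calibration under the null. Whether the
original analysis used pairwise two-group tests or an omnibus with
post-hoc contrasts is not determinable; pairwise two-group is implemented.

## The synthetic generator

Because raw whole-brain datasets of this kind are terabyte-scale and not
publicly deposited, the package ships a generator whose output has the
statistical structure the pipeline must survive, with exact ground truth:

* **Region layouts**: non-overlapping cuboid nuclei and layered slabs
  (emulating cortical layers) rasterized into an integer label volume;
  label 0 is background.
* **Placement**: per-region Poisson counts with mean intensity × volume,
  centers uniform within the region's voxels, optional minimum
  separation by rejection sampling.
* **Somas**: oriented ellipsoids (uniformly random 3D orientation,
  semi-axes uniform in the region's range) with quadratic intensity
  falloff from peak at center to background at the surface; peak
  brightness lognormal around the region mean (15% SD).
* **Trunk artifacts**: with region-specific probability, a bright
  cylinder (radius 1 μm, length 10–50 μm) from the soma surface in a
  random direction — the structure a soma detector must not count.
* **Counterstain**: a nucleus at every labeled soma plus unlabeled-cell
  nuclei at 5× the labeled density, reflecting that a nuclear
  counterstain marks all cells and labeled neurons are a minority.
* **Noise**: Poisson shot noise on signal-plus-background and additive
  Gaussian read noise, clipped to 16 bits. Background 100, read SD 5 by
  default. The source imaging system's noise statistics are not
  characterized publicly; these defaults are plausible for sCMOS
  epifluorescence, not fitted.

The default demonstration scene is 512 × 512 × 256 voxels at the native
anisotropic geometry with four regions spanning 2,500–60,000 cells/mm³ —
the density range from the sparsest to the densest brain regions — giving
a few hundred neurons per scene; it renders in well under two minutes.

What the generator does **not** emulate: optical PSF blur, vignetting,
stitching seams, section-transition artifacts, autofluorescence gradients,
realistic atlas geometry, or dendrite/axon arbors beyond the trunk stub.
Passing tests therefore demonstrate algorithmic correctness under the
stated statistical structure, not performance on real tissue; on real
data, registration quality and background heterogeneity would dominate
the error budget.

## Numerical choices and degenerate inputs

* Coordinates: origin at the corner of voxel (0,0,0); a voxel's center is
  at (index + 0.5) × edge; arrays are (z, y, x); windows and block bounds
  are half-open.
* Seeded RNG: every stochastic stage takes an explicit seed and pins the
  generator kind, so results are bit-reproducible regardless of session
  state; the caller's RNG state is restored.
* Flat (constant) volumes calibrate to zero dynamic range and return no
  detections rather than seeding on numerical noise.
* A region absent from the label volume has volume 0 (with a warning) and
  undefined density; nuclei distance is undefined below 2 neurons;
  similarity SDs below 2 concentrated rows are flagged, and degenerate
  zero-variance ANOVA inputs give p = 1 when means agree.
* Problem sizes in the test suite (scenes up to 512 × 512 × 256 voxels,
  point sets up to 2,000, 1,000 null replications) were chosen to give
  3-sigma statistical resolution on every recovery check while keeping a
  full run in tens of minutes on one CPU.

## Known limitations

* Detection assumes somas are the brightest compact structures; dense
  neuropil brighter than dim somas would require a locally adaptive
  background model that the current global calibration does not provide.
* The relative seed floor (`rel_floor` of the dynamic range) ties the
  faintest detectable soma to the brightest structure in the dataset;
  datasets with extreme brightness range may need it lowered.
* Somas larger than the guard width are flagged, not recovered.
* Surface area at the native 2 μm axial sampling is biased for small
  somas (few z-planes); radii and volume are more robust there.
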