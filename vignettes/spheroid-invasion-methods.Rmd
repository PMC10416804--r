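---
title: "Methods: spheroid invasion morphometrics and single-cell count QC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spheroid invasion morphometrics and single-cell count QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroquant)
```

## The measurement problem

A tumor spheroid embedded in a collagen matrix is imaged as a confocal
z-stack every one to three days. Three populations matter: compact
*epithelial* cells within the spheroid surface, elongated *escaping* cells
still attached to the periphery, and detached, rounded *amoeboid* cells
invading the matrix. The assay's outputs are population metrics per day —
spheroid volume, escaped-cell counts normalized to imaged surface area,
per-cell sphericity and distance from the spheroid — and, on the
transcriptomics side, a housekeeping-gene quality filter and Ward
clustering of single-cell count profiles.

Because single-photon excitation cannot penetrate the dense spheroid,
emission is only trustworthy down to the spheroid's widest plane. All
imaging analysis therefore operates on the *hemispheroid*: the slab between
the imaging face and the z-slice of maximal spheroid cross-section
(`crop_at_widest()`, ties broken toward the face — the tie direction is a
package convention, chosen so that cropping never keeps slices the physics
says are unreliable).

## Geometry estimators

With periphery-ellipse radii `a >= b` (least-squares conic fit to the
boundary of the widest slice) and imaging depth `z`:

* mean radius `r = (a + b + z)/3` and estimated volume `V = 4/3 * pi * r^3`.
  The estimator deliberately treats the spheroid as the sphere with the
  averaged radius; it is symmetric in `(a, b, z)`.
* mean ellipsoid axis `e = (a + b)/2` and spherical-cap area
  `SA = pi * (e^2 + z^2)`, the lateral area of a cap with base radius `e`
  and height `z`. For `z = e` this is the hemisphere area `2*pi*e^2`.
  Escaped-cell counts divided by `SA` give cells per square micrometre,
  comparable across spheroid sizes.
* Wadell sphericity `psi = pi^(1/3) * (6*V_p)^(2/3) / A_p` per cell,
  with `V_p` the cell volume and `A_p` its surface area.

The ellipse fit adds half a pixel to both semi-axes: boundary pixel
*centers* necessarily sit inside the continuous contour, and the half-pixel
term removes that rasterization bias (it vanishes as resolution increases).

## Surfaces, distances, phenotypes

**Segmentation.** Otsu or fixed thresholding, 26-connected components,
and a minimum object volume (default 65 um^3, roughly a 2.5 um-radius
sphere) to suppress noise specks. The largest component is the spheroid
mass; every other component is a candidate cell.

**Surface area.** `measure_object()` meshes each cell with spacing-aware
marching tetrahedra. Meshing the raw binary mask would measure the voxel
staircase (a ~1.5x overestimate that biases sphericity low), so the
indicator field is first Gaussian-smoothed by about one voxel per axis.
Smoothing alone would shrink small cells, so the iso level is chosen
per object such that the enclosed voxel count equals the object's
("volume-matched" level). On spheres spanning ten or more voxels per axis
this keeps surface areas within a few percent of the analytic value, and
sphericities of generated ellipsoids within 3% of closed form at spacing
of a tenth of the smallest semi-axis.

**Reference surface.** Distances must reflect travel from the bulk
spheroid core, not from elongated invasive cells still attached to the
periphery. The reference is therefore the spheroid mask opened with a ball
of radius `smoothing_scale` (default 10 um: comfortably thicker than a
cell protrusion, thinner than the spheroid), then closed with the same
ball. Opening removes protrusions thinner than the scale; closing fills
concavities of the same scale. Note that a pure morphological *closing*
would keep protrusions (closing is extensive), which would defeat the
reference's purpose — this is why the package smooths with
opening-then-closing rather than closing alone, and why the enclosure
property is guaranteed relative to the opened bulk core rather than the
raw mask.

**Distances.** `distance_to_reference()` samples an exact, spacing-aware
Euclidean distance transform of the reference at the cell's surface voxels
(zero on overlap). The transform is separable and exact — not a chamfer
approximation — and the test suite pins it against a brute-force all-pairs
oracle on 20^3 grids. A centroid-based variant is exposed
(`method = "centroid"`) because commercial "distance to surface"
statistics differ in this choice; nearest-surface is the default.

**Phenotypes.** `classify_phenotype()` uses attachment and shape:
detached (`d > 0`) cells are amoeboid; attached cells below the sphericity
threshold are escaping; attached, compact cells are epithelial. The default
threshold of 0.8 reflects that detached cells in this assay stay rounded
(sphericity 0.8-0.9) while actively escaping cells are markedly elongated;
it is configurable, and classification accuracy is only guaranteed when the
generated (or real) populations are separated by at least ~0.15 in
sphericity.

**Time series.** Each day's image shows every cell escaped so far, so
newly escaped cells are the day-over-day increase in the detached count
(never negative; no cell tracking), the cumulative count is their running
sum, and invasion density is the cumulative count over `SA`. Invasion
speed is the day-to-day change in mean escaped-cell distance — a
population-level rate, defined this way because per-cell tracking across
days is out of scope; when the population mix shifts (new escapers start
near the spheroid), this rate understates individual cell speed, which is
an accepted property of the metric, not a bug.

## Count QC, normalization, clustering

* `drop_zero_genes()` removes genes with zero reads across all cells.
* `housekeeping_qc()` excludes a cell when **more than** 30% of the
  housekeeping panel has counts **strictly below** 10. Both comparisons
  are strict — a count of exactly 10 passes, and a low-fraction of exactly
  30% is retained — and the boundary is unit-tested (7 of 22 low excludes,
  6 of 22 retains). The full panel must be present in the matrix; the
  filter errors rather than silently shrinking the denominator, so the
  30% threshold always refers to the complete panel.
* `normalize_for_clustering()` is a documented stand-in for a
  variance-stabilizing transformation: median-of-ratios size factors
  (geometric-mean reference over genes expressed in every cell; library
  -size fallback with a warning) followed by `log2(count/sf + 1)`. It is
  used only to put cells on a comparable scale for clustering, and the
  pipeline can equally ingest an externally transformed matrix.
  Model-based dispersion machinery is deliberately out of scope.
* `ward_cluster()` applies Ward variance minimization on Euclidean
  distances via `hclust(method = "ward.D2")`, whose height convention —
  two singletons merge at their Euclidean distance — matches the
  convention of the scientific Python stack. Heights differ between Ward
  variants by constant factors, which is why the convention is pinned and
  tested (including against an exhaustive minimum-ΔSS oracle for up to
  eight points).
* `flag_outliers()` flags cells that are still singletons when they join
  the dendrogram at more than `factor` (default 3) times the median merge
  height. The original outlier call this emulates was a judgment call on
  a dendrogram; the rule here is a reasonable, deterministic surrogate for
  that judgment, not a reproduction of it.

## The synthetic-data generator

`imaging_scenario()`/`generate_volume()` emulate the microscope: a
spherical spheroid plus peripheral cells of controlled shape (spheres,
ellipsoids, capsules) rasterized by the voxel-center rule, constant
foreground/background intensities, and additive Gaussian noise clipped at
zero. Defaults are chosen to resemble the real assay: a 120 um spheroid
tangent to the imaging face (the widest point one radius deep),
anisotropic 1 x 1 x 3 um voxels as in confocal stacks, and contrast far
above noise. Ground truth (volume, area, sphericity, distance, phenotype)
comes from closed forms: exact for spheres, prolate/oblate spheroids and
capsules; Knud Thomsen (p = 1.6075, error bound ~1.1%) for triaxial
ellipsoids, verified against a quadrature oracle in the tests.

`generate_timeseries()` grows the spheroid radius by a constant per-day
factor and accumulates escaped cells per a user schedule, each cohort
drifting outward at a fixed speed. The schedule, growth factor and drift
are free parameters of the emulation — the assay literature gives no
quantitative escape-rate model, and these values are not estimates of any
cell line's biology.

`count_scenario()`/`generate_counts()` emulate the sequencer:
negative-binomial counts (dispersion 0.4, typical of plate-based
single-cell libraries), a 22-gene housekeeping panel with a common high
mean, log-normal baseline means for other genes, two planted fold-change
blocks (up in escaping+amoeboid, up in amoeboid only) that create the
phenotype structure clustering should find, and a planted fraction of
failed cells (default 8 of 44, the cell-count split 12/16/16 mirroring the
study design) whose expected counts are uniformly scaled down — a failed
library, not biology.

What the generator does *not* emulate: point-spread functions,
photobleaching, depth-dependent attenuation, touching-cell clumps, doublet
libraries, gene-gene correlation, batch structure. Passing tests therefore
demonstrate the correctness of the measurement and filtering machinery on
idealized data, not robustness to every artifact of real microscopes and
sequencers.

## Numerical choices and degenerate inputs

* Voxel centers are the physical coordinates (`(i-1) * spacing`); z grows
  away from the imaging face; all operations honor anisotropic spacing.
* Widest-slice ties go toward the imaging face; equal-volume largest
  components tie to the lowest label with a warning.
* Cells touching the volume border are measured with a warning and a mesh
  closed at the border; single-slice masks crop to themselves with
  `z_depth = 0`; empty masks are errors for cropping/splitting but only a
  warning for segmentation (an all-background image is a legitimate
  observation).
* `smoothing_scale = 0` returns the raw spheroid surface; negative scales
  are errors. Ellipse fits require at least five boundary points and
  reject degenerate (collinear) boundaries.
* Problem sizes in the test suite are chosen for desk-scale verification:
  stacks up to ~1.5M voxels, spheroids of 40-90 um radius, count matrices
  of 44-600 genes x cells. These sizes keep the full suite under a minute
  while exercising every code path at resolutions where the documented
  tolerances hold.

## Known limitations

* The volume estimator inherits the sphere approximation; strongly
  aspherical spheroids bias `V` by construction of the formula, not by
  implementation error.
* Surface areas on objects under ~6 voxels across are only accurate to
  ~5-10%; sphericity comparisons should use adequate sampling (the 3%
  guarantee assumes spacing at most a tenth of the smallest semi-axis).
* Distances are voxel-center to voxel-center; sub-voxel surface
  localisation is not attempted, so distances carry an uncertainty of
  about one voxel diagonal.
* No cell tracking: all per-day metrics are population-level, and
  "cumulative" escaped counts assume escaped cells do not re-attach or
  leave the imaged hemisphere.
* Attached escaping cells are 26-connected to the spheroid mass and are
  therefore part of the spheroid component after segmentation; they are
  excluded from escaped-cell counts by design (escaped = detached), and
  their separate quantification requires the reference-surface route, not
  component splitting.
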