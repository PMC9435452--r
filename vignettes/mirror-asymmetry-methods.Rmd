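---
title: "Quantifying facial asymmetry against the mirrored surface: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying facial asymmetry against the mirrored surface: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirrormorph)
```

## The measurement problem

Progressive hemifacial atrophy (Parry-Romberg syndrome and the related
linear scleroderma en coup de sabre) removes soft tissue from one side of
the face, usually in children and adolescents. Monitoring whether the
condition is still active is hard precisely because the patient is
growing: the whole face changes shape between visits, so two captures
taken months apart cannot simply be subtracted. The mirroring approach
sidesteps growth entirely by making each capture its own control: reflect
the facial surface across the midsagittal plane, register the reflection
back onto the original, and measure how far the two surfaces are apart.
A perfectly symmetric face gives zero everywhere; a one-sided lesion
shows up as a localized band of large distances. Because original and
mirror come from the same capture, growth, weight change and pose cancel
by construction.

`mirrormorph` implements this measurement as a deterministic pipeline on
triangle meshes (millimetre units throughout), plus a synthetic-face
generator that produces capture series with known ground truth, so every
stage can be validated without patient data.

## The pipeline

For one capture the analysis runs these stages, each exposed as an
exported function and composed by `analyze_timepoint()`:

1. **ROI cropping** (`crop_roi`). Confounding regions (typically the neck
   and hair line) are excluded. Clinical tools do this interactively; here
   the ROI is declarative (`roi_spec`: whole, halfspace, sphere, or
   landmark polygon) so a run is reproducible from its configuration
   alone. Faces are kept only when all three vertices pass the predicate,
   which avoids creating sliver triangles at the boundary.
2. **Midsagittal plane** (`estimate_midsagittal_plane`). With three or
   more midline landmarks (nasion, subnasale, pogonion, ...) the plane is
   their least-squares fit. Without landmarks it is estimated
   automatically: the three principal planes of the vertex cloud are
   scored by the mean distance between a reflected vertex sample and the
   original surface, and the best candidate is refined by symmetry
   registration — reflect the mesh, register the reflection onto the
   original with ICP, extract the mirror plane of the composed improper
   transform (its linear part always has a real eigenvector with
   eigenvalue -1; that direction is the refined normal), and iterate to a
   fixed point. We score all three principal planes rather than assuming
   the normal is the least-variance axis because for a facial shell the
   width and depth variances can be close, and starting from the wrong
   principal plane would hand the refinement a reflection it cannot
   recover from.
3. **Mirroring** (`mirror_mesh`). A Householder reflection of the
   vertices; face winding is reversed so outward normals stay outward.
4. **Rough alignment** (`rough_align`). Centroid plus principal axes,
   with axis signs fixed by the third moments of the vertex projections:
   the two most-skewed axes determine their own sign (for a face, the
   height axis via the chin-forehead asymmetry and the depth axis via the
   nose) and the third axis completes a right-handed frame. This is
   deterministic and equivariant under rigid motion, which the pose
   invariance of the whole pipeline depends on. Landmark pairs, when
   available, use the closed-form Kabsch fit instead.
5. **Fine alignment** (`icp_align`). Iterative closest point with true
   point-to-triangle correspondences against an axis-aligned bounding-box
   tree (built in C++; ties between equidistant triangles go to the
   lowest index for determinism). Source points are sampled
   uniformly-by-area with a fixed seed (default 5000 per run).
   Correspondences beyond 10 mm or whose normals disagree (cosine < 0.5)
   are rejected, in the trimmed-ICP spirit: a genuine lesion has no true
   counterpart on the mirror and must not drag the global fit. Updates
   are point-to-plane (linearised least squares) after three stabilising
   point-to-point iterations; a candidate point-to-plane step is kept
   only if it reduces the closest-point RMS of the accepted set
   (re-evaluated with one extra surface query), otherwise the Kabsch step
   is taken, so the recorded per-iteration RMS never increases.
   Convergence is declared when the RMS changes by less than 1e-4 mm
   (or is itself below that), capped at 100 iterations.
6. **Distance map** (`signed_distance_map`). For each original vertex,
   the closest point on the registered mirror. The sign follows the
   rendering convention of clinical distance maps: positive (green) where
   the mirrored surface lies outside the original — the contralateral
   side carries more volume — and negative (red) where it lies inside.
   Zero distances take sign + by convention. Distances are measured from
   the original vertices to the mirrored surface (one well-defined
   per-vertex map, needed for colouring); a symmetrised average is
   available via `symmetric = TRUE`.
7. **Summary** (`summarize_asymmetry`, `build_longitudinal_table`).
   T_mean is the mean absolute distance in mm, T_sd its population
   standard deviation (divide by *n*; the choice is documented because
   conventions differ). `pct_within[c]` is the unweighted percentage of
   vertices with absolute distance <= c, inclusive, for cut-offs 1, 2 and
   5 mm by default. Area weighting is available as a flag but off by
   default, keeping the statistic transparent ("percentage of surface
   points"). The longitudinal table prints T_mean to one decimal and
   percentages as whole numbers, with full-precision columns kept
   alongside in the CSV.

## What the synthetic faces emulate

`generate_base_face()` builds a paraboloid-like open shell over an
elliptical domain (default half-axes 60 x 90 x 35 mm, about an adolescent
face) with a midline nose ridge, paired brow and cheek bumps and a chin
bump. Every height term depends on x only through x^2 and vertices are
generated in +-x pairs, so the base face is mirror-symmetric to the last
bit — the null case of the whole pipeline is exact, not approximate.

`apply_atrophy()` displaces vertices inward along their own normals with
a smooth radial falloff (Gaussian truncated at three radii, or a raised
cosine), emulating one-sided tissue loss that follows the surface
orientation. Defaults place the lesion on the mid-cheek with a 15 mm
falloff radius; depths are scenario parameters (0-6 mm covers the range
from sub-clinical to severe).

`simulate_series()` adds the confounds of longitudinal paediatric
imaging: global growth as a cumulative scale factor per visit (applied
about the origin, which lies on the symmetry plane, so growth commutes
exactly with mirroring; the lesion centre and radius scale along),
Gaussian acquisition noise along the vertex normals (default sigma
0.3 mm, the reproducibility scale reported for clinical
stereophotogrammetry systems, whose system error is about 0.2 mm), and a
random rigid pose per capture (up to 5 degrees and 10 mm by default —
enough to exercise rough alignment, small enough to stay inside ICP's
basin). Everything is a pure function of its parameters and seed.

What the generator does **not** emulate: realistic human shape variation
(no morphable model), differential regional growth, texture, hair,
expression, and capture artefacts such as holes or topological noise.
Passing the simulation suite therefore shows that the *measurement
machinery* is correct and unbiased under growth, pose and noise — it
does not certify performance on every real-world capture pathology.

## A geometric point worth stating: the mirror shows d, not 2d

A lesion of depth *d* on one cheek produces a distance map whose peak is
approximately *d*, not 2*d*. Reflecting across the midsagittal plane
maps the *healthy* side onto the lesion site, so at the lesion the
original (dented by *d*) is compared against the reflected healthy
contour — a gap of about *d*; the same gap appears mirrored on the
contralateral side of the map. One might intuit a doubling ("the mirror
bulges where the original dents"), but that would require the reflection
to map the lesion onto itself, which only happens for a midline lesion —
and there the dent cancels instead. Measured across depths 1-6 mm the
pipeline's peak-to-depth ratio is 0.86-0.87 (slightly below 1 because
the displacement follows tilted normals and the registration distributes
a small part of the misfit). A practical consequence: a lesion shallower
than about 2 mm leaves the whole surface within the 2 mm cut-off, so the
1 mm band is the sensitive one for early change — consistent with how
the cut-off ladder is read clinically.

## Numerical choices and degenerate inputs

* Closest-point queries are exact point-to-triangle (Ericson's region
  classification) over an AABB tree; the brute-force all-triangle scan is
  kept in the test suite as the oracle and agrees to well below 1e-9 mm.
* Binary PLY is written with double-precision coordinates so round-trips
  are bit-exact; OBJ uses 12 significant digits. OBJ indices are 1-based
  on disk and in memory (the R convention); PLY's 0-based face indices
  are converted at the I/O boundary only.
* Plane orientation is normalised by flipping the normal so its
  largest-magnitude component is positive; the two orientations describe
  the same plane, and a fixed rule keeps logs comparable across runs.
* Degenerate faces (repeated indices) and out-of-range face indices are
  rejected at construction; zero-area faces get zero normals rather than
  NaN; meshes may be open shells (facial captures are never watertight)
  and unreferenced vertices are dropped by the generator because an
  off-surface vertex has no meaningful surface distance.
* ICP raises an error naming the failing iteration if every
  correspondence is rejected; `analyze_timepoint()` wraps each stage so
  errors name their stage.
* All randomness (sampling, noise, pose) derives from explicit seeds;
  one run-level seed is fanned out per stage through a fixed hash of the
  stage name, so stages stay independent but reproducible.

## Validation sizes

The test and validation suites run the full pipeline at 20,000 vertices
for the exact-null case (under a second for the analysis itself), and at
3,000-8,000 vertices for the multi-run studies: 10 arbitrary rigid
pre-transforms (T_mean deviation stays below 1e-3 mm), 20 ICP recovery
cases (errors below 1e-3 degrees and 1e-3 mm against constructed truth),
10 noise-floor seeds (with 0.3 mm noise and no lesion, more than 95% —
measured ~99% — of the surface stays within 1 mm, and T_mean stays near
0.3 mm, far from lesion-scale values of several mm), and graded-depth
series whose T_mean increases strictly with the simulated depth. These
sizes were chosen as the smallest at which the statistics are stable;
the pipeline itself has no size-dependent switches.

## Known limitations

* The midsagittal plane of a severely asymmetric face is itself pulled
  slightly toward the lesion by the symmetry refinement; landmark
  override exists for such cases. The same is true of the clinical
  procedure this mirrors.
* Values are not corrected for the baseline asymmetry of healthy faces
  (population estimates differ by an order of magnitude); interpretation
  of the 1 mm band should keep that in mind, while the 2 and 5 mm bands
  are far above any physiological asymmetry.
* Rigid registration only, by design: the comparison is within a single
  capture, so scale or non-rigid alignment would absorb exactly the
  signal being measured.
* Vertex-count percentages weight dense mesh regions more than sparse
  ones; area weighting is available but changes the statistic's
  definition and is therefore opt-in.
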