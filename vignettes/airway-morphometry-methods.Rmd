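---
title: "Upper-airway CT morphometry: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Upper-airway CT morphometry: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airwaymorph)
```

## The problem

Morphometric evaluation of the pharyngeal airway on CT — volume, length,
surface area, the minimum cross-sectional area (MCA) and derived shape
indices — is used to characterize obstructive sleep apnea anatomy and to
quantify the effect of surgical or orthodontic treatment. Repeated scans of
the same person differ even without any intervention, because posture,
mandible and tongue position and breathing phase all move the soft-tissue
walls. Separating such test–retest noise from real change requires (a) a
deterministic measurement pipeline and (b) the agreement statistics that
turn paired measurements into a smallest detectable difference (SDD).

`airwaymorph` implements both halves: a landmark-driven segmentation and
measurement pipeline for airway CT, and the cohort statistics (relative
differences, intraclass correlation, Bland–Altman limits, SDD). Because real
paired CT scans cannot ship with a package, it also contains a first-class
synthetic phantom generator whose geometry is analytic, so every measurement
has an independent quadrature ground truth.

## Coordinate frame and reference plane

All coordinates are millimetres in a right-handed frame with +x left,
+y anterior, +z superior. The Frankfort Horizontal (FH) plane is constructed
from three cephalometric fiducials — by convention both porions and the
(left) orbitale; the source literature does not pin down which orbitale, so
the fiducial names are arguments, not assumptions. `reorient()` rotates the
volume about a point on that plane until its normal is +z; thereafter every
"axial" slice and every cutting plane is parallel to FH. The paired scan is
aligned by rigid least-squares superimposition of the shared fiducials
(Kabsch / orthogonal Procrustes with a det = +1 constraint). This replaces
voxel-based cranial-base registration: phantoms carry exact fiducials, so a
closed-form, deterministic alignment is both sufficient and testable; an
intensity-based method could be slotted in where `superimpose()` is called.

Airway landmarks: PNS (posterior nasal spine), TUV (uvula tip), TEP
(epiglottis tip), BEP (epiglottis base), and the derived midpoint
MUE = (TUV + TEP) / 2. PNS is a bony landmark: the pipeline localizes it on
the first scan only and reuses it for the second. A direct consequence of the
midpoint construction is that the oropharynx (TUV to MUE) and tongue-base
(MUE to TEP) slabs always have identical lengths.

## Segmentation rules and their interpretation

The lumen is extracted and cleaned in four steps. Each step mimics a manual
workflow whose exact algorithm was never published, so the operationalization
below is a documented *interpretation*, flagged as such:

1. **Threshold.** Air is HU **strictly below** −400 (`threshold_air()`); a
   voxel at exactly −400 is tissue. Whether the original interactive tools
   applied <, ≤ or partial-volume smoothing is unknowable; strictness is our
   fixed convention and is tested.
2. **Crop.** Keep voxels between the horizontal planes through PNS (superior)
   and BEP (inferior), and drop everything anterior to y(PNS) throughout the
   slab — a single sagittal-normal cut, the simplest reading of "a cut-off at
   the PNS point". Voxel centers exactly on a plane are kept; all plane
   comparisons use a 1 µm tolerance so lattices derived from landmark heights
   do not produce float ties.
3. **Islands.** 3D components (26-connectivity) that fail to intersect *both*
   boundary slices are removed. "Spanning top-to-bottom" is the operational
   reading of "loose air parts": the breathing path must span the slab,
   anything that does not is loose. If nothing spans (pathological input) the
   largest component is kept and a warning raised.
4. **Dead space.** Seeded slice descent: on the top slice keep the 2D
   component (8-connectivity) containing the seed (default: most posterior
   foreground voxel; ties go to the most posterior component centroid); on
   each lower slice keep the 2D components overlapping the kept set of the
   slice above. Pockets that open upward — the mouth space and the valleculae
   — are connected to the lumen only through a re-ascending path and are
   thereby excluded. The attachment channel itself, and the pocket sliver at
   channel height, are in-plane connected to the lumen and therefore
   *survive* this rule; that residue is inherent to the definition, small,
   and visible in the phantom tests.

Regions are then cut by horizontal planes through the landmarks into
velopharynx, oropharynx, tongue base and epiglottis slabs. Intervals are
half-open (lower-inclusive) so the four regions partition the cropped mask
exactly; the velopharynx is additionally closed at the PNS plane so a voxel
sitting exactly on it still belongs to exactly one region.

## Parameters

For the total airway and each region (units in parentheses; SA′ denotes the
closed surface including the planar caps):

| parameter | definition |
|---|---|
| V (mm³) | foreground voxels × voxel volume |
| L (mm) | boundary plane distance `z_top − z_bottom` |
| SA (mm²) | lateral (open) surface, without top and bottom |
| SA′ (mm²) | SA plus the two planar caps |
| MCA (mm²) | minimum per-slice area; ties go to the most superior slice |
| LAT (mm) | widest left–right extent over the MCA slice's rows |
| AP (mm) | anteroposterior extent on the midsagittal column of the MCA slice |
| meanCSA (mm²) | V / L |
| LAT/AP | ratio at the MCA slice |
| uniformity | MCA / meanCSA ∈ (0, 1] |
| sphericity | π^(1/3) (6V)^(2/3) / SA′ (1 for a sphere) |

Extents add one voxel pitch to the center-to-center distance (voxels are
cells, not points), which converges to the true extent as spacing shrinks.
If the midsagittal column misses the MCA slice (a crescent-shaped lumen),
the column through the slice centroid is used and a warning emitted. A
zero-area slice strictly inside the slab is a data error — a cleaned airway
must be continuous — never silently treated as MCA = 0.

## Surface estimation

Surface area is the only parameter where naive voxel counting fails badly:
summing exposed voxel faces overestimates oblique and curved walls (≈ +50 %
on spheres, +27 % on cylinders), which would wreck sphericity. The default
`"mesh"` method therefore:

1. replicates the top and bottom boundary slices outward so the slab has no
   artificial rims inside it;
2. smooths the padded binary mask with a separable Gaussian of σ = 1 voxel;
3. extracts the 0.5-level isosurface by **marching tetrahedra** (six
   tetrahedra per cell — no large case tables, identical topology guarantees);
4. sums the areas of triangles whose centroids lie inside the boundary slab —
   this is SA, the open lateral wall;
5. adds flat, pixel-counted caps at the two boundary slices to obtain SA′.

Step 1 + 4 is the load-bearing choice: smoothing a mask with sharp z-cut ends
rounds their rims and biases SA′ low (≈ −3 to −4 % on a short cylinder at
0.5 mm), while not smoothing leaves staircase bias of +3 to +9 %. Clipping an
extended mesh to the slab sidesteps both: at 0.5 mm the cylinder lateral wall
is recovered to ±0.3 %, sphere area at 0.25 mm to ±0.2 %, and sphericity of a
height-equals-diameter cylinder to ±0.3 % — comfortably inside the package's
acceptance bands (2 % V, 4 % SA, 1 % sphere sphericity). σ = 1 voxel sits on
a broad plateau (0.9–1.2 all pass); it is a smoothing radius for the
estimator, not a tunable model parameter. The `"voxel_face"` variant remains
available as a cross-check, and is exact for axis-aligned boxes.

## The phantom: what it emulates, and what it does not

`phantom_spec()` describes an air-filled tube (HU −1000) in a soft-tissue
block (HU +40) with Gaussian noise (default SD 10 HU — the default HU values
straddle the −400 threshold with such margin that segmentation is noise-proof
by design). The tube has an elliptical cross-section with prescribed area
profile A(t) and lateral-to-anteroposterior ratio r(t); `default_phantom_spec()`
uses a 66 mm axis, a 220 mm² baseline constricted to 80 mm² by a Gaussian
narrowing, and r = 2.6, numbers chosen to match a typical adult pharynx
(total length ≈ 66 mm, total MCA ≈ 80 mm², LAT/AP ≈ 2.6). Two upward-opening
pockets (mouth, vallecula) exercise the dead-space rule, two detached air
blobs exercise the island rule, and the landmark fractions put the region
cuts at anatomically plausible heights. Every feature exists because exactly
one cleanup rule needs it; the geometry is otherwise minimal.

Because the geometry is analytic, `analytic_truth()` computes V by Simpson
quadrature of A(t), SA by a 2-D surface-integral quadrature of the elliptic
tube (including the slope term from varying semi-axes and center line), MCA
by profile minimization refined with `optimize()`, and the derived indices
from their defining formulas — all to ≤ 1e−6 relative error and entirely
independent of any voxelization. Truth describes the *clean lumen*: pockets
and islands are by definition not part of the airway.

The paired-scan model (`perturb_phantom()`) multiplies the area profile by
`1 + a·sin(2πk t/L + φ)` with random phase and low order
k ∈ {0.5, 1, 1.5, 2} — smooth, bounded in [1−a, 1+a], with unit expectation
over phases (so T1/T0 volume ratios average to 1), and closed under the
quadrature truth. Landmark fractions of TUV/TEP/BEP are jittered (PNS never
moves); an optional anterior bowing term perturbs the center line. The
default amplitudes (a = 0.15, jitter SD 1 mm, bend 1 mm) are stated world,
**not** calibrated to any published variation table — the source study does
not decompose its variation into causes, so no calibration target exists.
Consequences worth knowing before reading test output:

* the ellipse ratio is not perturbed, so analytic-truth cohorts have exactly
  constant LAT/AP and the ICC of that parameter is degenerate (flagged
  `"undefined"`, not silently 0 or 1);
* phantom walls are smooth and high-contrast; real scans add partial-volume
  blur, motion, and soft-palate/wall contact, none of which are modeled. A
  green phantom test establishes the *pipeline's* correctness, not scanner
  robustness.

## Statistics

For paired vectors t0, t1 (one operator, two time points, n subjects):

* relative difference `100·|a−b| / ((a+b)/2)`, summarized per parameter and
  region by its mean/SD/min/max over subjects;
* ICC, default **ICC(2,1)** — two-way random effects, absolute agreement,
  single measurement — because interchangeability of the two scans is what a
  test-retest question asks; ICC(3,1) and ICC(1,1) are selectable. The Fleiss
  benchmarks classify ≤ 0.40 poor, ≤ 0.75 fair to good, > 0.75 excellent
  (boundaries to the lower class, since the quoted rule uses strict
  inequalities on both sides). Zero total variance raises a classed error —
  callers that tabulate (like `summarize_cohort()`) record `NA` +
  `"undefined"` rather than a fabricated number;
* Bland–Altman with differences d = t0 − t1, the sample (n−1) SD and fixed
  1.96 multipliers (the conventional constant, not a t-quantile), and
  SDD = 1.96·SD(d).

`summarize_cohort()` emits one row per parameter × region — 10 × 5 = 50 rows
for a complete cohort — with the descriptives, relative differences, ICC,
Bland–Altman fields and SDD, i.e. the canonical layout of a test-retest
airway study.

## Worked example

```{r example, eval = FALSE}
spec <- default_phantom_spec(noise_sd = 0)
ph   <- make_phantom(spec, seed = 1)
seg  <- segment_airway(ph$volume, ph$landmarks)
measure_airway(seg$mask, seg$partition)          # 5 rows, 13 parameters
ph$truth                                         # quadrature ground truth

cohort <- make_paired_cohort(10, seed = 1)
long <- do.call(rbind, lapply(cohort, function(s) rbind(
  parameters_to_long(analytic_truth(s$spec_t0), s$subject_id, "T0"),
  parameters_to_long(analytic_truth(s$spec_t1), s$subject_id, "T1"))))
summarize_cohort(long)                           # 50-row variation report
```

## Numerical conventions, edge cases

* Plane/voxel comparisons: 1e−6 mm tolerance; voxels on a plane belong to
  the upper slab.
* MCA ties: most superior slice. Seed component ties: most posterior
  centroid.
* Degenerate coincident landmarks (e.g. z(TUV) = z(MUE)) give an empty
  region and NA parameters with a warning, not an error; *misordered*
  landmarks are an error.
* Empty inputs, bad seeds, zero denominators and zero-variance statistics
  raise classed conditions (`aw_empty_input`, `aw_seed_error`,
  `aw_undefined_parameter`, `aw_undefined_statistic`, ...) so callers can
  distinguish data problems from bugs.
* Determinism: one integer seed feeds named sub-streams (geometry vs noise),
  so toggling noise never changes geometry; identical inputs give
  bit-identical outputs.
* File formats are deliberately minimal self-contained implementations
  (NIfTI-1 axis-aligned, DICOM explicit-VR little-endian uncompressed): the
  deployment environment offers no imaging I/O library, and the package's
  correctness burden is on the measurements, not on exotic header variants.
  Files the reader cannot represent faithfully are rejected with a format
  error rather than silently reinterpreted.

## Known limitations

* Cross-sections are strictly FH-parallel; centerline-perpendicular
  (curved-planar) areas are out of scope by design.
* The dead-space rule retains attachment channels (see above); on the
  default phantom this inflates the tongue-base region volume by ~10–15 %
  relative to the clean-lumen truth. Region-level accuracy claims are
  therefore stated on pocket-free phantoms.
* SA′ is not additive across regions (each internal cut contributes a cap to
  both neighbors); the open SA is additive to ~1 %.
* The DICOM reader handles the axial, uncompressed, explicit-VR
  little-endian subset only, and ignores oblique orientations.
* ICC confidence intervals and mixed-effects extensions are out of scope.
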