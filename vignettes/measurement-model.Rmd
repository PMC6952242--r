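---
title: "Scale-invariant 3D measurements: model, phantom and evaluation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scale-invariant 3D measurements: model, phantom and evaluation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caliper3d)
```

`caliper3d` implements, headlessly, the measurement machinery of an
immersive volume-rendering viewer: a transform scene graph, measurements
anchored to the image, and the statistics used to compare measurement
tools against each other. This vignette is the package's own account of
the science: the model and its assumptions, the tunable parameters and
their defaults, what the synthetic generators emulate (and what they do
not), and the numerical choices made where the design was genuinely open.

## The scene-graph measurement model

### Poses and composition

A node's local pose is translation–rotation–scale (TRS): a point `p` in a
node's frame maps to its parent's frame as `t + R (s ∘ p)`, with `R` a
rotation stored as a unit quaternion (normalised on construction, checked
to 1e-9) and `s` a positive per-axis scale. World coordinates are
right-handed, the medical-imaging convention; nothing measured depends on
handedness, and the triple-product tests assert it. One world unit is one
metre by convention, matching viewers whose physics world parallels the
real world.

Composition multiplies the 4×4 homogeneous matrices and re-decomposes into
TRS. The product of two TRS poses is TRS-representable exactly when no
anisotropic scale sits *above* a rotation in the chain; a product whose
linear part contains shear is rejected with a dedicated error rather than
silently approximated. This is deliberately stricter than game engines,
which happily carry skewed world matrices, but it is exact for every
configuration this system needs — image geometry keeps anisotropy inside
the voxel-to-physical affine (not the node scale), and user zoom is
uniform. The same rule motivates `accumulated_uniform_scale()`: the zoom
correction below is only defined for uniform zoom, so anisotropy along the
reference path (beyond a 1e-6 relative tolerance, under which the
geometric mean is used) is an error, not a guess about engine behaviour.

### Anchoring and the reference scale

A volume is attached to the scene with a millimetre-to-world factor `k`
(default 1000: mm of anatomy to a world of metres). The factor lives in
the mapping between physical mm space and the volume node's local frame,
*not* in the node's transform scale — the node's scale carries only user
zoom, starting at 1, and the node is flagged as the scene's unique
*reference scale*. A measurement is created as a child of the volume node,
so it translates, rotates and zooms with the image; its five children
(start, end, dashed connector, label, label connector) are plain scene
nodes.

The measured distance is computed in world space and divided by the
reference node's accumulated zoom `z`:

\[ d_{mm} = k \, \lVert x^{world}_{end} - x^{world}_{start} \rVert / z. \]

Why world space? The alternative — reading endpoint positions in
volume-local coordinates — is simpler and equally zoom-invariant, but it
breaks the moment a point is edited, because editing re-parents the point
under the controller and its local position is no longer in volume space.
The world-space-with-inverse-zoom form stays correct mid-edit. The package
implements both: the world-space form is primary, and
`measured_distance_volume_space()` is retained as an independent
cross-check that must agree (to 1e-9 relative) whenever nothing is
grabbed; the tests exercise exactly that dual route.

Editing is `reparent_keep_world()`: recompute the node's local pose
against the new parent so its world transform is unchanged, preserving the
world position of the whole subtree. Grab records the original parent;
release restores it. Grabbing the connector redirects to the measurement
node, so the whole five-child prefab moves rigidly. Pose-preservation
assertions use a 1e-9 tolerance throughout.

### Display

Markers and labels should keep constant *world* size under zoom, so their
render meshes are scaled by `1/z` (`marker_render_scale()`, with
`marker_render_scale(z) * z = 1` exact). The dashed connector is laid out
as `n = max(1, floor((d + gap) / (segment + gap)))` equal segments centred
symmetrically on the chord; segment length and gap default to 2 mm at
reference scale, and marker geometry (1 mm sphere, 4 mm spokes) is carried
as parameters in the sidecar format — all three defaults are arbitrary
display choices, documented as such, since only the endpoints enter any
measured quantity. Displayed distances are quantized to the tool's display
precision with ties away from zero, the common clinical display rule; the
rounding rule is exposed as a parameter because the commercial tools'
behaviour at exact ties is not documented. The tie is resolved on the
decimal value (an epsilon absorbs binary representation error, so 3.45 at
0.1 mm precision reads "3.5 mm").

### Coordinate conventions

Physical space is LPS millimetres (the DICOM convention); NIfTI's RAS
affine is converted on read and write by negating the first two affine
rows. Continuous voxel indices are 0-based at voxel centres:
`physical = origin + direction · (spacing ∘ ijk)`. MetaImage files are
read and written with a minimal reader/writer (plain-text header + raw
little-endian block, `TransformMatrix` listing the axis direction cosines
column by column), cross-validated against SimpleITK's implementation
during development; NIfTI I/O goes through RNifti. NIfTI stores affines in
single precision, so geometry round-trips to ~1e-7 relative through NIfTI
and exactly through MetaImage.

## The synthetic phantom and the automated caliper

### What is emulated

The phantom generator emulates an ultrasound calibration phantom
containing cylindrical low-scatter ("cyst") inserts of known diameter —
by default three parallel cylinders of 4, 6 and 10 mm, which measured both
horizontally and vertically give six sizing tasks. Voxels inside a
cylinder take the insert intensity (0.1), others the background (0.6);
optional multiplicative unit-mean Rayleigh speckle (σ = √(2/π), drawn by
inverse CDF from a seeded uniform stream) is applied, then an isotropic
Gaussian blur (default σ = 0.3 mm, separable shifted-sum convolution with
replicated edges) stands in for the system point-spread function.

This is an *appearance* emulation sufficient to exercise calipers and
observer models — deliberately not an acoustic simulation: there is no
beamforming, attenuation, shadowing, or depth-dependent resolution. The
phantom's documented insert diameters are the only geometry the reference
hardware fixes; insert depth/length, echogenicity values and scan
resolution are not published, so the defaults (40×30×20 mm volume, 0.2 mm
voxels, 14 mm-long cylinders staggered in depth so each horizontal profile
clears its neighbours) are declared package choices. Consequently, tests
passing on this phantom demonstrate the *measurement machinery* —
geometry, invariances, edge localisation — not performance on clinical
ultrasound texture.

### The caliper

Humans size a cyst by placing calipers on opposite edges.
`measure_insert_diameter()` automates the same judgement with the standard
half-contrast criterion: sample the intensity profile from the insert
centre outward along ± the probe direction (trilinear interpolation,
default step half a voxel); estimate the insert plateau as the mean within
1 mm of the centre and the background plateau from the outer 70–95% of
each side's reach; find on each side the first crossing of
`insert + 0.5 (background − insert)` and localise it by linear
interpolation between the straddling samples. The diameter is the distance
between the two crossings (full width at half contrast). The threshold
fraction and plateau window are parameters; 0.5 is the standard choice for
cyst sizing. Thresholds derived from plateau means make the estimate
exactly invariant to affine intensity rescaling. Degenerate profiles —
too short, no contrast, no crossing inside the volume — raise typed
"edge not found" errors.

On noise-free phantoms the caliper recovers truth within one voxel at
every spacing tested (0.4/0.2/0.1 mm, non-increasing error), and at 0.1 mm
recovers the 10 mm insert to 10.000 mm and the 4 mm insert to 3.991 mm —
the two quantities `scripts/acceptance.R` recomputes. With speckle on, the
mean over 50 seeds stays within two voxel spacings of truth.

## The observer-study simulator

The study protocol is a fixed task list: six phantom sizings plus, per
patient dataset, five standard echocardiographic dimensions (aortic valve
hingepoint and left atrial dimension in parasternal long axis at systole;
LV end-diastolic dimension in short axis at diastole; LV end-systolic and
aortic end-systolic dimensions in short axis at end systole). Four patient
datasets plus the phantom give 26 tasks per participant.

`simulate_observer()` corrupts each task's true length the way caliper
placement does: both endpoints of the segment receive independent
isotropic Gaussian noise of the tool's per-endpoint σ, and the *length of
the perturbed chord* is recorded, plus an optional additive bias, clipped
at zero, then quantized at the tool's display precision. Perturbing
endpoints rather than lengths matters: it induces the correct noncentral-χ
length distribution, including the positive bias that appears when σ is
not small against the true length. The tests check the induced SD against
an independent Monte-Carlo oracle of the chord length to within 5%.

Default tool models: display precisions 0.1 / 1 / 0.1 mm for the
QLAB-like reference, the Tomtec-like and the VR-like tool — these are the
tools' published read-out granularities — and per-endpoint σ of 0.25 /
0.45 / 0.70 mm. The σ values are a calibration, not ground truth: the
induced length SDs (≈ √2 σ = 0.35 / 0.64 / 0.99 mm) sit inside the
0.2–1.9 mm range of SDs reported for phantom sizing by the three real
tools. Biases default to zero. Patient-task truths (typical paediatric
values 18–45 mm with small fixed per-dataset offsets, patient mean
≈ 29 mm) match the scale of a real session; phantom truths are the insert
diameters.

Invalid records ("incorrectly recorded" observations) are simulated by
drawing the stated number of distinct (user, dataset, measurement)
instances without replacement and invalidating one tool's record within
each — a random tool, or a fixed one. Fixing the omissions on the
reference tool makes every pairwise comparison lose exactly that many
pairs, which is how a study with 5 users × 20 patient measurements and 5
omissions yields paired t-tests on 94 degrees of freedom for *both*
comparisons; scattering single records across three tools could let two
omissions collide on one pair and would only reproduce that structure by
luck.

## Evaluation statistics

All SDs use the sample (n−1) denominator; the population/sample choice is
not stated by the tools being emulated, and n−1 is the reporting norm.
Zero SD must be representable (identical quantized values produce it —
a real phenomenon at 1 mm display precision), and is distinct from an
undefined SD (a single record), reported as `NA`.

* **Phantom summary** — per insert × axis × tool: mean, sample SD, |mean −
  truth|, with per-row best-accuracy (smallest mean error) and
  best-precision (smallest SD) flags.
* **Agreement** — differences tool − reference over pairs matched on
  (user, dataset, measurement), invalid or unpaired records dropped by
  pairwise deletion and counted; mean, SD, the count of |diff| strictly
  below the 2 mm threshold ("less than" is read as strict), and an OLS
  regression of tool on reference *with* intercept (forcing through the
  origin would hide additive bias, the quantity of interest). A constant
  reference makes the regression degenerate; it is flagged, not fitted.
* **Paired t-test** — `t = mean(d) / (sd(d)/√n)`, `df = n − 1`, two-sided
  p (the convention consistent with the reported use of such tests), plus
  each sample's mean and SD. Authored from the closed form so degenerate
  inputs are explicit: identical samples give a "no variation" result with
  undefined t; zero-variance non-zero-mean differences give signed
  infinity with p = 0. `stats::t.test` serves as the cross-check oracle in
  the tests, never the implementation.
* **Intra-user variability** — for each (user, dataset, measurement)
  instance seen by ≥2 tools, each tool's deviation from the instance's
  cross-tool mean; per (user, tool), the sample SD of those deviations.
  Single-tool instances carry no cross-tool information and are excluded
  with a count.

### Calibration properties

Because the real study's raw measurements are not published, the
statistics are validated by construction instead: under the null (two
identical tool models, σ = 0.5 mm, precision 0.1 mm) the paired t-test
rejects at α = 0.05 in 5% ± 1.5% of 1000 replicate simulated studies; an
injected −1.57 mm tool bias is recovered by the agreement mean difference
to within Monte-Carlo error (≈ 0.006 mm SE over 200 replicates); and
coarsening a tool's display precision from 0.1 to 1 mm does not reduce the
SD of paired differences in expectation. These are the package's
acceptance properties, run by the test suite at those problem sizes
(chosen to keep the full suite around a minute on one core).

## Known limitations

* TRS-only poses: configurations requiring shear (anisotropic scale above
  a rotation) are rejected by design; engines that tolerate them will
  accept scenes this package refuses.
* The phantom emulates appearance, not acoustics; caliper accuracy on it
  upper-bounds what clinical speckle, gain dependence and anisotropic
  point-spread would allow.
* The observer model has no learning, fatigue, or per-structure
  difficulty; every task of a tool shares one σ.
* 4-D (cine) data are handled only as a `frame_index` tag in the sidecar
  format; vendor ultrasound DICOM must be converted to NIfTI/MetaImage
  upstream.
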