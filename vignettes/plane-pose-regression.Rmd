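---
title: "Plane pose regression in 3D ultrasound: model, data and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plane pose regression in 3D ultrasound: model, data and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Obstetric ultrasound operators must mentally reconstruct where a 2D imaging
plane sits inside the 3D fetal anatomy. `planepose` addresses the computational
version of that skill: given a single 2D grayscale slice of a 3D volume,
estimate its full 6D pose — translation $t \in \mathbb{R}^3$ and rotation
$R \in SO(3)$ — relative to the volume (brain) centre, with no tracking
hardware and no per-subject volume at inference time. The estimator is a
regression CNN; everything else in the package exists to train and evaluate
it reproducibly: an oblique-plane slicer standing in for a 3D visualisation
environment, a procedural speckle phantom standing in for scanned phantom
volumes, pose samplers that build labelled datasets, and Table-style error
reporting.

## The model

The network maps an image $I$ to nine numbers
$\theta = (t_1, t_2, t_3, r_1, \dots, r_6)$. The first three are the
normalized translation. The last six are the *continuous 6D rotation
representation*: the first two columns of the rotation matrix. In the forward
pass the matrix is reconstructed by Gram-Schmidt orthonormalization,

$$e_1 = \frac{v_1}{\lVert v_1\rVert},\quad
u_2 = v_2 - (e_1\!\cdot\!v_2)\,e_1,\quad
e_2 = \frac{u_2}{\lVert u_2\rVert},\quad
R' = (\,e_1\; e_2\; e_1\!\times\!e_2\,),$$

with $v_1 = (r_1,r_2,r_3)$, $v_2 = (r_4,r_5,r_6)$. This representation is
continuous over $SO(3)$ — unlike Euler angles, quaternions or axis-angle,
which have discontinuities that regression networks handle poorly — and the
projection guarantees a valid rotation for *any* head output. The map is
invariant to rescaling of $v_1$ and to the component of $v_2$ along $v_1$;
inputs with $\lVert v_1\rVert$ or $\lVert u_2\rVert$ below $10^{-8}$ raise an
error at the user-facing API (inside the training kernel the norms are
clamped at $10^{-8}$ so a pathological minibatch cannot produce NaNs).

The training loss is

$$\mathcal{L} = \underbrace{\tfrac1N\sum \lVert R' - R\rVert_F}_{\text{rotation}}
 \;+\; \lambda\, \underbrace{\tfrac1N\sum \lVert t' - t\rVert_2}_{\text{translation}},
 \qquad \lambda = 0.01 .$$

Both terms are means of *plain* norms; a `squared = TRUE` flag switches to
mean squared norms, because regression losses of this family are often
squared and the choice is worth exploring — the plain form is the default.
The rotation term is backpropagated *through* the Gram-Schmidt projection
(the analytic Jacobian is implemented in the C++ kernel and is checked
against finite differences in the test suite). For rotation matrices
$\lVert R'-R\rVert_F \le 2\sqrt2$, attained at 180°-apart orientations.

Errors are reported as the paper-standard pair: Euclidean translation
distance in mm (normalized units denormalized with the evaluated volume's own
extent, since normalized coordinates are volume-relative) and the geodesic
rotation error
$\arccos\!\big((\operatorname{tr}(R_1^\top R_2)-1)/2\big)$ in degrees, with
the trace argument clamped to $[-1,1]$. Note the relative rotation is
$R_1^\top R_2$ — both orientations enter; a formula using only the
prediction's inverse would not measure a distance to ground truth.

## Backbones

Two backbones share the 9-output contract:

* `resnet18` — the standard 18-layer residual topology (7×7 stride-2 stem,
  four stages of two basic blocks, global average pooling). It is the
  reference architecture for this task at full scale but is not practical to
  train on a single CPU; the package builds and runs it (shape tests, forward
  passes, finite-difference gradient checks) from random initialization.
  Externally pretrained weights are a documented toggle that errors, because
  no weight files ship with the package.
* `smallconv` — the CPU-trainable variant: five 3×3/5×5 conv-BatchNorm-ReLU
  blocks (32, 64, 128, 128, 256 channels; strides 2,2,2,1,2) and a split
  head. Rotation is regressed linearly from globally averaged features.
  Translation gets its own spatially aware branch — a 1×1 conv reducing to
  16 channels, flattened, then a 64-unit MLP to 3 outputs; pooling the
  translation branch too was tried and underfits (position information does
  not survive global averaging), while flattening the full 256-channel map
  memorizes desk-scale training sets. The split is deliberate: with
  $\lambda = 0.01$ the translation
  loss contributes almost nothing to the shared trunk's gradient, but Adam's
  per-parameter normalization means any parameter whose gradient comes
  *only* from the translation term still takes full-sized steps. A dedicated
  branch therefore learns translation at full speed without touching the
  $\lambda$ the protocol fixes. The global-average-pooled rotation head is
  equally deliberate: an earlier flatten-based head memorized desk-scale
  training sets without generalizing.

## Geometry conventions

One set of conventions is used everywhere and recorded in every manifest:

* Euler angles are intrinsic Z-X-Y, right-handed, degrees, stored as
  $(\alpha_x, \alpha_y, \alpha_z)$ with matrix
  $R_z(\alpha_z)R_x(\alpha_x)R_y(\alpha_y)$. The angle branch is
  $\alpha_x \in [-90°, 90°]$, the others in $[-180°, 180°)$; at gimbal lock
  ($\alpha_x = \pm90°$, where only a combination of the other two angles is
  observable) the tie-break sets $\alpha_y = 0$ and folds everything into
  $\alpha_z$. The source environments of such datasets rarely document their
  convention, so it is isolated in a single named constant
  (`EULER_CONVENTION`) and written into every artifact.
* Translations are normalized per axis so the volume spans $[-1, 1]$
  ($t_{norm} = t_{mm} / (\text{extent}/2)$); angles live in degrees in all
  files, radians only inside math kernels.
* The slice plane lies in its local x–y plane (z = plane normal), pixel
  centres at $(j - \tfrac12 - \tfrac{res}2)\cdot\frac{fov}{res}$; a plane
  point maps into the volume as $p_{vol} = R\,p_{plane} + t_{mm}$ (rotation
  about the volume centre, then offset). Voxel $k$ (0-based) sits at
  $(k + 0.5)\,\text{spacing} - \text{extent}/2$ mm; trilinear interpolation,
  fill value 0 outside (ultrasound background is black); a sample point is
  inside the volume iff $|p| \le \text{extent}/2$ per axis, and interpolation
  coordinates are clamped to the voxel-centre range at the boundary.

## The synthetic phantom

The generator replaces scanned phantom volumes with a procedural stand-in
whose only obligations are (a) *pose identifiability* — no rotation or mirror
symmetry, structure everywhere — and (b) ultrasound-like texture:

* a bright ellipsoidal skull shell (semi-axes 44% of the extent) around
  darker parenchyma;
* smooth seeded "value-noise" parenchyma texture (two octaves, coarse grids
  of 7³ and 13³ control points) so *every* interior region carries pose
  information — real tissue is textured everywhere, and without this a
  network can only memorize speckle instead of reading anatomy;
* a midline echo tilted 8° (so the midline is not a symmetry plane), two
  unequal dark ventricles at asymmetric offsets, a bright focal body and a
  posterior lobe;
* multiplicative speckle: voxelwise $\mathrm{Gamma}(4,4)$ noise (mean 1)
  smoothed with a one-voxel (1,2,1) kernel — fully developed speckle has a
  correlation length of about one resolution cell, not white voxel noise —
  entering as $v\,(1 - s + s\,\text{noise})$ with strength $s = 0.3$ by
  default, baked into the volume so texture is a fixed landmark field
  consistent across slices.

Defaults are a 64³ grid at 1 mm isotropic spacing (64 mm cube — fetal-brain
scale at mid-gestation). What the phantom does **not** emulate: attenuation,
shadowing, refraction, fan-beam geometry, probe-dependent point-spread
anisotropy, inter-subject anatomical variability, or motion. Passing tests on
this phantom therefore demonstrates that the geometry, representation and
optimization machinery work — not that the trained weights transfer to real
scans.

The phantom's "standard plane" is a fixed documented oblique pose
(`phantom_standard_plane()`: Euler (8°, −5°, 12°), translation
(0.04, 0.06, 0.10)) chosen to intersect the midline, the larger ventricle and
the focal body — the role a sonographer-annotated transventricular plane
plays for real data.

## Pose sampling and datasets

Random-pose (`RP`) planes draw each translation component uniformly in
±0.5 normalized units and each Euler angle uniformly in ±45°, then reject
poses whose slice overlaps the volume by less than 0.75 (all three values are
package defaults, recorded in every manifest; the rejection loop errors after
1000 consecutive failures rather than looping forever; `min_overlap = 0`
disables rejection, covering the reading that the source data constrained
ranges only). Near-standard-plane (`SP`) planes perturb the annotated pose
with per-axis uniform translation and rotation whose intervals ramp
*linearly* from 0.1 to 0.001 normalized units and from 7.9° to 1.9° across
the sequence — a linear schedule is the simplest reading of "decreased
from … to …", and the ramp endpoints are exposed as configuration.

Datasets are written as 8-bit grayscale PNGs plus a CSV manifest carrying the
normalized translation, Euler angles in degrees, subset tag and achieved
overlap per row, under a `# key: value` header with the Euler convention,
field of view, resolution and seed — files are self-describing and
re-slicing any row reproduces its PNG to within the 8-bit quantization step.
Poses live only in the manifest, never in filenames.

## Training protocol

`train_config()` defaults mirror the reference protocol: Adam
($\beta_1 = 0.9$, $\beta_2 = 0.999$), learning rate $10^{-4}$, batch size
100, 50 epochs, $\lambda = 0.01$ (selected over 0.1 and 0.001 at full
scale), a seeded 20% validation split, 128 px inputs, checkpoint selection
by minimum validation total loss. Training is deterministic given the seed,
which covers split, shuffling and initialization (He-normal draws from R's
RNG); no augmentation is applied because the reference protocol mentions
none. Inference-time preprocessing resizes preserving the aspect ratio and
centre-crops, scaling intensities to $[0,1]$ only — no further
normalization, the simplest defensible default.

The desk-scale phantom experiment (`run_phantom_experiment()`) is the
package's own scaled-down protocol sized for a single CPU: the default 64³
phantom, 4000 random-pose training slices and a test set of 500 random +
100 near-SP slices at 64×64 px, `smallconv`, 10 epochs. Within that fixed
epoch budget the recipe (`phantom_experiment_config()`) uses batch size 8
with a cosine learning-rate decay from $2\times10^{-3}$ to
$8\times10^{-5}$: on a short schedule the number of optimizer updates is
the binding constraint, so small batches and a decaying rate buy most of
the attainable quality. The trained model is compared against the strongest
constant predictor — the per-axis mean translation and the chordal
(SVD-projected) mean of the training rotations.

```{r}
library(planepose)
exp <- run_phantom_experiment(seed = 1)
print(exp$eval)
exp$summary$rot_improvement_factor
```

## Numerical choices and degenerate inputs

* Gram-Schmidt degeneracy threshold $10^{-8}$ on $\lVert v_1\rVert$ and
  $\lVert u_2\rVert$; errors at the API, clamps inside the training kernel.
* $\arccos$ arguments clamped to $[-1,1]$; geodesic distances are exact at
  0°, 90° and 180° on constructed pairs.
* Even-length medians are the midpoint of the central pair (R's default).
* Fully out-of-volume slices return all-zero images with overlap 0 rather
  than erroring; constant images are valid network inputs.
* Manifest numerics are written with `%.17g`, which round-trips IEEE
  doubles exactly.
* BatchNorm uses batch statistics in training and running averages
  (momentum 0.1) at evaluation; the running buffers are part of the
  checkpoint.

## Known limitations

* The phantom's realism is intentionally minimal (see above); reported
  phantom errors say nothing quantitative about real fetal scans.
* `resnet18` is provided and verified but not CPU-trainable at realistic
  scale; `pretrained = TRUE` errors because no weights ship with the
  package.
* The slicer models a parallel (linear-array) geometry; curvilinear
  fan-beam acquisition and volume-to-volume registration are out of scope.
* Euler conventions of external annotation sources must match the package
  convention; manifests and annotations refuse to load otherwise rather
  than silently reinterpreting angles.
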