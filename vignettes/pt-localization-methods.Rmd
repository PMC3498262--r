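---
title: "Locating the pyramidal tract relative to deep-seated tumors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating the pyramidal tract relative to deep-seated tumors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Thalamic and basal ganglia tumors displace — but, because the internal
capsule is a densely packed fiber corridor, do not encase — the pyramidal
tract (PT, the corticospinal tract). Before surgery the PT's position
relative to the tumor must be known, and when tractography is unavailable it
has to be inferred from anatomical landmarks. `ptclock` implements a
complete, testable version of a landmark-based prediction pipeline: tumors
are classified into eight types from three lines drawn on the axial slice
through the foramen of Monro, and each type maps to a characteristic
clock-face position of the PT around the tumor. The pipeline is exercised
end to end on digital tensor phantoms with analytic ground truth.

## Models and procedures

### Diffusion tensor fit

Each voxel's diffusion tensor $D$ is estimated from the Stejskal–Tanner
relation $S_j = S_0 \exp(-b_j\, g_j^\top D\, g_j)$ by log-linear least
squares: one design row per volume maps the six unique tensor components
plus $\log S_0$ to the log signal. Signals are floored at
$10^{-6} S_0$ before the log; negative eigenvalues from noisy fits are
clamped to zero for the derived maps but kept for diagnostics. FA uses the
standard definition
$\mathrm{FA} = \sqrt{3/2}\,\lVert\lambda-\bar\lambda\rVert / \lVert\lambda\rVert$
and ADC is the eigenvalue mean. The fit method and FA formula are the field
defaults; the clinical software behind the original cohort does not document
its internals, so these are stated assumptions of this package, not imported
facts.

### Tensor-deflection tracking

Streamlines are propagated bidirectionally from every seed-VOI voxel center
with the deflection update
$v_{k+1} = \mathrm{normalize}(0.2\, v_k + 0.8\, e_1)$, where $e_1$ is the
major eigenvector (sign-aligned to the incoming direction) of the tensor
interpolated component-wise (trilinear) at the new position. The parameter
set is the clinical protocol: FA threshold 0.2, turning-angle threshold 30
degrees per step, step size 1/3 of the smallest voxel dimension, minimum
retained length 50 mm. A march terminates when the next position leaves the
volume, local FA falls below threshold, or the turn exceeds the angular
threshold; a safety bound of $10\times$ (volume diagonal / step) caps runaway
marches. Numerical checks compare the propagator against an independently
written pure-R integrator at a 10-fold finer step (agreement within one
voxel Hausdorff distance on smooth curved fields).

Tract selection follows the three-VOI protocol: seeds cover the presumed PT
course; retained streamlines must intersect a precentral-gyrus VOI, cross a
cerebral-peduncle VOI with craniocaudal orientation (majority of in-VOI
tangents with $|t_z|$ exceeding the in-plane norm — the protocol gives no
numeric criterion, so this operationalization is ours), avoid all exclusion
masks, and reach 50 mm. Discarded streamlines record the first test they
failed.

### Landmark geometry and the clock face

All analysis happens on the axial slice containing the foramen of Monro
(slab convention: a point exactly on a slab boundary belongs to the lower
slice). Right-sided tumors are mirrored to the left hemisphere first;
mirroring is an involution and preserves the tract–tumor sector because the
anatomical frame flips its lateral axis with the hemisphere. Three lines are
built from landmarks supplied with each case (they are drawn manually in
clinical practice, so automatic detection is out of scope): line 1 vertical
through the anterior-limb vertex of the internal capsule; line 2 horizontal
through the foramen of Monro; line 3 horizontal through the junction of the
middle and lateral thirds of the posterior limb in the normal hemisphere,
taken as the point 2/3 of the way from the genu end to the posterior end.
This matches the reported typical PT position at about 64% of the posterior
limb.

The clock face is anchored anatomically: 12 o'clock anterior, 3 lateral, 6
posterior, 9 medial (after mirroring to the left hemisphere). Sectors are
eight 45-degree bins centered on the four axes and the four diagonals, with
boundaries at center ±22.5 degrees and the lower boundary inclusive. The
binning convention is an artifact decision — the original classification was
done by expert reading — and is tested exhaustively at 0.1-degree
resolution.

### Tumor typing

Areas are voxel counts on the Monro slice; a voxel exactly on a line goes to
the lower-coordinate side. When an abnormal-signal extent mask accompanies a
small enhancing core (core covering under half the extent), the extent
drives classification; the 50% trigger is our operationalization of the
qualitative clinical rule. Types 1 and 2 are "centered" tumors whose slice
centroid lies within 0.15 mask-widths of line 1 (tolerance configurable; no
clinical value exists), split posterior/anterior by line 2. Otherwise the
majority quadrant decides: posterior-lateral type 3, posterior-medial type
4, anterior-lateral type 5, anterior-medial type 6. Types 3 and 4 carry
subtype A when the posterior mass lies mostly beyond (posterior to) line 3
and B when it lies mostly between lines 2 and 3. The source descriptions of
the subtype convention conflict between the methods figure and the results
narrative; this package follows the results-consistent reading (A = beyond
line 3), which also matches the reported PT positions. Exact 50/50 area ties
raise an error demanding manual adjudication rather than silently guessing.

The prediction rule is a frozen total lookup: T1→12, T2→6, T3A→9–12,
T3B→6–9, T4A→12–3, T4B→3, T5→6–9, T6→3–6.

### Operator agreement

Two operators are simulated as two tracking runs whose seed VOIs differ by a
one-voxel dilation. Their voxelized tracts (a voxel is on if any streamline
point falls in it) are compared by Cohen's kappa over a restricted universe:
the brain/phantom mask limited to the axial slabs spanned by either tract,
since a whole-volume universe inflates kappa through empty background. The
exact universe used in the clinical reproducibility literature is not
restated in our source, so the restriction is a documented assumption. Cases
with kappa below 0.7 are excluded; the boundary value is included.

## The phantom: what it emulates and what it does not

The generator reproduces the acquisition geometry — 96×96×60 grid at
1.9×1.9×3 mm, b = 1000 s/mm², 12 Fibonacci-spread directions plus one b0,
five signal averages, Rician noise at a per-acquisition b0 SNR of 25
(default) — and the anatomical situation: an isotropic background (ADC
0.7×10⁻³ mm²/s), a craniocaudal PT-like tube (radius 4 mm, FA 0.70, gentle
S-curve) through the left internal-capsule corridor, and an ellipsoidal
tumor (in-plane semi-axis ~10 mm, craniocaudal 15 mm) whose center sits, for
each type, on the ray from the bundle's Monro-slice point at the clock angle
that type predicts, inside the region the three lines dictate. A smooth
radial displacement field (amplitude 4 mm at the surface, exponential decay
with ellipsoidal distance, scale 0.6) pushes the bundle outward; generation
fails loudly if the displaced centerline does not clear the tumor surface by
at least one voxel. Because displacement is radial from the tumor center,
the bundle's Monro-slice point moves along its own clock ray, so the
analytic truth sector equals the predicted sector *by construction* — the
end-to-end test is whether fitting, tracking, gating and classification
recover it through the noisy signal, not a voxel-level tautology.

Seed-dependent jitter (±0.5 mm center, ±0.6 mm radius) keeps replicates
distinct without leaving the type's region. The landmark set places the
anterior-limb vertex at the bundle's mediolateral position, consistent with
the observation that the vertical landmark line intersects the posterior
limb approximately at the PT.

What the phantom does **not** model: real head anatomy, crossing or fanning
fibers, partial-volume effects at the tube boundary, EPI distortion, eddy
currents, infiltrative tumor margins (beyond the optional FA-damping shell),
or inter-subject variability. Passing the in-silico concordance test
therefore shows the pipeline's internal consistency under the stated
geometry and noise, not clinical accuracy on patients.

## Numerical choices

* Tensor interpolation at off-grid points is component-wise trilinear with
  clamped faces, followed by eigen-decomposition.
* The initial direction at a seed is ±e₁ at the seed point (bidirectional);
  the two half-tracks are concatenated through the seed.
* The deflection's orthogonal-boundary case (incoming direction exactly
  perpendicular to e₁ with a zero resultant) terminates the streamline.
* Percentages round half-away-from-zero at 2 decimals by default with a
  per-call 1-decimal override, matching the printed style of the source
  cohort (which mixes both precisions).
* Seeding density is one seed per seed-VOI voxel center, keeping runs
  deterministic; all stochastic steps (noise, jitter) are seeded and
  restore the caller's RNG state.
* Problem sizes in the shipped experiments — 8 types × 5 replicates at SNR
  25, 40×40×40 oracle fields, 12×12×8 noise-recovery grids — were chosen to
  give stable statistics while keeping the full suite comfortably
  reproducible on a laptop.

## Known limitations

* The clinical software's exact deflection operator is unknown; the wording
  "20% previous direction, 80% major eigenvector" is implemented literally
  rather than as the full tensor-deflection operator $D\,v_{in}$.
* With a shared fitted field and deterministic seed-set perturbation, the
  two simulated operators' tracts share their core, so kappa stays high
  (≥ ~0.8) whenever both tracts exist; severely compromised corridors
  collapse tract construction to zero retained streamlines for both
  operators before a mid-range kappa can arise. The constructed failure
  case (SNR 10 plus FA-damping shell) is therefore excluded through the
  no-tract pathway, while the kappa threshold itself is verified directly
  on constructed mask pairs. Reproducing a mid-range kappa end to end would
  need operator-dependent preprocessing (registration, eddy correction),
  which is out of scope.
* Typing uses the single Monro slice, as the lines are defined there;
  volumetric majority voting is out of scope.
* The source cohort's "correlation analysis" between PT and tumor position
  names no statistic; this package reports per-type concordance rates
  instead.
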