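---
title: "Quantifying orthodontic clean-up from 3D surface scans: methods and design"
author: "adhevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying orthodontic clean-up from 3D surface scans: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

After a fixed orthodontic appliance is debonded, adhesive remnants must be
removed from the enamel ("clean-up"). Every clean-up technique trades
effectiveness (how much adhesive it removes) against safety (how much
enamel it abrades). Structured-light 3D scanning makes both quantities
directly measurable: a tooth is scanned intact (T0), after debonding with
adhesive remnants present (T1), and after clean-up (T2), all in a common
rack frame. Four endpoints summarize the outcome per tooth, all in mm³:

* **AV** — adhesive volume: material of T1 above T0;
* **RAV** — residual adhesive volume: material of T2 above T0;
* **dAV = RAV / AV** — fraction of the initial adhesive that survived
  clean-up (dimensionless);
* **EVL** — enamel volume loss: material of T0 above T2.

`adhevol` implements the full computational chain from STL mesh triplets to
these endpoints and to the group-level statistics comparing clean-up
treatments, plus a synthetic scan generator with closed-form ground truth
so that every stage is testable without physical specimens.

## Pipeline

### Rigid best-fit registration

Scan sessions share the rack frame only approximately; T1 and T2 are
brought into the T0 frame by a rigid best fit restricted to regions
unaffected by bonding. The fit is iterative closest point with
point-to-plane residuals: correspondences are closest points on the
reference surface (exact point-to-triangle distance through a uniform
spatial grid), residuals are projected on *smoothed* face normals (the
mean of the three vertex normals — raw facet normals of a noisy mesh with
0.075 mm edges carry ~0.1 rad of noise and destabilize the solve), and
correspondences beyond 3× the median distance are rejected each
iteration. The 6-DOF update is the standard linearized point-to-plane
solve with an exact Rodrigues retraction, so returned rotations are
orthonormal to machine precision. Iteration stops when the RMS improves
by less than `tol` (default 1e-6 mm) or after `maxIter` (50) iterations;
a worsening step is discarded, so the accepted RMS sequence is monotone.

The stable region can be given explicitly (vertex indices or a geometric
predicate). When it is not, `alignTriplet()` reproduces the operator's
manual selection in two passes: a robust full-surface fit first (the 3×
median rejection suppresses the adhesive zone, which occupies only a few
percent of the scanned patch), then a deviation map locates the bonded
zone and the fit is repeated on vertices farther than 1 mm from its
deviation-weighted centroid. The two-pass scheme exists because the
bonded-zone location is itself an output of registration; a single
masked pass would need the answer before computing it.

A post-alignment RMS above 0.2 mm raises a divergence warning. This
threshold is an engineering choice (roughly 10× the scanner error bound);
surfaces from the same tooth align far below it, mismatched teeth far
above.

### Signed deviation and ROI placement

`signedDeviation()` maps each test vertex to its closest reference point;
the sign is positive when the test point lies along the reference's
outward normal (material above — adhesive), negative below (material
loss). Vertices with no reference surface within the search radius
(default 0.5 mm) are flagged unmatched and excluded from summaries.

The analysis is restricted to a 5 mm × 5 mm square covering the bracket
zone. In the original workflow this square is positioned manually;
`placeROI()` automates it: the ROI center is the deviation-weighted
centroid of T1-vs-T0 deviations exceeding the clearance, and the local
viewing axis (+z, "top view") is the mean outward normal of the reference
patch under the square. A manual override is echoed exactly, which keeps
the automated placement a default rather than a constraint.

### Clipping, closed shells, Boolean volumes

The four lateral faces of the ROI prism are cutting planes:
`clipToROI()` splits crossing triangles exactly at the planes
(intersection vertices are cached per edge, so the clipped patch stays
topological without any merge pass) and returns the patch in ROI-local
coordinates. `closeShell()` extrudes the patch boundary down to the ROI
bottom plane and closes it with a flat square, giving a watertight,
outward-oriented solid whose volume is computed by the divergence
theorem. All three conditions share the bottom and side surfaces by
construction, so volume differences are insensitive to the bottom plane's
exact position (the pipeline lowers it automatically if a surface dips
below).

`booleanDifferenceVolume(a, b)` integrates the height-field difference of
the two shells on a regular lateral grid (default step 0.010 mm, cell
centers, half-open ROI interval so boundary rays are counted once).
Heights come from vertical ray casting against the shell triangles. Two
clearance semantics are implemented because the metrological convention
"Boolean subtraction with a clearance of 0.020 mm" admits both readings:

* **offset** (default): the reference surface is offset by +clearance, so
  only material thicker than the clearance counts, and only its excess —
  the measured volume of a patch of footprint area A is reduced by about
  clearance × A;
* **threshold**: the full deviation is counted wherever it exceeds the
  clearance.

The clearance default (0.020 mm) equals the scanner's certified maximum
measuring error; measured volume is monotone non-increasing in the
clearance in both modes, and the mode is recorded in every report row.

An independent **voxel-counting oracle** (`voxelOracleVolume()`, default
voxel 0.005 mm) rasterizes both shells into voxel columns and counts
voxel centers inside `a` and not inside `b` (dilated upward by the
clearance in offset mode). The test suite holds the integrator to within
0.5% of this oracle across analytic and composite fixtures in both
modes.

### Endpoint statistics

Volume endpoints are strongly right-skewed, so the group comparison runs
on power-transformed values v → max(v, floor)^p with floor 1e-6 mm³ (a
volume printed as "<0.001" stays finite and the transform monotone). The
canonical exponents are 0.125 for RAV, 0.225 for dAV and 0.25 for EVL;
`selectPower()` additionally offers a grid search (0.025…1 by 0.025) that
maximizes the minimum per-group Shapiro–Wilk p-value. Exponents whose
minimum p lies within 0.05 of the best are treated as ties and resolved
toward the *larger* exponent — the milder, more interpretable transform.
Without this tolerance the argmax wanders among statistically
indistinguishable exponents on near-normal data; with it, already-normal
groups select the identity transform and the selection-induced
perturbation of the downstream ANOVA's type-I error is negligible (the
test suite checks 5% ± 1% over 2000 null replicates).

ANOVA and Tukey HSD are the standard fixed-effects procedures
(`stats::aov`, `stats::TukeyHSD`, Tukey–Kramer for unequal n); the
Shapiro–Wilk test is Royston's AS R94 as implemented in
`stats::shapiro.test`. Undefined dAV values (AV below 1e-6 mm³) are
flagged NA and excluded from group statistics rather than coerced — a
ratio with a vanishing denominator carries no information about clean-up
efficacy. The a-priori sample-size computation uses the two-group normal
approximation n = ⌈2 (z₁₋α/₂ + z₁₋β)² / d²⌉ with d = Δ/σ; with α = 0.05,
power 0.8, Δ = 0.006 and σ = 0.007 it gives d = 0.86 and n = 22 per
group.

## The synthetic study

`generateStudy()` emulates the in-vitro study design: 3 treatment groups
× 25 teeth, each tooth a fresh crown surface with a bonded-then-cleaned
history and three "scans".

**Surface model.** A single-valued height field on an 8 mm × 8 mm patch
at the scanner's nominal point spacing (0.075 mm): a smooth dome (crown
curvature radii 9/11 mm), perikymata-like ripples (amplitude 0.005 mm,
wavelength 0.1 mm), and seed-random multi-scale anatomical undulations
(total amplitude 0.25 mm over wavelengths 3/1.5/0.8 mm, coarse scales
strongest). The undulations are not decoration: a smooth dome alone is
degenerate under tangential slide + tilt (a laterally shifted paraboloid
differs from itself by an exact plane), so without larger-scale anatomy a
rigid best fit cannot recover the session pose — real teeth supply this
anatomy for free. The grid's triangulation alternates its diagonal per
cell; a uniform diagonal direction biases closest-point correspondences
under noise by ~0.01 mm.

**Adhesive and clean-up.** The adhesive patch is a spherical cap with
closed-form volume πh²(3r−h)/3, drawn lognormal (median ≈ 0.55 mm³)
within 0.1–1.5 mm³; its height grows with volume (0.45–0.9 mm) so
remnants are dome-like rather than film-like. Clean-up scales the
adhesive height toward the baseline by a group-specific removal fraction
(Beta families with mean residual fractions ≈ 0.40/0.115/0.20 for the
three treatments) and carves enamel-loss dents — inverted spherical caps,
depth ≤ 0.48 mm (under a 0.5 mm physical bound), placed on a ring around
the adhesive footprint so dents and residual adhesive never overlap and
the recorded ground truth stays exact. Per-group enamel-loss volumes are
right-skewed lognormal (means ≈ 0.18/0.19/0.29 mm³) within
0.001–1.104 mm³. The group contrasts make the transformed ANOVA behave
qualitatively like the published treatment comparison; this is an
emulation choice, not a replication claim.

**Scanner model.** Each condition receives independent Gaussian vertex
noise along the surface normal with σ = 0.007 mm, so 3σ stays below the
0.020 mm certified error bound; T1 and T2 additionally receive a random
session pose within ±2° / ±0.5 mm per axis, returned for
registration-recovery testing. The generator does not model speckle,
occlusion, stitching seams, varying point density, or outlier points —
passing recovery tests therefore demonstrates correctness of the
geometry/statistics chain under the stated noise model, not robustness
to every artifact of a physical scanner.

**Recovery conditions.** With noise and the 0.020 mm offset-mode
clearance, the pipeline's AV/EVL estimates are expected to land within
~10% (median, for true volumes ≥ 0.05 mm³): the clearance offset alone
removes clearance × footprint ≈ 5–8% of a patch's volume, which is the
price of absorbing scanner error. The "exact data" arm of the validation
therefore runs with σ = 0 *and* clearance 0 — the clearance exists only
to absorb measurement error, and keeping it on noise-free data would
merely re-measure that bias; under exact data the chain is held to ~1%
(discretization only) and dAV to ±0.05.

## Numerical choices

* Units are mm everywhere; STL files carry no units, so this is a fixed
  convention.
* Vertex merge tolerance on STL load: 1e-6 mm (STL stores triangle soup;
  merging makes shared edges topological). Degenerate faces are dropped
  with a message, not an error — scanner exports contain slivers.
* Clip intersections are computed once per (edge, plane) from the lower
  vertex index, so shared edges receive bit-identical intersection
  vertices.
* Volume integration: 0.010 mm grid step (halving it moves results by
  < 0.25%); voxel oracle at 0.005 mm; rays at cell centers on a
  half-open interval per axis.
* ICP: point subsampling to 3000 (deterministic stride), search radius
  0.5 mm with automatic ×4 widening if a pass finds no matches,
  convergence at 1e-6 mm RMS improvement.
* Rotation validity is enforced at 1e-9 (orthonormality and det +1).
* Problem sizes in the shipped validation: the default 75-tooth study at
  full 0.075 mm resolution for recovery checks; smaller 6 mm / 0.1 mm
  meshes for pipeline plumbing tests; 2000 replicates for the null
  calibration of the transformed ANOVA.

## Known limitations

* All surfaces are treated as height fields over the ROI square
  (single-valued along the viewing axis). Undercuts, which real molar
  scans can contain near the gingival margin, would need the exact
  mesh-Boolean backend the integrator's oracle gate is designed to
  admit.
* The automated ROI placement keys on the T1-vs-T0 deviation signal; a
  tooth with essentially no adhesive after debonding needs a manual ROI
  override (the per-tooth JSON override file).
* Registration assumes near-aligned inputs (shared rack frame); there is
  no global feature-based initialization.
* The synthetic generator's distributional families (lognormal volumes,
  Beta removal fractions) are assumptions recorded in its configuration,
  chosen for right-skew realism, not derived quantities.
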