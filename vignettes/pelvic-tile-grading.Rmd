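---
title: "Self-ensembling fracture fusion and Bayesian Tile grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-ensembling fracture fusion and Bayesian Tile grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelvigrade)
```

## The problem

Pelvic ring injuries are graded on the Tile AO/OTA scale — A (stable),
B (rotationally unstable, translationally stable), C (globally unstable) —
and the grade drives triage and operative planning. Radiologists do not
read the grade off the image directly: they look for a small set of
fracture patterns (pubic symphysis diastasis, anteriorly divergent or
parallel sacroiliac joint diastasis, diastatic and non-diastatic sacral
fractures, ischial spine avulsion, other pelvic ring fractures), weigh them
together with patient age, and synthesize the two component instabilities,
rotational (R) and translational (T). `pelvigrade` mirrors that workflow on
top of any per-slice 2D fracture detector: it turns noisy per-slice boxes
into frequency-scored 3D findings, converts them into boolean evidence for
an expert-structured Bayesian network over fracture types, age, R and T,
and reads the Tile grade off the posterior instabilities. Because the
high-specificity operating point a clinical deployment demands will reject
some subtle true fractures, the package also implements a retrieval loop:
the network is asked which rejected low-confidence findings are probable
given everything else that was seen, and sufficiently probable ones are
promoted back into the evidence before the final grade is issued.

The package deliberately does not contain a trained detector. Detections
enter through a plain tabular interface (JSON-lines of
patient/scan/slice/box/type/score), and a simulator stands in for the
detector and a labeled cohort so every stage can be exercised and tested
end to end.

## Preprocessing and the augmentation grid

CT volumes in Hounsfield units are windowed to the bone range: intensities
are clipped to [-10, 1000] HU and linearly rescaled to integers in
[0, 255] (`clip_rescale_hu()`), with half-up rounding throughout so that
results are bit-exact across platforms. Axial maximum intensity
projections (`axial_mip()`) collapse consecutive non-overlapping slabs —
8 mm by default, i.e. `ceiling(8 / z_spacing)` source slices per slab —
into single 2D slices by per-pixel maximum; the trailing partial slab is
kept so no anatomy is lost. A detector operating on such MIP slices sees
"2.5D" context at 2D cost. Restricting to the pelvic region is expressed
as an optional axial slice range rather than an automated cropper.

Self-ensembling inference re-runs the detector over 25 mild photometric
variants of the scan: the Cartesian grid of intensity shifts
{-2, -1, 0, 1, 2} (8-bit units) and contrast factors
{0.8, 0.9, 1.0, 1.1, 1.2} (`augmentation_grid()`). The identity cell
(0, 1.0) serves as the original scan, so K = 25 scans total. The contrast
operation is not uniquely determined by "contrast adjustment"; we chose
multiplication about mid-gray 127.5 followed by the additive shift and a
final clip to [0, 255] — bounded, mid-range-preserving, and configurable.
The perturbations are small by design: fractures must remain visible in
every augmented copy, since the whole point is that detection *failures*,
not detectability, vary across copies.

## From 2D boxes to frequency-scored findings

Within one augmented scan, 2D detections with network score strictly
above 0.5 are linked whenever they share a fracture type, their boxes
overlap in-plane, and they lie on the same or adjacent slices; connected
components become 3D fractures (`fuse_2d_to_3d()`). All coordinates are
0-based and half-open, and a box on slice *s* occupies *z* in [*s*, *s*+1),
which makes the adjacency rule and 3D intersection tests uniform. A
component's cuboid is the minimal axis-aligned box over its constituents
and its network score the maximum over them.

Across scans, 3D fractures of the same type with intersecting cuboids are
again joined into connected components (`fuse_across_scans()`). Each fused
finding's confidence is its *frequency score*: the number of distinct
augmented scans contributing at least one member, divided by K. Two
fragments of one fracture in the same scan therefore count once — this is
what makes the score robust to the per-slice misses that split 3D
fractures within a single scan. "Overlap" means any nonempty half-open
intersection, with no IoU threshold: it is parameter-free and the merge
semantics follow from the component construction. Per-type existence
confidence is the maximum frequency over that type's findings, and two
operating points produce the nested sets FXhigh (confidence ≥ z_high,
default 0.8) and FXlow (≥ z_low, default 0.5). Thresholding uses ≥ so
that the strictest useful setting, z_high = 1.0 (present in every scan),
is attainable.

## The Bayesian grading model

The network (`default_structure()`) has one boolean node per fracture
type plus `age60` (age ≥ 60), `R`, and `T`, with edges age60 → R, age60 → T
and R → fx, T → fx for every fracture node. The generative orientation —
instability explains findings — was a genuine design choice: it keeps every
CPD at no more than four rows, fittable from a few hundred patients, and it
is the orientation under which observing one fracture changes the
conditional probability of another (through R and T), which is exactly what
the retrieval loop exploits. The Tile grade is a derived label of (R, T),
not a node: A = stable, B = R only, C = T (translational instability is the
hallmark of global instability, so the first-order-undefined combination
R = 0, T = 1 maps to C; this is documented and configurable at the mapping
function). Age receives edges only into R and T, matching its role as a
fragility modifier of injury severity rather than a direct cause of
specific fracture patterns.

CPDs are fit by Bayesian estimation with a Laplace pseudocount (α = 1 by
default): P(node = 1 | config) = (n₁ + α)/(n₁ + n₀ + 2α), with unobserved
configurations falling back to 0.5. Inference is exact: every CPD factor
is reduced by the evidence and the joint is summed over the remaining
unobserved variables only, which for these networks (at most 10 boolean
nodes, and in grading queries at most three free variables) is both exact
and fast. The test suite verifies it against an independent full-joint
enumeration oracle to 1e-9, and zero-probability evidence raises an
explicit error rather than returning NaN.

## Grade refinement

Grading conditions on *all* fracture nodes — absent findings are evidence
of absence at the chosen operating point, matching the boolean conversion
of the detection sets — plus the age flag. The initial grade uses FXhigh.
Refinement (`refine()`) then loops: candidates are FXlow \ current
positives; each candidate's *leave-one-out conditional* is computed (its
own state removed from the evidence, everything else fixed); if the best
candidate reaches z* (default 0.5) it is promoted and the loop repeats,
ties broken by the canonical fracture-type order. Additions are greedy and
sequential so each retrieval probability reflects previously accepted
findings; the loop terminates after at most 7 additions and never removes
a high-confidence finding. Candidates come from the full set of findings
at or above z_low (the candidates actually considered, FXlow \ FXhigh, are
the same under either reading of the low-confidence band). The acceptance
rule is a single threshold z* on the leave-one-out conditional; the
per-instability-state conditionals P(fx | R, T) are carried in the result's
audit record so a reviewer can see both views of why a fracture was
promoted. With z* > 1 no candidate can ever be accepted and refinement
degenerates to the initial grade, which the threshold sweep uses as its
endpoint sanity check.

## The synthetic study

The simulator stands in for a private trauma cohort and a trained
detector; it emulates the statistical structure the pipeline consumes, not
CT image content. `generate_cohort()` ancestrally samples age60, R, T and
the seven fracture booleans from generator CPDs over the same network
structure. The default generator CPDs encode clinically sensible
directions — anterior lesions (pubic symphysis diastasis, parallel SI
diastasis, diastatic sacral fracture) load on T, anteriorly divergent SI
diastasis marks purely rotational injury, ring fractures are common in any
unstable pelvis, and both instabilities are more frequent over 60 — with a
35% elderly fraction and base instability rates (R ≈ 0.42, T ≈ 0.30
marginally) typical of bleeding pelvic-trauma admissions. They are
configuration values chosen once, not estimates from any real dataset.

`simulate_detections()` places one random cuboid per true fracture
(10–30 px in-plane, 2–5 slices) in a 160×160×40 volume and emits, for each
of the K augmented scans: the fracture with per-type probability
`d[type]`; per-slice boxes each dropped with probability `m` but never all
of them, so `d` remains the sole per-scan detection probability (this
identifiability is what lets a test pin the mean frequency score to `d`);
±2 px coordinate jitter; and Poisson(λ) false-positive boxes per scan with
random type and position. True-positive scores are drawn from
Beta(8, 2) truncated above the 2D keep threshold — the `d`/`m` miss
processes already account for sub-threshold network scores, so emitted
true boxes are the ones a thresholded detector would report — while
false-positive scores are untruncated Beta(2, 5), so most false boxes are
filtered exactly as a real detector's would be. In the noiseless limit
(d = 1, m = 0, λ = 0) the entire pipeline provably recovers the
ground-truth fracture booleans with type confidence exactly 1.

What passing tests on this cohort do *not* show: the simulator draws
fracture locations independently and uniformly, carries no anatomy, no
bilateral symmetry (a documented source of real false positives), no
correlated misses across neighbouring types, and no reader disagreement in
the labels. Results on it validate the machinery — fusion exactness,
calibration of the frequency score, the direction of the refinement
effect — not clinical performance.

## Evaluation harness

`roc_auc()` is the Mann–Whitney rank statistic with midrank ties;
`cohen_kappa()` the closed 2×2 formula. Both are checked in the tests
against independent reference implementations (pROC, e1071) and small
counting oracles. `cross_validate()` makes patient-level folds stratified
by the translational label (the rarer instability, so folds stay
two-class), fits CPDs on the training patients' ground-truth booleans, and
runs fusion + refinement + grading on the held-out patients; single-class
folds report NA rather than a fabricated number. Hard predictions for
kappa use the same 0.5 posterior cut as grading. `threshold_sweep()`
re-grades the cohort along a z_low or z* grid and reports the AUCs of the
LOW / HIGH / REFINE prediction variants side by side.

The packaged experiments use deliberately desk-sized problems: the
refinement-benefit check runs 10 simulated cohorts of 400 patients
(200 train / 200 test, K = 25, per-type detection probabilities spread
over [0.5, 0.9], λ = 0.2) and asserts that refinement's rotational AUC is
not worse than grading on FXhigh alone by more than 0.01 while never
removing a high-confidence finding; oracle comparisons run on hundreds of
randomized small instances. These sizes were chosen to give stable
averages at interactive runtimes.

## Numerical and degenerate-input choices

* Half-up rounding (`floor(x + 0.5)`) everywhere intensities are
  quantized; base R's round-half-even would make examples platform-honest
  but less legible.
* Empty inputs: an empty detection table fuses to an empty finding table,
  grades as "no findings", and an empty file round-trips; an empty CPD
  training table yields the flat prior 0.5 everywhere.
* Exactly-at-threshold confidences are kept (≥), while the 2D keep
  threshold is strict (>), each matching its operating definition.
* All randomness (cohort, detector, folds) flows from explicit integer
  seeds; per-patient detector sub-seeds are derived from the cohort seed
  so single patients are reproducible in isolation.
* Deterministic ordering: findings sort by (type order, z, y, x); tied
  retrieval candidates resolve by the canonical fracture-type order.

## Known limitations

Refinement can only add findings; rejecting a high-confidence false
positive is out of scope. The evidence model is boolean — confidence
values are thresholded, not used as soft evidence. The network structure
is expert-specified; no structure learning is provided. Boxes are
axis-aligned, and overlap is binary rather than IoU-weighted. The
simulator's independence assumptions are listed above; real-data
performance must be established on real detections, which the tabular
interface is designed to accept unchanged.
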