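---
title: "The partitioned head/neck support model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The partitioned head/neck support model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pillowpart)
```

## The problem

A pillow supports the head and neck over a contact surface whose regions
differ strongly in pressure sensitivity: the temporal bone area tolerates
far less pressure error than the posterior parietal area. `pillowpart`
implements a complete workflow that turns body-pressure-mat recordings and
subjective comfort ratings into (i) a partitioned *ideal support model* —
a reference pressure distribution, its spatial partition into support
zones, and a sensitivity weight per zone — and (ii) a manufacturable
material specification: an equivalent stiffness per zone realized as a
staggered array of drilled pores in memory foam.

## The pressure indices

A recording is a matrix $P$ of contact pressures (kPa) on a regular sensor
grid with pitch $l$ (cm). Four indices summarize it:

* average pressure $P_v = \frac1N\sum_i P_i$ (by default over contact
  cells only, so off-body sensors do not dilute the mean; a global mode is
  retained),
* peak pressure $P_m = \max_i P_i$,
* a per-row gradient $G_i = \sum_j [p(x_i,y_j) - p(x_{i-1},y_j)]\,/\,l$,
  with $G_m = \max_i |G_i|$ and $G_v = \operatorname{mean}_i |G_i|$.

The row-sum form of $G_i$ is the *literal* mode and is the package
default; it is kept verbatim, including its conventional unit label
kPa/cm² (strictly the row sum has units kPa/cm summed over columns — we
document rather than "fix" this). A *pointwise* mode computes the
per-cell central-difference magnitude $\sqrt{g_x^2+g_y^2}/l$ and averages
it **over all mat points**, matching the index definition "arithmetic mean
over all test points": off-body cells carry near-zero gradient, so the
mean is deliberately diluted by the footprint fraction. Whether published
gradient values were computed row-wise or pointwise is not decidable from
their definitions alone; both modes are first-class and every result
records the mode used. Magnitudes are taken in both modes so that
$0 \le G_v \le G_m$ holds for arbitrary fields.

## The ideal matrix and its partitions

Trials are ranked by the subjective comfort total (four 1–5 sub-scores:
softness, wrapping, support, fit), with ties broken by the higher minimum
sub-score and then by trial id, so ranking is deterministic. The top
fraction (default 0.10 of the cohort, rounded **down** with a floor of
one — a 42-trial cohort keeps 4, matching the study design this package
emulates; `round_mode = "ceil"` is available) is averaged element-wise
into the approximate ideal pressure-distribution matrix.

Before averaging, each matrix is translated by an integer cell shift that
moves its center of pressure to the grid center. This keeps anatomically
corresponding peaks aligned without interpolation; it can be disabled
(`align = FALSE`). Integer alignment is a deliberate simplification: when
a center of pressure sits almost exactly between two cells, the rounded
shift can differ by one cell between otherwise similar recordings, which
slightly blurs the average. Sub-cell registration is out of scope.

Matrices are compared by cosine similarity of the flattened grids, which
is 1 exactly for positive scalar multiples and lies in [0, 1] for
non-negative fields.

Partitioning clusters **pressure values only** (1-D fuzzy c-means,
$c = 3$, fuzzifier $m = 2$), then lets spatial structure enter through
post-processing: each contact cell takes its argmax-membership cluster,
clusters are split into 4-connected components, and components smaller
than 1% of the contact cells are merged into the neighbouring region with
the longest shared boundary (ties to the lower label). This is how three
pressure levels can produce *four* lateral regions — two spatially
separate areas may share a level. The reconstruction of "3 clusters, 4
partitions" via connected components is this package's interpretation and
is flagged as such. FCM centers are initialized at evenly spaced
percentiles plus a small seeded jitter; the objective trace is recorded
and is non-increasing by construction of the alternating optimization.
4-connectivity (not 8) is used so diagonal touching cannot bridge
anatomically distinct regions.

Regions are named by position and pressure: supine maps order regions by
pressure-weighted centroid row from the neck edge — posterior neck (A1),
occipital (A2), posterior parietal (A3); lateral maps assign the neck-edge
region to the cervical area (B1), the parietal-edge region to the lateral
parietal area (B4), the highest-mean-pressure central region to the
temporal bone area (B3), and the remaining anterior region to the jaw
area (B2). In strict mode a wrong region count is an error; otherwise
surplus regions get deterministic suffixed names (B4a, B4b, ...).

## Sensitivity weights

Experts compare partition pairs on a nine-level strength scale. Because
the row-sum weighting
$W_i = \bigl(\sum_j V_{ij} + n/2 - 1\bigr)/\bigl(n(n-1)\bigr)$
only yields normalized weights for a fuzzy *complementary* matrix
($V_{ij} + V_{ji} = 1$, diagonal 0.5), nine-level scores are first
converted by $V'_{ij} = a_{ij}/(a_{ij} + a_{ji})$ — order-preserving,
indifference maps to 0.5, reciprocal-consistent.

The consistency test is the compatibility index
$CI = \frac{2}{n(n-1)}\sum_{i<j}\bigl|V_{ij} - 0.5 - (n-1)(W_i - W_j)\bigr|$
with threshold 0.1. The relation $V_{ij} = 0.5 + (n-1)(W_i - W_j)$ is the
one an additively consistent complementary matrix provably satisfies under
the row-sum weighting (summing the consistency identity over $k$ gives
$\sum_k V_{ik} - \sum_k V_{jk} = n(V_{ij} - 0.5)$), so $CI = 0$ exactly
characterizes additive consistency — this is why the package uses the
factor $(n-1)$ rather than $(n-1)/2$ sometimes seen in compatibility
indices.

The hierarchy has a posture layer (B) over the partition layer (C); final
weights are $W^B_g \times W^C_{g,i}$, and multi-expert results are
aggregated by averaging weights (not matrices) with renormalization. The
packaged reference weights decompose into posture blocks 0.320 (supine) /
0.680 (lateral), which is what motivates reading the middle layer as
posture. The weighted comfort score is simply
$\sum_i x_i w_i$ over per-partition ratings; when per-partition subjective
ratings are absent the score is omitted, never imputed.

## Material design

Per partition, the required equivalent stiffness is $k = \Delta F /
\Delta H$: the total supported force over the compression depth at the
partition's anthropometric contour node. Forces come from the ideal
matrix via $\Delta F = \sum P \cdot l^2 \cdot 0.1$ (1 kPa·cm² = 0.1 N);
$k$ is treated as N/mm throughout — the unit system (kPa, cm², N, mm) is
fixed and recorded in outputs. The pore-diameter calibration is fitted as
$d = a k^b$ by ordinary least squares on the log pairs; the packaged
measurement table for 110 mm, 60 D memory foam with a 30 mm staggered
pitch fits $d = 3.613\,k^{-0.769}$ ($R^2 = 0.987$). Predictions are
**clamped** to the calibrated domain $d \in [6, 21]$ mm (never
extrapolated), and clamping is flagged. The layout stage places a
hex-offset lattice at the 30 mm pitch across the pillow footprint, maps
each lattice point to the partition underneath (the partition map scaled
to the footprint bounds, default 500 × 350 mm), and assigns each hole its
partition's diameter; holes cannot overlap because the maximum diameter
(21 mm) is below the pitch.

## The synthetic-data generator

No pressure-mat recordings are distributable, so a seeded generator
stands in for the study inputs. Its defaults encode the emulated
conditions:

* **Grid**: 32 × 32 sensors at 0.6 cm pitch. The pitch was chosen
  together with the footprint extent so that a single parameter set is
  simultaneously consistent with the kPa index bands, the kPa/cm² comfort
  band, and published-magnitude equivalent stiffnesses (N/mm) under
  compression depths that fit inside a 110 mm slab — these constraints
  couple through the cell area, and a coarser pitch cannot satisfy all
  three at once.
* **Templates**: plateau-like support zones (super-Gaussian profiles)
  joined by saddles, plus a single dominant peak dome — the occipital
  apex when supine (three zones), the temporal bone when lateral (four
  zones, jaw separated by a shallow moat, parietal zone joined by a low
  bridge). A binomial smoothing pass keeps transitions at mat
  resolution. Supine templates peak near 8.2 kPa (within the 7.5–9.2
  band of top-comfort supine recordings), contact averages sit near
  1.6 kPa, and the pointwise $G_v$ of ideal matrices falls in the
  0.2–0.4 kPa/cm² comfort band.
* **Cohorts**: 7 pillows × 6 subjects per posture. Pillow $p$ distorts
  the template with severity $(p-1)/6$ (component shifts, width and
  amplitude jitter), so pillow 1 reproduces it; subjects add a small
  idiosyncratic distortion plus spatially correlated sensor noise
  (sd 0.10 kPa).
* **Comfort response**: each sub-score is a rounded, clipped latent
  $5.05 - 34\,(1 - \text{sim}) - 2\,|G_v - 0.3| - 0.5\,\max(0, P_m -
  9.21) + \varepsilon$, $\varepsilon \sim N(0, 0.35)$. The coefficients
  were chosen once so that the top decile of a cohort is dominated by the
  trials nearest the template (required for ideal-matrix recovery) and
  the similarity/comfort rank correlation is strongly positive, while
  integer 1–5 clipping still produces realistic ties. The response model
  itself is an assumption — ordered categorical with a monotone latent —
  not an empirical fit.
* **Contour nodes**: small-male (MS) base depths are calibrated so the
  noiseless templates' partition forces and the packaged per-partition
  stiffness magnitudes are mutually consistent; other groups scale those
  depths by stature ratios (ML 1.081, FS 0.912, FL 1.028), with a small
  node-wise irregularity shared across groups per seed so larger
  physiques are deeper at every node.

What the generator does **not** emulate: real tissue mechanics (bumps are
phenomenological), posture drift within a trial, sensor crosstalk or
saturation, inter-subject anatomical variation beyond smooth distortions,
and any EMG signal content (validity is a boolean flag). Passing tests
therefore demonstrate that the pipeline's logic is correct and stable
under realistic magnitudes — not that it reproduces any particular human
cohort.

## Numerical choices and degenerate inputs

* FCM declares convergence when the largest center shift drops below
  1e-6 (cap 300 iterations; non-convergence is flagged in the result,
  not raised). Points exactly on a center get crisp memberships.
* Cluster relabeling cannot change results: centers are sorted ascending
  and regions relabeled by mean pressure, so the partition map is
  invariant to the jitter seed.
* Empty contact sets, zero-norm matrices in cosine similarity,
  non-complementary judgment matrices (the offending cell is named),
  zero compression depths, and missing manifests are all explicit
  errors.
* All randomness flows through per-call seeds; the pipeline derives
  stage seeds from one master seed, and reruns are byte-identical except
  for the timestamped log.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data
at the study's own scale: 42-trial cohorts (40 for the recovery
property), 32 × 32 grids, 100-seed stability sweeps for the partition
structure, 1,000 random matrices for the algebraic weight identities, and
100 replicate Monte-Carlo panels for expert-weight recovery. These sizes
make every property estimate stable at the tolerances tested while a full
run stays in the tens of seconds.

## Known limitations

* The 3-cluster-to-4-partition mechanism is a reconstruction; other
  readings (e.g. spatially regularized clustering) are possible and out
  of scope, as is automatic selection of the cluster count.
* Literal-mode gradients are row-structured and not rotation-invariant;
  cross-row structure is only captured by the pointwise mode.
* The material model is a single equivalent spring per partition; no
  foam constitutive behaviour, creep, or finite-element verification.
* Integer center-of-pressure alignment can introduce one-cell jitter for
  near-boundary centers, as discussed above.
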