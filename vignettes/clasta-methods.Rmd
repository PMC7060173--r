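---
title: "Toroidal-shift significance testing for two-color SMLM nanocluster detection"
author: "clasta package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Toroidal-shift significance testing for two-color SMLM nanocluster detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clasta)
```

## The statistical model

Single-molecule localization microscopy observes each fluorescent label
many times ("blinking"), so every molecule appears as a tight cluster of
localizations. Univariate cluster analysis therefore cannot distinguish
biomolecular nanoclustering from overcounting. The test implemented here
uses two color channels attached stochastically to the *same* molecular
species: under the null hypothesis that the molecules follow a completely
spatially random (CSR) distribution, the two channels are independent
point patterns, whatever their internal blink structure. Genuine
oligomerization or domain enrichment, by contrast, correlates the
channels, because red- and blue-labeled molecules then co-occupy the same
nanoscale neighborhoods.

Given localization sets $R$ (query, conventionally red) and $B$
(reference, blue) in a rectangular region of interest (ROI), the test

1. computes for every $r_i \in R$ the distance to its nearest neighbor
   in $B$ and forms the empirical distribution $\mathrm{cdf}(r)$;
2. summarizes the curve as
   $g = \int_0^{r_\max} \mathrm{cdf}(r)\,dr$, evaluated exactly through
   the closed form $g = r_\max - \operatorname{mean}_i
   \min(r_i, r_\max)$;
3. repeats the computation $N$ times with the query channel translated
   by a shift vector drawn uniformly over the ROI and wrapped
   periodically at the boundary (toroidal shift). The shift destroys
   cross-channel correlations but leaves each channel's univariate
   structure — including all blinking artifacts — untouched, so the $N$
   control curves sample the null distribution without any model of the
   photophysics;
4. ranks $g_{\mathrm{data}}$ in the pooled set of $N + 1$ statistics and
   reports $p = \mathrm{rank}/(N+1)$.

For a stationary query process on the torus the $N + 1$ configurations
are exchangeable, so $p$ is exactly uniform on the grid
$\{1/(N+1), \dots, 1\}$ under the null: the false-positive rate at level
$\alpha$ equals $\alpha$ whenever $\alpha$ is a grid multiple, and the
smallest attainable p-value is $1/(N+1)$. With the default $N = 99$
controls the grid step is $0.01$ and $\alpha = 0.05$ is exact.

### Statistic variants

* `nn` (default): nearest-neighbor distance; parameter-free.
* `knn`: the mean distance to the $k$ nearest reference localizations
  ($k = 3, 5, 10$ are conventional); smooths single-point noise at the
  cost of a scale assumption through $k$.
* `lcross`: the per-point cross-type Ripley score
  $L_i = \sqrt{\hat K_i/\pi}$, with
  $\hat K_i = (A/n_B)\,\#\{b \in B: \lVert b - r_i\rVert \le r^*\}$ and
  default $r^* = 50$ nm, without edge correction — edge effects are
  shared by data and controls and cancel in the rank. Clustering
  *inflates* $L$, pushing its cdf right and deflating $g$, so the rank
  direction flips relative to the distance statistics (handled
  internally).

### Ranking conventions

Clustering shortens cross-channel distances, so for `nn`/`knn` the rank
is taken in descending order of $g$ (largest $g$ $\to$ rank 1);
`direction = "repulsion"` reverses it. Ties receive the worst rank, a
conservative choice that matters only for degenerate (duplicated)
coordinates. The rejection rule is boundary-inclusive, $p \le \alpha$:
on the discrete grid this makes the null rejection probability exactly
$\alpha$, whereas a strict inequality would give $\alpha - 1/(N+1)$.

### The `r_max` convention

With `rMax = "auto"` the integration limit is the maximum statistic
value occurring in the data *or any control*, so every cdf reaches 1
inside $[0, r_\max]$ and the method has no free parameter. Whether the
maximum should include the controls is ambiguous in principle; including
them makes $g$ comparisons use one common support and is the package
default, while a numeric `rMax` (of the order of the localization error
plus the expected cluster size) restricts the analysis to short
distances when prior knowledge exists. The p-value is typically
insensitive to this choice because a common additive extension of the
support shifts all $g$ values equally.

## The generative model

`simulateExperiment()` composes six stages, mirroring how a two-color
dSTORM experiment produces a localization table:

1. **Molecule placement** (`placeMolecules`): CSR monomers; $n$-mers
   (all $n$ protomers at the oligomer position, since label linkers are
   small on the 30 nm error scale — a configurable Gaussian
   `protomerOffset` exists but defaults to 0); or circular/rectangular
   domains with uniform random centers, per-domain Poisson occupancies
   targeting `total * fractionInDomains / nDomains`, and the remaining
   molecules rejection-sampled outside the domain union. Domains may
   overlap; molecules in overhanging domains are wrapped onto the torus.
2. **Labeling** (`assignLabels`): each molecule independently carries a
   label with probability `efficiency` and is red with probability
   `ratio` — binomial statistics, each molecule in at most one channel.
3. **Blinking** (`simulateBlinking`): each label emits $m \ge 1$
   detections. The default distribution is the ceiling of a log-normal
   with `meanlog = log(3.2)`, `sdlog = 0.8` (mean $\approx 5$
   detections/label, heavy right tail), chosen to match the regime of
   SNAP-tag dSTORM labels where roughly 1,000 molecules yield about
   5,000 localizations; geometric, fixed and user-supplied histogram
   families are available. Frames are i.i.d. uniform by default; a
   burst model (geometric on-/off-times) exists, but only the drift
   stage reads frames, so the uniform default is adequate for the
   questions studied here.
4. **Localization error**: i.i.d. Gaussian displacement with
   $\sigma = 30$ nm per axis by default, identical for both channels.
5. **Unspecific labels and background** (`addUnspecificAndBackground`):
   Poisson-distributed unspecifically bound labels (realistic density
   5/µm² per channel, blinked like the channel's labels) and
   false-positive background signals (1 and 2/µm² for red and blue;
   geometric blinking with mean 2, a stand-in for unlabeled-cell
   background whose empirical statistics are instrument-specific).
6. **Stage drift and chromatic aberration**: a linear drift
   $\vec d \cdot t/T$ applied identically to both channels (alternating
   excitation shares the stage), and the linear radial field
   $\beta\,(x - x_0, y - y_0)$ applied to the red channel only.

Two presets bundle the conventional parameter sets: `idealScenario()`
(100% labeling, no unspecific signals) and `realisticScenario()` (40%
labeling, 5/µm² unspecific, 1|2/µm² background), both at 75
molecules/µm² on a 10 × 10 µm² field with 30 nm error.

### Boundary handling: why the simulation closes the torus

The toroidal-shift test is exact for processes that are stationary on
the torus defined by the ROI. A naive simulation that lets localization
error, drift and aberration push detections across the ROI boundary
breaks this in two opposite ways, both measurable at 400-replicate
resolution: keeping spill-over makes the observed data "edge-free" while
wrapped controls are not (a conservative bias, mean null p $\approx$
0.54), and cropping spill-over at analysis time juxtaposes
edge-truncated blink clusters with the reference channel's edge
depletion in the data but not in the controls (anti-conservative,
false-positive rate $\approx 0.15$). `simulateExperiment()` therefore
wraps final coordinates periodically into the ROI: the simulated field
is genuinely torus-stationary, data and controls are exchangeable, and
the test attains its exact size. The individual stage functions remain
unwrapped so their geometry is directly testable.

For *experimental* data the analogous statement is the standard ROI
guidance: choose a central region of the cell, away from cell edges and
large-scale structures, so that the pattern is approximately stationary
across the ROI. `runClastaTest()` restricts both channels to the shared
ROI before analysis, exactly as drawing an ROI on real data would.

## What the simulations do and do not show

The generator emulates the statistical structure of two-color SMLM
tables: blinking multiplicity, labeling stochasticity, localization
error, unspecific signals, drift, chromatic offset. It does not render
images (no PSF or camera noise — the pipeline starts from fitted
positions), does not model 3D topography, dye-environment photophysics
variation, or large-scale cell-shape inhomogeneity. A passing
calibration here therefore shows the inference machinery is exact for
torus-stationary inputs; on real cells, non-stationarity across the ROI
remains the user's responsibility.

## Numerical and design choices

* **Units**: nanometers everywhere; ThunderSTORM `x [nm]` columns map
  1:1. Coordinates are continuous; frames 1-based (a missing frame
  column reads as frame 1, degenerating drift gracefully).
* **ROI membership** is half-open, $[\min, \max)$, so toroidal wrapping
  is a bijection and boundary points are never double-counted.
* **Direction of the NN statistic**: distances run from the query
  (red) to the reference (blue) channel, and the query channel is the
  one shifted. Only cross-correlations matter, so the choice of which
  channel plays query is immaterial to the null distribution; it is
  exposed as an argument rather than averaged over.
* **Distances** use the plain Euclidean metric even for shifted
  controls: points are wrapped, the metric is not.
* **Nearest-neighbor search** is a uniform-grid index in C++ (~2 points
  per cell, ring expansion with an exact termination bound). One index
  over the unshifted reference channel serves the observed pair and all
  $N$ controls, making a full 99-control test on ~2 × 20,000
  localizations run in well under a second.
* **`cdfIntegral`** uses the exact closed form, not quadrature;
  the test suite cross-checks it against an independent interval-sum
  integrator at $10^{-9}$ relative tolerance.
* **Seeding**: one master seed drives a counter-based sub-seed scheme
  (`(seed, replicate index)` $\to$ sub-seed), so replicate $i$ of a
  power run is reproducible regardless of execution order and batch
  size; `runClastaTest(seed = )` restores the session RNG state.
* **Degenerate inputs**: empty channels and a reference smaller than
  $k$ raise errors; all-zero distances (identical channels) yield the
  minimal p-value in the clustering direction by the descending-rank
  convention; the degenerate shift $v = (0,0)$ has probability zero and
  is not excluded.

## Problem sizes used in validation

The packaged checks estimate the false-positive rate and the mean null
p-value from 400 replicate CSR fields, the modal clustered p-value from
20 replicates, drift robustness for dimers from 100 replicates (all at
the full 10 × 10 µm², 75 molecules/µm², $N = 99$ scale), and the
oligomer-order monotonicity of sensitivity at a sparser 10 molecules/µm²
with 40 replicates per order, where the orders separate. Full
sensitivity surfaces over domain radius × density × occupancy grids are
reproducible with `runGrid()` at user-chosen replication.

## Known limitations

* The empirical detections-per-label histograms of specific dye/tag
  pairs are not bundled; the log-normal default is a synthetic stand-in
  with matched mean and a heavy tail. `BlinkModel("empirical",
  table = ...)` accepts measured histograms.
* The p-value is per ROI. Aggregating many cells needs care: selecting
  data sets by small p-values invalidates the error rate; report the
  full p-value distribution instead.
* The test detects *any* cross-channel correlation, including residual
  chromatic miscalibration or channel cross-talk; it attributes no
  cause. Registration quality upstream is assumed.
* Sensitivity falls with molecule number, labeling efficiency toward
  0 or 1 (one channel empties), and vanishing oligomer fraction; the
  power harness quantifies these trade-offs per scenario.
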