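---
title: "Quantitative analysis of SMLM localization data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative analysis of SMLM localization data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smlmtools)
```

Single-molecule localization microscopy (SMLM — dSTORM, PALM and related
techniques) reconstructs images from the fitted positions of individually
photoactivated fluorophores. The raw product of an SMLM experiment is not an
image but a *localization table*: one row per detected emission event, with
coordinates, the frame of detection, and photometric metadata. Because the
data are coordinates rather than pixels, quantities such as cluster size,
molecular stoichiometry and colocalization can be computed directly on the
point pattern. This package provides that post-processing layer: it consumes
localization tables produced by common localization software (rapidSTORM,
ThunderSTORM) and computes channel registration, localization precision,
spatial statistics and clustering, coordinate-based colocalization, Fourier
ring correlation resolution, and molecular counting from blinking kinetics.
This vignette documents the models behind each module, the tunable
parameters and their defaults, the numerical choices, and the deliberate
design decisions made where the problem left room for them.

## The data model

All analyses run on a `loc_table`: a data frame with mandatory columns `x`,
`y` (always nanometres) and `frame` (always 0-based), optional photometric
columns (`photons`, `psf_sigma`, `background`, `precision`, `channel`) and
arbitrary extra columns that are passed through untouched. The axis
convention is origin at the top-left of the field, x rightward, y downward —
the convention of the camera frame in which localization software reports
coordinates. ThunderSTORM counts frames from 1 and is re-based on reading;
rapidSTORM counts from 0.

Each table carries a rectangular *region* (the observation window). When not
supplied it is the tight bounding box of the data. The region matters: it is
the window for Ripley edge correction and the canvas for histogram
rendering. For cropped data you should pass the true field of view
explicitly, since a bounding box derived from a clustered pattern
underestimates the observed area.

Rectangular region-of-interest filters use the half-open convention
`[x0, x1) × [y0, y1)`, so a tiling of ROIs partitions localizations
uniquely. Polygon ROIs use standard point-in-polygon containment; points
exactly on a polygon edge may fall on either side at floating-point
precision, which is immaterial for continuous coordinates.

## Channel registration

Multi-colour SMLM requires mapping the channels onto a common coordinate
frame. Fiducial markers (bright beads visible in both channels through the
whole acquisition) provide control points. `find_fiducials()` selects bright
localizations, groups them spatially, and keeps groups present in at least
`persistent_frac` (default 0.9) of all frames — ordinary blinking molecules
never persist that long. `match_fiducials()` pairs the two channels'
markers by *mutual* nearest neighbours under a distance cap; mutuality
makes the pairing unambiguous without solving an assignment problem, which
is adequate for the handful of well-separated beads used in practice.

`estimate_transform()` fits one of three models by least squares: a pure
translation (mean displacement), a similarity transform (rotation +
isotropic scale + translation, solved in closed form by the SVD-based
Procrustes method), or a full affine transform (linear least squares).
Closed-form solvers were chosen deliberately: they are deterministic, have
no starting values or convergence tolerances, and their failure modes
(collinear or coincident fiducials) are explicit errors. The default model
is similarity — translation alone cannot absorb camera rotation or
magnification mismatch, while a full affine fit spends degrees of freedom
on shear that real two-camera setups rarely exhibit; with few fiducials
those extra degrees of freedom only add variance. The fit reports the
fiducial registration error (FRE), the RMS residual distance over the
fiducials after transformation. With isotropic noise of standard deviation
σ per coordinate on n pairs, the expected FRE is approximately
σ·√2·√(1 − k/(2n)) with k the model's degrees of freedom (4 for
similarity); the tests verify this calibration by Monte-Carlo.

## Localization precision

Two complementary estimates of the lateral localization precision are
provided.

**From photon statistics.** For a fitted emitter with `N` photons, PSF
standard deviation `s`, pixel size `a` and background standard deviation
`b`, `precision_thompson()` evaluates

σ² = s²/N + a²/(12N) + 8π s⁴ b²/(a² N²),

the classic least-squares error propagation, and `precision_mortensen()`
the maximum-likelihood variant

σ² = (s² + a²/12)/N · (16/9 + 8π (s² + a²/12) b²/(N a²)).

These are per-localization, closed-form, and vectorised; they measure what
precision the photon budget *should* allow.

**From the data (NeNA).** A molecule that stays on across consecutive
frames is localized repeatedly, and the distance between its
re-localizations in frames f and f+1 samples the localization error
directly. For isotropic Gaussian errors with per-axis deviation σ in both
frames the distances follow the Rayleigh-type density
p(d) = d/(2σ²)·exp(−d²/(4σ²)) (scale √2·σ; the same-molecule term
integrates to exactly 1). `nena()` collects, for every localization, the
nearest-neighbour distance to the next frame (capped at `max_dist`, default
500 nm), bins them (default 5 nm bins) and fits
`A·d/(2σ²)·exp(−d²/(4σ²)) + c·d` by nonlinear least squares
(Levenberg–Marquardt). The linear term `c·d` absorbs unrelated random
neighbours, whose short-range distance density grows linearly in d; a
fuller correction with several background components exists in the
literature, but on data where consecutive-frame pairs dominate the single
linear term is sufficient and keeps the fit well-conditioned — this is a
documented simplification. Initialisation uses the histogram mode (the mode
of the same-molecule term is √2·σ, so σ₀ = mode/√2), with σ bounded in
(0, max_dist/2]. The estimator assumes the nearest next-frame neighbour
*is* the same molecule; at high emitter density unrelated molecules
intrude and bias σ downward, so NeNA should be run on sparse data or a
sparse subregion.

## Spatial statistics and clustering

**Ripley functions.** `ripley()` estimates
K̂(r) = A/(n(n−1)) · Σ_{i≠j} e_ij·1(d_ij ≤ r) over a radius grid, with the
translation edge correction e_ij = A/((w−|Δx|)(h−|Δy|)) for a rectangular
w×h window (`edge_correction = "none"` sets e_ij = 1). L(r) = √(K/π) and
H(r) = L(r) − r are derived; under complete spatial randomness K(r) = πr²
and H ≈ 0, and for clustered patterns H peaks near the characteristic
cluster scale. The translation correction is implemented for rectangular
windows only — it is exact and closed-form there; non-rectangular windows
are out of scope and fall back to no correction. The implementation sorts
the pair distances once and accumulates corrected weights cumulatively, so
a fine radius grid costs no more than a coarse one. Radii beyond half the
shorter window side trigger a warning, as edge-corrected estimates become
unstable there. For a Thomas-type cluster process (cluster intensity κ,
Gaussian spread σ_c) the theoretical K(r) = πr² + (1 − e^{−r²/(4σ_c²)})/κ
gives a closed-form H-peak location; the test suite uses it as an
independent oracle for the simulated cluster recovery.

**DBSCAN and OPTICS.** `dbscan()` implements the standard semantics: a
point is *core* when its eps-neighbourhood holds at least `min_pts` points
*counting itself* (the ELKI convention; sklearn counts the same way), the
clusters are the connected components of the core points under the
within-eps relation, and non-core points within eps of a core point are
border points. One deliberate deviation from the textbook algorithm: border
points are assigned to the cluster of their *nearest* core point (ties by
lowest row index), not to whichever cluster's scan claims them first. The
classic scan-order rule makes the partition depend on the processing
order, and it makes DBSCAN and the OPTICS eps-cut disagree on border
points, which would be indistinguishable from an implementation bug. The
nearest-core rule is deterministic, order-independent, and makes
`dbscan()`, the brute-force reference implementation used in the tests, and
`extract_dbscan(optics(...), eps)` agree exactly. Neighbourhood queries use
a cell-grid index with eps-sized cells, so runtime is near-linear for
bounded densities.

`optics()` computes the standard cluster ordering with core and
reachability distances (priority queue on smallest reachability).
`extract_dbscan()` cuts the ordering at a radius eps′ ≤ max_eps: a point
with reachability above eps′ either starts a new cluster (if core at eps′)
or is provisional noise; the nearest-core border rule is then applied so
the cut reproduces `dbscan()` exactly, core and border alike. Cluster
extraction by reachability steepness (the xi method) is not implemented —
the eps-cut covers the package's use of OPTICS as a multi-scale view of
DBSCAN.

**Cluster morphology.** `cluster_morphology()` reduces each cluster to its
convex hull and reports area, perimeter, circularity 4πA/P² (1 for a disc,
π/4 ≈ 0.785 for a square), centroid, maximum hull diameter and the number
of member localizations. The convex hull is the v1 shape model: it is
parameter-free and exactly testable against a brute-force hull; an
alpha-shape would follow concave clusters better and is noted as an
extension. Clusters with fewer than three non-collinear points are flagged
`degenerate` with zero area and missing circularity rather than dropped,
so the cluster inventory stays complete. Localization counts per cluster
are a *copy-number proxy* only — converting them to molecule numbers
requires the blinking model of the counting module.

## Coordinate-based colocalization

`cbc()` assigns each localization of channel A a colocalization value
C ∈ [−1, 1]. On a radius grid r_j = j·r_max/n_steps (default 10 steps),
the neighbour counts of both channels are converted to distance-weighted
density curves D_{A,X}(r_j) = N(r_j)/N(r_max) · r_max²/r_j²; the Spearman
rank correlation S of the two curves, damped by the nearest-B distance E,
gives C = S·exp(−E/r_max). Positive values indicate correlated channel
densities at the location, values near zero independence, negative values
segregation.

Numerical choices: Spearman uses average ranks for ties; when either curve
is constant its rank correlation does not exist and C is reported as
missing (`NA`) — zero-filling would bias channel summaries toward
independence, so undefined values are excluded from summaries and counted
in `n_undefined`. Records at *exactly* zero distance in channel B are
excluded from the count curves (they contribute no shape information, and
this makes running a table against itself return C = 1 everywhere instead
of a self-biased value) but are retained in E, which is therefore 0 in the
self-comparison. When A and B are the same physical record list, the
`self = TRUE` flag excludes each record from its own channel-B
neighbourhood entirely. The C statistic is meaningful only when localized
neighbourhoods are populated: with fewer than a handful of B neighbours
within r_max the rank correlation is dominated by tied zero counts.
Informative two-channel comparisons need densities of roughly ≥ 10
expected neighbours within r_max, which guides the simulation settings
used in the tests (500–2000 points per channel at r_max = 200 nm in a
2 × 2 µm field).

`interaction_domains()` thresholds C (the threshold is an explicit
argument — no universal default exists, it depends on the biological
question) and clusters the passing localizations with DBSCAN, marking
candidate domains of molecular interaction.

## Fourier ring correlation

`frc_curve()` estimates image resolution from the localization table
itself: the localizations are split into two statistically independent
halves, each half is rendered as a 2D count histogram
(`render_histogram()`, default 10 nm pixels), and the two images are
correlated ring by ring in frequency space:
FRC(q) = Re Σ F₁F̄₂ / √(Σ|F₁|² Σ|F₂|²). Images are zero-padded to the next
power-of-two square; rings are one frequency-pixel wide; the curve is
smoothed with a 3-ring moving average; the resolution is 1/q* at the first
crossing below the fixed threshold 1/7 (linearly interpolated between
rings), the standard criterion. If the curve never crosses, the resolution
is reported as undefined rather than clamped.

Two split modes exist because the split determines what "independent"
means: `random_halves` (default, explicit seed) assigns each localization
by a fair coin; `odd_even_blocks` alternates blocks of consecutive frames
(default 50) between the halves. Repeated blinking of one fluorophore
produces several localizations of the same molecule; a random split places
them in both halves and correlates the halves beyond the true structural
information, flattering the resolution estimate. Frame-block splitting
keeps a blinking event's localizations together at the cost of exposure
differences between halves. The random split is the default for
compatibility with common practice; the caveat is the user's to weigh.

## Molecular counting from blinking kinetics

Under a Markov-chain photoswitching model in which a fluorophore cycles
between on and dark states until irreversible bleaching, the number N of
*re-activations* (blinking events after the first) is geometric:
P(N|q) = qᴺ(1−q) with blinking probability q. A complex of m independent
fluorophores therefore shows a negative-binomial count,
P(N|m,q) = C(N+m−1, N)·qᴺ(1−q)ᵐ (`blink_pmf()`). The package reduces the
full kinetic chain to this observable consequence deliberately: dwell-time
(on/off lifetime) fitting would require time-resolved trajectories that a
localization table only partially determines, while event counts survive
the reduction intact.

`extract_blink_counts()` turns a table into per-molecule counts: spatial
groups from DBSCAN are candidate molecules; within a group, sorted frames
are merged into on-events, where up to `dark_tolerance` (default 1)
intervening dark frames keep one event together — this absorbs the common
artefact of a single on-event split across a frame boundary by the
localization software. N is the number of on-events minus one.

`calibrate_q()` estimates q on a known monomeric standard by the
closed-form MLE q̂ = N̄/(1+N̄). `fit_oligomer()` then scores candidate
subunit numbers m by the log-likelihood of the counts under a
labelling-efficiency mixture: with label probability p, the number k of
active fluorophores in an m-mer is binomial, but complexes with k = 0 are
never observed, so the binomial weights are renormalised over k ≥ 1. This
conditioning is stated explicitly because ignoring it biases m̂ downward
at realistic labelling efficiencies (p ≈ 0.6–0.9). The search over m is
exhaustive over a user-bounded candidate set (default 1–8) — stoichiometry
is a small integer, and an exhaustive profile (with q either fixed from
calibration or profiled out by 1-D optimization per m) is more robust than
any continuous relaxation.

## The simulator

`simulate_points()`, `simulate_localizations()` and `simulate_two_color()`
generate data with exposed ground truth for every analysis above: CSR
(fixed-n uniform, so counts are exact rather than Poisson — exactness makes
count assertions sharp), Gaussian clusters, segregated two-channel halves,
filaments, geometric blinking with labelling efficiency, log-normal photon
counts, persistent bright fiducials, and a true channel transform.
Blinking is simulated directly as geometric event counts — the observable
of the counting model — rather than as continuous-time trajectories. All
generators require a seed and are bit-exact reproducible.

What the simulator does *not* emulate bounds what the tests can show: there
is no camera-frame PSF rendering or EMCCD noise (localization error enters
as isotropic Gaussian displacement), no drift, no astigmatic 3D, and no
multi-emitter fitting artefacts. Passing tests demonstrate that each
algorithm recovers the truth of its own generative model at realistic
parameters, not that it is robust to every artefact of real acquisitions.

## Validation scale and reproducibility

The test suite validates, among others: Ripley's K against the CSR closed
form πr² (200 replicates of n = 1000 in a 2×2 µm field, mean curve within
the 99% Monte-Carlo envelope); DBSCAN against a brute-force core-graph
oracle and against the OPTICS eps-cut on 500 random instances (n ≤ 200);
NeNA recovery of σ ∈ {5, 10, 25, 50} nm within 5% at 10⁴ pairs; CBC sign
behaviour for identical, independent and segregated channels; FRC
self-correlation ≡ 1 and resolution degrading monotonically with injected
noise; blinking-probability calibration to ±0.03 and oligomer recovery for
monomers, dimers (q profiled) and tetramers (q fixed, p = 0.8). These sizes
were chosen as the smallest at which the statistical assertions have
comfortable power; `scripts/acceptance.R` recomputes the same quantities
from scratch with a caller-supplied seed.

```{r example, eval = FALSE}
# a small end-to-end run
truth <- simulate_points(1000, c(0, 0, 2000, 2000), "gaussian_clusters",
                         n_clusters = 40, sigma_c = 50, seed = 1)
tab <- simulate_localizations(truth, sigma_loc = 10, n_frames = 100,
                              q = 0.3, seed = 2)
rip <- ripley(tab, radii = seq(10, 500, by = 10))
cl <- dbscan(tab, eps = 50, min_pts = 5)
head(cluster_morphology(tab, cl))
```

## Known limitations

Strictly 2D (no z column); translation edge correction limited to
rectangular windows; convex hulls only; the NeNA background model is a
single linear term; FRC has no spurious-correlation correction for
within-molecule blinking beyond the frame-block split mode; counting
assumes spatially separable complexes (no deconvolution of overlapping
groups) and independent fluorophores within a complex.
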