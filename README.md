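# smlmtools

Quantitative analysis of single-molecule localization microscopy (SMLM)
data in R.

SMLM techniques (dSTORM, PALM, GSDIM) reconstruct super-resolution images
from the positions of individually photoactivated fluorophores. The primary
data product is a *localization table* — one row per detected emission
event with coordinates (nm), frame index and photometric metadata — and
most of the biological information (cluster sizes, copy numbers,
stoichiometry, colocalization) is best extracted directly from these
coordinates rather than from rendered pixels. `smlmtools` is the
post-processing layer for that job. It is aimed at microscopists and image
analysts who already have localization tables from rapidSTORM or
ThunderSTORM and want reproducible, scriptable quantification.

## What it computes

| Task | Functions | Core quantity |
|---|---|---|
| I/O and filtering | `read_localizations`, `write_localizations`, `filter_localizations` | rapidSTORM / ThunderSTORM / internal TSV dialects; ROI, frame, photon filters |
| Channel registration | `find_fiducials`, `match_fiducials`, `estimate_transform`, `apply_transform` | translation / similarity / affine least-squares fit; FRE (nm) |
| Localization precision | `precision_thompson`, `precision_mortensen`, `nena` | σ² = s²/N + a²/(12N) + 8πs⁴b²/(a²N²) and the MLE variant; NeNA fit of p(d) = d/(2σ²)·exp(−d²/(4σ²)) + c·d to consecutive-frame nearest-neighbour distances |
| Spatial statistics | `ripley` | K̂(r) = A/(n(n−1)) Σ e_ij 1(d_ij ≤ r), translation edge correction; L = √(K/π), H = L − r |
| Density clustering | `dbscan`, `optics`, `extract_dbscan` | standard DBSCAN semantics (min_pts counts the point itself); OPTICS ordering + eps-cut |
| Cluster morphology | `cluster_morphology` | convex hull area, perimeter, circularity 4πA/P², centroid, diameter, copy-number proxy |
| Colocalization | `cbc`, `interaction_domains` | per-localization C = S·exp(−E/r_max) ∈ [−1,1], Spearman S of distance-scaled neighbour-count curves |
| Resolution | `render_histogram`, `frc_curve`, `frc_from_images` | Fourier ring correlation, fixed 1/7 threshold |
| Molecular counting | `extract_blink_counts`, `blink_pmf`, `calibrate_q`, `fit_oligomer` | negative-binomial blinking model P(N\|m,q) = C(N+m−1,N) qᴺ(1−q)ᵐ; label-efficiency mixture; m̂ by (profile) likelihood |
| Simulation | `simulate_points`, `simulate_localizations`, `simulate_two_color` | seeded ground-truth generators for all of the above |

The methods vignette
(`vignettes/smlm-quantitative-analysis.Rmd`) documents the models,
parameter defaults, numerical choices and limitations in detail.

## Worked example

Simulate a clustered two-state experiment, then quantify it:

```r
library(smlmtools)

truth <- simulate_points(1000, c(0, 0, 2000, 2000), "gaussian_clusters",
                         n_clusters = 40, sigma_c = 50, seed = 1)
tab <- simulate_localizations(truth, sigma_loc = 10, n_frames = 100,
                              q = 0.3, seed = 2)
tab
#> <loc_table> 1432 localizations, 100 frame(s)
#>   region: [8.0, 2009.4] x [-3.8, 1978.8] nm
#>   optional columns: photons

rip <- ripley(tab, radii = seq(10, 500, by = 10))
rip$r[which.max(rip$H)]        # H-function peak ~ cluster scale
#> [1] 140

cl <- dbscan(tab, eps = 50, min_pts = 5)
cl
#> <cluster_result> 20 clusters, 1432 localizations (63 noise)

head(cluster_morphology(tab, cl)[, c("cluster_id", "n_localizations",
                                     "area", "circularity")], 3)
#>   cluster_id n_localizations      area circularity
#> 1          0              75  65305.15       0.783
#> 2          1             195 124306.76       0.779
#> 3          2             140  91386.86       0.797
```

The H peak at 140 nm reflects the 50 nm cluster spread (for a
Thomas-type cluster process the theoretical peak for these settings is at
≈ 130 nm); areas are in nm², circularity is 1 for a disc.

Counting and precision work on sparse samples, where spatial groups
isolate single molecules:

```r
sparse <- simulate_points(500, c(0, 0, 3e4, 3e4), "csr", seed = 3)
stab <- simulate_localizations(sparse, sigma_loc = 10, n_frames = 500,
                               q = 0.3, seed = 4)
counts <- extract_blink_counts(stab, eps = 100, min_pts = 1,
                               dark_tolerance = 1)
calibrate_q(counts)            # blinking probability (simulated: 0.3)
#> [1] 0.3220339

relabeled <- simulate_localizations(
  simulate_points(500, c(0, 0, 5e4, 5e4), "csr", seed = 5),
  sigma_loc = 10, n_frames = 21, q = 0, frames_per_event = 21, seed = 6)
nena(relabeled, max_dist = 500, bin_width = 5)
#> <nena_result> sigma_loc = 10.04 nm from 10000 pairs
```

## Command line

A thin CLI over the same functions ships as `exec/smlmtools`:

```sh
smlmtools convert  --in locs.txt --out locs.csv --dialect thunderstorm
smlmtools filter   --in locs.csv --out roi.csv --roi 0,0,5000,5000 --min-photons 500
smlmtools register --moving ch2.csv --fixed ch1.csv --model similarity --max-dist 250
smlmtools ripley   --in roi.csv --out curve.csv --rmax 500 --dr 10
smlmtools cluster  --in roi.csv --out labeled.csv --eps 30 --min-pts 10
smlmtools cbc      --a ch1.csv --b ch2_registered.csv --rmax 300
smlmtools frc      --in roi.csv --pixel 10 --split random --seed 42
smlmtools count    --in sparse.csv --eps 50 --min-pts 3 --dark-tol 1
smlmtools simulate --pattern clusters --n 1000 --seed 7 --out sim.csv
```

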