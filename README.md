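# ivmtracks

Motility and anomalous-diffusion analysis of single-cell trajectories
from intravital microscopy.

## The problem

Timelapse intravital imaging of bone marrow lets individual leukemia
cells (and other hematopoietic cells) be tracked *in vivo*, typically as
spot-track tables exported from software such as Imaris: one row per
cell per timepoint with a track id, time and x/y/z position. The
scientific questions are usually threefold: how motile the cells are,
what *kind* of motion they perform, and whether a perturbation — for
example injecting the CXCR4 antagonist AMD3100 (plerixafor) between a
pre-drug and a post-drug acquisition of the same positions — changes
either. `ivmtracks` implements that analysis pipeline for researchers
working with such track exports:

- **Track I/O and quality control** — plain and Imaris-like CSV
  dialects, strict validation, a point-count/gap filter.
- **Motility statistics** — per-track mean speed (path length over
  elapsed time), local displacement over a time window, distinct grid
  sites visited, straightness.
- **Diffusivity analysis** — time-averaged mean-squared displacement
  (TA-MSD), the MSD/lag log-log representation, anomalous-exponent
  fitting and motion-regime classification.
- **Cohort comparisons** — unpaired t-tests of per-track metrics
  between epochs or cohorts; paired t-tests of cluster mean fluorescence
  intensity before/after treatment.
- **Synthetic cohorts** — exact Brownian, fractional-Brownian,
  persistent-random-walk and ballistic generators emulating a paired
  pre/post-drug imaging design, so every stage is verifiable against
  closed-form ground truth.
- **Orchestration** — a JSON-configurable runner producing
  byte-reproducible reports, plus a thin CLI
  (`inst/cli/ivmtracks.R`).

## The statistics at the core

For a track sampled at interval Δt, the time-averaged MSD at lag
τ = kΔt is the mean squared displacement over **all** point pairs
separated by τ (overlapping pairs, gaps included when both endpoints
exist). Fitting log MSD(τ) = log C + α log τ by least squares gives the
anomalous-diffusion exponent α:

| α | regime | interpretation |
|---|--------|----------------|
| < 0.9 | subdiffusive | confined / anti-persistent |
| 0.9–1.1 | diffusive | Brownian-like, explorative |
| > 1.1 | superdiffusive | persistent / directed |
| = 2 | ballistic | straight-line motion |

Equivalently, MSD(τ)/τ on log-log axes has slope α − 1: flat for
Brownian motion, rising for superdiffusion, falling for subdiffusion.
The generators obey known closed forms — Brownian MSD = 2dDτ, fBm
MSD = dKτ^(2H) (α = 2H), ballistic MSD = s²τ², and the persistent
random walk follows the Fürth relation
MSD(τ) = 2ds²P(τ − P(1 − e^(−τ/P))) — which the test suite and the
acceptance script check quantitatively.

Units are fixed package-wide: minutes and micrometres.

## Worked example

A demonstration scenario emulating a chemoresistant T-ALL cohort: 150
cells imaged every 3 min for 90 min, then — after a 15-min injection
gap — for a further 180 min, with 25% of cells mobilized (lost) at drug
time. Pre-drug motion is Brownian; post-drug motion is slow ballistic.

```r
library(ivmtracks)

cfg <- make_demo_config("tall-like", seed = 42)
rep <- run_analysis(cfg, write = FALSE)
print(rep)
#> <analysis_report> 2 stats table(s), 1 MSD result(s), 1 comparison(s)
#>   tall-like: regime shift diffusive -> superdiffusive
#>   pre vs post (unpaired-t): p = 7.442e-194 ****
print(rep$msd[["tall-like"]]$pre$fit)
#> <alpha_fit> alpha = 0.9837 (se 0.0023), diffusive; 7 lags in [3, 21] min
print(rep$msd[["tall-like"]]$post$fit)
#> <alpha_fit> alpha = 1.8607 (se 0.0263), superdiffusive; 15 lags in [3, 45] min
```

The report states the designed signature: the exponent fitted to the
pre-drug ensemble is ≈ 1 (diffusive), the post-drug ensemble is called
superdiffusive (α pulled slightly below 2 by the 0.3-µm localization
noise at short lags), and per-track mean speed drops with an unpaired
t-test p-value far below the 0.0001 star threshold.

The same machinery works piecewise on any trackset:

```r
ts <- simulate_brownian(n_tracks = 200, n_frames = 31,
                        frame_interval = 3, dims = 2, D = 1, seed = 1)
m <- ensemble_msd(ts)
head(as.data.frame(m), 4)
#>   lag      msd n_pairs
#> 1   3 12.02349    6000
#> 2   6 24.21453    5800
#> 3   9 36.30465    5600
#> 4  12 48.16735    5400
fit_anomalous_exponent(m)
#> <alpha_fit> alpha = 0.9973 (se 0.0023), diffusive; 7 lags in [3, 21] min
```

The ensemble MSD tracks the closed form 2dDτ = 12, 24, 36, 48 µm² at
the first four lags, and the fitted exponent recovers α = 1.

For real data, replace the simulation with
`read_tracks("tracks.csv")` (or `dialect = "imaris"`), filter with
`filter_tracks()`, and feed the result to the same functions — or drive
everything from a JSON config via `run_analysis()` /
`inst/cli/ivmtracks.R`.

## Documentation

The methods vignette (`vignettes/track-motility-analysis.Rmd`) documents
the estimators, motion models, default parameters and their rationale,
the paired imaging design, and known limitations.
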