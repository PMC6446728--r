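---
title: "Methods: trajectory motility statistics, TA-MSD diffusivity analysis and paired drug-response comparisons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory motility statistics, TA-MSD diffusivity analysis and paired drug-response comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and scientific setting

`ivmtracks` analyzes single-cell trajectories of the kind exported from
semi-automatic spot tracking of intravital microscopy timelapses — for
example, leukemia blasts migrating through calvarium bone marrow, imaged
before and after injection of the CXCR4 antagonist AMD3100 (plerixafor).
The questions such experiments pose are:

1. *How motile are the cells?* — per-track mean speed, local displacement
   over a fixed time window, and the number of distinct sites visited.
2. *What kind of motion is it?* — the time-averaged mean-squared
   displacement (TA-MSD) as a function of lag, summarized by the anomalous
   diffusion exponent $\alpha$ in $\mathrm{MSD}(\tau) \propto \tau^\alpha$:
   $\alpha \approx 1$ diffusive (explorative, foraging-like), $\alpha < 1$
   subdiffusive (confined or anti-persistent), $1 < \alpha < 2$
   superdiffusive, $\alpha = 2$ ballistic (environment-agnostic, directed).
3. *Did the drug change either?* — unpaired comparisons of per-track
   metrics between pre- and post-drug epochs, and paired comparisons of
   cluster mean fluorescence intensity (MFI) in the same regions before
   and after treatment.

Because raw intravital imaging data are rarely deposited, the package
ships a synthetic-trajectory generator whose motion models have known
closed-form MSDs. Every analysis stage is validated against those closed
forms, against brute-force oracles, and against textbook statistics; the
generator is therefore a first-class, tested component, not a test
fixture.

# Data model and units

Units are fixed package-wide: time in **minutes**, positions in
**micrometres**. Readers never convert; inputs are declared in these
units. A `trackset` is a data.frame of `(track_id, t, x, y[, z])` rows
with optional `disease`/`stage`/`epoch` label columns, carrying the frame
interval (modal time step, if not given) and dimensionality as
attributes. Within a track, times must be strictly increasing; duplicate
`(track_id, t)` rows are an error rather than being deduplicated, since
they indicate a broken export. Two CSV dialects are read: a plain
`track_id,t,x,y[,z]` table and an Imaris-like export (metadata lines
skipped until a header containing "Position X"; `Position X/Y/Z`, `Time`,
`TrackID` mapped). An Imaris `Time` column holding frame indices must be
converted to minutes by the caller.

## Quality filter

Tracks shorter than `min_points = 5` points, or containing a gap longer
than `max_gap = 2` frame intervals, are dropped before statistics. The
published track data this design emulates state no inclusion threshold,
so these are declared defaults, chosen so that every retained track
supports an exponent fit over at least 4 lags at the default
quarter-duration lag cap. When a trackset carries epoch labels, the gap
rule applies within each epoch: the interval between the pre-drug and
post-drug acquisitions is part of the imaging design, not a tracking
dropout.

# Motility statistics

* **Mean speed** is total path length over total elapsed time
  (`sum of step lengths / (t_n - t_1)`), the "track mean speed"
  convention of Imaris-style exports — not net displacement over time.
  Gaps contribute their true elapsed time to the denominator.
* **Local displacement** over a window $W$: for every point with a
  partner at $t + W$ (matched within half a frame interval, to survive
  export jitter), the straight-line distance between the two positions.
  With $W$ equal to one frame it reduces exactly to the step-displacement
  sequence; with $W$ equal to the track duration, to the net
  displacement.
* **Distinct sites visited**: the count of unique grid cells
  (half-open, origin at 0, cell edge default 10 µm ≈ one cell diameter)
  containing at least one track point. Grid size and origin are declared
  choices; the origin convention makes the count reproducible but means
  it is not translation-invariant, which is irrelevant for within-study
  comparisons that share a coordinate frame.
* **Straightness** is net displacement over path length, defined as 0
  for zero-length paths (the 0/0 case).

# TA-MSD estimation and exponent fitting

For one track sampled at times $t_i$, the time-averaged MSD at lag
$\tau = k\,\Delta t$ is the mean of $\lVert x(t+\tau) - x(t)\rVert^2$
over **all** available point pairs separated by $\tau$ — the overlapping
(maximal-pair) estimator standard in single-particle tracking. Pairs
across gaps are included whenever both endpoints exist. Points are
matched to the frame grid by nearest integer (tolerance a quarter frame;
off-grid times trigger a warning). The implementation is index-matched
($O(n \times \text{lags})$); tests require exact equality with an
$O(n^2)$ all-pairs double loop, including on gapped tracks.

Defaults: lags up to **0.25 of track duration** (longer lags average few
pairs and are dominated by noise), and ensemble lags supported by fewer
than **10 pooled pairs** are dropped. The ensemble curve is the
pair-count-weighted mean of per-track values — identical to pooling all
pairs; an unweighted per-track mean is available (`weighting =
"tracks"`) for sensitivity analysis, since pair weighting favors long
tracks.

The exponent is the slope of an ordinary least-squares fit of
$\log \mathrm{MSD}$ on $\log \tau$ (natural logs internally; at least 3
lags required). Zero-MSD lags — possible for stationary tracks — are
excluded with a warning rather than clamped. The **MSD-over-lag**
representation divides each value by its lag, so a log-log plot is flat
for Brownian motion, rises for superdiffusion and falls for subdiffusion;
its log-log slope is identically $\alpha - 1$, which the tests verify to
$10^{-6}$ on exact power laws.

**Regime thresholds.** Motion is called subdiffusive below
$\alpha = 0.9$, superdiffusive above $\alpha = 1.1$, diffusive between.
Published track analyses report these regimes qualitatively; explicit,
configurable thresholds make the call reproducible. An optional
standard-error-aware mode refuses to leave "diffusive" unless
$|\alpha - 1| > 2\,\mathrm{se}(\alpha)$. Dimensionality enters only
closed-form comparisons, never the fit.

# Motion models

All generators sample their exact step distributions — there is no Euler
discretization error at the 3-minute frame interval:

* **Brownian**: independent Gaussian increments per axis, variance
  $2D\Delta t$; ensemble MSD $2dD\tau$.
* **Fractional Brownian motion**: each axis has stationary fractional
  Gaussian noise increments with the exact covariance implied by
  $E[X(t)^2] = K t^{2H}$, sampled via a Cholesky factorization of the
  $n \times n$ increment covariance (exact, and cheap at the ≤ 100
  frames of this imaging design; a circulant-embedding FFT method would
  be preferred only for much longer tracks). Ensemble MSD
  $dK\tau^{2H}$, so $\alpha = 2H$.
* **Persistent random walk**: per-axis velocity follows a stationary
  Ornstein–Uhlenbeck process (stationary s.d. $s$, correlation time
  $P$); position and velocity advance each frame by their exact joint
  Gaussian update (variances
  $\mathrm{Var}(\xi_v) = s^2(1 - a^2)$,
  $\mathrm{Var}(\xi_x) = s^2 P^2 (2\Delta t/P - 3 + 4a - a^2)$,
  $\mathrm{Cov} = s^2 P (1-a)^2$ with $a = e^{-\Delta t/P}$). The
  ensemble MSD follows the Fürth relation
  $2 d s^2 P\,(\tau - P(1 - e^{-\tau/P}))$ — ballistic for
  $\tau \ll P$, diffusive for $\tau \gg P$ — with no step-size bias.
* **Ballistic**: constant speed along a per-track heading drawn
  uniformly on the circle/sphere; MSD exactly $s^2\tau^2$.
* **Localization noise**: independent Gaussian jitter of s.d. $\sigma$
  on every coordinate, modeling spot-centroid error; it adds exactly
  $2d\sigma^2$ to the expected MSD at every positive lag, which the
  tests verify on simulated cohorts.

**Seeding.** The master seed drives a single sample-without-replacement
of per-track 31-bit sub-seeds; track $i$ always receives sub-seed $i$, so
cohorts are bit-reproducible and an individual trajectory does not depend
on how many tracks are simulated after it.

# The paired cohort design

`imaging_design()` defaults encode the emulated protocol: frames every
**3 min**, a **90-min** pre-drug epoch, a **15-min** injection gap
(a time offset only — no frames are sampled during it), then a
**180-min** post-drug epoch. In `simulate_cohort()`, each cell receives a
pre-epoch trajectory; unless mobilized it continues from its last
position under the post-epoch model. Mobilization — cells leaving the
imaging volume for the circulation when CXCR4 retention is antagonized —
is modeled as track termination at drug time: a seeded random subset of
$\lfloor f \cdot n \rfloor$ cells has no post-epoch points. No published
value quantifies the mobilized fraction, so cohort defaults (0.25 in the
demo scenarios) are illustrative, not calibrated.

## Demo scenarios

`make_demo_config()` encodes two ground-truth drug-response signatures,
150 cells each, 3D, localization noise 0.3 µm:

* **aml-like** — pre and post epochs share a Brownian generator
  ($D = 0.5\,\mu m^2/min$): speed and regime unchanged, emulating
  parenchymal AML cells whose migration is CXCR4-independent.
* **tall-like** — the post epoch switches to a slow ballistic generator
  (0.3 µm/min): mean speed drops sharply while the exponent rises toward
  2, emulating the chemoresistant T-ALL shift to superdiffusive motion
  under CXCR4 antagonism.

$D = 0.5$ gives a pre-epoch mean track speed near 1 µm/min — the order
of magnitude typical of leukemia blasts in marrow — and the ballistic
speed is set well below it so the designed speed decrease dominates
sampling noise at the cohort size used. Validation requires the designed
signature (regime shift and speed comparison for tall-like; stability
and non-significance for aml-like) in at least 90% of 50 seeded
replicates.

# Statistical comparisons

Epoch comparisons of per-track metrics are **unpaired** two-sided
t-tests (pre- and post-epoch tracks are distinct samplings of the cell
population, not matched observations); Student's equal-variance variant
is the default, Welch's behind a flag. Cluster MFI uses the **paired**
two-sided t-test on after − before differences, reporting the mean
difference and its 95% CI. Stars follow the figure-legend convention
(\*, \*\*, \*\*\*, \*\*\*\* at 0.05, 0.01, 0.001, 0.0001). No
multiple-testing correction is applied; reports list every comparison so
users can adjust externally. One degenerate-input convention: a paired
comparison whose differences are all exactly zero is reported as
statistic 0, p = 1 (the identity pairing), while constant non-zero
differences raise a degenerate-variance error, since the statistic is
then genuinely undefined.

Cells are treated as independent observations pooled across animals, as
is common in intravital track analyses. Whether the animal should enter
as a blocking factor is a real design question this package does not
resolve: label columns are carried through, but no mixed-effects
modeling is attempted.

# Reproducible reports

`run_analysis()` executes a declarative JSON-serializable configuration:
per-cohort loading or simulation, filtering, statistics, MSD reports
(per epoch where labels exist, with a regime-shift statement) and the
planned comparisons. All numeric output is written at full double
precision with fixed newline and quoting conventions, and the manifest
records the configuration echo, package version, seed and per-file MD5
hashes — identical configurations yield byte-identical reports, and
every number is recomputable from the manifest alone. Output is staged
and moved into place only after every stage succeeds, so failed runs
leave no partial report. A thin command-line script
(`inst/cli/ivmtracks.R`; subcommands `simulate`, `stats`, `msd`,
`compare`, `run`, `demo`) wraps the same functions.

# What the synthetic cohorts do and do not show

The generators reproduce the imaging schedule, known motion regimes,
mobilization as track loss, and localization noise. They deliberately
omit features of real intravital data: tissue confinement and vessel
geometry, cell–cell interactions, proliferation and death, drift of the
preparation, heterogeneous per-cell motility parameters, and anisotropic
(z-inflated) localization error. Passing validation therefore
demonstrates that the estimators recover known ground truth under the
study's sampling design — not that any particular biological dataset
satisfies these models. Problem sizes used in validation (500 tracks ×
31 frames for exponent recovery, 1000 tracks for closed-form MSD
agreement, 50 replicates for the demo scenarios) were chosen so
Monte-Carlo error sits comfortably inside the stated tolerances.

# Known limitations

* The exponent fit is OLS on log-log coordinates, adequate for regime
  classification; no maximum-likelihood or Bayesian diffusivity
  inference, per-track regime mixtures, or velocity-autocorrelation
  analysis is provided.
* TA-MSD values at different lags are strongly correlated; the reported
  `alpha_se` is the OLS slope error and understates the true sampling
  variability of $\alpha$ for single tracks. Ensemble fits over
  hundreds of tracks, as used throughout, are unaffected in practice.
* `distinct_sites_visited` depends on the declared grid origin (above).
* The Imaris-like reader handles CSV exports only; proprietary `.ims`
  files and image data are out of scope, as is the tracking step itself.
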