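---
title: "Doppelganger simulations of intracellular diffusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Doppelganger simulations of intracellular diffusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doppelsim)
```

## The problem

Single-particle-tracking nanorheology measures the motion of ~40 nm
genetically encoded multimeric nanoparticles (GEMs) in the cytoplasm of
living cells. The apparent diffusivities fitted to individual tracks spread
over orders of magnitude, both within one cell and across a genetically
identical population. The central question such data pose is: how much of
that spread is *biology* (a genuinely heterogeneous cytoplasm) and how much
is *statistics* (short, noisy tracks produce wide diffusivity
distributions even for a perfectly homogeneous medium)?

`doppelsim` answers this with a *doppelganger simulation*: a stochastic
Brownian-dynamics run that replicates the experimental bookkeeping
particle-for-particle. Every experimental cell has a simulated twin with
the same long-axis length and the same number of tracks, and every
experimental track has a twin simulated for exactly the same number of
frames at the same frame interval. Because the measurement statistics are
identical by construction, any difference between the experimental and
simulated diffusivity distributions must come from the physical model —
and the spread a *homogeneous* model produces is precisely the statistical
floor.

## The physical model

Particles diffuse by fixed-timestep Brownian dynamics inside a 2D
rectangular cell $[0, L] \times [0, W]$ with reflecting walls. The
Stokes–Einstein relation sets the diffusivity

$$D = \frac{k_B T}{\gamma}, \qquad \gamma = 6 \pi \eta R,$$

and each timestep draws independent per-axis displacements from
$\mathcal{N}(0,\ \xi^2)$ with $\xi = \sqrt{2 k_B T \Delta t / \gamma}$,
the viscosity $\eta$ being evaluated at the step's starting position.
Defaults (all in nm/ms/pN/K units): $k_B = 0.0138$ pN nm/K, $T = 303.15$ K,
$R = 20$ nm, $\Delta t = 10$ ms, $W = 3\ \mu$m, and a population mean
viscosity of 40 times that of water,
$\eta_w(T) = 2.414\times10^{-8} \cdot 10^{247.8/(T-140)}$ pN ms/nm², which
gives $\gamma \approx 0.012$ pN ms/nm and $D \approx 350$ nm²/ms
(0.35 µm²/s). The per-axis convention for $\xi$ makes the mean 2D step
length $\xi\sqrt{\pi/2} \approx 104$ nm at these defaults.

Four heterogeneity models share this engine (`model_config()`):

* **uniform** — one viscosity everywhere (the statistical-floor model);
* **spatial** — each cell is tiled with square domains of side $\Lambda$
  (default 1 µm) whose viscosities are drawn log-normally about the
  population mean with shape $\sigma_{\eta,s}$ (default 0.85);
* **cellular** — one log-normal draw per cell (shape $\sigma_{\eta,c}$,
  default 0.45);
* **combined** — cell means drawn with $\sigma_{\eta,c}$, then domains
  drawn with $\sigma_{\eta,s}$ about each cell mean.

Draws follow $\eta = \mu e^{\sigma z}$ with $z$ standard normal — $\mu$ is
therefore the *median*, not the mean, of the resulting log-normal. We
implement the formula literally and do not "correct" the shape parameters
to linear-scale CVs. No viscosity may fall below that of water; draws are
clipped at the floor (at the default parameters a clipped draw is a
~16-sigma event, so clipping is cosmetic; at the largest calibrated shapes
it affects a small fraction of domains).

Domain grids are 3-across for the default 3 µm width; when a cell dimension
is not an integer multiple of $\Lambda$, the remainder becomes its own
narrower column (or row) of domains at the high-coordinate edge. Viscosity
lookups use the half-open convention: a point exactly on an interior
boundary belongs to the higher-index domain. Steps are never
straddle-averaged across domains — $\Lambda \gg \xi$ for all calibrated
parameter sets, so a step rarely spans more than one boundary.

Reflection is implemented by folding, $r = v \bmod 2U$ then $2U - r$ if
$r > U$, which handles arbitrarily many bounces in one step.

### Reproducibility

One root seed expands to per-cell seeds and then to per-track seeds
(`sample.int` substreams), so any single track can be re-simulated without
replaying the whole run and results are independent of execution order.
Simulating each track directly at its ledger duration is bit-equivalent to
the "simulate longest, then prune to the leading frames" description,
because pruning keeps the first $N_i$ frames and experimental tracks are
contiguous from their own first frame anyway.

## MSD analysis

The time-averaged MSD of one track uses **nonoverlapping windows**: for lag
$k$ frames the windows tile forward from the first point, discarding any
remainder (a 7-point track at lag 3 contributes two windows). Per-axis
means are summed over $x$ and $y$. Ensemble (cell- or condition-level)
curves are unweighted means of the per-track curves at each lag, so lags
beyond a short track's span are *absent*, not zero — error bars grow with
lag exactly as the surviving-track count shrinks.

Fits use ordinary least squares of $\ln \mathrm{MSD}$ on
$\ln(\tau/\tau_0)$ over the first 7 available lags (~70 ms):
$\mathrm{MSD} = A(\tau/\tau_0)^\alpha$, $\alpha$ the anomalous exponent,
and $D_{app,\tau_0} = A / (2 n \tau_0)$ with $n = 2$ dimensions and
$\tau_0 = 100$ ms. $\tau_0$ lies beyond the fitted range; the
extrapolation is deliberate and matched between experiment-style analysis
and simulation. The natural log is used for fitting; all downstream spread
statistics use $\log_{10}$. Bootstrap 95% CIs resample tracks (their
time-averaged curves) with replacement — basic percentile method, sample
size equal to the number of tracks.

Velocity autocorrelations define $v(t)$ as the single-frame displacement
divided by $\Delta t$ and average $v(t)\cdot v(t+\tau)$ over nonoverlapping
$t$; pure diffusion gives $\mathrm{VAC}(0) = 4D/\Delta t$ and zero at
positive lags, with no negative viscoelastic peak. The amplitude
normalisation (dividing by $\Delta t$) is a convention; sign and shape
conclusions do not depend on it.

## Spread statistics

Diffusivity distributions are closer to log-normal than normal, so
summaries are computed on $\log_{10} D_{app}$: the mean of logs
$\mu_{log}$ ("median order of magnitude", reported in linear space as
$10^{\mu_{log}}$), the SD of logs $\sigma_{log}$, and the **fold range**
$10^{5\sigma_{log}}$ — the ratio of values 2.5 SDs above and below the
centre.

Variance decomposition uses a sequential nested sums-of-squares ANOVA,
day → session(day) → cell(session) → residual(track); fractions are
$SS_{level}/SS_{total}$. For a strictly nested hierarchy the four terms
decompose the total SS exactly. We chose SS proportions over REML variance
components because the decomposition is exact, assumption-light and
directly comparable between an experiment and its doppelganger (which
shares the identical design matrix); for unbalanced designs the two differ,
and a mixed-model variant is a natural extension point.

Group comparisons follow the conventions of the field: Levene's test in
its classic form (absolute deviations from the group *mean*, then a
one-way F) for equality of variances, and the two-sided Wilcoxon rank-sum
test for equality of medians (exact null distribution when the combined
n ≤ 20 without ties, otherwise normal approximation with tie and
continuity corrections), both applied to $\log_{10}$ values. The
within-cell pair correlation draws one random unordered pair of tracks per
eligible cell and reports Spearman's r: purely cell-level (extrinsic)
spread drives r toward 1, purely track-level (intrinsic) spread toward 0.

## Ergodicity

The ensemble-averaged (EA) MSD takes each track's squared displacement
from its *own first tracked frame* (there is no absolute time zero for
tracks that begin mid-movie); the time-ensemble-averaged (TEA) MSD is the
ensemble of nonoverlapping-window time averages — byte-identical to the
MSD used everywhere else (single implementation). Nonergodicity is
quantified as $(\mathrm{EA} - \mathrm{TEA}) \cdot 100 / \mathrm{EA}$ per
lag and fitted with a weighted exponential decay $y = Ae^{-Bt} + C$,
weights $1/\mathrm{SE}$ where the SE of the percent difference comes from
bootstrapping EA and TEA over the *same* track resample (propagating their
correlation). Lags with fewer than 10 contributing tracks are excluded
from the fit (configurable tail guard). Decay fits initialise
$C_0$ = tail mean, $A_0$ = head mean − $C_0$, $B_0$ from the half-decay
lag, then Gauss–Newton (`nls`, port algorithm) with an `optim` fallback.

Testing "statistically indistinguishable from zero" per lag with 95% CIs
is miscalibrated — each interval has nominal 95% coverage, so the expected
fraction of covering lags *equals* 0.95 and a perfectly ergodic run fails
a "≥ 95% of lags" rule about half the time. The package therefore tests
the bootstrap CI of the **lag-averaged** percent difference (exposed as
the `mean_pd` attribute of `ergodicity_curves()`), with per-lag coverage
retained only as a ≥ 85% sanity floor.

`domain_size_scan()` repeats the combined model across domain sizes with
the per-size calibrated parameters (`domain_calibration_defaults()`),
fitting each replicate's decay and averaging parameters across replicates
— smaller domains self-average within a track and shift nonergodicity
toward shorter lags, which is what makes the decay profile informative
about the spatial scale of viscosity heterogeneity.

## Calibration

`calibrate_model()` finds combined-model parameters reproducing three
statistics of a target distribution: $\mu_{log}$, the track-wise
$\sigma_{log}$, and the cell-wise $\sigma_{log}$ (SD of per-cell means of
track log values). The declared loss is the sum of squared mismatches of
the three (all in log10 units; SDs are the monotone equivalents of the
variances). Because $D \propto 1/\eta$ exactly, rescaling the mean
viscosity shifts $\mu_{log}$ without touching the spreads (up to the water
floor), so the search is a coarse grid plus Nelder–Mead over the two
shapes only, followed by solving the mean directly from the median offset
(two passes absorb any floor-clipping feedback). Every evaluation uses the
same replicate seeds (common random numbers), making the optimisation
deterministic and smooth; the result reports the replicate spread of each
statistic and a converged flag.

Cell-wise spread is deliberately defined on per-cell means of track-wise
fits — symmetric between a simulated data set and a reference
distribution that has no trajectories. True cell-wise MSD fits remain
available via `fit_hierarchy(level = "cell")`.

## The synthetic experiment

`generate_experiment_stats()` emulates the printed summary of the
reference data set: 145 cells over 5 sessions and 3 days (round-robin
assignment; the real session-to-day mapping is unpublished), per-cell
track counts from a rounded truncated normal (25 ± 10, minimum 1), track
durations from a truncated exponential on [100 ms, 10 s] — the underlying
rate is solved numerically so the *truncated* mean is 273 ms, since
conditioning Exp(273 ms) on ≥ 100 ms would inflate the mean to ~373 ms —
and cell lengths uniform on 7–14 µm (a two-fold range; MSDs at ≤ 70 ms
lags are insensitive to the exact lengths). Track counts and durations are
generated independently; any correlation between them in real data is not
emulated.

`generate_reference_diffusivities()` draws per-track
$\log_{10} D_{app}$ from a two-level hierarchy: median 0.29 µm²/s,
total track-wise SD $\log_{10}(392)/5$ (a 392-fold range), of which 20% of
the variance sits at the cell level (extrinsic) and 80% at the track level
(intrinsic).

What a green test on this synthetic world does *not* establish: the
generator contains no localisation error, blinking, detection dropout or
track-splitting, no correlation between expression level and mobility, and
its duration distribution is exactly exponential. Conclusions about those
failure modes need real tracker output (the `mosaic` reader dialect, with
mandatory, never-guessed pixel-size and frame-interval conversions).

## Boundary effects and a deliberately failing check

Reflecting walls at the default 3 µm cell width suppress measured
displacements: direct Monte Carlo shows the one-step variance is already
~3% below $2D\Delta t$, growing to ~8% by lag 7, because a particle within
a step-length of a wall has its outward excursions folded back. The
condition-wise fit of in-cell uniform-model tracks therefore lands at
$\alpha \approx 0.97$ and $D_{app,100ms} \approx 323$ nm²/ms — a ~7%
systematic below the 350 nm²/ms input, amplified by the extrapolation to
$\tau_0 = 100$ ms — while the identical estimator on an unconfined box
recovers both parameters within the bootstrap CI (both behaviours are
pinned by tests). The package keeps an acceptance check that demands exact
recovery inside real cell geometry; it fails, and is left failing, because
"fixing" it would mean either distorting the stated geometry or widening
an interval that is doing its job. Mildly sub-unity exponents are an
expected signature of tracking in micron-scale confinement.

## Worked example

```{r example, eval = FALSE}
stats <- generate_experiment_stats(synth_config(seed = 1))
sim <- run_doppelganger(stats, model_config("combined", seed = 2),
                        physical_params())
fits <- fit_hierarchy(sim, "track")
ok <- fits$status == "ok"
log_space_summary(fits$d_app[ok])
nested_anova_fractions(log10(fits$d_app[ok]),
                       fits[ok, c("day_id", "session_id", "cell_id")])
```

## Known limitations

2D geometry only (the imaging modality sees a ~2D slab); no hydrodynamic
wall interactions, active transport, viscoelastic memory or time-varying
fields; viscosity is piecewise constant on the domain grid; ANOVA
fractions are SS proportions, not variance-component estimates; the exact
rank-sum path requires tie-free data; calibration assumes the combined
model family contains a good fit (it flags, but cannot repair,
unattainable targets).
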