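---
title: "Characterising escape trajectories: structure functions, straightness and directional entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising escape trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protean)
```

## The problem

Benthic invertebrates such as sea urchins respond to predator chemical cues
by changing how they move. In a typical laboratory assay, animals are
released one at a time at the centre of a circular arena, photographed at a
fixed interval (30 s here, roughly one body length of displacement per
frame), and tracked until they approach the arena wall. The question is not
only *whether* treated animals move differently, but *how*: are their paths
straighter, faster, more or less variable as a population, and more or less
predictable?

`protean` implements the full analysis chain for such two-treatment
trajectory experiments: per-individual kinematics, an anomalous-diffusion
characterisation, directional-entropy unpredictability, circular uniformity
checks, and the group-comparison statistics. A synthetic-trajectory
generator emulating the study design makes every stage testable end to end.

## Data model

A trajectory is a regularly sampled 2-D path: positions
$(x_t, y_t)$ at times $t = 0, \Delta, 2\Delta, \dots$ with frame interval
$\Delta$ (seconds) and no missing frames. Gaps are an error, never
interpolated: all downstream estimators assume strictly regular sampling.
Coordinates stay in their native unit (pixels for camera digitisations);
speed is unit-covariant while straightness, the scaling exponents and
entropy are unit-invariant, so no calibration is required for the
dimensionless comparisons. The interchange format is a long CSV
(`id, frame, x, y[, treatment, frame_interval, unit]`), matching how
time-lapse digitisations are usually exported.

## Kinematics

* **Mean speed** — per-step speed (step length / $\Delta$) averaged over
  the path.
* **Headings** — the *final* heading is the direction of the vector from
  first to last position. The *initial* heading deliberately skips a
  settling period: it is the direction of the vector spanning the first
  five steps. Whether that vector starts at position 0 or position 1 is a
  genuinely ambiguous convention in the field; `headings()` exposes
  `initial_start` (default 0). Trajectories with fewer than 6 positions
  report a missing initial heading rather than falling back to a shorter
  vector.
* **Turning angles** — signed differences of successive step headings,
  wrapped to $(-\pi, \pi]$. A perfect reversal is mapped to $+\pi$, not
  $-\pi$; a fixed choice is needed for deterministic binning downstream.
  Steps of zero length carry no heading, so they are skipped and the angle
  is taken between the surviving flanking steps (`min_step` generalises
  this to a displacement threshold; animals genuinely pause between
  frames).
* **Straightness index** $I_s$ — net displacement over path length,
  with the path length computed at a window of $w$ steps: hops between
  positions $0, w, 2w, \dots$; a trailing remainder shorter than $w$
  contributes its own hop so numerator and denominator always span the
  same endpoints and $I_s \le 1$ holds exactly. $I_s = 1$ for a straight
  sampled path, $0$ for a closed one; a path with no net movement at all
  is defined as 0. The default window of 1 step matches the 30-s
  reporting convention; treatment comparisons are insensitive to the
  window, so any consistent convention serves.

## Anomalous diffusion via structure functions

The central characterisation is the family of $q$th-order structure
functions of the displacement modulus
$\|\Delta X_\tau\| = \sqrt{(x_{t+\tau}-x_t)^2 + (y_{t+\tau}-y_t)^2}$:

$$\langle \|\Delta X_\tau\|^q \rangle \sim \tau^{\zeta(q)}.$$

For each lag $\tau$ the moment is a time average over *all* ordered
position pairs separated by $\tau$ (the standard overlapping
structure-function estimator, which extracts the most information from
short paths). $\zeta(q)$ is the OLS slope of $\log M(q,\tau)$ on
$\log\tau$; the lag grid is log-spaced so the regression points are evenly
spread in log–log space.

The whole function is summarised by the slope of $\zeta(q)$ versus $q$
constrained through the origin ($\zeta(0)=0$ holds by construction). This
single coefficient places a path on the Brownian-to-ballistic continuum:

| summary slope | regime |
|---|---|
| $< 0.5$ | subdiffusive |
| $= 0.5$ | Brownian ($\zeta(q) = q/2$) |
| $0.5$–$1$ | superdiffusive |
| $= 1$ | ballistic ($\zeta(q) = q$) |

`classify_diffusion()` applies these bands with a half-width of 0.05 by
default — a reporting convenience; the underlying comparison against the
two reference lines is what carries the science.

**Numerical choices.** The moment orders default to
$q \in \{0.5, 1, \dots, 3\}$: an infinite family of moments characterises
the displacement distribution in principle, but high orders are dominated
by the few largest displacements on short paths, so moderate $q$ keeps the
per-$q$ regressions stable. Twelve log-spaced lag candidates from 1 to
$\lfloor N/4 \rfloor$ frames (de-duplicated after rounding) keep at least
$3N/4$ pairs in every estimate and bound the autocorrelation between
regression points. Non-positive moments cannot enter a log fit; such lags
are dropped per $q$ with a warning, and a $q$ with fewer than 3 surviving
lags is excluded from the summary fit. Per-$q$ regressions are unweighted.
All of `q_grid`, `n_taus` and `max_tau_fraction` are exposed as arguments.

## Directional entropy and uniformity

Unpredictability is measured as the Shannon entropy of the binned turning
angles: bins of width 0.05 rad partition $(-\pi, \pi]$ from $-\pi$ upward
(126 bins; the last is narrower because $2\pi/0.05$ is not an integer), and
$H = -\sum_i p_i \ln p_i$ over occupied bins — the plug-in
maximum-likelihood estimator, in nats. Three conventions are fixed so that
counts are reproducible: the bin anchor at $-\pi$, half-open $(lo, hi]$
intervals, and the $+\pi$ reversal wrap above. The log base only rescales
$H$, so between-treatment *ratios* are base-invariant; absolute values are
comparable only within one convention. No small-sample bias correction is
applied: the quantity compared between groups is the plain Shannon index
of the count vector, and any correction would shift both groups alike.

The Rayleigh test checks that initial and final headings are uniform on
the circle (they should be when the cue is diffuse; directionality would
indicate an arena artefact). The statistic is $z = n\bar R^2$ with $\bar R$
the mean resultant length, and the p-value uses the standard second-order
series approximation, clamped to $[0,1]$. Its type-I calibration at the
study's group size is verified by simulation in the test suite.

## Group comparisons

Each individual is one replicate throughout.

* **Speed and straightness**: one-way linear models (the F on 1 and
  $n-2$ df equals the squared pooled two-sample t).
* **Summary $\zeta(q)$ slope**: the two groups differ strongly in spread
  (Levene's test on absolute deviations from the group mean quantifies
  this), so the comparison uses a Gaussian model with one mean *and one
  residual variance per group*, fitted by maximum likelihood. The
  treatment effect is a likelihood-ratio $\chi^2$ on 1 df against the
  equal-means, variance-per-group null. The two-group case is essentially
  closed-form: free-means ML estimates are the group means and ML
  variances; the equal-means null iterates the variance-weighted common
  mean to a fixed point. ML (not REML) estimation keeps likelihood ratios
  across mean structures valid; a Wald $\chi^2$ is available via
  `test = "Wald"`. The test suite cross-checks the fit against
  `nlme::gls(weights = varIdent(...))`.
* **Entropy ANCOVA**: `entropy ~ treatment + slope + treatment:slope`,
  with F tests on 1 df per term. The default table uses sequential
  (type-I) sums of squares, matching the usual single-ordering
  presentation. One property of sequential tables is worth knowing: when
  the covariate has a real effect, the *first* term's F absorbs chance
  between-group imbalance in the covariate while the denominator MSE is
  conditional on the covariate, so the sequential treatment test is
  anticonservative under a true treatment null. `ss = "marginal"`
  (type-II) gives the calibrated treatment test, and that is the version
  the package's null-calibration checks exercise; the choice is exposed
  because both orderings are defensible summaries.

A day-of-trial random effect is accepted in the input but ignored: in the
motivating design it added no explained variance, and modelling it is out
of scope here.

## The synthetic study generator

`simulate_trajectory()` provides four reference processes — Brownian
(i.i.d. Gaussian displacements), ballistic (constant heading and speed,
optional heading jitter), correlated random walk (gamma step lengths,
wrapped-normal turning angles with concentration $\kappa$; the angle SD is
$1/\sqrt\kappa$, with $\kappa = 0$ meaning uniform turns), and a Lévy walk
(heavy-tailed run lengths between uniform reorientations). Brownian and
ballistic paths have known slopes (0.5 and 1) and the CRW interpolates
between them, which is what the parameter-recovery tests rely on.

`simulate_study()` emulates the two-treatment design: 29 control and 21
treated individuals, released at the centre of a 3-m arena (internal unit
0.1 cm, so radius 1500), trial durations drawn uniformly from 16–208
steps of 30 s (8–104 min), and truncation at the first frame within 10 cm
of the wall. Control animals draw $\log_{10}\kappa \sim U(-0.6, 2.4)$ —
a deliberately broad range producing summary slopes from Brownian to
marginal ballistic, emulating the wide intrinsic behavioural
heterogeneity observed in unconstrained animals. Treated animals draw
$\log_{10}\kappa \sim U(1.9, 2.8)$ (concentrated, near-ballistic) with a
mean speed multiplier of 1.34, mirroring the reported 34% speed increase —
a generator parameter, not a mechanistic claim. Step length is
gamma-distributed with mean one body length (3.6 cm) per frame and shape
9, and each individual carries a log-normal speed multiplier
(SD 0.2 on the log scale) for between-animal variability.

What the generator does *not* emulate: pixel geometry and digitisation
noise, any interaction with the wall before the stop margin, within-path
behavioural switching, and light-field heterogeneity. Passing tests
therefore demonstrate that the estimators and tests recover known
generative structure under the study's design — not that any particular
field dataset satisfies the generator's assumptions.

## What the checks compute

The simulation-based checks in the test suite use: 200 replicates of
500-step Gaussian walks for Brownian slope recovery; 100 random paths of
up to 50 positions against a brute-force all-pairs oracle for the moment
estimator; 5000 replicates at $n = 29$ for Rayleigh calibration; 200
seeded studies for direction-of-effects recovery; and 1000 seeded studies
with identical group parameters for the type-I calibration of all four
treatment tests. These sizes give Monte-Carlo standard errors comfortably
inside the asserted bands.

```{r example}
d <- simulate_study(seed = 1)
report <- analyze_study(d, verbose = FALSE)
report
```

## Known limitations

* Two treatment groups only; no multi-level designs or random effects.
* No step-length distribution fitting (paths at this sampling rate are
  too short to discriminate such models) and no multifractal analysis
  beyond the linear summary slope.
* The Rayleigh test's distributional assumptions (unimodality under the
  alternative) are taken as given, not tested.
* Irregular sampling is rejected, not resampled.
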