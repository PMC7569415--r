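---
title: "Methods: calibrated ERK activity, trace metrics, and the internal-factors cascade model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrated ERK activity, trace metrics, and the internal-factors cascade model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erkrescale)
```

`erkrescale` analyses live-cell FRET reporter measurements of ERK kinase
activity in cells engineered to express a single RAS isoform (wild type or an
oncogenic mutant). This vignette is the package's account of the models it
implements, the parameters that matter, the estimator and numerical choices
that were genuinely open, and what the synthetic-data tests do and do not
demonstrate.

## From photons to an activity ratio

An EKAR-type reporter is a synthetic ERK substrate: phosphorylation drives an
intramolecular conformation change that produces FRET, read out as the ratio
of cyan to yellow channel intensities. Three layers connect raw intensities
to a biochemically interpretable number.

**Ratiometric correction.** The corrected reporter signal is

$$E = 1 - \frac{CFP/YFP}{R_P},$$

where $R_P$ is the ratio of total optical power collected in the cyan channel
over the yellow channel. Each channel's power is the product of six scalar
factors — relative excitation intensity, exposure time, molar extinction
coefficient, quantum yield, and the excitation- and emission-side spectral
overlap integrals (`power_ratio()`, with overlaps computed by trapezoidal
integration on a shared 1-nm wavelength grid). $E$ is linear in the fraction
of reporter molecules in the FRET conformation. Negative $E$ (signal below
the spontaneous-association background) is allowed and flagged, never
silently clipped at this stage.

**Calibration.** Because spontaneous fluorophore association contributes
background FRET, $E$ is affine in the phosphorylated fraction $p$:
$E = E_0 + \beta p$, with $E_0$ the background at $p = 0$ and
$E_0 + \beta \le 1$. The curve is fit by ordinary least squares of mean $E$
on $p$ measured by Phos-Tag immunoblot under matched conditions
(`fit_calibration()`). Unweighted OLS is used because each calibration point
is a mean over replicates of one cell line and condition; errors-in-variables
refinements are not supported by the handful of calibration points such
designs produce.

**Mass action.** The reporter cycles between phosphorylation by active ERK
(rate $k_f\,[\mathrm{ERK}^*]$) and dephosphorylation by opposing phosphatases
(rate $k_r\,[\mathrm{Ptase}^*]$). At steady state
$k_f [\mathrm{ERK}^*](1-p) = k_r [\mathrm{Ptase}^*]\,p$, so

$$\rho \equiv \frac{k_f [\mathrm{ERK}^*]}{k_r [\mathrm{Ptase}^*]}
      = \frac{p}{1-p}.$$

$\rho$ — the ERK:phosphatase activity ratio — is the package's activity
unit. The constant $k_f/k_r$ is not identifiable from imaging data and is
fixed to 1, so all $\rho$ values are relative; every downstream comparison is
a ratio or difference of $\rho$ values and is unaffected by this choice.
`activity_from_signal()` inverts the calibration with $p$ clipped to
$[0, 1-10^{-6}]$ and the clip counts reported: measurement noise can push $E$
below $E_0$ or above $E_0+\beta$, and the package's policy is to clamp and
count rather than propagate impossible fractions.

## Per-cell trace metrics

All metrics operate on traces normalized to the cell's MEK-inhibitor
reference: a saturating MEKi dose at the end of each experiment drives the
reporter to its cell-specific residual signal, and the minimum over the
first hour of MEKi treatment is subtracted (mode `"min"`; subtracting the
MEKi-period median is available as `"median"`). Windows follow the
experiment timeline (defaults in minutes, configurable in
`experiment_design()`):

* baseline: mean over the 2 h before the stimulus, $[t_s - 120, t_s)$;
* peak and time to peak: first maximum over $(t_s, t_s + 60]$ — maxima after
  the attenuation phase are not the stimulus peak, hence the 60-min horizon;
* post-stimulus mean: $[t_s, t_s + 120]$, truncated (and flagged) at MEKi;
* steady state: mean over $[t_s + 105, t_s + 135]$, a 30-min window centered
  2 h after stimulation — "2 h after stimulation" needs bounds to be
  computable, and a symmetric 30-min window is wide enough to average noise
  without bleeding into the attenuation phase; the width is configurable;
* volatility: the mean-scaled mean absolute derivative,
  $V = \mathrm{mean}_i\!\left(|x_{i+1}-x_i|/\Delta t\right) / \bar{x}$, over
  $[t_s, t_s+120)$ (or the baseline window). The mean — not the sum — of
  $|dx/dt|$ is used so that $V$ is invariant to sampling rate; with the sum,
  identical dynamics sampled twice as often would double the statistic.
  Windows are half-open so a 2-h window holds a whole number of frames.

**Responder classification.** A cell is a responder when both hold:

1. its mean activity over the 30 min after the stimulus exceeds its baseline
   mean by at least 5% of full scale *and* a one-sided unequal-variance
   comparison of the two windows is significant at $\alpha = 0.05$. The 5%
   floor is stated relative to full scale, interpreted as the population's
   maximum activity (per-trace maximum when a single trace is classified
   standalone); a baseline-relative mode is available because the reference
   scale of the floor is genuinely ambiguous;
2. its maximum derivative in the 15 min after the stimulus exceeds the
   maximum absolute derivative anywhere in the 2-h baseline — this is what
   separates a stimulus-locked rise from slow drift that accumulates a large
   increase without one.

For criterion 2 the derivative is estimated on a 5-frame (15 min) running
mean, computed separately within the baseline segment and the post-stimulus
segment so the stimulus step can never leak into baseline derivatives. The
width matches the rise timescale of the response. Raw single-frame
differences are deliberately not used here: the maximum of ~40 single-frame
baseline differences is an extreme order statistic of measurement noise and
grows with window length, which at realistic noise swamps the true rise of
smaller responders and caps classifier sensitivity well below the intended
operating point. Volatility, whose definition *is* the raw absolute
derivative, is not smoothed.

**Quality control.** Whole traces are dropped when too short or containing
too long a run of missing frames. The outlier rule — exclusion beyond 6
standard deviations of the dataset mean — applies to per-cell metric values,
in a single pass with mean and SD computed once on the full dataset, so the
rule is idempotent and does not cascade.

## The internal-factors cascade model

The model predicts steady-state phosphorylated ERK (ppERK) per cell line
from the "internal" factors only — GTPase-cycle kinetics, effector binding,
and first-order kinase/phosphatase cycles — deliberately omitting feedback,
scaffolds, and phosphatase regulation. The gap between its predictions and
measurements is then an estimate of those "external" factors.

1. **RAS nucleotide cycle.** Exchange (rate $k_{ex}$, raised by growth
   factor via GEF recruitment) against hydrolysis (intrinsic $k_{int}$ plus
   GAP-stimulated $k_{gap}$):
   $f_{GTP} = k_{ex} / (k_{ex} + k_{int} + k_{gap})$. Oncogenic mutants are
   GAP-insensitive ($k_{gap} \approx 0$) with total hydrolysis reduced
   50–800-fold versus wild type and RAF affinity weakened up to 7-fold; the
   shipped parameter file satisfies these relative bounds and is labelled
   synthetic — tests assert only the bounds, never the shipped numbers.
2. **RAF recruitment.** One-site equilibrium binding of RAS·GTP
   ($G = f_{GTP} R_t$) to pooled RAF ($R\!A\!F_t = BRAF_t + CRAF_t$):
   the complex solves $C^2 - C(G + R\!A\!F_t + K_d) + G\,R\!A\!F_t = 0$,
   physical root $C \le \min(G, R\!A\!F_t)$, evaluated in the
   numerically stable form $C = 2\,G\,R\!A\!F_t / (b + \sqrt{b^2 - 4 G
   R\!A\!F_t})$ which is continuous through $K_d = 0$. BRAF and CRAF are
   pooled because the model schematic does not resolve RAF isoforms; an
   isoform-resolved split with per-isoform $K_d$ is a documented extension
   point.
3. **Push–pull tiers.** MEK and ERK each follow a linear
   kinase/phosphatase cycle far from saturation:
   $f_{ppMEK} = a_1 C / (a_1 C + d_1)$, and with active MEK
   $M^* = f_{ppMEK} M_t$, $f_{ppERK} = a_2 M^* / (a_2 M^* + d_2)$.
   First-order (non-saturating) kinetics are justified by fractional ppERK
   staying in the low-percent range throughout; a Michaelis–Menten variant
   would add parameters the data cannot constrain. Dephosphorylation
   constants are condition-independent here by construction — the model must
   exclude the phosphatase regulation that `phosphatase_ratio()` and the
   MEKi decay fits estimate, or the discrepancy analysis would be circular.

Panel predictions are normalized to the reference (wild-type) line's
baseline, so both panels' arbitrary units cancel in
`model_measurement_discrepancy()`, whose measured/predicted ratios per line
and condition are the external-factor rescaling estimate. A single global
rate set $(a_1, d_1, a_2, d_2)$ is shared across lines, the parsimonious
reading of a model whose per-line inputs are abundances and GTPase kinetics.

## Phosphatase inference

Two independent routes estimate substrate-level phosphatase activity:

* **ppERK/activity ratio.** The FRET measurement is
  $\propto [\mathrm{ERK}^*]/[\mathrm{Ptase}^*]$ while immunoblot ppERK is
  $\propto [\mathrm{ERK}^*]$; their ratio per line and condition isolates
  relative phosphatase activity. Uncertainty is propagated by bootstrap
  resampling over replicates.
* **Post-MEKi decay.** With MEK inhibited, rephosphorylation stops and the
  reporter relaxes as $y(t) = a e^{-b (t - t_{MEKi})} + c$; $b$ is in
  principle proportional to phosphatase activity. Fits use
  constrained nonlinear least squares ($b \ge 0$, $c \ge 0$), initialized
  from the window endpoints with $b_0 = \ln 2 / (w/3)$. The offset $c$ is
  included by default because traces plateau at the cell-specific MEKi
  floor; a pure-exponential mode is available. The fit window is 45 min of
  the 1-h MEKi period, avoiding end-of-experiment edge effects. Nearly
  constant windows return an explicit degenerate flat fit ($a = 0$, $b = 0$)
  rather than a spurious rate; non-convergence is reported, never silent.
  Group summaries report medians and quartiles over converged fits only.

## Statistics

**Two-level-error t-test.** Single-cell experiments repeat across replicate
cultures, and a cell's deviation decomposes as
$\varepsilon = \varepsilon_{cell} + \varepsilon_{exp}$. For each group the
variance of each experiment's mean is estimated from its cells
($s_j^2/n_j$) and added to the variance across experiment means; groups are
compared by a Welch-style $t$ on experiment means with Satterthwaite degrees
of freedom (the specific unequal-variance test being otherwise unspecified,
Satterthwaite is the standard completion). When within-experiment variance
vanishes the statistic collapses exactly to Welch's t-test on experiment
means. Families of comparisons are corrected by the Benjamini–Hochberg
step-up procedure at $\alpha = 0.05$.

**PLSR with permutation-null bounds.** Partial least squares regression
(NIPALS, univariate response; predictors and response standardized
internally) regresses ppERK on the presence of stimulation and the measured
abundances. Reported weights are the standardized regression coefficients at
2 components (configurable; the variance-explained-versus-components curve
is also reported so the choice is inspectable). Significance bounds come
from refitting after permuting the response rows — scrambling breaks the
X–Y association, which is the quantity of interest; permuting Y rather than
X is pure bookkeeping. Bounds are the order statistics at ranks
$\lfloor 0.025(m+1) \rfloor$ and $\lceil 0.975(m+1) \rceil$ of the $m$
permutation weights: with the $(m+1)$ convention a null weight falls outside
its band with probability 5% exactly, whereas interpolated percentiles
under-cover at $m = 200$.

**Tjur's D.** The discrimination coefficient of a logistic fit of the
responder flag on baseline activity: the difference in mean fitted
probability between responders and non-responders. Under complete separation
the ML fit diverges, so a Jeffreys-prior (Firth-type) penalized fit is used
and flagged; on very small samples the penalty visibly shrinks D, which is
preferred over an infinite slope.

## The synthetic-data generator

The generator exists so that every stage has known ground truth. It
emulates: spontaneous pulsatile baseline activity (Poisson-timed rectangular
pulses — the simplest process with a rate, amplitude and duration);
an EGF-stimulated rise peaking ~15 min after stimulus with attenuation over
roughly 2 h to an intermediate steady state (difference of exponentials —
the kinetics being emulated are described qualitatively, and two time
constants are the minimal shape with independent rise and adaptation); a responder /
non-responder mixture; universal exponential signal decay after MEKi
(non-responders' baseline activity is also MEK-dependent, so they decay
too); multiplicative lognormal noise applied to raw intensities (fluorescence
noise is multiplicative; applying it on $\rho$ would skip the nonlinear
calibration inverse that real noise passes through); and condition-level
lognormal immunoblot noise with the internal-model prediction as the
noiseless mean.

Defaults, chosen once as plausible for fibroblast reporter imaging (the
source measurements do not constrain single-cell heterogeneity
distributions): 3-min sampling; baseline $\rho \sim$ lognormal(log 0.35,
0.25); responder amplitude $\sim$ lognormal(log 0.7, 0.35) floored at 0.2;
rise $\tau = 6$ min and adaptation $\tau = 45$ min, which place the full
curve's maximum (including the steady-state drift term) at ~15 min; steady
state at 15–35% of the amplitude above baseline; pulses at 1/h, amplitude
0.1, duration 9 min; decay $b \sim$ lognormal(log 0.1, 0.4) truncated to
[0.02, 0.3] min$^{-1}$; noise CV 2%. The shipped calibration curve
($E = 0.10 + 0.50\,p$) and optical configuration are synthetic stand-ins on
the right order of magnitude, not instrument values.

The generator does **not** emulate: photobleaching or focus drift, cell
division and tracking errors, spatially resolved (nuclear/cytoplasmic)
signals, receptor-level dose–response, growth-factor-specific kinetics
beyond its presets, or correlated noise between neighboring frames. Passing
tests therefore demonstrate internal consistency of the pipeline — forward
model, inversion, classification and inference agree at realistic noise —
not robustness to every artifact of real imaging data.

## Numerical choices and degenerate inputs

* Clipping of inverted fractions at $[0, 1-10^{-6}]$ with counts reported.
* Peak ties break to the earliest time; windows are half-open on the right
  where a whole number of frames matters.
* The binding quadratic uses the stable root form (no catastrophic
  cancellation; continuous at $K_d = 0$).
* Decay fits: endpoint-based initialization, bounded parameters, degenerate
  flat-fit shortcut for constant windows, explicit convergence flags.
* PLSR stops early if the response residual becomes orthogonal to the
  predictors; constant predictor columns are an error naming the column.
* Seeds: every stochastic operation takes an explicit seed; population
  simulation derives per-cell seeds from the master seed, so outputs are
  byte-identical across runs.

## Problem sizes in the tests

The test suite exercises the pipeline at the scale a workstation handles in
about a minute: 200-cell populations for calibration round trips, a
1,000-cell mixture for classifier operating characteristics, 300 decay fits
for rate recovery, 2,000 null replicates for test size, 500 replications of
200-permutation PLSR nulls, and 100 random parameter sets for the
ODE-versus-closed-form cascade check (tolerance $10^{-6}$). The
demonstration pipeline simulates the five shipped KRAS lines with two
replicate experiments of 50 cells each — 500 cells total, mirroring the
scale of one imaging replicate per condition.

## Known limitations

* All activity values are relative ($k_f/k_r \equiv 1$); absolute molarities
  are out of reach by design.
* The cascade model is steady-state only; it cannot predict the transient
  peak, and its "stimulated" condition is a single elevated-exchange state.
* The responder classifier's magnitude floor depends on the population full
  scale; classifying a lone trace uses its own maximum, which is noisier.
* The two-level test treats experiments as exchangeable replicates; it does
  not model batch structure beyond one level.
* Tjur's D under the penalized fallback is conservative on small samples.
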