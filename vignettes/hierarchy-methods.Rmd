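---
title: "Measuring brain hierarchy with trophic levels on generative effective connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring brain hierarchy with trophic levels on generative effective connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophicbrain)
```

## The problem

Functional connectivity — the correlation structure of resting-state BOLD
signals — is symmetric by construction and therefore blind to the
*direction* of influence between brain regions. This package implements a
pipeline that recovers a directed, weighted network per subject and
summarizes its hierarchical organization, with the downstream statistical
and machine-learning stages needed to compare that organization across
diagnostic groups of an aging/dementia cohort.

The pipeline has four scientific layers:

1. **Generative effective connectivity (GEC).** Each region is a
   Stuart–Landau oscillator at a stable fixed point (supercritical Hopf
   normal form with bifurcation parameter $a_j < 0$). The coupled,
   linearized system is a $2N$-dimensional Ornstein–Uhlenbeck process
   whose stationary covariance and lag-$\tau$ covariances are analytic.
   Anatomical connection strengths are tuned by a heuristic
   pseudo-gradient until the model reproduces (i) the empirical
   functional connectivity and (ii) the difference between forward and
   time-reversed lagged correlations — the statistical arrow of time that
   carries the directional information.
2. **Trophic hierarchy.** The fitted coupling matrix defines a directed
   graph. Trophic levels $h$ solve $\Delta h = v$ with
   $\Delta = \mathrm{diag}(u) - C - C^\top$, $u = d^{in} + d^{out}$ and
   $v = d^{out} - d^{in}$; the incoherence
   $F_0 = \sum_{edges} w\,(h_{tail} - h_{head} - 1)^2 / \sum w$ measures
   how far the graph is from a perfectly layered flow, and directedness
   $1 - F_0$ is the global hierarchy summary. Regions are classified into
   sources, mediators and sinks by equal-width terciles of the z-scored
   group-mean levels.
3. **Harmonization and inference.** Multi-site location/scale effects are
   removed by an empirical-Bayes (ComBat-style) model that preserves
   modeled biology; group contrasts use Freedman–Lane covariate-adjusted
   permutation tests with Benjamini–Hochberg FDR; biomarker coupling uses
   a mixed-effects ridge regression with subject random intercepts;
   cognition is predicted by per-network linear models.
4. **Staging classifier.** Binary logistic-regression staging with mRMR
   feature selection, nested leave-one-out hyperparameter search, Monte
   Carlo 75/25 splits, Youden-threshold decisions, test-label permutation
   tests, vertically averaged ROC curves and exact linear Shapley feature
   importance.

Because the cohort data this design targets are controlled-access, the
package ships a first-class synthetic cohort generator that plants all
the structure the downstream stages are meant to detect, so the entire
pipeline is testable end to end.

## The synthetic cohort: what it emulates and what it does not

`generate_cohort()` draws one ground-truth layered network (feedforward
weights between adjacent layers, sparser and weaker feedback), scales it
into a realistic synchrony regime, and derives each diagnostic group's
couplings by *symmetrization*: group $g$ uses
$C_g = (1-\lambda_g) C + \lambda_g (C + C^\top)/2$ with flattening
fractions $\lambda = (0, 0.2, 0.4, 0.7)$ for HC$-$, HC$+$, MCI$+$ and
AD$+$. Symmetrization directly manipulates the quantity the hierarchy
metrics measure — the planted mean directedness decreases strictly across
stages — without changing total connection mass much. Per-subject
multiplicative weight jitter (5% SD) individualizes couplings.

Defaults mirror the acquisition this pipeline targets: TR = 3 s, 197
volumes per subject, four groups, three acquisition sites. Hopf
parameters sit in the standard noisy-fixed-point regime
($a_j = -0.02\,\mathrm{s}^{-1}$, $\sigma = 0.01$, intrinsic frequencies
uniform in $2\pi\,[0.01, 0.08]$ rad/s); integration is Euler–Maruyama at
$dt = 0.1$ s with the first 60 s discarded as burn-in (the trajectory
starts at the fixed point, and 60 s is several relaxation times of the
slowest mode). The global coupling scale (0.1) was chosen so the median
empirical FC off-diagonal sits near 0.3–0.4, the range typical of
denoised parcellated resting-state data; weaker scaling gives
unrealistically sparse correlation structure, stronger scaling saturates
it.

Biomarkers and cognition are *linear* in the subject's planted hierarchy
summaries plus Gaussian noise: amyloid and tau load rise as directedness
falls, grey-matter volume tracks regional trophic level with a negative
age slope, and the four cognitive scores decline as the hierarchy
flattens. Multi-site effects are additive and multiplicative
(`plant_site_effects()`), with the ground-truth site parameters stored
for recovery testing.

What the generator does **not** emulate: hemodynamic convolution,
head-motion artifacts, voxel-level structure, nonlinear
biomarker-hierarchy relationships, and longitudinal change. Passing
tests on this cohort therefore demonstrate that the pipeline recovers
planted linear structure through the full estimation chain under
realistic noise and scan lengths — not that it is robust to motion or
hemodynamic confounds, which upstream preprocessing tools are
responsible for.

## The linearized model and the lagged-covariance conventions

With coupling entry $C_{mn}$ = influence of region $m$ over $n$, the
Jacobian at the fixed point is block-structured,
$J = [[A, -\Omega], [\Omega, A]]$ with $A_{nm} = C_{mn}$ off the
diagonal, $A_{nn} = a_n - \sum_m C_{mn}$ and
$\Omega = \mathrm{diag}(\omega)$. By Gershgorin's theorem the column-sum
compensation keeps every eigenvalue's real part below $\max_n a_n < 0$,
so stability holds for any nonnegative coupling. The stationary
covariance solves the continuous Lyapunov equation
$J K + K J^\top + \sigma^2 I = 0$ (solved via the eigendecomposition of
$J$, with a Kronecker-product fallback for defective matrices), and the
lag-$\tau$ covariance is $e^{\tau J} K$.

One convention needs care: we define the empirical shifted correlation as
$FS_{ij}(\tau) \propto \mathrm{cov}(x_i(t), x_j(t+\tau))$, so entry
$(i, j)$ is large when region $i$ *leads* region $j$ — aligned with
$C_{ij}$. Under this orientation the model-side matrix is the transpose
of $e^{\tau J} K$ restricted to the observed components. The
time-reversed counterpart of a stationary linear process is exactly the
transpose of the forward matrix, an identity the estimator reproduces to
machine precision and the model side adopts directly. A long-simulation
test validates the orientation: the analytic matrix matches the
empirical one elementwise, and clearly beats its transpose.

Noise enters both oscillator components independently
($Q = \sigma^2 I_{2N}$), the simplest choice consistent with the additive
noise of the generative model.

## Fitting the GEC: update rule, stopping, and the two-stage schedule

The update is the heuristic pseudo-gradient
$$C_{ij} \leftarrow C_{ij} + \alpha\,(FC^{emp} - FC^{mod})_{ij}
  + \varsigma\,[(FS^{emp}_f - FS^{emp}_r) - (FS^{mod}_f - FS^{mod}_r)]_{ij},$$
restricted to anatomically allowed entries, clipped at zero, with a
stability re-check after every step (instability triggers step halving).
Defaults $\alpha = 5\times10^{-3}$ and $\varsigma = 2.5\times10^{-3}$
were set by requiring reliable convergence on noiseless
self-consistency benchmarks — targets generated analytically from a
known coupling must be recovered at $r > 0.95$ on masked entries; an
order of magnitude smaller and the iteration stalls visibly short of the
optimum. The monitored error is
$\tfrac12(1 - \mathrm{corr}(FC^{emp}, FC^{mod})) + \tfrac12\,
\mathrm{MSE}$ of the asymmetry difference; fitting stops when the best
error has not improved by $10^{-7}$ for 100 iterations. An optional
heavy-ball momentum term (`fit_config(momentum = )`) accelerates
convergence through the shallow plateaus that frequency-heterogeneous
systems produce; the velocity is reset whenever an instability forces a
halved step.

Cohorts are fitted in two stages: a group-level fit of the averaged
empirical statistics provides the warm start for every subject's
individual fit. The group stage fits the *functional connectivity only*
($\varsigma = 0$). This choice matters: carrying the group-average
asymmetry into each subject's initialization biases every subject toward
one directional pattern, and in simulation it erases — even inverts — the
between-group directedness ordering the cohort plants. With an FC-only
group stage the shared anatomical strengths are estimated once, and each
subject's time-reversal asymmetry is learned from a directionally
neutral starting point.

### Known limitations: frequency identifiability and the update's operating envelope

Node frequencies $\omega_j$ are estimated from Welch periodograms pooled
across subjects (Hann windows, 50% overlap, parabolically interpolated
peaks in the 0.008–0.08 Hz band). In a *coupled* oscillator network the
observed spectral peak of a region is pulled toward shared network
modes, so pooled peak estimates recover intrinsic frequencies only
approximately (RMSE near 0.1 rad/s at the default coupling scale).
Simulation shows the directional recovery degrades smoothly with
frequency error: with errors below ~0.03 rad/s the planted four-group
directedness ordering is recovered strictly; at ~0.1 rad/s the
ordering of adjacent groups becomes unreliable while the extreme-group
contrast and the staging classifier remain robust. Model-consistent
refinement schemes (matching model-predicted to observed spectral peaks)
do not help: the coupling fit compensates any frequency assignment,
which is precisely why the parameter is weakly identifiable.

A second, sharper limitation concerns the elementwise pseudo-gradient
itself. The update assumes that raising $C_{ij}$ mainly raises the
model's $(i, j)$ statistics; for oscillatory systems this sensitivity
structure rotates with the phase advance $\omega\tau$ accumulated over
the lag. When intrinsic frequencies approach the top of the band
(0.08 Hz, i.e. $\omega\tau \approx 1.5$ rad at TR = 3 s), the combined
error plateaus at a floor that is independent of the learning rates,
the stopping rule and momentum, and the fitted coupling stays nearly
symmetric even though the empirical asymmetry demonstrably carries the
directional signal (correlation near 0.9 with the true model's
asymmetry). Cohort draws dominated by slower oscillations fit well;
draws with several fast nodes do not. A Gauss–Newton-style
preconditioner (mapping the discrepancy back through the lag
propagator) would likely remove this envelope, but it would replace the
elementwise update that defines this estimator family, so we document
the boundary instead. Practically: the hierarchy contrast between
clearly separated stages is the robust readout, and fine-grained
orderings of adjacent stages at short scan lengths — or inferences that
hinge on the fastest nodes — should be interpreted with caution.

## Hierarchy metrics: conventions and degenerate inputs

The Laplacian $\Delta$ is exactly singular (its nullspace contains the
constant vector), so $\Delta h = v$ is solved by minimum-norm least
squares and then min-shifted so the lowest node sits at level 0. The
edge residual is oriented $(h_{tail} - h_{head} - 1)$: with
$v = d^{out} - d^{in}$, sources sit high and each ideal edge drops one
level from tail to head; this is the orientation whose least-squares
minimizer is exactly the Laplacian solution, which we verify against
direct numerical minimization of the incoherence energy. $F_0$ is
invariant to uniform weight rescaling and to the global sign convention.
Disconnected graphs are solved and shifted per weakly connected
component (with a warning); isolated nodes get level 0; zero-variance
level vectors make every region a mediator in the regime
classification, again with a warning. Regime terciles are *equal-width*
intervals of the z-scored (population SD) group-mean levels, not
equal-count bins.

## Harmonization

`fit_combat()` implements the parametric empirical-Bayes location/scale
model: per feature, least-squares covariate effects with site means
constrained to a weighted-average zero; standardization by the pooled
residual scale; normal prior on the additive site effects and
inverse-gamma prior on the multiplicative ones, estimated by moments and
solved by the standard iterative conditional updates.
`apply_combat()` then subtracts the shrunk site location, rescales, and
reinstates the covariate effects. The split into a fitted model object
and an apply step (rather than a one-shot transform) lets the same model
harmonize held-out data and exposes $\gamma^*, \delta^*$ for recovery
tests; agreement with the reference one-shot implementation is verified
in the test suite. Subjects at single-subject sites are excluded first
(`filter_unique_sites()`), and harmonization runs at the regional level
before any network averaging. The quality check mirrors the design's
two validation criteria: within-group site differences must vanish after
harmonization while the sign of the age slope is preserved.

## Statistics

Covariate adjustment in the permutation test follows the Freedman–Lane
scheme: the outcome is residualized on the nuisance covariates, the
residuals are permuted and added back to the nuisance fit, and the
covariate-adjusted group $t$ statistic is recomputed; the two-sided
p-value uses the add-one correction, so it can never fall below
$1/(n_{perm}+1)$. Calibration is verified over a thousand null
simulations. FDR control is Benjamini–Hochberg.

The biomarker model is ridge-penalized on the fixed effects (continuous
predictors standardized) with unpenalized subject intercepts estimated
by closed-form shrinkage, alternating to convergence; the penalty is
selected by generalized cross-validation unless supplied. Significance
comes from permuting the focal predictor within subject. Cognition
models are ordinary least squares per (score, network) pair with FDR
over the whole family, on complete cases.

## The classifier

Features are the regional trophic levels, the seven network means and
global directedness. The mRMR ranking (F-statistic relevance over mean
absolute correlation redundancy, the quotient variant) is greedy and
therefore nested, so one ranking per training fold serves every
candidate feature count. The nested LOOCV grid search pools out-of-fold
probabilities into a single ROC per hyperparameter cell (per-fold AUC is
undefined for single held-out samples); ties prefer fewer features,
stronger regularization, then L2. Regularized logistic models are fitted
by glmnet with $\lambda = 1/(n\,\mathrm{C})$ mapping the
inverse-regularization grid. The decision threshold maximizes Youden's
$J$ on the training refit probabilities (ties to the lowest threshold);
the permutation test permutes *test* labels against fixed predictions;
ROC curves are averaged vertically on a 0.01-step FPR grid; Shapley
values use the exact linear form $\phi_j = w_j (x_j - \bar x_j)$ with
unselected features at exactly zero.

## Problem sizes used by the shipped analyses

The analysis scripts and acceptance checks run a 20-region, 40-subject
cohort (10 per group, 197 volumes at TR = 3 s), chosen as the smallest
configuration in which every pipeline stage — spectral estimation,
two-stage GEC fitting, hierarchy metrics, harmonization across three
sites, the four group contrasts and the staging classifier — operates in
its intended regime. Statistical calibration checks use 1,000 null
simulations; oracle checks for the Lyapunov solver use a $10^6$-step
simulated trajectory. The full-scale protocol (80 regions, hundreds of
subjects) is a direct parameter change in `cohort_config()`.
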