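---
title: "Estimating relative transcription rates with unknown copy number"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating relative transcription rates with unknown copy number}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiertxn)
```

## The problem

Transient transfection is the workhorse for comparing promoter and enhancer
constructs in live-cell reporter assays, but each cell receives an unknown
number of plasmid copies. The fluorescence a cell produces depends on the
*product* of its copy number $c$ and its per-copy transcription rate
$\tau$: from a single onset curve, $c$ and $\tau$ are not separately
identifiable. hiertxn implements a hierarchical Bayesian treatment of a
population of such curves in which the copy numbers of all cells are tied
together by one shared distribution, which makes *relative* per-copy rates —
ratios between construct groups — identifiable even though the absolute
scale is not.

## The kinetic model

Each cell follows the standard two-stage expression model, written as a pair
of Itô SDEs for mRNA $M(t)$ and reporter protein $P(t)$ in molecule-number
units:

$$
dM = \big(c\,\tau(t) - \delta_M M\big)\,dt
   + \sqrt{c\,\tau(t) + \delta_M M}\; dW_1, \qquad
dP = \big(\alpha M - \delta_P P\big)\,dt
   + \sqrt{\alpha M + \delta_P P}\; dW_2 ,
$$

with the diffusion terms given by the *sum* of birth and death propensities
(the central-limit construction for birth–death processes). Transcription is
a single changepoint function: a basal level $\tau_{\mathrm{off}}$ before
the switch time $s$ and an active level $\tau_{\mathrm{on}}$ from $s$
onwards (the boundary instant belongs to the on-phase; since observations at
exactly $s$ have probability zero, any consistent convention would do). No
ordering $\tau_{\mathrm{on}} > \tau_{\mathrm{off}}$ is imposed — phases are
labelled by time, and in practice the data and priors order them. The
measurement equation is linear with additive Gaussian noise,
$y_t = \kappa P(t) + \varepsilon_t$, $\varepsilon_t \sim N(0,
\sigma^2_\varepsilon)$.

Both the drift and the diffusion depend on $c$ and $\tau$ only through
$c\tau$, which is the identifiability degeneracy in exact, function-level
form; the package tests assert that the likelihood is invariant to machine
precision under $(c, \tau_{\mathrm{on}}, \tau_{\mathrm{off}}) \to
(\gamma c, \tau_{\mathrm{on}}/\gamma, \tau_{\mathrm{off}}/\gamma)$.

## Likelihood: linear noise approximation

The per-cell likelihood uses the linear noise approximation: the mean of
$(M, P)$ follows the deterministic rate equations and fluctuations are
Gaussian, so the data likelihood is a Gaussian state-space filter. The mean
has an exact closed form per phase (the system is linear with constant
coefficients within each phase); the covariance ODE
$\dot\Sigma = A\Sigma + \Sigma A^\top + D(\phi(t))$ is integrated by
fixed-substep RK4 against that closed-form mean (default 20 substeps per
inter-observation interval, validated against a brute-force fine-step Euler
oracle to $10^{-6}$ relative error). Substeps are added automatically when
an interval is long relative to the fastest relaxation rate, keeping RK4
inside its stability region. Integration is split at the switch time when it
falls inside an interval. Filtering starts at transfection,
$M(0) = P(0) = 0$ with zero covariance — onset curves are assembled from the
transfection time, and this is the package's choice of initial law.

Each observation triggers a scalar Kalman update with predictive variance
$S = \kappa^2\Sigma_{PP} + \sigma^2_\varepsilon$. The log-likelihood keeps
every normalization constant, so that cells observed for different numbers
of frames contribute comparably — dropping constants would let long series
dominate. After each update the $2\times 2$ covariance is checked for
positive semi-definiteness; eigenvalues are clipped at
$-10^{-10}\,\mathrm{tr}\,\Sigma$ and anything more negative raises an error
rather than being silently repaired.

One genuinely open choice is where to evaluate the diffusion matrix $D$:
along the unconditioned deterministic mean (the textbook formulation) or
along the filtered mean restarted after every update. The package defaults
to the filtered variant, which re-centres the noise level on what the data
say the trajectory is doing; the deterministic variant is available via
`linearization = "deterministic"` and is the one for which sequential
filtering coincides *exactly* with the dense joint-Gaussian likelihood (the
package tests both that exact identity and the close agreement between the
two variants).

## The population layer

Per-cell parameters are drawn from population distributions whose
parameters are estimated jointly:

* $\tau_{\mathrm{on}}$ and $\tau_{\mathrm{off}}$: lognormal, location/scale
  per construct group (a config switch collapses $\tau_{\mathrm{off}}$ to a
  single global family; the group-wise default parallels the on-rate);
* $\alpha$: one global lognormal (same reporter protein in every group);
* $1/\sigma^2_\varepsilon$: gamma — each cell has its own variance drawn
  from the shared gamma (a `shared_sigma_eps2` switch forces one common
  variance instead);
* $c$: zero-truncated *continuous* Poisson (rate $\lambda$ shared by all
  groups). The continuous form replaces the factorial by
  $\Gamma(c + 1)$, because the magnitude of $c$ is confounded with $\tau$ so
  an integer support would be an artificial constraint. Truncation reflects
  that untransfected cells are never observed. Its normalizer
  $R(\lambda) = \int_0^\infty \lambda^c e^{-\lambda}/\Gamma(c+1)\,dc$ is
  computed by adaptive quadrature and cached on a $\lambda$-grid with spline
  interpolation (grid error below $10^{-6}$, exact quadrature off-grid);
* switch times: flat over each cell's observation window — they are
  cell-specific events, deliberately *not* hierarchical.

Degradation rates $\delta_M$, $\delta_P$ and the fluorescence constant
$\kappa$ are fixed, known inputs: with a single off→on switch the data carry
little information about degradation, so these are supplied from
independent (population-level) measurements.

Hyperpriors are proper but weak, and deliberately simple: $N(0, 10^2)$ on
every lognormal location, half-normal(5) on every scale, exponential(0.01)
on the precision shape, precision rate and $\lambda$. Each form is a single
function so alternates can be swapped.

## Sampling

All positive parameters are sampled on the log scale; the Jacobian
$\sum(\ln\theta' - \ln\theta)$ enters the acceptance ratio. Switch times are
proposed on their natural scale with reflection at the window bounds. Each
iteration updates a round-robin block of cells (default: all of them),
perturbing three parameters per cell, alternating the kinetic triple
$(\tau_{\mathrm{on}}, \tau_{\mathrm{off}}, s)$ with
$(\alpha, c, \sigma^2_\varepsilon)$ so every parameter is covered. Within a
block the per-cell likelihood evaluations are mutually independent, and two
acceptance styles are provided: `per_cell` (the default — valid because
cells are conditionally independent given the population layer, and it
mixes better) and `joint_block` (one accept/reject decision for the whole
block). Both are tested to target the same posterior.

After each block update comes a *ridge move*: per cell, $c$ is scaled by
$e^\epsilon$ and both transcription levels by $e^{-\epsilon}$. The
likelihood is exactly invariant along this direction, so the move is
arbitrated by the priors and Jacobian alone and costs no likelihood
evaluation. Without it the copy number freezes near its starting value —
single-coordinate moves off the $c\tau$ ridge are rejected by the
likelihood — and group ratios then reflect the confounded products rather
than the per-copy rates. A *group-level* ridge move follows: an entire
group's copy numbers scale up while its rates (and, in hierarchical mode,
the group's lognormal rate locations — a location shift has unit Jacobian)
move down together. This addresses the collective degree of freedom that
sets between-group allocations, which per-cell moves traverse only by a
slow random walk. A second, weaker trade-off direction exists through
the translation rate (the protein mean constrains the triple product
$c\,\tau\,\alpha$; only the intrinsic-noise structure separates $\alpha$
from transcription), but unlike the copy direction it is
likelihood-informed and mixes under the ordinary proposals, so no dedicated
move is used for it. Per-cell summaries should be read accordingly: the
tightly identified quantity is $c\,\tau\,\alpha$ (and, through the shared
distributions, $c\,\tau$), not any factor alone.

Population-layer updates are serial: lognormal locations by exact conjugate
normal Gibbs draws, scales by log-space MH against the half-normal
hyperprior (the half-normal is not inverse-gamma conjugate, so a joint
conjugate update is unavailable by construction), and the precision pair and
$\lambda$ by log-space MH. Proposal scales adapt by Robbins–Monro toward 0.3
acceptance during burn-in only and are frozen afterwards, so the retained
chain is a valid MH chain. Split-$\hat R$ and a crude autocorrelation ESS
are reported for every population-layer quantity but never used as stopping
rules.

The non-hierarchical baseline (`mode = "standard"`) replaces the population
layer with fixed wide priors — lognormal with log-scale sd 10 on each
positive rate, a vague gamma on the precision, and the truncated Poisson
copy prior at a fixed configured $\lambda$ (some proper prior on $c$ is
unavoidable) — and never updates them.

Starting values are heuristic: the switch at the steepest smoothed signal
increase (window midpoint for flat cells, with a warning), the on-rate from
the terminal signal level through the stationary mean with $c$ at the copy
prior mean, everything else from jittered defaults; the population layer
starts at the moments of the per-cell starts.

## The synthetic benchmark

The generator emulates the validation design: three construct groups with
on-rate means in ratio 1:2:5 and lognormal variance equal to the mean (Fano
factor 1), translation rates lognormal, measurement error variances
inverse-gamma, copy numbers integer zero-truncated Poisson (rejection
sampling — exact and trivially correct), one uniformly drawn switch per
cell, and exact Gillespie simulation of every trajectory with the
changepoint handled by propensity re-draw at the switch (exact for a
piecewise-constant rate). Degradation rates and $\kappa$ are generator
constants, mirroring their "known and fixed" role in estimation.

Only the design ratios and the Fano factor are treated as ground truth from
the validation design; absolute parameter values are this package's own
choices, made once to sit inside the LNA's cited validity range (at least
~5 mRNA and ~100 protein molecules): group on-rate means 2/4/10 per copy
per unit time, basal rate mean 0.2 (Fano 0.1), translation mean 1 (Fano 1),
$\delta_M = 0.2$, $\delta_P = 0.1$, $\kappa = 1$, $\lambda = 5$,
inverse-gamma(3, 50) measurement variance, 50 observations over 25 time
units, switches in [2, 10]. Desk-scale defaults are 15 cells per group and
30,000 iterations (10,000 burn-in, thin 5); the smaller property-suite
experiments use 10–20 cells and 8,000 iterations.

What passing the benchmark does *not* show: the generator contains no
tracking/segmentation artifacts, photobleaching, maturation delay, cell
division, or bursting/refractory transcription — real onset curves violate
the single-changepoint model in ways the synthetic suite cannot expose.
Conclusions about real data rest on the model being an adequate description
of the ascending onset phase.

## Numerical choices and degenerate inputs

* Mean propagation uses `expm1`-based stable forms of
  $(1 - e^{-a\,dt})/a$ and its relatives, with series limits below
  $a\,dt < 10^{-8}$, so near-zero rates degrade gracefully to the pure-birth
  formulas.
* Likelihood failures inside MCMC proposals are treated as $-\infty$
  (rejection) with a warning context, not as crashes; a non-finite *initial*
  posterior aborts with the offending cell named.
* Empty observation sets have log-likelihood 0 (empty product); one-point
  series reduce to a closed-form normal density (both tested).
* The sorted-posterior heat-strip uses 100 bins over the pooled 0.5–99.5
  percentile range — purely a rendering choice.

## Reporting conventions

Two population summaries are computed, matching the dual reporting
convention of the study design: *hierarchical* statistics (lognormal
moments at the posterior means of each group's location and scale) and
*pooled* statistics (sample moments of per-cell posterior means). Ratios
between groups use the hierarchical means when available; because every
group shares the same copy-number distribution, these ratios are the
comparable quantity — absolute rates are defined only relative to that
distribution. The ratio point estimate follows the "mean of the chains"
convention; the full posterior of the ratio can be formed from the stored
hyperparameter samples when an interval is wanted.

## How much ratio accuracy to expect

Between-group ratios are identified *through the shared distributions*, not
directly: each cell's likelihood pins essentially one number (the product
$c\,\tau\,\alpha$), and the split among its factors is arbitrated by the
copy-number and translation-rate populations. The recoverable ratio
therefore degrades toward the ratio of group-mean *products* as the copy
and translation spreads grow. At the default benchmark conditions
($\lambda = 5$, so copy CV $\approx 0.45$; translation Fano 1, so CV
$\approx 0.83$) the posterior standard deviation of a between-group
log-ratio with 15 cells per group is roughly 0.3, and the realized group
means of the unidentified factors shift the center by a comparable amount.
Concretely: point estimates of a true 2-fold difference can land anywhere
from ~1.4- to ~2.7-fold. More cells per group, narrower translation-rate
heterogeneity, or higher mean copy number (which shrinks the *relative*
copy spread) all tighten this; report interval summaries of the ratio, not
bare points, when the decision depends on it.

## Known limitations

* One changepoint only: no oscillations, bursts, or multiple switches.
* Additive Gaussian measurement noise; multiplicative noise is out of scope.
* The absolute scale of per-copy rates (equivalently of $\lambda$) is a
  flat direction constrained only by priors; only ratios should be
  interpreted.
* Single-chain diagnostics (split-$\hat R$ on one chain) are necessarily
  optimistic; for publication-grade inference run several seeds and pool.
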