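---
title: "Profile-likelihood identifiability analysis for fMRI effective connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-likelihood identifiability analysis for fMRI effective connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcmprofile)
```

## The problem

Dynamic causal modeling (DCM) infers directed ("effective") connectivity
between brain regions from fMRI time series. Before acquiring data it is
hard to know whether a planned acquisition — repetition time (TR), session
length, stimulus epoch structure, attainable signal-to-noise ratio (SNR) —
will actually pin down the connectivity parameters, or whether the
estimates will mostly echo whatever priors a Bayesian inversion imposes.
`dcmprofile` answers that question by simulation: it generates synthetic
BOLD data from a candidate DCM under a candidate design, estimates all
parameters by maximum likelihood *without priors*, traces each parameter's
profile likelihood, and reports likelihood-based confidence intervals (CIs)
and an identifiability verdict per parameter, plus a single design-level
score. The deliberate omission of priors is the worst case: it shows what
the *data alone* can determine.

## The model

Hidden neuronal activity $z(t) \in \mathbb{R}^m$ of $m$ regions follows the
deterministic bilinear state equation

$$\dot z = \Big(A + \sum_i B^{(i)} u_i(t)\Big) z + C\, u(t),$$

where $u(t)$ are the experimental inputs (unit-height boxcars over
half-open intervals $[\text{onset}, \text{onset}+\text{duration})$; a
"stick" event is a boxcar one microtime bin long). $A$ holds the fixed
coupling rates (Hz), $B^{(i)}$ the modulation of couplings by input $i$,
and $C$ the driving-input strengths. Diagonal entries of $A$ are always
free parameters and should be negative (inhibitory self-connections that
prevent run-away excitation). The nonlinear (second-order) term of the
full DCM state equation is not modeled — the common bilinear
approximation.

The observable is the BOLD signal, modeled as the convolution of $z$ with
the canonical hemodynamic response function

$$\mathrm{HRF}(t) = \Gamma_{pdf}(6, 1, t) - \tfrac16\,\Gamma_{pdf}(16, 1, t),$$

a difference of two gamma densities with a peak near 5 s, an undershoot
near 16 s and a 1:6 peak-to-undershoot coefficient. The canonical kernel,
rather than a full biophysical hemodynamic state model, keeps every
observation parameter fixed and the computation fast; the cost is that
regional hemodynamic variability is not represented (see *Limitations*).
In `gamma_pdf(h, l, t)` the second argument is treated as a **rate**
($\propto l^h t^{h-1} e^{-lt}$); for the canonical kernel with $l = 1$ the
rate/scale distinction is moot, but the convention matters for
user-supplied kernels and is fixed here.

## Numerics of the forward model

The neuronal ODE is integrated on the *microtime* grid with step
$t_s = \mathrm{TR}/\#\text{slices}$. Because the inputs are piecewise
constant, the time axis is split wherever any input changes, and within
each bin the frozen affine system $\dot z = Mz + c$ is propagated with the
matrix exponential of the augmented $(m{+}1)\times(m{+}1)$ system — exact
up to `expm` itself, with bin boundaries coinciding exactly with input
change points and microtime samples (times are bookkept in integer
nanoseconds so coincident points are exactly coincident). Only a handful
of (input pattern, bin width) combinations occur in a design, so their
propagators are computed once and reused.

The convolution with the sampled HRF kernel (default support 32 s) is a
discrete causal convolution scaled by $t_s$, i.e. a left Riemann sum of
the convolution integral; refining the grid changes the result at the
$10^{-3}$ relative level or below, which is far inside the noise at any
realistic SNR. Observations are taken once per TR at the first microtime
bin of each TR period by default (`sample_offset` exposes other slice
references). The initial condition is $z(0) = 0$, the resting baseline.

Candidate parameter sets explored during optimization can make the system
unstable. Any state exceeding $10^6$ in magnitude (or turning non-finite)
flags the trajectory as *diverged*; the objective then reports a fixed cap
of $10^{12}$ rather than a partial sum, so the optimizer sees divergence
as uniformly terrible rather than as noise.

## Estimation

With known per-region noise SDs $\sigma_i$, the objective is the weighted
sum of squared residuals

$$\chi^2(\theta) = \sum_{i=1}^m \sum_k
  \frac{\big(Y_i(t_k) - \hat Y_i(t_k, \theta)\big)^2}{\sigma_i^2},$$

whose minimizer is the maximum-likelihood estimate under Gaussian noise
($\chi^2 = \text{const} - 2\log L$). Note the **squared** $\sigma_i$ in the
denominator: only this convention is consistent with the Gaussian
likelihood, and the package uses it throughout. Minimization uses
Levenberg–Marquardt (`minpack.lm::nls.lm`) on the residual vector
$(Y - \hat Y)/\sigma$ with forward-difference Jacobians (step
$\approx 10^{-6}$), gradient tolerance $10^{-8}$, step tolerance
$10^{-10}$, at most 500 iterations.

Start values emulate "a previous estimate, slightly perturbed": each free
parameter of the generating vector is shifted by $\pm 0.1$ with random
signs (`perturb_start()`). Such a start can itself lie in a diverging
regime — marginally stable networks lose stability quickly when
excitatory couplings grow — and on the divergence plateau the gradient
vanishes. `fit_dcm()` therefore checks the start, and on divergence (or a
failed optimization) retries with modified off-diagonal $A$ start values
(damped, sign-flipped, then zeroed; self-connections are never touched) up
to a restart budget of 5. An exhausted budget yields `converged = FALSE`,
never an error.

## Synthetic data: what it emulates, what it does not

`simulate_dataset()` produces the deterministic BOLD response and adds
independent Gaussian noise per region and volume, calibrated as
$\sigma_i = \mathrm{sd}(Y_i^{clean})/\mathrm{SNR}$ — SNR as an SD ratio,
the usual fMRI convention. The same $\sigma_i$ are handed to the
estimator, i.e. the "known measurement error" regime the $\chi^2$
objective assumes; for external data the user must supply noise SDs. Not
emulated: temporal autocorrelation, scanner drift, motion, physiological
noise, regional HRF variability. Passing tests therefore certify the
statistical machinery under the model's own assumptions; on real data the
reported CIs will be optimistic to the extent these nuisances matter.

The bundled three-region visual-attention fixtures (V1, V5, SPC; driving
input Photic on V1; modulations Motion and Attention) follow the classic
forward/backward model pair: both share bidirectional V1–V5 and V5–SPC
coupling with three self-connections and one driving input (10 free
parameters); in the forward variant both modulations act on V1→V5, in the
backward variant Motion stays on V1→V5 and Attention moves to SPC→V5.
Which modulation sits on which backward-model connection is genuinely
underdetermined by the verbal description of that model family; the
assignment here follows the standard usage and is configurable in the
fixture file. The original study's posterior parameter values and exact
stimulus onsets are not public, so the fixtures carry documented,
deliberately plausible values — self-connections $-0.5$ Hz, inter-regional
couplings $+0.3$ Hz, driving input $0.8$, modulations $0.4$ — and a
rule-generated blocked train: per input, onsets every 64.4 s with 32.2 s
epochs, Photic on every block, Motion on even blocks, Attention on odd
blocks, under the original acquisition (TR 3.22 s, 32 slices, 360 volumes,
19.32 min, SNR 10). Consequently the package reproduces the *qualitative*
design trends, not any particular published mCI number, which depended on
those unpublished values and on single noise draws.

## Profile likelihood and confidence intervals

For each parameter $\theta_i$ the profile likelihood is

$$\chi^2_{PL}(\theta_i) = \min_{\theta_{j \ne i}} \chi^2(\theta),$$

computed by scanning $\theta_i$ away from $\hat\theta_i$ in both
directions and re-optimizing all other parameters at every grid point,
warm-started from the neighbouring point's optimum (falling back to
$\hat\theta$ after an inner divergence). The likelihood-based CI is
$\{\theta_i : \chi^2_{PL}(\theta_i) - \chi^2(\hat\theta) < \Delta_\alpha\}$
with $\Delta_\alpha$ the $(1-\alpha)$ quantile of $\chi^2_{df}$;
point-wise intervals use $df = 1$, so $\alpha = 0.05$ gives
$\Delta_\alpha = 3.84$. Unlike Hessian-based asymptotic intervals, these
CIs need no quadratic approximation — important here because the BOLD
observables depend non-linearly on the connectivity parameters — and they
are reparameterization-invariant.

Scan mechanics (the step rule is a design choice; the scanned quantity is
not): the initial step is $\max(0.01, 0.05\,|\hat\theta_i|)$, grown by 1.5
when a step raises $\chi^2$ by less than $\Delta_\alpha/10$ and retracted
and halved when a proposed step would raise it by more than
$\Delta_\alpha/3$, so the threshold crossing is always bracketed by a
fine-enough pair for linear interpolation (the retraction matters when the
true CI is narrower than the initial step). A direction stops after
overshooting the threshold by $0.5\,\Delta_\alpha$, at 100 points
(configurable), or when the divergence cap is hit — a cap counts as an
upper-side crossing, since parameter values that force divergence are
certainly incompatible with the data.

Classification follows the standard taxonomy:

* **identifiable** — both crossings exist; the CI is finite.
* **practically non-identifiable** (lower/upper/both) — the profile has a
  minimum but never reaches the threshold on one or both sides; the CI is
  open on that side. More volumes, shorter TR, better epochs or higher
  SNR can restore identifiability.
* **structurally non-identifiable** — the profile is flat (total
  variation below $0.01\,\Delta_\alpha$ over the scanned range, neither
  crossing found): other parameters compensate exactly, and no amount of
  the same kind of data helps.

`contains_zero` is reported per CI because a CI that straddles zero means
the data cannot even establish the connection's existence.

The design-level score is the **mean CI width (mCI)** across all
parameters — the A-optimality criterion. Any open bound makes it
infinite, so mCI is finite exactly when every parameter is identifiable.

## Design sweeps

`vary_tr()`, `vary_session()` and `vary_epoch()` generate design variants
along the axes that matter in practice. Changing TR holds the *session
length* fixed (volume count rescales, rounding down) because session
duration is its own axis; a `hold_volumes` mode is provided. Extending a
session repeats each input's stimulus pattern at its original onset
spacing; shrinking truncates. Changing epoch duration keeps every onset
and the stimulus count, so epoch length is varied in isolation; epochs
longer than the onset spacing would overlap and are rejected.
`run_sweep()` assesses every variant × replicate with seed
`base_seed + 1000*variant + replicate` (the factor keeps seeds distinct
across the grid, so every row is an independent noise realization) and
returns a tidy table. Replicates are an extension over a single-draw
evaluation of each variant: single-draw mCI values are noticeably seed
dependent, so trend statements should be made over replicates.

## Problem sizes used in the shipped checks

The package's own validation (test suite and `scripts/acceptance.R`) runs
at sizes chosen to make each check sharp but affordable: the full
three-region fixture at its original acquisition for the SNR-10 and SNR-1
assessments; a two-region chain (4 parameters, TR 2 s, 180 s session) for
the 200-replicate coverage study of the 95% CIs; reduced microtime/session
scale (8 slices, half session) for the TR-trend replication over seed
pairs; and closed-form linear submodels (driving strengths with the
self-connection held fixed) for oracle comparisons against analytic
weighted-least-squares CIs and a brute-force 2-D profile grid. The
vignette states these sizes as the package's choices; all are
configurable.

## Known limitations

* The canonical HRF is shared by all regions; hemodynamic parameters are
  not estimated. With a richer hemodynamic model some parameters could
  become structurally non-identifiable (hidden hemodynamic states are not
  observed) — worth keeping in mind when extrapolating the verdicts.
* Noise is white and Gaussian with known SD; real fMRI noise is neither.
* The stochastic variant of DCM, Bayesian inversion, priors, and model
  comparison are out of scope; the likelihood-only analysis is the point.
* mCI from a single noise realization is seed-dependent; use replicates
  for design decisions.
* MAT-file containers from other toolboxes are not read; models and
  designs are interchanged through the documented YAML/JSON schema
  (`inst/extdata/config-schema.md`).
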