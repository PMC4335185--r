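# dcmprofile

Will a planned fMRI acquisition actually pin down the effective-connectivity
parameters of a dynamic causal model (DCM), or will the estimates mostly
reflect whatever priors a Bayesian inversion imposes? `dcmprofile` answers
this *before* data acquisition, for researchers designing DCM studies: it
simulates BOLD data from a candidate bilinear DCM under a candidate
acquisition design, estimates every connectivity parameter by maximum
likelihood **without priors**, traces each parameter's profile likelihood,
and classifies each parameter as identifiable, practically
non-identifiable, or structurally non-identifiable. Whole designs are
scored with the mean confidence-interval width (A-optimality), so the
effect of repetition time (TR), session duration, epoch duration and SNR
on identifiability can be compared directly.

## The model and the statistic

Hidden neuronal activity `z(t)` of `m` regions follows the bilinear state
equation

    dz/dt = (A + Σᵢ B⁽ⁱ⁾ uᵢ(t)) z + C u(t)

with fixed couplings `A` (Hz), input-dependent modulations `B⁽ⁱ⁾`, driving
inputs `C`, and boxcar stimulus functions `u(t)`. The observable BOLD
signal is `z` convolved with the canonical double-gamma hemodynamic
response `HRF(t) = Γpdf(6,1,t) − (1/6)·Γpdf(16,1,t)`, sampled once per TR,
plus Gaussian noise with per-region SD `σᵢ = sd(signal)/SNR`.

Parameters are estimated by minimizing the weighted sum of squared
residuals `χ²(θ) = Σᵢₖ (Yᵢ(tₖ) − Ŷᵢ(tₖ,θ))²/σᵢ²` (Levenberg–Marquardt),
which is maximum likelihood for Gaussian noise. For each parameter `θᵢ`
the profile likelihood `χ²PL(θᵢ) = min over θⱼ≠ᵢ of χ²(θ)` is scanned, and
the likelihood-based confidence interval is the set where
`χ²PL − χ²(θ̂) < Δα` with `Δα = qchisq(1−α, 1)` (3.84 for 95% point-wise
intervals). Finite bounds on both sides → identifiable; a minimum that
never crosses the threshold on one or both sides → practically
non-identifiable (fixable with more/better data); a flat profile →
structurally non-identifiable (exact parameter compensation). The mean CI
width across parameters (mCI; infinite if any bound is open) scores the
design.

## Worked example

Assess the bundled three-region visual-attention "forward" model (V1, V5,
SPC; driving input Photic on V1; Motion and Attention both modulating
V1→V5; 10 free parameters) under its original acquisition — TR 3.22 s,
32 slices, 360 volumes (19.32 min), SNR 10:

```r
library(dcmprofile)
fx  <- load_fixture("forward")
rep <- assess_model(fx$model, fx$design, snr = 10, seed = 1,
                    settings = profile_settings(max_points = 20,
                      control = fit_control(maxiter = 100, restarts = 0,
                                            ftol = 1e-6, gtol = 1e-6,
                                            xtol = 1e-8)))
print(rep)
```

```
Identifiability report (SNR 10, seed 1)
             parameter truth   estimate       lower      upper       status contains_zero
              A:V1->V1  -0.5 -0.5106698 -0.56427886 -0.4658196 identifiable         FALSE
              A:V5->V1   0.3  0.3094560  0.28069595  0.3438855 identifiable         FALSE
              A:V1->V5   0.3  0.4649713  0.27457869  0.8173142 identifiable         FALSE
              A:V5->V5  -0.5 -0.5274577 -0.65851986 -0.4496001 identifiable         FALSE
             A:SPC->V5   0.3  0.1707733 -0.03116378  0.3050698 identifiable          TRUE
             A:V5->SPC   0.3  0.2956668  0.27716060  0.3166318 identifiable         FALSE
            A:SPC->SPC  -0.5 -0.4927767 -0.52801497 -0.4616949 identifiable         FALSE
      B(Motion):V1->V5   0.4  0.4032301  0.37560785  0.4387819 identifiable         FALSE
   B(Attention):V1->V5   0.4  0.4035361  0.37591929  0.4390940 identifiable         FALSE
          C:Photic->V1   0.8  0.6723282  0.52726024  0.8077375 identifiable         FALSE
mCI = 0.1762
```

Every parameter is identifiable at SNR 10 (finite CIs covering the truth),
but the connections into the densely connected hub V5 (`A:V1->V5`,
`A:SPC->V5`) carry the widest intervals, and `A:SPC->V5` is compatible
with zero — its existence cannot be settled by this design. Repeating the
assessment at `snr = 1` leaves several parameters with open CI bounds, so
`mCI = inf`. `render_report(rep, "out/")` writes the CI table, the
per-parameter profile curves, a multi-panel profile plot (profile in blue,
χ² threshold in red, true value in green) and a summary whose last line is
the `mCI = ...` verdict.

Design questions are asked with the sweep tools: `vary_tr()` (session
length preserved), `vary_session()` (stimulus train truncated or
cyclically extended), `vary_epoch()` (onsets and stimulus count
preserved), and `run_sweep()` to tabulate mCI and identifiability over a
grid with replicate noise realizations. A command-line front end is in
`inst/cli/dcmprofile.R` (`simulate | fit | profile | sweep | report`);
model/design configs are plain YAML/JSON
(`inst/extdata/config-schema.md`).

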