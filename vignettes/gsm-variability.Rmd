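---
title: "Posterior uncertainty and spike-count variability in a Gaussian scale mixture model of V1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Posterior uncertainty and spike-count variability in a Gaussian scale mixture model of V1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsmv1)
```

## The model

Neurons in primary visual cortex respond variably across repeated
presentations of the same stimulus. Under the neural-sampling hypothesis this
variability is not noise: instantaneous activity is a sample from the
posterior distribution over the stimulus feature the neuron encodes, so
across-trial variance reports the width of that posterior — the uncertainty
of the inference. `gsmv1` implements this idea for the Gaussian scale mixture
(GSM) model of local image statistics and provides everything needed to
simulate and test its predictions.

The generative model of the observable filter responses $\mathbf{x}$ is

$$\mathbf{x} = \nu\,\mathbf{g} + \boldsymbol{\eta},\qquad
\mathbf{g}\sim\mathcal N(0, C_g),\quad
\nu\sim\mathrm{Rayleigh}(\sigma),\quad
\boldsymbol{\eta}\sim\mathcal N(0, C_{\mathrm{noise}}).$$

The local features $\mathbf g$ (oriented contrast at the receptive field and
eight surround positions) are what model neurons encode; the scalar mixer
$\nu$ is a global modulator (overall contrast/energy) shared by all features;
$\boldsymbol\eta$ is observation noise that keeps responses and variability
realistic for weak inputs. Because $\nu$ multiplies $\mathbf g$, observing
$\mathbf x$ leaves an ambiguity that couples the inferred magnitude of
$\mathbf g$ and its uncertainty: in one dimension without noise, $\nu g = x$
pins the pair to a hyperbola, and a larger inferred $\nu$ shrinks both the
mean and the spread of $g$ (`mixer_constraint_interval(10, 4, 5)` gives the
admissible interval $[2, 2.5]$; a weaker belief $\nu\in[1,2]$ gives
$[5, 10]$). An additive modulator has no such effect — the conjugate-Gaussian
control `additive_control_posterior_1d()` has posterior variance exactly
independent of the input — so the mean–variance coupling is specifically a
signature of multiplicative latent structure.

### The mixer parametrization

We parametrize the mixer prior by its Rayleigh **scale** $\sigma$ (default
1), not its mean. With $\sigma = 1$ the large-$\lambda$ expansions used
throughout,

$$\mathrm E[\nu\,|\,\mathbf x]=\sqrt\lambda\,[1+O(\lambda^{-1})],\qquad
\mathrm E[g_{1+}|\mathbf x]=\frac{x_{1+}}{\sqrt\lambda}[1+O(\lambda^{-1})],\qquad
\mathrm{FF}[g_{1+}|\mathbf x]=\frac{x_{1+}}{4\lambda\sqrt\lambda}[1+O(\lambda^{-1})],$$

with $\lambda=\sqrt{\mathbf x^\top C_g^{-1}\mathbf x}$, are exact up to
relative corrections of order $1/\lambda$; we verified by quadrature on the
exact scalar posterior that a unit-*mean* parametrization instead leaves a
persistent $\approx 11\%$ offset in these forms at every $\lambda$. The two
parametrizations describe the same generative model up to a relabeling of
$\nu$ and $\mathbf g$ (rescaling $\sigma$ is equivalent to rescaling $C_g$),
so nothing of substance depends on the choice; the scale-1 convention is the
one in which the printed asymptotics are clean. The moment-matching divisor
follows the convention: $C_g = \widehat{\mathrm{cov}}(\mathbf x)/\mathrm
E[\nu^2]$ with $\mathrm E[\nu^2]=2\sigma^2$.

$\lambda$ is the model's divisive-normalization signal: it pools the inputs
to *all* filters, divides the posterior mean by $\sqrt\lambda$ and the
variance by $\lambda^2$. Every contextual effect in the package flows through
it.

## Inference: exact scalar marginalization

Because the mixer is scalar, the posterior factorizes through a
one-dimensional marginalization. `posterior_noisy()` computes
$p(\nu\,|\,\mathbf x)\propto p_{\mathrm{Ray}}(\nu)\,\mathcal N(\mathbf x; 0,
\nu^2C_g + C_{\mathrm{noise}})$ on 2,000 log-spaced grid points covering the
prior's $[10^{-4},\,1-10^{-8}]$ quantile range, and draws
$\mathbf g\,|\,\nu,\mathbf x$ from the exact conditional Gaussian for each
$\nu$ drawn from the grid weights. This Rao–Blackwellized scheme needs no
burn-in or convergence diagnostics, is deterministic given a seed, and also
yields the *exact* posterior mean and covariance of $\mathbf g$ by
integrating the conditional moments over the grid (law of total variance).
Numerical safeguards:

* the grid's upper bound doubles automatically while the posterior mass in
  the top five grid points exceeds $10^{-6}$ (strong inputs concentrate
  $p(\nu|\mathbf x)$ near $\sqrt\lambda$, far above the prior's quantiles);
* a (near-)singular $C_{\mathrm{noise}}$ is floored at
  $10^{-10}\,\overline{\mathrm{diag}(C_g)}$ so the conditional is proper —
  this is how the noiseless limit is reached in practice;
* $C_g$ estimates are eigenvalue-floored at $10^{-8}$ of the largest
  eigenvalue before use.

The implementation is cross-checked two independent ways: against numeric
quadrature on the exact noiseless 1-D posterior
(`noiseless_posterior_1d()`), and against a brute-force importance sampler
over $(\nu, \mathbf g)$ with prior proposals on two-dimensional toy models
(agreement within 3 Monte Carlo standard errors; see the test suite).

## The filter bank and stimuli

`build_filterbank()` constructs 9 quadrature pairs of Gabor filters sharing
one orientation: one pair at the patch center (the RF) and eight on a ring.
Defaults: 80 px patch at 0.05°/px (a 4° patch, chosen so the full awake
size series up to 3.8° fits inside), 1 cycle/°, envelope SD 0.2° (RF
diameter roughly 0.8–1°), ring radius 0.5° — close enough that surround
envelopes overlap the RF envelope, as surround mechanisms partly overlap V1
RFs. The exact filter family and geometry of this class of models is a
convention rather than a measurement; all of it lives in `filterbank_spec()`
and is serialized with every trained model. Kernels are DC-free and
L2-normalized so outputs are comparable across positions and white-noise
output covariances are well conditioned. Coordinates: origin at the patch
center, x rightward along columns, y upward, angles counterclockwise from
horizontal; `orientation` is the stripe orientation (90 = vertical).

Stimuli use hard-edged circular apertures on mean-gray background (no
taper), matching the masked presentation of the experiments. Gratings at
`phase = 0` are spatially in phase with the odd center filter. The
natural-image surrogate is the `pink_texture` ensemble — random-phase images
with a $1/f$ amplitude spectrum, standardized to unit RMS luminance across
the ensemble so that individual patches keep natural contrast variability.
This surrogate reproduces the second-order (spectral) statistics of natural
images but none of their higher-order structure (edges, objects,
sparseness), so tests run on it demonstrate the model's *mechanisms* —
divisive coupling of mean and uncertainty, surround effects through the
mixer — not quantitative agreement with any published natural-image number.
Real image patches can be substituted through `load_image_patches()`
(PNG/TIFF, luminance rescaled to $[-1,1]$ around the mean, optional
selection of patches with RF energy above the ensemble median).

## Training

`train_gsm()` follows the moment-matching recipe: $C_g$ is the empirical
covariance of filter outputs over 10,000 training patches divided by
$\mathrm E[\nu^2]$ (training images treated as noise-free), and
$C_{\mathrm{noise}}$ is 0.1 times the empirical output covariance over
10,000 white-noise patches. The white-noise pixel SD is matched to the RMS
luminance of the (standardized) training ensemble, so the heuristic 0.1
keeps the noise a small fraction of the signal covariance. Training on white
noise instead of the $1/f$ surrogate changes the parameter values but not
the qualitative predictions, which depend on the multiplicative structure of
the model rather than on fine-tuned parameters.

## Spike counts and the simulated experiments

`spike_transform()` maps each posterior sample of the RF pair to a count,
$r = c\sqrt{g_{1+}^2+g_{1-}^2}$, with $c$ in spikes per unit feature
magnitude set per experiment (defaults 2 for broad image ensembles, 15 for
size tuning, 40 for surround tuning). Counts stay continuous by default; the
rounding error is negligible for the $c$ values used. The alternative
rectified expansive readout $c\max(g_{1+},0)^p$ (default $p=2$) exists
because the energy readout mispredicts the sign of contrast effects on
variance at fixed size, while size and surround-orientation predictions are
robust to the choice. Statistics per condition come from 400 posterior
samples, matching the study conditions; means, unbiased variances, Fano
factors and 68% percentile bootstrap CIs (1,000 resamples) are reported
with every tuning curve.

Three experiment drivers reproduce the model's signature behaviors:

* `run_mean_variance_scan()` — across an image ensemble (RF energy above the
  ensemble median), spike-count variance grows with the mean and the FF
  correlates positively with the mean (Pearson test against zero).
* `run_size_tuning()` — the mean count peaks for apertures near the RF size
  and is surround-suppressed for larger ones, while $\lambda$ keeps growing
  and the FF keeps falling: uncertainty decreases with stimulus size well
  after the mean has turned down. One caveat of the default geometry: the
  2.4° and 3.8° apertures both already cover the full filter support, so
  their true FFs differ by under 0.1% — strictly ordered in the exact
  grid moments (column `g1_ff_exact`) but below the resolution of 400
  samples (column `ff`). The tuning tables carry both columns for exactly
  this reason.
* `run_surround_orientation()` — a matched-orientation annulus raises the
  inferred mixer more than an orthogonal one, hence suppresses both the mean
  count and the FF more; the orientation tuning of variability suppression
  mirrors that of rate suppression.

## The recording-analysis pipeline

`analyze_size_tuning()` / `analyze_two_size_ff()` run the spike-count
pipeline on trial tables (real or surrogate): counts in a half-open window
`[latency, latency + duration)` shifted by each neuron's latency; baseline
from the fixed $[-20, 30)$ ms window; latency as the first post-onset
crossing of baseline mean + 1 SD by the smoothed PSTH (1 ms bins, smoothing
cubic spline with roughness parameter $2\times10^{-6}$ applied on the
seconds time axis — the printed parameter is convention-dependent, so the
convention is pinned here and validated on synthetic step-rate fixtures to
±10 ms); inclusion rules (responsivity, average FF ≤ 2, peak-size sanity,
RF centering, minimum surround suppression) each logged when they fire;
arithmetic means of counts and geometric means of FFs across conditions;
the symmetric percent FF change
$100\,(\mathrm{FF}_\alpha-\mathrm{FF}_\beta)/\tfrac12(\mathrm{FF}_\alpha+\mathrm{FF}_\beta)$
between the sizes nearest (by absolute log-ratio, respecting the
multiplicative size series) to half, one and two RF sizes; mean matching by
per-bin subsampling to *exactly* identical mean-count histograms (unit-width
bins by default, counts being integers) followed by a one-sided paired t
test; and significance by non-overlap of 68% bootstrap CIs
(touching intervals count as overlapping). Variances are unbiased
($n-1$) throughout; all resampling is seeded.

## The surrogate-recording generator

`generate_recording()` emits gain-modulated Poisson trains: per trial a
gamma-distributed gain with mean 1 and coefficient of variation `gain_cv`
scales the evoked rate after the neuron's latency, giving the analytic
ground truth $\mathrm{FF} = 1 + \bar n\,\mathrm{cv}^2$ for the counting
window. `make_size_tuning_fixture()` inverts this identity to program FF
targets per size; targets below 1 are outside the family (sub-Poisson counts
would need a different count model) and raise an error. The generator
emulates exactly the structure the pipeline assumes — independent trials,
stationary rates, no across-neuron correlations, no adaptation or
oscillations — so pipeline tests on it validate the *estimators*, not any
claim about real cortical dynamics.

## Problem sizes and determinism

The packaged defaults are the study conditions: 10,000 training patches,
400 posterior samples per condition, 1,000 bootstrap resamples,
1,000-patch scan ensembles, 2,000-trial recovery fixtures. The test suite
and the acceptance script run these in about a minute on a laptop core.
Every stochastic operation takes an explicit seed, records it in its output,
and restores the caller's RNG state; rerunning any experiment with the same
configuration reproduces its output files byte for byte.

## Known limitations

* The $1/f$ surrogate stands in for natural images; quantitative
  natural-image statistics (e.g. the exact mean–FF correlation value) are
  expected to differ from published natural-image analyses.
* Contextual modulation of the FF is much stronger in the model than in
  cortex, where additional latent sources of variability dilute the effect
  of spatial context; model-to-data comparisons should be directional, not
  quantitative.
* The spike readout's scaling constant $c$ is heuristic; only dimensionless
  quantities (FF ratios, percent changes, correlations) transfer across
  implementations with different filter normalizations.
* The mixer prior is fixed Rayleigh; richer mixer priors (and fitting GSM
  parameters to neural data) are out of scope.
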