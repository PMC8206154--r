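# gsmv1 — Gaussian scale mixture inference and spike-count variability in V1

Trial-to-trial variability of visual cortical responses is usually treated
as noise. Under the neural-sampling hypothesis it is signal: each response
is a sample from the posterior distribution over the stimulus feature the
neuron encodes, so across-trial variance reports posterior *uncertainty*.
`gsmv1` implements this account for the Gaussian scale mixture (GSM) model
of local image statistics and is aimed at computational neuroscientists who
want to simulate, test, or extend it, and at experimentalists who want the
matching spike-count analysis pipeline for their own recordings.

## The model in one paragraph

Observable filter responses follow **x** = ν **g** + **η**, with local
oriented features **g** ~ N(0, C_g), a scalar global modulator
ν ~ Rayleigh(σ) shared by all features, and observation noise
**η** ~ N(0, C_noise). **x** comes from 9 quadrature pairs of Gabor filters
(one RF pair, eight surround pairs on a ring, one shared orientation).
Because ν is multiplicative, inference couples the estimate of **g** to its
uncertainty through the divisive-normalization signal
λ = √(**x**ᵀ C_g⁻¹ **x**): for large λ,

    E[ν | x] ≈ √λ,   E[g₁₊ | x] ≈ x₁₊ / √λ,   FF[g₁₊ | x] ≈ x₁₊ / (4 λ √λ).

Spike counts are r = c·√(g₁₊² + g₁₋²) per posterior sample. Anything that
raises λ — higher contrast, larger stimuli, a matched-orientation surround —
shrinks posterior uncertainty and with it the Fano factor (FF), which is how
the model explains the observed mean–variance dependence, surround
suppression of variability, and its orientation tuning. Inference is exact:
the scalar mixer is marginalized on a grid and **g** | ν, **x** is
conditionally Gaussian (no MCMC).

## Worked example

Train the model on 10,000 1/f texture patches (the packaged surrogate for
natural images) and run the size-tuning experiment:

```r
library(gsmv1)
bank  <- build_filterbank(filterbank_spec())
model <- train_gsm(bank, "pink_texture", n_train = 10000, seed = 1)
st <- run_size_tuning(model, make_grating(bank$spec, diameter = 4),
                      c = 15, seed = 2)
st[, c("size_deg", "mean", "ff", "lambda", "E_nu")]
#>   size_deg  mean    ff lambda   E_nu
#> 1     0.34  67.3 15.10  0.761 0.0636
#> 2     0.55 107.1  3.33  2.874 0.7052
#> 3     0.90 140.3  3.79  4.365 1.0851
#> 4     2.40  88.8  2.19  8.037 1.8723
#> 5     3.80  88.8  1.91  8.041 1.8731
```

The mean spike count peaks at the 0.9° aperture (the model RF size) and is
surround-suppressed for larger stimuli, while λ and the inferred modulator
E[ν|x] keep growing — so the FF keeps falling long after the mean has turned
down. That dissociation is the model's core prediction. Surround orientation
tuning shows the same logic:

```r
so <- run_surround_orientation(model, seed = 3)
so[, c("condition", "mean", "ff", "E_nu")]
#>      condition mean    ff E_nu
#> 1 center_alone  374 10.25 1.09
#> 2  surround_90  252  5.53 1.65   # matched surround
#> 3 surround_135  271  6.31 1.50
#> 4 surround_180  346  9.93 1.18   # orthogonal surround
#> 5 surround_225  283  6.67 1.46
```

A matched surround (90°, the bank orientation) raises the inferred modulator
most and therefore suppresses both the mean count and the FF most; an
orthogonal surround barely does either.

For recordings, `generate_recording()` produces gain-modulated Poisson
surrogates with analytically known FF = 1 + mean·cv², and
`analyze_size_tuning()` / `analyze_two_size_ff()` run the full spike-count
pipeline (latency estimation, inclusion criteria, FFs with bootstrap CIs,
symmetric percent changes, mean matching, t tests) on any trial table with
the documented CSV schema. A thin command-line wrapper lives at
`inst/scripts/gsmv1.R` (`train`, `experiment`, `analyze`, `generate`,
`show-config`).

## Layout

| Path | Contents |
| --- | --- |
| `R/filterbank.R`, `R/stimuli.R` | oriented quadrature bank; gratings, compound gratings, texture ensembles, image loaders |
| `R/gsm.R`, `R/posterior.R` | generative model, moment-matched training, analytic noiseless forms, exact grid posterior and sampler |
| `R/response.R` | spike readout and the three simulated experiments |
| `R/neural-analysis.R` | spike-count analysis pipeline for trial tables |
| `R/synthetic-recordings.R` | gain-modulated Poisson surrogate recordings |
| `R/cli.R`, `inst/scripts/gsmv1.R` | configuration, model serialization, command entry points |
| `vignettes/gsm-variability.Rmd` | the methods vignette: model, assumptions, numerical choices, limitations |
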