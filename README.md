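# flimtd

Non-iterative time-domain fluorescence lifetime estimation in R.

Fluorescence lifetime imaging (FLIM) assigns each pixel the exponential
decay constant of its fluorescence emission. Iterative least-squares
fitting is accurate but far too slow for video-rate imaging on modern
SPAD/TCSPC sensor arrays, so real-time systems lean on closed-form
estimators computed from a handful of gate counts, a binned histogram, or
raw photon time tags. This package implements that estimator family, the
theory that says how many photons each one wastes, and the simulation
machinery to validate both — for people building or evaluating fast FLIM
pipelines: sensor developers choosing gate settings, microscopists
comparing readouts, and methodologists who need a tested reference
implementation.

## What is inside

**Estimators** (all non-iterative unless noted, all returning a flagged
`LifetimeEstimate`):

| method | input | formula |
|---|---|---|
| `fitRLD2` | two equal gates | τ̂ = h / ln(N₁/N₂) |
| `fitGRLD` | two overlapping gates [0,h), [Sh,Rh) | solves x^S(1−x^{R−S})/(1−x) = N₂/N₁ |
| `fitRLDM` | M-bin histogram | closed-form slope of ln Nⱼ on jh |
| `fitIEM` | odd-M histogram | h·Σ C̄ⱼNⱼ / (N₀ − N_{M−1}), Simpson weights |
| `fitCMM` | photon codes or histogram | (mean code + ½)h, Ω-calibrated for truncation |
| `fitMLE` | histogram (reference, iterative) | binned multinomial ML |
| `fitBiexp` | histogram (reference, iterative) | two-component variable projection + Poisson ML |

**Photon economy**: closed-form F-value curves
(F = √N_c·σ_τ/τ; 1 = shot-noise ideal) for the gating estimators, a
Fisher-information floor, optimal-setting search (`optimizeSetting`), and
a Monte-Carlo harness (`mcFValue`) that checks theory against simulated
acquisitions.

**Simulation**: truncated-mixture photon sampling, correlated /
uncorrelated gated acquisition, and synthetic two-region FLIM image
stacks (`defaultPhantom`, `simulateImageStack`).

**Bi-exponential readout prediction**: what each single-exponential
estimator reports on a two-component decay (`tauAve`, `biexpCurve`, ...),
and per-pixel lifetime imaging with masking, region statistics and
between-method contrast reports (`mapEstimator`, `regionStats`,
`contrastReport`).

A command-line wrapper (`inst/scripts/flim`, or `flimCLI()` from R)
exposes `simulate`, `fit`, `fcurve`, `optimize`, `biexp-curve`, `image`
and `make-fixtures` subcommands over CSV/TIFF/JSON files.

## Worked example

```r
library(flimtd)
model <- decayModel(1000, 2.5)              # single 2.5 ns decay
cfg <- binnedConfig(window = 10, bins = 51) # 10 ns window, 51 bins
sp <- simSpec(model, cfg, nPhotons = 2000, seed = 7)
hist <- sampleHistogram(sp)
lut <- buildOmegaLUT()

fitMLE(hist)
#> LifetimeEstimate [mle]: tau = 2.47753 ns
fitRLDM(hist)
#> LifetimeEstimate [rldm]: tau = 2.46967 ns
fitIEM(hist)
#> LifetimeEstimate [iem]: tau = 2.30923 ns
fitCMM(hist, lut)
#> LifetimeEstimate [cmm]: tau = 2.47938 ns
fitRLD2(gateCountsFromHistogram(hist, 1, 2))
#> LifetimeEstimate [rld2]: tau = 2.55442 ns
fitGRLD(gateCountsFromHistogram(hist, 0.2, 3.2))
#> LifetimeEstimate [grld]: tau = 2.35455 ns
```

Every estimator lands within its expected shot-noise scatter of the true
2.5 ns: with 2000 photons and F-values between ~1.2 and ~2.5, one
standard deviation is 0.07–0.14 ns, and the cheap two-gate readouts
scatter the widest — that trade is exactly what the F-value theory
quantifies:

```r
optimizeSetting("rld2")$hOverTau      # best gate width for RLD-2
#> [1] 2.399357                        # i.e. h = 2.4 tau, window 4.8 tau
fValueCurve("cgrld", gateStart = 0.2, gateEnd = 3.2)
#> FValueCurve [cgrld; S = 0.2, R = 3.2]: 400 points, min F = 1.241 at tau/T = 0.04004
```

The correlated overlapping-gate estimator needs only two counters yet
comes within ~24% of the shot-noise ideal at its optimum, and holds a
usable F over a far wider lifetime range than RLD-2 — which is why it is
attractive for in-pixel hardware.

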