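---
title: "Non-iterative time-domain FLIM: estimators, photon economy, and synthetic validation"
author: "flimtd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-iterative time-domain FLIM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimtd)
```

## The model

Fluorescence lifetime imaging (FLIM) reports, per pixel, the exponential
decay constant of fluorescence emission rather than its intensity. The
package works with the idealized time-domain model

$$f(t) = \sum_k A_k e^{-t/\tau_k}\,u(t) + b,$$

a sum of exponential components with amplitudes $A_k$ (photons/ns) and
lifetimes $\tau_k$ (ns) plus a uniform background rate $b$, observed
through a measurement window $[0, T)$ split into $M$ bins of width
$h = T/M$ (or into two gates for the gating estimators). Two idealizations
matter and are deliberate:

* the instrument response is a delta at $t = 0$ — no IRF convolution
  anywhere; real systems with an IRF comparable to $\tau$ need
  deconvolution that is out of this package's scope;
* photon detection is shot-noise limited — no dead time, afterpulsing,
  pile-up, TDC jitter or repetition-period wrap-around.

Expected counts follow in closed form: a bin $[jh, (j+1)h)$ holds
$\sum_k A_k \tau_k x_k^j (1 - x_k) + bh$ photons on average, with
$x_k = e^{-h/\tau_k}$ (`expectedBinCounts()`, `expectedGateCounts()`,
`expectedTotal()`). Every estimator, predictor, and theory curve in the
package is built on these integrals.

## The estimators

All estimators return a `LifetimeEstimate` with a validity flag instead of
raising on degenerate input, so per-pixel mapping stays robust.

**RLD-2** (`fitRLD2`): two equal gates,
$\hat\tau = h / \ln(N_1/N_2)$. Invalid when $N_2 \ge N_1$ or $N_2 = 0$.

**GRLD** (`fitGRLD`): gate 1 on $[0,h)$ and gate 2 on $[Sh, Rh)$, possibly
overlapping ($S < 1$). The ratio equation
$P(x) = x^S(1-x^{R-S})/(1-x) = N_2/N_1$ has a strictly increasing left side
on $(0,1)$, so the root is found by bisection to $|\Delta x| < 10^{-12}$;
an optional precomputed inverse (`flimtd:::.grldInverse`, used by the
vectorized image path) is knotted uniformly in $\log(\tau/h)$ over
$[10^{-2}, 10^3]$ so its relative accuracy in $\tau$ is even across
decades — the lower knot is set where $x^S$ would underflow at $S = 1$.
Agreement with bisection to $10^{-6}$ relative is enforced by test. The
geometry must satisfy the integer constraints ($1/S$ and $R-S$ integer)
under which the ratio equation takes this form; `expectedGateCounts`
accepts continuous $S, R$, the estimator refuses them.

**RLD-M** (`fitRLDM`): the closed-form least-squares slope of $\ln N_j$
on the bin **left edges** $t_j = jh$. Left edges (not centers) are forced
by the requirement that the $M = 2$ case reduce algebraically to RLD-2 —
the reduction identity is the disambiguating anchor and is tested on
random counts.

**IEM** (`fitIEM`): $\hat\tau = h \sum_j \bar C_j N_j / (N_0 - N_{M-1})$
with Simpson weights $\bar C = [1/3, 4/3, 2/3, \dots, 4/3, 1/3]$. Simpson
weights need an even interval count, so $M$ must be odd; an even $M$ is
refused rather than silently re-weighted — callers rebin
(`rebinStack()`) or truncate explicitly. A constant offset added to every
bin cancels in the denominator, which is the root of IEM's background
tolerance.

**CMM** (`fitCMM`): $\tau_{CMM} = (\bar D + \tfrac12) h$ from photon codes
(or the equivalent histogram centroid — the two forms agree exactly on the
same data), then calibrated for window truncation through
$\Omega = g^{-1}$ where $g(u) = u - e^{-1/u}/(1 - e^{-1/u})$ is the
normalized centroid of a truncated single-exponential. `buildOmegaLUT()`
tabulates $g$ on a 4096-point log grid over $\tau/T \in [10^{-3}, 10^2]$
and inverts it by monotone (Hyman) cubic interpolation; the grid density
and interpolation rule are this package's choices, verified by the
round-trip property $\Omega(g(u)) = u$ to $10^{-3}$ relative over
$u \in [0.01, 10]$. Centroids at or above the uniform-distribution limit
$1/2$ are flagged saturated.

**Reference fitters**: `fitMLE` maximizes the binned multinomial
single-exponential likelihood by a safeguarded 1-D search over
$\log\tau \in [\log(10^{-3} h), \log(10^{3} M h)]$; `fitBiexp` fits the
two-component model by a variable-projection grid (closed-form
non-negative amplitudes per lifetime pair) followed by a bounded
4-parameter Poisson maximum-likelihood refinement. Poisson ML rather than
pure weighted least squares is used because at a few hundred counts per
pixel observed-count weights bias the fit visibly (on the phantom's
long-lifetime region the average-lifetime readout shifts from 2.72 to
2.92 ns against a truth of 2.78, with almost double the spread).
Lifetimes are boxed to $[h/2, 2T]$: components outside that range are not
resolvable from the window, and the box prevents a vanishing-amplitude
component from drifting onto a flat design.

## Photon economy

Estimator precision is scored by the photon economy
$F = \sqrt{N_c}\,\sigma_\tau/\tau$, the factor by which the estimator's
noise exceeds the shot-noise ideal $F = 1$; $N_c$ counts the photons in
the estimator's own window ($2h$ for RLD-2, $Rh$ for GRLD, $Mh$
otherwise), background included — the definition is about the
measurement's total count, not about signal photons alone.

The closed forms (`fValueRLD2`, `fValueGRLD`, `fValueRLDM`) come from
Poisson error propagation. Two of them required reconstruction, and both
reconstructions are pinned by identities that ship as tests:

* `fValueRLD2`: $F = 2\cosh(u/2)/u$ in $u = h/\tau$, minimized at
  $u = 2.399$ where $(u/2)\tanh(u/2) = 1$, i.e. $T = 4.80\,\tau$ with
  $F = 1.509$;
* `fValueGRLD`: $F = (\tau/h)\sqrt{k(x)}/B(x)$, with $k_1$ (uncorrelated
  gates: two independent acquisitions) or $k_2 \le k_1$ (correlated
  gates: one photon stream, overlap events shared). Pinned by exact
  reduction to RLD-2 at $S=1, R=2$ and by the correlated optimum
  $F \approx 1.24$ at $S = 0.2, R = 3.2$;
* `fValueRLDM`: here the algebraic reductions alone are ambiguous — the
  prefactor $6/(M(M^2-1))$ equals 1 at $M = 2$, so the $M = 2$ reduction
  cannot tell whether it belongs inside or outside the radical. The
  placement outside was fixed by direct Monte-Carlo validation of the
  estimator variance (theory/MC ratio exactly
  $\sqrt{M(M^2-1)/6}$ with the other placement, 1 with this one), and
  with it the multi-gate minima saturate beyond $M = 8$ (0.6% change
  from $M=8$ to $M=16$) and multi-gate beats two-gate only near
  $T \sim \tau$.

`fValueFisherMLE` supplies the Cramér–Rao floor from the per-photon
Fisher information of the binned multinomial model; it matches the
continuous truncated-exponential information integral (an independent
oracle in the tests) and equals the RLD-2 curve at $M = 2$, where the
two-bin split is sufficient. Note that the floor is close to 1 only while
the window is generous: at $M = 256$ it stays within $[1, 1.1]$ for
$\tau/T \lesssim 0.2$ but rises to 1.32 at $\tau/T = 0.3$ and 1.90 at
$\tau/T = 0.5$ — window truncation genuinely destroys information, and no
estimator evades it.

`optimizeSetting()` locates optima by a coarse log-grid in $\tau/T$
followed by 1-D refinement (tolerance $10^{-4}$ in the ratio); the
curves are smooth and unimodal near their optima, so nothing fancier is
warranted.

## Monte-Carlo validation and what it assumes

`mcFValue()` replays an acquisition thousands of times and reports
$\hat F = \sqrt{\bar N_c}\, s(\hat\tau)/\tau$ with a bootstrap CI, the
invalid-replicate fraction (reported, never imputed), and an RMSE-based
variant that also charges bias.

The total-count law matters. The error equations assume shot-noise
(Poisson) counting, under which the three gate regions are independent
and overlap sharing makes $\mathrm{Cov}(N_1, N_2) = \mathrm{Var}(N_{ov})
> 0$. Conditioning on a fixed total instead induces multinomial
*negative* covariance between disjoint regions; that leaves the
exhaustive two-gate RLD-2 untouched (the two-category log-ratio variance
is identical) but visibly breaks the uncorrelated-gate equation
(measured $F$ 1.24 against a predicted 2.22 at $\tau/T = 0.1$). The
package therefore supports both laws, defaults `simSpec()` to fixed
totals for plain sample generation, and runs every theory-vs-MC
comparison under the Poisson law. Similarly, the log-linear RLD-M
variance formula is asymptotic in per-bin counts; comparisons are made
where each bin holds at least a few tens of expected photons.

Samplers draw arrival times i.i.d. from the window-truncated density by
inverse CDF (never rejection), so "$N_c$ photons" always means photons
inside $[0, T)$, consistent with the $F$ normalization. Gate-count
replicates are drawn directly as region counts (multinomial or
independent Poissons over the partition $\{[0,Sh), [Sh,h), [h,Rh)\}$) —
the exact distribution of binning i.i.d. arrivals, at a fraction of the
cost. All randomness flows from one seed through R's stream in a fixed
documented order (column-major within label, labels ascending for image
stacks), so identical inputs give byte-identical outputs; per-pixel
streams are not independently addressable, which is the one simplification
against a counter-based seeding design.

## Bi-exponential readouts and the synthetic phantom

Applied to a two-component decay, each single-exponential estimator
reports its own kind of "average lifetime". The predictors
(`tauAve`, `tauRLD2Pred`, `tauCMMPred`, `tauIEMPred`, `tauCGRLDPred`)
evaluate each estimator on the *expected* counts — they are exactly the
estimators composed with the closed-form integrals, and that identity is
the module's master test. Relative to the amplitude-weighted mean
$\tau_{ave} = \sum A_k\tau_k / \sum A_k$: the half-window log-ratio of
RLD-2 and the $\tau_k^2$ moment weighting of CMM both over-represent the
long component, so those two readouts sit farthest above $\tau_{ave}$,
while a fine-binned IEM and an overlapping-gate GRLD track it closely.
The CMM predictor uses the continuous first-moment ratio (its binned
counterpart differs only by the half-bin centroid quantization, which the
tests bound); the GRLD predictor maps a window $T$ to gate width
$h = T/(S+R)$.

The imaging testbed is a synthetic stand-in for an in-vivo scene the
package cannot ship: `defaultPhantom()` builds a 64×64 two-region image —
a vessel-rich network (~53% coverage) against extra-vascular tissue —
where both regions share the lifetime pair 0.3/3.4 ns and differ only in
the short-component amplitude fraction (0.8 in vessels, 0.2 outside),
giving amplitude-weighted means of 0.92 and 2.78 ns. Per-pixel totals are
Poisson with mean 500. The companion acquisition uses $T = 8$ ns and
$M = 51$ bins: 8 ns is the natural window for this lifetime pair (about
$2.4\times$ the long lifetime), and the choice is deliberate — at
windows beyond ~10 ns the RLD-2 map's two-region contrast collapses
below 3 pooled standard deviations, the known contrast loss of
ratio-of-halves readouts on mixtures, while much shorter windows starve
the IEM and bi-exponential maps instead. 51 bins keeps the odd count IEM
needs at a realistic TDC resolution (~157 ps).

`mapEstimator()` applies any estimator independently per pixel; pixels
below `minCounts` (default 50 — below that the gating estimators'
invalid fraction explodes) or flagged invalid are masked, never imputed.
Gate methods aggregate each pixel's histogram into two gates spanning
the window, apportioning boundary bins linearly (photons uniform within
a bin). `regionStats()` and `contrastReport()` summarize region
separation (mean difference over pooled SD) and between-method agreement;
the method-pair slope is the ordinary least-squares slope of the second
map on the first, the natural reading of a per-pixel scatter of one
readout against another. Because both maps estimate from the *same*
photons, their errors are positively correlated, which partly offsets
errors-in-x attenuation.

What passing these tests shows — and what it does not: the phantom
validates estimator behaviour under shot noise, window truncation, and
amplitude-fraction contrast. It does not emulate IRF blur, detector
artifacts, autofluorescence, scattering, or spatially varying photon
budgets; conclusions about real tissue data need the bi-exponential
route and IRF-aware tooling beyond this package.

## Numerical choices, in one place

* GRLD bisection tolerance $10^{-12}$ in $x$; inverse-table fast path
  must agree to $10^{-6}$ relative in $\tau$ (tested).
* $\Omega$ table: 4096 log-spaced points on $[10^{-3}, 10^2]$, Hyman
  monotone cubic; round-trip $10^{-3}$; saturation sentinel at centroid
  $\ge 1/2$.
* `fitMLE` search bracket $\tau \in [10^{-3} h, 10^{3} M h]$, tolerance
  $10^{-10}$ on $\log\tau$.
* `fitBiexp` lifetime box $[h/2, 2T]$; degeneracy flagged when the
  amplitude ratio falls below $10^{-6}$ or the lifetimes come within 5%.
* Optimum location: coarse 300-point log grid + `optimize` refinement,
  $10^{-4}$ tolerance.
* Invalid estimates: flagged, excluded from summaries, reported as an
  invalid fraction — never imputed.
* Problem sizes in the shipped tests: $10^4$ replicates for the four
  theory-vs-MC comparisons, 3000–4000 for the secondary ones, a 64×64
  phantom at 500 counts/pixel for the imaging study, and $10^6$ photons
  for the sampler's distributional check. These sizes put the MC
  standard error well under the tolerances they are tested against.

## Known limitations

* Single-exponential truth is assumed by every $F$-value formula; on
  mixtures the estimators are *predictably biased* readouts, which is
  exactly what the bi-exponential module quantifies.
* No IRF, dead time, pile-up, jitter, or wrap-around; background is
  uniform on the window only.
* IEM and CMM have no closed-form $F$ curves here (their published
  derivations are not reproduced); their photon economy is available
  through `mcFValue()` only, and the CMM harness reports both SD-based
  and RMSE-based $\hat F$ since its truncation-bias accounting admits
  both readings.
* The uncorrelated-gate scheme models two equal-duration independent
  acquisitions; detector-splitting schemes with unequal efficiencies are
  not modelled.
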