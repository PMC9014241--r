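---
title: "FRET-lines: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FRET-lines: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretlines)
```

## The two observables and why two are enough

A single-molecule FRET burst supplies two complementary estimators. The
photon-count ratio $E = n_A/(n_A+n_D)$ estimates the *species-weighted*
quantity $1 - \langle\tau\rangle_x/\tau_{D0}$, because the donor photon
yield of each species is proportional to its lifetime. The mean donor
TCSPC delay time estimates the *intensity-weighted* lifetime
$\tau_F = m_2/m_1$, the ratio of the second to the first moment of the
donor-lifetime distribution sampled during the burst: long-lived
(low-FRET) species contribute disproportionately many photons, and each
photon's delay is drawn from that species' exponential decay. In the
ideal $\delta$-pulse, zero-background regime the mean delay coincides
with the maximum-likelihood lifetime estimate, so no fitting machinery is
modelled here.

The pair $(E, \tau_F)$ therefore determines the first two moments of the
lifetime distribution,
$$ m_1 = (1-E)\,\tau_{D0}, \qquad m_2 = \tau_F\, m_1, $$
and hence its variance $m_2 - m_1^2 = (1-E)(E-E_\tau)\tau_{D0}^2$ with
$E_\tau = 1-\tau_F/\tau_{D0}$. Any physical model enters only through
these two moments: two models with identical $m_1, m_2$ are
indistinguishable in this plane, which bounds what the method can and
cannot resolve.

A **FRET-line** is the parametric curve swept in $(E, \tau_F)$ by varying
one model parameter while holding the rest fixed; the package's generic
engine (`line_from_lifetime_distribution`) computes $m_1(\lambda),
m_2(\lambda)$ for an arbitrary lifetime distribution and maps them to
observables, and every specialized generator is equivalent to it (a
tested oracle).

## The moment-difference representation

The transform
$$ \Gamma = (1-E)\Bigl(1-\frac{\tau_F}{\tau_{D0}}\Bigr)
         = \frac{m_1}{\tau_{D0}} - \frac{m_2}{\tau_{D0}^2} $$
is linear in the moments, so it is linear in species fractions: all
kinetic mixing lines — two-state, three-state, donor mixtures, linker
broadened states, folding transitions — are exactly straight in
$(E, \Gamma)$, while the static line becomes the parabola $(1-E)E$ with
maximum $(1/2, 1/4)$. This is not a cosmetic replot: straightness is what
makes the three-state mixing region an exact triangle and lets species
fractions be read off as barycentric coordinates
(`fractions_from_position`, implemented by the segment-ratio
construction and verified against the linear-algebra solution). The
geometric inversion is limited to three states; with more states the 2-D
plane is underdetermined.

For multi-exponential donors the normalization lifetime changes: $\Gamma$
is then formed with the intensity-weighted donor-only lifetime
$\tau_{D0F}$ of the mixture, and each `fret_line` records which
normalization it used (`attr(x, "tau_norm")`). With this normalization
$\Gamma$ can be negative — specifically for a donor species whose own
donor-only lifetime exceeds $\tau_{D0F}$.

## Dynamic shift

For two-state exchange between efficiencies $E_1, E_2$ the maximal
orthogonal distance between the dynamic and static lines, in the plane of
$E$ versus the *normalized* lifetime $\tau_F/\tau_{D0}$, has the closed
form
$$ \mathrm{ds} = \tfrac{1}{\sqrt{2}}\bigl(\sqrt{1-E_1}-\sqrt{1-E_2}\bigr)^2 .$$
The $1/\sqrt 2$ prefactor is confirmed independently by brute-force
maximization of the point-to-line distance over a dense sampling of the
dynamic line (`dynamic_shift(..., method = "numeric")`); the two routes
agree to $10^{-6}$ over random efficiency pairs, and reproduce the
conventional worked values 0.28, 0.06 and 0.17 for the pairs (0.1, 0.9),
(0.3, 0.7) and (0.5, 0.95). The shift depends only on the limiting
efficiencies — not on exchange rates — which is exactly why it
complements intensity-only indicators whose sensitivity dies at fast
exchange.

## Distance distributions

Dye linkers and polymer disorder are modelled through a stationary
distance distribution $p(R)$, assumed to fluctuate slowly compared with
the fluorescence lifetime but quickly compared with the burst duration.
Moments follow by quadrature of $\tau(R)^\nu p(R)$ with
$\tau(R) = \tau_{D0}/(1+(R_0/R)^6)$.

* **Non-central $\chi$** (two isotropic Gaussian dye clouds separated by
  $R_{mp}$, per-axis width $\sigma$): the physically motivated model.
  Its $R_{mp}\to 0$ limit is the Maxwell form
  $\sqrt{2/\pi}\,R^2\sigma^{-3} e^{-R^2/2\sigma^2}$ with
  $\langle R^2\rangle = 3\sigma^2$ exactly — this is the **Gaussian
  chain** density used for ideal polymers. In the narrow-width limit the
  density approaches a normal; the residual $R/R_{mp}$ prefactor leaves a
  maximal deviation that scales as $1/R_{mp}$ (about $2\times10^{-3}$ at
  $\sigma/R_{mp} = 1/100$), which the tests assert as a convergence law
  rather than a fixed threshold.
* **Truncated normal**: the common approximation; renormalized on
  $R \ge 0$. It overweights small distances relative to the $\chi$ model,
  most visibly at large widths and high efficiencies.
* **Worm-like chain**: the mean-field interpolation radial density
  $$ p(R) \propto R^2\,\bigl(1-(R/L)^2\bigr)^{-9/2}
     \exp\!\Bigl(-\frac{3}{4\kappa\,(1-(R/L)^2)}\Bigr), \quad R < L, $$
  with stiffness $\kappa = \ell_p/L$, normalized numerically (the
  normalization constant is always computed, never assumed). Its
  flexible limit recovers ideal-chain statistics
  $\langle R^2\rangle \to 2\kappa L^2$ and its stiff limit concentrates
  at full extension; both limits are tested. Different $(\kappa, L)$
  pairs can share an efficiency yet differ in $\tau_F$, which is what the
  two-dimensional analysis exploits for disordered proteins.

Default linker width for reference lines is $\sigma_{DA} = 6$ Å, a
typical value for the common 10–20 Å dye linkers; it is always
user-settable, including per state (no coupling between state and width
is imposed, since no general prescription exists).

**Numerics.** Quadrature uses `stats::integrate` (adaptive
Gauss–Kronrod) with relative tolerance $10^{-9}$ on
$[\max(0, R_{mp}-10\sigma),\, R_{mp}+10\sigma]$ for $\chi$/normal models
and on $[0, L]$ for the WLC; failures are surfaced as errors, never
silenced. $\tau(R)$ is evaluated with a floor $R \ge 10^{-3}$ Å to avoid
0/0 at the origin, where all supported densities are negligible.
Mixture distributions are never re-integrated as a summed density in
production code: moments are computed per component and combined
linearly (the oracle tests do the opposite and check agreement). The
variance of a linker-broadened multi-state mixture decomposes exactly
into conformational plus linker parts (`variance_decomposition`), tested
to $10^{-10}$.

## The burst simulator

`simulate_experiment` emulates the idealized confocal experiment that
the line formalism describes, and nothing more:

* conformational exchange is a continuous-time Markov chain (Gillespie
  dwell sampling, started from the stationary distribution; rates in
  1/ms);
* photon arrivals are homogeneous Poisson at the configured count rate
  (default 100 photons/ms, the typical 100 kHz) — the diffusion-profile
  brightness modulation of a real confocal transit is deliberately not
  simulated, since the reference curves depend only on count rate and
  duration;
* each photon is an acceptor photon with probability $E$ of the state
  active at its arrival; donor photons carry exponential delay times
  with mean $\tau_{DA}$ of that state. Acceptor delays are not generated
  (no estimator in scope uses them); background, IRF and acceptor
  photophysics are out of scope.

Burst durations default to an exponential with mean equal to the 0.5 ms
diffusion time, truncated at $10\times$ the mean; a fixed-duration mode
exists for clean estimator oracles. Bursts below 50 photons are
discarded and counted. Each burst derives its own RNG stream from the
root seed, so burst $b$ is bit-identical regardless of how many bursts
are requested.

What passing simulator-based tests shows — and what it does not: the
synthetic data realize exactly the assumptions of the theory (stationary
Markov exchange, ideal color splitting, $\delta$-IRF). Agreement
demonstrates internal consistency of estimators and lines at realistic
photon statistics; it cannot certify robustness to detector artifacts,
background, acceptor blinking or brightness variation, which real data
add on top.

## Estimators and their small-sample behavior

Per burst, `burst_observables` returns $\hat E$, $\hat\tau_F$ (mean
donor delay; bursts with zero donor photons are excluded from
lifetime-derived columns with a message), the BVA standard deviation
over consecutive non-overlapping windows of $N = 5$ photons (the
trailing partial window is discarded; an overlapping-window option
exists), the shot-noise reference $\sqrt{E(1-E)/N}$, and the
variance-from-observables estimate $(1-\hat E)(\hat E-\hat E_\tau)$.

Two small-sample facts matter when validating against theory. First,
BVA's windowed averaging underestimates the conformational variance, and
shot-noise and dynamics contributions are not strictly additive, so the
shot-noise-subtracted BVA value is approximate by construction (and
degenerates at $N=1$, which is rejected). Second, the quadratic
observables estimator carries a $-\mathrm{Var}_{shot}(\hat E)$ bias of
order $E(1-E)/N_{photons}$ (about 0.003 at 80 photons); the simulation
tests therefore debias it with the per-burst binomial term — the same
logic as BVA's subtraction — before comparing to the two-state variance
parabola $(E-E_1)(E_2-E)$.

For centroid tests the representation matters: with exchange at
1 ms$^{-1}$ and 0.5 ms bursts, per-burst occupancies are broadly spread,
and the centroid of points on the *curved* $(E, \tau_F)$ dynamic line is
displaced from the line (a Jensen gap) even though every point lies on
it. The moment representation is linear in the fractions, so there the
population centroid genuinely sits on the dynamic line; the tests check
centroids in $\Gamma$ and per-burst unbiasedness (against recorded true
occupancies) in $(E, \tau_F)$.

## Problem sizes and reproducibility

Stochastic validations use 300–2000 bursts per configuration, $2\times
10^5$ Monte-Carlo draws per quadrature cross-check and $10^6$ draws for
delay-time laws, with fixed seeds throughout; these sizes put 3-standard-
error bands well inside the effects being detected while keeping the
whole suite inexpensive. The BVA rate sweep uses 0.1, 1, 10 and
100 ms$^{-1}$, evaluated on the mixed subpopulation ($\hat E$ between
0.4 and 0.65, bracketing the equal-mixture efficiency): at the slowest
rate most bursts never switch state, so a whole-population average would
dilute the within-burst variance signal that the sweep is about.

## Design decisions and limitations

* Units are fixed (Å, ns, 1/ms for exchange rates); no conversions in
  the numerical core.
* Mixture fractions must sum to 1 within $10^{-9}$; silent
  renormalization is off by default so caller bugs surface.
* $E = 1$ maps to $\tau = 0$; downstream divisions guard with a
  $10^{-12}$ ns epsilon and raise on true zero.
* Radiative rate and donor quantum yield are carried for documentation
  only — all formulas use $\tau_{D0}$ and quantum-yield *ratios*, so
  absolute rates never enter.
* Out-of-gamut points in the three-state inversion report signed
  barycentric coordinates instead of clamping, so noise excursions can be
  distinguished from genuine model violation.
* The Förster radius is an input; computing it from spectral overlap is
  out of scope, as are detector/background corrections, accessible-volume
  geometry from structures, and fitting lines to measured histograms
  (the package generates reference curves; it does not fit).
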