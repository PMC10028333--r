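---
title: "Methods: fractional couple-stress Casson tri-hybrid nanofluid channel flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fractional couple-stress Casson tri-hybrid nanofluid channel flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thnflow)
```

## The physical model and its assumptions

The package solves the unsteady, laminar, fully developed flow of a
non-Newtonian suspension between two parallel plates a dimensionless unit
distance apart. The suspension is blood carrying three nanoparticle
species at once — Fe3O4, Zn and Au — each entering the mixture rules with
its own shape-dependent correlation set. The constitutive picture combines
two non-Newtonian ingredients:

* a **Casson parameter** `beta`, scaling the momentum diffusivity by
  `(1 + 1/beta)` (absorbed into the dimensionless groups; `1/beta -> 0`
  recovers a Newtonian-type momentum balance),
* a **couple-stress parameter** `lambda >= 0`, adding a fourth-order
  spatial derivative to momentum (micro-rotation effects), with hinged-end
  conditions `w'' = 0` at both walls.

Time derivatives are taken in the **Atangana-Baleanu (AB) sense** of order
`alpha` in `(0, 1]`: a fractional operator with a non-singular
Mittag-Leffler kernel whose normalisation is taken as 1 for all orders
(the derived Laplace-domain forms assume it; the normalisation is only
pinned at the endpoints anyway). `alpha = 1` is the classical local-in-time
model and is handled by a dedicated code path, because the per-mode
coefficients contain `1/(1 - alpha)` factors.

Assumptions worth keeping in mind: constant thermophysical properties (no
temperature dependence), one-dimensional fields `w(xi, tau)`,
`theta(xi, tau)`, no magnetic or radiative terms, a unit-step start of the
hot moving wall, and a dimensionless channel height fixed to `h = 1` —
inputs with `h != 1` are rejected rather than half-supported, since the
boundary conditions are posed on `[0, 1]`.

Two wrinkles of the source formulation are resolved explicitly:

* the dimensional energy balance is read with the conduction term
  `d2T/dy2` (an obvious misprint writes the field variable in place of the
  temperature); the pipeline logs this reading once per `run_profile()`
  call;
* the wall forcing is interpreted as the unit step, so `w(0, tau) = 1` for
  every `tau > 0`.

## Mixture thermophysics

All mixture information enters through eleven dimensionless ratios.
Density, heat capacitance and thermal expansion mix linearly in the volume
fractions (`chi1`, `chi7`, `chi6`). Viscosity and conductivity are
shape-specific: the viscosity polynomials `1 + a1*phi + a2*phi^2` with
`(a1, a2)` = (2.5, 6.2) spherical, (13.5, 904.4) cylindrical,
(37.1, 612.6) platelet, and the Maxwell/Hamilton-Crosser conductivity form
with coefficient `c = n - 1` for shape factors `n` = 3, 4.9, 5.7. Two
conventions are fixed deliberately:

* **the fraction inside the shape correlations is the total fraction**
  `phi_hnf = phi1 + phi2 + phi3`, matching the way the per-shape
  correlations are stated for the suspension as a whole;
* **`chi5` and `chi11` are fraction-weighted interpolations** of the
  per-species ratios and are 0/0 at `phi_hnf = 0`; they are defined there
  by their continuous limit 1, so the particle-free fluid is a regular
  special case rather than an error.

A note on shape labels. In this literature the 13.5/904.4/3.9 coefficient
set is the *cylindrical* one and 37.1/612.6/4.7 the *platelet* one. The
governing mixture equations of this model pair species 2 (Zn) with the
former and species 3 (Au) with the latter, and only that pairing
reproduces the published per-species heat-transfer enhancements; prose
descriptions of the same model sometimes swap the two labels between Zn
and Au. The built-in material table therefore records Zn as cylindrical
and Au as platelet; users can supply any other assignment through a custom
material table (CSV round-trip is provided and bit-exact).

The conductivity denominators keep the `phi` term
(`k_p + c k_bf - phi (k_p - k_bf)`); dropping it — as one compressed
restatement of the ratios does — produces absurd ratios for high-contrast
particles (a factor ~135 for gold), so the full form is authoritative.

## Closed-form solution

A Laplace transform in `tau` and a finite sine Fourier transform in `xi`
(modes `sigma_n = n pi`) reduce both balances to per-mode rational images
in `q^alpha`. Their exact inverses are built from two primitives,

* the Robotnov-Hartley function
  `F_beta(-r, tau) = tau^(beta-1) E_{beta,beta}(-r tau^beta)`
  (inverse of `1/(q^beta + r)`), and
* its convolutions `1 * F = (1 - E_beta(-r tau^beta))/r` and
  `h * F = E_beta(-r tau^beta)` with the singular kernel
  `h(t) = t^(-beta)/Gamma(1-beta)`,

which the package evaluates through their Mittag-Leffler closed forms
(direct quadrature of the defining convolutions is retained as a test
oracle only). The temperature field is the conduction profile `1 - xi`
plus a sine series with per-mode fractional relaxation rates
`r4 = r2 sigma_n^2 / (r1 + sigma_n^2)`; the velocity field is a steady
part plus a sine series combining relaxations at rates `r4`
(thermal forcing) and `r8` (momentum).

**The steady velocity part.** The mode-wise steady content of the
transformed solution is
`[G (1-(-1)^n) + s_n] / (sigma_n s_n)` with
`s_n = sigma_n^2 + lambda sigma_n^4`. Resumming this series in closed form
gives

```
w_s(xi) = (1 - xi) + G [ xi(1-xi)/2
          - lambda (1 - cosh((xi - 1/2)/sqrt(lambda)) / cosh(1/(2 sqrt(lambda)))) ]
```

which satisfies `0 = G + w'' - lambda w''''` and the hinged-end conditions
exactly for *every* `lambda >= 0` (at `lambda = 0` the boundary-layer term
vanishes). The widely quoted polynomial-plus-`cosh(h/2 - xi)/cosh(h/2)`
form of this steady profile is the `lambda = 1` special case of the same
expression; using it at other `lambda` would leave an O(0.01) residual
against the mode sum at the default `lambda = 3` and break the
oracle-equivalence tolerance, so the general-`lambda` form is used. The
non-decaying buoyancy residue of the series (`A2 - A3/r4 + A4/r8` per
mode, equal to `B2/(sigma_n s_n)`) stays in the series; it decays like
`n^-5` for `lambda > 0`.

**Degenerate inputs.** When the two relaxation rates `r4` and `r8` of a
mode nearly coincide the partial-fraction amplitudes `A3`, `A4` blow up
individually while their combination stays finite; the implementation
detects relative coincidence below 1e-10 and nudges `r8` by one part in
1e7 (with a warning), which perturbs the combined term by far less than
the series tolerance. `alpha = 1` requests are routed to the classical
path: exponential per-mode relaxation at rates `sigma_n^2/B3`
(temperature) and `s_n/B0` (velocity), with the exact two-exponential
particular solution for the buoyancy coupling (and an analytic limit when
those two rates coincide).

## Evaluating the Mittag-Leffler family

All fractional transients reduce to `E_alpha(-x)` and
`E_{alpha,alpha}(-x)` for `x >= 0`. With `y = x^(1/alpha)` the alternating
power series has a largest term of order `e^y`, so its double-precision
cancellation error is ~`e^y * 1e-16`, while the algebraic asymptotic
expansion has optimal-truncation error ~`e^-y`. Neither alone covers the
intermediate band to the accuracy the oracle and identity tests require,
so evaluation is three-route:

* `y <= 9`: direct series (cancellation below ~1e-12), with the term
  budget scaled as `5 y / alpha` because factorial decay only sets in
  around term `y/alpha`;
* `9 < y <= 30`: the completely monotone **spectral integral
  representation** (a smooth, positive integrand over `[0, infinity)`;
  accurate to ~1e-13), in both the one-parameter and the
  `E_{alpha,alpha}` forms;
* `y > 30`: the asymptotic expansion truncated at its smallest term
  (error ~`e^-30` and below).

Two-parameter cases other than `order2 = order` (not used by the flow
pipeline) use series up to `y = 16` and the asymptotic expansion beyond.
The raw Robotnov-Hartley *series route* — kept as an independent
cross-check of the Mittag-Leffler route — is rejected outside
`r tau^beta <= 3`, the domain where its own leading-term cancellation
stays below ~1e-9; property tests draw from that domain. Reciprocal gamma
factors are computed through the reflection formula, which is exactly zero
at the poles and avoids overflow for large negative arguments.

The quadrature oracles for the convolutions regularise the integrable
endpoint singularities with exact power substitutions (`s = v^(1/beta)`
near 0, `tau - s = u^(1/(1-beta))` near `tau`) and retry one decade of
tolerance relaxation before giving up, since near machine precision the
error estimator of adaptive quadrature can trip on roundoff.

## The independent oracle

`oracle_profile()` re-solves the problem from the per-mode Laplace-domain
images alone: each image is evaluated as the printed rational function of
`(q, q^alpha)` on the principal branch and inverted numerically — by the
fixed Talbot contour (default) or the Euler-accelerated Bromwich series —
at the requested time. The two inversion methods agree to better than
1e-6 on every mode image (a tested invariant), and the oracle shares no
Mittag-Leffler code with the analytic path. The exactly known steady
(final-value) coefficient of each image is split off before inversion so
the contour acts on a decaying transient, and the slowly converging steady
sine series is replaced by its elementary closed form — the same closed
form the analytic solution uses, which is deliberate: the comparison is
meant to validate the fractional machinery, not elementary Fourier sums
(a separate test validates the steady resummation against a long partial
sum). Analytic series and oracle agree to 1e-4 (temperature) and 1e-3
(velocity) across `alpha` in {0.3, 0.5, 0.9} and `tau` in {0.5, 1, 2}; in
practice the agreement is 1e-6 or better.

## Nusselt number and the calibration of its definition

The wall gradient is computed by term-wise differentiation of the
temperature series at `xi = 0`. The raw derivative series decays only like
`n^-2`, so the constant part of the mode factors is resummed exactly with
`sum_n r1/(r1 + n^2 pi^2) = (sqrt(r1) coth sqrt(r1) - 1)/2`, leaving a
`n^-4` remainder; doubling the mode budget then changes the result by
less than 1e-6.

The published tables this model targets print Nusselt values but never the
defining formula. Two standard candidates — the bare wall gradient and the
conductivity-scaled gradient `chi11 * (-dtheta/dxi)|_0` (the usual
nanofluid convention `Nu = k_hnf/k_bf * gradient`) — coincide in the
particle-free baseline, where the computed value 4.712 matches the printed
4.708 to 0.09% and validates the temperature solution itself. The
tri-hybrid `phi = 0.02` row separates the candidates: the
conductivity-scaled form matches (4.902 vs 4.898) while the bare gradient
does not (4.51). `calibrate_nusselt_definition()` performs exactly this
comparison at run time, selects the conductivity-scaled form, and the
selection is recorded in every run's metadata. Under it, all printed
Nusselt variations and the four headline enhancement percentages (8.05%,
4.63%, 8.984%, 10.407%) are reproduced to 0.2% or better.

No skin-friction formula is printed either; `skin_friction()` implements
the natural candidate `(1 + 1/beta) w'(0) - lambda w'''(0)` by term-wise
differentiation and labels the result as a candidate definition in its
attributes.

## Parameters, defaults and problem sizes

| parameter | meaning | default |
|---|---|---|
| `alpha` | AB fractional order (memory strength; 1 = classical) | 0.5 |
| `beta_casson` | Casson parameter (dimensionless) | 1.2 |
| `lam` | couple-stress parameter | 3 |
| `G` | axial pressure gradient | 2 |
| `Gr`, `Pr`, `Re` | Grashof, Prandtl, Reynolds numbers | 4, 21, 1.2 |
| `phi1..3` | species volume fractions | 0.02/3 each |
| `tau` | dimensionless time | 1 |
| `n_modes` | sine-series cap | 1000 |
| `series_tol` | absolute series-tail tolerance | 1e-7 |

The defaults are the figure-baseline conditions of the study (blood with a
0.02 total fraction split equally; `Pr = 21` is the standard blood value).
`Gr` is always a direct input: its defining velocity and viscosity scales
are never assigned numerically by the model. The equal three-way split of
the total fraction is the configurable default because the study never
states how its 0.02 is divided among the species. Adaptive truncation cuts
the series at the first mode whose amplitude bound falls below a tenth of
`series_tol` (never below 20 modes), the factor ten being a tail-sum
safety margin; an unreachable tolerance raises an error carrying the tail
estimate instead of returning a silently degraded field. Test and
acceptance runs use 41-101 point grids, up to 2000 modes and 120-200
oracle inversions per field — a few seconds per full cross-validation grid
on one core.

## Monotone trends: what holds and what does not

At the figure baseline (`tau = 1`, `xi = 0.5`) the implemented solution
responds monotonically as expected to most controls: temperature rises
with the volume fraction and falls with `Re` and `Pr`; velocity rises with
`Gr`, `G` and falls with `Re`, `Pr`, `lambda`. Three published directional
claims are *not* properties of the printed closed forms at these
conditions, and the package does not pretend otherwise:

* **velocity vs `alpha`** decreases only at early times
  (`tau <~ 0.3`, where the memory kernel suppresses the initial rise —
  the regular test suite asserts exactly that early-time property); by
  `tau = 1` the direction has reversed;
* **velocity vs `beta`** increases only at early times; at `tau >= 0.5`
  the buoyancy coupling `B2 ~ 1/beta` dominates and the direction
  reverses;
* **velocity vs `phi`** increases (weakly) at every time: with `G` and
  `lambda` held fixed — as the figure captions do — the viscosity penalty
  of loading the fluid is hidden inside those dimensionless groups, and
  the only remaining `phi` sensitivity is the weak buoyancy and
  relaxation-rate route;
* **temperature vs `alpha`** is monotone increasing at `tau = 1` only up
  to `alpha ~ 0.7` and reverses by 0.9 (at `tau = 0.5` it decreases
  throughout, at `tau = 2` it increases throughout) — the direction is
  genuinely time-dependent.

All these responses are of order 1e-3 at `xi = 0.5` — invisible at plot
scale — so figure panels showing well-separated curves in these parameters
cannot have been produced from the closed forms implemented here. The
acceptance-level trend test asserts the published directions verbatim and
is expected to fail for those four items; the regular suite asserts the
directions the equations actually possess.

## What the synthetic configurations do and do not show

The package generates all of its inputs: parameter sets mirroring the
figure baselines (`generate_sweep_fixtures()`) and the built-in material
table. Passing tests therefore demonstrate internal correctness — exact
boundary conditions, convergent series, agreement with an independent
inversion method, reproduction of the published tables — not agreement
with laboratory data. Real blood is shear-thinning with
temperature-dependent properties, nanoparticle suspensions sediment and
agglomerate, and the correlation coefficients used here come from
room-temperature fits for other base fluids; none of that physics is in
scope (`Non-goals`: no temperature-dependent properties, no preparation or
stability modelling, no 2-D or magnetohydrodynamic effects).

## Known limitations

* `h = 1` only; `alpha > 1` is not supported.
* The Nusselt and skin-friction definitions are calibrated/candidate
  choices, clearly labelled as such in outputs.
* Worst-case Mittag-Leffler accuracy at the series/spectral hand-over is
  ~1e-9; applications needing uniform 1e-12 would require extended
  precision.
* The raw Robotnov-Hartley series route is domain-restricted (see above);
  it exists for cross-validation, not production use.
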