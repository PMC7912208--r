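---
title: "Spectra of projected generators: models, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectra of projected generators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `projgen`, the estimator
conventions, the tunable parameters, and the numerical decisions that were
genuinely open when the package was designed. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## Models and assumptions

The package works with Itô diffusions `dX = b(X) dt + σ(X) dB` on `R^d`.
Two concrete families are built in:

* **Overdamped Langevin** (`kind = "overdamped"`):
  `b = −(1/γ)∇V`, `a = σσᵀ = (2/(βγ)) I`. The process is reversible with
  Boltzmann density `ρ ∝ exp(−βV)` and uniformly elliptic diffusion; `β` is
  the inverse temperature (1/energy), `γ` the friction (1/time).
* **Underdamped Langevin** (`kind = "underdamped"`): state `(q, p)`,
  `dq = p dt`, `dp = (−∇V(q) − γp) dt + sqrt(2γ/β) dB`. The diffusion acts
  on the momentum block only, so the model is *not* uniformly elliptic and
  not reversible; its invariant density factorizes into `exp(−βV(q))` times
  a Gaussian momentum marginal with variance `1/β` per component. The
  quadratic form degenerates (vanishes) on observables of the positions
  alone, which is why `quadratic_form()` and the reversible estimator are
  refused or return zero there: the conditional-expectation coefficients of
  a position-only coordinate are identically zero, and only finite-offset
  (Kramers–Moyal) estimators at offsets beyond the momentum relaxation time
  `1/γ` yield meaningful effective dynamics.

For a reaction coordinate `ξ` the *projected generator* acts on functions
of `z = ξ(x)` with effective drift `b_ξ = P(Lξ)` and diffusion
`a_ξ = P(∇ξᵀ a ∇ξ)` (`P` the conditional expectation over level sets of
`ξ`). Its nonzero eigenvalues `ω_i` never fall below the corresponding full
rates `κ_i` (min–max), and Ritz values of any finite dictionary bound them
from above again: `κ_i ≤ ω_i ≤ ω̂_i`. Implied-timescale estimates from a
Galerkin model are therefore *lower* bounds in expectation.

## Estimators

All three assemblers build `S[i,j] ≈ ⟨−Lφ_i, φ_j⟩_μ` and the Gram matrix
`G` from samples, with basis gradients pulled back through the chain rule
`∇(φ∘ξ) = ∇ξ ∇_z φ`:

* `assemble_reversible()` uses the quadratic-form identity
  `⟨−Lφ_i, φ_j⟩ = ½E[∇φ_iᵀ a ∇φ_j]` — needs `a`, valid for reversible
  models, symmetric by construction.
* `assemble_nonreversible()` evaluates `Lφ_i` directly — needs `b`, `a`
  and the Hessian of `ξ` (coordinate selections and the polar angle and
  oscillating coordinates carry analytic Hessians; the dihedral coordinate
  does not, so use the other two estimators there).
* `assemble_km()` replaces the generator application by finite differences
  `d_sξ(x_m) = ξ(x_{m+s/Δt}) − ξ(x_m)` at offset `s`:
  drift `d_sξ/s`, diffusion `d_sξ ⊗ d_sξ / s`. Consistent as `s → 0`,
  `M → ∞`; at positive `s` it approximates the generator of a different,
  time-coarsened effective dynamics. Angular outputs are wrapped into
  `(−π, π]` by the minimal-image convention before differencing — without
  this, every crossing of the branch cut would register as a ±2π jump.

On one-step Euler–Maruyama data the KM estimator at `s = Δt` matches the
exact-parameter estimator up to `O(Δt)`; the test suite verifies the decay
by quartering `Δt` at fixed total simulation time (so that the
`1/sqrt(sM)`-type sampling noise, which does not shrink with `Δt`, stays
below the bias being measured).

## Basis dictionaries and the bandwidth convention

Gaussian dictionaries are `φ_i(z) = exp(−(z − z_i)²/(2ρ))` and their
2π-periodic analogue `exp(−sin²((z−z_i)/2)/(2ρ))`. The bandwidth `ρ` is a
*squared* width that divides the exponent: with the dictionary scales used
throughout (`ρ = 0.1` with centers 0.4 apart; `ρ = 0.05` on a 10×10 grid)
this is the only reading that yields localized, non-degenerate functions.
Because the alternative literal reading (ρ multiplying) is defensible, it
remains available via `rho_convention = "multiply"`. Hermite dictionaries
are probabilists' polynomials normalized to orthonormality under the
standard normal weight, so `He₁(z) = z` is an exact Ornstein–Uhlenbeck
eigenfunction. Two-dimensional dictionaries are tensor products with
product-rule derivatives.

## Solving the generalized eigenproblem

`solve()` whitens by the mass matrix through a symmetric eigendecomposition,
discarding directions with mass eigenvalue below `mass_tol` times the
largest. The *default* is `mass_tol = 1e-10` (rank revelation only). The
bundled experiment configurations pass `mass_tol = 1e-6`: on strongly
metastable data, dictionary members centered in barely-visited regions
produce mass directions that are pure sampling noise, and whitening them
amplifies that noise into spurious complex eigenvalues. Truncating at 1e-6
is the standard EDMD remedy and is reported via `mass_rank`.

For the non-symmetric estimators the eigenvalues are sorted by real part;
the largest imaginary part among the retained eigenvalues is recorded in
`discarded_imag`, and the solve aborts if `|Im|/|Re|` of a retained nonzero
eigenvalue exceeds `imag_tol` (default 0.1; the offset-scan experiments use
0.5–0.6 since moderate imaginary noise at large offsets is expected and the
scan records failures per offset rather than aborting). The eigenpair with
the smallest `|ω|` is taken as the stationary pair and excluded from
implied timescales; nonpositive rates past it are flagged as spurious
rather than silently inverted.

Sampling uncertainty is quantified by a moving-block bootstrap: assemblers
called with `n_blocks > 1` retain contiguous block partial sums (default
experiments: 100 blocks, 100 resamples), which `bootstrap_timescales()`
resamples with replacement. The block construction respects the
autocorrelation of the underlying trajectory at lags up to the block length.

## Effective coefficients

`km_binned()` estimates `b_ξ` and `a_ξ` by hard-binned conditional
averages: 50 uniform bins by default over the observed range (the full
circle for periodic coordinates), masking bins with fewer than 100 samples
(`NA`, never zero-filled). Hard binning rather than kernel smoothing is the
most direct reading of the conditional-average definition; kernels are out
of scope. Only one-dimensional reduced coordinates are binned — every
histogrammed comparison in the bundled experiments is one-dimensional.

For the lemon-slice polar angle the coefficients are also available in
closed form up to one radial quadrature: the potential separates into an
angular part `g(φ) = cos 4φ + 1/cos(φ/2)` plus radial terms, so the radial
conditional density `∝ r exp(−β(10(r−1)² + 1/r))` is independent of `φ`
and `a_ξ = (2/(βγ)) E[r⁻²|φ]` is a constant while
`b_ξ = −(g'(φ)/γ) E[r⁻²|φ]`. The radial factor is computed by
Gauss–Legendre quadrature on `r ∈ [10⁻⁴, 8]` (the integrand is negligible
outside), with convergence enforced by doubling the node count and
requiring agreement to 1e-8.

## PCCA

`pcca()` uses the inner-simplex (vertex-seeking) construction: rows of the
dominant-eigenfunction matrix span a simplex whose vertices are found by
pivoted orthogonalization; memberships are barycentric coordinates with
respect to those vertices, hence row sums are exactly one. No subsequent
objective optimization is applied — the construction is deterministic and
sufficient for the well-separated spectra of the bundled systems. Negative
memberships from sampling noise are clipped to `[0, 1]` and renormalized,
with the largest pre-clip violation reported. Points whose largest
membership stays below 0.6 are marked as transition states. Eigenfunctions
are evaluated on a regular grid over the reduced domain (membership curves
and maps are grid objects, not per-sample labels).

## Error-bound verification

The oscillating family `ξ_m(x, y) = x + 0.1 sin(my)` on the 2-D
Ornstein–Uhlenbeck model (`α_x = 1`, `α_y = 5`, `β = γ = 1`) probes the
energy-norm bound on the relative eigenvalue error: as `m` grows the level
sets oscillate, leaving the L² projection error of the exact slowest
eigenfunction `ψ = x` nearly unchanged while the derivative-weighted
energy-norm error grows. `check_bound()` reports, per `m`, the Ritz value
(tensor Gauss–Hermite quadrature; order 60 suffices for the slowest Ritz
value at `m ≤ 10`, order ~120 for agreement to 1e-8 under doubling), the
relative eigenvalue error against `κ₁ = α_x`, both squared eigenfunction
errors, and the bound's right-hand side. Two deliberate simplifications
mirror the illustrative character of the computation: the reported
`‖ψ − ψ̂‖²_Q` is an upper bound for the true Q-orthogonal projection error
(the exact projection onto the infinite-dimensional reduced space is not
computable), and the bound is evaluated for the slowest eigenvalue, where
its prefactor is exactly 1; evaluation at higher indices uses Ritz values
as proxies for the projected-generator eigenvalues and is labelled
approximate.

## The synthetic five-bead chain

The `chain5` potential is this package's own molecular analogue: five beads
in 3-D with harmonic bonds (`k_b = 50`, `r₀ = 1`), harmonic angles
(`k_a = 10`, `θ₀ = 1.91`), and cosine dihedral terms
`2.5(1 + cos 3φ₁) + 2(1 + cos 2φ₂)`, giving 3 × 2 = 6 metastable states in
the dihedral plane with barriers of 5 and 4 energy units (β = 1). Energy
and time units are synthetic; the system resembles a small molecule only
qualitatively (no solvent, no physical force field, no momenta). The
bundled configuration integrates at `Δt = 10⁻³` for 4·10⁶ steps: the
stiffest mode (bond stretching, relaxation rate ≈ 2k_b/γ = 100) then sits
at `λΔt = 0.1`, which keeps the Euler–Maruyama discretization bias on the
slow dihedral rates at the few-percent level — at `λΔt = 0.5` the measured
slow rates of this system are visibly distorted, which is why a larger step
is not offered as a default. The dihedral angles carry substantial fast
vibrational content, so KM-gEDMD rates on this system inflate noticeably
with the offset (an `O(s·λ_fast)` effect); the six-state structure and the
spectral gap persist across an offset decade, which is the property the
tests assert.

## What the synthetic generators do and do not emulate

The bundled simulators produce equilibrium trajectories of low-dimensional
model potentials with known parameters, exactly the regime in which the
estimators' consistency can be checked against analytic references. They do
not emulate molecular force fields, solvent collisions, thermostat
artifacts, sampling non-stationarity, or observation noise on the reaction
coordinates. Passing tests therefore demonstrate the correctness of the
estimators and the qualitative phenomenology (offset robustness for good
coordinates, the underdamped crossover at `s ≈ 1/γ`, metastable
decompositions) — not that real molecular data will yield timescales of
any particular accuracy.

## Problem sizes and determinism

The test suite runs the lemon-slice experiment at its full 5·10⁶ steps, the
double well at 5·10⁶, and the chain at 2·10⁶; the acceptance script uses
5·10⁶ (lemon) and 10⁷ (double well). All stochastic stages derive their
randomness from a single integer seed per run: the compiled steppers draw
from R's RNG, so `set.seed()` makes trajectories bit-reproducible, and
`run_experiment()` writes byte-identical outputs for identical
configurations.

## Known limitations

* Euler–Maruyama only; stiff potentials need small steps (the integrator
  aborts on divergence rather than silently producing biased data).
* Effective-coefficient binning is one-dimensional.
* The non-reversible estimator requires an analytic reaction-coordinate
  Hessian.
* PCCA without an optimization pass can mislabel strongly overlapping
  states; the bundled systems have well-separated spectra by design.
* Implied-timescale estimates inherit the Ritz upper-bound bias of the
  dictionary: a too-coarse basis shortens timescales systematically.
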