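---
title: "Binding constants from fluorescence quenching titrations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding constants from fluorescence quenching titrations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quenchfit)
```

## The problem

Serum albumin carries most small acidic drugs in blood. When a drug binds
near the protein's fluorophores (chiefly Trp214 and the tyrosines), the
protein fluorescence is quenched, and a titration — successive additions of
drug to a fixed protein aliquot, a spectrum recorded after each — encodes
the binding constants. `quenchfit` implements the two standard ways of
decoding it:

* **single-wavelength analyses** (Stern–Volmer and its double-logarithm
  form), quick but built on restrictive assumptions; and
* a **global multiwavelength analysis** that models every species in
  equilibrium and fits whole spectra across several acquisition modes
  simultaneously.

Because raw titration spectra for the studied systems are not publicly
deposited, the package also ships a synthetic titration generator; every
fitting stage is validated by parameter recovery against known ground truth.

## Equilibrium model and speciation

The chemistry is a two-component equilibrium system: macromolecule `S`,
ligand `Q`, complexes `SsQq` with formation constants

    Kb(s,q) = [SsQq] / ([S]^s [Q]^q)

Constants are stored *cumulatively* (referenced to the free components; the
form that enters the mass balances) and reported *stepwise*
(`K1 = [SQ]/[S][Q]`, `K2 = [SQ2]/[SQ][Q]`), the convention of the published
tables. `stepwise_log_k()` converts.

Given totals, `solve_mass_balance()` finds the free concentrations solving

    total_S = sum_i s_i C_i      total_Q = sum_i q_i C_i

by Newton–Raphson on `(ln[S], ln[Q])`. The log parameterisation guarantees
positivity; a step is halved whenever it worsens the larger relative
mass-balance error, and a step longer than 5 natural-log units is clamped
(wild early steps otherwise overflow the exponentials). Default tolerance
is `1e-10` relative on both balances, max 100 iterations — speciation
problems of this size converge in ~5. `total_Q = 0` is answered
analytically (no ligand-containing species), avoiding `log(0)`. Titration
series are warm-started from the previous point, which changes speed only;
a test compares both code paths.

The solver is cross-checked against two independent oracles: the 1:1
closed-form quadratic (to `1e-10` relative) and a nested-bisection solver
for 1:1 + 1:2 ladders (to `1e-8`).

## Spectral model

A solution's spectrum is the concentration-weighted sum of unitary species
spectra,

    If_j = sum_i C_i * Phi_{i,j}

with `Phi_{i,j}` the molar fluorescence of species `i` at wavelength `j`
(per mode: emission with 285 nm excitation, and synchronous scans at
offsets 15 and 60 nm). For fixed concentrations this is linear, so given a
titration's speciation the `Phi` matrix is the ordinary least-squares
solution of `Y = C Phi`, solved wavelength-by-wavelength
(`estimate_molar_fluorescence()`). Design choices:

* `Phi` is unconstrained; small negative estimates are a useful diagnostic
  and only produce a warning. An exact non-negative solver (best feasible
  subset per wavelength, practical for the ≤ 5 species handled here) is
  available behind `nonneg = TRUE`, off by default.
* Collinear concentration profiles raise an error naming the offending
  species rather than silently dropping columns.
* Per-mode `Phi` matrices are independent; no cross-mode coupling.

Savitzky–Golay smoothing (`smooth_spectrum()`) is provided for raw exported
traces but is applied nowhere by default — bench instruments already smooth,
and the window/order of the original instrument settings are unknown, so no
fidelity is claimed. It is implemented from the local-polynomial projection
matrix (the `signal` package is deliberately not a dependency) and verified
by the property that polynomials up to the filter order pass unchanged.

## Global fit

`refine_constants()` minimises the multimode sum of squares

    U = sum_modes sum_solutions sum_wavelengths (If_exp - If_calc)^2

over the refined log constants. The problem is *separable*: for any trial
constants the optimal `Phi` is a linear solve. The implementation therefore
alternates, inside every Gauss–Newton iteration: (i) speciation at all
titration points, (ii) the linear `Phi` solve per mode (skipped when the
user supplies `Phi`), (iii) a Gauss–Newton step on the refined log10
constants with a finite-difference Jacobian (step `1e-4` log units) of the
*profiled* residuals. Numerical safeguards, none of which changes a
converged answer:

* step-halving (≤ 10 halvings) so accepted iterations never increase `U` —
  the accepted-`U` trace is stored and asserted monotone in the tests;
* a step clamp of 2 log units per iteration;
* a small ridge (`1e-8 · max diag`) on near-singular normal equations:
  far from the optimum a constant whose complex has not yet formed is
  locally inert and its Jacobian column vanishes. A *structurally*
  unidentifiable problem — no quencher added, or a complex whose spectrum
  never differs from the protein's — still raises an identifiability error,
  which is diagnosed at the solution, not at a bad start;
* multi-start (default 3 starts at ±1 log unit) with all basins reported;
* failed speciation at an absurd trial point is treated as a rejected step.

Convergence: relative ΔU below `1e-8` or a parameter step below `1e-12`,
max 200 iterations; non-convergence is flagged, not hidden.

Standard errors come from `sigma^2 (JᵀJ)^{-1}` at the solution with
`sigma^2 = U / dof` and `dof = ns·nw − p − n_phi`: the linearly estimated
molar fluorescences are counted against the degrees of freedom because the
source material does not define its denominator; with ~10⁴ data points the
choice is numerically minor, but it is stated here for reproducibility.
Stepwise-constant errors are obtained from the cumulative covariance by the
linear ladder transform. Default starting value for any refined constant is
log K = 4.0 — the generic order of magnitude of NSAID–albumin association —
so no fit is seeded with its own truth.

Mode weights default to 1 (`U` simply concatenates modes); per-mode weights
are exposed for pathological intensity imbalances but no default rescaling
is applied.

### The staged fit

For drugs whose Δλ = 60 nm synchronous spectra are far more intense than
the other modes, the joint fit degrades: with noise proportional to each
mode's maximum intensity, the bright mode contributes mostly noise. (This
is measurable in the synthetic flurbiprofen system: the three-mode joint
fit determines the 1:1 constant *worse* than the two-mode fit.)
`staged_fit()` therefore:

1. fits the constants on a mode subset (canonically emission + sync15);
2. fixes every stage-1 constant not re-refined in stage 2;
3. re-refines the remaining constant(s) on (possibly) all modes,
   warm-started from stage 1.

Two superficially plausible alternatives were tested and rejected during
development: fitting stage 1 with a 1:1-only model biases the 1:1 constant
severely when the 1:2 constant is the larger one (the dominant species is
missing from the model), and iterating the fix/refine alternation between
the two different mode subsets diverges (each stage optimises a different
objective). The adopted reading — stage 1 fits both constants where the
data are clean, and only the 1:2 constant is recalculated with the bright
mode included — is stable and recovers both constants.

`compare_models()` ranks candidate models by residual standard deviation
with a parsimony override: a model with fewer constants within 5 %
(configurable) of the best `sd_residual` is promoted, and the note says so.
Nothing is ever deleted automatically.

## Classical single-wavelength analyses

The Stern–Volmer fit regresses `(F0−F)/F` on `[Q]` *through the origin*
(the equation has no intercept); `KSV` is the slope and `Kq = KSV/τ` with
the unquenched lifetime `τ` a user input (default 5 ns, the midpoint of the
2–7 ns range quoted for protein fluorophores; values outside that range
warn). `classify_quenching()` calls the mechanism static when the apparent
`Kq` exceeds the ~1e10 M⁻¹s⁻¹ diffusion limit — a ground-state complex, not
collisions, is then removing the fluorescence.

The double-logarithm form regresses `log10((F0−F)/F)` on `log10[Q]` with a
*free* intercept (the intercept is `log Kb`; the slope is the Hill
coefficient `nH`). Total drug concentration stands in for free drug, which
is accurate only with the protein in large deficit; the tests quantify the
bias as the protein:quencher ratio grows — this is the model restriction
that makes the global fit preferable whenever drug or complex fluorescence
interferes. Points with `F ≥ F0` carry no information on the log scale and
are dropped with a warning (early-titration noise), never silently.

Wavelength selection for these fits follows the stated criterion: among
wavelengths where the drug's interference `100·I_drug/I_total` is at most
10 % (configurable), take the one with the maximum protein signal; if no
wavelength qualifies the result is explicitly "none usable" — for strongly
fluorescent drugs the single-wavelength route is simply unavailable.

## The synthetic titration generator

`simulate_titration()` emulates the cuvette protocol the analysis assumes:
a 2700 µL aliquot of 3–5 µM albumin; sixteen consecutive additions of a
1000 µM drug stock (300 µM for the poorly soluble flurbiprofen-like preset)
covering a drug:protein total-concentration ratio of 0.4–14; exact dilution
bookkeeping (protein moles are conserved to 1e-12 relative — a test); three
acquisition modes on 1-nm grids; i.i.d. Gaussian noise with sd equal to
0.5 % of each mode's maximum clean intensity; a mandatory seed with no
global RNG state touched. Ratios are geometrically spaced by default (the
protocol source states only the range; geometric spacing samples both the
stoichiometric and the excess regime, and linear spacing is available).
Additions that would grow the cuvette volume beyond 20 % are rejected with
a suggestion to raise the stock concentration.

Species spectra are sums of Gaussian bands. The protein band peaks at
346 nm in emission and 285–286 nm in the synchronous modes; complexes are
attenuated, slightly blue-shifted copies of the protein bands (a changed
fluorophore microenvironment); free drugs carry their own bands in the
modes where they fluoresce.

**Calibration of the stated world.** The noise level (0.5 %) is fixed; the
spectral contrast between species was calibrated once so that the standard
errors *recovered by the fits* land near the ±0.01–0.02 reported for such
experiments — the criterion the generator is designed around. Pure scalar
attenuation (complex spectrum = damped protein spectrum) proved
insufficient: the two complex species are then spectrally near-collinear
and the recovered sd is 5–10× too large. With attenuation 0.6/0.05 and
shifts of −12/−30 nm the two-site recoveries reach sd ≈ 0.015–0.03. The
flurbiprofen-like system remains the least precise (the 1:1 complex is a
minority species at every titration point when K2 > K1; its staged-fit sd
is ≈ 0.07 per titration) — the mean over replicates recovers the constant,
but the printed 0.01 precision for that particular constant is *not*
reproduced by this synthetic world, and we record that as a limitation
rather than quietly inflating the information content further.

What the generator deliberately does **not** emulate: inner-filter
effects, photobleaching, temperature drift, Raman/scatter peaks, detector
saturation (only flaggable), instrument response. A green recovery test
therefore establishes that the *estimators* are correct and well
calibrated for data satisfying the model's assumptions — not that any
particular laboratory spectrum satisfies them.

The four presets (`drug_presets()`) encode the qualitative archetypes:
naproxen-like (one site, drug fluoresces in emission + sync60),
diflunisal-like (two sites an order of magnitude apart, minor drug
interference), flurbiprofen-like (two close sites, interference in all
modes, overwhelming sync60 intensity — the staged-fit case; its protocol
uses 5 µM protein and tops out at ratio 12, the most a 300 µM stock can
reach within the volume budget), and ibuprofen-like (binding far from the
fluorophores: the complex emits exactly like free protein, so the fit
rightly finds no stable constant; its nominal constant is a synthetic
stand-in, not a measured value).

## Numerical and interface conventions

* Concentrations are µM in files and user-facing tables, mol/L internally;
  conversion happens once at the solver boundary.
* Spectra travel as long-format CSV (`solution_id,mode,wavelength_nm,intensity`)
  with a JSON sidecar; all floats are written with 17 significant digits, so
  write∘read is bit-exact (a test asserts identity). Grids must match
  exactly across solutions — no silent interpolation.
* Constants are reported as "estimate (standard error)" with the estimate
  rounded to the error's leading decade, e.g. `5.74 (0.01)`.
* A capacity note is emitted above 300 solutions or 500 points per
  spectrum; nothing hard-fails.

## Known limitations

* Two components only; no protonation equilibria (pH is assumed buffered),
  no activity corrections, no cross-temperature (van 't Hoff) analysis.
* The alternating (variable-projection-style) refinement treats `Phi` as
  exactly eliminated; its uncertainty enters the constants' errors only
  through the degrees-of-freedom correction.
* The DLSV estimator is offered with its known bias (total ≈ free drug);
  users with comparable protein and drug concentrations should read the
  global fit instead.
* Close binding constants with a dominant higher complex (the
  flurbiprofen-like case) are intrinsically weakly determined at this
  noise level; expect per-experiment scatter well above the two-site
  well-separated case.
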