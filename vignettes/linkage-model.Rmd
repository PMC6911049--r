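---
title: "Thermodynamic linkage of fold switching and toroidal assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamic linkage of fold switching and toroidal assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(allofold)
```

## The system and the model

Chymotrypsin inhibitor 2 (CI2) is a small (~7 kDa), hyper-stable,
strictly monomeric two-state folder. Engineered variants of it
interconvert between the native fold (N) and an alternate,
"fold-switched" conformation (S) that exposes a sticky interface and
assembles into a hexameric ring (H, six monomers) and a dodecameric
double ring (H2, two stacked hexamers with D6 symmetry). A short
peptide matching the protein's C-terminal segment (the "C-peptide", P)
binds the native conformation only, forming NP. `allofold` implements
the equilibrium thermodynamics of this five-species scheme and the
observables used to probe it, with the aim of making the whole
analysis exercisable on synthetic data with parameter recovery as the
benchmark.

The species are linked by five equilibria, all referenced to the
1 M standard state:

* N ⇌ S (fold switch), N ⇌ U (unfolding): each a thermal two-state
  step with Gibbs–Helmholtz free energy
  ΔG(T) = ΔH~m~(1 − T/T~m~) + ΔC~p~[(T − T~m~) − T ln(T/T~m~)],
  so ΔG(T~m~) = 0 exactly.
* 6 S ⇌ H and 2 H ⇌ H2: mass-action association steps parameterised
  by (ΔG~ref~, ΔH~ref~, ΔC~p~) at a reference temperature, giving
  K(T) = exp(−ΔG(T)/RT) with K~H~ in M^−5^ and K~H2~ in M^−1^.
* N + P ⇌ NP: bimolecular binding, K~P~ in M^−1^.

Only the switched conformation assembles, and hexamerisation is
all-or-none (no intermediate oligomers): the experiments resolve only
monomer, hexamer and dodecamer, and the model mirrors that. The
peptide binds only N, which is how it acts as a negative allosteric
effector of assembly — binding drains the monomer pool toward the
native state, pulling the S ⇌ H equilibria apart.

With x = [N], every other concentration is an explicit function of x:
[S] = K~S~x, [U] = K~U~x, [H] = K~H~(K~S~x)^6^,
[H2] = K~H2~K~H~^2^(K~S~x)^12^, [NP] = K~P~x·P~free~ with
P~free~ = P~tot~/(1 + K~P~x). The total monomer balance is strictly
increasing in x, so the equilibrium is the unique root of a
one-dimensional monotone equation.

## Numerical solution

`solve_species()` finds ln x by bisection on the bracket
[ln(C~tot~·10^−14^), ln C~tot~] with relative tolerance 10^−12^ and an
iteration cap of 300. Bisection is chosen over Newton because strict
monotonicity makes it unconditionally convergent, and the x^6^ and
x^12^ terms make Newton steps overflow-prone; all high-order terms are
evaluated in log space with the exponent capped so that overflow
saturates to +Inf and simply drives the bracket downward. The solver
is vectorised across conditions, so temperature scans and titrations
solve in a single call. At the returned root, mass balance holds to
~10^−11^ relative and detailed balance holds by construction (species
are computed from x through the equilibrium constants). The tests
check both against an independent dense log-grid scan oracle and on
1000 randomised parameter draws.

Degenerate inputs are handled explicitly: a disabled (`NULL`) step has
K = 0 and its species never populate; the all-disabled model returns a
pure native monomer; pathological constants that push even the lower
bracket above C~tot~ raise an error naming the bracket rather than
returning a wrong root.

## Observables

`melt_curve()` synthesises optical melts as population-weighted linear
baselines, y(T) = Σ f~i~(a~i~ + b~i~T). The default
`signal_basis()` is the tryptophan-fluorescence convention for this
system: N and NP bright, everything else dark, because the first
(switch/assembly) transition erases the whole fluorescence signal.

`excess_enthalpy()` returns the population-weighted molar enthalpy per
monomer referenced to N, with ΔH(T) = ΔH~m~ + ΔC~p~(T − T~m~) per
step; assembled species carry the per-monomer share of the association
enthalpies (ΔH~H~/6, ΔH~H2~/12). `dsc_thermogram()` differentiates it
by central differences with a default half-step of 0.02 K — small
enough that the truncation error is far below the width of any
transition the model can produce, while keeping the observable layer
agnostic to solver internals. Peaks are interior local maxima filtered
by topographic prominence (default 1% of the trace maximum); no
smoothing is applied because model traces are noise-free unless the
generators add noise. For a two-state step with ΔC~p~ = 0 the peak
reproduces the closed-form van't Hoff maximum ΔH~m~^2^/(4RT~m~^2^) to
better than 0.5%, which the tests assert. The model emits positive
excess heat capacity for endothermic transitions; presentation-level
sign flips (exotherm-down conventions) are left to the caller.

## Two-state models and their conventions

Chemical denaturation uses the linear extrapolation model
ΔG(D) = ΔG~0~ − m~eq~D with linear native/unfolded baselines (the
standard treatment; baselines are instrument-dependent and are free
parameters of the fit). Chevron kinetics use
ln k(D) = ln k^0^ + mD/RT, i.e. kinetic m-values are slopes of
RT·ln k versus denaturant, in kJ mol^−1^ M^−1^ as published. Under
this (only supported) convention the published kinetic m-values of
these proteins are numerically incompatible with the published
equilibrium midpoints — no standard unit reading reconciles them — so
the package deliberately never cross-constrains kinetic and
equilibrium fits: parameters are treated per-model. The one
cross-check that is unit-safe, RT·ln(k~f~^0^/k~u~^0^) versus the
equilibrium ΔG~0~ in water, agrees within 0.5 kJ/mol for the wild
type and is asserted in the tests.

A practical consequence is that synthetic chevrons must span both
arms of the V: the default grid runs from water to 1.6× the closed
-form chevron minimum, which for the wild-type parameters lies at
~25 M in model space. That number is physically meaningless — it is
the direct consequence of the m-value inconsistency above — but the
synthetic protocol is self-consistent, which is what parameter
recovery requires.

## Synthetic data and the noise model

Every generator produces the model mean plus additive homoscedastic
Gaussian noise, parameterised as a fraction of the noise-free signal
range (default 2%, a conventional optical-data magnitude; the source
experiments do not report noise levels). Rates are noised on the log
scale (default 1%), matching the log-normal error structure of
relaxation rates. Each dataset draws from its own pseudorandom
stream, derived from the master seed by a stable hash of the generator
configuration, so replicate suites are reproducible bit for bit and
different dataset kinds never share a stream. What the generators do
*not* emulate: instrument drift beyond linear baselines, scan-rate
lag in DSC, mixing dead time. Passing recovery tests therefore
demonstrate estimator correctness and calibration under the stated
noise model, not robustness to instrument artifacts.

## Fitting

All fitters are least squares with analytic-model residuals:
`fit_lem()` and `fit_thermal_two_state()` in signal space,
`fit_chevron()` in log-rate space (matching the generator's error
structure), via `minpack.lm`; `fit_linkage_global()` minimises the
pooled residual sum of squares across condition series with bounded
L-BFGS-B. Each fitter first tries a data-driven start (baseline means,
midpoint crossing, arm slopes) and falls back to Latin-hypercube
restarts within bounds (default cap 20) — the models are
low-dimensional and smooth, so multi-start local optimisation is both
sufficient and reproducible, and exotic global optimisers are avoided
on purpose. Standard errors come from the local quadratic
approximation at the optimum; `Cm` and the rate constants get
delta-method errors for the derived/back-transformed scales.

Identifiability is policed rather than assumed: chevron fits reject
single-arm data (minimum at the grid edge), melt fits warn when the
grid never leaves the transition (T~m~/ΔH~m~ confounding), and the
global linkage fit refuses masks that free association parameters
without multi-concentration data or peptide affinity without
titration data.

`recovery_study()` wraps the generate–fit loop: R replicates, seeds
drawn deterministically from a master seed, per-parameter bias and
RMSE against the generating truth, with fitter failures counted and
reported. Under the package's reference protocol (100 replicates,
2%-of-range noise) the wild-type stability and both midpoints are
recovered with sub-percent bias; the engineered variant's ΔG~0~ has a
per-replicate spread of ~13%, so its 100-replicate mean carries a
~1.4% standard error — worth knowing when comparing means against
point targets.

## Fixture parameters

The shipped two-state fixtures (`ci2_fixture("ci2_wt")`,
`"ci2_eng"`) carry the published equilibrium and kinetic parameters.
The linkage fixtures (`"ci2_eng_linkage"`, `"ci2_158_linkage"`) are a
different matter: no numerical ΔG/ΔH values for the switch or
association steps have been published, so these are illustrative
defaults calibrated once to reproduce the qualitative behaviour of
the system — native-fold destabilisation that grows with protein
concentration, a DSC profile that splits into two peaks moving apart
with concentration, assembly that rises then melts out with
temperature, and peptide rescue that gets harder at warmer
temperatures. They are tuning constants, not measurements, and are
documented as such. Concretely: switch step ΔG(298 K) ≈ +17 kJ/mol
(ΔH~m~ = 100 kJ/mol, T~m~ = 359 K), unfolding step T~m~ = 337 K with
ΔH~m~ = 300 kJ/mol, hexamerisation ΔG~ref~ = −170 kJ/mol at 298 K
with a modest endothermic ΔH~ref~ = +60 kJ/mol (entropy-driven
association, as expected for burial of a hydrophobic interface), ring
stacking ΔG~ref~ = −23 kJ/mol, and peptide binding
ΔG~ref~ = −23 kJ/mol (K~d~ ≈ 100 μM) with ΔH~ref~ = −40 kJ/mol so
binding weakens on warming.

```{r species}
lp <- ci2_fixture("ci2_eng_linkage")
st <- solve_species(lp, conditions(C_tot = 600e-6, T = seq(285, 375, 0.5)))
autoplot(st)
```

```{r dsc}
autoplot(dsc_thermogram(lp, C_tot = 600e-6, T_grid = seq(280, 375, 0.25)))
```

## Worked recovery example

```{r recovery}
wt <- ci2_fixture("ci2_wt")
rec <- recovery_study(
  generate = function(s) gen_chem_denaturation(
    wt$chem, seq(0, 7, length.out = 25), T = 298,
    noise = noise_spec(0.02, seed = s)),
  fit = fit_lem,
  true = c(dG0 = wt$chem$dG0, Cm = wt$chem$Cm),
  R = 100, seed = 1)
rec
```

## Problem sizes and other choices

The reference analyses are deliberately desk-scale: recovery studies
use 100 replicates of 20–25-point curves (seconds of compute);
property suites use 1000 random solver draws and a 50-case oracle
comparison; temperature grids use 0.25–0.5 K spacing over
280–375 K. These sizes were chosen as the smallest at which the
reported statistics are stable; all of them are arguments, not
constants, so larger studies are one call away.

Other decisions worth recording: temperatures are kelvin everywhere,
energies kJ/mol, concentrations molar; the gas constant is defined
once (`fold_constants$R`); sequence masses use average (not
monoisotopic) residue masses because the comparisons are against
light-scattering-scale molecular masses; the D6 toroid builder places
coarse pseudo-atom placeholders (no side-chain model — atomic fitting
into density is out of scope) with ring radius (outer + channel)/4 and
the second ring staggered by half the inter-subunit angle, which is
exactly the condition for the perpendicular two-fold axes of the
dihedral group; and the Michaelis–Menten module implements the
classical competitive-inhibition expressions as published, with the
documented caveat that the reference assay (53 nM enzyme, 200 nM
inhibitor) sits near the tight-binding regime where a Morrison-type
treatment would be more accurate.

## Known limitations

Assembly kinetics are out of scope (the system is treated as under
thermodynamic control), as are intermediate oligomers, domain-swapped
dimer linkage, crowding corrections, proline-isomerisation slow
phases and three-state chevron rollover. The linkage fixtures are
qualitative stand-ins, so quantitative conclusions about the real
proteins should come from fitting real data with
`fit_linkage_global()`, not from the fixtures.
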