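# allofold

Thermodynamic analysis of allosteric protein assembly driven by a
monomer fold switch.

Chymotrypsin inhibitor 2 (CI2) is a small (~7 kDa), hyper-stable,
strictly monomeric two-state folder. Suitably engineered variants
interconvert between the native fold and an alternate, assembly-prone
conformation that oligomerises into hexameric rings and D6-symmetric
dodecameric toroids. Because assembly proceeds *through* the
conformational switch, the system behaves as an allosteric machine:
temperature and protein concentration promote assembly, and a short
C-terminal peptide that binds only the native fold dissolves it.

`allofold` is an R package for scientists who want to model, simulate
and fit this class of coupled equilibria:

* **Two-state folding models** — linear extrapolation for chemical
  denaturation, ΔG(D) = ΔG₀ − m·D; Gibbs–Helmholtz stability curves,
  ΔG(T) = ΔHₘ(1 − T/Tₘ) + ΔCₚ[(T − Tₘ) − T·ln(T/Tₘ)]; chevron
  kinetics, ln λ(D) = ln[k_f⁰ e^(m_f·D/RT) + k_u⁰ e^(m_u·D/RT)].
* **The five-species linkage model** — N, NP, S, U monomers, hexamer
  H = 6S, dodecamer H2 = 2H, solved by monotone mass-action root
  finding at any (C_tot, T, P_tot), in log space so the x⁶ and x¹²
  terms never overflow.
* **Observables** — fluorescence/CD melts, DSC excess heat capacity
  with peak extraction, species distributions, peptide-rescue
  titrations.
* **Enzyme inhibition** — competitive Michaelis–Menten analysis:
  V₀ = V_max·S/(K_m^app + S) with K_m^app = K_m(1 + I/K_i).
* **Seeded synthetic-data generators and fitting** — Gaussian-noise
  generators for every curve shape, multi-start nonlinear
  least-squares fitters with broom-style `tidy()`/`glance()`, global
  linkage fits across condition series, and `recovery_study()` for
  bias/RMSE calibration.
* **Composition & geometry** — average sequence masses (monomer ≈
  7.3 kDa, hexamer ≈ 44 kDa, dodecamer ≈ 88 kDa for the engineered
  variant) and a D6 double-ring pseudo-atom builder with exact
  symmetry checks and PDB export.

## Worked example

Simulate a wild-type chemical denaturation experiment from the
published parameters (ΔG₀ = 30.9 kJ/mol, C_m = 4.07 M), refit it, and
calibrate the estimator over 100 seeded replicates:

```r
library(allofold)

wt <- ci2_fixture("ci2_wt")
cv <- gen_chem_denaturation(wt$chem, seq(0, 7, length.out = 25),
                            T = 298, noise = noise_spec(0.02, seed = 7))
fit_lem(cv)
#> <fold_fit: lem_two_state, converged, rss = 0.005497, 0 restart(s)>
#>                dG0     m_eq       aN        bN       aU       bU       Cm
#> estimate  29.18639 7.158076 0.994640 -0.013777 0.203351 0.009524 4.077407
#> std.error  2.55767 0.641212 0.009953  0.006509 0.079849 0.012717 0.040730
```

A single 2%-noise replicate pins the midpoint to 1% (4.077 ± 0.041 M)
while the stability carries the usual ~8% uncertainty — which is why
recovery is judged on replicate means:

```r
recovery_study(
  generate = function(s) gen_chem_denaturation(
    wt$chem, seq(0, 7, length.out = 25), T = 298,
    noise = noise_spec(0.02, seed = s)),
  fit = fit_lem, true = c(dG0 = wt$chem$dG0, Cm = wt$chem$Cm),
  R = 100, seed = 1)
#> <recovery_report: 100 replicates, 0 failure(s), seed 1>
#> # A tibble: 2 x 6
#>   term   true  mean     bias   rmse     sd
#> * <chr> <dbl> <dbl>    <dbl>  <dbl>  <dbl>
#> 1 Cm     4.07  4.06 -0.00621 0.0349 0.0345
#> 2 dG0   30.9  31.4   0.534   2.27   2.22
```

The linkage model reproduces the system's signature behaviour: at low
protein concentration DSC shows a single unfolding transition, while
at high concentration the thermogram splits into a switch/assembly
peak and a dissolution peak that move apart:

```r
lp <- ci2_fixture("ci2_eng_linkage")
dsc_thermogram(lp, C_tot = 6e-6,   T_grid = seq(280, 375, 0.25))
#> <dsc_trace: 381 points, C_tot = 6e-06 M, 1 peak(s) at 337.2 K>
dsc_thermogram(lp, C_tot = 600e-6, T_grid = seq(280, 375, 0.25))
#> <dsc_trace: 381 points, C_tot = 0.0006 M, 2 peak(s) at 307.2 K, 356.8 K>
```

Species distributions report what size-exclusion or sedimentation
experiments resolve — monomer, hexamer, dodecamer — with masses scaled
from the sequence:

```r
seqs <- read_sequences(system.file("extdata", "ci2_variants.fasta",
                                   package = "allofold"))
species_distribution(lp, conditions(C_tot = 1e-3, T = 308),
                     monomer_mass = average_mass(seqs$seq[2]))
#> # A tibble: 3 x 6
#>   C_tot     T P_tot species fraction mass_da
#>   <dbl> <dbl> <dbl> <chr>      <dbl>   <dbl>
#> 1 0.001   308     0 M          0.461   7332.
#> 2 0.001   308     0 H          0.273  43995.
#> 3 0.001   308     0 H2         0.266  87990.
```

Each result type has an `autoplot()` method; fitted objects have
`tidy()` and `glance()`. The methods vignette
(`vignettes/linkage-model.Rmd`) documents the model, the numerical
choices and the fixture calibration in detail.

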