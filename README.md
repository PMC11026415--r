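# capion

Solution-speciation thermodynamics for aqueous calcium orthophosphate:
determine the ion-association constants of the three calcium-phosphate ion
pairs from potentiometric titration curves, and everything around that —
Davies-corrected speciation, thermodynamic analysis, speciation diagrams,
pKa titrations, and a faithful titration simulator.

## The science

When CaCl₂ is dosed into a phosphate buffer at constant pH, a calcium
ion-selective electrode reads less free Ca²⁺ than was added. Before any
solid nucleates, the deficit is carried by 1:1 ion pairs,

    Ca²⁺ + H₂PO₄⁻  ⇌  [CaH₂PO₄]⁺   K₁
    Ca²⁺ + HPO₄²⁻  ⇌  [CaHPO₄]⁰    K₂
    Ca²⁺ + PO₄³⁻   ⇌  [CaPO₄]⁻     K₃

with activity-based constants Kᵢ = a_pair / (a_Ca · a_anion) (dimensionless,
c⁰ = 1 M) and activities from the Davies equation,
log₁₀ γ = −0.5085 z² (√I/(1+√I) − 0.3 I). The size of K₃ controls whether
[CaPO₄]⁻ or the neutral [CaHPO₄]⁰ pair dominates calcium-phosphate
speciation near physiological pH — and therefore which species feed the
pre-nucleation stages of apatite biomineralization. Historical K₃ values
are biased upward by a premature phase separation at the dosing tip that
sequesters calcium and masquerades as binding; the package's simulator
reproduces that artifact, and the fitting pipeline is designed around the
acidified-titrant protocol that avoids it.

The package implements:

* **chemistry core** — triprotic phosphate speciation, ionic strength,
  Davies coefficients, and a self-consistent equilibration of the coupled
  pair equilibria (`phosphate_fractions()`, `davies_gamma()`,
  `equilibrate()`, `speciation_state()`);
* **two titration models** — the direct (measured-bound) calculation and
  the predictive coupled mass-action solve, plus curve prediction with full
  volume/counter-titrant bookkeeping (`direct_free_calcium()`,
  `predictive_solve()`, `predict_curve()`);
* **fitting** — direct low-pH K₁ determination, global multi-pH
  least-squares for K₁–K₃ in log space, and tolerance-scan error bounds
  (`fit_k1_direct()`, `fit_binding_constants()`, `binding_error_bounds()`),
  with broom-style `tidy()`/`glance()` methods;
* **thermodynamics** — ΔG⁰ = −RT ln K, two-temperature van't Hoff ΔH⁰,
  ΔS⁰, and linear ΔG(T) fits (`delta_g0()`, `vant_hoff_dh0()`,
  `entropy0()`, `fit_gibbs_line()`, `thermo_table()`);
* **speciation diagrams** — pair mole fractions and bound-calcium fractions
  across pH, with revised and legacy constant presets
  (`pair_speciation()`, `bound_fraction()`, `autoplot()`);
* **pKa analysis** — equivalence-point detection on the smoothed derivative
  and half-equivalence pKa reading (`find_equivalence_points()`,
  `estimate_pka()`);
* **simulators** — seeded titration and acid-titration generators with ISE
  noise, counter-titration, the dosing-tip artifact and a nucleation cutoff
  (`simulate_titration()`, `simulate_acid_titration()`);
* **I/O and CLI** — a fixed-unit CSV dialect, YAML run configs, and a
  `cap_cli()` dispatcher with `speciate/simulate/fit/thermo/diagram/pka`
  subcommands (thin wrapper script in `inst/cli/capion.R`).

## Worked example

Simulate triplicate titrations at the five working pH values with the
revised 25 °C constants and 1% electrode noise, then recover the constants:

```r
library(capion)
library(dplyr)

k <- binding_preset("revised_25C")    # K1 = 4.5, K2 = 470, K3 = 50,000
curves <- bind_rows(lapply(c(4.3, 8.3, 9.8, 10.8, 11.3), function(ph)
  simulate_titration(
    titration_protocol(target_ph = ph, replicates = 3, n_steps = 40,
                       seed = 11L + round(10 * ph)),
    k, noise_cv = 0.01)))

fit <- fit_binding_constants(curves, init = binding_constants(5, 300, 3e4))
fit
#> <capion_fit> predictive model, K1 = 5.2 (direct_low_ph), K2 = 469.4, K3 = 50006
#>   SSE = 5.571e-11 over 480 points at pH { 4.3,  8.3,  9.8, 10.8, 11.3}
tidy(fit)
#> # A tibble: 3 × 3
#>   term  estimate source
#>   <chr>    <dbl> <chr>
#> 1 K1        5.20 direct_low_ph
#> 2 K2      469.   fitted
#> 3 K3    50006.   fitted
```

K₂ and K₃ come back within a fraction of a percent of the generating
values. K₁ is read directly from the pH 4.3 curve by single-pair mass
action; with all three pairs active about a tenth of the binding there is
actually the neutral pair, so the estimate runs slightly high — well inside
its ±2.4 uncertainty.

The thermodynamic chain from the constants at 25 °C and 37 °C:

```r
thermo_table(binding_preset("revised_25C"), binding_preset("revised_37C"))
#>         pair   k_ref   k_alt dg0_kj_mol dh0_kj_mol ds0_j_k_mol t_ref_k
#> 1 [CaH2PO4]+     4.5     4.5     -3.728      0.000       12.50   298.1
#> 2  [CaHPO4]0   470.0   480.0    -15.252      1.349       55.68   298.1
#> 3   [CaPO4]- 50000.0 69500.0    -26.820     21.098      160.72   298.1
```

All three associations are exergonic but entropy-driven: the enthalpies are
zero-to-positive and the large positive ΔS⁰ (release of hydration water)
carries the binding. And the pKa pipeline on a simulated 0.01 M phosphoric
acid titration:

```r
estimate_pka(simulate_acid_titration(n_steps = 300))
#> # A tibble: 2 × 3
#>    step v_equivalence_ml   pka
#>   <int>            <dbl> <dbl>
#> 1     1             5.00  2.58
#> 2     2            10.00  6.98
```

Speciation diagrams contrasting the revised and legacy constants:

```r
autoplot(pair_speciation(binding_preset("revised_25C")))
plot_bound_fraction(revised = binding_preset("revised_25C"),
                    legacy  = binding_preset("legacy_25C"))
```

With the revised constants [CaHPO₄]⁰ stays the majority pair up to
pH ≈ 10.4; the legacy reconstruction hands dominance to [CaPO₄]⁻ already
near pH 8.4.

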