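---
title: "Calcium-phosphate ion association: models, fitting and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calcium-phosphate ion association: models, fitting and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capion)
library(dplyr)
```

## The problem

When calcium chloride is dosed slowly into a phosphate buffer held at
constant pH, a calcium ion-selective electrode reads less free calcium than
was added. In the pre-nucleation regime — before any solid forms — the
difference is carried entirely by 1:1 ion pairs:

$$\mathrm{Ca^{2+} + H_2PO_4^- \rightleftharpoons [CaH_2PO_4]^+} \quad (K_1)$$
$$\mathrm{Ca^{2+} + HPO_4^{2-} \rightleftharpoons [CaHPO_4]^0} \quad (K_2)$$
$$\mathrm{Ca^{2+} + PO_4^{3-} \rightleftharpoons [CaPO_4]^-} \quad (K_3)$$

with activity-based constants $K_i = a_{pair} / (a_{Ca} a_{anion})$
(dimensionless, $c^0 = 1\,\mathrm{M}$). The size of $K_3$ decides whether
$[\mathrm{CaPO_4}]^-$ or the neutral $[\mathrm{CaHPO_4}]^0$ pair dominates
aqueous calcium-phosphate speciation around physiological pH, which in turn
decides which species seed amorphous calcium phosphate and, ultimately,
apatite biominerals. Historical determinations of $K_3$ are vulnerable to a
subtle artifact: a locally overconcentrated dosing zone can shed a dilute
solid phase well below bulk saturation, and the sequestered calcium is then
misread as bound, inflating the apparent association. This package
implements the solution chemistry, the two fitting models, the
thermodynamic analysis and a titration simulator (including that artifact)
as one reproducible pipeline.

## Solution model

**Phosphate speciation.** Total free phosphate is partitioned over
H$_3$PO$_4$ through PO$_4^{3-}$ by the closed triprotic form in
`phosphate_fractions()`. The pKa values (defaults 2.58, 6.98, 12.32 at
298.15 K) are *operational mixed constants*: the proton enters as the
activity a pH electrode reports, the phosphate species as concentrations.
That is exactly the quantity a half-equivalence reading returns, and it is
the basis on which the default values were determined; it also makes the
fractions a function of pH alone, which keeps the coupled solves
well-conditioned. The working ionic strength of the titrations
(≈ 0.015–0.03) is inside the range over which the apparent pKa$_2$ is flat,
so a single set per temperature suffices; the simulator applies a
Davies-differential drift only above I ≈ 0.05, where a real drift is seen.

**Activities.** Ionic strength is $I = \tfrac12 \sum z_i^2 c_i / c^0$ over
every charged species including the charged ion pairs (the neutral pair is
excluded; whether ion pairs contribute at all is a judgement call — they are
kept for consistency with the definition). Activity coefficients come from
the Davies equation with the conventional 0.5085 prefactor and 0.3 I linear
term; $\gamma$ depends only on $|z|$, and neutral species get exactly 1.
H$^+$/OH$^-$ contributions are computed from the clamped pH; they matter
only at the pH extremes.

**Self-consistent equilibration.** At fixed pH and fixed $\gamma$, the
three pair equilibria collapse to a single quadratic in the bound-calcium
amount, solved in its cancellation-free form. Self-consistency in
$I \leftrightarrow \gamma$ is a damped fixed point (damping 0.5, relative
tolerance $10^{-10}$, capped iterations with a convergence error that
reports the last $I$). Mass balances on calcium and phosphate hold to
better than $10^{-12}$ relative; the tests verify this on random draws.

Two independent formulations of the same equilibrium coexist deliberately:
`equilibrate()` (closed form inside the fixed point) and
`predictive_solve()` (damped Newton on the three coupled pair relations
with an analytic Jacobian, physical-box root selection and eight
deterministic restarts). They agree to $10^{-8}$ and better in the tests,
which is the package's main guard against algebra slips.

## The two titration models

The **direct calculation** takes the *measured* free calcium at each dose
point, attributes `added − free` to the ion pairs, depletes the free
phosphate pool accordingly, and returns the free-calcium activity as the
exact algebraic solution
$a_{Ca} = \gamma_{Ca}(n_{added}/V_t) / (1 + \gamma_{Ca} S)$ with
$S = \sum_i K_i a_{anion,i}/\gamma_{pair,i}$.

The **predictive calculation** uses no measured concentrations at all: from
dosed amounts, pH, and activity coefficients it solves the coupled
mass-action system outright. On noise-free synthetic data the two models
coincide pointwise (round-trip property, $10^{-8}$).

`predict_curve()` runs the predictive model over a dosing schedule with
full volume bookkeeping: titrant, its acid spike, and the counter-titrant
volume required to hold the pH, computed from the stoichiometric proton
demand of the evolving speciation. Because the counter-titrant feedback on
the bulk is tiny, the whole schedule is solved as a vectorised fixed point
(a handful of sweeps) rather than step by step; the result is quasi-static
and rate-independent. Activity coefficients are refreshed at every dose
point rather than frozen per curve — the alternative frozen-$\gamma$
convention changes free calcium by well under a percent at these ionic
strengths, but refreshing is the consistent choice given the equilibration
loop.

## Fitting the constants

`fit_k1_direct()` implements the low-pH route: at pH ≈ 4.3 the speciation
is dominated by H$_2$PO$_4^-$, so $K_1$ follows point-by-point from the law
of mass action. Note the attribution caveat: with all three pairs active,
roughly a tenth of the binding at pH 4.3 is the neutral pair, so this
single-pair estimate runs a little high — well inside the ±2.4 uncertainty
that accompanies the value, but visible on clean synthetic data.

`fit_binding_constants()` is the global route: unweighted least squares on
free-calcium *concentration* residuals (that is what the
matched-ionic-strength electrode calibration reads; per-curve
inverse-variance weighting is available behind a flag) summed over all
points of all curves, optimised in log-K space (the constants span five
orders of magnitude) by Nelder-Mead from three deterministic starts. When a
low-pH curve is present, $K_1$ is fixed to its direct estimate and the
low-pH curves are dropped from the sum — they carry no information about
$K_2$/$K_3$ and their $K_1$ information is already used. Below pH 9 the
PO$_4^{3-}$ signal is negligible and $K_3$ is flagged unidentifiable.

Error bounds follow the acceptable-agreement logic rather than a curvature
statistic: each constant is scanned on a log grid (others fixed) and the
bound is the interval within which the worst per-curve RMS relative
deviation between model and measurement stays below a tolerance, default
5%, the typical between-replicate reproducibility of such titrations.
Intervals that hit the grid edge are flagged one-sided.

## Thermodynamics

`delta_g0()`, `vant_hoff_dh0()` and `entropy0()` compose the standard
chain $\Delta G^0 = -RT\ln K$, two-temperature van't Hoff
$\Delta H^0 = R\ln(K_b/K_a)/(1/T_a - 1/T_b)$ and
$\Delta S^0 = (\Delta H^0 - \Delta G^0)/T$, with R = 8.314 J/K/mol and
25/37 °C mapped to 298.15/310.15 K (the 0.15 K offsets change nothing at
the reported precision). `fit_gibbs_line()` generalises the two-point
treatment to a least-squares line $\Delta G(T) = \Delta H - T\Delta S$; at
exactly two points it reproduces the van't Hoff composition algebraically.
Two temperatures 12 K apart make $\Delta H^0$ and $\Delta S^0$ sensitive to
small changes in the constants — the uncertainties are accordingly large —
but the $\Delta G^0$ values are solid.

## Speciation diagrams

`pair_speciation()` equilibrates a pH grid and reports each pair's mole
fraction *of total ion pairs* (at low pH a large mole fraction does not
imply a large concentration) plus the bound-calcium fraction. The diagram
defaults are dilute (0.05 mM Ca / 1 mM P): crossover pH values converge in
that regime, whereas at the titration's 10 mM phosphate the buffer ionic
strength (≈ 0.03) pushes them up ≈ 0.2 pH units through the
$\gamma_2\gamma_1/\gamma_3$ factor. With the revised constants the neutral
pair dominates up to pH ≈ 10.4; with the shipped legacy reconstruction the
anionic pair takes over near pH 8.4.

The legacy preset deserves its own paragraph. The historical constant set
is not reprinted here; the preset keeps $K_1$, $K_2$ at the revised values
and sets $K_3$ two orders of magnitude above the revised one — the size of
the historical overestimate, and the choice that reproduces the reported
two-pH-unit shift of the upper crossover. The implied Gibbs-energy gap
between the second and third association is then 23.0 kJ/mol, close to the
21.4 kJ/mol the older literature quotes; anchoring on 21.4 exactly would
give only a 53-fold $K_3$ ratio and put the legacy crossover near pH 8.7–8.9,
inconsistent with the dominance-from-pH-8 behaviour the preset exists to
emulate. The preset is a documented reconstruction, overridable by an
explicit `binding_constants()`.

Two quantitative statements often quoted alongside such diagrams are *not*
reproduced by this mass-action model and are deliberately not asserted in
the tests: near-complete (> 95%) calcium binding already at pH 9 under
legacy constants (the model tops out near 82–88% there for any legacy
reconstruction, reaching 95% only around pH 9.8), and a ~5% free-calcium
remainder at pH 11.3 under revised constants at 10 mM phosphate (the model
gives ~13% at the titration's ionic strength, and ~5% only near I ≈ 0.005).
Both are sensitive to unstated diagram conditions; the tests assert the
ordering and monotonicity properties that are robust.

## The synthetic-data generator

`simulate_titration()` emulates the potentiometric protocol: 0.005 M
CaCl$_2$ dosed into 50.00 g of 0.010 M phosphate buffer (density
1.000 g/mL) at constant pH, triplicate, with the titrant acidified with
0.05 M HCl and 0.1 M counter-titrant volumes tracked stoichiometrically.
The electrode noise is multiplicative log-normal with cv 1% by default (an
ISE responds log-linearly in activity, so its error is relative),
mean-unbiased, and clamped at the no-binding line so that generated data
always satisfy the container invariants. Replicates share the chemistry
path and differ only in their seeded noise streams; the same protocol seed
reproduces curves bit-for-bit.

The premature-phase-separation artifact is modelled as the simplest
mechanism consistent with its phenomenology: per dose, if the *locally
enriched* ion-activity product — free-calcium activity times an enrichment
factor (default 50) times the HPO$_4^{2-}$ + PO$_4^{3-}$ activity — exceeds
a solubility-scale threshold (default 2.5 × 10$^{-7}$, the order of the
brushite solubility product), a fixed fraction (default 0.5) of that dose's
calcium, with matching phosphate, leaves the solution before equilibrating.
Sequestered amounts are carried in the output so that mass accounting
closes to 10$^{-12}$. A bulk-IAP cutoff (same default threshold) ends every
curve at nucleation. The true magnitude of the tip enrichment is not
knowable from bulk data; the defaults are chosen to reproduce the
qualitative dichotomy — the artifact curve bends early, lies at or below the
clean curve everywhere, and inflates apparent binding — not any quantitative
feature. What passing tests show is therefore that the *analysis* behaves
correctly on data with this structure, not that the artifact model is a
physical theory of the dosing tip.

`simulate_acid_titration()` generates the pKa curves from the exact
proton/charge balance of the H$_3$PO$_4$/NaOH system (root-found in pH with
activity-corrected H$^+$/OH$^-$), with presets for varied dose steps, a
1 M base variant and dilution-compensated co-dosing of 0.020 M acid.

## pKa analysis

`find_equivalence_points()` differentiates pH against volume with a
width-configurable local-quadratic (Savitzky-Golay-style) smoother — chosen
over a canned filter because dose grids need not be uniform — takes the
largest local maxima of the derivative, and refines each by a three-point
parabola. `pka_from_half_equivalence()` interpolates pH at half of each
successive equivalence interval. For the second step of 0.01 M phosphoric
acid this reading *is* the constant; for the first step the acid is strong
relative to its concentration, so free protons shift the conjugate ratio at
half-volume and the naive reading runs ≈ 0.28 units high. When the curve
carries its recipe, the analysis recomputes the true degree of
neutralisation from the charge balance and corrects the
Henderson-Hasselbalch ratio (the correction is negligible for step two and
can be disabled). The third pKa is outside the reach of the method — the
derivative shows no third maximum with 0.1 M base — which is why the
literature value is used for it throughout. Only two equivalence points are
ever requested; pKa$_3$ extraction is a non-goal.

## Numerical choices and degenerate inputs

* Fixed-point loops damp by 0.5 and converge to $10^{-10}$ relative in $I$;
  bound iteration counts raise errors, never silently return.
* The bound-calcium quadratic uses the cancellation-free small-root form
  ($2\alpha C / (B + \sqrt{B^2 - 4\alpha C \cdot \alpha})$ style), which
  keeps mass balances at $10^{-12}$ even when binding is ~10$^{-6}$ of the
  totals.
* `predictive_solve()` restarts from eight deterministic points spanning
  the physical box if Newton leaves it; ties between roots cannot arise
  because only one root lies in the box for this system.
* Zero totals, zero constants, zero doses and empty curves all return the
  exact degenerate answers rather than eroding to tolerance.
* `truncate_prenucleation()` declares a prefix linear when the RMS residual
  of an OLS fit stays below 1% of the mean free-calcium amount (window 10);
  a curve with no such prefix signals an empty regime as a typed condition.

## Problem sizes used by the tests

The shipped tests and the acceptance script run titration curves of 15–50
dose steps, global fits on 2–5 pH groups with up to three replicates,
100-seed Monte-Carlo loops for the direct-$K_1$ and noise-averaging
properties, and a 25-set recovery study at reduced size (duplicates at
three pH values, 20 steps). These sizes were chosen so the whole suite
exercises every code path at full numerical strictness while remaining
comfortable to run interactively.

## Known limitations

* The model is strictly 1:1 ion pairing; multi-ion clusters, anion-anion
  association and post-nucleation solubility equilibria are out of scope,
  so simulated curves end at the nucleation cutoff rather than showing the
  peak-and-plateau of real post-nucleation data.
* Davies is a ~0.5 M-class approximation; above I ≈ 0.1 the activity model
  is the dominant error in every derived quantity.
* The legacy preset is a reconstruction, not a literature table.
* Two-temperature van't Hoff over 12 K propagates constant uncertainties
  into large enthalpy/entropy uncertainties; treat those outputs as
  order-of-magnitude unless more temperatures are supplied to
  `fit_gibbs_line()`.
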