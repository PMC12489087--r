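# vofde

Simulation and qualitative analysis of enzyme–substrate kinetics driven by
a **variable-order Caputo fractional derivative with constant time delays**.

Classical mass-action models of the enzyme reaction
S + E ⇌ H → E + P respond instantaneously to the current state.  Real
enzymatic systems carry memory — slow binding/unbinding, conformational
rearrangement, cofactor regeneration — and that memory strength itself can
drift as substrate depletes or conditions change.  `vofde` models this with
a four-compartment network whose dynamics are governed by a Caputo
derivative of time-varying order δ(t) ∈ (0, 1] and two constant delays:

    D^{δ(t)} S = β₂ H − β₁ E S
    D^{δ(t)} E = β₃ H + β₂ H − β₁ E S
    D^{δ(t)} H = −β₃ H − β₂ H + β₁ E(t−τ₁) S(t−τ₂)
    D^{δ(t)} P = β₃ P        (an optional variant uses the classical β₃ H)

with β₁ the binding rate, β₂ the product-formation rate, β₃ the catalysis
rate.  The operator is interpreted through its Volterra integral form with
the order frozen at the outer evaluation time: at time t the kernel is
(t−v)^{δ(t)−1}/Γ(δ(t)).  Only the complex-formation term sees delayed
states; pre-history is constant at the initial state.

The package is aimed at researchers in fractional dynamics and systems
biology who want a reproducible, tested reference implementation of this
model class rather than one-off scripts: a general variable-order
fractional delay solver, the enzyme model on top of it, the model's
Lipschitz/uniqueness/Ulam–Hyers machinery, and table/figure reproduction
with an auditable comparison report.

## What is inside

* **Solver core** — `solve_vofdde()`: Adams–Bashforth–Moulton
  product-integration predictor–corrector (rectangle predictor, trapezoid
  corrector, full-memory convolution, per-step frozen order
  α = δ(t_{n+1}), refined start-up substeps for the t^α singularity).
  `solve_reference_order1()` provides a classical RK4 delay-DE path for
  δ ≡ 1 cross-validation, `pece_weights()`/`rl_integral()` expose the
  quadrature, `mittag_leffler()` the series oracle,
  `convergence_probe()` an empirical-order check.
* **Enzyme model** — `simulate_enzyme()` returns a classed trajectory with
  `print`/`summary`/`plot`/`coef`/`predict` methods;
  `conservation_check()` (E+H is invariant for zero delays),
  `positivity_check()`, `total_mass()`.
* **Qualitative analysis** — `trajectory_bounds()`,
  `lipschitz_constants()` (Φ₁ = β₁b₂, Φ₂ = β₁b₁, Φ₃ = β₂+β₃, Φ₄ = β₃,
  ζ = max Φⱼ), `uniqueness_condition()` (κⱼ = t^{δ(t)}/Γ(δ(t)+1)·Φⱼ ≤ 1),
  `ulam_hyers_constants()` (ψⱼ = κ̃/(1−κ̃Φⱼ)), and `uh_experiment()`, which
  verifies the bound ‖y − ŷ‖ ≤ ψⱼεⱼ by actually integrating a perturbed
  system.
* **Reproduction** — `enzyme_table()`, `figure_series()`,
  `reference_table()` (the printed values, kept as comparison inputs),
  `compare_table()`, `estimate_time_offset()`,
  `validate_parameter_mapping()`, plus a CLI at `inst/cli/vofde.R`
  (`simulate`, `table`, `figures`, `stability`, `convergence`, `compare`).

## Worked example

```r
library(vofde)

tb <- enzyme_table(4)      # no-delay scenario, three order functions
print(tb)
#> Reproduced table 4: H(t) for delays (0, 0); variant = as_printed
#>   columns: delta(t) = 1 | delta(t) = 0.97 | delta(t) = 0.99 + -0.0001*t
#>    t  order1 order097  linear
#>    0  4.0000   4.0000  4.0000
#>   20  6.5765   6.6958  6.6232
#>   40  3.9241   4.4692  4.1843
#>   ...
```

The complex H rises from 4 to a peak and then decays as substrate is
consumed; lowering the order (stronger memory) slows the decay, so the
fractional columns sit above the integer column at late times.

```r
print(stability_report(interval = c(0, 1)))
#> Stability report on [0, 1], delta(t) = 1
#>   trajectory bounds b1..b4: 10.00000  5.00000  5.68091  0.10408
#>   Lipschitz constants: Phi1 = 0.265, Phi2 = 0.530, Phi3 = 0.052, Phi4 = 0.040
#>   zeta = max Phi = 0.53
#>   uniqueness factors kappa: 0.265 0.530 0.052 0.040
#>   condition satisfied: yes (all kappa <= 1)
#>   Ulam-Hyers constants psi: 1.361 2.128 1.055 1.042
```

On [0, 1] all κⱼ < 1, so solutions are unique there and an ε-perturbed
trajectory stays within ψⱼ·ε of the exact one — `uh_experiment()` confirms
this empirically (observed deviations reach about a third of the bound).
On [0, 200] κ = 200·ζ = 106 and the certificate is vacuous; the report
says so rather than extrapolating.

`compare_table()` documents how the reproduction relates to the printed
reference values cell by cell.  Of note: the printed integer-order columns
match the model's solution about **2 time units earlier** than their row
labels state (`estimate_time_offset()` recovers the offset at run time,
residual ≈ 0.06%), and rows t = 160/180 are printed as duplicates; the
comparison flags both instead of hiding them.

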