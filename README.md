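# chasekin

Kinetic analysis of two-step mitochondrial presequence processing from
cycloheximide-chase time courses.

## The problem

When a nuclear-encoded protein is imported into the mitochondrial matrix,
its N-terminal targeting sequence is removed by the mitochondrial
processing peptidase (MPP).  For some substrates — the model case here is
C-terminally 3HA-tagged acetohydroxyacid synthase (Ilv2) in yeast —
cleavage happens in two sequential steps, producing two processed forms (A
and B) that are resolved as separate bands on a western blot.  In a
cycloheximide (CHX) chase, protein synthesis is blocked at t = 0 and the
fate of the pre-existing bands is followed by quantifying band intensities
at 20-min intervals.  The band kinetics are then described by three
consecutive, irreversible, homogeneous first-order reactions in a closed
system:

    PP --k_pa--> A --k_ab--> B --k_bx--> X

(PP precursor, A and B the cleavage products, X degraded material, rates in
min⁻¹).  The closed-form solution is the classical Bateman cascade, e.g.

    P(t) = P₀ e^(−k_pa t)
    A(t) = k_pa P₀ (e^(−k_ab t) − e^(−k_pa t)) / (k_pa − k_ab) + A₀ e^(−k_ab t)

and a three-exponential expression for B(t).  Because the precursor is
cleaved much faster than the downstream steps (k_pa ≫ k_ab), the system
simplifies for most chases to A(t) = A₀ e^(−k_ab t) plus a two-exponential
B(t).  Rate constants are estimated from normalized band intensities by
bounded nonlinear least squares, and half-lives follow as τ = ln 2 / k.

In some genetic backgrounds (loss of the i-AAA protease Yme1, where MPP
activity becomes limiting) the chase shows "too much B-form" at early time
points and the sequential model no longer fits.  The package therefore also
implements a *branched* network with a direct precursor-to-B route
(rate k_pb), solved by matrix exponentiation of the full linear system, and
discriminates between the sequential and branched topologies with a
small-sample information criterion (AICc) computed from the residual sums
of squares of both nested fits.

## What is in the package

* `solve_full_sequential()`, `solve_simplified()`,
  `solve_matrix_exponential()` — analytic and general linear-system
  trajectories for any rate configuration (repeated rates included), with
  the degraded mass X tracked so conservation is observable.
* `timecourse()`, `normalize_to_reference()`, `fit_sequential()`,
  `fit_branched()`, `compare_models()`, `report_half_lives()` — chase
  fitting and model discrimination.
* `chase_scenarios()`, `simulate_chase()`, `generate_panel()`,
  `recovery_experiment()`, `selection_experiment()` — a seeded synthetic
  densitometry generator with named wild-type/mutant scenarios and the
  simulation experiments used to validate estimation and selection.
* `read_timecourse()`, `write_timecourse()`, `write_report()`, `run_cli()`
  (plus the thin `exec/chasekin` script) — TSV/CSV tables, TSV/JSON
  reports, and a `simulate | fit | compare | demo` command line.

## Worked example

Simulate a wild-type chase with 5% multiplicative densitometry noise,
normalize it to the A-band at t₀, and fit the simplified sequential model:

```r
library(chasekin)
sc <- chase_scenarios(sigma = 0.05)[["wild-type"]]
sc$noise$seed <- 42
tc  <- normalize_to_reference(simulate_chase(sc))
fit <- fit_sequential(tc)
fit
#> <chase_fit: sequential-simplified model, 12 observations>
#>   k_ab = 0.01841 /min (tau_A = 37.6 min)
#>   k_bx = 0.02909 /min (tau_B = 23.8 min)
#>   rss = 0.002908, converged: TRUE
report_half_lives(fit)
#>    k_ab tau_A   k_bx tau_B
#>  0.0184    38 0.0291    24
```

The generating rates were k_ab = 0.0189 and k_bx = 0.0287 min⁻¹; the fit
recovers them to within a few percent from a single noisy 6-point chase,
and prints the half-lives of the A- and B-forms in minutes.

The `demo` subcommand (or `demo_summary()`) regenerates the whole strain
panel without noise and round-trips every scenario through
simulate → normalize → fit → report:

```r
demo_summary(seed = 1)
#>                 scenario           model    k_ab tau_A    k_bx tau_B
#>                wild-type sequential-full 0.01890    37 0.02870    24
#>                    yta10 sequential-full 0.00575   121 0.04370    16
#>                     yme1        branched 0.00599   116 0.00979    71
#>                     mcx1 sequential-full 0.00503   138 0.00679   102
#>  yme1-MPP-overexpression sequential-full 0.00161   431 0.02310    30
```

Each row reproduces exactly the rate constants the scenario was generated
with; τ columns are ln 2/k rounded to the nearest minute.  (The published
turnover table this panel is parameterized from contains one internally
inconsistent cell — a τ_A of 43 min next to k_ab = 0.00161 min⁻¹, whose
ln 2/k is ≈ 431 min; the package reports the value implied by the rate
constant and documents the discrepancy rather than silently correcting it.)

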