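---
title: "Methods: chase kinetics of two-step presequence processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chase kinetics of two-step presequence processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chasekin)
```

## The kinetic model and its assumptions

A cycloheximide chase stops protein synthesis at t = 0; thereafter the
precursor (PP), the first cleavage product (A-form) and the second
cleavage product (B-form) of a twice-processed mitochondrial preprotein
evolve only by interconversion and degradation.  chasekin models this as a
closed linear system of irreversible, homogeneous first-order reactions

$$\mathrm{PP} \xrightarrow{k_{pa}} A \xrightarrow{k_{ab}} B
  \xrightarrow{k_{bx}} X,$$

optionally extended by a direct precursor-to-B edge $k_{pb}$ (the
*branched* model).  All times are minutes and all rates min⁻¹ throughout;
there is no unit-conversion layer.  The assumptions inherited from this
formulation are worth keeping in mind:

* every reaction is first order and its rate constant is time-invariant
  over the chase (no synthesis, no saturation of the proteases);
* the bands interconvert in the stated order only — no reverse reactions,
  and degradation acts on the B-form alone;
* band intensity is proportional to species abundance (linear
  densitometry).

$X$ (degraded material) is carried explicitly as total mass minus
$P+A+B$, so mass conservation is an observable invariant of every solver
rather than an implicit assumption — the test suite asserts
$P+A+B+X = P_0+A_0+B_0$ to 1e-10 on every call.

## Solvers

Three routes produce trajectories:

1. `solve_full_sequential()` — the closed-form (Bateman) solution of the
   three-step chain for arbitrary initial abundances.
2. `solve_simplified()` — the two-species limit used when the precursor is
   cleaved much faster than the downstream steps ($k_{pa} \gg k_{ab}$): the
   precursor vanishes within the first sampling interval and
   $A(t) = A_0 e^{-k_{ab}t}$ with a two-exponential $B(t)$.  A property
   test quantifies the regime of validity: with $k_{pa} \ge 50\,k_{ab}$ and
   $P_0 \le 0.1\,A_0$, the full and simplified curves (with the vanished
   precursor mass carried in the A-pool) differ by at most $0.02\,A_0$
   anywhere in the fitted window of 20–100 min.
3. `solve_matrix_exponential()` — $x(t) = e^{Mt}x(0)$ on the 4×4 rate
   matrix from `build_network()`; valid for any configuration, including
   repeated rates and the branched network.

**Degeneracy handling.**  The closed forms divide by rate differences.
Whenever two relevant rates coincide to within a relative tolerance of
1e-9, the call is routed silently (with a message) through the matrix
exponential instead of risking catastrophic cancellation.  Inside the
matrix-exponential solver the same tolerance decides between a fast
eigendecomposition (the rate matrix is triangular, so its eigenvalues are
the diagonal) and dense scaling-and-squaring via `Matrix::expm()` for
genuinely repeated eigenvalues, where the eigenvector matrix is singular.

## Normalization and fitting

Chase intensities are normalized to the A-band at t₀
(`normalize_to_reference()`), the standard convention for this experiment;
fitted parameters are invariant to the raw intensity scale.

`fit_sequential()` and `fit_branched()` minimize the unweighted ordinary
least-squares objective over the chosen bands,

$$\mathrm{RSS}(\theta) = \sum_{\text{bands } b}\sum_{\text{times } i}
  \left(\hat y_b(t_i;\theta) - y_{bi}\right)^2,$$

with bounded Levenberg–Marquardt (`minpack.lm::nls.lm`).  Choices, with
reasons:

* **Free parameters.**  The default fit uses the A and B bands with the
  simplified model (free: $k_{ab}, k_{bx}, A_0, B_0$), because on real
  blots the precursor band is typically too faint to quantify.  Including
  the PP band (or `full = TRUE`) switches to the full solution with
  $k_{pa}$ and $P_0$ additionally free.  The branched fit always frees
  $k_{pa}, k_{pb}, k_{ab}, k_{bx}, P_0, A_0, B_0$ and uses the
  matrix-exponential solver.
* **Bounds.**  Rates in $[0, 1]$ min⁻¹ (a half-life of 42 s is far below
  anything resolvable at 20-min sampling); initial abundances in
  $[0, 10\times$ max observed intensity$]$.
* **Multistart.**  Without a user guess, five deterministic starts span
  1e-4–0.1 min⁻¹ log-uniformly.  The per-rate start values are staggered
  (3× for $k_{pa}$, 1.7× for $k_{bx}$, 0.5× for $k_{pb}$) so that no start
  sits exactly on the equal-rates manifold, which is both a removable
  singularity of the closed forms and a plausible basin boundary.  Best
  final RSS wins; ties go to the first start found.
* **Under-determination and degenerate data** raise errors (fewer
  observations than free parameters + 1; all-zero fitted intensities).  A
  rate estimate at its upper bound converges but warns — e.g. a
  permanently empty B band drives $k_{bx}$ to the bound because any
  B-form produced must disappear instantly.
* **Unidentifiable branch rate.**  When the fitted precursor pool $P_0$ is
  (near) zero, $k_{pb}$ has no effect on the curves and the optimizer
  would report whatever value it happened to stop at.  After optimization
  the branched fit therefore sets $k_{pb} = 0$ whenever doing so increases
  the RSS by less than 1e-9 relative — a parsimony tie-break, not a
  constraint.

Half-lives are derived as $\tau = \ln 2 / k$ and reported both at full
precision and rounded half-up to integer minutes, matching how turnover
tables are printed (rates at 3 significant figures).  One published cell
in the strain table that parameterizes the scenario panel is internally
inconsistent (τ_A = 43 min alongside k_ab = 0.00161 min⁻¹, though
ln 2/0.00161 ≈ 431 min; every other cell satisfies τ = ln 2/k to the
printed precision).  chasekin reports the value implied by the rate
constant and flags the discrepancy here instead of silently correcting
either number.

## Model discrimination

`compare_models()` decides between the sequential and the branched
topology.  Design choices:

* **Both candidates track the precursor.**  The sequential side is the
  *full* sequential model with $P_0$ free, not the simplified one, so the
  two candidates differ in exactly one edge ($k_{pb}$) and the comparison
  asks precisely whether a direct precursor-to-B route is supported.
* **All quantified bands enter the objective**, including PP when present.
  The branched question is about the precursor's fate; with the PP band
  ignored, a large, slowly cleaved phantom precursor pool can mimic the
  branched signature in the A/B curves and the comparison loses most of
  its power.  (With only A and B available the function still runs, at
  reduced power.)
* **Criterion.**  Small-sample AICc under a Gaussian error model,
  $n\log(\mathrm{RSS}/n) + 2k + 2k(k+1)/(n-k-1)$ with $k$ = free
  parameters + 1 for the error variance.  The choice is this package's
  own (visual fit assessment is not reproducible); AIC and BIC are
  available through the `criterion` argument, but their weaker penalties
  admit noticeably more spurious branched selections on
  sequential-generated data in this design ($n = 18$, $k = 8$ vs $9$).
* **Nesting is enforced.**  The branched optimization is seeded with the
  sequential optimum embedded at $k_{pb} = 0$, so its RSS can never exceed
  the sequential RSS.  Before taking logarithms the RSS is floored at
  $n\,(10^{-8}\times\text{max intensity})^2$: noise-free data fitted
  exactly by both nested models then resolve by the parsimony penalty
  (sequential wins) instead of by comparing logarithms of floating-point
  residue.  Ties go to the sequential model; if either fit fails to
  converge the comparison is flagged inconclusive.

The selection accuracy under the study conditions is computed by
`selection_experiment()` in the acceptance script and the test suite (200
replicates per topology at 5% noise), not asserted here.

## The synthetic densitometry generator

`chase_scenarios()` fixes one simulation scenario per strain, each
carrying its published A→B and B→X rate constants verbatim, sampled at
the chase design of 0–100 min in 20-min steps:

| scenario | k_ab | k_bx | model | notes |
|---|---|---|---|---|
| wild-type | 0.0189 | 0.0287 | sequential | |
| yta10 | 0.00575 | 0.0437 | sequential | A→B conversion impaired |
| yme1 | 0.00599 | 0.00979 | branched | k_pb = k_pa/2, P0 = 0.5 |
| mcx1 | 0.00503 | 0.00679 | sequential | both forms stabilized |
| yme1-MPP-overexpression | 0.00161 | 0.0231 | sequential | suppressed mutant |

Values the strain table does not determine were fixed once, before any
testing, on kinetic grounds:

* $k_{pa} = 0.1$ min⁻¹ — the precursor band is barely visible at t₀ and
  gone by the first chase point, which requires $k_{pa} \gg k_{ab}$; 0.1
  min⁻¹ empties the pool with a ~7-min half-life.
* Initial state $P_0 = 0.05, A_0 = 1, B_0 = 0.4$ for sequential
  scenarios — a faint precursor and a sub-stoichiometric B-form, the
  steady-state banding pattern the chase starts from.
* The yme1 scenario uses $P_0 = 0.5$ (precursor accumulates when MPP
  activity is limiting) and $k_{pb} = k_{pa}/2$, large enough that the
  early-time B-form excess — the diagnostic feature of that mutant — is
  visible at 20-min sampling.

**Noise.**  The default noise model is multiplicative lognormal with
σ = 0.05, because chemiluminescent band quantification has
signal-proportional error; an additive-Gaussian option (clipped at zero)
is retained for sensitivity checks.  The lognormal factors use
meanlog $= -\sigma^2/2$ so the noise is unbiased (unit mean), and σ = 0
reproduces the noiseless trajectory bit-exactly.  Each band at each time
is perturbed independently with a seeded generator; the same scenario and
seed give bit-identical tables, and simulation restores the caller's RNG
state.

What the generator does *not* emulate: band overlap and bleed-through,
detection-limit censoring of faint bands, saturation of strong bands,
lane-to-lane loading variation, and any correlation of errors across
times or bands.  Passing recovery tests therefore demonstrate that the
estimator works when its own error model holds, not that real blots meet
that model.

## Simulation experiment sizes

The validation experiments use 200 replicates each: wild-type rate
recovery at σ = 0.05 (simplified fit, A/B bands), branched-rate recovery
for the yme1 scenario (PP band included — the direct-route rate is only
weakly identified from 6 points without it), and model selection for one
sequential-generated and one branched-generated panel ($k_{pb} = k_{pa}$
for the latter, the strong-branching condition).  Solver cross-validation
uses 100 random rate draws, log-uniform in $[10^{-4}, 1]$ min⁻¹ with at
least 1e-3 relative pairwise separation, checked against an independent
adaptive-ODE integration (deSolve, lsoda) to 1e-8 relative.

## Known limitations

* With 6 time points and the PP band unquantified, the branched model's
  precursor parameters ($k_{pa}, k_{pb}, P_0$) are weakly identified;
  estimates of $k_{ab}$ and $k_{bx}$ remain stable but the branch split
  should not be over-interpreted without a precursor signal.
* The Gaussian information criteria are computed from unweighted RSS; with
  multiplicative noise this is an approximation (variance grows with
  signal), which is one reason the comparison retains a conservative
  small-sample penalty.
* No confidence intervals are produced; the recovery experiments quantify
  estimator spread under the stated noise model instead.
* The temperature-shift experiment style of chase (a precursor completely
  blocked from processing) has no kinetic parameters to fit and is out of
  scope.
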