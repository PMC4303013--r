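---
title: "Intensive parameter identifiability for kinetic models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intensive parameter identifiability for kinetic models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(identestim)
```

## The problem

Dynamic models of metabolic networks couple tens of metabolite mass
balances through kinetic rate laws that carry far more parameters than the
available time-course data can pin down. Three features make the
estimation problem ill-posed in practice even when the model is
structurally identifiable: only a fraction of the metabolites is measured;
some initial conditions are themselves unknown; and initial estimates for
most parameters come from heterogeneous literature sources and may be off
by orders of magnitude. The pragmatic response is *practical
identifiability* analysis: select the subset of parameters that the data
actually support, estimate exactly those, and freeze the rest.

The trap in the classical pipeline — rank once, select until a failure,
then estimate — is that every selection decision is made at the *initial*
parameter values. Re-estimating the selected subset moves those values,
which changes the sensitivities, which can change which other parameters
are estimable. This package implements the intensive variant: selection
and estimation are interleaved one parameter at a time, and every
previously failed parameter is returned to the candidate pool after each
successful re-estimation, so that each parameter is judged against the
best current vector rather than the starting guess.

## Model abstraction

A `kinetic_model` is a set of states with initial conditions (each tagged
known or unknown), named rate laws $r_k(C, \theta)$ in mM/s, a signed
stoichiometric map from rates to state derivatives, an optional dilution
term $-\mu C$ on intracellular states (growth-driven volume expansion,
$\mu$ in 1/s, treated as a constant input), and optional forcing terms for
reactor feeds. Units are fixed as mM and seconds; there is no unit
conversion layer. Rate laws are either user closures or the string
`"default"`, which expands to a generic Michaelis–Menten form in the
states the rate consumes — this keeps the bundled 18-state *E. coli*
central-carbon skeleton fully simulable while its literature rate
expressions remain pluggable through a registry.

Integration uses `deSolve`'s variable-order stiff solver (`lsoda`) with
rtol $10^{-6}$, atol $10^{-9}$ by default; metabolic turnover on the
second scale mixed with slow pool dynamics makes stiffness the norm.
Numerical breakdown is a *typed* condition, not a crash: step-size
collapse, non-finite derivatives, or a trajectory falling below
$-100\cdot\mathrm{atol}$ all raise an integration-failure condition that
the selection loop interprets as a failed estimation attempt.
Concentrations are clipped at zero only when rate laws are evaluated,
never in the stored trajectory, precisely so that pathological parameter
regions remain visible to that failure detector.

## Estimation and uncertainty

With independent Gaussian errors and a diagonal covariance, maximum
likelihood reduces to weighted least squares,
$$ S(\theta) = \sum_i \frac{(y_i^C(\theta) - y_i^E)^2}{\sigma_i^2},
   \qquad \sigma_i = a\,y_i^E + b , $$
with the error model evaluated on the *experimental* values so that the
weights are constant during optimization and $S$ is a fixed quadratic
form in the residuals. The proportional coefficient $a$ is dimensionless,
the floor $b$ is in mM; both non-negative, not both zero.

Subsets are optimized by Levenberg–Marquardt (`minpack.lm::nls.lm`, max
200 iterations, ftol/ptol $10^{-8}$) on the weighted residuals, with all
non-subset parameters frozen. Positive parameters are estimated on the log
scale, which enforces positivity of rate constants and concentrations and
makes steps multiplicative; each log-parameter moves inside a ±6-decade
box around its entry value — wide enough for initial estimates that are
wrong by several orders of magnitude, but bounded, because unbounded
steps routinely push stiff kinetic models into regions the integrator
cannot traverse.

At the optimum, the Fisher information matrix over the subset columns of
the raw sensitivity matrix gives the covariance and the reported relative
uncertainty $\sigma_\theta/\theta$:
$$ \mathrm{FIM} = B^\top V_Y^{-1} B, \qquad V_\Theta = \mathrm{FIM}^{-1}. $$
Singularity is judged on the parameter-scaled matrix
$D\,\mathrm{FIM}\,D$ with $D = \mathrm{diag}|\theta|$ (the FIM in
relative coordinates): the raw FIM mixes units of mM and mM/s and its
condition number is dominated by scale, not by information content. The
reciprocal eigenvalue ratio of the scaled matrix must exceed $10^{-10}$,
otherwise no inversion is attempted; the covariance is likewise inverted
through the scaled form.

### When is an estimation attempt a failure?

An attempt fails — and the candidate is demoted, with the full vector
rolled back to its entry state — on any of six conditions:

1. the optimizer does not converge;
2. an integration failure interrupts any objective evaluation;
3. the scaled FIM at the optimum is numerically singular;
4. the final objective exceeds its entry value;
5. the fitted value of a log-transformed parameter is pinned at the edge
   of its search box (the apparent optimum is not interior);
6. any normalized standard deviation exceeds 0.5, the two-sided 95 %
   significance rule $\theta/\sigma_\theta \ge 2$.

The first four are the conventional criteria. The last two were added
after the synthetic benchmark exposed a failure mode they are needed to
catch: early in a run, with most parameters still at wrong values, the
one-parameter objective surface can descend monotonically onto a
saturation plateau (an uptake $V_{max}$ running to infinity compensates
arbitrary downstream errors). On the plateau the model output no longer
responds to the parameter, finite-difference sensitivities degenerate to
integrator noise, and a 1×1 FIM built from that noise can look
spuriously informative. An estimate pinned at the box edge, or one whose
standard deviation rivals its value, carries no usable information; both
are demotions, not terminations — the parameter returns to the pool and
is retried after the selected set has moved, which is exactly the
intensive procedure's mechanism. Published parameter tables in this field
report $\sigma_\theta/\theta$ of 0.01–0.2, so the 0.5 cap is permissive.

## Ranking and the collinearity screen

Sensitivities are obtained by finite differences around the current
vector (forward by default, step $10^{-6}\max(|\theta_j|, 10^{-8})$;
central differences optional with $O(h^2)$ error), stacked over exactly
the observed (time, variable) records. Ranking operates on the
normalized matrix $B_N$ with entries
$(\partial y_i/\partial\theta_j)(\theta_j/y_i)$, so outputs and
parameters of different magnitudes are comparable; rows with
$|y_i| < 10^{-12}$ are normalized by that floor instead, which prevents
zero observations from dominating the ranking. Unknown-initial-condition
pseudo-parameters receive columns exactly like kinetic parameters.

The most estimable candidate maximizes the Euclidean norm of its column
*after* orthogonalization against the span of the already-selected
columns. The implementation uses modified Gram–Schmidt (numerically
stable, identical to the classical procedure in exact arithmetic) with a
pivot-drop tolerance of $10^{-12}$ relative to the largest selected
column; ties are broken by declaration order so runs are reproducible.
Orthogonalization discounts only the *selected* set — parameters sitting
in the evaluated set do not shadow the ranking, since they are not part
of the estimation subset.

The pairwise collinearity angle
$\angle_{i,j} = \arccos\!\big(b_{\theta_i}^\top b_{\theta_j} /
(\|b_{\theta_i}\|\|b_{\theta_j}\|)\big) \in [0°,180°]$ is a cheap
preliminary screen: values near 0° or 180° mark pairs the data cannot
separate, values near 90° mark independence. It inspects pairs only — the
Gram–Schmidt ranking handles higher-order dependence — and zero-norm
columns are reported as degenerate rather than silently included. The
evaluation point is recorded with every angle matrix, because the angles
(like all local sensitivities) change when the parameter values move.

## The intensive loop

```{r worst-case}
trace <- run_identifiability(
  NULL, NULL, candidates = c("a", "b", "c"),
  estimator = oracle_estimator(make_worst_case_oracle(3)))
trace$evaluation_count
```

All candidates start in $\Theta^{(NS)}$. Each round: re-rank
$\Theta^{(NS)}$ at the current vector, move the top candidate into
$\Theta^{(S)}$, re-estimate all of $\Theta^{(S)}$. Success updates the
vector, returns all of $\Theta^{(E)}$ to $\Theta^{(NS)}$, and triggers a
re-rank; failure rolls back, demotes the candidate to $\Theta^{(E)}$, and
tries the next entry of the *existing* rank — no re-ranking, because no
estimation succeeded and the evaluation point is unchanged. The run stops
when $\Theta^{(NS)}$ is empty. Recycling after *every* success (not only
at exhaustion) is what produces the triangular worst case: with three
candidates and an adversarial failure pattern the rounds cost 3 + 2 + 1
= 6 attempts, as the dry run above shows, and in general at most
$nP(nP+1)/2$. Termination is guaranteed for any deterministic failure
rule: a round either contains a success (the selected set grows
permanently) or exhausts $\Theta^{(NS)}$.

The set partition — $\Theta^{(S)}, \Theta^{(NS)}, \Theta^{(E)}$ pairwise
disjoint, union constant — is asserted inside the loop after every
attempt. A candidate may fail repeatedly across recycles; there is no
per-candidate retry cap (the global bound caps total work), and an
optional wall-clock budget covers expensive real models. The final state
keeps $\Theta^{(E)}$ members at their last rolled-back values, i.e. at
their entry-to-this-run estimates. The procedure itself is deterministic;
randomness exists only in synthetic-data generation.

`compare_baseline()` reruns the same problem in first-failure mode — the
classical scheme that stops at the first unsuccessful inclusion — and
reports both selected-set sizes and objectives. By construction the
intensive mode selects at least as many parameters and ends at an
objective no worse; both modes share identical failure criteria, so the
comparison isolates the recycling strategy.

## Unknown initial conditions

Initial concentrations of unmeasured intracellular metabolites cannot be
left at zero: zero starts can break the integration or bias predictions.
The bootstrap keeps them at zero only for a single small integration step
(default $10^{-3}$ of the first observation interval) and takes the
reached values — strictly positive wherever the network produces the
metabolite — as initial *estimates*, which then join the candidate vector
as `ic_<state>` pseudo-parameters and are refined like any kinetic
parameter. The bootstrap value scales linearly with the step size; this
is harmless because it serves only as a starting point, and the
parameter-recovery tests confirm the downstream estimates are insensitive
to the choice within an order of magnitude.

## The E. coli central-carbon skeleton

`build_ecoli_skeleton()` encodes the 18 printed mass balances of the
*E. coli* K-12 W3110 central carbon metabolism — extracellular glucose
plus 17 intracellular metabolites across glycolysis, the pentose
phosphate pathway and PTS uptake — coupled through 30 kinetic rates, each
balance carrying the $-\mu C$ dilution term and the glucose balance
carrying feed, pulse, and biomass-scaled uptake
($D(C_{glc}^{feed}-C_{glc}) + f_{pulse} - (C_x/\rho_x)\,r_{PTS}$, with
the $C_x/\rho_x$ scaling taken as a constant input). The literature rate
expressions for this network are not bundled; every rate defaults to the
generic Michaelis–Menten form with placeholder parameters at 1, and any
subset can be overridden through the rate registry. The skeleton is
therefore a *structural* fixture: its stoichiometric signs, dilution and
feed terms, and its five default unknown initial conditions (pgp, 3pg,
xyl5p, sed7p, g1p — the complement of the 13 typically measured species)
are faithful and tested, while its default kinetics are placeholders, and
no quantitative claims attach to simulations run with them.

```{r ecoli}
m <- build_ecoli_skeleton()
length(m$states)
bootstrap_unknown_ics(m)
```

## What the synthetic generator does and does not emulate

`make_chain_pathway()` builds linear enzymatic chains
$S_0 \to \dots \to S_n$ with Michaelis–Menten (or mass-action) steps;
`sample_dataset()` adds heteroscedastic Gaussian noise
$\varepsilon_i \sim N(0, (a y^{true}_i + b)^2)$ per record, resampling
negative draws (zero truncation, counted); `make_scenario()` assembles
the standard benchmark. Generator conventions, fixed once: $V_{max}$
log-uniform in 0.05–0.2 mM/s and $K_m$ in 0.5–5 mM on a 10 mM substrate
pool, so the dynamics resolve over the default 0–300 s horizon sampled at
21 points (mirroring the data density of typical pulse experiments);
initial estimates perturbed from the generating values by a log-normal
factor of sd 0.3 (≈ ±35 %, the "inadequate literature estimates" regime);
measurement masks for partial observation; withheld initial conditions
with their true values used only for data generation.

Two negative controls can be injected: an exactly duplicated parameter
(additive with its partner — collinearity angle 0, singular FIM whenever
both are in the subset) and a near-collinear parameter that leaks 2 %
into a second rate, landing inside the critical angle band without exact
degeneracy. Injected parameters keep their generating values as initial
estimates: a duplicate's partner absorbs any error in the frozen
duplicate, so perturbing both would make "recovery of the genuine
parameter" ill-defined as a test criterion.

What passing these benchmarks does *not* show: real metabolome data are
asynchronous across instruments (the long format supports this; the
generator only emulates per-variable masks), errors are rarely exactly
Gaussian or exactly $a y + b$, real rate laws are far more entangled than
a chain (allosteric regulation, shared cofactors), and co-metabolite
dynamics (atp/adp, nad(p)h) appear only as constants inside user rate
laws. Recovery on the chain demonstrates the machinery is correct and the
accounting exact, not that any real network is identifiable.

## Numerical choices, degenerate inputs, problem sizes

Tie-breaks in the ranking follow declaration order. Zero sensitivity
columns rank last (residual norm 0) and are flagged in the angle screen.
Datasets must carry strictly positive $\sigma_i$ — an additive floor
$b > 0$ or strictly positive measurements. A model that cannot be
simulated at its initial vector aborts the run before any selection, with
a diagnostic. Dry runs (`model = NULL` plus a mock estimator) exercise
the selection accounting alone and rank by declaration order, which is
how the worst-case and random failure oracles drive the procedure's
property tests.

The shipped test suite uses desk-scale problem sizes chosen to exercise
every code path at comfortable margins: 2–3-enzyme chains (5–7
candidates including injections), 21-point grids, 20-replicate recovery
benchmarks at $a = 0.01, b = 10^{-6}$, and dry-run property tests over
100 random failure oracles at 3–10 candidates. On these sizes a full
intensive run costs a few seconds.

## Known limitations

Sensitivities come from finite differences, not forward sensitivity
ODEs; for very stiff models the finite-difference step interacts with
integrator tolerances (tighten `rtol`/`atol` before shrinking
`step_rel`). Only diagonal error covariances are supported. The
uncertainty report is the local FIM approximation — no profile
likelihood or confidence-region geometry. The Levenberg–Marquardt
estimator is local: the intensive recycling reduces, but cannot
eliminate, dependence on initial estimates, and alternatives such as
swarm-based pre-optimization are deliberately out of scope because, on
stiff kinetic models, most random parameter vectors are not even
simulable. The ranking criterion (norms + Gram–Schmidt) is the shipped
default; the `estimator` and ranking hooks exist so other criteria from
the estimability literature can be plugged in without touching the loop.
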