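# identestim

Practical parameter identifiability with simultaneous subset selection and
estimation for ODE kinetic models — the situation of metabolic-network
modelling, where models carry dozens to hundreds of kinetic parameters, the
metabolome is only partially observed, several initial conditions are
unknown, and estimating *all* parameters from the available time courses is
an ill-posed problem. The package is for systems-biology and
chemical-engineering modellers who need to decide *which* parameters their
data can support, estimate exactly those, and keep the rest at literature
values.

## The method

Measurements `y_i^E` at times/variables `(t_i, v_i)` are fitted by weighted
least squares under a heteroscedastic error model:

    S(θ) = Σ_i (y_i^C(θ) − y_i^E)² / σ_i²,        σ_i = a·y_i^E + b

For a candidate subset the Fisher information matrix and the parameter
covariance follow from the raw sensitivity matrix `B = ∂Y/∂Θ`:

    FIM = Bᵀ V_Y⁻¹ B,    V_Θ = FIM⁻¹,    reported uncertainty: σ_θ/θ

Estimability is ranked on the normalized sensitivity matrix `B_N` with
entries `(∂y_i/∂θ_j)·(θ_j/y_i)`: the most estimable parameter has the
largest Euclidean column norm, and every candidate column is first
orthogonalized (Gram–Schmidt) against the columns of the already-selected
parameters so that linear dependence is discounted. A pairwise screen
computes the collinearity angle between sensitivity vectors,

    ∠(i,j) = arccos( b_θi·b_θj / (‖b_θi‖‖b_θj‖) ) ∈ [0°, 180°],

flagging near-parallel (< 5°) and near-antiparallel (> 175°) pairs.

The core loop — *intensive* one-by-one selection — maintains three sets:
selected Θ⁽S⁾, non-selected Θ⁽NS⁾, and evaluated Θ⁽E⁾ (failed at the
current configuration). The top-ranked candidate joins Θ⁽S⁾ and the whole
selected set is re-estimated. On success, *all* of Θ⁽E⁾ is returned to
Θ⁽NS⁾ — re-estimation moves the parameter values, so previously failed
parameters may now be estimable — and the ranking is recomputed at the
updated vector. On failure the candidate is rolled back and demoted to
Θ⁽E⁾, and the next-ranked candidate is tried. The run ends when Θ⁽NS⁾ is
empty, so every parameter gets evaluated; the total number of estimation
attempts is bounded by `nP(nP+1)/2`. Unknown initial conditions are
bootstrapped (integrate one small step from a zero start) and enter the
candidate set as pseudo-parameters.

## Worked example

A three-enzyme Michaelis–Menten chain with a deliberately injected
duplicated parameter (`rmax_v1_dup` enters the first rate additively with
`rmax_v1`, so the pair is structurally non-identifiable), noisy data
(σ = 0.01·y + 10⁻⁶) on a 0–300 s grid, and initial estimates perturbed
away from the generating values:

```r
library(identestim)

sc <- make_scenario(n_enzymes = 3, duplicate = TRUE, seed = 3)
trace <- run_identifiability(sc$model, sc$dataset)
print(trace)
#> <identifiability_trace> mode = intensive
#>   candidates: 7; selected: 6; failed (evaluated): 1
#>   estimation attempts: 10 (worst-case bound 28)
#>   objective: 64986111882 -> 57.49302

report <- selection_report(trace)
report$true_value <- sc$true_parameters[report$parameter]
print(report, digits = 3)
#>   parameter initial_estimate estimated_value normalized_std true_value
#> 1   rmax_v2           0.0979          0.1534        0.00506     0.1532
#> 2   rmax_v1           0.0424          0.0631        0.00141     0.0631
#> 3   rmax_v3           0.0891          0.0865        0.00610     0.0853
#> 4   K_v1_S0           1.0846          1.0605        0.00234     1.0634
#> 5   K_v2_S1           3.3345          2.0071        0.00605     2.0002
#> 6   K_v3_S2           2.9103          2.0615        0.01075     2.0108
```

All six genuine parameters are selected and recovered within their
reported uncertainties (`normalized_std` is σ_θ/θ); the objective drops
from 6.5×10¹⁰ at the perturbed initial estimates to 57.5, the order of
the number of residuals, and the redundant `rmax_v1_dup` ends in Θ⁽E⁾ —
every attempt to include it alongside `rmax_v1` produces a singular FIM.
The pairwise screen spots the same pathology up front:

```r
ang <- collinearity_angles(compute_sensitivities(sc$model, dataset = sc$dataset))
flag_collinear_pairs(ang)
#>   parameter_1 parameter_2    angle
#> 1     rmax_v1 rmax_v1_dup 3.45e-05
```

The bundled 18-state *E. coli* central-carbon skeleton (glycolysis,
pentose phosphate pathway, PTS uptake; 30 kinetic rates with pluggable
rate laws, five unknown initial conditions) exercises the same machinery
at realistic scale:

```r
m <- build_ecoli_skeleton()
length(m$states)          # 18
bootstrap_unknown_ics(m)  # positive starting estimates for pgp, 3pg, ...
```

Models are serializable as YAML and datasets as long-format CSV
(`time,variable,value`); `inst/cli/identestim` wraps the workflow for
shell use (`run`, `angles`, `rank`, `simulate` subcommands).

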