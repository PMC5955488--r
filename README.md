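# povdyn

Age-by-state Markov models of poverty dynamics and mortality.

People cross income thresholds throughout life, and being below a
threshold carries excess mortality.  povdyn is for demographers and
population-health researchers who want to turn longitudinal panel data on
a binary income state (below/above 1×, 2×, or 3× an official poverty
line) into a full cohort analysis: age-specific survival and
poverty-crossing probabilities, the age-by-state projection matrix, state
structure of a cohort at every age, remaining life expectancy and its
variance by starting state, and simulated individual lifetime
trajectories showing the dynamic heterogeneity behind the averages.

## The model

Four annual probability functions parameterise a two-state,
discrete-age chain: state-specific survival s₁(x), s₂(x) and, conditional
on survival, the exit probability t₂₁(x) (below → above) and the stay
probability t₂₂(x) (above → above); state 1 is below the threshold and
transition subscripts are destination-then-origin.  The per-age block

    Q(x) = [ s₁t₁₁  s₂t₁₂ ]
           [ s₁t₂₁  s₂t₂₂ ]

sits on the block subdiagonal of the age-by-state matrix **L** (202 × 202
for ages 0–100), which projects a cohort as n(x) = Lˣ n(0).  Appending a
mortality row gives an absorbing chain whose fundamental matrix
N = (I − L)⁻¹ yields, per (age, state) starting cell, remaining life
expectancy (column sums), expected remaining years below the threshold
(below-state row sums), and the variance of remaining life via the
factorial-moment identity η₂′ = η₁′(2N − I).  The dominant eigenvector of
the cumulative product Qcum(x) = Q(x)⋯Q(1) gives the quasi-stable state
structure that any initial cohort approaches with age.

Rates are estimated from panel data by pooled repeated observations:
consecutive responded interview pairs feed weighted logistic regressions
(survival; next state) per age segment, fitted interval probabilities are
annualised by the constant-hazard rule 1 − (1 − p)^(12/i), and segments
are concatenated over ages 22–95.  A synthetic-panel generator with known
logit-scale ground truth makes the whole pipeline testable without
restricted survey microdata.

## Worked example

```r
library(povdyn)

truth <- poverty_truth("1x")                      # synthetic ground truth
panel <- generate_panel(truth, panel_design(cohort_size = 8000), seed = 42)
fit   <- fit_rates(panel, degree = 1)             # pooled weighted logistic
print(fit)
#> Annual poverty-dynamics rates fitted from 72422 pooled pairs
#>   segment 22-33: n_surv = 26005, n_trans = 25917, mean interval 12.0 mo
#>   segment 34-50: n_surv = 25656, n_trans = 25391, mean interval 24.0 mo
#>   segment 51-95: n_surv = 20278, n_trans = 17430, mean interval 24.0 mo
#> Annual rate set, ages 22-95
#>  age     s1     s2     t21    t22    t11     t12
#>   22 0.9959 0.9987 0.38133 0.9437 0.6187 0.05628
#>   37 0.9869 0.9971 0.20565 0.9759 0.7944 0.02415
#>   51 0.9772 0.9923 0.16341 0.9773 0.8366 0.02271
#>   66 0.9479 0.9715 0.11826 0.9783 0.8817 0.02165
#>   80 0.8927 0.9101 0.08571 0.9793 0.9143 0.02071
#>   95 0.7882 0.7477 0.05971 0.9803 0.9403 0.01975
#> segment seams at ages: 33, 50

model <- markov_model(fit, ages = 22:100)
fundamental_summary(model)
#> Absorbing-chain summary (counting the current year), ages 22-100
#>  age state expectancy years_below proportion_below variance     cv
#>   22     1     48.576      7.9222          0.16309   266.93 0.3363
#>   22     2     48.940      5.7040          0.11655   252.21 0.3245
#>   42     1     30.336      8.1234          0.26778   186.40 0.4500
#>   42     2     31.801      3.4924          0.10982   157.98 0.3952
#>   61     1     15.599      6.9157          0.44335    90.51 0.6099
#>   61     2     17.289      1.7405          0.10067    82.49 0.5253
#>   80     1      7.110      5.1601          0.72578    25.52 0.7106
#>   80     2      7.399      0.5414          0.07317    24.91 0.6746

traj <- simulate(model, nsim = 10000, seed = 42)  # individual trajectories
residence_summary(traj)
#> Years below threshold: mean 6.31, sd 6.82, mode 0 (n = 10000)
#> entries into the below state: 14466; exits (incl. death): 14466
```

Read this as: a 22-year-old below the 1× threshold expects 48.6 more
years of life, 7.9 of them below the threshold; a 22-year-old above it
expects 48.9 years, 5.7 below.  The survival columns show the
below-threshold penalty opening through mid-age (s₂ − s₁ ≈ 0.02 around
age 80) and reversing in late old age.  Variance of remaining life is
consistently larger for those below the threshold — a wider range of life
courses.  Simulated individuals spend a mean 6.3 years below the
threshold; the most common outcome is zero.

`run_pipeline(run_config(...))` chains generation, estimation, analysis
and simulation, writing CSV tables, JSON metadata and PNG figures;
`inst/cli/povdyn.R` wraps it for the shell.

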