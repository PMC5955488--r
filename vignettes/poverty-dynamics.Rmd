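---
title: "Age-by-state Markov models of poverty dynamics and mortality"
author: "povdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-by-state Markov models of poverty dynamics and mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(povdyn)
```

## The model

povdyn studies a cohort in which every person is classified, at each integer
age, as *below* (state 1) or *above* (state 2) an income threshold — one,
two, or three times an official poverty line.  Four annual probability
functions drive everything:

* $s_1(x), s_2(x)$ — probability of surviving from age $x$ to $x+1$ for a
  person below/above the threshold at $x$;
* $t_{21}(x)$ — probability of exiting the below state by $x+1$,
  conditional on survival ($t_{11} = 1 - t_{21}$ is staying below);
* $t_{22}(x)$ — probability of staying above, conditional on survival
  ($t_{12} = 1 - t_{22}$ is entering the below state).

Subscripts are destination-then-origin.  The per-age block
$$Q(x) = \begin{pmatrix} s_1 t_{11} & s_2 t_{12}\\ s_1 t_{21} & s_2 t_{22}
\end{pmatrix}$$
moves survivors one age ahead while reshuffling states; its column $j$ sums
to $s_j(x)$, the deficit from 1 being annual mortality.  Placing the blocks
on the block subdiagonal of a square matrix $L$ (ages 0–100 by default,
hence $202 \times 202$ with two states) gives a cohort projection operator
without reproduction: a cohort vector $n(0)$ evolves as $n(x) = L^x n(0)$,
and an individual lifetime is a sample path of the absorbing Markov chain
obtained by appending a mortality row $m = 1 - \mathbf{1}'L$ and an
absorbing death state, which makes every column of
$P = \left(\begin{smallmatrix} L & 0\\ m & 1\end{smallmatrix}\right)$ sum
to one.

Because age strictly advances, $L$ is nilpotent, and the fundamental matrix
$N = (I - L)^{-1}$ is a finite sum of powers of $L$.  Its entry $(i, j)$ is
the expected number of one-year visits to cell $i$ starting from cell $j$,
counting the starting year.  Column sums give remaining life expectancy per
(age, state) starting cell; summing only below-threshold rows gives
expected remaining years below the threshold; and the standard
factorial-moment identity
$\eta_2' = \eta_1'(2N - I)$, $\mathrm{Var} = \eta_2 - \eta_1 \circ \eta_1$
gives the variance of remaining life, hence the coefficient of variation.
The quasi-stable state structure at age $x$ is the dominant right
eigenvector of the cumulative product
$Q_{cum}(x) = Q(x)Q(x-1)\cdots Q(x_0)$, and the damping ratio
$|\lambda_1|/|\lambda_2|$ of the cumulative *conditional* product (survival
removed) measures how fast any initial cohort composition converges to it.

## Estimation from panel data

Rates are estimated from longitudinal interview data by the pooled
repeated-observation design: every pair of consecutive responded interviews
of one person contributes a row with age and state at time $t$ and the fate
at $t+i$.  A missing interview at either end omits the pair; later pairs of
the same person remain.  Two weighted logistic regressions are fitted per
age segment — survival to $t+i$, and being above the threshold at $t+i$
conditional on survival — with a polynomial in age, a below-threshold main
effect and, by default, age-by-state interactions.  Fits use
`stats::glm(family = quasibinomial, weights = w)`, whose point estimates
equal those of a survey-weighted GLM; standard errors are
dispersion-scaled weighted-likelihood errors (replicate-weight designs are
out of scope).  Rescaling all weights leaves the estimates unchanged.

Interview spacing differs by segment (about 12 months for ages 22–33,
about 24 months for 34–50 and 51–95, emulating the wave designs of the
youth and retirement panels this pipeline is modelled on).  Fitted
interval-scale probabilities are converted to annual rates by the
constant-hazard rule applied to the event side,
$p_{12} = 1 - (1 - p_m)^{12/m}$ at the segment's weighted mean observed
interval $m$ — exact for survival under a constant hazard and always
defined.  A matrix alternative (the $12/m$-th root of the 2×2 interval
block through its eigendecomposition) is available via
`annualization = "matrix"`; it can fail for strongly switching chains,
which is why the per-probability rule is the default.  Segment results are
concatenated over ages 22–95, boundary ages 33 and 50 belonging to the
younger segment; seams are recorded and drawn on every age-axis figure.
Discontinuities at the seams are expected — the segments are different
surveys, fitted separately.

`rates_from_coefficients()` and `read_coefficients()` accept a
coefficients-only JSON, so the chain can be parameterised directly from
published regression tables without any microdata.

## The synthetic-data generator

Restricted survey microdata cannot ship with a package, so
`generate_panel()` manufactures panels with the statistical structure the
estimator assumes, from a known `ground_truth()`.  Design choices that
matter:

* **Coefficients live on the per-interval scale.**  Each segment reads the
  truth's inverse-logit as the probability over its own interview interval,
  exactly what the regression estimates before annualisation.  The fitted
  logistic family therefore contains the truth and recovery is unbiased.
  (An earlier annual-scale formulation made the 24-month segments'
  interval relationship non-logistic and biased recovered survival
  downward by up to 0.03 at old ages — the reason for this choice.)
  `true_rateset()` applies the estimator's own annualisation per segment,
  so the implied annual curves may step at the seams, as survey-estimated
  curves do.
* **Fates first, response after.**  Death or survival over the realised
  interval is sampled first (realised spacing is normal around the nominal
  interval, truncated at one month, rounded to whole months; the event
  probability is rescaled by the constant-hazard rule), then the next state
  conditional on survival.  Non-response is applied afterwards,
  independently of fate: a death row is thinned by the same draw as a live
  interview.  Making deaths always observed while survivors respond at
  90% would over-represent deaths among complete pairs and bias survival
  low — a differential-ascertainment artefact worth remembering with real
  panels.  A state-dependent odds multiplier is available to exercise the
  non-response-by-state diagnostic.
* **Cohort layout.**  Younger segments are closed cohorts whose non-final
  waves stay inside the segment's age range (so every age appears as a
  time-$t$ observation without leaking one segment's interview spacing
  into the next); the oldest segment enrols uniformly across its whole
  range, like an open ongoing panel, and follow-up beyond age 95 is
  dropped at estimation.  Ages advance as baseline age plus cumulative
  months rounded to years, matching the discrete one-year grid.
* **Weights** are lognormal (sdlog 0.5, normalised to mean 1, a design
  effect of about 1.28) — survey weights' true distribution is not public,
  so a right-skewed unit-mean family stands in.
* **Initial state** defaults to the stationary distribution of the truth's
  conditional transition block at the person's baseline age.

The built-in `poverty_truth()` parameterisations are synthetic stand-ins
with the qualitative structure of fitted survey regressions: Gompertz-like
logit-linear survival; a below-threshold survival penalty widest in the
70s with a late-old-age crossover (around age 91 for the 1× threshold, 88
for 2×/3×); a high flat probability of staying above a 1× threshold; a
mid-age peak in staying above 2× and, more sharply, 3×; and exit
probabilities that decline with age.  They were fixed once, on demographic
plausibility, and are not fitted to any survey.  What the generator does
*not* emulate: income measurement itself (only the binary state process),
oversampling designs, duration dependence, and period effects — so green
tests certify the estimator and the chain algebra under the model's
assumptions, not the model's adequacy for any real survey.

## Numerical choices

* $N$ is computed by block back-substitution along the age axis (the
  column block of $N$ is a running product of $Q$ blocks), exact in
  $O(\mathrm{ages}^2)$ 2×2 multiplications; a dense `solve()` is exposed as
  a cross-check and agrees to $10^{-10}$.
* 2×2 eigenproblems use the closed form; dominant eigenvectors are
  normalised nonnegative, and an eigenvalue tie is flagged with a warning
  rather than silently resolved.  A rank-1 conditional product reports an
  infinite damping ratio.
* Life-expectancy conventions: the current year is counted by default;
  the exclusive convention (exactly 1 less for every cell) is one flag
  away.  The variance is convention-invariant.
* Terminal age: the final age class dies at the next step (no self-loop),
  so the chain is absorbing by construction.  Ages outside the 22–95 data
  range on the 0–100 grid hold the boundary rates constant; a restricted
  grid (ages 22–100) is used for substantive summaries.
* Cohort projections shown against the $Q_{cum}$ eigenvector start at age
  0 on the padded grid — the projection-from-birth convention — where
  convergence of the below-threshold proportion is complete well before
  age 30 for all built-in parameterisations (damping ratios per year of
  roughly 1.7–2 at young ages).
* Simulation draws two uniform vectors per age across the whole cohort
  (survival first, then switching), one seeded generator end to end, so
  output is bitwise reproducible given the seed and cohort size.
* Residence accounting: starting below counts as an entry at the start
  age; death while below counts as an exit at the age class the person
  failed to reach; the mode of the residence-time distribution uses
  integer-year bins with ties broken toward the smaller value.
* Separation in a logistic fit (e.g. frozen states) is detected from
  non-convergence or a fitted linear predictor beyond ±25 and reported as
  an error, never returned as coefficients.

## Sample sizes and what recovery can promise

Unit tests run on cohorts of a few hundred to a few thousand persons and
simulations of $10^3$–$10^5$ individuals, sized so the whole suite runs in
well under a minute while Monte-Carlo checks keep 3-standard-error
resolution.  The full recovery experiment uses about 100,000 pooled pairs
per segment (roughly 30,000–40,000 persons each).  At that size the
estimator is unbiased and the *average* absolute error of the recovered
annual rates is a few thousandths, but the *maximum* over all 74 ages × 4
functions is set by the thinnest cells — the below-state transition when
only ~12% of the cohort is below a 1× threshold, and edge ages of
quadratic-family fits — whose single standard error is 0.004–0.008 on the
probability scale.  The realised maximum therefore lands around
0.01–0.03; driving it below 0.01 everywhere needs roughly 4–9× more data.
This is a property of the design (weights, non-response, segment layout),
not of the code: balanced-occupancy conditions (a 2× threshold) reach
maxima under 0.01 at the same sample size.

## Known limitations

The chain is memoryless by construction: entry and exit depend only on
current age and state, not on poverty history or duration — a neutral
model of income dynamics.  The state is binary; richer income gradations,
intergenerational linkage, period effects, and reward-based extensions are
out of scope.  Standard errors are weighted-likelihood approximations, not
design-based replicate-weight estimates.
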