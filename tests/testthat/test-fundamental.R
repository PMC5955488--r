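test_that("the absorbing chain closes every column to 1", {
  m <- markov_model(true_rateset(poverty_truth("1x")), ages = 0:100)
  ch <- absorbing_chain(m)
  expect_true(all(abs(colSums(ch$P) - 1) < 1e-12))
  expect_true(all(ch$m >= 0))
  # certain survival: mortality only at the terminal age class
  cm <- markov_model(const_rateset(1:5, 1, 1, 0.1, 0.9), ages = 1:5,
                     pad = FALSE)
  chc <- absorbing_chain(cm)
  expect_true(all(chc$m[1:8] == 0) && all(chc$m[9:10] == 1))
  # the zero matrix dies immediately
  ch0 <- absorbing_chain(matrix(0, 4, 4))
  expect_equal(ch0$m, rep(1, 4))
  expect_error(absorbing_chain(matrix(0.6, 2, 2)), "substochastic")
})

test_that("N = (I - L)^(-1): identity, power series, and solver agreement", {
  expect_equal(fundamental_matrix(matrix(0, 4, 4)), diag(4))
  set.seed(17)
  rs <- rateset(1:5, runif(5, 0.7, 1), runif(5, 0.7, 1), runif(5), runif(5))
  m <- markov_model(rs, ages = 1:5, pad = FALSE)
  N <- fundamental_matrix(m)
  powers <- diag(10); acc <- diag(10)
  for (k in 1:200) { acc <- acc %*% m$L; powers <- powers + acc }
  expect_lt(max(abs(N - powers)), 1e-10)
  expect_lt(max(abs(N - fundamental_matrix(m, "dense"))), 1e-10)
  expect_true(all(N >= 0))
  expect_equal(unname(diag(N)), rep(1, 10))  # ages strictly advance
})

test_that("expectancy and variance match geometric closed forms", {
  # frozen below state with constant survival s: a single-state chain
  s <- 0.9
  m <- markov_model(const_rateset(1:500, s, 1, 0, 1), ages = 1:500,
                    pad = FALSE)
  N <- fundamental_matrix(m)
  start <- 1L  # (age 1, below)
  eta <- remaining_life_expectancy(N)
  expect_equal(unname(eta[start]), 1 / (1 - s), tolerance = 1e-10)
  expect_equal(unname(remaining_life_expectancy(N, FALSE)[start]),
               1 / (1 - s) - 1, tolerance = 1e-10)
  v <- variance_remaining_life(N)
  expect_equal(v$variance[start], s / (1 - s)^2, tolerance = 1e-8)
  # immediate death: expectancy 1 (current year counted), variance 0
  m0 <- markov_model(const_rateset(1:2, 1e-12, 1e-12, 0.5, 0.5),
                     ages = 1:2, pad = FALSE)
  N0 <- fundamental_matrix(m0)
  expect_equal(unname(remaining_life_expectancy(N0)[1]), 1,
               tolerance = 1e-10)
  expect_equal(variance_remaining_life(N0)$variance[1], 0,
               tolerance = 1e-9)
})

test_that("expectancy satisfies the one-step recursion", {
  m <- markov_model(true_rateset(poverty_truth("3x")), ages = 22:100)
  N <- fundamental_matrix(m)
  eta <- remaining_life_expectancy(N)
  # eta_j = 1 + sum_i L_ij eta_i for every starting cell
  expect_equal(unname(eta), unname(1 + as.numeric(eta %*% m$L)),
               tolerance = 1e-10)
})

test_that("years below threshold: frozen states give all or nothing", {
  m <- markov_model(const_rateset(1:50, 0.92, 0.95, 0, 1), ages = 1:50,
                    pad = FALSE)
  N <- fundamental_matrix(m)
  eta <- remaining_life_expectancy(N)
  yb <- expected_years_below(N)
  below_starts <- seq(1, 100, by = 2)
  expect_equal(yb[below_starts], eta[below_starts], tolerance = 1e-12)
  expect_equal(unname(yb[-below_starts]), rep(0, 50))
  # conventions differ by exactly one year for every cell
  expect_equal(remaining_life_expectancy(N) -
                 remaining_life_expectancy(N, FALSE),
               setNames(rep(1, 100), colnames(N)))
})

test_that("years below and variance agree with Monte-Carlo simulation", {
  rs <- const_rateset(1:40, 0.9, 0.93, 0.25, 0.9)
  m <- markov_model(rs, ages = 1:40, pad = FALSE)
  N <- fundamental_matrix(m)
  traj <- simulate_cohort(rs, 60000, start_age = 1, init_below = 1,
                          seed = 23, max_age = 40)
  res <- residence_summary(traj)
  life <- traj$death_age - 1
  i1 <- 1L  # (age 1, below)
  expect_lt(abs(mean(life) - remaining_life_expectancy(N)[i1]),
            3 * sd(life) / sqrt(traj$n))
  expect_lt(abs(res$mean - expected_years_below(N)[i1]),
            3 * res$sd / sqrt(traj$n))
  v <- variance_remaining_life(N)$variance[i1]
  # sampling SE of a variance: sqrt((m4 - v^2)/n)
  se_v <- sqrt((mean((life - mean(life))^4) - var(life)^2) / traj$n)
  expect_lt(abs(var(life) - v), 3 * se_v)
})

test_that("lower survival lowers expectancy everywhere", {
  hi <- true_rateset(poverty_truth("1x"))
  lo <- rateset(hi$age, hi$s1 * 0.97, hi$s2 * 0.97, hi$t21, hi$t22)
  e_hi <- remaining_life_expectancy(
    fundamental_matrix(markov_model(hi, 22:100)))
  e_lo <- remaining_life_expectancy(
    fundamental_matrix(markov_model(lo, 22:100)))
  last <- length(e_hi) - c(1, 0)  # terminal-age cells equal 1 in both
  expect_true(all(e_lo[-last] < e_hi[-last]))
  expect_equal(unname(e_lo[last]), c(1, 1))
})

test_that("chain expectancy equals the cohort mean age at death", {
  m <- markov_model(true_rateset(poverty_truth("2x")), ages = 22:100)
  n0 <- initial_cohort(m, init_below = 0.3, age = 22)
  masses <- vapply(0:78, function(k) sum(project_cohort(m, n0, k)),
                   numeric(1))
  # deaths between steps k and k+1 happen at age 22 + k + 1
  deaths <- c(-diff(masses), masses[79])
  mean_age_at_death <- sum((22 + seq_along(deaths)) * deaths) / sum(deaths)
  N <- fundamental_matrix(m)
  eta0 <- 0.3 * remaining_life_expectancy(N)[1] +
    0.7 * remaining_life_expectancy(N)[2]
  expect_equal(mean_age_at_death, 22 + unname(eta0), tolerance = 1e-9)
  # and the mass deficit at each step equals cumulative chain deaths
  ch <- absorbing_chain(m)
  dead <- 0; v <- n0
  for (k in 1:20) {
    dead <- dead + sum(ch$m * v)
    v <- m$L %*% v
    expect_equal(sum(n0) - sum(v), dead, tolerance = 1e-12)
  }
})
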