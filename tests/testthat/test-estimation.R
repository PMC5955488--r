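test_that("pooling keeps only consecutive responded wave pairs", {
  # responded, missing, responded: no usable pair
  expect_error(pool_observations(manual_panel(c(TRUE, FALSE, TRUE))),
               "no usable")
  # six responded waves give five pooled rows
  po <- pool_observations(manual_panel(rep(TRUE, 6)))
  expect_equal(nrow(po), 5L)
  # a missing middle wave removes exactly the two pairs touching it
  po <- pool_observations(manual_panel(c(TRUE, TRUE, FALSE, TRUE, TRUE)))
  expect_equal(nrow(po), 2L)
})

test_that("pair completeness matches the binomial oracle under non-response", {
  tr <- ground_truth(survival = c(30, 0), transition = c(0, 0))
  pan <- generate_panel(tr, small_design(1000, nonresponse = 0.1), seed = 21)
  po <- pool_observations(pan)
  expected <- 4000 * 0.9^2
  se <- sqrt(4000 * 0.81 * 0.19)
  expect_lt(abs(nrow(po) - expected), 3 * se)
})

test_that("survival fit finds a null state effect when there is none", {
  tr <- const_truth(s1 = 0.95, s2 = 0.95)
  pan <- generate_panel(tr, small_design(12000), seed = 31)
  fit <- fit_survival(pool_observations(pan), degree = 1,
                      interaction = FALSE)
  z <- fit$coefficients["below"] / fit$se["below"]
  expect_lt(abs(z), 3)
})

test_that("survival and transition fits recover known coefficients", {
  tr <- linear_truth()
  seg <- one_segment(age_min = 22L, age_max = 50L, waves = 5L)
  pan <- generate_panel(tr, small_design(13000, seg), seed = 41)
  po <- pool_observations(pan)
  expect_gt(nrow(po), 45000)
  fs <- fit_survival(po, degree = 1, interaction = TRUE)
  ft <- fit_transition(po, degree = 1, interaction = TRUE)
  for (term in c("intercept", "age", "below", "age_below")) {
    expect_lt(abs(fs$coefficients[term] - tr$survival[term]),
              3 * fs$se[term])
    expect_lt(abs(ft$coefficients[term] - tr$transition[term]),
              3 * ft$se[term])
  }
})

test_that("degenerate inputs raise informative failures", {
  tr <- ground_truth(survival = c(30, 0), transition = c(0, 0))
  pan <- generate_panel(tr, small_design(200), seed = 6)
  po <- pool_observations(pan)
  expect_error(fit_survival(po), "no variation")
  po$weight[which(po$survived == 1L)[1]] <- 0
  expect_error(fit_transition(po), "weights")
  # frozen states: outcome perfectly separated by current state
  tr2 <- ground_truth(survival = c(30, 0), transition = c(30, 0, 0, -60))
  pan2 <- generate_panel(tr2, small_design(500, init_below = 0.5), seed = 6)
  expect_error(fit_transition(pool_observations(pan2)), "separation")
})

test_that("interval probabilities invert the logit exactly", {
  zero <- structure(
    list(outcome = "survival", coefficients = povdyn:::pad6(numeric(0)),
         se = povdyn:::pad6(numeric(0)), degree = 1, interaction = TRUE,
         age_range = c(22, 95), mean_interval_months = 12, n = 0L),
    class = "interval_fit")
  expect_equal(predict_interval_probability(zero, 40, 1), 0.5)
  fixed <- zero
  fixed$coefficients["intercept"] <- qlogis(0.9)
  expect_equal(predict_interval_probability(fixed, c(22, 60, 95), 2),
               rep(0.9, 3))
  tr <- poverty_truth("2x")
  truthy <- zero
  truthy$coefficients <- tr$transition
  expect_equal(predict_interval_probability(truthy, 37, 1),
               truth_probability(tr, 37, 1, "transition"), tolerance = 1e-12)
  expect_error(predict_interval_probability(zero, 96, 1), "outside")
})

test_that("annualization follows the constant-hazard closed form", {
  expect_equal(annualize(0, 17), 0)
  expect_equal(annualize(0.3, 12), 0.3)
  expect_equal(annualize(0.96, 24, "survival"), sqrt(0.96))
  # compounding check: two 12-month survivals of 0.96^(1/2) give 0.96
  expect_equal(annualize(0.96, 24, "survival")^2, 0.96)
  expect_error(annualize(0.5, 0), "positive")
  # monotone in the event probability, and 24-month events de-compound
  p <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(diff(annualize(p, 24)) > 0))
  expect_true(all(annualize(p, 24) <= p))
})

test_that("matrix-root annualization agrees with compounding", {
  # the 24-month interval block is the square of a known annual block
  A <- build_Q(const_rateset(22:23, 0.95, 0.99, 0.3, 0.96), 22)
  A2 <- A %*% A
  s1i <- sum(A2[, 1]); s2i <- sum(A2[, 2])
  back <- annualize_matrix(s1i, s2i, A2[2, 1] / s1i, A2[2, 2] / s2i, 24)
  expect_equal(back$s1, 0.95, tolerance = 1e-10)
  expect_equal(back$s2, 0.99, tolerance = 1e-10)
  expect_equal(back$t21, 0.3, tolerance = 1e-10)
  expect_equal(back$t22, 0.96, tolerance = 1e-10)
})

test_that("segment concatenation is constant without seams, steps at them", {
  mk <- function(intercept) {
    one <- function(outcome) structure(
      list(outcome = outcome,
           coefficients = povdyn:::pad6(c(intercept, 0, 0, -0.5)),
           se = povdyn:::pad6(numeric(0)), degree = 1, interaction = TRUE,
           age_range = NULL, mean_interval_months = 12, n = 0L),
      class = "interval_fit")
    one
  }
  seg <- function(lo, hi, intercept) {
    f <- mk(intercept)
    s <- list(age_min = lo, age_max = hi,
              survival = f("survival"), transition = f("transition"))
    s$survival$age_range <- s$transition$age_range <- c(lo, hi)
    s
  }
  same <- rates_from_coefficients(
    list(seg(22, 33, 2), seg(34, 50, 2), seg(51, 95, 2)))
  expect_true(all(diff(same$rates$s1) == 0))
  expect_true(all(diff(same$rates$t22) == 0))
  diff_int <- rates_from_coefficients(
    list(seg(22, 33, 2), seg(34, 50, 2.5), seg(51, 95, 3)))
  jumps <- which(diff(diff_int$rates$s1) != 0)
  expect_equal(diff_int$rates$age[jumps], c(33L, 50L))
  # coverage gap is an error naming the missing ages
  expect_error(rates_from_coefficients(list(seg(22, 33, 2), seg(51, 95, 2))),
               "do not cover ages")
})

test_that("rescaling all weights leaves fitted coefficients unchanged", {
  pan <- generate_panel(linear_truth(), small_design(2000), seed = 51)
  po <- pool_observations(pan)
  f1 <- fit_survival(po)
  po$weight <- po$weight * 2
  f2 <- fit_survival(po)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
})

test_that("end-to-end estimation recovers the implied annual rates", {
  # moderate n: the estimator is unbiased, so errors shrink toward zero
  # with n and stay inside a loose envelope here; mean error is near zero
  tr <- poverty_truth("1x")
  des <- panel_design(cohort_size = 6000)
  pan <- generate_panel(tr, des, seed = 61)
  fit <- fit_rates(pan, degree = 1)
  truth <- true_rateset(tr, 22:95)
  err <- as.matrix(fit$rates[c("s1", "s2", "t21", "t22")]) -
    as.matrix(truth[c("s1", "s2", "t21", "t22")])
  expect_lt(max(abs(err)), 0.05)
  expect_lt(mean(abs(err)), 0.01)
  expect_lt(abs(mean(err)), 0.005)
})

test_that("coefficient JSON round-trips and reproduces the rates", {
  pan <- generate_panel(poverty_truth("2x"),
                        panel_design(cohort_size = 3000), seed = 71)
  fit <- fit_rates(pan, degree = 1)
  f <- tempfile(fileext = ".json")
  write_coefficients(fit, f)
  fit2 <- rates_from_coefficients(read_coefficients(f))
  expect_equal(as.data.frame(fit2$rates), as.data.frame(fit$rates),
               tolerance = 1e-9)
})

test_that("non-response diagnostic behaves under known designs", {
  tr <- const_truth()
  # zero non-response: all observed proportions are zero
  pan0 <- generate_panel(tr, small_design(400, nonresponse = 0), seed = 81)
  d0 <- nonresponse_by_state_age(pan0)
  expect_true(all(d0$p_below[d0$n_below > 0] == 0))
  expect_true(all(d0$p_above[d0$n_above > 0] == 0))
  # state-independent non-response: between-state difference is null
  pan1 <- generate_panel(tr, small_design(8000, nonresponse = 0.1), seed = 82)
  d1 <- nonresponse_by_state_age(pan1)
  ok <- d1$n_below >= 200 & d1$n_above >= 200
  se <- sqrt(0.1 * 0.9 * (1 / d1$n_below + 1 / d1$n_above))
  expect_true(all(abs(d1$diff[ok]) < 3 * se[ok]))
  # doubled odds of non-response below: positive difference throughout
  pan2 <- generate_panel(tr, small_design(8000, nonresponse = 0.1,
                                          nonresponse_odds_below = 2),
                         seed = 83)
  d2 <- nonresponse_by_state_age(pan2)
  ok2 <- d2$n_below >= 200 & d2$n_above >= 200
  expect_true(all(d2$diff[ok2] > 0))
})
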