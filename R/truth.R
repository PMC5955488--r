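#' Logit-scale ground truth for the two-state poverty process
#'
#' A `ground_truth` object holds the coefficient vectors that define, on the
#' logit scale, the annual state-specific survival probability and the annual
#' probability of being above the income threshold at the next age,
#' conditional on survival.  Both linear predictors share one parameterisation
#' in age `x` and the below-threshold indicator `b`:
#'
#'   logit p = c0 + c1 x + c2 x^2 + b (c3 + c4 x + c5 x^2)
#'
#' State 1 is below the threshold (`b = 1`), state 2 above (`b = 0`).
#' Coefficients live on the per-interval (wave-spacing) scale, exactly like
#' the regression coefficients the estimation stage produces before
#' annualisation: a survey segment interviewed every `m` months interprets
#' `plogis(lp)` as the probability over an `m`-month interval.  This keeps
#' the generator and the estimator on one scale — the fitted logistic
#' family contains the truth — and the implied annual rates are obtained by
#' the same constant-hazard annualisation the estimator applies (see
#' [true_rateset()]).  For a segment interviewed every 12 months the
#' interval scale and the annual scale coincide.
#'
#' @param survival numeric coefficient vector, length up to 6, in the order
#'   (intercept, age, age^2, below, age:below, age^2:below); shorter vectors
#'   are zero-padded.  Linear predictor of interval survival.
#' @param transition same layout; linear predictor of the interval
#'   probability of being above the threshold at the next interview,
#'   conditional on survival.  For a person below the threshold this is the
#'   exit probability; for a person above it is the stay probability.
#' @param label short name for the threshold (e.g. "1x").
#' @param ages age range over which the truth must yield valid probabilities.
#' @return an object of class `ground_truth`.
#' @seealso [poverty_truth()] for the built-in default parameterisations,
#'   [true_rateset()] for the implied annual rates.
#' @export
ground_truth <- function(survival, transition, label = "truth",
                         ages = 22:95) {
  survival <- pad6(survival)
  transition <- pad6(transition)
  obj <- structure(
    list(survival = survival, transition = transition,
         label = label, ages = ages),
    class = "ground_truth")
  validate_ground_truth(obj)
  obj
}

pad6 <- function(x) {
  if (length(x) > 6L)
    stop("coefficient vectors have at most 6 elements", call. = FALSE)
  out <- c(as.numeric(x), rep(0, 6L - length(x)))
  names(out) <- c("intercept", "age", "age2", "below", "age_below",
                  "age2_below")
  out
}

truth_logit <- function(coefs, age, below) {
  unname(coefs[1L] + coefs[2L] * age + coefs[3L] * age^2 +
           below * (coefs[4L] + coefs[5L] * age + coefs[6L] * age^2))
}

#' Interval-scale probability implied by a ground truth
#'
#' Inverse logit of the truth's linear predictor: the probability over one
#' interview interval of the segment the person belongs to.
#'
#' @param truth a `ground_truth`.
#' @param age vector of ages in years.
#' @param state 1 (below threshold) or 2 (above), recycled against `age`.
#' @param outcome "survival" or "transition" (probability of being above the
#'   threshold at the next interview, conditional on survival).
#' @return vector of probabilities in (0, 1).
#' @export
truth_probability <- function(truth, age, state,
                              outcome = c("survival", "transition")) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(truth, "ground_truth"), all(state %in% c(1, 2)))
  below <- as.numeric(state == 1)
  stats::plogis(truth_logit(truth[[outcome]], age, below))
}

validate_ground_truth <- function(truth) {
  ages <- truth$ages
  for (st in c(1, 2)) {
    for (oc in c("survival", "transition")) {
      p <- truth_probability(truth, ages, st, oc)
      bad <- which(!(p > 0 & p < 1))
      if (length(bad))
        stop(sprintf(
          "ground truth: %s probability degenerate at age %d, state %d",
          oc, ages[bad[1L]], st), call. = FALSE)
    }
    s <- truth_probability(truth, ages[ages <= 80], st, "survival")
    if (any(s <= 0.5))
      stop(sprintf(
        "ground truth: survival at or below 0.5 before age 80 in state %d",
        st), call. = FALSE)
  }
  invisible(truth)
}

#' Built-in synthetic ground truths for the three poverty thresholds
#'
#' Default parameterisations emulating a US-like cohort classified at 1x, 2x
#' or 3x the official poverty line: Gompertz-like logit-linear decline of
#' annual survival with age, a below-threshold survival penalty that widens
#' through mid-age and reverses in late old age (a survival crossover around
#' ages 88-91); a high, flat probability of staying above a 1x threshold; a
#' mid-age peak in the probability of staying above 2x and (more sharply) 3x
#' thresholds; and exit probabilities from the low-income state that decline
#' with age.  These are synthetic stand-ins with the qualitative structure of
#' fitted survey regressions, not fitted values from any survey.
#'
#' @param threshold "1x", "2x" or "3x".
#' @return a `ground_truth`.
#' @export
poverty_truth <- function(threshold = c("1x", "2x", "3x")) {
  threshold <- match.arg(threshold)
  surv_base <- c(8.65, -0.0885, 0)
  switch(threshold,
    "1x" = ground_truth(
      survival   = c(surv_base, -2.184, 0.024, 0),
      transition = c(2.7, 0.006, 0, -2.565, -0.0267, 0),
      label = "1x"),
    "2x" = ground_truth(
      survival   = c(surv_base, -2.024, 0.023, 0),
      transition = c(0.7075, 0.0753, -0.000753, -1.1205, -0.0950, 0.000753),
      label = "2x"),
    "3x" = ground_truth(
      survival   = c(surv_base, -2.024, 0.023, 0),
      transition = c(-0.795, 0.1248, -0.0013, 0.203, -0.1479, 0.0013),
      label = "3x"))
}

#' Annual rate set implied by a ground truth
#'
#' Evaluates the four annual probability functions s1(x), s2(x), t21(x),
#' t22(x): each age's interval-scale probabilities are converted to the
#' 12-month scale by the same constant-hazard annualisation the estimation
#' stage applies, at the interview interval of the segment owning that age.
#' This is the recovery target for the estimation pipeline.  For a
#' 12-month segment the conversion is the identity, so the annual
#' probability is simply the inverse logit of the linear predictor.  Like
#' the survey curves it emulates, the implied annual rate functions may
#' step at segment seams.
#'
#' @inheritParams truth_probability
#' @param ages integer ages to evaluate.
#' @param segments segment table mapping ages to interview intervals
#'   (see [default_segments()]); ages outside every segment use the nearest
#'   segment's interval.
#' @return a [rateset].
#' @export
true_rateset <- function(truth, ages = truth$ages,
                         segments = default_segments()) {
  if (!all(ages >= min(truth$ages) & ages <= max(truth$ages)))
    stop("requested ages outside the domain of the ground truth")
  mi <- vapply(ages, function(a) {
    k <- which(a >= segments$age_min & a <= segments$age_max)
    if (!length(k))
      k <- which.min(pmax(segments$age_min - a, a - segments$age_max))
    segments$interval_months[k[1L]]
  }, numeric(1))
  s1 <- annualize(truth_probability(truth, ages, 1, "survival"), mi,
                  "survival")
  s2 <- annualize(truth_probability(truth, ages, 2, "survival"), mi,
                  "survival")
  t21 <- annualize(truth_probability(truth, ages, 1, "transition"), mi,
                   "event")
  t12 <- annualize(1 - truth_probability(truth, ages, 2, "transition"), mi,
                   "event")
  rateset(age = ages, s1 = s1, s2 = s2, t21 = t21, t22 = 1 - t12,
          seams = segments$age_max[-nrow(segments)])
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth '%s' (interval-scale logit coefficients)\n",
              x$label))
  m <- rbind(survival = x$survival, transition = x$transition)
  print(round(m, 5))
  ages <- range(x$ages)
  cat(sprintf("valid ages: %d-%d\n", ages[1], ages[2]))
  invisible(x)
}
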