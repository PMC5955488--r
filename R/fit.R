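#' Convert a probability between interview-interval and annual scales
#'
#' Constant-hazard conversion acting on one probability at a time.  For an
#' event probability p over an interval of i months, the annual probability
#' is \eqn{1 - (1 - p)^{12/i}}; equivalently an interval survival s maps to
#' the annual survival \eqn{s^{12/i}}.  The conversion is the identity at
#' i = 12 and exact for survival under a constant hazard.
#'
#' @param p probability in [0, 1] (event probability, or survival when
#'   `type = "survival"`).
#' @param months interval length in months, > 0.
#' @param type whether `p` is the probability of the event occurring within
#'   the interval ("event") or of surviving it ("survival").
#' @return the corresponding annual (12-month) probability.
#' @export
annualize <- function(p, months, type = c("event", "survival")) {
  type <- match.arg(type)
  if (any(months <= 0)) stop("interval length must be positive")
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  if (type == "event") 1 - (1 - p)^(12 / months) else p^(12 / months)
}

#' Matrix-root annualization of an interval transition block
#'
#' Alternative to the per-probability constant-hazard rule: forms the 2x2
#' unconditional interval transition block from the four interval-scale
#' probabilities and takes its 12/i-th power through the eigendecomposition.
#' Fails informatively when the root is not a valid substochastic block
#' (complex or negative eigenvalues, negative entries), which can happen for
#' strongly switching chains; the per-probability rule is always defined.
#'
#' @param s1,s2,t21,t22 interval-scale probabilities (survival below/above;
#'   exit and stay conditional on survival).
#' @param months interval length in months.
#' @return named list of the four annual probabilities.
#' @export
annualize_matrix <- function(s1, s2, t21, t22, months) {
  if (months <= 0) stop("interval length must be positive")
  Qi <- matrix(c(s1 * (1 - t21), s1 * t21, s2 * (1 - t22), s2 * t22), 2)
  ev <- eigen(Qi)
  if (is.complex(ev$values) || any(Re(ev$values) < 0))
    stop("matrix annualization undefined: interval block has no real ",
         "nonnegative matrix root")
  A <- ev$vectors %*% diag(ev$values^(12 / months)) %*% solve(ev$vectors)
  A <- Re(A)
  if (any(A < -1e-12))
    stop("matrix annualization produced negative transition probabilities")
  A <- pmax(A, 0)
  s1a <- sum(A[, 1]); s2a <- sum(A[, 2])
  list(s1 = s1a, s2 = s2a,
       t21 = if (s1a > 0) A[2, 1] / s1a else 0,
       t22 = if (s2a > 0) A[2, 2] / s2a else 1)
}

canonical_terms <- function(degree, interaction) {
  stopifnot(degree %in% 1:2)
  terms <- c("intercept", "age", if (degree == 2) "age2", "below")
  if (interaction) terms <- c(terms, "age_below",
                              if (degree == 2) "age2_below")
  terms
}

fit_model_matrix <- function(age, below, degree, interaction) {
  cols <- cbind(intercept = 1, age = age,
                age2 = if (degree == 2) age^2,
                below = below,
                age_below = if (interaction) age * below,
                age2_below = if (interaction && degree == 2) age^2 * below)
  cols[, canonical_terms(degree, interaction), drop = FALSE]
}

fit_interval_glm <- function(y, age, below, weight, interval_months,
                             degree, interaction, outcome, age_range) {
  if (any(weight <= 0) || !all(is.finite(weight)))
    stop("degenerate weights: all weights must be positive and finite")
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L)
    stop(sprintf(
      "cannot fit %s model: outcome has no variation (perfect separation)",
      outcome))
  X <- fit_model_matrix(age, below, degree, interaction)
  dat <- data.frame(y = y, X[, -1L, drop = FALSE], check.names = FALSE)
  dat$.w <- weight
  fml <- stats::as.formula(
    paste("y ~", paste(sprintf("`%s`", colnames(X)[-1L]), collapse = " + ")))
  fit <- suppressWarnings(
    stats::glm(fml, family = stats::quasibinomial(), data = dat,
               weights = .w))
  cf <- stats::coef(fit)
  lp <- stats::predict(fit, type = "link")
  if (!fit$converged || any(!is.finite(cf)) || max(abs(lp)) > 25)
    stop(sprintf("%s model did not converge (probable separation)", outcome))
  full <- pad6(numeric(0))
  full[colnames(X)] <- cf
  sm <- summary(fit)
  se <- pad6(numeric(0)); se[] <- NA_real_
  se[colnames(X)] <- sm$coefficients[, "Std. Error"]
  structure(
    list(outcome = outcome,
         coefficients = full,
         se = se,
         vcov = stats::vcov(fit),
         terms = colnames(X),
         degree = degree, interaction = interaction,
         age_range = age_range,
         mean_interval_months =
           stats::weighted.mean(interval_months, weight),
         n = length(y)),
    class = "interval_fit")
}

#' Weighted pooled logistic regression for interval survival
#'
#' Fits survival to the next interview against age and current income state
#' by weighted maximum-likelihood logistic regression on the pooled
#' wave-pair observations.  The linear predictor is a polynomial in age
#' (degree 1 by default) with a below-threshold main effect and, by default,
#' age-by-state interaction terms of the same degree.
#'
#' @param pooled a `pooled_obs` table from [pool_observations()].
#' @param degree polynomial degree in age (1 or 2).
#' @param interaction include age-by-state interaction terms?
#' @param age_range ages the fit is allowed to predict for, default the
#'   observed range.
#' @return an object of class `interval_fit` holding the coefficients (in
#'   the canonical slot order intercept, age, age^2, below, age:below,
#'   age^2:below), their standard errors, the covariance matrix, and the
#'   weighted mean interview interval in months.
#' @export
fit_survival <- function(pooled, degree = 1, interaction = TRUE,
                         age_range = range(pooled$age)) {
  keep <- pooled$age >= age_range[1] & pooled$age <= age_range[2]
  p <- pooled[keep, ]
  fit_interval_glm(p$survived, p$age, as.numeric(p$state == 1L), p$weight,
                   p$interval_months, degree, interaction, "survival",
                   age_range)
}

#' Weighted pooled logistic regression for the next income state
#'
#' Among pooled wave pairs where the person survived and the next state was
#' observed, fits the probability of being above the threshold at the next
#' interview against age and current state.
#'
#' @inheritParams fit_survival
#' @export
fit_transition <- function(pooled, degree = 1, interaction = TRUE,
                           age_range = range(pooled$age)) {
  keep <- pooled$survived == 1L & !is.na(pooled$state_next) &
    pooled$age >= age_range[1] & pooled$age <= age_range[2]
  p <- pooled[keep, ]
  fit_interval_glm(as.integer(p$state_next == 2L), p$age,
                   as.numeric(p$state == 1L), p$weight, p$interval_months,
                   degree, interaction, "transition", age_range)
}

#' Probability on the interview-interval scale from a fitted model
#'
#' Inverse logit of the fitted linear predictor at a given age and state.
#' Ages outside the fit's declared range raise an error rather than
#' extrapolating silently.
#'
#' @param fit an `interval_fit` from [fit_survival()] or [fit_transition()],
#'   or a coefficients-only fit from [read_coefficients()].
#' @param age age in years.
#' @param state 1 (below threshold) or 2 (above).
#' @return probability in (0, 1) on the fit's interval scale.
#' @export
predict_interval_probability <- function(fit, age, state) {
  stopifnot(inherits(fit, "interval_fit"), all(state %in% c(1, 2)))
  if (any(age < fit$age_range[1] | age > fit$age_range[2]))
    stop(sprintf("age outside fitted segment range %d-%d",
                 fit$age_range[1], fit$age_range[2]))
  stats::plogis(truth_logit(fit$coefficients, age, as.numeric(state == 1)))
}

#' @export
print.interval_fit <- function(x, ...) {
  cat(sprintf(
    "Pooled logistic fit: %s, ages %s-%s, n = %d, mean interval %.1f months\n",
    x$outcome, x$age_range[1], x$age_range[2], x$n,
    x$mean_interval_months))
  tab <- cbind(estimate = x$coefficients[x$terms], se = x$se[x$terms])
  print(round(tab, 5))
  invisible(x)
}

segment_rates <- function(seg_fits, ages = NULL,
                          annualization = c("probability", "matrix")) {
  annualization <- match.arg(annualization)
  owned <- lapply(seg_fits, function(f) f$age_min:f$age_max)
  covered <- sort(unique(unlist(owned)))
  if (is.null(ages)) ages <- seq(min(covered), max(covered))
  missing <- setdiff(ages, covered)
  if (length(missing))
    stop("segments do not cover ages: ", paste(missing, collapse = ", "))
  cols <- matrix(NA_real_, length(ages), 4,
                 dimnames = list(NULL, c("s1", "s2", "t21", "t22")))
  for (f in seg_fits) {
    sel <- which(ages %in% (f$age_min:f$age_max))
    if (!length(sel)) next
    a <- ages[sel]
    m <- f$survival$mean_interval_months
    mt <- f$transition$mean_interval_months
    ps1 <- predict_interval_probability(f$survival, a, 1)
    ps2 <- predict_interval_probability(f$survival, a, 2)
    pt21 <- predict_interval_probability(f$transition, a, 1)
    pt22 <- predict_interval_probability(f$transition, a, 2)
    if (annualization == "probability") {
      cols[sel, "s1"] <- annualize(ps1, m, "survival")
      cols[sel, "s2"] <- annualize(ps2, m, "survival")
      cols[sel, "t21"] <- annualize(pt21, mt, "event")
      cols[sel, "t22"] <- 1 - annualize(1 - pt22, mt, "event")
    } else {
      for (jj in seq_along(sel)) {
        ann <- annualize_matrix(ps1[jj], ps2[jj], pt21[jj], pt22[jj], m)
        cols[sel[jj], ] <- unlist(ann)[c("s1", "s2", "t21", "t22")]
      }
    }
  }
  seams <- sort(unname(vapply(seg_fits, function(f) f$age_max, numeric(1))))
  seams <- seams[-length(seg_fits)]
  rateset(ages, cols[, "s1"], cols[, "s2"], cols[, "t21"], cols[, "t22"],
          seams = seams)
}

#' Estimate annual rates from a longitudinal panel
#'
#' The main fitting function of the package.  Pools consecutive interview
#' pairs ([pool_observations()]), fits weighted logistic regressions for
#' survival and for the next income state separately within each age
#' segment, converts the fitted interval probabilities to annual rates by
#' the constant-hazard rule applied at each segment's weighted mean
#' interview interval, and concatenates the segments over the full age
#' range.  Boundary ages belong to the younger segment; the seam ages are
#' recorded for plotting.
#'
#' @param panel a `panel_table`, or an already-pooled `pooled_obs` table.
#' @param segments data frame of segment definitions
#'   (see [default_segments()]); each segment is fitted on the pooled rows
#'   whose age at time t falls in its range.
#' @param degree polynomial degree in age (1 or 2) for the survival model,
#'   recycled across segments, so narrow age windows can use the linear
#'   form while wide ones allow curvature.
#' @param degree_transition degree for the next-state model (defaults to
#'   `degree`); the two outcomes need not share a functional form.
#' @param interaction include age-by-state interaction terms?
#' @param annualization "probability" (constant-hazard conversion of each
#'   probability, the default) or "matrix" (12/i-th matrix root of the 2x2
#'   interval block, see [annualize_matrix()]).
#' @return an object of class `rate_fit` with components `rates` (a
#'   [rateset]), `fits` (per-segment survival and transition
#'   `interval_fit`s) and `segments`.  Methods: `print`, `summary`, `coef`,
#'   `predict`, `plot`.
#' @export
fit_rates <- function(panel, segments = default_segments(), degree = 1,
                      interaction = TRUE,
                      annualization = c("probability", "matrix"),
                      degree_transition = degree) {
  pooled <- if (inherits(panel, "pooled_obs")) panel
            else pool_observations(panel)
  degree <- rep_len(degree, nrow(segments))
  degree_transition <- rep_len(degree_transition, nrow(segments))
  seg_fits <- lapply(seq_len(nrow(segments)), function(k) {
    rng <- c(segments$age_min[k], segments$age_max[k])
    list(age_min = segments$age_min[k], age_max = segments$age_max[k],
         survival = fit_survival(pooled, degree[k], interaction, rng),
         transition = fit_transition(pooled, degree_transition[k],
                                     interaction, rng))
  })
  structure(
    list(rates = segment_rates(seg_fits, annualization = annualization),
         fits = seg_fits,
         segments = segments,
         n_pooled = nrow(pooled)),
    class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("Annual poverty-dynamics rates fitted from %d pooled pairs\n",
              x$n_pooled))
  for (f in x$fits)
    cat(sprintf(
      "  segment %d-%d: n_surv = %d, n_trans = %d, mean interval %.1f mo\n",
      f$age_min, f$age_max, f$survival$n, f$transition$n,
      f$survival$mean_interval_months))
  print(x$rates)
  invisible(x)
}

#' @export
summary.rate_fit <- function(object, ...) {
  for (f in object$fits) {
    cat(sprintf("== Segment ages %d-%d ==\n", f$age_min, f$age_max))
    print(f$survival); print(f$transition)
  }
  invisible(object)
}

#' @export
coef.rate_fit <- function(object, ...) {
  rows <- lapply(object$fits, function(f)
    rbind(survival = f$survival$coefficients,
          transition = f$transition$coefficients))
  out <- do.call(rbind, rows)
  rownames(out) <- paste0(
    rep(vapply(object$fits,
               function(f) sprintf("%d-%d", f$age_min, f$age_max),
               character(1)), each = 2), ":",
    rownames(out))
  out
}

#' Predict annual (or interval-scale) probabilities from a rate fit
#'
#' @param object a `rate_fit`.
#' @param age ages in years (each must fall in a fitted segment).
#' @param state 1 (below threshold) or 2 (above).
#' @param outcome "survival" or "transition" (probability of being above the
#'   threshold next year, conditional on survival).
#' @param scale "annual" for 12-month probabilities (default), "interval"
#'   for the raw fitted interview-interval scale.
#' @param ... unused.
#' @export
predict.rate_fit <- function(object, age, state,
                             outcome = c("survival", "transition"),
                             scale = c("annual", "interval"), ...) {
  outcome <- match.arg(outcome)
  scale <- match.arg(scale)
  n <- max(length(age), length(state))
  age <- rep_len(age, n); state <- rep_len(state, n)
  out <- numeric(n)
  for (j in seq_len(n)) {
    f <- NULL
    for (sf in object$fits)
      if (age[j] >= sf$age_min && age[j] <= sf$age_max) { f <- sf; break }
    if (is.null(f))
      stop(sprintf("age %s not covered by any fitted segment", age[j]))
    fit <- f[[outcome]]
    p <- predict_interval_probability(fit, age[j], state[j])
    if (scale == "interval") { out[j] <- p; next }
    m <- fit$mean_interval_months
    out[j] <- if (outcome == "survival") annualize(p, m, "survival")
      else if (state[j] == 1) annualize(p, m, "event")
      else 1 - annualize(1 - p, m, "event")
  }
  out
}

#' @export
plot.rate_fit <- function(x, ...) plot(x$rates, ...)
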