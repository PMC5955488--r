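#' Augment L into a column-stochastic absorbing chain
#'
#' Appends a mortality row m = 1 - (column sums of L) and an absorbing Death
#' state with self-probability 1, giving the full chain matrix
#' P = [[L, 0], [m, 1]] whose every column sums to 1.
#'
#' @param model a `poverty_markov` or a bare substochastic matrix L.
#' @param tol tolerance on column sums exceeding 1.
#' @return a list of class `absorbing_chain` with components `P`, `m` and
#'   `L`.
#' @export
absorbing_chain <- function(model, tol = 1e-12) {
  L <- if (inherits(model, "poverty_markov")) model$L else model
  cs <- colSums(L)
  if (any(cs > 1 + tol))
    stop("matrix is not substochastic: column sums exceed 1")
  m <- pmax(0, 1 - cs)
  P <- rbind(cbind(L, 0), c(m, 1))
  rn <- c(if (is.null(rownames(L))) paste0("t", seq_len(nrow(L)))
          else rownames(L), "death")
  dimnames(P) <- list(rn, rn)
  structure(list(P = P, m = m, L = L), class = "absorbing_chain")
}

#' Fundamental matrix of the age-by-state chain
#'
#' Computes \eqn{N = (I - L)^{-1}}, whose entry (i, j) is the expected
#' number of one-year visits to cell i for a person starting in cell j,
#' counting the starting visit.  Because ages strictly advance, L is
#' nilpotent and I - L block lower-triangular, so the default method solves
#' by block back-substitution along the age axis: the block of N in age-row
#' b, start-column a is the cumulative product
#' \eqn{Q(x_{b-1}) \cdots Q(x_a)} (identity when b = a).  The "dense"
#' method is a direct `solve()` and agrees to within 1e-10; both are exposed
#' so they can be cross-checked.
#'
#' @param model a `poverty_markov`, or a bare matrix L (dense method only).
#' @param method "block" (age back-substitution) or "dense" (direct solve).
#' @return the matrix N, same dimension and dimnames as L.
#' @export
fundamental_matrix <- function(model, method = c("block", "dense")) {
  method <- match.arg(method)
  if (!inherits(model, "poverty_markov")) {
    L <- model
    return(solve(diag(nrow(L)) - L))
  }
  if (method == "dense")
    return(solve(diag(nrow(model$L)) - model$L))
  ages <- model$ages
  n <- length(ages)
  Q <- lapply(ages[-n], function(x) build_Q(model$rates, x))
  N <- matrix(0, 2L * n, 2L * n, dimnames = dimnames(model$L))
  for (a in seq_len(n)) {
    cols <- 2L * (a - 1L) + c(1L, 2L)
    cum <- diag(2)
    N[cols, cols] <- cum
    if (a < n) for (b in (a + 1L):n) {
      cum <- Q[[b - 1L]] %*% cum
      N[2L * (b - 1L) + c(1L, 2L), cols] <- cum
    }
  }
  N
}

state1_rows <- function(N) seq(1L, nrow(N), by = 2L)

#' Remaining life expectancy from the fundamental matrix
#'
#' Column sums of N give the expected total number of (age, state) cell
#' visits — the remaining years of life — for each starting cell.  By
#' default the year currently being lived is counted
#' (`include_current = TRUE`); the exclusive convention subtracts exactly 1.
#'
#' @param N fundamental matrix from [fundamental_matrix()].
#' @param include_current count the current year?
#' @return named vector of expectancies per starting cell.
#' @export
remaining_life_expectancy <- function(N, include_current = TRUE) {
  colSums(N) - if (include_current) 0 else 1
}

#' Expected remaining years below the threshold
#'
#' Sums the rows of N belonging to below-threshold cells, per starting
#' cell.  Under the exclusive convention the current year is not counted,
#' so 1 is subtracted for starts already below the threshold.
#'
#' @inheritParams remaining_life_expectancy
#' @export
expected_years_below <- function(N, include_current = TRUE) {
  yb <- colSums(N[state1_rows(N), , drop = FALSE])
  if (!include_current) {
    below_start <- seq_len(ncol(N)) %% 2L == 1L
    yb <- yb - as.numeric(below_start)
  }
  yb
}

#' Variance and CV of remaining life from the fundamental matrix
#'
#' Uses the standard absorbing-chain factorial-moment identity: with first
#' moments \eqn{\eta_1' = 1'N}, the second factorial moments are
#' \eqn{\eta_2' = \eta_1'(2N - I)} and the variance is
#' \eqn{\eta_2 - \eta_1 \circ \eta_1}.  The variance is invariant to the
#' current-year counting convention (a shift by a constant).
#'
#' @param N fundamental matrix.
#' @param include_current convention used for the mean in the CV.
#' @return data frame with columns mean, variance, cv (one row per starting
#'   cell).
#' @export
variance_remaining_life <- function(N, include_current = TRUE) {
  eta1 <- colSums(N)
  eta2 <- as.numeric(eta1 %*% (2 * N - diag(nrow(N))))
  v <- eta2 - eta1^2
  if (any(v < -1e-9))
    stop("internal inconsistency: negative variance of remaining life")
  v <- pmax(v, 0)
  mu <- eta1 - if (include_current) 0 else 1
  data.frame(mean = mu, variance = v,
             cv = ifelse(mu > 0, sqrt(v) / mu, NA_real_),
             row.names = colnames(N))
}

#' Per (age, state) summary of the absorbing-chain analysis
#'
#' Tabulates, for every (age, state) starting cell of the model, the
#' remaining life expectancy, the expected remaining years below the
#' threshold, their ratio, and the variance and coefficient of variation of
#' remaining life.
#'
#' @param model a `poverty_markov`.
#' @param include_current count the year currently being lived?
#' @return data frame of class `fundamental_summary` with columns age,
#'   state, expectancy, years_below, proportion_below, variance, cv.
#' @export
fundamental_summary <- function(model, include_current = TRUE) {
  N <- fundamental_matrix(model)
  eta <- remaining_life_expectancy(N, include_current)
  yb <- expected_years_below(N, include_current)
  vv <- variance_remaining_life(N, include_current)
  out <- data.frame(
    age = rep(model$ages, each = 2L),
    state = rep(c(1L, 2L), length(model$ages)),
    expectancy = eta,
    years_below = yb,
    proportion_below = ifelse(eta > 0, yb / eta, NA_real_),
    variance = vv$variance,
    cv = vv$cv,
    row.names = NULL)
  attr(out, "include_current") <- include_current
  attr(out, "seams") <- model$seams
  class(out) <- c("fundamental_summary", "data.frame")
  out
}

#' @export
print.fundamental_summary <- function(x, ...) {
  cat(sprintf(
    "Absorbing-chain summary (%s the current year), ages %d-%d\n",
    if (attr(x, "include_current")) "counting" else "excluding",
    min(x$age), max(x$age)))
  pick <- x$age %in% unique(round(seq(min(x$age), max(x$age),
                                      length.out = 5)))
  print(format(as.data.frame(x)[pick, ], digits = 4), row.names = FALSE)
  invisible(x)
}

#' Write the fundamental summary as CSV
#'
#' @param summary a `fundamental_summary`.
#' @param file CSV path.
#' @export
write_fundamental_summary <- function(summary, file) {
  utils::write.csv(as.data.frame(summary), file, row.names = FALSE)
  invisible(file)
}

#' @export
summary.poverty_markov <- function(object, include_current = TRUE, ...) {
  fundamental_summary(object, include_current)
}

#' Plot life expectancy or its variance against age
#'
#' Mirrors the panel layout of state-conditional expectancy figures: solid
#' lines are remaining life expectancy (or its variance), dashed lines the
#' expected years below the threshold (or the CV), red for starts below the
#' threshold and blue for starts above.
#'
#' @param x a `fundamental_summary`.
#' @param what "expectancy" or "variance".
#' @param ... passed to [graphics::matplot].
#' @export
plot.fundamental_summary <- function(x, what = c("expectancy", "variance"),
                                     ...) {
  what <- match.arg(what)
  b <- x[x$state == 1L, ]; a <- x[x$state == 2L, ]
  if (what == "expectancy") {
    graphics::matplot(b$age, cbind(b$expectancy, a$expectancy,
                                   b$years_below, a$years_below),
                      type = "l", lty = c(1, 1, 2, 2),
                      col = c("red", "blue", "red", "blue"),
                      xlab = "age", ylab = "years",
                      main = "Remaining life expectancy and years below threshold",
                      ...)
  } else {
    graphics::matplot(b$age, cbind(b$variance, a$variance),
                      type = "l", lty = 1, col = c("red", "blue"),
                      xlab = "age", ylab = "variance (years^2)",
                      main = "Variance of remaining life", ...)
  }
  if (!is.null(attr(x, "seams")))
    graphics::abline(v = attr(x, "seams"), col = "darkgreen", lty = 3)
  graphics::legend("topright", c("below", "above"), col = c("red", "blue"),
                   lty = 1, bty = "n")
  invisible(x)
}
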