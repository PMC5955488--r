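#' Per-age unconditional state transition block
#'
#' The 2x2 block Q(x) combines state-specific survival with the conditional
#' state transitions: element (i, j) is \eqn{s_j(x) t_{ij}(x)}, the
#' probability that a person in state j at age x is alive and in state i at
#' age x+1.  Columns are the state at age x (1 below, 2 above), rows the
#' state at age x+1; column j sums to \eqn{s_j(x)}, the deficit from 1 being
#' the chance of death over the year.
#'
#' @param rates a [rateset].
#' @param x a single age in the rateset's range.
#' @return a 2x2 numeric matrix.
#' @export
build_Q <- function(rates, x) {
  r <- rates_at(rates, x)
  matrix(c(r$s1 * r$t11, r$s1 * r$t21,
           r$s2 * r$t12, r$s2 * r$t22),
         nrow = 2, dimnames = list(state_next = c("below", "above"),
                                   state = c("below", "above")))
}

#' Conditional transition block (survival excluded)
#'
#' The column-stochastic 2x2 matrix T(x) of state transitions conditional on
#' survival: element (i, j) = \eqn{t_{ij}(x)}.
#'
#' @inheritParams build_Q
#' @export
conditional_T <- function(rates, x) {
  r <- rates_at(rates, x)
  matrix(c(r$t11, r$t21, r$t12, r$t22),
         nrow = 2, dimnames = list(state_next = c("below", "above"),
                                   state = c("below", "above")))
}

pad_rateset <- function(rates, ages) {
  ages <- as.integer(ages)
  lo <- min(rates$age); hi <- max(rates$age)
  idx <- pmin(pmax(ages, lo), hi)
  r <- rates_at(rates, idx)
  rateset(ages, r$s1, r$s2, r$t21, r$t22, seams = attr(rates, "seams"))
}

#' Assemble the age-by-state block matrix L
#'
#' Builds the substochastic block matrix with Q(x) on the block subdiagonal
#' and zeros elsewhere: the block taking age class x to x+1 is Q(x).  With
#' the default full grid of age classes 0-100 and two states the matrix is
#' 202 x 202.  The final age class maps to nothing (death at the terminal
#' age), so its block column is zero.  Ages outside the rateset's range are
#' padded by holding the boundary rates constant when `pad = TRUE`;
#' otherwise an uncovered age is an error.
#'
#' @param rates a [rateset].
#' @param ages integer vector of consecutive age classes (default 0:100).
#' @param pad extend boundary rates to uncovered ages?
#' @return a dense matrix of dimension `2 * length(ages)`, with cell names
#'   `a<age>_s<state>`.
#' @export
assemble_L <- function(rates, ages = 0:100, pad = TRUE) {
  ages <- as.integer(ages)
  stopifnot(length(ages) >= 2L, all(diff(ages) == 1L))
  need <- ages[-length(ages)]
  if (pad) rates <- pad_rateset(rates, need)
  else {
    missing <- setdiff(need, rates$age)
    if (length(missing))
      stop("rateset does not cover ages ",
           paste(range(missing), collapse = "-"),
           " (use pad = TRUE or a restricted grid)")
  }
  n <- length(ages)
  L <- matrix(0, 2L * n, 2L * n)
  cells <- paste0("a", rep(ages, each = 2L), "_s", c(1L, 2L))
  dimnames(L) <- list(cells, cells)
  for (k in seq_len(n - 1L)) {
    rows <- 2L * k + c(1L, 2L)
    cols <- 2L * (k - 1L) + c(1L, 2L)
    L[rows, cols] <- build_Q(rates, ages[k])
  }
  L
}

#' Age-by-state Markov model of poverty dynamics
#'
#' Packages an annual [rateset] into the block matrix form used for cohort
#' projection, absorbing-chain analysis and simulation.  The default grid
#' runs over age classes 0-100 (a 202 x 202 matrix), with rates held
#' constant outside the data range; `ages = 22:100` gives the restricted
#' grid used for substantive outputs.
#'
#' @param rates a [rateset] or a `rate_fit` (its rates are used).
#' @param ages consecutive integer age classes.
#' @param pad hold boundary rates constant outside the rateset's range?
#' @return an object of class `poverty_markov` with components `L`, `ages`,
#'   `rates` (padded to the grid) and `seams`.  Methods: `print`,
#'   `summary`, `plot`, `simulate`.
#' @export
markov_model <- function(rates, ages = 0:100, pad = TRUE) {
  if (inherits(rates, "rate_fit")) rates <- rates$rates
  stopifnot(inherits(rates, "rateset"))
  L <- assemble_L(rates, ages, pad)
  padded <- if (pad) pad_rateset(rates, ages[-length(ages)]) else rates
  structure(
    list(L = L, ages = as.integer(ages), rates = padded,
         seams = attr(rates, "seams")),
    class = "poverty_markov")
}

#' @export
print.poverty_markov <- function(x, ...) {
  n <- length(x$ages)
  cat(sprintf(
    "Age-by-state Markov model: %d age classes (%d-%d), 2 states, L is %dx%d\n",
    n, x$ages[1], x$ages[n], 2 * n, 2 * n))
  invisible(x)
}

cell_index <- function(model, age, state) {
  k <- match(as.integer(age), model$ages)
  if (anyNA(k)) stop("age not on the model's grid")
  2L * (k - 1L) + as.integer(state)
}

#' Project a cohort through the age-by-state matrix
#'
#' Computes \eqn{n(x) = L^x n(0)} by repeated application of L.  Total mass
#' is non-increasing in x; the deficit relative to the initial mass is the
#' cumulative number of deaths.
#'
#' @param model a `poverty_markov` (or a bare matrix L).
#' @param n0 cohort vector over the (age, state) cells, length `nrow(L)`.
#' @param steps number of one-year projection steps, >= 0.
#' @return the projected cohort vector.
#' @export
project_cohort <- function(model, n0, steps) {
  L <- if (inherits(model, "poverty_markov")) model$L else model
  if (length(n0) != nrow(L)) stop("cohort vector length must match dim(L)")
  if (steps < 0) stop("steps must be non-negative")
  v <- as.numeric(n0)
  for (k in seq_len(steps)) v <- L %*% v
  as.numeric(v)
}

#' Initial cohort vector concentrated at one age
#'
#' @param model a `poverty_markov`.
#' @param init_below proportion (or count) of the cohort below the threshold.
#' @param total cohort size.
#' @param age starting age class (default the first on the grid).
#' @return numeric vector over the model's cells.
#' @export
initial_cohort <- function(model, init_below, total = 1, age = model$ages[1]) {
  v <- numeric(nrow(model$L))
  v[cell_index(model, age, 1L)] <- total * init_below
  v[cell_index(model, age, 2L)] <- total * (1 - init_below)
  v
}

#' Below-threshold proportion of a projected cohort at each age
#'
#' Starting from a cohort concentrated at the grid's first age class,
#' projects age by age and reports the proportion of survivors below the
#' threshold together with the surviving mass.
#'
#' @param model a `poverty_markov`.
#' @param init_below initial proportion below the threshold.
#' @param age starting age class.
#' @return data frame with columns age, alive (surviving fraction of the
#'   initial cohort) and prop_below.
#' @export
cohort_proportions <- function(model, init_below, age = model$ages[1]) {
  k0 <- match(as.integer(age), model$ages)
  v <- c(init_below, 1 - init_below)
  out <- data.frame(age = model$ages[k0:length(model$ages)],
                    alive = NA_real_, prop_below = NA_real_)
  for (j in seq_len(nrow(out))) {
    tot <- sum(v)
    out$alive[j] <- tot
    out$prop_below[j] <- if (tot > 0) v[1] / tot else NA_real_
    if (j < nrow(out)) v <- build_Q(model$rates, out$age[j]) %*% v
  }
  out
}

#' Cumulative product of transition blocks
#'
#' Right-to-left ordered product of per-age blocks from the first model age
#' through x: for the unconditional blocks this is
#' \eqn{Q_{cum}(x) = Q(x) Q(x-1) \cdots Q(x_0)}; with
#' `conditional = TRUE` the survival-free blocks T(x) are multiplied
#' instead.
#'
#' @param rates a [rateset].
#' @param x final age of the product.
#' @param from first age (default the rateset's first age).
#' @param conditional use conditional transition blocks T(x) instead of
#'   Q(x)?
#' @return a 2x2 matrix.
#' @export
cumulative_Q <- function(rates, x, from = min(rates$age),
                         conditional = FALSE) {
  if (x < from) stop("x must not precede the first age of the product")
  M <- diag(2)
  blk <- if (conditional) conditional_T else build_Q
  for (a in seq(from, x)) M <- blk(rates, a) %*% M
  dimnames(M) <- list(state_next = c("below", "above"),
                      state = c("below", "above"))
  M
}

eigen2 <- function(M) {
  stopifnot(is.matrix(M), all(dim(M) == 2L))
  tr <- M[1, 1] + M[2, 2]
  det <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  disc <- tr^2 - 4 * det
  if (disc < 0) {
    s <- sqrt(as.complex(disc))
  } else s <- sqrt(disc)
  l1 <- (tr + s) / 2
  l2 <- (tr - s) / 2
  if (Mod(l2) > Mod(l1)) { tmp <- l1; l1 <- l2; l2 <- tmp }
  list(values = c(l1, l2))
}

#' Quasi-stable state distribution of a 2x2 nonnegative matrix
#'
#' Dominant right eigenvector, normalised to sum 1, of a cumulative
#' transition product: the state structure a cohort approaches.  The first
#' component is the proportion below the threshold.  If the two eigenvalues
#' have equal modulus there is no strict dominance; the result carries
#' attribute `tie = TRUE` and a warning rather than a silent choice.
#'
#' @param M nonnegative, nonzero 2x2 matrix.
#' @param tol relative tolerance for detecting an eigenvalue tie.
#' @return length-2 nonnegative vector summing to 1.
#' @export
quasi_stable_distribution <- function(M, tol = 1e-12) {
  stopifnot(all(M >= 0), any(M > 0))
  ev <- eigen2(M)
  l1 <- ev$values[1]
  tie <- isTRUE(abs(Mod(ev$values[1]) - Mod(ev$values[2])) <=
                  tol * max(Mod(ev$values[1]), 1))
  l1 <- Re(l1)
  if (M[2, 1] > 0) {
    v <- c(l1 - M[2, 2], M[2, 1])
  } else if (M[1, 2] > 0) {
    v <- c(M[1, 2], l1 - M[1, 1])
  } else {
    v <- if (M[1, 1] >= M[2, 2]) c(1, 0) else c(0, 1)
  }
  v <- abs(v)
  v <- v / sum(v)
  if (tie) {
    warning("eigenvalues have equal modulus: no strictly dominant eigenvector")
    attr(v, "tie") <- TRUE
  }
  v
}

#' Damping ratio of a transition matrix
#'
#' Ratio of the dominant to subdominant eigenvalue modulus of a cumulative
#' conditional transition matrix; larger values mean faster convergence of
#' the cohort state structure to the quasi-stable distribution.  A rank-1
#' matrix (subdominant eigenvalue 0) gives `Inf`.
#'
#' @param M 2x2 matrix, typically [cumulative_Q()] with
#'   `conditional = TRUE`.
#' @return positive number (possibly `Inf`).
#' @export
damping_ratio <- function(M) {
  ev <- eigen2(M)
  m1 <- Mod(ev$values[1]); m2 <- Mod(ev$values[2])
  if (m2 == 0) Inf else m1 / m2
}

#' Write the age-by-state matrix with a JSON sidecar
#'
#' Dense CSV of L plus `<file>.json` recording the age grid, state labels
#' and indexing convention.
#'
#' @param model a `poverty_markov`.
#' @param file CSV path; the sidecar is written alongside.
#' @export
write_age_state_matrix <- function(model, file) {
  utils::write.csv(model$L, file, row.names = TRUE)
  jsonlite::write_json(
    list(ages = model$ages, states = c("below", "above"),
         convention = "column j = origin cell, row i = destination cell",
         dimension = nrow(model$L)),
    paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}
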