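#' Simulate individual lifetime trajectories
#'
#' Samples a cohort of independent individuals from the annual chain: at
#' each age the person first survives with the state-specific probability
#' s_state(x), then, conditional on survival, switches state with the
#' conditional transition probability; the terminal age class forces death.
#' Rates are padded (boundary values held constant) onto the simulation
#' grid, matching the padding of [markov_model()], so simulated means are
#' directly comparable with fundamental-matrix quantities on the same grid.
#' One seeded generator drives everything; draws are made age by age across
#' the whole cohort (two uniform vectors per age, survival first), so output
#' is bitwise reproducible for a fixed seed and cohort size.
#'
#' @param rates a [rateset] or `rate_fit`.
#' @param n number of individuals.
#' @param start_age starting age (default the rateset's first age).
#' @param init_below probability of starting below the threshold; default is
#'   the quasi-stable distribution of the conditional transition block at
#'   the start age.
#' @param seed RNG seed.
#' @param max_age terminal age class; survivors reaching it die before the
#'   next age.
#' @return an object of class `trajectory_set`: a list with `states` (n x
#'   ages integer matrix, 1 below / 2 above, NA after death), `ages`,
#'   `death_age` (the age class a person failed to reach), and the
#'   simulation metadata.
#' @export
simulate_cohort <- function(rates, n, start_age = NULL, init_below = NULL,
                            seed = 1L, max_age = 100L) {
  if (inherits(rates, "rate_fit")) rates <- rates$rates
  stopifnot(inherits(rates, "rateset"), n >= 1)
  if (is.null(start_age)) start_age <- min(rates$age)
  if (max_age <= start_age) stop("max_age must exceed start_age")
  ages <- start_age:max_age
  padded <- pad_rateset(rates, ages[-length(ages)])
  if (is.null(init_below))
    init_below <- quasi_stable_distribution(
      conditional_T(padded, start_age))[1]
  stopifnot(init_below >= 0, init_below <= 1)

  set.seed(seed)
  n_ages <- length(ages)
  states <- matrix(NA_integer_, n, n_ages,
                   dimnames = list(NULL, paste0("a", ages)))
  state <- ifelse(stats::runif(n) < init_below, 1L, 2L)
  alive <- rep(TRUE, n)
  death_age <- rep(max_age + 1L, n)
  for (j in seq_len(n_ages)) {
    states[alive, j] <- state[alive]
    if (j == n_ages) break
    x <- ages[j]
    r <- rates_at(padded, x)
    s <- ifelse(state == 1L, r$s1, r$s2)
    dies <- alive & stats::runif(n) >= s
    p_sw <- ifelse(state == 1L, r$t21, r$t12)
    sw <- stats::runif(n) < p_sw
    death_age[dies] <- x + 1L
    alive <- alive & !dies
    flip <- alive & sw
    state[flip] <- 3L - state[flip]
  }
  structure(
    list(states = states, ages = ages, death_age = death_age,
         start_age = start_age, init_below = init_below, seed = seed,
         n = as.integer(n)),
    class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf(
    "Simulated cohort: %d individuals from age %d (P(below) = %.3f, seed %d)\n",
    x$n, x$start_age, x$init_below, x$seed))
  cat(sprintf("mean age at death %.2f; %d reached the terminal age\n",
              mean(x$death_age), sum(x$death_age > max(x$ages))))
  invisible(x)
}

#' Simulate trajectories from a fitted Markov model
#'
#' @param object a `poverty_markov`.
#' @param nsim number of individuals.
#' @param seed RNG seed.
#' @param start_age,init_below see [simulate_cohort()].
#' @param ... unused.
#' @return a `trajectory_set` on the model's age grid.
#' @export
simulate.poverty_markov <- function(object, nsim = 10000L, seed = 1L,
                                    start_age = NULL, init_below = NULL,
                                    ...) {
  if (is.null(start_age)) start_age <- object$ages[1]
  simulate_cohort(object$rates, nsim, start_age, init_below, seed,
                  max_age = object$ages[length(object$ages)])
}

#' @export
plot.poverty_markov <- function(x, ...) plot(x$rates, ...)

last_observed <- function(traj) {
  pmin(traj$death_age - traj$start_age, length(traj$ages))
}

#' Residence times and entry/exit ages for the low-income state
#'
#' Counts, per individual, the total person-years observed below the
#' threshold, every age of entry into the below state (a transition from
#' above, plus starting below at the start age, counted as an entry there),
#' and every age of exit (a transition to above, or death while below —
#' recorded at the age class the person failed to reach).  Cohort-level
#' mean, standard deviation and mode (integer-year bins, ties broken toward
#' the smaller value) of the residence-time distribution are reported.
#'
#' @param traj a `trajectory_set`.
#' @return a list of class `residence_summary` with `per_individual` (data
#'   frame: years_below, lifespan), `entries` and `exits` (data frames:
#'   individual, age), and `mean`, `sd`, `mode` of years below.
#' @export
residence_summary <- function(traj) {
  st <- traj$states
  years_below <- rowSums(st == 1L, na.rm = TRUE)
  lifespan <- last_observed(traj)

  prev <- st[, -ncol(st), drop = FALSE]
  cur <- st[, -1L, drop = FALSE]
  ent <- which(!is.na(cur) & !is.na(prev) & cur == 1L & prev == 2L,
               arr.ind = TRUE)
  entries <- data.frame(individual = ent[, 1],
                        age = traj$ages[ent[, 2] + 1L])
  init1 <- which(st[, 1L] == 1L)
  entries <- rbind(data.frame(individual = init1,
                              age = rep(traj$start_age, length(init1))),
                   entries)
  ex <- which(!is.na(cur) & !is.na(prev) & cur == 2L & prev == 1L,
              arr.ind = TRUE)
  exits <- data.frame(individual = ex[, 1], age = traj$ages[ex[, 2] + 1L])
  last_state <- st[cbind(seq_len(nrow(st)), last_observed(traj))]
  died_below <- which(last_state == 1L & traj$death_age <= max(traj$ages) + 1L)
  exits <- rbind(exits,
                 data.frame(individual = died_below,
                            age = traj$death_age[died_below]))
  o <- order(entries$individual, entries$age); entries <- entries[o, ]
  o <- order(exits$individual, exits$age); exits <- exits[o, ]
  rownames(entries) <- rownames(exits) <- NULL

  tab <- table(years_below)
  mode <- as.integer(names(tab)[which.max(tab)])  # which.max: first = smallest
  structure(
    list(per_individual = data.frame(years_below = years_below,
                                     lifespan = lifespan),
         entries = entries, exits = exits,
         mean = mean(years_below), sd = stats::sd(years_below),
         mode = mode),
    class = "residence_summary")
}

#' @export
print.residence_summary <- function(x, ...) {
  cat(sprintf(
    "Years below threshold: mean %.2f, sd %.2f, mode %d (n = %d)\n",
    x$mean, x$sd, x$mode, nrow(x$per_individual)))
  cat(sprintf("entries into the below state: %d; exits (incl. death): %d\n",
              nrow(x$entries), nrow(x$exits)))
  invisible(x)
}

#' Survivorship counts by state and an individual-level snapshot
#'
#' `survivorship_counts` tallies, at each age, the simulated individuals
#' alive in each state (the survivorship-curve-shaped raster).
#' `snapshot_raster` extracts the state sequences of the first k individuals
#' over an age window for a close-up raster.
#'
#' @param traj a `trajectory_set`.
#' @return data frame with columns age, below, above, alive.
#' @export
survivorship_counts <- function(traj) {
  data.frame(age = traj$ages,
             below = colSums(traj$states == 1L, na.rm = TRUE),
             above = colSums(traj$states == 2L, na.rm = TRUE),
             alive = colSums(!is.na(traj$states)))
}

#' @rdname survivorship_counts
#' @param window length-2 age range of the snapshot.
#' @param k number of individuals, <= n.
#' @export
snapshot_raster <- function(traj, window = c(50, 60), k = 100L) {
  if (k > traj$n) stop("k exceeds the number of simulated individuals")
  cols <- which(traj$ages >= window[1] & traj$ages <= window[2])
  if (!length(cols)) stop("window outside the simulated age range")
  traj$states[seq_len(k), cols, drop = FALSE]
}

#' Write a trajectory set as long-format CSV plus JSON metadata
#'
#' CSV columns (individual, age, state); a death row (state 0) is written at
#' each death age.  Metadata (seed, n, start age, initial distribution) go
#' to `<file>.json`.
#'
#' @param traj a `trajectory_set`.
#' @param file CSV path.
#' @export
write_trajectories <- function(traj, file) {
  idx <- which(!is.na(traj$states), arr.ind = TRUE)
  long <- data.frame(individual = idx[, 1], age = traj$ages[idx[, 2]],
                     state = traj$states[idx])
  died <- which(traj$death_age <= max(traj$ages))
  long <- rbind(long, data.frame(individual = died,
                                 age = traj$death_age[died], state = 0L))
  long <- long[order(long$individual, long$age), ]
  utils::write.csv(long, file, row.names = FALSE)
  jsonlite::write_json(
    list(seed = traj$seed, n = traj$n, start_age = traj$start_age,
         init_below = traj$init_below),
    paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Plot simulated lifetime trajectories
#'
#' Left panel: the whole cohort as a state raster sorted by lifespan (red =
#' above threshold, green = below, white = dead), tracing a survivorship
#' curve.  Right panel: a snapshot of `k` individuals over an age window.
#'
#' @param x a `trajectory_set`.
#' @param window,k snapshot window and size (see [snapshot_raster()]).
#' @param ... unused.
#' @export
plot.trajectory_set <- function(x, window = c(50, 60),
                                k = min(100L, x$n), ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  pal <- c("green3", "red")
  o <- order(x$death_age)
  graphics::image(x$ages, seq_len(x$n), t(x$states[o, ]), col = pal,
                  xlab = "age", ylab = "individual (sorted by lifespan)",
                  main = "Cohort trajectories", useRaster = TRUE)
  snap <- snapshot_raster(x, window, k)
  graphics::image(x$ages[x$ages >= window[1] & x$ages <= window[2]],
                  seq_len(k), t(snap), col = pal, xlab = "age",
                  ylab = "individual", main = "Snapshot", useRaster = TRUE)
  invisible(x)
}

#' Histograms of residence times and transition ages
#'
#' Three panels: total years spent below the threshold, ages of entry into
#' the below state, and ages of exit (exit by transition or by death).
#'
#' @param x a `residence_summary`.
#' @param seams optional seam ages to mark.
#' @param ... unused.
#' @export
plot.residence_summary <- function(x, seams = c(33, 50), ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::hist(x$per_individual$years_below, breaks = "FD",
                 main = "Years below threshold", xlab = "years")
  graphics::hist(x$entries$age, breaks = "FD", main = "Ages of entry",
                 xlab = "age")
  if (!is.null(seams)) graphics::abline(v = seams, col = "darkgreen", lty = 2)
  graphics::hist(x$exits$age, breaks = "FD",
                 main = "Ages of exit (incl. death)", xlab = "age")
  if (!is.null(seams)) graphics::abline(v = seams, col = "darkgreen", lty = 2)
  invisible(x)
}
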