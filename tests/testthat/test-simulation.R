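test_that("certain survival and frozen states reach the terminal age", {
  rs <- const_rateset(22:49, 1, 1, 0, 1)
  traj <- simulate_cohort(rs, 300, init_below = 0.4, seed = 2, max_age = 50)
  expect_true(all(traj$death_age == 51L))
  expect_true(all(traj$states == traj$states[, 1]))
  expect_equal(dim(traj$states), c(300L, 29L))
})

test_that("lifespans follow the geometric law at constant survival", {
  rs <- const_rateset(22:95, 0.5, 0.5, 0.3, 0.9)
  traj <- simulate_cohort(rs, 20000, seed = 3, max_age = 100)
  life <- traj$death_age - 22
  expect_lt(abs(mean(life) - 2), 3 * sd(life) / sqrt(traj$n))
})

test_that("residence accounting follows the documented counting rules", {
  st <- rbind(c(1L, 1L, 2L, 1L))
  traj <- manual_traj(st, start_age = 40L, death_age = 44L)
  res <- residence_summary(traj)
  expect_equal(res$per_individual$years_below, 3)
  expect_equal(res$entries$age, c(40, 43))
  expect_equal(res$exits$age, c(42, 44))
  # all-above cohort: residence zero, mode zero, no entries
  st2 <- matrix(2L, 5, 4)
  res2 <- residence_summary(manual_traj(st2, 40L, rep(44L, 5)))
  expect_equal(res2$mean, 0)
  expect_equal(res2$mode, 0L)
  expect_equal(nrow(res2$entries), 0L)
})

test_that("entries and exits alternate within every individual", {
  traj <- simulate_cohort(true_rateset(poverty_truth("2x")), 2000, seed = 5)
  res <- residence_summary(traj)
  ent <- split(res$entries$age, res$entries$individual)
  ex <- split(res$exits$age, res$exits$individual)
  ids <- union(names(ent), names(ex))
  ok <- vapply(ids, function(id) {
    e <- ent[[id]]; x <- ex[[id]]
    if (is.null(e)) e <- numeric(0)
    if (is.null(x)) x <- numeric(0)
    # every entry is eventually closed by an exit (death counts as exit),
    # and episodes interleave: e1 < x1 < e2 < x2 < ...
    length(e) == length(x) && all(e < x) &&
      (length(e) < 2 || all(utils::head(x, -1) < e[-1]))
  }, logical(1))
  expect_true(all(ok))
  # total years below never exceed the lifespan
  expect_true(all(res$per_individual$years_below <=
                  res$per_individual$lifespan))
})

test_that("simulation is bitwise reproducible for a fixed seed", {
  rs <- true_rateset(poverty_truth("1x"))
  a <- simulate_cohort(rs, 500, seed = 77)
  b <- simulate_cohort(rs, 500, seed = 77)
  expect_identical(a$states, b$states)
  expect_identical(a$death_age, b$death_age)
  c <- simulate_cohort(rs, 500, seed = 78)
  expect_false(identical(a$states, c$states))
})

test_that("survivorship counts recount the empirical survival function", {
  traj <- simulate_cohort(true_rateset(poverty_truth("3x")), 3000, seed = 11)
  sc <- survivorship_counts(traj)
  expect_equal(sc$alive, vapply(traj$ages,
                                function(a) sum(traj$death_age > a),
                                numeric(1)))
  expect_equal(sc$below + sc$above, sc$alive)
  expect_equal(sc$alive[1], traj$n)
  expect_true(all(diff(sc$alive) <= 0))
})

test_that("the snapshot is the raster restricted to the window", {
  traj <- simulate_cohort(true_rateset(poverty_truth("1x")), 120, seed = 13)
  snap <- snapshot_raster(traj, window = c(50, 60), k = 120)
  cols <- which(traj$ages >= 50 & traj$ages <= 60)
  expect_identical(snap, traj$states[, cols])
  expect_error(snapshot_raster(traj, c(50, 60), k = 500), "exceeds")
})

test_that("frozen states give residence proportional to lifespan", {
  rs <- const_rateset(22:95, 0.93, 0.93, 0, 1)
  traj <- simulate_cohort(rs, 30000, init_below = 0.3, seed = 17)
  res <- residence_summary(traj)
  life <- traj$death_age - 22
  # states never change, so years below = lifespan for the 30% starting below
  expect_equal(res$mean, mean(life * (traj$states[, 1] == 1L)))
  expect_lt(abs(res$mean - 0.3 * mean(life)), 0.15)
})

test_that("simulated lifetimes agree with the fundamental matrix", {
  rs <- true_rateset(poverty_truth("1x"))
  m <- markov_model(rs, ages = 55:100)
  N <- fundamental_matrix(m)
  for (st in c(1L, 2L)) {
    traj <- simulate_cohort(rs, 30000, start_age = 55,
                            init_below = c(1, 0)[st], seed = 19 + st)
    life <- traj$death_age - 55
    expect_lt(abs(mean(life) - remaining_life_expectancy(N)[st]),
              3 * sd(life) / sqrt(traj$n))
    res <- residence_summary(traj)
    expect_lt(abs(res$mean - expected_years_below(N)[st]),
              3 * res$sd / sqrt(traj$n))
  }
})

test_that("trajectory CSV export round-trips states and deaths", {
  traj <- simulate_cohort(true_rateset(poverty_truth("2x")), 50, seed = 29)
  f <- tempfile(fileext = ".csv")
  write_trajectories(traj, f)
  long <- utils::read.csv(f)
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(meta$n, 50)
  expect_equal(meta$seed, 29)
  obs <- long[long$state > 0, ]
  expect_equal(nrow(obs), sum(!is.na(traj$states)))
  deaths <- long[long$state == 0, ]
  expect_equal(deaths$age, unname(traj$death_age[traj$death_age <=
                                                 max(traj$ages)]))
})
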