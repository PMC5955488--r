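# Shared fixtures: tiny ground truths, constant ratesets, single-segment
# designs.  Everything is built in code at test time.

# constant annual rates over an age range
const_rateset <- function(ages, s1, s2, t21, t22) {
  n <- length(ages)
  rateset(ages, rep(s1, n), rep(s2, n), rep(t21, n), rep(t22, n))
}

# truth with age-constant probabilities chosen on the annual scale
const_truth <- function(s1 = 0.98, s2 = 0.99, t21 = 0.3, t12 = 0.05,
                        ages = 22:95) {
  ground_truth(
    survival   = c(qlogis(s2), 0, 0, qlogis(s1) - qlogis(s2), 0, 0),
    transition = c(qlogis(1 - t12), 0, 0, qlogis(t21) - qlogis(1 - t12)),
    label = "const", ages = ages)
}

# age-linear truth with state interaction, suitable for degree-1 recovery
linear_truth <- function() {
  ground_truth(
    survival   = c(8.0, -0.07, 0, -1.5, 0.015, 0),
    transition = c(2.0, 0.01, 0, -2.5, -0.01, 0),
    label = "linear")
}

one_segment <- function(age_min = 22L, age_max = 33L, interval = 12,
                        sd = 0, waves = 5L) {
  data.frame(age_min = age_min, age_max = age_max,
             interval_months = interval, interval_sd = sd, waves = waves)
}

small_design <- function(n = 500L, segments = one_segment(),
                         nonresponse = 0, ...) {
  panel_design(segments, cohort_size = n, nonresponse = nonresponse, ...)
}

# hand-built panel table for pooling edge cases
manual_panel <- function(waves_responded, person_id = 1L, age0 = 30L) {
  k <- length(waves_responded)
  df <- data.frame(
    person_id = person_id, wave = seq_len(k),
    age = age0 + seq_len(k) - 1L,
    state = ifelse(waves_responded, 1L, NA_integer_),
    alive = 1L, weight = 1,
    interval_months = c(rep(12, k - 1L), NA),
    responded = waves_responded)
  class(df) <- c("panel_table", "data.frame")
  df
}

# hand-built trajectory set
manual_traj <- function(states, start_age, death_age) {
  structure(
    list(states = states, ages = start_age + seq_len(ncol(states)) - 1L,
         death_age = death_age, start_age = start_age,
         init_below = mean(states[, 1] == 1L), seed = 0L,
         n = nrow(states)),
    class = "trajectory_set")
}
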