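#' Generate a synthetic longitudinal panel
#'
#' Samples person histories from the per-interval survival and transition
#' probabilities implied by a [ground_truth()] at each person's current age
#' and state: each segment's coefficients give probabilities on its own
#' interview-interval scale, and the realised interval only rescales the
#' event probability by the constant-hazard rule.  Persons enter a segment
#' at a uniform baseline age (younger segments are closed cohorts; the
#' oldest enrols across its whole range) and are followed for the segment's
#' number of waves.  At each wave the realised interval to the next
#' interview is drawn (truncated normal, rounded to whole months), death or
#' survival over the interval is sampled first, then the state at the next
#' interview conditional on survival; non-response is applied afterwards,
#' independently of fate, and never alters fates.  The wave at which a
#' person is first dead carries `alive = 0` and no state — and, like any
#' interview, may itself be missed — after which the person leaves the
#' panel.  Ages advance as baseline age
#' plus cumulative months rounded to whole years, matching the discrete
#' one-year age grid of the Markov model.
#'
#' @param truth a [ground_truth()].
#' @param design a [panel_design()].
#' @param seed integer RNG seed; output is deterministic given the seed.
#' @return data frame of class `panel_table` with columns person_id, wave,
#'   age, state (1 below / 2 above, NA when unobserved), alive, weight,
#'   interval_months (realised months to the next interview, NA at the final
#'   wave and on death rows), responded.
#' @export
generate_panel <- function(truth, design, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"), inherits(design, "panel_design"))
  validate_ground_truth(truth)
  set.seed(seed)
  pieces <- vector("list", nrow(design$segments))
  id_offset <- 0L
  for (k in seq_len(nrow(design$segments))) {
    pieces[[k]] <- generate_segment(truth, design, k, id_offset)
    id_offset <- id_offset + design$cohort_size[k]
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "truth_label") <- truth$label
  class(out) <- c("panel_table", "data.frame")
  out
}

interval_event_prob <- function(p_nominal, months, nominal_months) {
  1 - (1 - p_nominal)^(months / nominal_months)
}

generate_segment <- function(truth, design, k, id_offset) {
  seg <- design$segments[k, ]
  n <- design$cohort_size[k]
  # younger segments are closed cohorts whose interview (non-final) waves
  # stay inside the segment's age range, so every age of the range appears
  # as a time-t observation without leaking this segment's interview spacing
  # into the next one; the oldest segment enrols at any age up to its
  # maximum (an open panel) and follow-up beyond the overall range is
  # dropped at estimation
  pair_span <- max(0L, seg$waves - 2L) * floor(seg$interval_months / 12)
  last_seg <- k == nrow(design$segments)
  base_max <- if (last_seg) seg$age_max
              else max(seg$age_min, seg$age_max - pair_span)
  baseline <- sample(seg$age_min:base_max, n, replace = TRUE)

  w <- stats::rlnorm(n, meanlog = -design$weight_sdlog^2 / 2,
                     sdlog = design$weight_sdlog)
  w <- w / mean(w)

  if (is.null(design$init_below)) {
    t21 <- truth_probability(truth, baseline, 1, "transition")
    t12 <- 1 - truth_probability(truth, baseline, 2, "transition")
    p_below <- t12 / (t12 + t21)
  } else {
    p_below <- rep(design$init_below, n)
  }
  state <- ifelse(stats::runif(n) < p_below, 1L, 2L)

  alive <- rep(TRUE, n)
  in_panel <- rep(TRUE, n)   # dead persons stay for one recording wave
  age <- baseline
  cum_months <- rep(0, n)
  rows <- vector("list", seg$waves)

  for (wv in seq_len(seg$waves)) {
    idx <- which(in_panel)
    p_nr <- rep(design$nonresponse, length(idx))
    if (design$nonresponse_odds_below != 1) {
      odds <- p_nr / (1 - p_nr) *
        ifelse(state[idx] == 1L, design$nonresponse_odds_below, 1)
      p_nr <- odds / (1 + odds)
    }
    # non-response is independent of fate: a death is recorded only if the
    # wave would have been observed (e.g. through an exit interview or
    # registry check attempted like any interview), so survivors and
    # deaths are thinned identically and pooled pairs stay unbiased
    responded <- stats::runif(length(idx)) >= p_nr

    last_wave <- wv == seg$waves
    months <- rep(NA_real_, length(idx))
    if (!last_wave) {
      live <- alive[idx]
      m <- round(stats::rnorm(sum(live), seg$interval_months,
                              seg$interval_sd))
      months[live] <- pmax(1, m)
    }

    rows[[wv]] <- data.frame(
      person_id = id_offset + idx,
      wave = wv,
      age = age[idx],
      state = ifelse(alive[idx] & responded, state[idx], NA_integer_),
      alive = as.integer(alive[idx]),
      weight = w[idx],
      interval_months = months,
      responded = responded)

    if (last_wave) break

    # fates over the coming interval, for currently alive panel members
    in_panel[idx[!alive[idx]]] <- FALSE       # dead row recorded; drop
    live_idx <- idx[alive[idx]]
    mi <- months[match(live_idx, idx)]
    p_die <- interval_event_prob(
      1 - truth_probability(truth, age[live_idx], state[live_idx],
                            "survival"), mi, seg$interval_months)
    dies <- stats::runif(length(live_idx)) < p_die
    p_sw_nominal <- ifelse(
      state[live_idx] == 1L,
      truth_probability(truth, age[live_idx], 1, "transition"),
      1 - truth_probability(truth, age[live_idx], 2, "transition"))
    switches <- stats::runif(length(live_idx)) <
      interval_event_prob(p_sw_nominal, mi, seg$interval_months)
    survivors <- live_idx[!dies]
    state[survivors[switches[!dies]]] <-
      3L - state[survivors[switches[!dies]]]
    alive[live_idx[dies]] <- FALSE
    cum_months[live_idx] <- cum_months[live_idx] + mi
    age[live_idx] <- baseline[live_idx] + round(cum_months[live_idx] / 12)
  }
  do.call(rbind, rows)
}

#' Read or write a panel table as CSV
#'
#' Plain CSV with header `person_id,wave,age,state,alive,weight,
#' interval_months,responded`; logical `responded` round-trips losslessly.
#'
#' @param panel a `panel_table`.
#' @param file CSV path.
#' @export
write_panel <- function(panel, file) {
  utils::write.csv(as.data.frame(panel), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_panel
#' @export
read_panel <- function(file) {
  df <- utils::read.csv(file)
  needed <- c("person_id", "wave", "age", "state", "alive", "weight",
              "interval_months", "responded")
  if (!all(needed %in% names(df)))
    stop("panel CSV missing columns: ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  df$responded <- as.logical(df$responded)
  class(df) <- c("panel_table", "data.frame")
  df
}

#' @export
print.panel_table <- function(x, ...) {
  cat(sprintf("Panel table: %d observations of %d persons, ages %d-%d\n",
              nrow(x), length(unique(x$person_id)), min(x$age), max(x$age)))
  cat(sprintf("deaths observed: %d; non-response rows: %d\n",
              sum(x$alive == 0L), sum(!x$responded)))
  print(utils::head(as.data.frame(x)), row.names = FALSE)
  invisible(x)
}
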