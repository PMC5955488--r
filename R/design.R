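#' Default estimation/generation segments
#'
#' The pipeline splits ages 22-95 into three segments mirroring the wave
#' design of the longitudinal surveys it emulates: young adults interviewed
#' at roughly 12-month intervals (ages 22-33), mid-life respondents at
#' 24-month intervals (34-50), and an older panel also at 24-month intervals
#' (51-95).  Boundary ages 33 and 50 belong to the younger segment.
#'
#' @return data frame with columns age_min, age_max, interval_months,
#'   interval_sd, waves.
#' @export
default_segments <- function() {
  data.frame(
    age_min = c(22L, 34L, 51L),
    age_max = c(33L, 50L, 95L),
    interval_months = c(12, 24, 24),
    interval_sd = c(1, 2, 2),
    waves = c(5L, 5L, 5L))
}

#' Design of a synthetic longitudinal panel
#'
#' Describes the survey structure the generator emulates: per-segment age
#' ranges and nominal interview spacing, cohort sizes, lognormal survey
#' weights, and wave non-response (optionally state-dependent, to exercise
#' the non-response diagnostic).  Interval lengths are drawn per person-wave
#' from a normal distribution truncated at 1 month and rounded to integer
#' months.
#'
#' @param segments data frame as returned by [default_segments()].
#' @param cohort_size persons per segment (recycled across segments).
#' @param nonresponse per-wave probability that an alive respondent misses an
#'   interview, in [0, 1).
#' @param nonresponse_odds_below odds multiplier on non-response for persons
#'   below the threshold (1 = state-independent).
#' @param weight_sdlog sdlog of the lognormal survey weights (normalised to
#'   mean 1).
#' @param init_below probability of starting below the threshold; `NULL`
#'   (default) uses the stationary distribution of the ground truth's annual
#'   conditional transition matrix at each person's baseline age.
#' @return an object of class `panel_design`.
#' @export
panel_design <- function(segments = default_segments(),
                         cohort_size = 30000L,
                         nonresponse = 0.1,
                         nonresponse_odds_below = 1,
                         weight_sdlog = 0.5,
                         init_below = NULL) {
  stopifnot(is.data.frame(segments),
            all(c("age_min", "age_max", "interval_months", "interval_sd",
                  "waves") %in% names(segments)),
            all(segments$interval_months > 0),
            all(segments$waves >= 2L),
            nonresponse >= 0, nonresponse < 1,
            nonresponse_odds_below > 0,
            is.null(init_below) || (init_below >= 0 && init_below <= 1))
  o <- order(segments$age_min)
  segments <- segments[o, , drop = FALSE]
  if (any(segments$age_max[-nrow(segments)] + 1L != segments$age_min[-1L]))
    stop("segments must partition a contiguous age range")
  structure(
    list(segments = segments,
         cohort_size = as.integer(rep_len(cohort_size, nrow(segments))),
         nonresponse = nonresponse,
         nonresponse_odds_below = nonresponse_odds_below,
         weight_sdlog = weight_sdlog,
         init_below = init_below),
    class = "panel_design")
}

#' @export
print.panel_design <- function(x, ...) {
  cat("Synthetic panel design\n")
  seg <- x$segments
  seg$cohort_size <- x$cohort_size
  print(seg, row.names = FALSE)
  cat(sprintf("non-response %.3f (odds multiplier below threshold %.2f)\n",
              x$nonresponse, x$nonresponse_odds_below))
  cat(sprintf("weights lognormal sdlog %.2f, mean 1\n", x$weight_sdlog))
  if (!is.null(x$init_below))
    cat(sprintf("initial P(below) fixed at %.3f\n", x$init_below))
  else
    cat("initial state from truth's stationary distribution at baseline age\n")
  invisible(x)
}
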