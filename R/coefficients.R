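#' Export fitted regression coefficients to JSON
#'
#' Serialises the per-segment survival and transition logistic coefficients
#' (with standard errors and mean interview intervals) so a model can later
#' be re-parameterised without any panel data via [read_coefficients()] and
#' [rates_from_coefficients()].
#'
#' @param fit a `rate_fit` from [fit_rates()].
#' @param file JSON path.
#' @export
write_coefficients <- function(fit, file) {
  stopifnot(inherits(fit, "rate_fit"))
  segs <- lapply(fit$fits, function(f) {
    one <- function(m) list(
      coefficients = as.list(m$coefficients),
      se = as.list(m$se),
      degree = m$degree, interaction = m$interaction,
      mean_interval_months = m$mean_interval_months,
      n = m$n)
    list(age_min = f$age_min, age_max = f$age_max,
         survival = one(f$survival), transition = one(f$transition))
  })
  jsonlite::write_json(list(segments = segs), file, auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' Import regression coefficients from JSON
#'
#' Reads the JSON dialect written by [write_coefficients()]: a list of
#' segments, each with an age range and, for the survival and transition
#' outcomes, coefficient values in the canonical slot order (intercept, age,
#' age2, below, age_below, age2_below; absent slots default to 0) and the
#' mean interview interval in months used for annualisation.  This is the
#' entry point for parameterising the Markov model directly from published
#' regression tables.
#'
#' @param file JSON path.
#' @return a list of segment fits suitable for [rates_from_coefficients()].
#' @export
read_coefficients <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (is.null(obj$segments)) stop("coefficient JSON lacks a 'segments' list")
  segs <- obj$segments
  build <- function(m, rng, outcome) {
    cf <- pad6(numeric(0))
    got <- unlist(m$coefficients)
    cf[names(got)] <- got
    se <- pad6(numeric(0)); se[] <- NA_real_
    if (!is.null(m$se)) { g <- unlist(m$se); se[names(g)] <- g }
    structure(
      list(outcome = outcome, coefficients = cf, se = se, vcov = NULL,
           terms = names(cf)[cf != 0 | names(cf) == "intercept"],
           degree = if (!is.null(m$degree)) m$degree else 2,
           interaction = if (!is.null(m$interaction)) m$interaction else TRUE,
           age_range = rng,
           mean_interval_months = m$mean_interval_months,
           n = if (!is.null(m$n)) m$n else NA_integer_),
      class = "interval_fit")
  }
  if (is.data.frame(segs)) segs <- split(segs, seq_len(nrow(segs)))
  lapply(segs, function(s) {
    s <- as.list(s)
    rng <- c(s$age_min, s$age_max)
    list(age_min = s$age_min, age_max = s$age_max,
         survival = build(as.list(s$survival), rng, "survival"),
         transition = build(as.list(s$transition), rng, "transition"))
  })
}

#' Annual rates from imported coefficients (no panel data)
#'
#' Evaluates and annualises the per-segment logistic coefficients exactly as
#' [fit_rates()] does after fitting, bypassing estimation entirely.
#'
#' @param seg_fits list of segment fits from [read_coefficients()], or the
#'   `fits` component of a `rate_fit`.
#' @param annualization passed to the internal concatenation; see
#'   [fit_rates()].
#' @return a `rate_fit` whose rates derive from the supplied coefficients.
#' @export
rates_from_coefficients <- function(seg_fits,
                                    annualization = c("probability",
                                                      "matrix")) {
  structure(
    list(rates = segment_rates(seg_fits, annualization = annualization),
         fits = seg_fits,
         segments = data.frame(
           age_min = vapply(seg_fits, `[[`, numeric(1), "age_min"),
           age_max = vapply(seg_fits, `[[`, numeric(1), "age_max")),
         n_pooled = NA_integer_),
    class = "rate_fit")
}
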