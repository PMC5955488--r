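#' Pool consecutive interview-wave pairs
#'
#' Implements the pooled repeated observation design: every pair of
#' consecutive waves (w, w+1) of one person contributes one row with the
#' person's age and state at time t and their fate at t+i, provided both
#' interviews were observed.  A missing response at either end omits the
#' pair; later pairs of the same person are retained.  A recorded death
#' counts as an observed interview, so deaths enter the survival outcome.
#'
#' @param panel a `panel_table` (see [generate_panel()], [read_panel()]).
#' @return data frame of class `pooled_obs` with columns person_id, age,
#'   state, survived, state_next (NA unless survived and observed),
#'   interval_months, weight.
#' @export
pool_observations <- function(panel) {
  p <- as.data.frame(panel)
  p <- p[order(p$person_id, p$wave), ]
  same <- p$person_id[-1L] == p$person_id[-nrow(p)] &
    p$wave[-1L] == p$wave[-nrow(p)] + 1L
  i <- which(same)           # index of the t row; i + 1 is the t+i row
  ok <- p$responded[i] & p$alive[i] == 1L & !is.na(p$state[i]) &
    p$responded[i + 1L]
  i <- i[ok]
  if (!length(i))
    stop("no usable consecutive responded wave pairs in this panel")
  out <- data.frame(
    person_id = p$person_id[i],
    age = p$age[i],
    state = p$state[i],
    survived = as.integer(p$alive[i + 1L] == 1L),
    state_next = ifelse(p$alive[i + 1L] == 1L, p$state[i + 1L], NA_integer_),
    interval_months = p$interval_months[i],
    weight = p$weight[i])
  class(out) <- c("pooled_obs", "data.frame")
  out
}

#' Non-response by state and age
#'
#' Diagnostic for differential attrition: among alive respondents at age x
#' whose next scheduled interview exists and who are still alive at it
#' (deceased persons are excluded from the denominators), the proportion who
#' fail to respond at that next interview, split by income state at x, with
#' the between-state difference (below minus above).  Empty cells are
#' reported as NA, not 0.
#'
#' @param panel a `panel_table`.
#' @return data frame with columns age, n_below, n_above, p_below, p_above,
#'   diff.
#' @export
nonresponse_by_state_age <- function(panel) {
  p <- as.data.frame(panel)
  p <- p[order(p$person_id, p$wave), ]
  same <- p$person_id[-1L] == p$person_id[-nrow(p)] &
    p$wave[-1L] == p$wave[-nrow(p)] + 1L
  i <- which(same)
  keep <- p$responded[i] & p$alive[i] == 1L & !is.na(p$state[i]) &
    p$alive[i + 1L] == 1L
  i <- i[keep]
  age <- p$age[i]
  state <- p$state[i]
  nr <- !p$responded[i + 1L]
  ages <- sort(unique(age))
  cell <- function(a, s) {
    sel <- age == a & state == s
    c(n = sum(sel), p = if (any(sel)) mean(nr[sel]) else NA_real_)
  }
  below <- t(vapply(ages, cell, numeric(2), s = 1L))
  above <- t(vapply(ages, cell, numeric(2), s = 2L))
  data.frame(age = ages,
             n_below = below[, 1], n_above = above[, 1],
             p_below = below[, 2], p_above = above[, 2],
             diff = below[, 2] - above[, 2])
}
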