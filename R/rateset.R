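#' Age-indexed annual survival and transition probabilities
#'
#' A `rateset` tabulates, for each integer age x, the four annual
#' probabilities that parameterise the two-state poverty chain:
#' \describe{
#'   \item{s1(x)}{survival from x to x+1 for a person below the threshold}
#'   \item{s2(x)}{survival from x to x+1 for a person above the threshold}
#'   \item{t21(x)}{exit: probability of being above the threshold at x+1 for
#'     a person below it at x, conditional on survival}
#'   \item{t22(x)}{stay: probability of being above the threshold at x+1 for
#'     a person above it at x, conditional on survival}
#' }
#' The complements t11 = 1 - t21 (stay below) and t12 = 1 - t22 (entry) are
#' derived columns, so row sums of the conditional transition pairs are 1
#' exactly.  State 1 is below the threshold, state 2 above; transition
#' subscripts are destination-then-origin (t12 moves from state 2 to 1).
#'
#' @param age integer ages.
#' @param s1,s2,t21,t22 annual probabilities, one per age, each in [0, 1].
#' @param seams optional ages marking boundaries between estimation segments
#'   (drawn on plots).
#' @return a data frame of class `rateset` with columns age, s1, s2, t21,
#'   t22, t11, t12.
#' @export
rateset <- function(age, s1, s2, t21, t22, seams = NULL) {
  age <- as.integer(age)
  stopifnot(!anyDuplicated(age), all(diff(age) == 1L))
  df <- data.frame(age = age, s1 = s1, s2 = s2, t21 = t21, t22 = t22,
                   t11 = 1 - t21, t12 = 1 - t22)
  for (col in c("s1", "s2", "t21", "t22"))
    if (any(df[[col]] < 0 | df[[col]] > 1 | !is.finite(df[[col]])))
      stop(sprintf("rateset: column %s outside [0, 1]", col))
  attr(df, "seams") <- seams
  class(df) <- c("rateset", "data.frame")
  df
}

rates_at <- function(rates, x) {
  i <- match(as.integer(x), rates$age)
  if (anyNA(i))
    stop(sprintf("age %s not covered by this rateset",
                 paste(x[is.na(i)], collapse = ", ")))
  rates[i, , drop = FALSE]
}

#' Read or write a rateset as CSV
#'
#' The on-disk dialect is a plain CSV with header
#' `age,s1,s2,t21,t22`; derived complements are recomputed on read.
#'
#' @param rates a [rateset].
#' @param file path to a CSV file.
#' @return `read_rateset` returns a [rateset]; `write_rateset` returns
#'   `file` invisibly.
#' @export
write_rateset <- function(rates, file) {
  utils::write.csv(as.data.frame(rates)[c("age", "s1", "s2", "t21", "t22")],
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_rateset
#' @export
read_rateset <- function(file) {
  df <- utils::read.csv(file)
  rateset(df$age, df$s1, df$s2, df$t21, df$t22)
}

#' @export
print.rateset <- function(x, ...) {
  ages <- range(x$age)
  cat(sprintf("Annual rate set, ages %d-%d\n", ages[1], ages[2]))
  show <- x[x$age %in% unique(round(seq(ages[1], ages[2], length.out = 6))), ]
  print(format(as.data.frame(show), digits = 4), row.names = FALSE)
  if (!is.null(attr(x, "seams")))
    cat("segment seams at ages:", paste(attr(x, "seams"), collapse = ", "),
        "\n")
  invisible(x)
}

#' Plot annual survival and transition probabilities against age
#'
#' Two panels: state-specific annual survival (top) and the conditional
#' probability of being above the threshold at the next age (bottom), with
#' below-threshold curves in red and above-threshold in blue.  Vertical green
#' lines mark estimation-segment seams when recorded.
#'
#' @param x a [rateset].
#' @param ... passed to [graphics::matplot].
#' @export
plot.rateset <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  seams <- attr(x, "seams")
  graphics::matplot(x$age, cbind(x$s1, x$s2), type = "l", lty = 1,
                    col = c("red", "blue"), xlab = "age",
                    ylab = "annual survival", main = "Survival by state", ...)
  if (!is.null(seams)) graphics::abline(v = seams, col = "darkgreen", lty = 2)
  graphics::legend("bottomleft", c("below threshold", "above threshold"),
                   col = c("red", "blue"), lty = 1, bty = "n")
  graphics::matplot(x$age, cbind(x$t21, x$t22), type = "l", lty = 1,
                    col = c("red", "blue"), xlab = "age",
                    ylab = "P(above at x+1 | survive)",
                    main = "Conditional transition to above-threshold", ...)
  if (!is.null(seams)) graphics::abline(v = seams, col = "darkgreen", lty = 2)
  invisible(x)
}
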