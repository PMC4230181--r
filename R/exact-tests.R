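#' @include AllClasses.R
#' @importFrom stats dhyper binom.test
NULL

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computes the two-sided exact p-value as the sum of hypergeometric
#' probabilities, over all tables with the observed margins, whose point
#' probability does not exceed that of the observed table (with a relative
#' tie tolerance of 1e-7, so tables tied with the observed one up to
#' rounding are included).  This is the standard two-sided convention for
#' comparing observed association counts against the random expectation.
#'
#' @param tab a 2x2 matrix (or something coercible to one) of non-negative
#'   counts; row 1 is conventionally the observed (associated, not
#'   associated) split and row 2 the expected one.
#' @return The two-sided p-value.
#' @examples
#' fisherExactTwoSided(matrix(c(27, 173, 20, 180), 2, byrow = TRUE))
#' @export
fisherExactTwoSided <- function(tab) {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L)))
    stop("tab must be a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table entries must be non-negative integers", call. = FALSE)
  if (sum(tab) == 0)
    stop("table must contain at least one observation", call. = FALSE)
  a <- tab[1, 1]
  m <- tab[1, 1] + tab[2, 1]   # column-1 margin
  n <- tab[1, 2] + tab[2, 2]   # column-2 margin
  k <- tab[1, 1] + tab[1, 2]   # row-1 margin
  support <- max(0, k - n):min(k, m)
  d <- dhyper(support, m, n, k)
  p0 <- dhyper(a, m, n, k)
  min(1, sum(d[d <= p0 * (1 + 1e-7)]))
}

#' Significance tier of a p-value
#'
#' Maps a p-value to the conventional star annotation: \code{"***"} for
#' p < 0.001, \code{"**"} for p < 0.01, \code{"*"} for p < 0.05 and \code{""}
#' otherwise (strict inequalities).
#'
#' @param p a p-value in \[0, 1\].
#' @return One of \code{""}, \code{"*"}, \code{"**"}, \code{"***"}.
#' @examples
#' significanceStars(0.04)
#' @export
significanceStars <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("p must be a single probability in [0, 1]", call. = FALSE)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Compare an observed frequency against a null expectation
#'
#' Builds the 2x2 table \code{rbind(c(k, n - k), c(k0, n - k0))} with
#' \code{k0 = round(nullPercent * n / 100)} — the expected associated count
#' at the same sample size — and tests it with the two-sided Fisher's exact
#' test (default).  Alternatively (\code{method = "binomial"}) the observed
#' count is tested directly against the fixed null proportion with an exact
#' binomial test; the null is then treated as known rather than as a second
#' sample of size \code{n}.
#'
#' @param observed a [FrequencySummary-class] (or a list with \code{k} and
#'   \code{n}).
#' @param nullPercent null expectation in percent, in \[0, 100\] — e.g. a
#'   [referenceNull()] constant or [percent()] of an [estimateNull()] run.
#' @param method \code{"fisher"} (default) or \code{"binomial"}.
#' @return A [TestResult-class] with the table, p-value and star tier.
#' @examples
#' obs <- FrequencySummary("association:F28P5-T29H11", 27, 200)
#' compareToNull(obs, referenceNull("2C", "trans"))
#' @export
compareToNull <- function(observed, nullPercent,
                          method = c("fisher", "binomial")) {
  method <- match.arg(method)
  if (is(observed, "FrequencySummary")) {
    k <- successes(observed); n <- trials(observed)
  } else {
    k <- as.integer(observed$k); n <- as.integer(observed$n)
  }
  if (n < 1L) stop("observed frequency must have n >= 1", call. = FALSE)
  if (!is.numeric(nullPercent) || nullPercent < 0 || nullPercent > 100)
    stop("nullPercent must lie in [0, 100]", call. = FALSE)
  k0 <- as.integer(round(nullPercent * n / 100))
  tab <- matrix(c(k, n - k, k0, n - k0), nrow = 2, byrow = TRUE,
                dimnames = list(c("observed", "expected"),
                                c("associated", "not_associated")))
  p <- switch(method,
    fisher = fisherExactTwoSided(tab),
    binomial = binom.test(k, n, p = nullPercent / 100,
                          alternative = "two.sided")$p.value)
  new("TestResult", table = tab, pValue = p, stars = significanceStars(p))
}
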