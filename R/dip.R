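# Hartigan & Hartigan's dip statistic for unimodality: the largest
# vertical distance between the empirical cdf and the closest unimodal cdf
# (convex left of its mode, concave right of it, an atom permitted at the
# mode). Computed exactly by bisecting on the tube half-width around the
# empirical cdf and testing, in compiled code, whether a unimodal cdf fits
# inside the tube: each candidate mode splits the points into a convex and
# a concave side, each side is checked against the pointwise-minimal
# convex (maximal concave) envelope compatible with the tube, and the two
# sides must join monotonically at the mode.

#' Hartigan dip statistic
#'
#' The dip of the empirical distribution of `x`: the maximum difference
#' between the empirical cdf and the unimodal cdf closest to it. Large
#' values indicate multimodality; the smallest possible value is
#' `1 / (2 n)` (attained e.g. by equally spaced data) and the supremum is
#' 1/4 (approached by two well-separated point masses).
#'
#' @param x Numeric vector (n >= 1). Heavily tied samples have a
#'   degenerate dip; jitter count data before testing.
#' @param tol Bisection tolerance on the dip (default 1e-8).
#' @return The dip statistic, a number in `[1/(2n), 1/4]`.
#' @examples
#' dip_statistic(runif(100))                    # small: unimodal
#' dip_statistic(c(rnorm(100), rnorm(100, 8)))  # large: bimodal
#' @export
dip_statistic <- function(x, tol = 1e-8) {
  t <- sort(as.numeric(x))
  n <- length(t)
  if (n < 1) stop("empty sample", call. = FALSE)
  if (n < 2 || t[n] == t[1]) return(0.5 / n)
  # bisect on the tube half-width in count units, e in [0.5, n/4]
  lo <- 0.5
  hi <- n / 4
  if (.dip_feasible_cpp(t, lo)) return(0.5 / n)
  while ((hi - lo) / n > tol) {
    mid <- (lo + hi) / 2
    if (.dip_feasible_cpp(t, mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2 / n
}
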