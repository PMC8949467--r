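#' First-order statistics of a value distribution
#'
#' Computes the 13-statistic first-order panel used for both the HSV colour
#' channels and the wavelet subbands: `mean`, `median`, `min`, `max`,
#' `range`, `variance`, `mean_absolute_deviation`, `root_mean_square`,
#' `skewness`, `kurtosis`, `energy`, `entropy`, `uniformity`.
#'
#' Moment statistics are computed on the raw values (population variance;
#' skewness and kurtosis as standardised third and fourth moments, kurtosis
#' without the excess-3 correction; both defined as 0 for zero-variance
#' input). `energy` is the mean squared value. `entropy` (base 2, with
#' `0*log 0 = 0`) and `uniformity` (sum of squared bin probabilities) are
#' computed on an equal-width histogram of `n_bins` bins spanning the
#' observed `[min, max]`; constant input occupies a single bin, giving
#' entropy 0 and uniformity 1.
#'
#' @param values Numeric vector (or matrix/array, flattened) of observations.
#' @param n_bins Number of histogram bins for entropy/uniformity (default 32).
#' @return A named numeric vector of length 13.
#' @export
first_order_stats <- function(values, n_bins = 32L) {
  x <- as.numeric(values)
  if (length(x) == 0L) abort("first_order_stats() requires a non-empty input.")
  if (anyNA(x)) abort("first_order_stats() input contains missing values.")
  stopifnot(n_bins >= 1L)

  m <- mean(x)
  v <- mean((x - m)^2)                      # population variance
  s <- sqrt(v)
  mn <- min(x); mx <- max(x)

  if (s > 0) {
    skew <- mean((x - m)^3) / s^3
    kurt <- mean((x - m)^4) / s^4
  } else {
    skew <- 0; kurt <- 0                    # degenerate-moment convention
  }

  p <- histogram_probs(x, n_bins)
  c(mean = m,
    median = median(x),
    min = mn,
    max = mx,
    range = mx - mn,
    variance = v,
    mean_absolute_deviation = mean(abs(x - m)),
    root_mean_square = sqrt(mean(x^2)),
    skewness = skew,
    kurtosis = kurt,
    energy = mean(x^2),
    entropy = -sum(p[p > 0] * log2(p[p > 0])),
    uniformity = sum(p^2))
}

# Equal-width bin probabilities over [min(x), max(x)]; the max value falls in
# the last bin. A zero-range input occupies one bin with probability 1.
histogram_probs <- function(x, n_bins) {
  rng <- max(x) - min(x)
  if (rng == 0 || n_bins == 1L) return(1)
  bin <- pmin(floor((x - min(x)) / rng * n_bins) + 1L, n_bins)
  tabulate(bin, nbins = n_bins) / length(x)
}
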