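#' One-level 2D wavelet decomposition and subband features
#'
#' A single-level separable 2D discrete wavelet transform with the 8-tap
#' least-asymmetric Daubechies orthonormal filter pair splits each grayscale
#' tile into four quarter-size subbands (LL, LH, HL, HH); the 13 first-order
#' statistics per subband give the pipeline's 52 wavelet features.
#'
#' @name wavelet-features
NULL

# 8-tap least-asymmetric Daubechies scaling (low-pass) filter. Defining
# properties (unit l2 norm, sum sqrt(2), vanishing moments of the QMF
# high-pass partner) are unit tested.
LA8_DEC_LO <- c(-0.0757657147892733, -0.0296355276459985,
                 0.4976186676320155,  0.8037387518059161,
                 0.2978577956052774, -0.0992195435768472,
                -0.0126039672620378,  0.0322231006040427)

# Quadrature-mirror high-pass partner: g[k] = (-1)^k h[L-1-k], k = 0..L-1.
LA8_DEC_HI <- rev(LA8_DEC_LO) * c(1, -1)

# N/2 x N analysis operator for one filter under periodic extension:
# row n applies the filter at shift 2(n-1). For even N >= 8 the stacked
# low/high operator is orthogonal, giving exact reconstruction and energy
# conservation.
wavelet_operator <- function(n, filt) {
  taps <- length(filt)
  w <- matrix(0, n %/% 2L, n)
  for (k in seq_len(taps)) {
    cols <- (2L * (seq_len(n %/% 2L) - 1L) + (k - 1L)) %% n + 1L
    w[cbind(seq_len(n %/% 2L), cols)] <- w[cbind(seq_len(n %/% 2L), cols)] + filt[k]
  }
  w
}

check_dwt_dims <- function(x) {
  d <- dim(x)
  if (any(d < 8L)) {
    abort(sprintf(
      "dwt2() needs at least 8 pixels per dimension (filter length 8); got %d x %d.",
      d[1], d[2]))
  }
  if (any(d %% 2L != 0L)) {
    abort(sprintf(
      "dwt2() requires even dimensions for the periodized transform; got %d x %d.",
      d[1], d[2]))
  }
}

#' One-level 2D discrete wavelet transform
#'
#' Separable one-level transform with the LA8 orthonormal filter pair and
#' periodic boundary extension. Columns are filtered first, then rows; the
#' four half-size coefficient planes are `ll` (low/low), `lh` (low rows,
#' high columns), `hl` (high rows, low columns), `hh` (high/high). Because
#' the periodized operator is orthogonal, [idwt2()] reconstructs the input
#' exactly (to numerical precision) and total squared-coefficient energy
#' equals the input energy.
#'
#' @param x Numeric matrix with even dimensions, each at least 8.
#' @return An object of class `rrf_dwt`: a list of the four subband
#'   matrices, each `nrow(x)/2 x ncol(x)/2`.
#' @export
dwt2 <- function(x) {
  stopifnot(is.matrix(x))
  check_dwt_dims(x)
  wl_r <- wavelet_operator(nrow(x), LA8_DEC_LO)
  wh_r <- wavelet_operator(nrow(x), LA8_DEC_HI)
  wl_c <- wavelet_operator(ncol(x), LA8_DEC_LO)
  wh_c <- wavelet_operator(ncol(x), LA8_DEC_HI)
  lo <- wl_r %*% x      # low-pass down the rows dimension
  hi <- wh_r %*% x
  structure(
    list(ll = lo %*% t(wl_c), lh = lo %*% t(wh_c),
         hl = hi %*% t(wl_c), hh = hi %*% t(wh_c)),
    class = "rrf_dwt", input_dim = dim(x))
}

#' Inverse one-level 2D discrete wavelet transform
#'
#' @param subbands An `rrf_dwt` object from [dwt2()].
#' @return The reconstructed matrix.
#' @export
idwt2 <- function(subbands) {
  stopifnot(inherits(subbands, "rrf_dwt"))
  d <- attr(subbands, "input_dim")
  wl_r <- wavelet_operator(d[1], LA8_DEC_LO)
  wh_r <- wavelet_operator(d[1], LA8_DEC_HI)
  wl_c <- wavelet_operator(d[2], LA8_DEC_LO)
  wh_c <- wavelet_operator(d[2], LA8_DEC_HI)
  lo <- subbands$ll %*% wl_c + subbands$lh %*% wh_c
  hi <- subbands$hl %*% wl_c + subbands$hh %*% wh_c
  t(wl_r) %*% lo + t(wh_r) %*% hi
}

#' @export
print.rrf_dwt <- function(x, ...) {
  cat(sprintf("<rrf_dwt> 1-level LA8 decomposition: 4 subbands of %d x %d\n",
              nrow(x$ll), ncol(x$ll)))
  invisible(x)
}

#' Wavelet features of a tile
#'
#' Luminance conversion, one-level LA8 decomposition, then the 13
#' first-order statistics of [first_order_stats()] on the coefficients of
#' each subband: 52 features named `wavelet.<subband>.<stat>`.
#'
#' @inheritParams tile_to_hsv
#' @param n_bins Histogram bins for the entropy/uniformity statistics.
#' @return Named numeric vector of length 52.
#' @export
wavelet_features <- function(tile, n_bins = 32L) {
  sb <- dwt2(tile_to_gray(tile))
  out <- purrr::imap(unclass(sb), function(plane, band) {
    stats <- first_order_stats(plane, n_bins = n_bins)
    setNames(stats, paste("wavelet", band, names(stats), sep = "."))
  })
  unlist(unname(out))
}
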