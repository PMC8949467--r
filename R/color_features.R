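#' HSV conversion and colour features
#'
#' Gomori trichrome renders muscle fibers blue-green and mitochondrial
#' accumulations red, so hue/saturation carry most of the class signal;
#' tiles are converted from RGB to HSV and summarised channel-wise.
#'
#' @name color-features
NULL

#' Convert a tile to HSV channel planes
#'
#' Standard RGB to HSV mapping with all three channels scaled to `[0, 1]`
#' (hue wraps on `[0, 1)`). Achromatic pixels get saturation 0 and, for
#' black, hue 0 by convention.
#'
#' @param tile An `rrf_tile` (or a `S x S x 3` array on the 0-255 scale).
#' @return A list with matrices `h`, `s`, `v`, each the tile's spatial size.
#' @export
tile_to_hsv <- function(tile) {
  px <- tile_pixels(tile)
  d <- dim(px)[1:2]
  rgb <- matrix(aperm(px, c(3, 1, 2)), nrow = 3)   # 3 x N, column per pixel
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  list(h = matrix(hsv["h", ], d[1], d[2]),
       s = matrix(hsv["s", ], d[1], d[2]),
       v = matrix(hsv["v", ], d[1], d[2]))
}

tile_pixels <- function(tile) {
  px <- if (inherits(tile, "rrf_tile")) tile$pixels else tile
  if (!(is.array(px) && length(dim(px)) == 3L && dim(px)[3] == 3L)) {
    abort("Expected an rrf_tile or an S x S x 3 pixel array.")
  }
  px
}

#' Colour features of a tile
#'
#' The 13 first-order statistics of [first_order_stats()] computed on each
#' HSV channel, 39 features named `color.<channel>.<stat>`.
#'
#' @inheritParams tile_to_hsv
#' @param n_bins Histogram bins for the entropy/uniformity statistics.
#' @return Named numeric vector of length 39.
#' @export
color_features <- function(tile, n_bins = 32L) {
  hsv <- tile_to_hsv(tile)
  out <- purrr::imap(hsv, function(plane, ch) {
    stats <- first_order_stats(plane, n_bins = n_bins)
    setNames(stats, paste("color", ch, names(stats), sep = "."))
  })
  unlist(unname(out))
}
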