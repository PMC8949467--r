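#' Feature extraction pipeline
#'
#' Each tile is summarised by a fixed-order vector of 134 features: 39
#' colour (`color.*`), 43 texture (`texture.*`) and 52 wavelet
#' (`wavelet.*`). Feature names are part of the public contract — trained
#' models refuse to predict on a table whose columns do not match.
#'
#' @name feature-pipeline
NULL

#' Extract the 134-feature vector of one tile
#'
#' @inheritParams tile_to_hsv
#' @param n_bins Histogram bins for first-order entropy/uniformity.
#' @param n_levels Gray levels for texture quantization.
#' @param delta GLCM offset distance in pixels.
#' @return Named numeric vector of length 134 (39 colour, 43 texture, 52
#'   wavelet, in that order).
#' @export
extract_features <- function(tile, n_bins = 32L, n_levels = 32L, delta = 1L) {
  v <- c(color_features(tile, n_bins = n_bins),
         texture_features(tile, n_levels = n_levels, delta = delta),
         wavelet_features(tile, n_bins = n_bins))
  bad <- names(v)[!is.finite(v)]
  if (length(bad) > 0) {
    abort(paste0("Non-finite feature value(s): ", paste(bad, collapse = ", ")))
  }
  v
}

#' Extract a feature table for a set of tiles
#'
#' @param tiles A list of `rrf_tile` objects.
#' @param ... Passed on to [extract_features()].
#' @return A tibble with `tile_id`, `label`, and 134 feature columns, one
#'   row per tile in input order.
#' @export
extract_feature_table <- function(tiles, ...) {
  stopifnot(length(tiles) > 0)
  rows <- purrr::map(tiles, function(t) {
    c(list(tile_id = t$tile_id, label = t$label),
      as.list(extract_features(t, ...)))
  })
  purrr::map_dfr(rows, as_tibble)
}

feature_columns <- function(table) {
  grep("^(color|texture|wavelet)\\.", names(table), value = TRUE)
}

#' Fit a z-score normalization record
#'
#' Per-feature mean and population standard deviation over the given rows —
#' fit this on the training split only and apply it everywhere, so held-out
#' folds and the test split never leak into the normalization.
#'
#' @param table A feature table from [extract_feature_table()].
#' @param rows Integer row indices to fit on (default: all rows).
#' @return A tibble with columns `feature`, `mean`, `sd`.
#' @export
zscore_fit <- function(table, rows = seq_len(nrow(table))) {
  if (length(rows) == 0L) abort("zscore_fit() needs a non-empty row set.")
  feats <- feature_columns(table)
  x <- as.matrix(table[rows, feats, drop = FALSE])
  mu <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2, mu)^2))  # population SD
  tibble(feature = feats, mean = unname(mu), sd = unname(sdev))
}

#' Apply a z-score normalization record
#'
#' Maps every feature to `(x - mean) / sd`; features with zero training SD
#' map to 0.
#'
#' @inheritParams zscore_fit
#' @param record A record from [zscore_fit()].
#' @return The table with feature columns standardized.
#' @export
zscore_apply <- function(table, record) {
  feats <- feature_columns(table)
  if (!setequal(feats, record$feature)) {
    off <- c(setdiff(feats, record$feature), setdiff(record$feature, feats))
    abort(paste0("Feature columns do not match the normalization record: ",
                 paste(head(off, 10), collapse = ", ")))
  }
  rec <- record[match(feats, record$feature), ]
  x <- as.matrix(table[, feats, drop = FALSE])
  z <- sweep(x, 2, rec$mean)
  z <- sweep(z, 2, ifelse(rec$sd > 0, rec$sd, 1), "/")
  z[, rec$sd == 0] <- 0
  table[feats] <- as_tibble(z)
  table
}

#' Read or write a feature table as CSV
#'
#' Comma-separated text with a header: `tile_id`, `label`, then the 134
#' feature columns.
#'
#' @param table A feature table.
#' @param path File path.
#' @return `read_feature_table()` returns the tibble; `write_feature_table()`
#'   returns it invisibly.
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(table)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    tile_id = readr::col_character(), label = readr::col_character(),
    .default = readr::col_double()
  ))
}
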