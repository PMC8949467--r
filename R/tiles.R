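#' Acquisition images and tiles
#'
#' An acquisition image is a full microscopy field (nominally 1653 x 1239 px
#' at 20x magnification); a tile is one 110 x 110 px sub-image cut from its
#' regular grid. Both store 8-bit RGB intensities in `[0, 255]` as a
#' `H x W x 3` numeric array.
#'
#' @name rrf-images
NULL

new_acquisition_image <- function(pixels, source_id) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  structure(
    list(pixels = pixels, source_id = source_id,
         height = dim(pixels)[1], width = dim(pixels)[2]),
    class = "rrf_image"
  )
}

#' @export
print.rrf_image <- function(x, ...) {
  cat(sprintf("<rrf_image> %s: %d x %d px, 3 channels\n",
              x$source_id, x$width, x$height))
  invisible(x)
}

new_tile <- function(pixels, grid_row = 0L, grid_col = 0L,
                     source_id = "tile", label = "unlabeled",
                     tile_id = NULL) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  label <- normalize_label(label)
  structure(
    list(pixels = pixels, grid_row = as.integer(grid_row),
         grid_col = as.integer(grid_col), source_id = source_id,
         label = label,
         tile_id = tile_id %||%
           sprintf("%s_r%02d_c%02d", source_id, grid_row, grid_col)),
    class = "rrf_tile"
  )
}

#' @export
print.rrf_tile <- function(x, ...) {
  cat(sprintf("<rrf_tile> %s [%s]: %d x %d px at grid (%d, %d)\n",
              x$tile_id, x$label, dim(x$pixels)[1], dim(x$pixels)[2],
              x$grid_row, x$grid_col))
  invisible(x)
}

# Case-folds free-text labels ("Not Ragged", "not-ragged") to the canonical
# lower-snake vocabulary; manifests are hand-edited so this is forgiving on
# purpose. Unknown tokens are an error at the call site that validates.
normalize_label <- function(label) {
  out <- gsub("[ -]+", "_", tolower(trimws(as.character(label))))
  out[out == ""] <- "unlabeled"
  out
}

#' Read an RGB acquisition image from disk
#'
#' Reads a JPEG or PNG raster into an acquisition-image object. Grayscale
#' rasters are replicated to three channels; an alpha channel, if present,
#' is dropped. Intensities are returned on the 8-bit `[0, 255]` scale.
#'
#' @param path Path to a `.jpg`/`.jpeg` or `.png` file.
#' @param source_id Identifier recorded on the image and inherited by its
#'   tiles. Defaults to the file name without extension.
#' @return An `rrf_image` object (fields `pixels`, `source_id`, `width`,
#'   `height`).
#' @export
load_image <- function(path, source_id = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("Cannot read image: file '%s' does not exist.", path))
  }
  ext <- tolower(tools::file_ext(path))
  reader <- switch(ext,
    jpg = , jpeg = jpeg::readJPEG,
    png = png::readPNG,
    abort(sprintf("Unsupported image format '.%s' for '%s' (expected JPEG or PNG).",
                  ext, path))
  )
  raw <- tryCatch(reader(path), error = function(e) {
    abort(sprintf("File '%s' is not a valid %s image: %s",
                  path, toupper(ext), conditionMessage(e)))
  })
  px <- raster_to_rgb255(raw)
  new_acquisition_image(px, source_id %||% tools::file_path_sans_ext(basename(path)))
}

# [0,1] decoded raster (matrix or H x W x {1,2,3,4}) -> H x W x 3 in [0,255]
raster_to_rgb255 <- function(raw) {
  if (is.matrix(raw)) raw <- array(raw, dim = c(dim(raw), 1L))
  nc <- dim(raw)[3]
  px <- if (nc >= 3L) raw[, , 1:3, drop = FALSE]
        else array(raw[, , 1L], dim = c(dim(raw)[1:2], 3L))
  round(px * 255)
}

#' Cut an acquisition image into its tile grid
#'
#' Cuts the image into non-overlapping `tile_side x tile_side` tiles anchored
#' at the top-left corner; residual right and bottom margins narrower than one
#' tile are discarded. A 1653 x 1239 acquisition therefore yields the
#' 15 x 11 = 165 tile grid used throughout the pipeline. Tiles are returned
#' in row-major order with 0-based grid coordinates: tile `(r, c)` covers
#' pixel rows `[r*S, (r+1)*S)` and columns `[c*S, (c+1)*S)`.
#'
#' @param img An `rrf_image` from [load_image()] (or a `H x W x 3` array).
#' @param tile_side Tile side length in pixels (default 110).
#' @return A list of `rrf_tile` objects, empty (with a warning) when the
#'   image is smaller than one tile in either dimension.
#' @export
tile_image <- function(img, tile_side = 110L) {
  stopifnot(tile_side >= 1L)
  if (is.array(img) && length(dim(img)) == 3L) {
    img <- new_acquisition_image(img, "image")
  }
  stopifnot(inherits(img, "rrf_image"))
  s <- as.integer(tile_side)
  n_rows <- img$height %/% s
  n_cols <- img$width %/% s
  if (n_rows == 0L || n_cols == 0L) {
    warn(sprintf("Image '%s' (%d x %d) is smaller than one %d px tile; skipping.",
                 img$source_id, img$width, img$height, s))
    return(list())
  }
  grid <- expand.grid(col = seq_len(n_cols) - 1L, row = seq_len(n_rows) - 1L)
  purrr::map2(grid$row, grid$col, function(r, co) {
    new_tile(img$pixels[r * s + seq_len(s), co * s + seq_len(s), , drop = FALSE],
             grid_row = r, grid_col = co, source_id = img$source_id)
  })
}

#' Tile manifests
#'
#' A manifest is the tabular index of a tile set: one row per tile with
#' columns `tile_id`, `source_id`, `grid_row`, `grid_col`, `label`. Labels
#' are drawn from `ragged`, `not_ragged`, `waste`, or `unlabeled`; tokens are
#' case-folded to that vocabulary on read (e.g. `"Not Ragged"` ->
#' `"not_ragged"`).
#'
#' @param tiles A list of `rrf_tile` objects.
#' @return A tibble with the five manifest columns.
#' @export
tile_manifest <- function(tiles) {
  validate_manifest(purrr::map_dfr(tiles, function(t) {
    tibble(tile_id = t$tile_id, source_id = t$source_id,
           grid_row = t$grid_row, grid_col = t$grid_col, label = t$label)
  }))
}

manifest_cols <- c("tile_id", "source_id", "grid_row", "grid_col", "label")

validate_manifest <- function(m) {
  missing <- setdiff(manifest_cols, names(m))
  if (length(missing) > 0) {
    abort(paste0("Manifest is missing column(s): ", paste(missing, collapse = ", ")))
  }
  m$label <- normalize_label(m$label)
  bad <- setdiff(unique(m$label), .rrf_labels_ext)
  if (length(bad) > 0) {
    abort(paste0("Unknown label token(s) in manifest: ",
                 paste(sQuote(bad), collapse = ", "),
                 ". Expected ragged, not_ragged, waste or unlabeled."))
  }
  dup <- unique(m$tile_id[duplicated(m$tile_id)])
  if (length(dup) > 0) {
    abort(paste0("Duplicate tile_id(s) in manifest: ",
                 paste(sQuote(head(dup, 10)), collapse = ", ")))
  }
  m$grid_row <- as.integer(m$grid_row)
  m$grid_col <- as.integer(m$grid_col)
  as_tibble(m[manifest_cols])
}

#' @rdname tile_manifest
#' @param path Path of a comma-separated manifest file with header
#'   `tile_id,source_id,grid_row,grid_col,label`.
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, col_types = readr::cols(
    tile_id = readr::col_character(), source_id = readr::col_character(),
    grid_row = readr::col_integer(), grid_col = readr::col_integer(),
    label = readr::col_character()
  ))
  validate_manifest(m)
}

#' @rdname tile_manifest
#' @param manifest A manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  manifest <- validate_manifest(manifest)
  readr::write_csv(manifest, path)
  invisible(manifest)
}

#' Plot a tile
#'
#' Renders the RGB pixels of one tile with ggplot2, mainly for inspecting
#' synthetic fixtures and misclassified tiles.
#'
#' @param tile An `rrf_tile`.
#' @return A ggplot object.
#' @export
plot_tile <- function(tile) {
  stopifnot(inherits(tile, "rrf_tile"))
  px <- tile$pixels / 255
  ggplot2::ggplot() +
    ggplot2::annotation_raster(grDevices::rgb(px[, , 1], px[, , 2], px[, , 3]) |>
                                 matrix(nrow = dim(px)[1]),
                               xmin = 0, xmax = dim(px)[2],
                               ymin = 0, ymax = dim(px)[1]) +
    ggplot2::coord_fixed(xlim = c(0, dim(px)[2]), ylim = c(0, dim(px)[1]),
                         expand = FALSE) +
    ggplot2::labs(title = sprintf("%s [%s]", tile$tile_id, tile$label)) +
    ggplot2::theme_void()
}
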