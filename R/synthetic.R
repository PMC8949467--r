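#' Synthetic trichrome-like tile generation
#'
#' Generates labelled 110 x 110 RGB tiles emulating the three tile classes
#' of a Gomori trichrome-stained muscle field: `not_ragged` — a green-hued
#' mosaic of fiber cross-sections; `ragged` — the same mosaic plus a
#' contiguous red, speckled subsarcolemmal rim; `waste` — pale background
#' with dark artifact blobs (bubbles, folds). A separation scalar `s`
#' interpolates every class-specific parameter toward the across-class
#' mean, so at `s = 0` the three generators are identical (labels carry no
#' information) and at `s = 1` the classes are maximally distinct.
#'
#' @name synthetic-data
NULL

# Per-class generator parameters at full separation (s = 1). Hue/sat/val on
# [0, 1]; noise_sd on the 0-255 intensity scale; rim_frac is the target
# fraction of tile pixels covered by the rim annulus.
.synthetic_class_params <- list(
  not_ragged = c(fiber_hue = 0.42, fiber_sat = 0.45, fiber_val = 0.58,
                 cell_jitter = 0.05, n_fibers = 11, boundary_dark = 0.22,
                 rim_frac = 0, rim_hue = 0.42, rim_sat = 0.45,
                 rim_val = 0.58, rim_speckle = 0, n_artifacts = 0),
  ragged     = c(fiber_hue = 0.42, fiber_sat = 0.45, fiber_val = 0.58,
                 cell_jitter = 0.05, n_fibers = 11, boundary_dark = 0.22,
                 rim_frac = 0.22, rim_hue = 0.98, rim_sat = 0.75,
                 rim_val = 0.50, rim_speckle = 0.35, n_artifacts = 0),
  waste      = c(fiber_hue = 0.36, fiber_sat = 0.06, fiber_val = 0.93,
                 cell_jitter = 0.02, n_fibers = 11, boundary_dark = 0.03,
                 rim_frac = 0, rim_hue = 0.36, rim_sat = 0.06,
                 rim_val = 0.93, rim_speckle = 0, n_artifacts = 3)
)

#' Configuration of the synthetic tile generator
#'
#' @param separation Class-separation scalar `s` in `[0, 1]`: parameters of
#'   class `c` are `(1 - s) * mean + s * par_c` where `mean` averages the
#'   three classes, so `s = 0` collapses all classes onto one common
#'   generator.
#' @param tile_side Tile side in pixels (default 110).
#' @param noise_sd SD of additive Gaussian pixel noise, 0-255 intensity
#'   units (default 6).
#' @param rim_frac_range Declared admissible range of the ragged-rim pixel
#'   fraction at `s = 1`.
#' @return An `rrf_synth_config` list.
#' @export
synthetic_config <- function(separation = 1, tile_side = 110L, noise_sd = 6,
                             rim_frac_range = c(0.10, 0.35)) {
  stopifnot(separation >= 0, separation <= 1, tile_side >= 16L, noise_sd >= 0)
  common <- purrr::reduce(.synthetic_class_params, `+`) /
    length(.synthetic_class_params)
  params <- purrr::map(.synthetic_class_params, function(p) {
    (1 - separation) * common + separation * p
  })
  structure(list(separation = separation, tile_side = as.integer(tile_side),
                 noise_sd = noise_sd, rim_frac_range = rim_frac_range,
                 params = params),
            class = "rrf_synth_config")
}

#' Generate one labelled synthetic tile
#'
#' Rendering is identical for all labels and driven only by the label's
#' interpolated parameter vector: a seeded Voronoi mosaic of fiber
#' cross-sections with darkened boundaries, an optional red speckled rim
#' annulus (area set by `rim_frac`), optional dark artifact blobs, then HSV
#' to RGB conversion and additive Gaussian noise.
#'
#' @param label One of `ragged`, `not_ragged`, `waste`.
#' @param cfg An [synthetic_config()].
#' @param seed Optional integer seed; when given, the tile is a
#'   deterministic function of `(label, cfg, seed)`.
#' @param tile_id,source_id,grid_row,grid_col Metadata stored on the tile.
#' @return An `rrf_tile`.
#' @export
generate_tile <- function(label, cfg = synthetic_config(), seed = NULL,
                          tile_id = NULL, source_id = "synthetic",
                          grid_row = 0L, grid_col = 0L) {
  label <- normalize_label(label)
  if (!label %in% .rrf_labels) {
    abort(sprintf("Unknown tile class '%s'; expected ragged, not_ragged or waste.",
                  label))
  }
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  p <- cfg$params[[label]]
  s <- cfg$tile_side
  n <- s * s
  xs <- matrix(rep(seq_len(s), each = s), s, s)   # column coordinate
  ys <- matrix(rep(seq_len(s), times = s), s, s)  # row coordinate

  # Voronoi fiber mosaic: nearest of k seed points, per-cell colour jitter
  k <- max(2L, as.integer(round(p[["n_fibers"]])))
  cx <- runif(k, 1, s); cy <- runif(k, 1, s)
  d2 <- vapply(seq_len(k),
               function(i) as.vector((xs - cx[i])^2 + (ys - cy[i])^2),
               numeric(n))
  nearest <- max.col(-d2, ties.method = "first")
  d_first <- d2[cbind(seq_len(n), nearest)]
  d2[cbind(seq_len(n), nearest)] <- Inf
  d_second <- do.call(pmin, lapply(seq_len(k), function(i) d2[, i]))
  gap <- sqrt(d_second) - sqrt(d_first)

  jit <- p[["cell_jitter"]]
  hue <- (p[["fiber_hue"]] + rnorm(k, 0, jit / 2))[nearest] %% 1
  sat <- pmin(pmax(p[["fiber_sat"]] + rnorm(k, 0, jit)[nearest], 0), 1)
  val <- pmin(pmax(p[["fiber_val"]] + rnorm(k, 0, jit)[nearest], 0), 1)

  # darken thin inter-fiber boundaries (small gap to second-nearest seed)
  boundary <- gap < 1.4
  val[boundary] <- pmax(val[boundary] - p[["boundary_dark"]], 0)

  # subsarcolemmal rim: an annulus whose area matches the target fraction
  rim_frac <- p[["rim_frac"]]
  r_out <- runif(1, 0.28, 0.38) * s
  centre <- runif(2, r_out + 2, s - r_out - 2)
  target <- rim_frac * n
  thick <- r_out - sqrt(max(r_out^2 - target / pi, 0))
  rd <- sqrt(as.vector((xs - centre[1])^2 + (ys - centre[2])^2))
  rim <- rd <= r_out & rd >= r_out - thick
  if (any(rim)) {
    hue[rim] <- (p[["rim_hue"]] + rnorm(sum(rim), 0, 0.01)) %% 1
    sat[rim] <- pmin(pmax(p[["rim_sat"]] + rnorm(sum(rim), 0, jit), 0), 1)
    val[rim] <- pmin(pmax(p[["rim_val"]] + rnorm(sum(rim), 0, jit), 0), 1)
    speckle <- rim & (runif(n) < p[["rim_speckle"]])
    val[speckle] <- pmin(pmax(val[speckle] +
                                sample(c(-0.3, 0.3), sum(speckle), TRUE), 0), 1)
  }

  # artifact blobs: dark low-saturation ellipses (bubbles, folds)
  n_art <- as.integer(round(p[["n_artifacts"]]))
  for (i in seq_len(n_art)) {
    ac <- runif(2, 0.15 * s, 0.85 * s)
    ar <- runif(2, 0.06 * s, 0.22 * s)
    th <- runif(1, 0, pi)
    dx <- as.vector(xs) - ac[1]; dy <- as.vector(ys) - ac[2]
    u <- dx * cos(th) + dy * sin(th); v <- -dx * sin(th) + dy * cos(th)
    inside <- (u / ar[1])^2 + (v / ar[2])^2 <= 1
    val[inside] <- pmax(val[inside] - runif(1, 0.35, 0.6), 0)
    sat[inside] <- sat[inside] * 0.5
  }

  rgb <- grDevices::col2rgb(grDevices::hsv(hue, sat, val))
  px <- array(0, dim = c(s, s, 3))
  px[, , 1] <- matrix(rgb[1, ], s, s)
  px[, , 2] <- matrix(rgb[2, ], s, s)
  px[, , 3] <- matrix(rgb[3, ], s, s)
  px <- px + array(rnorm(3 * n, 0, cfg$noise_sd), dim = dim(px))
  px <- round(pmin(pmax(px, 0), 255))

  new_tile(px, grid_row = grid_row, grid_col = grid_col,
           source_id = source_id, label = label, tile_id = tile_id)
}

#' Generate a labelled synthetic tile set with its manifest
#'
#' Default class counts (250 waste, 100 ragged, 138 not-ragged; 488 tiles)
#' mirror the composition of a curated RRF tile dataset. Tiles are laid out
#' on virtual 15 x 11 acquisition grids, one synthetic source image per 165
#' tiles.
#'
#' @param n_waste,n_ragged,n_not_ragged Tiles per class.
#' @param cfg An [synthetic_config()].
#' @param seed Integer seed; the whole set is a deterministic function of
#'   `(counts, cfg, seed)`.
#' @return A list with `tiles` (list of `rrf_tile`) and `manifest` (tibble).
#' @export
generate_dataset <- function(n_waste = 250L, n_ragged = 100L,
                             n_not_ragged = 138L,
                             cfg = synthetic_config(), seed = 1L) {
  stopifnot(n_waste >= 0L, n_ragged >= 0L, n_not_ragged >= 0L)
  labels <- rep(c("waste", "ragged", "not_ragged"),
                times = c(n_waste, n_ragged, n_not_ragged))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tile_seeds <- sample.int(.Machine$integer.max, max(length(labels), 1L))
  tiles <- purrr::imap(labels, function(lb, i) {
    grid_i <- (i - 1L) %% 165L
    generate_tile(lb, cfg, seed = tile_seeds[i],
                  tile_id = sprintf("sim%02d_t%04d", (i - 1L) %/% 165L + 1L, i),
                  source_id = sprintf("sim%02d", (i - 1L) %/% 165L + 1L),
                  grid_row = grid_i %/% 15L, grid_col = grid_i %% 15L)
  })
  manifest <- if (length(tiles) > 0) tile_manifest(tiles) else {
    tibble(tile_id = character(), source_id = character(),
           grid_row = integer(), grid_col = integer(), label = character())
  }
  list(tiles = tiles, manifest = manifest)
}

#' Write tiles as PNG files
#'
#' @param tiles List of `rrf_tile` objects.
#' @param dir Output directory (created if needed); one
#'   `<tile_id>.png` per tile.
#' @return Invisibly, the written paths.
#' @export
write_tiles_png <- function(tiles, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::map_chr(tiles, function(t) {
    path <- file.path(dir, paste0(t$tile_id, ".png"))
    png::writePNG(t$pixels / 255, path)
    path
  })
  invisible(paths)
}
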