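test_that("image loading round-trips PNG pixels and replicates grayscale", {
  px <- array(runif(12 * 10 * 3), dim = c(10, 12, 3))
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(px, path)
  img <- load_image(path)
  expect_s3_class(img, "rrf_image")
  expect_equal(img$width, 12)
  expect_equal(img$height, 10)
  expect_equal(img$pixels, round(px * 255))

  gray <- matrix(runif(20), 4, 5)
  gpath <- withr::local_tempfile(fileext = ".png")
  png::writePNG(gray, gpath)
  gimg <- load_image(gpath)
  expect_equal(dim(gimg$pixels), c(4, 5, 3))
  expect_equal(gimg$pixels[, , 1], gimg$pixels[, , 3])

  one <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(1, 1, 1), one)
  expect_equal(load_image(one)$pixels, array(255, dim = c(1, 1, 3)))
})

test_that("unreadable or non-image files raise informative errors", {
  expect_error(load_image("no/such/file.png"), "does not exist")
  bad <- withr::local_tempfile(fileext = ".png")
  writeLines("this is not an image", bad)
  expect_error(load_image(bad), "not a valid PNG")
  txt <- withr::local_tempfile(fileext = ".txt")
  writeLines("x", txt)
  expect_error(load_image(txt), "Unsupported image format")
})

test_that("a 1653 x 1239 acquisition yields the 15 x 11 = 165 tile grid", {
  img <- rrfdetect:::new_acquisition_image(
    array(255, dim = c(1239, 1653, 3)), "acq")
  tiles <- tile_image(img, tile_side = 110)
  expect_length(tiles, 165)
  expect_equal(max(purrr::map_int(tiles, "grid_row")), 10L)
  expect_equal(max(purrr::map_int(tiles, "grid_col")), 14L)
  expect_true(all(purrr::map_lgl(tiles, ~identical(dim(.x$pixels),
                                                   c(110L, 110L, 3L)))))
})

test_that("tile count, disjoint coverage and determinism hold on random sizes", {
  set.seed(42)
  for (i in 1:20) {
    h <- sample(1:90, 1); w <- sample(1:90, 1); s <- sample(1:40, 1)
    px <- array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
    img <- rrfdetect:::new_acquisition_image(px, "r")
    tiles <- suppressWarnings(tile_image(img, tile_side = s))
    expect_length(tiles, (h %/% s) * (w %/% s))
    if (length(tiles) > 0) {
      # each covered pixel belongs to exactly one tile, and pixel values
      # survive the cut
      cover <- matrix(0L, h, w)
      for (t in tiles) {
        rows <- t$grid_row * s + seq_len(s)
        cols <- t$grid_col * s + seq_len(s)
        cover[rows, cols] <- cover[rows, cols] + 1L
        expect_identical(t$pixels, px[rows, cols, , drop = FALSE])
      }
      expect_true(all(cover <= 1L))
      expect_equal(sum(cover), length(tiles) * s * s)
    }
  }
  img <- rrfdetect:::new_acquisition_image(
    array(sample(0:255, 50 * 60 * 3, replace = TRUE), dim = c(50, 60, 3)), "d")
  expect_identical(tile_image(img, 13), tile_image(img, 13))
})

test_that("images smaller than one tile give an empty list with a warning", {
  img <- rrfdetect:::new_acquisition_image(array(0, dim = c(330, 109, 3)), "s")
  expect_warning(tiles <- tile_image(img, 110), "smaller than one")
  expect_length(tiles, 0)
  one <- rrfdetect:::new_acquisition_image(array(0, dim = c(110, 110, 3)), "o")
  tiles1 <- tile_image(one, 110)
  expect_length(tiles1, 1)
  expect_equal(tiles1[[1]]$grid_row, 0L)
  expect_equal(tiles1[[1]]$grid_col, 0L)
})

test_that("manifests round-trip, case-fold labels and reject bad input", {
  m <- tibble::tibble(
    tile_id = c("a", "b", "c"), source_id = "img1",
    grid_row = 0:2, grid_col = c(0L, 0L, 1L),
    label = c("ragged", "not_ragged", "waste"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(m, path)
  expect_equal(read_manifest(path), m)

  # case-folding of hand-edited labels
  m2 <- m; m2$label <- c("Ragged", "Not Ragged", "WASTE")
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(m2, path2)
  expect_equal(read_manifest(path2)$label, c("ragged", "not_ragged", "waste"))

  # header-only file -> empty manifest
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("tile_id,source_id,grid_row,grid_col,label", path3)
  expect_equal(nrow(read_manifest(path3)), 0)

  expect_error(write_manifest(dplyr::mutate(m, label = "fiber"), path),
               "Unknown label")
  dup <- dplyr::bind_rows(m, m[1, ])
  expect_error(write_manifest(dup, path), "Duplicate tile_id")
})
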