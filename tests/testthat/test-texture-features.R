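test_that("luminance and quantization follow their defining formulas", {
  expect_equal(unique(as.vector(tile_to_gray(constant_tile(255)))), 255)
  expect_equal(unique(as.vector(tile_to_gray(constant_tile(0, 255, 0)))),
               0.587 * 255)
  t1 <- random_tile(side = 8, seed = 2)
  expect_equal(dim(tile_to_gray(t1)), c(8, 8))

  # bin-edge arithmetic
  g <- matrix(c(0, 85, 170, 255), 2, 2)
  expect_equal(as.vector(quantize_gray(g, 4)), 1:4)
  # constant image collapses to level 1
  expect_true(all(quantize_gray(matrix(7, 5, 5), 32) == 1L))
  # monotone in the input values
  set.seed(4)
  g2 <- matrix(runif(64, 0, 255), 8, 8)
  q2 <- quantize_gray(g2, 8)
  ord <- order(as.vector(g2))
  expect_true(all(diff(as.vector(q2)[ord]) >= 0))
})

test_that("GLCM on the 4x4 block image matches brute-force enumeration", {
  q <- block_image()
  m <- glcm_matrix(q, angle = 0)
  expect_equal(m, oracle_glcm(q, 4, angle = 0))
  p <- m / sum(m)
  expect_equal(p[1, 1], 4 / 24)
  expect_equal(unname(rrfdetect:::glcm_panel(p)["contrast"]), 1 / 3)
})

test_that("constant image gives the degenerate GLCM panel", {
  q <- quantize_gray(matrix(3, 8, 8), 32)
  f <- glcm_features(q)
  expect_length(f, 21)
  expect_equal(unname(f[c("energy", "entropy", "contrast",
                          "maximum_probability", "correlation")]),
               c(1, 0, 0, 1, 0))
})

test_that("GLRLM/GLSZM worked examples match run and zone enumeration", {
  q <- block_image()
  rl <- glrlm_matrix(q, angle = 0)
  expect_equal(sum(rl), 8)               # 8 runs, all of length 2
  expect_equal(unname(colSums(rl)[2]), 8)
  pan <- rrfdetect:::rl_panel(rl, 16)
  expect_equal(unname(pan["short_run_emphasis"]), 0.25)
  expect_equal(unname(pan["run_percentage"]), 0.5)

  const <- quantize_gray(matrix(1, 4, 4), 4)
  rlc <- glrlm_matrix(const, angle = 0)
  expect_equal(unname(rrfdetect:::rl_panel(rlc, 16)["run_percentage"]), 4 / 16)

  sz <- glszm_matrix(q)
  expect_equal(sum(sz), 4)               # 4 zones of size 4
  expect_equal(sz[cbind(1:4, 4)], rep(1L, 4))
  expect_equal(sum(col(sz) * sz), 16)    # mass conservation
})

test_that("matrix builders equal brute-force oracles on random images", {
  # moderate-size randomized equivalence check; the full 200-image sweep
  # runs in the acceptance suite
  for (seed in 1:25) {
    ng <- sample(c(2, 4, 8), 1)
    q <- random_quantized(side = 8, ng = ng, seed = seed)
    for (a in c(0, 45, 90, 135)) {
      expect_identical(glcm_matrix(q, angle = a), oracle_glcm(q, ng, angle = a))
      expect_identical(glrlm_matrix(q, angle = a), oracle_glrlm(q, ng, angle = a))
    }
    expect_identical(glszm_matrix(q), oracle_glszm(q, ng))
  }
})

test_that("normalization mass and run/zone mass conservation hold", {
  for (seed in 1:10) {
    q <- random_quantized(side = 10, ng = 6, seed = seed)
    for (a in c(0, 45, 90, 135)) {
      m <- glcm_matrix(q, angle = a)
      expect_equal(sum(m / sum(m)), 1)
      expect_equal(m, t(m))  # symmetric accumulation
      rl <- glrlm_matrix(q, angle = a)
      expect_equal(sum(col(rl) * rl), 100)
    }
    sz <- glszm_matrix(q)
    expect_equal(sum(col(sz) * sz), 100)
  }
})

test_that("GLSZM features are invariant under rotation and mirroring", {
  q <- random_quantized(side = 9, ng = 5, seed = 77)
  f <- glszm_features(q)
  expect_length(f, 11)
  rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  variants <- list(rot90(q), rot90(rot90(q)), rot90(rot90(rot90(q))),
                   q[nrow(q):1, ], q[, ncol(q):1])
  for (v in variants) {
    expect_equal(glszm_features(structure(v, n_levels = 5L)), f)
  }
})

test_that("texture_features returns the 43-feature panel tied to luminance", {
  t1 <- random_tile(side = 16, seed = 11)
  f <- texture_features(t1)
  expect_length(f, 43)
  expect_equal(sum(startsWith(names(f), "texture.glcm.")), 21)
  expect_equal(sum(startsWith(names(f), "texture.glrlm.")), 11)
  expect_equal(sum(startsWith(names(f), "texture.glszm.")), 11)

  # swapping R and B channels changes luminance, hence (generally) features;
  # swapping values that preserve luminance does not
  px <- t1$pixels
  swapped <- px[, , c(3, 2, 1)]
  expect_false(isTRUE(all.equal(
    texture_features(rrfdetect:::new_tile(swapped)), f)))
  expect_equal(texture_features(rrfdetect:::new_tile(px)), f)

  fc <- texture_features(constant_tile(90))   # one zone covering all 16x16 px
  expect_equal(unname(fc["texture.glcm.energy"]), 1)
  expect_equal(unname(fc["texture.glszm.zone_percentage"]), 1 / 256)
})

test_that("single-pixel-pair degenerate inputs error informatively", {
  q <- structure(matrix(1L, 1, 1), n_levels = 2L)
  expect_error(glcm_features(q), "No valid pixel pair")
})
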