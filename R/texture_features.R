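#' Second-order texture features
#'
#' Tiles are converted to luminance, quantized to `Ng` gray levels, and
#' summarised by three matrix families: the gray-level co-occurrence matrix
#' (GLCM; ordered pixel pairs at offset distance delta along four angles),
#' the gray-level run-length matrix (GLRLM; maximal collinear runs of equal
#' level per angle), and the gray-level size-zone matrix (GLSZM; 8-connected
#' equal-level zones, direction independent). Together they contribute the
#' 43 texture features of the pipeline (21 GLCM + 11 GLRLM + 11 GLSZM).
#'
#' @name texture-features
NULL

# (dr, dc) pixel offsets for the four standard angles, in matrix coordinates
# (row index grows downward).
.texture_offsets <- list(
  `0`   = c(0L, 1L),
  `45`  = c(-1L, 1L),
  `90`  = c(-1L, 0L),
  `135` = c(-1L, -1L)
)

#' Convert a tile to grayscale luminance
#'
#' ITU-R BT.601 luminance `0.299 R + 0.587 G + 0.114 B` on the `[0, 255]`
#' scale.
#'
#' @inheritParams tile_to_hsv
#' @return A numeric matrix of the tile's spatial size.
#' @export
tile_to_gray <- function(tile) {
  px <- tile_pixels(tile)
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

#' Quantize a grayscale image to discrete levels
#'
#' Equal-width binning of the observed `[min, max]` range into levels
#' `1..n_levels`; the maximum maps to level `n_levels` and a constant image
#' maps entirely to level 1. Quantization is monotone in the input values.
#'
#' @param gray Numeric matrix of gray values.
#' @param n_levels Number of gray levels `Ng` (default 32).
#' @return Integer matrix of levels with attribute `n_levels`.
#' @export
quantize_gray <- function(gray, n_levels = 32L) {
  stopifnot(is.matrix(gray), n_levels >= 1L)
  rng <- max(gray) - min(gray)
  q <- if (rng == 0) {
    matrix(1L, nrow(gray), ncol(gray))
  } else {
    matrix(pmin(floor((gray - min(gray)) / rng * n_levels) + 1L, n_levels),
           nrow(gray), ncol(gray))
  }
  structure(q, n_levels = as.integer(n_levels))
}

q_levels <- function(q, n_levels = NULL) {
  ng <- n_levels %||% attr(q, "n_levels") %||% max(q)
  stopifnot(all(q >= 1L), all(q <= ng))
  as.integer(ng)
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pairs of quantized levels in pixels separated by `delta`
#' steps along `angle`, accumulated symmetrically (each pair counted in both
#' directions), so the matrix satisfies `P(i,j) = P(j,i)`.
#'
#' @param q Quantized image from [quantize_gray()].
#' @param delta Offset distance in pixels (default 1).
#' @param angle One of 0, 45, 90, 135 (degrees).
#' @param n_levels Number of gray levels; taken from `q` when absent.
#' @return An `Ng x Ng` integer count matrix.
#' @export
glcm_matrix <- function(q, delta = 1L, angle = 0, n_levels = NULL) {
  ng <- q_levels(q, n_levels)
  off <- .texture_offsets[[as.character(angle)]]
  if (is.null(off)) abort("angle must be one of 0, 45, 90, 135.")
  off <- off * as.integer(delta)
  nr <- nrow(q); nc <- ncol(q)
  rs <- seq_len(nr); rs <- rs[rs + off[1] >= 1L & rs + off[1] <= nr]
  cs <- seq_len(nc); cs <- cs[cs + off[2] >= 1L & cs + off[2] <= nc]
  if (length(rs) == 0L || length(cs) == 0L) {
    return(matrix(0L, ng, ng))
  }
  i <- q[rs, cs, drop = FALSE]
  j <- q[rs + off[1], cs + off[2], drop = FALSE]
  m <- matrix(tabulate((j - 1L) * ng + i, nbins = ng * ng), ng, ng)
  m + t(m)
}

# 21-feature panel on one normalized symmetric GLCM.
glcm_panel <- function(p) {
  ng <- nrow(p)
  i <- row(p); j <- col(p)
  mu <- sum(i * p)
  sigma2 <- sum((i - mu)^2 * p)
  autocorr <- sum(i * j * p)
  cl <- i + j - 2 * mu
  d <- abs(i - j)
  # marginal distributions of i+j (k = 2..2Ng) and |i-j| (k = 0..Ng-1)
  psum <- as.vector(rowsum(as.vector(p), group = as.vector(i + j)))
  ks <- 2:(2 * ng)
  pdiff <- as.vector(rowsum(as.vector(p), group = as.vector(d)))
  kd <- 0:(ng - 1)
  sum_avg <- sum(ks * psum)
  pos <- p > 0
  c(mean = mu,
    variance = sigma2,
    autocorrelation = autocorr,
    cluster_prominence = sum(cl^4 * p),
    cluster_shade = sum(cl^3 * p),
    cluster_tendency = sum(cl^2 * p),
    contrast = sum((i - j)^2 * p),
    correlation = if (sigma2 > 0) (autocorr - mu^2) / sigma2 else 0,
    difference_entropy = -sum(pdiff[pdiff > 0] * log2(pdiff[pdiff > 0])),
    dissimilarity = sum(d * p),
    energy = sum(p^2),
    entropy = -sum(p[pos] * log2(p[pos])),
    homogeneity1 = sum(p / (1 + d)),
    homogeneity2 = sum(p / (1 + d^2)),
    idmn = sum(p / (1 + (d / ng)^2)),
    idn = sum(p / (1 + d / ng)),
    inverse_variance = sum(p[d > 0] / d[d > 0]^2),
    maximum_probability = max(p),
    sum_average = sum_avg,
    sum_entropy = -sum(psum[psum > 0] * log2(psum[psum > 0])),
    sum_variance = sum((ks - sum_avg)^2 * psum))
}

#' GLCM features averaged over the four angles
#'
#' For each angle the symmetric co-occurrence matrix is normalized to unit
#' mass and the 21-feature panel computed; features are then averaged over
#' the angles that contain at least one pixel pair.
#'
#' @inheritParams glcm_matrix
#' @param angles Angles (degrees) to average over.
#' @return Named numeric vector of 21 features.
#' @export
glcm_features <- function(q, delta = 1L, angles = c(0, 45, 90, 135),
                          n_levels = NULL) {
  panels <- purrr::map(angles, function(a) {
    m <- glcm_matrix(q, delta = delta, angle = a, n_levels = n_levels)
    if (sum(m) == 0) return(NULL)
    glcm_panel(m / sum(m))
  })
  panels <- purrr::compact(panels)
  if (length(panels) == 0L) {
    abort("No valid pixel pair for any angle; image too small for the GLCM offset.")
  }
  purrr::reduce(panels, `+`) / length(panels)
}

# Maximal runs of equal level along one angle, as (level, length) pairs.
# Rows/columns are isolated by adding a per-line offset > Ng so runs cannot
# continue across line boundaries; diagonals are grouped by (row +/- col).
runs_in_direction <- function(q, angle, ng) {
  enc <- switch(as.character(angle),
    `0`  = rle(as.vector(t(q + (seq_len(nrow(q)) - 1L) * (ng + 1L)))),
    `90` = rle(as.vector(t(t(q) + (seq_len(ncol(q)) - 1L) * (ng + 1L)))),
    `45` = diag_runs(q, row(q) + col(q)),
    `135` = diag_runs(q, row(q) - col(q)),
    abort("angle must be one of 0, 45, 90, 135.")
  )
  list(level = (enc$values - 1L) %% (ng + 1L) + 1L, length = enc$lengths)
}

diag_runs <- function(q, groups) {
  rr <- purrr::map(split(as.vector(q), as.vector(groups)), rle)
  list(values = unlist(purrr::map(rr, "values"), use.names = FALSE),
       lengths = unlist(purrr::map(rr, "lengths"), use.names = FALSE))
}

#' Gray-level run-length matrix for one angle
#'
#' `P[i, j]` counts the maximal runs of `j` consecutive pixels of level `i`
#' along the given angle; `sum(j * P[i, j])` equals the pixel count.
#'
#' @inheritParams glcm_matrix
#' @return An `Ng x Lmax` integer count matrix.
#' @export
glrlm_matrix <- function(q, angle = 0, n_levels = NULL) {
  ng <- q_levels(q, n_levels)
  runs <- runs_in_direction(q, angle, ng)
  lmax <- max(runs$length)
  matrix(tabulate((runs$length - 1L) * ng + runs$level, nbins = ng * lmax),
         ng, lmax)
}

# 11-feature run-length panel (Galloway / Chu / Dasarathy set).
rl_panel <- function(counts, n_pixels, prefix = "run") {
  i <- row(counts); j <- col(counts)
  nr <- sum(counts)
  f <- c(sum(counts / j^2), sum(counts * j^2),
         sum(rowSums(counts)^2), sum(colSums(counts)^2)) / nr
  f <- c(f, nr / n_pixels,
         sum(counts / i^2) / nr, sum(counts * i^2) / nr,
         sum(counts / (i^2 * j^2)) / nr, sum(counts * i^2 / j^2) / nr,
         sum(counts * j^2 / i^2) / nr, sum(counts * i^2 * j^2) / nr)
  names(f) <- if (prefix == "run") {
    c("short_run_emphasis", "long_run_emphasis", "gray_level_nonuniformity",
      "run_length_nonuniformity", "run_percentage",
      "low_gray_level_run_emphasis", "high_gray_level_run_emphasis",
      "short_run_low_gray_level_emphasis", "short_run_high_gray_level_emphasis",
      "long_run_low_gray_level_emphasis", "long_run_high_gray_level_emphasis")
  } else {
    c("small_area_emphasis", "large_area_emphasis", "intensity_variability",
      "size_zone_variability", "zone_percentage",
      "low_intensity_emphasis", "high_intensity_emphasis",
      "low_intensity_small_area_emphasis", "high_intensity_small_area_emphasis",
      "low_intensity_large_area_emphasis", "high_intensity_large_area_emphasis")
  }
  f
}

#' GLRLM features averaged over the four angles
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 11 features.
#' @export
glrlm_features <- function(q, angles = c(0, 45, 90, 135), n_levels = NULL) {
  np <- length(q)
  panels <- purrr::map(angles, function(a) {
    rl_panel(glrlm_matrix(q, angle = a, n_levels = n_levels), np)
  })
  purrr::reduce(panels, `+`) / length(panels)
}

#' Gray-level size-zone matrix
#'
#' Zones are 8-connected components of equal quantized level (two pixels are
#' connected when their Chebyshev distance is 1); `P[i, j]` counts zones of
#' level `i` and size `j` pixels. A single matrix covers all directions, so
#' the GLSZM — and every feature derived from it — is invariant under image
#' rotation and mirroring.
#'
#' @inheritParams glcm_matrix
#' @return An `Ng x Zmax` integer count matrix.
#' @export
glszm_matrix <- function(q, n_levels = NULL) {
  ng <- q_levels(q, n_levels)
  zones <- label_zones(q)
  zmax <- max(zones$size)
  matrix(tabulate((zones$size - 1L) * ng + zones$level, nbins = ng * zmax),
         ng, zmax)
}

# 8-connected equal-level components via an undirected adjacency graph:
# forward edges to the E, S, SE, SW neighbours where levels match.
label_zones <- function(q) {
  nr <- nrow(q); nc <- ncol(q)
  idx <- matrix(seq_along(q), nr, nc)
  edge_pairs <- function(a, b) {
    keep <- q[a] == q[b]
    rbind(a[keep], b[keep])
  }
  edges <- cbind(
    if (nc > 1L) edge_pairs(idx[, -nc], idx[, -1L]),                       # E
    if (nr > 1L) edge_pairs(idx[-nr, ], idx[-1L, ]),                       # S
    if (nr > 1L && nc > 1L) edge_pairs(idx[-nr, -nc], idx[-1L, -1L]),      # SE
    if (nr > 1L && nc > 1L) edge_pairs(idx[-nr, -1L], idx[-1L, -nc])       # SW
  )
  g <- igraph::make_graph(edges = as.vector(edges), n = length(q),
                          directed = FALSE)
  comp <- igraph::components(g)
  list(level = q[match(seq_len(comp$no), comp$membership)],
       size = comp$csize)
}

#' GLSZM features
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 11 features.
#' @export
glszm_features <- function(q, n_levels = NULL) {
  rl_panel(glszm_matrix(q, n_levels = n_levels), length(q), prefix = "zone")
}

#' All 43 texture features of a tile
#'
#' Luminance conversion, quantization to `n_levels` gray levels, then the
#' GLCM (21), GLRLM (11) and GLSZM (11) panels, named
#' `texture.<matrix>.<stat>`.
#'
#' @inheritParams tile_to_hsv
#' @param n_levels Number of gray levels (default 32).
#' @param delta GLCM offset distance in pixels (default 1).
#' @return Named numeric vector of length 43.
#' @export
texture_features <- function(tile, n_levels = 32L, delta = 1L) {
  q <- quantize_gray(tile_to_gray(tile), n_levels = n_levels)
  glcm <- glcm_features(q, delta = delta)
  glrlm <- glrlm_features(q)
  glszm <- glszm_features(q)
  c(setNames(glcm, paste0("texture.glcm.", names(glcm))),
    setNames(glrlm, paste0("texture.glrlm.", names(glrlm))),
    setNames(glszm, paste0("texture.glszm.", names(glszm))))
}
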