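# Shared fixtures and independent brute-force oracles.

# A uniform-colour tile (default mid-gray).
constant_tile <- function(r = 128, g = r, b = r, side = 16L) {
  px <- array(0, dim = c(side, side, 3))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  rrfdetect:::new_tile(px, source_id = "const")
}

random_tile <- function(side = 16L, seed = 1L) {
  set.seed(seed)
  px <- array(sample(0:255, side * side * 3, replace = TRUE),
              dim = c(side, side, 3))
  rrfdetect:::new_tile(px, source_id = "rand")
}

# The 4x4 two-by-two block image used in worked texture examples.
block_image <- function() {
  q <- matrix(c(1, 1, 2, 2,
                1, 1, 2, 2,
                3, 3, 4, 4,
                3, 3, 4, 4), 4, 4, byrow = TRUE)
  structure(q, n_levels = 4L)
}

random_quantized <- function(side = 8L, ng = 4L, seed = 1L) {
  set.seed(seed)
  structure(matrix(sample.int(ng, side * side, replace = TRUE), side, side),
            n_levels = as.integer(ng))
}

# --- Brute-force oracles (loops only; independent of the package's
# --- vectorized builders) -------------------------------------------------

oracle_offsets <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                       `90` = c(-1L, 0L), `135` = c(-1L, -1L))

# Symmetric GLCM by explicit enumeration of every pixel pair.
oracle_glcm <- function(q, ng, delta = 1L, angle = 0) {
  off <- oracle_offsets[[as.character(angle)]] * delta
  m <- matrix(0L, ng, ng)
  for (r in seq_len(nrow(q))) {
    for (c in seq_len(ncol(q))) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        i <- q[r, c]; j <- q[r2, c2]
        m[i, j] <- m[i, j] + 1L
        m[j, i] <- m[j, i] + 1L
      }
    }
  }
  m
}

# Maximal runs along one angle by walking each line pixel by pixel.
oracle_runs <- function(q, angle = 0) {
  step <- switch(as.character(angle), `0` = c(0L, 1L), `45` = c(-1L, 1L),
                 `90` = c(-1L, 0L), `135` = c(1L, 1L))
  nr <- nrow(q); nc <- ncol(q)
  inside <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc
  # line starts: cells with no predecessor along -step
  starts <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!inside(r - step[1], c - step[2])) starts[[length(starts) + 1]] <- c(r, c)
  }
  levels <- integer(0); lengths <- integer(0)
  for (st in starts) {
    r <- st[1]; c <- st[2]
    cur <- q[r, c]; len <- 0L
    while (inside(r, c)) {
      if (q[r, c] == cur) {
        len <- len + 1L
      } else {
        levels <- c(levels, cur); lengths <- c(lengths, len)
        cur <- q[r, c]; len <- 1L
      }
      r <- r + step[1]; c <- c + step[2]
    }
    levels <- c(levels, cur); lengths <- c(lengths, len)
  }
  data.frame(level = levels, length = lengths)
}

oracle_glrlm <- function(q, ng, angle = 0) {
  runs <- oracle_runs(q, angle)
  m <- matrix(0L, ng, max(runs$length))
  for (i in seq_len(nrow(runs))) {
    m[runs$level[i], runs$length[i]] <- m[runs$level[i], runs$length[i]] + 1L
  }
  m
}

# 8-connected zones by breadth-first flood fill.
oracle_zones <- function(q) {
  nr <- nrow(q); nc <- ncol(q)
  seen <- matrix(FALSE, nr, nc)
  zones <- data.frame(level = integer(0), size = integer(0))
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (seen[r0, c0]) next
    lvl <- q[r0, c0]
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE; size <- 0L
    while (length(queue) > 0) {
      cell <- queue[[1]]; queue <- queue[-1]; size <- size + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r <- cell[1] + dr; c <- cell[2] + dc
        if ((dr != 0 || dc != 0) && r >= 1 && r <= nr && c >= 1 && c <= nc &&
            !seen[r, c] && q[r, c] == lvl) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
    zones <- rbind(zones, data.frame(level = lvl, size = size))
  }
  zones
}

oracle_glszm <- function(q, ng) {
  z <- oracle_zones(q)
  m <- matrix(0L, ng, max(z$size))
  for (i in seq_len(nrow(z))) {
    m[z$level[i], z$size[i]] <- m[z$level[i], z$size[i]] + 1L
  }
  m
}

# Pairwise-comparison (Mann-Whitney) AUC oracle with ties counted 1/2.
oracle_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# --- Memoised full-scale synthetic run shared by acceptance tests ---------

.fixture_env <- new.env(parent = emptyenv())

default_feature_table <- function() {
  if (is.null(.fixture_env$ft)) {
    ds <- generate_dataset(250, 100, 138, cfg = synthetic_config(1), seed = 101)
    .fixture_env$ft <- extract_feature_table(ds$tiles)
  }
  .fixture_env$ft
}
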