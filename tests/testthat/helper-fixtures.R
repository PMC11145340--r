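# Fixtures and independent brute-force oracles shared by the tests.

# random connected-ish blob mask with at least `min_fg` foreground pixels
random_mask <- function(n, m, p = 0.4, min_fg = 3L) {
  repeat {
    mk <- matrix(as.integer(stats::runif(n * m) < p), n, m)
    if (sum(mk) >= min_fg) return(mk)
  }
}

disk_mask <- function(r, pad = 2L) {
  sz <- 2L * (r + pad) + 1L
  ctr <- r + pad + 1L
  m <- matrix(0L, sz, sz)
  for (i in seq_len(sz)) for (j in seq_len(sz))
    if ((i - ctr)^2 + (j - ctr)^2 <= r^2) m[i, j] <- 1L
  m
}

region_from_mask <- function(mask, gray = NULL, levels = 8L) {
  if (is.null(gray)) gray <- matrix(100, nrow(mask), ncol(mask))
  nucleus_region(mask, gray, levels)
}

# --- oracles ----------------------------------------------------------

# raw and central moments by an explicit double loop over all pixels
oracle_moments <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  M <- matrix(0, 3, 3)
  for (p in 0:2) for (q in 0:2) {
    if (p + q > 2) next   # module contract: orders p + q <= 2
    acc <- 0
    for (r in seq_len(n)) for (c in seq_len(m))
      acc <- acc + (c - 1)^p * (r - 1)^q * (mask[r, c] > 0)
    M[p + 1, q + 1] <- acc
  }
  xb <- M[2, 1] / M[1, 1]; yb <- M[1, 2] / M[1, 1]
  mu <- matrix(0, 3, 3)
  for (p in 0:2) for (q in 0:2) {
    if (p + q > 2) next
    acc <- 0
    for (r in seq_len(n)) for (c in seq_len(m))
      acc <- acc + ((c - 1) - xb)^p * ((r - 1) - yb)^q * (mask[r, c] > 0)
    mu[p + 1, q + 1] <- acc
  }
  list(M = M, mu = mu, xbar = xb, ybar = yb)
}

# number of in-mask pixel pairs at a given offset, by explicit loop
oracle_glcm_pairs <- function(mask, dx, dy) {
  n <- nrow(mask); m <- ncol(mask)
  cnt <- 0L
  for (r in seq_len(n)) for (c in seq_len(m)) {
    r2 <- r + dy; c2 <- c + dx
    if (r2 >= 1 && r2 <= n && c2 >= 1 && c2 <= m &&
        mask[r, c] > 0 && mask[r2, c2] > 0)
      cnt <- cnt + 1L
  }
  cnt
}

# full GLCM count matrix by explicit loop
oracle_glcm <- function(mask, gray, l, dx, dy) {
  n <- nrow(mask); m <- ncol(mask)
  G <- matrix(0L, l, l)
  for (r in seq_len(n)) for (c in seq_len(m)) {
    r2 <- r + dy; c2 <- c + dx
    if (r2 >= 1 && r2 <= n && c2 >= 1 && c2 <= m &&
        mask[r, c] > 0 && mask[r2, c2] > 0) {
      i <- gray[r, c] + 1L; j <- gray[r2, c2] + 1L
      G[i, j] <- G[i, j] + 1L
    }
  }
  G
}

# directed K-NN-within-cutoff selection by all-pairs scan
oracle_knn <- function(pts, K, dmin) {
  n <- nrow(pts)
  lapply(seq_len(n), function(i) {
    d <- sqrt((pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2)
    cand <- setdiff(order(d, seq_len(n)), i)
    cand <- cand[d[cand] < dmin]
    cand[seq_len(min(K, length(cand)))]
  })
}

# contour-pixel adjacency counts by explicit pair enumeration
oracle_boundary_counts <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  is_contour <- function(r, c) {
    if (mask[r, c] == 0) return(FALSE)
    nb <- c(if (r > 1) mask[r - 1, c] else 0,
            if (r < n) mask[r + 1, c] else 0,
            if (c > 1) mask[r, c - 1] else 0,
            if (c < m) mask[r, c + 1] else 0)
    any(nb == 0)
  }
  cont <- outer(seq_len(n), seq_len(m),
                Vectorize(function(r, c) is_contour(r, c)))
  cnt <- c(Nv = 0L, Nh = 0L, Nd1 = 0L, Nd2 = 0L)
  for (r in seq_len(n)) for (c in seq_len(m)) {
    if (!cont[r, c]) next
    if (c < m && cont[r, c + 1]) cnt["Nh"] <- cnt["Nh"] + 1L
    if (r < n && cont[r + 1, c]) cnt["Nv"] <- cnt["Nv"] + 1L
    if (r < n && c < m && cont[r + 1, c + 1]) cnt["Nd1"] <- cnt["Nd1"] + 1L
    if (r > 1 && c < m && cont[r - 1, c + 1]) cnt["Nd2"] <- cnt["Nd2"] + 1L
  }
  cnt
}

# a small ready-made dataset for pipeline tests (kept tiny for speed)
tiny_dataset <- function(seed = 5L, slides = 3L, tiles = 4L,
                         tile_size = 96L, nuclei = c(6L, 10L)) {
  generate_dataset(synthetic_config(
    seed = seed, n_slides_per_class = slides, tiles_per_slide = tiles,
    tile_size = tile_size, nuclei_per_tile = nuclei))
}
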