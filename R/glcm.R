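# Gray-level co-occurrence texture features, restricted to pixel pairs
# that lie entirely inside the nucleus mask.

glcm_directions <- list(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L))

#' Gray-level co-occurrence matrix of a nucleus region
#'
#' Counts ordered pairs of quantised gray values at offset
#' `(dx, dy)` (x = column, y = row) where *both* pixels belong to the
#' nucleus mask.  The four supported offsets (1,0), (1,1), (0,1), (-1,1)
#' are the usual 0/45/90/135-degree directions.
#'
#' @param region a [nucleus_region()]
#' @param direction length-2 integer offset `(dx, dy)`
#' @return object of class `glcm`: `counts` (l x l), `P` (normalised,
#'   sums to 1), `epsilon` (mean of `P`), `direction`
#' @export
compute_glcm <- function(region, direction = c(1L, 0L)) {
  ok <- any(vapply(glcm_directions,
                   function(d) all(d == direction), logical(1L)))
  if (!ok) stop("direction must be one of (1,0), (1,1), (0,1), (-1,1)")
  l <- region$gray_levels
  if (l < 2L) stop("need at least 2 gray levels")
  dx <- direction[1L]; dy <- direction[2L]
  n <- nrow(region$mask); m <- ncol(region$mask)
  r1 <- seq_len(n); c1 <- seq_len(m)
  r1 <- r1[r1 + dy >= 1L & r1 + dy <= n]
  c1 <- c1[c1 + dx >= 1L & c1 + dx <= m]
  counts <- matrix(0, l, l)
  if (length(r1) && length(c1)) {
    m1 <- region$mask[r1, c1, drop = FALSE] > 0
    m2 <- region$mask[r1 + dy, c1 + dx, drop = FALSE] > 0
    both <- m1 & m2
    if (any(both)) {
      i <- region$gray[r1, c1, drop = FALSE][both]
      j <- region$gray[r1 + dy, c1 + dx, drop = FALSE][both]
      counts <- matrix(tabulate(i * l + j + 1L, nbins = l * l),
                       l, l, byrow = TRUE)
    }
  }
  tot <- sum(counts)
  if (tot == 0) stop("degenerate GLCM: no in-mask pixel pair at this offset")
  structure(list(counts = counts, P = counts / tot,
                 epsilon = 1 / l^2, direction = direction),
            class = "glcm")
}

# the seven texture statistics of one normalised co-occurrence matrix
glcm_stats <- function(P, epsilon) {
  l <- nrow(P)
  iv <- matrix(rep(0:(l - 1L), times = l), l)   # row index i
  jv <- matrix(rep(0:(l - 1L), each = l), l)    # col index j
  d <- iv - jv
  lp <- ifelse(P > 0, log2(P), 0)
  c(Con = sum(d^2 * P),
    Diss = sum(abs(d) * P),
    Hom = sum(P / (1 + d^2)),
    Ent = -sum(P * lp),
    ASM = sum(P^2),
    Dsip = sum((P - epsilon)^2))
}

#' The seven texture nucleus features
#'
#' Contrast, dissimilarity, homogeneity, entropy (log base 2, with
#' 0 log 0 = 0), angular second moment and dispersion are computed on the
#' normalised co-occurrence matrix of each of the four directions and
#' averaged; roughness is the ratio of the contour perimeter to the
#' convex-hull perimeter.
#'
#' @param region a [nucleus_region()]
#' @param geo output of [geometric_features()] for the same region (for
#'   the two perimeters); computed on the fly if omitted
#' @param average average the four directions (default) or return the
#'   per-direction matrix when `FALSE`
#' @return named numeric of `Con`, `Diss`, `Hom`, `Ent`, `ASM`, `Rou`,
#'   `Dsip` (or, with `average = FALSE`, a 4 x 6 matrix plus `Rou`)
#' @export
texture_features <- function(region, geo = NULL, average = TRUE) {
  if (is.null(geo)) geo <- geometric_features(region)
  per_dir <- t(vapply(glcm_directions, function(d) {
    g <- compute_glcm(region, d)
    glcm_stats(g$P, g$epsilon)
  }, numeric(6L)))
  Rou <- geo$aux$counts$Ph / geo$aux$hull$Pn
  if (!average) return(list(per_direction = per_dir, Rou = Rou))
  avg <- colMeans(per_dir)
  c(Con = avg[["Con"]], Diss = avg[["Diss"]], Hom = avg[["Hom"]],
    Ent = avg[["Ent"]], ASM = avg[["ASM"]], Rou = Rou,
    Dsip = avg[["Dsip"]])
}
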