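# Geometric nucleus features from image moments.
#
# The nine features are those a pathologist-facing morphometry table would
# carry: equivalent-ellipse axes and orientation from second-order
# moments, area, eccentricity, ellipticity, equivalent diameter, a
# direction-weighted contour perimeter, and the convex hull area.

#' Raw, central and normalised image moments of a region
#'
#' `M` holds raw moments \eqn{M_{pq} = \sum x^p y^q H(x,y)} for
#' \eqn{p+q \le 2} (indexed `M[p+1, q+1]`), `mu` the centralised versions,
#' and `nmu20`, `nmu02`, `nmu11` the second-order central moments divided
#' by \eqn{M_{00}} (the per-pixel covariance of the region).
#'
#' @param region a [nucleus_region()]
#' @return object of class `moment_set`
#' @export
compute_moments <- function(region) {
  if (sum(region$mask) < 1L) stop("empty region")
  px <- region_pixels(region$mask)
  x <- px[, "x"]; y <- px[, "y"]
  M <- matrix(0, 3L, 3L, dimnames = list(paste0("p", 0:2), paste0("q", 0:2)))
  for (p in 0:2) for (q in 0:2) if (p + q <= 2L)
    M[p + 1L, q + 1L] <- sum(x^p * y^q)
  m00 <- M[1L, 1L]
  xbar <- M[2L, 1L] / m00
  ybar <- M[1L, 2L] / m00
  mu <- matrix(0, 3L, 3L, dimnames = dimnames(M))
  for (p in 0:2) for (q in 0:2) if (p + q <= 2L)
    mu[p + 1L, q + 1L] <- sum((x - xbar)^p * (y - ybar)^q)
  structure(list(
    M = M, mu = mu, centroid = c(x = xbar, y = ybar),
    nmu20 = M[3L, 1L] / m00 - xbar^2,
    nmu02 = M[1L, 3L] / m00 - ybar^2,
    nmu11 = M[2L, 2L] / m00 - xbar * ybar), class = "moment_set")
}

#' Directional adjacency counts along the nucleus contour
#'
#' The contour is the set of foreground pixels with at least one
#' 4-connected background neighbour (image border counts as background).
#' `Nh`, `Nv`, `Nd1`, `Nd2` count unordered pairs of contour pixels
#' adjacent along the horizontal, vertical and the two diagonal
#' directions.  The perimeter is
#' `Per = Nv + Nh + w (Nd1 + Nd2)` with `w = diagonal_weight`; the
#' default weight 2 keeps the printed form of the estimator, `sqrt(2)`
#' gives the Euclidean variant.
#'
#' @param mask binary matrix
#' @param diagonal_weight weight of the diagonal adjacencies in `Per`
#' @return list with `Nv`, `Nh`, `Nd1`, `Nd2`, `Per` and `Ph` (the
#'   perimeter used in the roughness ratio, equal to `Per`)
#' @export
boundary_counts <- function(mask, diagonal_weight = 2) {
  mask <- (as.matrix(mask) > 0)
  n <- nrow(mask); m <- ncol(mask)
  pad <- matrix(FALSE, n + 2L, m + 2L)
  pad[2:(n + 1L), 2:(m + 1L)] <- mask
  core <- pad[2:(n + 1L), 2:(m + 1L), drop = FALSE]
  bgnb <- !pad[1:n, 2:(m + 1L), drop = FALSE] |
          !pad[3:(n + 2L), 2:(m + 1L), drop = FALSE] |
          !pad[2:(n + 1L), 1:m, drop = FALSE] |
          !pad[2:(n + 1L), 3:(m + 2L), drop = FALSE]
  cont <- core & bgnb
  Nh <- if (m > 1L) sum(cont[, -m, drop = FALSE] & cont[, -1L, drop = FALSE]) else 0L
  Nv <- if (n > 1L) sum(cont[-n, , drop = FALSE] & cont[-1L, , drop = FALSE]) else 0L
  Nd1 <- if (n > 1L && m > 1L)
    sum(cont[-n, -m, drop = FALSE] & cont[-1L, -1L, drop = FALSE]) else 0L
  Nd2 <- if (n > 1L && m > 1L)
    sum(cont[-1L, -m, drop = FALSE] & cont[-n, -1L, drop = FALSE]) else 0L
  Per <- Nv + Nh + diagonal_weight * (Nd1 + Nd2)
  list(Nv = Nv, Nh = Nh, Nd1 = Nd1, Nd2 = Nd2, Per = Per, Ph = Per)
}

# shoelace area of a polygon given 0-based vertex coordinates
shoelace <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Convex hull of a region's pixel set
#'
#' The hull polygon is taken over pixel centres.  `AreaHull` is the
#' number of lattice points (pixels) inside or on the hull polygon —
#' i.e. the pixel count of the rasterised hull region, so it is always
#' at least the region's own pixel count.  The shoelace area of the hull
#' polygon and the polygon itself are returned alongside; `Pn` is the
#' polygon perimeter and feeds the roughness ratio.  Masks whose pixels
#' are collinear (including singletons) fall back to `AreaHull = Area`
#' and are flagged `degenerate`.
#'
#' @param mask binary matrix
#' @return list with `AreaHull`, `Pn`, `T` (hull vertices, columns x, y),
#'   `poly_area` (shoelace) and `degenerate`
#' @export
hull_area <- function(mask) {
  mask <- (as.matrix(mask) > 0)
  px <- region_pixels(mask)
  if (nrow(px) < 1L) stop("empty region")
  area <- nrow(px)
  h <- grDevices::chull(px[, "x"], px[, "y"])
  hx <- px[h, "x"]; hy <- px[h, "y"]
  poly_area <- shoelace(hx, hy)
  nh <- length(h)
  if (nh < 3L || poly_area == 0) {
    d <- if (nh >= 2L) sqrt(diff(range(hx))^2 + diff(range(hy))^2) else 0
    return(list(AreaHull = area, Pn = max(2 * d, 1),
                T = cbind(x = hx, y = hy), poly_area = 0, degenerate = TRUE))
  }
  jx <- c(hx[-1L], hx[1L]); jy <- c(hy[-1L], hy[1L])
  Pn <- sum(sqrt((jx - hx)^2 + (jy - hy)^2))
  # lattice points inside/on the convex polygon: half-plane tests over the
  # bounding box (regions are small, so this stays cheap)
  gx <- seq(min(hx), max(hx)); gy <- seq(min(hy), max(hy))
  G <- expand.grid(x = gx, y = gy)
  orient <- sign(sum((jx - hx) * (jy + hy)))  # polygon winding
  inside <- rep(TRUE, nrow(G))
  for (e in seq_len(nh)) {
    cr <- (jx[e] - hx[e]) * (G$y - hy[e]) - (jy[e] - hy[e]) * (G$x - hx[e])
    inside <- inside & (orient * cr <= 1e-9)
    if (!any(inside)) break
  }
  list(AreaHull = sum(inside), Pn = Pn, T = cbind(x = hx, y = hy),
       poly_area = poly_area, degenerate = FALSE)
}

#' The nine geometric nucleus features
#'
#' Axis lengths follow the equivalent-ellipse convention
#' \eqn{Major = \sqrt{8(\bar\mu_{20}+\bar\mu_{02}+\sqrt{4\bar\mu_{11}^2+(\bar\mu_{20}-\bar\mu_{02})^2})}}
#' (and dually `Minor`), so that a solid disk of radius r reports
#' `Major = Minor = 2r`.  The orientation is
#' \eqn{\theta = \tfrac12\arctan(2\bar\mu_{11}/(\bar\mu_{20}-\bar\mu_{02}))},
#' folded into \eqn{(-\pi/4, \pi/4]}.  Collinear or singleton masks get
#' `Minor` clamped to 1 px and are flagged.
#'
#' @param region a [nucleus_region()]
#' @param diagonal_weight passed to [boundary_counts()]
#' @return list of the nine features (`Major`, `Minor`, `Area`, `theta`,
#'   `Ecc`, `Ell`, `Dia`, `Per`, `AreaHull`) plus `aux` (moments, contour
#'   counts, hull details, degeneracy flag)
#' @export
geometric_features <- function(region, diagonal_weight = 2) {
  mo <- compute_moments(region)
  a <- mo$nmu20; b <- mo$nmu02; cxy <- mo$nmu11
  disc <- sqrt(4 * cxy^2 + (a - b)^2)
  Major <- sqrt(8 * pmax(a + b + disc, 0))
  Minor <- sqrt(8 * pmax(a + b - disc, 0))
  degenerate <- Minor < 1
  if (degenerate) {
    Minor <- 1
    Major <- max(Major, Minor)
  }
  den <- a - b
  theta <- if (abs(cxy) < 1e-12 && abs(den) < 1e-12) 0
           else if (abs(den) < 1e-12) sign(cxy) * pi / 4
           else 0.5 * atan(2 * cxy / den)
  if (theta <= -pi / 4 + 1e-15) theta <- theta + pi / 2  # fold to (-pi/4, pi/4]
  if (theta > pi / 4) theta <- theta - pi / 2
  Area <- mo$M[1L, 1L]
  Ell <- Minor / Major
  Ecc <- sqrt(pmax(1 - Ell^2, 0))
  Dia <- sqrt(4 * Area / pi)
  bc <- boundary_counts(region$mask, diagonal_weight)
  hl <- hull_area(region$mask)
  list(Major = Major, Minor = Minor, Area = Area, theta = theta,
       Ecc = Ecc, Ell = Ell, Dia = Dia, Per = bc$Per,
       AreaHull = hl$AreaHull,
       aux = list(moments = mo, counts = bc, hull = hl,
                  degenerate = degenerate || hl$degenerate))
}
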