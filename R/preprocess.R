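# Tissue extraction, fixed-grid tiling and patch feature extraction.
#
# The core pipeline consumes plain images and manifests; pyramidal
# whole-slide formats are expected to be rendered to a working level by
# an external backend before entering here.

#' Tissue mask of a slide image
#'
#' The image is converted to HSV; an Otsu threshold on the saturation
#' channel separates stained tissue from white background, small holes
#' are closed with a disc structuring element, and connected components
#' below an area threshold are dropped.  Coordinates scale to level 0 by
#' `2^level`.
#'
#' @param rgb H x W x 3 array in \[0, 1\] (or 0-255), at pyramid level
#'   `level`
#' @param level pyramid level the image was read at (0 = full
#'   resolution); the default 4 suits typical whole-slide pyramids, use
#'   0 for small synthetic slides
#' @param closing_radius disc radius of the morphological closing
#' @param area_threshold minimum component area in level-`level` pixels;
#'   the default keeps components of at least 64 tiles' worth of pixels
#'   at the masking level
#' @param min_saturation below this maximum saturation the slide is
#'   treated as blank (empty mask, with a warning)
#' @return object of class `tissue_mask`: logical `mask`, labeled
#'   `components`, `contours` (list of boundary pixel matrices, level-0
#'   coordinates), `level`, `scale`
#' @export
tissue_mask <- function(rgb, level = 4L, closing_radius = 2L,
                        area_threshold = NULL, min_saturation = 0.05) {
  if (max(rgb) > 1) rgb <- rgb / 255
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3L] >= 3L)
  h <- dim(rgb)[1L]; w <- dim(rgb)[2L]
  scale <- 2^level
  if (is.null(area_threshold))
    area_threshold <- 64 * (512 / scale)^2
  px <- rbind(as.vector(rgb[, , 1L]), as.vector(rgb[, , 2L]),
              as.vector(rgb[, , 3L]))
  S <- matrix(grDevices::rgb2hsv(px, maxColorValue = 1)[2L, ], h, w)
  empty <- function(msg) {
    warning(msg)
    structure(list(mask = matrix(FALSE, h, w),
                   components = matrix(0L, h, w), contours = list(),
                   level = level, scale = scale), class = "tissue_mask")
  }
  if (max(S) < min_saturation || diff(range(S)) == 0)
    return(empty("no saturated tissue found; empty mask"))
  thr <- EBImage::otsu(EBImage::Image(S), range = c(0, 1))
  m <- S > thr
  brush <- EBImage::makeBrush(2L * closing_radius + 1L, shape = "disc")
  m <- EBImage::closing(EBImage::Image(m * 1), brush) > 0
  m <- matrix(as.logical(m), h, w)
  if (!any(m)) return(empty("tissue mask empty after closing"))
  lab <- matrix(as.integer(EBImage::bwlabel(m * 1)), h, w)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= area_threshold)
  if (!length(keep)) return(empty("all tissue components below area threshold"))
  lab[!(lab %in% keep)] <- 0L
  m <- lab > 0L
  # relabel kept components consecutively and trace their boundaries
  contours <- list()
  for (k in seq_along(keep)) {
    cm <- lab == keep[k]
    bc <- boundary_pixels(cm)
    contours[[k]] <- cbind(x = (bc[, "x"]) * scale,
                           y = (bc[, "y"]) * scale)
    lab[cm] <- k
  }
  structure(list(mask = m, components = lab, contours = contours,
                 level = level, scale = scale), class = "tissue_mask")
}

# 0-based coordinates of foreground pixels that touch background
boundary_pixels <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  pad <- matrix(FALSE, n + 2L, m + 2L)
  pad[2:(n + 1L), 2:(m + 1L)] <- mask
  core <- pad[2:(n + 1L), 2:(m + 1L), drop = FALSE]
  bg <- !pad[1:n, 2:(m + 1L), drop = FALSE] |
        !pad[3:(n + 2L), 2:(m + 1L), drop = FALSE] |
        !pad[2:(n + 1L), 1:m, drop = FALSE] |
        !pad[2:(n + 1L), 3:(m + 2L), drop = FALSE]
  idx <- which(core & bg, arr.ind = TRUE)
  cbind(x = idx[, 2L] - 1L, y = idx[, 1L] - 1L)
}

#' Grid tiles intersecting the tissue mask
#'
#' Scans the fixed tile grid over the level-0 extent and keeps every
#' window that intersects the tissue mask.  Windows overrunning the
#' slide edge are discarded, keeping every tile exactly
#' `tile_size x tile_size`.
#'
#' @param slide_dims level-0 (width, height) in pixels
#' @param mask a [tissue_mask()]
#' @param tile_size window side length (default 512)
#' @return object of class `tile_index`: data.frame `tiles` with level-0
#'   top-left `x`, `y`, plus `slide_dims` and `tile_size`
#' @export
tile_index <- function(slide_dims, mask, tile_size = 512L) {
  w <- slide_dims[1L]; h <- slide_dims[2L]
  s <- mask$scale
  xs <- seq(0L, w - tile_size, by = tile_size)
  ys <- seq(0L, h - tile_size, by = tile_size)
  keep <- list()
  mh <- nrow(mask$mask); mw <- ncol(mask$mask)
  for (y in ys) for (x in xs) {
    r1 <- max(1L, floor(y / s) + 1L); r2 <- min(mh, ceiling((y + tile_size) / s))
    c1 <- max(1L, floor(x / s) + 1L); c2 <- min(mw, ceiling((x + tile_size) / s))
    if (r1 > r2 || c1 > c2) next
    if (any(mask$mask[r1:r2, c1:c2]))
      keep[[length(keep) + 1L]] <- data.frame(x = x, y = y)
  }
  tiles <- if (length(keep)) do.call(rbind, keep)
           else data.frame(x = integer(0), y = integer(0))
  structure(list(tiles = tiles, slide_dims = slide_dims,
                 tile_size = as.integer(tile_size)),
            class = "tile_index")
}

#' Crop the indexed tiles out of a slide image
#'
#' @param slide_image level-0 gray matrix (rows = y, columns = x)
#' @param index a [tile_index()]
#' @return list of tile matrices in index order
#' @export
extract_tiles <- function(slide_image, index) {
  ts <- index$tile_size
  lapply(seq_len(nrow(index$tiles)), function(k) {
    x <- index$tiles$x[k]; y <- index$tiles$y[k]
    slide_image[(y + 1L):(y + ts), (x + 1L):(x + ts), drop = FALSE]
  })
}

#' Reassemble tiles onto a blank slide canvas
#'
#' Inverse of [extract_tiles()]: within the tiled extent the round trip
#' is pixel-exact.
#'
#' @param tiles list of tile matrices
#' @param index a [tile_index()]
#' @param fill background value for untiled areas
#' @return level-0 matrix of the slide dimensions
#' @export
reassemble_tiles <- function(tiles, index, fill = 0) {
  w <- index$slide_dims[1L]; h <- index$slide_dims[2L]
  out <- matrix(fill, h, w)
  ts <- index$tile_size
  for (k in seq_along(tiles)) {
    x <- index$tiles$x[k]; y <- index$tiles$y[k]
    out[(y + 1L):(y + ts), (x + 1L):(x + ts)] <- tiles[[k]]
  }
  out
}

#' Deterministic stub patch feature extractor
#'
#' A drop-in stand-in for a pretrained convolutional backbone: the tile
#' is block-averaged into a small multi-scale pyramid (by default 16x16,
#' 4x4 and the global mean — mirroring how pooled backbone features mix
#' fine texture with coarse intensity), centred by a fixed constant, and
#' mapped through a fixed seeded random projection to `width`
#' dimensions.  Fixed centering (rather than per-tile standardisation)
#' preserves the between-tile intensity contrasts the classifier needs.
#' Identical tiles always give identical vectors; distinct tiles collide
#' with probability zero.  Any object with fields `width`,
#' `deterministic` and `fun(tile) -> numeric(width)` conforms to the
#' interface, so a real backbone can be plugged in unchanged.
#'
#' @param width output feature width (default 1024)
#' @param pools side lengths of the pooled pyramid levels
#' @param seed seed of the projection matrix
#' @return extractor object (list with `width`, `deterministic`, `fun`)
#' @export
stub_extractor <- function(width = 1024L, pools = c(16L, 4L, 1L),
                           seed = 7L) {
  in_dim <- sum(pools^2)
  proj <- with_seed(seed, matrix(stats::rnorm(in_dim * width), in_dim,
                                 width) / sqrt(in_dim))
  block_mean <- function(tile, pool) {
    n <- nrow(tile); m <- ncol(tile)
    if (n %% pool == 0L && m %% pool == 0L) {
      rf <- n %/% pool; cf <- m %/% pool
      th <- matrix(0, pool, pool)
      for (i in seq_len(pool)) for (j in seq_len(pool))
        th[i, j] <- mean(tile[((i - 1L) * rf + 1L):(i * rf),
                              ((j - 1L) * cf + 1L):(j * cf)])
      th
    } else {
      as.matrix(EBImage::resize(EBImage::Image(tile), pool, pool))
    }
  }
  # inverse-noise weighting: a block mean over k pixels has noise sd
  # proportional to 1/sqrt(k), so coarser levels are scaled up by their
  # linear support to equalise channel noise before projection
  lvl_w <- rep(max(pools) / pools, pools^2)
  fun <- function(tile) {
    tile <- as.matrix(tile)
    if (max(tile) > 1) tile <- tile / 255
    v <- unlist(lapply(pools, function(p) as.vector(block_mean(tile, p))))
    as.vector(((v - 0.5) * lvl_w) %*% proj)
  }
  structure(list(width = as.integer(width), deterministic = TRUE,
                 fun = fun, pools = as.integer(pools), seed = seed),
            class = "feature_extractor")
}

#' Extract a patch bag from a list of tiles
#'
#' @param tiles list of gray tile matrices
#' @param extractor a [stub_extractor()] or conforming object
#' @param coords N x 2 matrix of tile top-left coordinates (optional)
#' @param slide_id,label carried into the bag
#' @return a [patch_bag()] with rows aligned to `tiles`
#' @export
extract_features <- function(tiles, extractor, coords = NULL,
                             slide_id = NA_character_,
                             label = NA_integer_) {
  stopifnot(length(tiles) >= 1L)
  feats <- t(vapply(tiles, function(tl) {
    v <- extractor$fun(tl)
    if (length(v) != extractor$width)
      stop("extractor output width mismatch")
    v
  }, numeric(extractor$width)))
  patch_bag(feats, coords, slide_id, label)
}

#' Build patch bags for every slide of a synthetic dataset
#'
#' @param dataset output of [generate_dataset()]
#' @param extractor a [stub_extractor()] or conforming object
#' @return named list of [patch_bag()] objects
#' @export
build_bags <- function(dataset, extractor = stub_extractor()) {
  lapply(dataset, function(slide) {
    tiles <- lapply(slide$tiles, `[[`, "image")
    coords <- do.call(rbind, lapply(slide$tiles, `[[`, "origin"))
    extract_features(tiles, extractor, coords, slide$slide_id,
                     slide$label)
  })
}

#' Compose a synthetic slide's tiles into one image
#'
#' @param slide one element of [generate_dataset()] output
#' @param fill background value for unoccupied grid cells
#' @return gray matrix of the assembled slide
#' @export
compose_slide <- function(slide, fill = 255) {
  ox <- vapply(slide$tiles, function(t) t$origin[["x"]], numeric(1L))
  oy <- vapply(slide$tiles, function(t) t$origin[["y"]], numeric(1L))
  ts <- nrow(slide$tiles[[1L]]$image)
  out <- matrix(fill, max(oy) + ts, max(ox) + ts)
  for (t in seq_along(slide$tiles)) {
    out[(oy[t] + 1L):(oy[t] + ts), (ox[t] + 1L):(ox[t] + ts)] <-
      slide$tiles[[t]]$image
  }
  out
}
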