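# Attention heatmap export: per-tile scores painted at their recorded
# grid coordinates.

#' Render attention scores as a slide heatmap
#'
#' Each tile's score is min-max normalised over the bag and painted as a
#' constant block at its recorded top-left coordinate, then colormapped.
#' With all scores equal the map is constant at mid-scale.
#'
#' @param coords N x 2 matrix of tile top-left (x, y) level-0 coordinates
#' @param scores attention scores, length N
#' @param slide_dims level-0 (width, height)
#' @param tile_size tile side length
#' @param downscale integer factor applied before painting (keeps PNG
#'   exports small)
#' @param palette colour ramp function, e.g. the default viridis ramp
#' @return list with `intensity` (matrix in \[0, 1\], NA = untiled) and
#'   `rgb` (H x W x 3 array)
#' @export
attention_heatmap <- function(coords, scores, slide_dims,
                              tile_size = 512L, downscale = 8L,
                              palette = NULL) {
  stopifnot(nrow(coords) == length(scores))
  rng <- range(scores)
  norm <- if (diff(rng) > 0) (scores - rng[1L]) / diff(rng)
          else rep(0.5, length(scores))
  w <- ceiling(slide_dims[1L] / downscale)
  h <- ceiling(slide_dims[2L] / downscale)
  ts <- max(1L, round(tile_size / downscale))
  inten <- matrix(NA_real_, h, w)
  for (k in seq_along(scores)) {
    x0 <- floor(coords[k, 1L] / downscale)
    y0 <- floor(coords[k, 2L] / downscale)
    rows <- (y0 + 1L):min(y0 + ts, h)
    cols <- (x0 + 1L):min(x0 + ts, w)
    inten[rows, cols] <- norm[k]
  }
  pal <- palette %||% function(n) grDevices::hcl.colors(n, "viridis")
  ramp <- grDevices::colorRamp(pal(256L))
  rgb <- array(1, c(h, w, 3L))
  filled <- which(!is.na(inten))
  if (length(filled)) {
    cols <- ramp(inten[filled]) / 255
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[filled] <- cols[, ch]
      rgb[, , ch] <- plane
    }
  }
  list(intensity = inten, rgb = rgb)
}

#' Write an attention heatmap to PNG
#'
#' @param heatmap output of [attention_heatmap()]
#' @param path output PNG path
#' @export
write_heatmap <- function(heatmap, path) {
  png::writePNG(heatmap$rgb, path)
  invisible(path)
}
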