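# Nucleus regions: the unit of handcrafted feature extraction.
#
# Coordinate convention throughout: x = column, y = row, both 0-based at
# the region's top-left corner; `offset` places the region in tile
# coordinates.  The gray patch is stored already quantised to
# `gray_levels` bins (0 .. l-1), which is what the co-occurrence matrix
# consumes.

#' Construct a nucleus region
#'
#' Bundles the binary mask of one segmented nucleus with the matching
#' gray-level patch, quantised to `gray_levels` bins.
#'
#' @param mask integer/logical matrix, 1 = nucleus, 0 = background
#' @param gray numeric matrix of the same shape; 8-bit intensities unless
#'   `quantized = TRUE`, in which case values must already lie in
#'   `0 .. gray_levels - 1`
#' @param gray_levels number of gray bins l used for texture features
#' @param offset length-2 integer (x, y) of the region's top-left corner
#'   in tile coordinates (0-based)
#' @param quantized set to `TRUE` when `gray` is pre-binned
#' @return an object of class `nucleus_region`
#' @export
nucleus_region <- function(mask, gray, gray_levels = 8L,
                           offset = c(0L, 0L), quantized = FALSE) {
  mask <- (as.matrix(mask) > 0) * 1L
  if (sum(mask) < 1L) stop("empty region")
  gray <- as.matrix(gray)
  if (!all(dim(gray) == dim(mask)))
    stop("gray patch and mask shapes differ")
  if (!quantized) {
    gray <- quantize_gray(gray, gray_levels)
  } else {
    if (any(gray < 0) || any(gray > gray_levels - 1L))
      stop("quantized gray values must lie in 0 .. gray_levels - 1")
    storage.mode(gray) <- "integer"
  }
  structure(list(mask = mask, gray = gray,
                 gray_levels = as.integer(gray_levels),
                 offset = as.numeric(offset)),
            class = "nucleus_region")
}

#' @export
print.nucleus_region <- function(x, ...) {
  cat(sprintf("<nucleus_region> %d x %d px, area %d, l = %d\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$gray_levels))
  invisible(x)
}

# foreground pixel coordinates, 0-based, columns x then y
region_pixels <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  cbind(x = idx[, 2L] - 1L, y = idx[, 1L] - 1L)
}

#' Split a labeled instance mask into nucleus regions
#'
#' @param gray_tile 8-bit gray image matrix of the tile
#' @param instance_mask integer matrix, 0 = background, k > 0 = nucleus k
#' @param gray_levels gray bins for texture quantisation
#' @param min_area instances smaller than this many pixels are dropped
#' @return named list of `nucleus_region` objects (names = instance label)
#' @export
split_instances <- function(gray_tile, instance_mask, gray_levels = 8L,
                            min_area = 4L) {
  fg <- which(instance_mask > 0)
  if (!length(fg)) return(list())
  lab <- instance_mask[fg]
  rows <- (fg - 1L) %% nrow(instance_mask) + 1L
  cols <- (fg - 1L) %/% nrow(instance_mask) + 1L
  out <- list()
  for (k in sort(unique(lab))) {
    sel <- lab == k
    if (sum(sel) < min_area) next
    r <- range(rows[sel]); c <- range(cols[sel])
    sub_mask <- (instance_mask[r[1L]:r[2L], c[1L]:c[2L], drop = FALSE] == k) * 1L
    sub_gray <- gray_tile[r[1L]:r[2L], c[1L]:c[2L], drop = FALSE]
    out[[as.character(k)]] <- nucleus_region(
      sub_mask, sub_gray, gray_levels,
      offset = c(c[1L] - 1L, r[1L] - 1L))
  }
  out
}
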