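# Seeded synthetic slides with class-conditional nucleus morphology.
#
# Slides are grids of gray tiles carrying dark elliptical nuclei on a
# light background.  Nuclei are filled rotated ellipses with additive
# texture noise, so the geometric features have analytic ground truth and
# the class contrasts (area, chromatin darkness, texture roughness) are
# configurable.  A positive slide carries cancer-like nuclei on a subset
# of "witness" tiles — the multiple-instance bag assumption that a
# positive bag holds at least one positive instance.

#' Per-class nucleus morphology parameters
#'
#' Nucleus areas are log-normal with mean `area_mean` px^2 and log-scale
#' sd `area_sdlog`; the aspect ratio (major/minor) is normal truncated at
#' 1; orientations are uniform; `intensity_mean`/`intensity_sd` set the
#' per-nucleus chromatin gray level (8-bit, dark on a light background)
#' and `noise_sd` the additive per-pixel texture noise.
#'
#' The default class contrast mirrors the empirical cancer/normal ratios
#' of nucleus morphometry in breast tissue: cancer nuclei are on average
#' 1.3726 times larger in area, slightly rounder, darker (higher
#' contrast) and noisier in texture (lower homogeneity and angular second
#' moment, higher entropy).
#'
#' @param class integer 0 (normal) or 1 (cancer-like)
#' @param area_ratio cancer/normal mean-area ratio used for class 1
#' @return named list of distribution parameters
#' @export
class_params <- function(class = 0L, area_ratio = 1.3726) {
  base <- list(area_mean = 120, area_sdlog = 0.35,
               aspect_mean = 1.6, aspect_sd = 0.25,
               intensity_mean = 110, intensity_sd = 10,
               noise_sd = 12)
  if (class == 1L) {
    base$area_mean <- 120 * area_ratio
    base$aspect_mean <- 1.35
    base$aspect_sd <- 0.2
    base$intensity_mean <- 85
    base$noise_sd <- 20
  }
  base
}

check_class_params <- function(p) {
  stopifnot(is.list(p))
  if (!is.finite(p$area_mean) || p$area_mean <= 0)
    stop("degenerate nucleus distribution: area_mean must be positive")
  if (p$area_sdlog < 0 || p$aspect_mean < 1 || p$noise_sd < 0)
    stop("invalid class parameters")
  invisible(p)
}

#' Configuration of the synthetic slide generator
#'
#' @param seed integer; fixes every random draw of the generator
#' @param n_slides_per_class slides per class (labels 0 and 1)
#' @param tiles_per_slide tiles in each slide's grid
#' @param tile_size tile side length in pixels
#' @param nuclei_per_tile integer range (min, max) of nuclei per tile
#' @param params list of two [class_params()] lists, names "0" and "1"
#' @param witness_rate fraction of a positive slide's tiles that carry
#'   cancer-like nuclei; must lie in (0, 1], and at least one witness
#'   tile is always present.  The default 0.75 models a section whose
#'   tissue is predominantly lesional — the strong-contrast regime the
#'   default study conditions represent
#' @param background,background_noise tile background gray level and sd
#' @param gray_levels texture quantisation bins recorded for downstream
#'   feature extraction
#' @return object of class `synthetic_config`
#' @export
synthetic_config <- function(seed = 1L, n_slides_per_class = 30L,
                             tiles_per_slide = 8L, tile_size = 512L,
                             nuclei_per_tile = c(15L, 30L),
                             params = list("0" = class_params(0L),
                                           "1" = class_params(1L)),
                             witness_rate = 0.75,
                             background = 230, background_noise = 4,
                             gray_levels = 8L) {
  if (witness_rate <= 0 || witness_rate > 1)
    stop("witness_rate must lie in (0, 1]")
  stopifnot(n_slides_per_class >= 1L, tiles_per_slide >= 1L,
            tile_size >= 32L, length(nuclei_per_tile) == 2L,
            nuclei_per_tile[1L] >= 1L,
            nuclei_per_tile[2L] >= nuclei_per_tile[1L])
  check_class_params(params[["0"]])
  check_class_params(params[["1"]])
  structure(list(seed = as.integer(seed),
                 n_slides_per_class = as.integer(n_slides_per_class),
                 tiles_per_slide = as.integer(tiles_per_slide),
                 tile_size = as.integer(tile_size),
                 nuclei_per_tile = as.integer(nuclei_per_tile),
                 params = params, witness_rate = witness_rate,
                 background = background,
                 background_noise = background_noise,
                 gray_levels = as.integer(gray_levels)),
            class = "synthetic_config")
}

# draw per-nucleus generative parameters for one class
sample_nucleus_params <- function(n, p) {
  area <- stats::rlnorm(n, log(p$area_mean) - p$area_sdlog^2 / 2,
                        p$area_sdlog)
  aspect <- pmax(stats::rnorm(n, p$aspect_mean, p$aspect_sd), 1)
  phi <- stats::runif(n, -pi / 2, pi / 2)
  intensity <- pmin(pmax(stats::rnorm(n, p$intensity_mean,
                                      p$intensity_sd), 5), 250)
  data.frame(area = area, aspect = aspect, phi = phi,
             intensity = intensity, noise_sd = p$noise_sd,
             a = sqrt(area * aspect / pi),
             b = sqrt(area / (aspect * pi)))
}

# 0/1 raster of a rotated ellipse with semi-axes a >= b, orientation phi,
# centred in a square patch; returns the mask and the patch half-size
raster_ellipse <- function(a, b, phi) {
  h <- ceiling(a) + 1L
  d <- seq(-h, h)
  dx <- matrix(rep(d, each = 2L * h + 1L), 2L * h + 1L)   # columns = x
  dy <- matrix(rep(d, times = 2L * h + 1L), 2L * h + 1L)  # rows = y
  u <- (dx * cos(phi) + dy * sin(phi)) / a
  v <- (-dx * sin(phi) + dy * cos(phi)) / b
  list(mask = (u^2 + v^2 <= 1) * 1L, half = h)
}

#' Sample standalone nucleus regions of one class
#'
#' Renders `n` nuclei, each in its own patch, for Monte-Carlo recovery of
#' the configured morphology through the feature extractor.
#'
#' @param n number of nuclei
#' @param p a [class_params()] list
#' @param seed integer seed
#' @param background background gray level of the patches
#' @param gray_levels texture quantisation bins
#' @return list with `regions` (list of [nucleus_region()]) and `truth`
#'   (data.frame of the generative parameters per nucleus)
#' @export
sample_nuclei <- function(n, p, seed = 1L, background = 230,
                          gray_levels = 8L) {
  check_class_params(p)
  with_seed(seed, {
    truth <- sample_nucleus_params(n, p)
    regions <- vector("list", n)
    for (i in seq_len(n)) {
      re <- raster_ellipse(truth$a[i], truth$b[i], truth$phi[i])
      npx <- sum(re$mask)
      gray <- matrix(background, nrow(re$mask), ncol(re$mask))
      gray[re$mask > 0] <- pmin(pmax(
        truth$intensity[i] + stats::rnorm(npx, 0, truth$noise_sd[i]),
        0), 255)
      regions[[i]] <- nucleus_region(re$mask, gray, gray_levels)
    }
    list(regions = regions, truth = truth)
  })
}

# render one tile: non-overlapping nuclei via rejection sampling of
# centres; returns image (8-bit values), instance mask and realised truth
render_tile <- function(n_nuclei, p, tile_size, background,
                        background_noise) {
  img <- matrix(pmin(pmax(stats::rnorm(tile_size^2, background,
                                       background_noise), 0), 255),
                tile_size, tile_size)
  mask <- matrix(0L, tile_size, tile_size)
  pars <- sample_nucleus_params(n_nuclei, p)
  placed <- 0L
  cx <- numeric(0); cy <- numeric(0); cr <- numeric(0)
  keep <- logical(n_nuclei)
  centers <- matrix(NA_real_, n_nuclei, 2L)
  for (i in seq_len(n_nuclei)) {
    re <- raster_ellipse(pars$a[i], pars$b[i], pars$phi[i])
    h <- re$half
    if (2L * h + 1L >= tile_size) next
    ok <- FALSE
    for (try in 1:40) {
      x <- sample.int(tile_size - 2L * h, 1L) + h   # 1-based centre col
      y <- sample.int(tile_size - 2L * h, 1L) + h
      if (!length(cx) ||
          all((cx - x)^2 + (cy - y)^2 > (cr + pars$a[i] + 2)^2)) {
        ok <- TRUE; break
      }
    }
    if (!ok) next
    placed <- placed + 1L
    keep[i] <- TRUE
    centers[i, ] <- c(x, y)
    cx <- c(cx, x); cy <- c(cy, y); cr <- c(cr, pars$a[i])
    rows <- (y - h):(y + h); cols <- (x - h):(x + h)
    sel <- re$mask > 0
    npx <- sum(sel)
    sub_img <- img[rows, cols]
    sub_img[sel] <- pmin(pmax(
      pars$intensity[i] + stats::rnorm(npx, 0, pars$noise_sd[i]), 0), 255)
    img[rows, cols] <- sub_img
    sub_mask <- mask[rows, cols]
    sub_mask[sel] <- placed
    mask[rows, cols] <- sub_mask
  }
  truth <- pars[keep, , drop = FALSE]
  truth$label <- seq_len(placed)
  truth$cx <- centers[keep, 1L] - 1
  truth$cy <- centers[keep, 2L] - 1
  list(image = round(img), mask = mask, truth = truth)
}

#' Generate a seeded synthetic slide dataset
#'
#' Produces `n_slides_per_class` slides per class.  Negative slides draw
#' every tile from the class-0 morphology; positive slides draw a random
#' witness subset of tiles (at least one, on average `witness_rate` of
#' the grid) from the class-1 morphology and the rest from class 0.
#' Identical configurations produce bit-identical output.
#'
#' @param config a [synthetic_config()]
#' @return list of slides; each slide is a list with `slide_id`, `label`,
#'   `tiles` (each holding `image`, `mask`, `origin`, `witness`) and
#'   `truth` (per-tile data.frames of generator parameters)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    ts <- config$tile_size
    nt <- config$tiles_per_slide
    grid_w <- ceiling(sqrt(nt))
    slides <- list()
    for (label in c(0L, 1L)) {
      for (s in seq_len(config$n_slides_per_class)) {
        slide_id <- sprintf("S%d_%03d", label, s)
        n_wit <- if (label == 1L)
          max(1L, round(config$witness_rate * nt)) else 0L
        wit <- rep(FALSE, nt)
        if (n_wit > 0L) wit[sample.int(nt, n_wit)] <- TRUE
        tiles <- vector("list", nt)
        truth <- vector("list", nt)
        for (t in seq_len(nt)) {
          p <- config$params[[if (wit[t]) "1" else "0"]]
          n_nuc <- sample(config$nuclei_per_tile[1L]:
                          config$nuclei_per_tile[2L], 1L)
          td <- render_tile(n_nuc, p, ts, config$background,
                            config$background_noise)
          origin <- c(x = ((t - 1L) %% grid_w) * ts,
                      y = ((t - 1L) %/% grid_w) * ts)
          tiles[[t]] <- list(image = td$image, mask = td$mask,
                             origin = origin, witness = wit[t])
          td$truth$tile <- t
          truth[[t]] <- td$truth
        }
        slides[[slide_id]] <- list(slide_id = slide_id, label = label,
                                   tiles = tiles,
                                   truth = do.call(rbind, truth))
      }
    }
    slides
  })
}

#' Toy segmenter for synthetic tiles
#'
#' Global Otsu threshold (dark foreground) followed by 4-connected
#' component labeling.  Intended only for synthetic fixtures: touching
#' nuclei merge into one label, so the component count may undershoot
#' the generating truth.  Tiles without a separable dark class (blank or
#' pure background noise) give an all-zero mask.
#'
#' @param image 8-bit gray matrix (dark nuclei on light background)
#' @param min_contrast minimum gray-level separation between the two
#'   Otsu classes for the tile to count as non-blank
#' @return integer instance mask with attribute `n_objects`
#' @export
toy_segment <- function(image, min_contrast = 25) {
  img <- as.matrix(image)
  out <- matrix(0L, nrow(img), ncol(img))
  if (diff(range(img)) > 0) {
    thr <- EBImage::otsu(EBImage::Image(img / 255), range = c(0, 1)) * 255
    fg <- img < thr
    if (any(fg) && any(!fg) &&
        mean(img[!fg]) - mean(img[fg]) >= min_contrast) {
      lab <- EBImage::bwlabel(fg * 1)
      out <- matrix(as.integer(lab), nrow(img))
    }
  }
  attr(out, "n_objects") <- max(out)
  out
}

#' Write a synthetic dataset to disk
#'
#' Tiles become 8-bit gray PNG, instance masks 16-bit TIFF, and the
#' dataset gets a `manifest.csv` (slide_id, label, tile_path, mask_path,
#' x, y) plus one JSON truth file per slide.
#'
#' @param dataset output of [generate_dataset()]
#' @param dir output directory (created if missing)
#' @return the manifest data.frame, invisibly
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (slide in dataset) {
    sdir <- file.path(dir, slide$slide_id)
    dir.create(sdir, showWarnings = FALSE)
    for (t in seq_along(slide$tiles)) {
      tl <- slide$tiles[[t]]
      tp <- file.path(slide$slide_id, sprintf("tile_%03d.png", t))
      mp <- file.path(slide$slide_id, sprintf("mask_%03d.tif", t))
      png::writePNG(tl$image / 255, file.path(dir, tp))
      tiff::writeTIFF(tl$mask / 65535, file.path(dir, mp),
                      bits.per.sample = 16L)
      rows[[length(rows) + 1L]] <- data.frame(
        slide_id = slide$slide_id, label = slide$label,
        tile_path = tp, mask_path = mp,
        x = tl$origin[["x"]], y = tl$origin[["y"]])
    }
    jsonlite::write_json(slide$truth,
                         file.path(sdir, "truth.json"), digits = NA)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.csv`
#' @return list of slides in the [generate_dataset()] structure (truth
#'   tables are reloaded from the per-slide JSON files)
#' @export
read_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  slides <- list()
  for (sid in unique(manifest$slide_id)) {
    rows <- manifest[manifest$slide_id == sid, , drop = FALSE]
    tiles <- lapply(seq_len(nrow(rows)), function(k) {
      img <- round(png::readPNG(file.path(dir, rows$tile_path[k])) * 255)
      msk <- round(tiff::readTIFF(file.path(dir, rows$mask_path[k])) * 65535)
      storage.mode(msk) <- "integer"
      list(image = img, mask = msk,
           origin = c(x = rows$x[k], y = rows$y[k]), witness = NA)
    })
    tp <- file.path(dir, sid, "truth.json")
    truth <- if (file.exists(tp))
      jsonlite::read_json(tp, simplifyVector = TRUE) else NULL
    slides[[sid]] <- list(slide_id = sid, label = rows$label[1L],
                          tiles = tiles, truth = truth)
  }
  slides
}

#' Positive/negative composition of a slide-label manifest
#'
#' @param labels vector of slide labels (0 = normal, 1 = cancerous)
#' @return list with counts and the positive/negative percentages,
#'   rounded half-up to two decimals
#' @export
dataset_summary <- function(labels) {
  stopifnot(all(labels %in% c(0L, 1L)))
  n <- length(labels)
  pos <- sum(labels == 1L)
  list(n = n, n_positive = pos, n_negative = n - pos,
       positive_pct = round_half_up(100 * pos / n, 2L),
       negative_pct = round_half_up(100 * (n - pos) / n, 2L))
}
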