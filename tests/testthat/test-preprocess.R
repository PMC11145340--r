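# fixtures: small RGB slides with known saturated regions
white_slide <- function(h = 128, w = 128) array(1, c(h, w, 3))

blob_slide <- function(h = 256, w = 256, r1 = 60, r2 = 160,
                       c1 = 60, c2 = 160) {
  s <- white_slide(h, w)
  s[r1:r2, c1:c2, 1] <- 0.85   # pink-ish, saturated block
  s[r1:r2, c1:c2, 2] <- 0.35
  s[r1:r2, c1:c2, 3] <- 0.55
  s
}

test_that("tissue masking isolates saturated regions", {
  expect_warning(tm <- tissue_mask(white_slide(), level = 0L,
                                   area_threshold = 10),
                 "empty")
  expect_false(any(tm$mask))

  tm2 <- tissue_mask(blob_slide(), level = 0L, area_threshold = 100)
  got <- which(tm2$mask, arr.ind = TRUE)
  # single component covering the blob up to the closing radius
  expect_equal(max(tm2$components), 1L)
  expect_true(all(got[, 1] >= 60 - 3 & got[, 1] <= 160 + 3))
  expect_true(all(got[, 2] >= 60 - 3 & got[, 2] <= 160 + 3))
  expect_gte(sum(tm2$mask), 101 * 101 * 0.95)

  # a small interior hole is closed
  s <- blob_slide()
  s[100:102, 100:102, ] <- 1
  tm3 <- tissue_mask(s, level = 0L, area_threshold = 100)
  expect_true(all(tm3$mask[100:102, 100:102]))

  # idempotence: re-closing the mask changes nothing
  brush <- EBImage::makeBrush(5L, "disc")
  reclosed <- EBImage::closing(EBImage::Image(tm2$mask * 1), brush) > 0
  expect_equal(matrix(as.logical(reclosed), 256, 256), tm2$mask)

  # components below the area threshold are dropped
  s4 <- blob_slide()
  s4[10:13, 10:13, 1] <- 0.9; s4[10:13, 10:13, 2] <- 0.3
  tm4 <- tissue_mask(s4, level = 0L, area_threshold = 100)
  expect_false(any(tm4$mask[10:13, 10:13]))
  expect_equal(max(tm4$components), 1L)
})

test_that("tiling covers exactly the windows that touch tissue", {
  full <- tissue_mask(blob_slide(1024, 1024, 20, 1024, 20, 1024),
                      level = 0L, area_threshold = 100)
  ti <- tile_index(c(1024, 1024), full, 512L)
  expect_equal(nrow(ti$tiles), 4L)
  expect_equal(ti$tiles$x, c(0L, 512L, 0L, 512L))
  expect_equal(ti$tiles$y, c(0L, 0L, 512L, 512L))

  suppressWarnings(
    none <- tissue_mask(white_slide(), level = 0L, area_threshold = 10))
  expect_equal(nrow(tile_index(c(128, 128), none, 64L)$tiles), 0L)

  # oracle: brute-force scan of every grid window against the mask
  set.seed(71)
  blob <- tissue_mask(blob_slide(256, 256, 33, 140, 90, 220),
                      level = 0L, area_threshold = 100)
  ti2 <- tile_index(c(256, 256), blob, 64L)
  want <- list()
  for (y in seq(0, 192, 64)) for (x in seq(0, 192, 64)) {
    if (any(blob$mask[(y + 1):(y + 64), (x + 1):(x + 64)]))
      want[[length(want) + 1]] <- c(x, y)
  }
  want <- do.call(rbind, want)
  expect_equal(nrow(ti2$tiles), nrow(want))
  expect_true(all(ti2$tiles$x == want[, 1] & ti2$tiles$y == want[, 2]))

  # round trip: crop + reassemble reproduces the tiled extent exactly
  img <- matrix(stats::runif(256 * 256), 256, 256)
  tiles <- extract_tiles(img, ti2)
  back <- reassemble_tiles(tiles, ti2, fill = NA)
  filled <- !is.na(back)
  expect_true(any(filled))
  expect_equal(back[filled], img[filled])
})

test_that("the stub extractor is deterministic with distinct outputs", {
  ex <- stub_extractor(width = 256L, pools = c(8L, 1L), seed = 72)
  set.seed(73)
  t1 <- matrix(stats::runif(64 * 64, 0, 255), 64, 64)
  t2 <- matrix(stats::runif(64 * 64, 0, 255), 64, 64)
  expect_identical(ex$fun(t1), ex$fun(t1))
  expect_gt(sum(abs(ex$fun(t1) - ex$fun(t2))), 0)

  bag <- extract_features(list(t1, t2), ex,
                          coords = rbind(c(0, 0), c(64, 0)),
                          slide_id = "s", label = 0L)
  expect_equal(dim(bag$features), c(2L, 256L))
  expect_equal(bag$features[1, ], ex$fun(t1))
  expect_equal(bag$coords[2, ], c(64, 0))

  bad <- ex; bad$width <- 999L
  expect_error(extract_features(list(t1), bad), "width")

  # non-multiple tile sizes fall back to resize, still deterministic
  t3 <- matrix(stats::runif(50 * 50, 0, 255), 50, 50)
  expect_identical(ex$fun(t3), ex$fun(t3))
})

test_that("synthetic slides compose and bag consistently", {
  ds <- tiny_dataset(seed = 74, slides = 1L, tiles = 4L, tile_size = 64,
                     nuclei = c(3L, 5L))
  slide <- ds[[1]]
  img <- compose_slide(slide)
  expect_equal(dim(img), c(128L, 128L))
  # tile origins land on the grid and bag rows align with tiles
  bags <- build_bags(ds, stub_extractor(width = 64L, pools = c(8L, 1L)))
  expect_equal(nrow(bags[[1]]$features), 4L)
  expect_equal(bags[[1]]$label, slide$label)
})
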