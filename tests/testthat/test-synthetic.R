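test_that("the generator is bit-deterministic under a fixed seed", {
  cfg <- synthetic_config(seed = 21, n_slides_per_class = 2,
                          tiles_per_slide = 2, tile_size = 64,
                          nuclei_per_tile = c(4L, 6L))
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a, b)
  # a different seed changes the pixels
  c3 <- generate_dataset(synthetic_config(seed = 22,
                                          n_slides_per_class = 2,
                                          tiles_per_slide = 2,
                                          tile_size = 64,
                                          nuclei_per_tile = c(4L, 6L)))
  expect_false(identical(a[[1]]$tiles[[1]]$image,
                         c3[[1]]$tiles[[1]]$image))
})

test_that("bag structure follows the label and witness configuration", {
  ds <- tiny_dataset(seed = 23)
  labels <- vapply(ds, `[[`, integer(1), "label")
  expect_equal(unname(dataset_summary(labels)$positive_pct), 50)
  for (slide in ds) {
    wit <- vapply(slide$tiles, `[[`, logical(1), "witness")
    if (slide$label == 1L) expect_gte(sum(wit), 1L)
    else expect_equal(sum(wit), 0L)
  }
  # witness_rate 1 marks every tile of a positive slide
  full <- generate_dataset(synthetic_config(seed = 24,
                                            n_slides_per_class = 1,
                                            tiles_per_slide = 4,
                                            tile_size = 64,
                                            nuclei_per_tile = c(3L, 5L),
                                            witness_rate = 1))
  pos <- full[[which(vapply(full, `[[`, integer(1), "label") == 1L)]]
  expect_true(all(vapply(pos$tiles, `[[`, logical(1), "witness")))
})

test_that("instance masks hold single 4-connected components on the grid", {
  ds <- tiny_dataset(seed = 25, slides = 1L, tiles = 2L)
  for (slide in ds) {
    for (tl in slide$tiles) {
      expect_true(all(tl$origin %% 96 == 0))
      labs <- setdiff(unique(as.vector(tl$mask)), 0L)
      expect_identical(sort(labs), seq_along(labs))
      for (k in labs) {
        comp <- EBImage::bwlabel((tl$mask == k) * 1)
        expect_equal(max(comp), 1)
      }
    }
  }
})

test_that("degenerate morphology configurations are rejected", {
  bad <- class_params(0L); bad$area_mean <- 0
  expect_error(synthetic_config(params = list("0" = bad,
                                              "1" = class_params(1L))),
               "area_mean")
  expect_error(synthetic_config(witness_rate = 0), "witness_rate")
  expect_error(synthetic_config(witness_rate = 1.2), "witness_rate")
})

test_that("toy segmentation recovers disjoint nuclei and flags the count", {
  ds <- tiny_dataset(seed = 26, slides = 1L, tiles = 1L,
                     nuclei = c(5L, 5L))
  tl <- ds[[1]]$tiles[[1]]
  seg <- toy_segment(tl$image)
  expect_equal(attr(seg, "n_objects"), max(tl$mask))

  # blank tile segments to nothing
  blank <- matrix(230, 64, 64)
  expect_equal(max(toy_segment(blank)), 0)
  expect_equal(attr(toy_segment(blank), "n_objects"), 0)

  # two touching disks merge into one component: count undershoots
  img <- matrix(230, 40, 40)
  for (r in 1:40) for (c in 1:40) {
    if ((r - 20)^2 + (c - 15)^2 <= 36 || (r - 20)^2 + (c - 25)^2 <= 36)
      img[r, c] <- 80
  }
  merged <- toy_segment(img)
  expect_equal(attr(merged, "n_objects"), 1L)
})

test_that("dataset round-trips through the on-disk format", {
  ds <- tiny_dataset(seed = 27, slides = 1L, tiles = 2L, tile_size = 64,
                     nuclei = c(3L, 5L))
  dir <- withr::local_tempdir()
  manifest <- write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(nrow(manifest), 2L * length(ds))
  back <- read_dataset(dir)
  expect_equal(names(back), names(ds))
  for (nm in names(ds)) {
    expect_equal(back[[nm]]$label, ds[[nm]]$label)
    expect_equal(back[[nm]]$tiles[[1]]$image, ds[[nm]]$tiles[[1]]$image)
    expect_equal(back[[nm]]$tiles[[1]]$mask, ds[[nm]]$tiles[[1]]$mask)
  }
})
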