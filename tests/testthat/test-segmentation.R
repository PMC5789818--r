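test_that("a blank image yields zero objects", {
  img <- make_projected(matrix(0, 64, 64))
  mask <- segment_category(img, segmentation_params("DAPI", threshold = 10),
                           "dapi")
  expect_equal(nrow(mask$features), 0L)
  expect_true(all(mask$labels == 0L))
})

test_that("a rasterised disk segments as one object with circularity >= 0.9", {
  dapi <- matrix(0, 96, 96)
  dapi[disk_mask(96, 48, 48, 20)] <- 5000
  img <- make_projected(dapi)
  mask <- segment_category(img, segmentation_params("DAPI", threshold = 1000),
                           "dapi")
  expect_equal(nrow(mask$features), 1L)
  expect_gte(mask$features$circularity, 0.9)
  ## oracle: area and chain-perimeter computed on the raster directly
  d <- disk_mask(96, 48, 48, 20)
  expect_equal(mask$features$area, sum(d))
  expect_equal(mask$features$circularity,
               min(1, 4 * pi * sum(d) / mask_perimeter(d)^2))
})

test_that("circularity bounds hold for disks (>= 0.9) and 5:1 bars (< 0.6)", {
  for (r in c(10, 15, 20, 30)) {
    expect_gte(mask_circularity(disk_mask(96, 48, 48, r)), 0.9)
    expect_lte(mask_circularity(disk_mask(96, 48, 48, r)), 1.0)
  }
  for (w in c(10, 16, 20)) {
    expect_lt(mask_circularity(bar_mask(128, 64, 64, 5 * w, w)), 0.6)
  }
})

test_that("the circularity filter keeps a disk and drops an equal-area 5:1 bar", {
  ## disk r ~ 17.8 px has area ~1000; bar 70x14 px REALLY 980 px
  dapi <- matrix(0, 160, 160)
  d <- disk_mask(160, 45, 45, 17.8)
  b <- bar_mask(160, 110, 110, 70, 14)
  dapi[d | b] <- 5000
  img <- make_projected(dapi)
  ## brute-force circularities of the two rasterised shapes
  circ_d <- mask_circularity(d); circ_b <- mask_circularity(b)
  expect_gt(circ_d, 0.8); expect_lt(circ_b, 0.8)
  mask <- segment_category(img, segmentation_params("DAPI", threshold = 1000,
                                                    min_circularity = 0.8),
                           "dapi")
  expect_equal(nrow(mask$features), 1L)
  ## the survivor is the disk (centroid near 45,45)
  expect_lt(abs(mask$features$cx - 45), 1)
  expect_lt(abs(mask$features$cy - 45), 1)
})

test_that("area bounds filter objects on both sides", {
  dapi <- matrix(0, 96, 96)
  dapi[disk_mask(96, 25, 25, 4)] <- 5000   # area ~ 50
  dapi[disk_mask(96, 65, 65, 15)] <- 5000  # area ~ 700
  img <- make_projected(dapi)
  mask <- segment_category(img, segmentation_params("DAPI", threshold = 1000,
                                                    min_area_px = 100,
                                                    max_area_px = 2000),
                           "dapi")
  expect_equal(nrow(mask$features), 1L)
  expect_gt(mask$features$area, 600)
})

test_that("connected components are 8-connected", {
  dapi <- matrix(0, 16, 16)
  dapi[cbind(c(4, 5, 6), c(4, 5, 6))] <- 5000  # diagonal chain
  img <- make_projected(dapi)
  mask <- segment_category(img, segmentation_params("DAPI", threshold = 1000),
                           "dapi")
  expect_equal(nrow(mask$features), 1L)
  expect_equal(mask$features$area, 3)
})

test_that("masks saved and reloaded reproduce identical measurements", {
  sp <- tiny_scene_params(seed = 21L, z = 4L)
  gen <- generate_scene(sp)
  out <- analyze_field(gen$stack, 1L, imaging_config())
  mask <- out$cell_set$dapi_mask
  f <- withr::local_tempfile(fileext = ".tif")
  write_mask(mask, f)
  m <- channel_matrix(out$subtracted, "DAPI")
  back <- read_mask(f, category = "dapi", intensity = m)
  expect_identical(back$labels, mask$labels)
  expect_equal(back$features$area, mask$features$area)
  expect_equal(back$features$circularity, mask$features$circularity)
  expect_equal(back$features$mean_intensity, mask$features$mean_intensity)
})

test_that("otsu thresholding separates bright objects from background automatically", {
  set.seed(7)
  dapi <- matrix(rnorm(96 * 96, 500, 30), 96, 96)
  dapi[disk_mask(96, 48, 48, 18)] <- rnorm(sum(disk_mask(96, 48, 48, 18)), 8000, 100)
  img <- make_projected(pmax(dapi, 0))
  mask <- segment_category(img, segmentation_params("DAPI", threshold = "otsu",
                                                    min_area_px = 50),
                           "dapi")
  expect_equal(nrow(mask$features), 1L)
  expect_gt(mask$threshold, 600)
  expect_lt(mask$threshold, 8000)
})
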