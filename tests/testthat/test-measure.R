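## one interphase nucleus mask on a hand-built projection
simple_cellset <- function(n = 96, r = 15, cx = 48, cy = 48) {
  dapi <- matrix(0, n, n)
  dapi[disk_mask(n, cx, cy, r)] <- 8000
  img <- make_projected(dapi)
  dm <- segment_category(img, segmentation_params("DAPI", threshold = 1000), "dapi")
  classify_cells(dm)
}

test_that("a zero PLA channel measures zero", {
  cs <- simple_cellset()
  pla <- matrix(0, 96, 96)
  out <- measure_pla(pla, cs, "nucleus")
  expect_equal(out$pla_sum_intensity, 0)
})

test_that("two rendered puncta inside the mask measure their summed flux within 2%", {
  sp <- tiny_scene_params(cells = c(0L, 0L), size = 96L, z = 6L,
                          noise = noise_free())
  sc <- simulate_ground_truth(sp)
  sc$puncta <- data.frame(cell_id = 1L, field = 1L,
                          x = c(44, 52), y = c(46, 50), z = c(3L, 4L),
                          integrated_intensity = c(500, 300),
                          compartment = "nucleus", punctum_id = 1:2)
  st <- render_acquisition(sc, sp)
  proj <- max_intensity_projection(st, 1L)
  ## a generous mask fully containing both puncta
  cs <- simple_cellset(96, r = 30)
  ## sum of the full TRITC stack is the conserved flux; the projection keeps
  ## at least the in-focus plane's share, so measure on the summed z instead
  tot <- matrix(0, 96, 96)
  for (z in 1:6) tot <- tot + st$data[, , 3, z, 1]
  out <- measure_pla(tot, cs, "nucleus")
  expect_lt(abs(out$pla_sum_intensity - 800) / 800, 0.02)
})

test_that("measurement is monotone under mask inclusion and additive over disjoint masks", {
  set.seed(33)
  pla <- matrix(rpois(96 * 96, 50), 96, 96)
  cs_small <- simple_cellset(96, r = 10)
  cs_big <- simple_cellset(96, r = 25)
  small <- measure_pla(pla, cs_small, "nucleus")$pla_sum_intensity
  big <- measure_pla(pla, cs_big, "nucleus")$pla_sum_intensity
  expect_lte(small, big)
  ## additivity: two disjoint nuclei sum to the union measurement
  dapi <- matrix(0, 128, 128)
  dapi[disk_mask(128, 35, 35, 12)] <- 8000
  dapi[disk_mask(128, 90, 90, 12)] <- 8000
  img <- make_projected(dapi)
  dm <- segment_category(img, segmentation_params("DAPI", threshold = 1000), "dapi")
  cs2 <- classify_cells(dm)
  pla2 <- matrix(rpois(128 * 128, 50), 128, 128)
  per_cell <- measure_pla(pla2, cs2, "nucleus")$pla_sum_intensity
  expect_equal(sum(per_cell), sum(pla2[dm$labels > 0]))
})

test_that("invalid selections for a cell class raise errors", {
  cs <- simple_cellset()
  pla <- matrix(0, 96, 96)
  expect_error(measure_pla(pla, cs, "spindle"), "not available")
  expect_error(measure_pla(pla, cs, "chromosomes"), "not defined")
  ## union works for any class
  expect_equal(measure_pla(pla, cs, "union")$pla_sum_intensity, 0)
})

test_that("mitotic union selection covers chromosomes plus linked spindle", {
  dapi <- matrix(0, 128, 128)
  dapi[bar_mask(128, 60, 60, 40, 14)] <- 20000
  fitc <- matrix(0, 128, 128)
  fitc[bar_mask(128, 60, 78, 16, 40)] <- 15000
  img <- make_projected(dapi, fitc)
  dm <- segment_category(img, segmentation_params("DAPI", threshold = 1000), "dapi")
  sm <- segment_category(img, segmentation_params("FITC", threshold = 1000), "spindle")
  cs <- classify_cells(dm, sm)
  pla <- matrix(1, 128, 128)  # uniform: measurement equals mask area
  u <- measure_pla(pla, cs, "union")$pla_sum_intensity
  chr <- measure_pla(pla, cs, "chromosomes")$pla_sum_intensity
  spv <- measure_pla(pla, cs, "spindle")$pla_sum_intensity
  union_area <- sum((dm$labels > 0) | (sm$labels > 0))
  expect_equal(u, union_area)
  expect_lte(chr, u)
  expect_lte(spv, u)
  expect_gte(chr + spv, u)  # overlap counted once in the union
})
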