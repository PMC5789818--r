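test_that("empty fields render as background plus noise only", {
  sp <- tiny_scene_params(cells = c(0L, 0L), z = 4L, size = 64L)
  gen <- generate_scene(sp)
  expect_equal(nrow(gen$scene$objects), 0L)
  expect_equal(nrow(gen$scene$puncta), 0L)
  bg <- sp$noise$background
  for (ci in 1:3) {
    m <- mean(gen$stack$data[, , ci, , 1])
    expect_lt(abs(m - bg[ci]), 5 * sp$noise$read_sd)
  }
})

test_that("identical seed and parameters give bit-identical scenes and stacks", {
  sp <- tiny_scene_params(seed = 11L, z = 4L)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(a$scene$objects, b$scene$objects)
  expect_identical(a$scene$puncta, b$scene$puncta)
  expect_identical(a$stack$data, b$stack$data)
  cc <- generate_scene(update_scene_params(sp, rng_seed = 12L))
  expect_false(identical(a$stack$data, cc$stack$data))
})

test_that("stack dimensions follow the acquisition protocol (fields x z x 3 channels)", {
  sp <- tiny_scene_params(fields = 2L, z = 10L, size = 128L, cells = c(1L, 1L))
  gen <- generate_scene(sp)
  expect_equal(dim(gen$stack$data)[3:5], c(3L, 10L, 2L))
  expect_equal(gen$stack$channels, c("DAPI", "FITC", "TRITC"))
  ## the full-protocol grid is 60 fields x 10 z x 3 channels
  sp60 <- scene_params()
  expect_equal(sp60$field_grid_count, 60L)
  expect_equal(sp60$z_planes, 10L)
  expect_equal(length(sp60$channels), 3L)
})

test_that("mitotic chromosome masses are brighter and less round than interphase nuclei", {
  ## ground-truth contrast over ~1000 cells, measured straight from the
  ## generator's object list (no imaging involved)
  sp <- scene_params(field_grid_count = 170L, mitotic_fraction = 0.5,
                     rng_seed = 42L)
  sc <- simulate_ground_truth(sp)
  ob <- sc$objects[sc$objects$channel == "DAPI", ]
  expect_gt(nrow(ob), 900L)
  mit <- ob[ob$class == "mitotic_chromosomes", ]
  intp <- ob[ob$class == "interphase_nucleus", ]
  expect_gt(mean(mit$peak_intensity), mean(intp$peak_intensity))
  expect_lt(mean(mit$circularity), mean(intp$circularity))
  ## single threshold pair separates the classes with <= 5% overlap error
  thr_int <- 13000; thr_circ <- 0.91
  mis_mit <- mean(!(mit$peak_intensity > thr_int & mit$circularity < thr_circ))
  mis_int <- mean(intp$peak_intensity > thr_int & intp$circularity < thr_circ)
  expect_lt(mis_mit, 0.05)
  expect_lt(mis_int, 0.05)
})

test_that("importazole thinning reduces expected puncta by the configured fold", {
  base <- tiny_scene_params(fields = 40L, mitotic_fraction = 1,
                            cells = c(4L, 4L), size = 256L, seed = 5L)
  ## ground truth only; no rendering needed for the thinning property
  ctr <- simulate_ground_truth(base)
  ipz <- simulate_ground_truth(update_scene_params(base, condition = "IPZ"))
  fold <- base$ipz_puncta_fold_reduction
  ratio <- nrow(ctr$puncta) / nrow(ipz$puncta)
  ## binomial thinning: observed count ratio close to the configured fold
  expect_gt(ratio, fold * 0.75)
  expect_lt(ratio, fold * 1.35)
  ## placement is unchanged: IPZ puncta compartments are a subset pattern
  expect_true(all(ipz$puncta$compartment %in%
                    c("spindle", "chromosome_periphery", "cytoplasm", "nucleus")))
})

test_that("an image too small for the requested cells fails with a placement error", {
  sp <- tiny_scene_params(cells = c(30L, 30L), size = 128L)
  expect_error(simulate_ground_truth(sp), "placement failure")
  sp2 <- tiny_scene_params(cells = c(1L, 1L), size = 32L)
  expect_error(simulate_ground_truth(sp2), "placement failure")
})

test_that("rendered puncta conserve integrated intensity in the noise-free limit", {
  sp <- tiny_scene_params(cells = c(0L, 0L), size = 96L, z = 10L,
                          noise = noise_free())
  sc <- simulate_ground_truth(sp)
  sc$puncta <- data.frame(cell_id = 1L, field = 1L,
                          x = c(48, 30), y = c(48, 60), z = c(5L, 2L),
                          integrated_intensity = c(5000, 800),
                          compartment = "spindle", punctum_id = 1:2)
  st <- render_acquisition(sc, sp)
  total <- sum(st$data[, , 3, , 1])
  expect_lt(abs(total - 5800) / 5800, 0.01)
})

test_that("a single-plane acquisition equals its own maximum projection", {
  sp <- tiny_scene_params(z = 1L, cells = c(2L, 2L), seed = 3L)
  gen <- generate_scene(sp)
  proj <- max_intensity_projection(gen$stack, 1L)
  expect_equal(proj$data[, , 1], gen$stack$data[, , 1, 1, 1])
  expect_equal(proj$data[, , 3], gen$stack$data[, , 3, 1, 1])
})

test_that("scene ground truth round-trips through JSON", {
  sp <- tiny_scene_params(seed = 9L)
  sc <- simulate_ground_truth(sp)
  f <- withr::local_tempfile(fileext = ".json")
  write_scene_json(sc, f)
  back <- read_scene_json(f)
  n <- 192L
  expect_equal(back$objects$object_id, sc$objects$object_id)
  expect_equal(back$objects$circularity, sc$objects$circularity, tolerance = 1e-12)
  expect_equal(back$puncta$integrated_intensity, sc$puncta$integrated_intensity,
               tolerance = 1e-12)
  expect_equal(length(back$shapes), length(sc$shapes))
  ## analytic membership identical after reload
  o1 <- sc$objects$object_id[1]
  xs <- seq(1, n, by = 7); ys <- seq(1, n, by = 7)
  g <- expand.grid(x = xs, y = ys)
  expect_equal(mitopla:::truth_object_contains(back, o1, g$x, g$y),
               mitopla:::truth_object_contains(sc, o1, g$x, g$y))
})

test_that("acquisition stacks round-trip through 16-bit multi-page TIFF", {
  sp <- tiny_scene_params(fields = 2L, z = 3L, size = 160L, cells = c(1L, 2L))
  gen <- generate_scene(sp)
  f <- withr::local_tempfile(fileext = ".tif")
  write_stack(gen$stack, f)
  back <- read_stack(f)
  expect_equal(back$data, gen$stack$data)
  expect_equal(back$channels, gen$stack$channels)
  expect_equal(back$pixel_size_um, gen$stack$pixel_size_um)
})
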