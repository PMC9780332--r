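# build a minimal cell_region by hand (used for degenerate geometries)
manual_cell <- function(mask_idx, medial_axis01, dim) {
  structure(list(label = 1L, mask_idx = mask_idx,
                 centroid = c(NA, NA), medial_axis = medial_axis01,
                 area_px = length(mask_idx), length_um = NA, width_um = NA,
                 circularity = NA, angularity = NA, image_dim = dim,
                 pixel_size = 0.065),
            class = "cell_region")
}

test_that("midpoint reference reads the dilute cytoplasm", {
  # uniform cell: reference equals the uniform intensity
  p <- clean_scene_params(n_cells = 3L, condensate_fraction = 0,
                          cytoplasm_intensity = 77, seed = 31)
  sc <- generate_scene(p)
  cells <- segment_cells(sc$image)
  for (cell in cells) {
    expect_equal(midpoint_reference(cell, sc$image), 77)
  }
  # polar focus at rho = 2 does not contaminate the midpoint
  p2 <- clean_scene_params(n_cells = 3L, condensate_fraction = 1,
                           partition_ratio = 2, cytoplasm_intensity = 100,
                           seed = 32)
  sc2 <- generate_scene(p2)
  cells2 <- segment_cells(sc2$image)
  expect_gt(length(cells2), 0)
  for (cell in cells2) {
    expect_equal(midpoint_reference(cell, sc2$image), 100)
  }
})

test_that("midpoint reference handles a 1-px-wide cell", {
  img <- matrix(0, 20, 20)
  img[10, 4:16] <- 50
  img[10, 10] <- 60  # midpoint pixel itself
  idx <- (c(4:16) - 1L) * 20L + 10L
  ax <- cbind(rep(9, 13), 3:15)  # 0-based (row, col)
  cell <- manual_cell(idx, ax, c(20L, 20L))
  # disk radius 3 on a 1-px line = the 7 midpoint-adjacent pixels
  expect_equal(midpoint_reference(cell, img), median(img[10, 7:13]))
  # degenerate: empty disk/mask intersection
  cell_far <- manual_cell(idx, cbind(rep(0, 3), 0:2), c(20L, 20L))
  expect_error(midpoint_reference(cell_far, img),
               class = "degenerate_cell")
  # too-short medial axis
  cell_short <- manual_cell(idx, ax[1:2, , drop = FALSE], c(20L, 20L))
  expect_error(midpoint_reference(cell_short, img),
               class = "degenerate_cell")
})

test_that("condensate detection respects the intensity-ratio threshold", {
  # rho = 1 (uniform): never called
  p1 <- clean_scene_params(n_cells = 6L, partition_ratio = 1,
                           condensate_fraction = 1, seed = 33)
  r1 <- run_scene_pipeline(p1)
  expect_true(all(!vapply(r1$calls, `[[`, TRUE, "has_condensate")))
  # rho = 2: every cell called, enrichment exactly 2 without blur
  p2 <- clean_scene_params(n_cells = 6L, partition_ratio = 2,
                           condensate_fraction = 1, seed = 34)
  sc2 <- generate_scene(p2)
  cells2 <- segment_cells(sc2$image)
  calls2 <- call_cells(cells2, sc2$image)
  expect_true(all(vapply(calls2, `[[`, TRUE, "has_condensate")))
  er <- vapply(calls2, `[[`, 0, "enrichment_ratio")
  expect_true(all(abs(er - 2) <= 0.05))
  # rho = 1.15 sits below the 1.20 threshold: never called
  p3 <- clean_scene_params(n_cells = 6L, partition_ratio = 1.15,
                           condensate_fraction = 1, seed = 35)
  sc3 <- generate_scene(p3)
  cells3 <- segment_cells(sc3$image)
  calls3 <- call_cells(cells3, sc3$image)
  expect_true(all(!vapply(calls3, `[[`, TRUE, "has_condensate")))
  expect_error(detect_condensates(cells3[[1]], sc3$image, threshold = 1.0),
               class = "invalid_argument")
})

test_that("calls are invariant to global intensity scaling", {
  p <- scene_params(n_cells = 10L, condensate_fraction = 0.6, seed = 36)
  sc <- generate_scene(p)
  cells <- segment_cells(rolling_ball_subtract(sc$image, 100))
  img1 <- rolling_ball_subtract(sc$image, 100)
  img2 <- micrograph(as_pix <- img1$pixels * 3.7, img1$pixel_size)
  c1 <- call_cells(cells, img1)
  c2 <- call_cells(cells, img2)
  expect_identical(vapply(c1, `[[`, TRUE, "has_condensate"),
                   vapply(c2, `[[`, TRUE, "has_condensate"))
  expect_equal(vapply(c1, `[[`, 0, "enrichment_ratio"),
               vapply(c2, `[[`, 0, "enrichment_ratio"), tolerance = 1e-9)
})

test_that("fraction statistic counts correctly", {
  expect_equal(fraction_with_condensates(
    c(rep(TRUE, 7), rep(FALSE, 3)))$fraction, 0.7)
  expect_equal(fraction_with_condensates(rep(FALSE, 5))$fraction, 0)
  expect_error(fraction_with_condensates(list()), class = "empty_input")
})

test_that("strain classification uses an inclusive 0.11 cutoff", {
  expect_false(classify_strain(0.10))
  expect_true(classify_strain(0.11))
  expect_true(classify_strain(0.95))
  fr <- fraction_with_condensates(c(TRUE, rep(FALSE, 9)))
  expect_false(classify_strain(fr))
})

test_that("threshold sweep steps at the true partition ratio", {
  # all cells at rho = 1.5: fraction 1 below, 0 above
  p <- clean_scene_params(n_cells = 8L, partition_ratio = 1.5,
                          condensate_fraction = 1, seed = 37)
  sc <- generate_scene(p)
  cells <- segment_cells(sc$image)
  sw <- threshold_sweep(cells, sc$image, thresholds = c(1.05, 1.45, 1.55, 1.9))
  expect_equal(sw$fraction, c(1, 1, 0, 0))
  # mixed rho {1.2, 1.8} in equal numbers
  pm <- clean_scene_params(n_cells = 8L, partition_ratio = c(1.2, 1.8),
                           condensate_fraction = 1, seed = 38)
  scm <- generate_scene(pm)
  cellsm <- segment_cells(scm$image)
  swm <- threshold_sweep(cellsm, scm$image, thresholds = c(1.05, 1.5, 1.9))
  expect_equal(swm$fraction, c(1, 0.5, 0))
})

test_that("sweep fractions are non-increasing and inputs validated", {
  p <- scene_params(n_cells = 12L, condensate_fraction = 0.7, seed = 39)
  r <- run_scene_pipeline(p)
  sw <- threshold_sweep(r$cells, r$bg)
  expect_identical(nrow(sw), 20L)
  expect_true(all(diff(sw$fraction) <= 1e-12))
  expect_error(threshold_sweep(r$cells, r$bg, thresholds = c(1.5, 1.2)),
               class = "invalid_argument")
  expect_error(threshold_sweep(r$cells, r$bg, thresholds = c(0.9, 1.2)),
               class = "invalid_argument")
})
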