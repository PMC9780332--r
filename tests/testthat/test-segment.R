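test_that("rolling ball flattens constants and keeps small bright features", {
  flat <- matrix(25, 64, 64)
  out <- rolling_ball_subtract(flat, 10)
  expect_true(all(abs(out) < 1e-9))
  # constant + one bright 3x3 spot, large ball: spot survives at spot - c
  img <- matrix(40, 150, 150)
  img[70:72, 70:72] <- 140
  out <- rolling_ball_subtract(img, 100)
  expect_equal(max(out), 100, tolerance = 1e-6)
  expect_true(all(abs(out[70:72, 70:72] - 100) < 1e-6))
  out[70:72, 70:72] <- 0
  expect_true(all(abs(out) < 1e-6))
})

test_that("rolling ball matches brute-force grayscale opening", {
  set.seed(21)
  # random texture with a bright blob
  img <- matrix(runif(64 * 64, 0, 50), 64, 64)
  img[20:28, 35:43] <- img[20:28, 35:43] + 120
  expect_equal(rolling_ball_subtract(img, 8),
               oracle_ball_opening_subtract(img, 8), tolerance = 1e-9)
  # linear ramp, radius 10: the ball tracks the plane, so away from the
  # border kink (where the replicate-extended ramp flattens and the ball
  # cannot reach into the corner) the residual is far below the range
  ramp <- matrix(rep(seq(0, 100, length.out = 64), each = 64), 64, 64)
  res <- rolling_ball_subtract(ramp, 10)
  expect_lt(max(res[, 13:52]), 5)
  expect_equal(res, oracle_ball_opening_subtract(ramp, 10),
               tolerance = 1e-9)
})

test_that("rolling ball is monotone and translation-equivariant", {
  set.seed(22)
  a <- matrix(runif(48 * 48, 0, 80), 48, 48)
  b <- a + matrix(runif(48 * 48, 0, 15), 48, 48)  # pointwise larger
  ra <- rolling_ball_subtract(a, 6)
  rb <- rolling_ball_subtract(b, 6)
  # monotonicity holds for the background estimate (opening), so the
  # subtracted images cannot be reordered by more than the added offset
  bg_a <- a - ra; bg_b <- b - rb
  expect_true(all(bg_b - bg_a >= -1e-9))
  # translation: shift the content by 5 px; away from the shift cliff and
  # the borders (the opening depends on a 2-radius neighbourhood) the
  # subtracted image translates with it
  sh <- matrix(0, 48, 48)
  sh[6:48, ] <- a[1:43, ]
  rs <- rolling_ball_subtract(sh, 6)
  expect_equal(rs[18:41, ], ra[13:36, ], tolerance = 1e-9)
})

test_that("rolling ball rejects out-of-range radii", {
  expect_error(rolling_ball_subtract(matrix(1, 32, 32), 0),
               class = "invalid_argument")
  expect_error(rolling_ball_subtract(matrix(1, 32, 32), 32),
               class = "invalid_argument")
})

test_that("Li threshold separates two-valued images", {
  v <- c(rep(10, 900), rep(100, 124))
  t <- li_threshold(matrix(v, 32, 32))
  expect_gt(t, 10)
  expect_lt(t, 100)
  expect_error(li_threshold(matrix(5, 16, 16)), class = "degenerate_image")
})

test_that("Li fixed point attains the brute-force cross-entropy minimum", {
  set.seed(23)
  for (k in 1:50) {
    img <- random_bimodal_image(32)
    v <- as.numeric(img)
    t_impl <- li_threshold(img)
    minima <- oracle_li_minima(v)
    # canonical decision boundary: largest observed level below threshold
    b_impl <- max(v[v <= t_impl])
    expect_lte(min(abs(b_impl - minima)), 1)
  }
})

test_that("Li binarisation recovers the true cell mask on clean scenes", {
  p <- clean_scene_params(n_cells = 10L, condensate_fraction = 0, seed = 24)
  sc <- generate_scene(p)
  t <- li_threshold(sc$image)
  mask <- sc$image$pixels > t
  truth_idx <- unlist(lapply(sc$truth$cells, `[[`, "mask_idx"))
  expect_gte(mean(mask[truth_idx]), 0.99)
})

test_that("segmentation finds every cell with accurate centroids", {
  p <- clean_scene_params(n_cells = 20L, condensate_fraction = 0,
                          image_shape = c(520L, 520L), seed = 25)
  sc <- generate_scene(p)
  cells <- segment_cells(sc$image)
  expect_length(cells, 20L)
  truth <- sc$truth$summary
  for (cell in cells) {
    d <- sqrt((truth$centroid_row - cell$centroid[1])^2 +
              (truth$centroid_col - cell$centroid[2])^2)
    expect_lt(min(d), 1.0)
  }
})

test_that("shape descriptors recover the rendered geometry", {
  set.seed(26)
  for (k in 1:6) {
    L <- runif(1, 2.2, 3.9)
    W <- runif(1, 0.9, 1.1)
    p <- clean_scene_params(n_cells = 1L, image_shape = c(128L, 128L),
                            condensate_fraction = 0,
                            cell_length_range = c(L, L),
                            cell_width_range = c(W, W),
                            seed = 100 + k)
    cells <- segment_cells(generate_scene(p)$image)
    expect_length(cells, 1L)
    px <- 0.065
    expect_lt(abs(cells[[1]]$length_um - L) / px, 2)   # within 2 px
    expect_lt(abs(cells[[1]]$width_um - W) / px, 1)    # within 1 px
    expect_gte(cells[[1]]$length_um, cells[[1]]$width_um)
  }
})

test_that("round debris is rejected by the circularity constraint", {
  img <- matrix(0, 200, 200)
  # one genuine rod
  p <- clean_scene_params(n_cells = 1L, image_shape = c(200L, 200L),
                          condensate_fraction = 0, seed = 27)
  img <- generate_scene(p)$image$pixels
  # plus a round blob of similar brightness
  rr <- matrix(1:200, 200, 200); cc <- t(rr)
  img[(rr - 160)^2 + (cc - 160)^2 <= 12^2] <- 120
  cells <- segment_cells(micrograph(img))
  expect_length(cells, 1L)
  rej <- attr(cells, "rejects")
  expect_gte(rej[["circularity"]], 1L)
  # the kept region is the rod, not the blob
  expect_lt(cells[[1]]$circularity, 0.9)
})

test_that("blank images yield an empty cell list, not an error", {
  expect_length(segment_cells(matrix(0, 64, 64)), 0L)
})

test_that("border-touching components are discarded", {
  img <- matrix(0, 150, 150)
  img[1:20, 60:75] <- 120           # touches row 1
  p <- clean_scene_params(n_cells = 1L, image_shape = c(150L, 150L),
                          condensate_fraction = 0, seed = 28)
  img2 <- generate_scene(p)$image$pixels
  combined <- pmax(img, img2)
  cells <- segment_cells(micrograph(combined))
  expect_length(cells, 1L)
  expect_gte(attr(cells, "rejects")[["border"]], 1L)
})

test_that("segmentation recall and precision exceed 0.95 under default noise", {
  p <- scene_params(n_cells = 40L, condensate_fraction = 0.5, seed = 29)
  sc <- generate_scene(p)
  bg <- rolling_ball_subtract(sc$image, 100)
  cells <- segment_cells(bg)
  truth <- sc$truth$cells
  matched <- 0
  for (tc in truth) {
    for (cl in cells) {
      inter <- length(intersect(tc$mask_idx, cl$mask_idx))
      if (inter == 0) next
      un <- length(tc$mask_idx) + length(cl$mask_idx) - inter
      if (inter / un > 0.5) { matched <- matched + 1; break }
    }
  }
  expect_gte(matched / length(truth), 0.95)   # recall
  expect_gte(matched / length(cells), 0.95)   # precision
})
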