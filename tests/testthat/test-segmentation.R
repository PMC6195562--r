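test_that("dynamic threshold selects pixels relative to the frame maximum", {
  env <- matrix(c(100, 60, 49, 50, 10, 0), 2, 3)
  p <- segmentation_params(threshold_fraction = 0.5)
  expect_equal(threshold_binary(env, p), env >= 50)
  p99 <- segmentation_params(threshold_fraction = 0.999)
  expect_equal(which(threshold_binary(env, p99)), which(env == 100))
  expect_true(all(threshold_binary(matrix(5, 3, 3), p)))
  expect_error(threshold_binary(matrix(0, 2, 2), p), "all-zero")
})

test_that("opening removes single pixels and preserves solid blocks", {
  m <- matrix(FALSE, 9, 9)
  m[5, 5] <- TRUE
  expect_false(any(morph_clean(m, 1)))
  block <- matrix(FALSE, 14, 14)
  block[3:12, 3:12] <- TRUE
  opened <- morph_clean(block, 1)
  expect_true(all(opened[4:11, 4:11]))        # >= 8x8 core retained
  expect_true(all(opened[block == FALSE] == FALSE))
  expect_equal(morph_clean(matrix(FALSE, 4, 4), 1), matrix(FALSE, 4, 4))
  # agreement with brute-force opening on random masks
  withr::with_seed(9, {
    for (k in 1:5) {
      rm <- matrix(runif(15 * 15) < 0.4, 15, 15)
      expect_equal(morph_clean(rm, 1), morph_open_oracle(rm, 1))
    }
  })
})

test_that("component labeling respects the connectivity convention", {
  m <- matrix(FALSE, 6, 6)
  m[1, 1:3] <- TRUE
  m[5, 4:6] <- TRUE
  lab <- label_components(m, 8)
  expect_equal(sort(unname(lab$areas)), c(3, 3))
  expect_equal(length(label_components(matrix(FALSE, 3, 3), 8)$areas), 0)
  diagm <- matrix(FALSE, 3, 3)
  diagm[1, 1] <- diagm[2, 2] <- TRUE
  expect_equal(length(label_components(diagm, 8)$areas), 1)
  expect_equal(length(label_components(diagm, 4)$areas), 2)
  withr::with_seed(4, rnd <- matrix(runif(100) < 0.5, 10, 10))
  expect_equal(sum(label_components(rnd, 4)$areas), sum(rnd))
})

test_that("tip label selection requires a distinct area outlier", {
  p <- segmentation_params(min_area = 1)
  # quartiles by linear interpolation: fence = 4 + 1.5 * 1 = 5.5
  expect_equal(select_tip_label(c(2, 3, 3, 4, 50), p), 5L)
  expect_true(is.na(select_tip_label(c(3, 3, 4, 4), p)))
  expect_true(is.na(select_tip_label(integer(0), p)))
  expect_true(is.na(select_tip_label(c(40, 40, 2, 3, 3), p)))  # tied maxima
  expect_equal(select_tip_label(c(30), p), 1L)
  expect_true(is.na(select_tip_label(c(30),
                                     segmentation_params(min_area = 31))))
  # with two or three labels the largest must dominate 2:1
  expect_equal(select_tip_label(c(86, 5), p), 1L)
  expect_true(is.na(select_tip_label(c(86, 80), p)))
  # min_area applies on the fence path too
  expect_true(is.na(select_tip_label(c(2, 3, 3, 4, 50),
                                     segmentation_params(min_area = 60))))
})

test_that("region centroids are unweighted pixel means", {
  m <- matrix(0L, 12, 12)
  m[6, 8] <- 1L
  expect_equal(region_centroid(m, 1), c(row = 6, col = 8))
  m2 <- matrix(0L, 12, 12)
  m2[5:6, 10:11] <- 2L
  expect_equal(region_centroid(m2, 2), c(row = 5.5, col = 10.5))
  m3 <- matrix(0L, 3, 3)
  m3[1, 1] <- m3[2, 1] <- m3[2, 2] <- 3L
  expect_equal(region_centroid(m3, 3), c(row = 5 / 3, col = 4 / 3))
  expect_error(region_centroid(m3, 9), "not present")
})

test_that("segment_frame recovers injected blobs and rejects artifacts", {
  geom <- small_geom()
  grid <- small_grid(geom)
  p <- segmentation_params()
  withr::with_seed(21, {
    pos <- cbind(runif(25, -3, 3), runif(25, 8, 16))
  })
  for (i in seq_len(nrow(pos))) {
    img <- blob_image(grid,
                      list(list(lateral = pos[i, 1], axial = pos[i, 2],
                                amp = 1, sigma_lat = 0.8, sigma_ax = 0.4)),
                      floor_level = 0.05, seed = i)
    det <- segment_frame(img, p)
    expect_true(det$found)
    expect_lt(abs(det$tip_mm[1] - pos[i, 1]), grid$lateral_spacing)
    expect_lt(abs(det$tip_mm[2] - pos[i, 2]), 2 * grid$axial_spacing)
  }
  # a dimmer, smaller reflection artifact below the tip is rejected
  img <- blob_image(grid, list(
    list(lateral = -1, axial = 10, amp = 1, sigma_lat = 0.8, sigma_ax = 0.4),
    list(lateral = -1, axial = 15, amp = 0.6, sigma_lat = 0.4,
         sigma_ax = 0.25)), floor_level = 0.05, seed = 1)
  det <- segment_frame(img, p)
  expect_true(det$found)
  expect_lt(abs(det$tip_mm[2] - 10), 1)
  # all-zero image: not found, not an error
  zero <- pa_image(matrix(0, grid$n_axial, grid$n_lateral), grid)
  expect_false(segment_frame(zero, p)$found)
})

test_that("centroids are translation-equivariant for whole-pixel shifts", {
  geom <- small_geom()
  grid <- small_grid(geom)
  p <- segmentation_params()
  img <- blob_image(grid, list(list(lateral = -1, axial = 10, amp = 1,
                                    sigma_lat = 0.8, sigma_ax = 0.4)),
                    floor_level = 0.05, seed = 2)
  d0 <- segment_frame(img, p)
  dr <- 6L
  dc <- 4L
  shifted <- matrix(0, grid$n_axial, grid$n_lateral)
  shifted[(1 + dr):grid$n_axial, (1 + dc):grid$n_lateral] <-
    img$envelope[1:(grid$n_axial - dr), 1:(grid$n_lateral - dc)]
  d1 <- segment_frame(pa_image(shifted, grid), p)
  expect_equal(unname(d1$tip_pixel - d0$tip_pixel), c(dr, dc))
})

test_that("segmentation of a fixed image is deterministic", {
  geom <- small_geom()
  grid <- small_grid(geom)
  img <- acquire_image(fiber_source(c(1, 0, 12)), geom,
                       tissue_preset("liver"), grid, seed = 5,
                       n_samples = 512L)
  expect_identical(segment_frame(img), segment_frame(img))
})

test_that("temporal consensus averages consistent detections", {
  p <- segmentation_params()
  h <- detection_history(5)
  for (i in 1:5) h <- history_push(h, make_detection(10, 20))
  res <- temporal_consensus(h, p)
  expect_equal(unname(res$p_bar), c(10, 20))
  expect_equal(res$history$consecutive_failures, 0L)

  h2 <- detection_history(5)
  for (x in c(9.8, 9.9, 10.0, 10.1, 10.2))
    h2 <- history_push(h2, make_detection(x, 20))
  expect_equal(unname(temporal_consensus(h2, p)$p_bar), c(10, 20))

  # one missing detection breaks consensus and counts a failure
  h3 <- detection_history(5)
  for (i in 1:4) h3 <- history_push(h3, make_detection(10, 20))
  h3 <- history_push(h3, make_detection(NA, NA, found = FALSE))
  res3 <- temporal_consensus(h3, p)
  expect_null(res3$p_bar)
  expect_equal(res3$history$consecutive_failures, 1L)

  # spatial inconsistency beyond the radius also fails
  h4 <- detection_history(5)
  for (x in c(8, 9, 10, 11, 12)) h4 <- history_push(h4, make_detection(x, 20))
  expect_null(temporal_consensus(h4, p)$p_bar)

  # the buffer is bounded and failures reset on success
  h5 <- detection_history(5)
  h5$consecutive_failures <- 3L
  for (i in 1:9) h5 <- history_push(h5, make_detection(10, 20))
  expect_equal(length(h5$detections), 5L)
  expect_equal(temporal_consensus(h5, p)$history$consecutive_failures, 0L)
})

test_that("false-positive rate on seeded noise images is low", {
  geom <- small_geom()
  grid <- small_grid(geom)
  med <- tissue_preset("liver")
  src <- fiber_source(c(0, 0, 12), pulse_energy = 0)
  hits <- sum(sapply(1:40, function(s) {
    segment_frame(acquire_image(src, geom, med, grid, seed = s,
                                n_samples = 512L))$found
  }))
  expect_lte(hits / 40, 0.05)
})
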