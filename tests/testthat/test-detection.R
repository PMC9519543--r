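test_that("temporal averaging reduces noise and drops incomplete tail blocks", {
  set.seed(11)
  arr <- array(1 + stats::rnorm(96 * 96 * 8, sd = 0.05), c(96, 96, 8))
  st <- frame_stack(arr, axis_values = (0:7) * 10)

  expect_identical(temporal_average(st, 1), st)
  expect_error(temporal_average(st, 9))

  st3 <- temporal_average(st, 3)
  expect_equal(dim(st3$frames)[3], 2L)
  expect_equal(st3$axis_values, c(10, 40))  # block means of frame times
  expect_equal(st3$frames[, , 1],
               (arr[, , 1] + arr[, , 2] + arr[, , 3]) / 3)

  st4 <- temporal_average(st, 4)
  ratio <- stats::sd(st4$frames[, , 1]) / 0.05
  expect_lt(abs(ratio - 0.5), 0.05)  # sd scales as 1/sqrt(n)
})

test_that("pseudomedian smoothing suppresses small structures", {
  const <- matrix(7, 32, 32)
  expect_equal(pseudomedian_smooth(const, 5), const)

  img <- matrix(100, 41, 41)
  img[20:22, 20:22] <- 200  # 3x3 bump
  sm <- pseudomedian_smooth(img, 9)
  expect_lt(sm[21, 21], 110)
  dn <- pseudomedian_smooth(img, 9, dense = TRUE)
  expect_lt(dn[21, 21], 110)

  expect_error(pseudomedian_smooth(img, 6), "odd")
  expect_error(pseudomedian_smooth(matrix(1, 4, 4), 5), "larger")
})

test_that("sparse pseudomedian tracks the dense reference on smooth fields", {
  set.seed(12)
  for (rep in 1:3) {
    xx <- outer(rep(1, 40), seq_len(40))
    yy <- t(xx)
    img <- stats::runif(1, 1, 3) * sin(xx / stats::runif(1, 8, 15)) +
      cos(yy / stats::runif(1, 8, 15)) + 0.02 * stats::rnorm(1600)
    img <- matrix(img, 40, 40)
    sp <- pseudomedian_smooth(img, 7)
    dn <- pseudomedian_smooth(img, 7, dense = TRUE)
    expect_lt(max(abs(sp - dn)), 0.02 * diff(range(img)))
  }
})

test_that("per-pixel median normalization behaves as defined", {
  const <- frame_stack(array(5, c(8, 8, 5)))
  expect_true(all(normalize_stack(const)$frames == 1))

  arr <- array(1, c(4, 4, 3))
  arr[2, 3, ] <- c(90, 100, 110)
  nrm <- normalize_stack(frame_stack(arr))
  expect_equal(nrm$frames[2, 3, ], c(0.9, 1.0, 1.1))

  # odd frame count: per-pixel median of the output is exactly 1
  set.seed(13)
  arr5 <- array(stats::runif(8 * 8 * 5, 0.5, 2), c(8, 8, 5))
  nrm5 <- normalize_stack(frame_stack(arr5))
  med <- apply(nrm5$frames, c(1, 2), stats::median)
  expect_true(all(med == 1))

  bad <- array(1, c(4, 4, 3)); bad[1, 1, ] <- c(-1, -1, -1)
  expect_error(normalize_stack(frame_stack(bad)), "median")
  expect_error(normalize_stack(frame_stack(array(1, c(4, 4, 2)))), "3 frames")
})

test_that("differential image is the per-pixel max-min", {
  const <- frame_stack(array(3, c(6, 6, 4)))
  expect_true(all(differential_image(const) == 0))
  arr <- array(1, c(4, 4, 3)); arr[3, 2, ] <- c(0.9, 1.0, 1.1)
  d <- differential_image(frame_stack(arr))
  expect_equal(d[3, 2], 0.2)
  expect_true(all(d >= 0))
})

test_that("ZNCC scores a planted template at 1.0 and noise well below threshold", {
  k <- gaussian_kernel(1.5)
  img <- matrix(1, 64, 64)
  tpl <- k$template
  img[20:30, 35:45] <- img[20:30, 35:45] + 0.2 * tpl  # kernel is 11x11
  sm <- correlate(img, k)
  pk <- which(sm == max(sm), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(25, 40))
  expect_gt(max(sm), 1 - 1e-9)
  expect_true(all(sm >= -1 & sm <= 1))

  # FFT route agrees with the direct windowed sums, borders included
  set.seed(14)
  img2 <- matrix(stats::rnorm(40 * 31, 1, 0.05), 40, 31)
  expect_lt(max(abs(correlate(img2, k) - spiris:::correlate_direct(img2, k))),
            1e-9)

  # pure-noise null: maximum score stays below the detection threshold
  set.seed(15)
  mx <- replicate(20, max(correlate(matrix(stats::rnorm(64 * 64, 1, 0.01), 64), k)))
  expect_true(all(mx < 0.55))
  expect_gte(mean(mx < 0.5), 0.9)
})

test_that("two planted particles give two correlation maxima at their centres", {
  cfg <- simulation_config(image_shape = c(64, 64), shot_noise_scale = 0)
  pts <- data.frame(x = c(20.4, 40.6), y = c(32.2, 32.8))
  zs <- render_zstack(cfg, pts, noise = FALSE)
  sm <- correlate(differential_image(normalize_stack(zs)), gaussian_kernel(1.5))
  for (i in 1:2) {
    r0 <- round(pts$y[i]) + 1 - 4; c0 <- round(pts$x[i]) + 1 - 4
    win <- sm[r0:(r0 + 8), c0:(c0 + 8)]
    pk <- which(win == max(win), arr.ind = TRUE)
    peak_y <- r0 + pk[1, 1] - 1 - 1  # back to 0-based pixel coordinates
    peak_x <- c0 + pk[1, 2] - 1 - 1
    expect_lt(abs(peak_y - pts$y[i]), 1)
    expect_lt(abs(peak_x - pts$x[i]), 1)
  }
})

test_that("binarization is monotone in the threshold", {
  set.seed(16)
  sm <- matrix(stats::runif(400), 20, 20)
  m1 <- binarize(sm, 0.4); m2 <- binarize(sm, 0.7)
  expect_true(all(m1[m2]))  # mask(t2) subset of mask(t1)
  expect_identical(which(binarize(sm, 1.0)), which(sm >= 1.0))
  expect_error(binarize(sm, 0))
})

test_that("keypoint filtering keeps round blobs and rejects lines", {
  params <- detection_params()
  empty <- extract_and_filter_keypoints(matrix(FALSE, 10, 10),
                                        matrix(0, 10, 10), params)
  expect_equal(nrow(empty), 0)

  # disc of radius 3 (area 29) vs a 1x29 line of equal area
  mask <- matrix(FALSE, 40, 60)
  for (r in -3:3) for (cc in -3:3) {
    if (r^2 + cc^2 <= 9) mask[15 + r, 15 + cc] <- TRUE
  }
  mask[30, 16:44] <- TRUE
  score <- matrix(0, 40, 60); score[mask] <- 0.9
  kp_all <- extract_and_filter_keypoints(
    mask, score, detection_params(area_range = c(1, 1e5),
                                  ratio_range = c(0, 1e5)))
  expect_equal(nrow(kp_all), 2)
  disc <- kp_all[which.min(kp_all$y), ]
  line <- kp_all[which.max(kp_all$y), ]
  expect_equal(disc$area, 29)
  expect_equal(line$area, 29)
  expect_equal(line$ratio, 1.0)       # every line pixel is a border pixel
  expect_gt(disc$ratio, 1.5)
  kp <- extract_and_filter_keypoints(mask, score,
                                     detection_params(area_range = c(5, 200)))
  expect_equal(nrow(kp), 1)           # the line fails the ratio filter
  expect_equal(kp$x, disc$x)
})

test_that("endpoint detection recovers planted particles exactly without noise", {
  set.seed(17)
  cfg <- simulation_config(image_shape = c(96, 96), shot_noise_scale = 0)
  pts <- planted_positions(9, 96, margin = 14, jitter = 2)
  zs <- render_zstack(cfg, pts, noise = FALSE)
  det <- detect_stack(zs)
  expect_equal(nrow(det), 9)
  expect_true(all(det$frame_index == -1))
  err <- sapply(seq_len(9), function(i)
    min(sqrt((det$x - pts$x[i])^2 + (det$y - pts$y[i])^2)))
  expect_lt(max(err), 0.5)
})

test_that("kinetic detection finds a binder in the frame it binds", {
  set.seed(18)
  cfg <- simulation_config(image_shape = c(64, 64), frame_interval = 15,
                           duration = 900)
  blank <- render_timelapse(cfg, empty_events())
  expect_equal(nrow(detect_stack(blank)), 0)

  ev <- events_from_positions(data.frame(x = 30.3, y = 33.6), t_bind = 300)
  movie <- render_timelapse(cfg, ev)
  det <- detect_stack(movie)
  expect_gt(nrow(det), 30)
  expect_lte(abs(min(det$frame_index) - 20), 1)  # t_bind / frame_interval = 20
  expect_lt(mean(abs(det$x - 30.3)), 1.0)
  expect_lt(mean(abs(det$y - 33.6)), 1.0)
})
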