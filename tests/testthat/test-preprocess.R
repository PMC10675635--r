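test_that("distance limiting zeroes far pixels and is idempotent", {
  f <- depth_frame(matrix(c(1000L, 3000L), 1, 2), "TOP")
  expect_equal(unclass(distance_limit(f, 2000))[1, ], c(1000L, 0L),
               ignore_attr = TRUE)
  expect_identical(unclass(distance_limit(f, 3000)), unclass(f))

  set.seed(8)
  r <- depth_frame(matrix(sample(0:4500, 2500, TRUE), 50, 50), "REAR")
  lim <- distance_limit(r, 2200)
  # brute-force per-pixel recount
  expect_equal(sum(lim > 0), sum(r > 0 & r <= 2200))
  expect_identical(unclass(distance_limit(lim, 2200)), unclass(lim))
})

test_that("cropping copies the window and rejects bad geometry", {
  f <- ramp_frame(4, 4)
  expect_identical(unclass(crop_frame(f, c(1, 1, 4, 4))), unclass(f))
  tl <- crop_frame(f, c(1, 1, 2, 2))
  expect_equal(unclass(tl), matrix(c(0L, 4L, 1L, 5L), 2, 2),
               ignore_attr = TRUE)
  expect_error(crop_frame(f, c(3, 3, 3, 3)), "out of bounds")
  expect_error(crop_frame(f, c(0, 1, 2, 2)), "out of bounds")
})

test_that("binarization forms a silhouette with the no-data rule", {
  f <- depth_frame(matrix(c(0L, 1200L, 2500L), 1, 3), "TOP")
  expect_equal(binarize(f, 2000)[1, ], c(0, 1, 0))
  near <- depth_frame(matrix(900L, 3, 3), "TOP")
  expect_true(all(binarize(near, 2000) == 1))
  # boundary pixel at exactly the threshold counts as far
  expect_equal(binarize(depth_frame(matrix(2000L, 1, 1), "TOP"), 2000)[1, 1],
               0)

  set.seed(5)
  r <- depth_frame(matrix(sample(0:3000, 900, TRUE), 30, 30), "TOP")
  fracs <- vapply(seq(300, 3000, by = 300), function(th) {
    expect_equal(sum(binarize(r, th)), sum(r > 0 & r < th))  # recount
    mean(binarize(r, th))
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))  # non-decreasing in threshold
})

test_that("the first derivative is left-to-right with a capped magnitude", {
  const <- depth_frame(matrix(1500L, 5, 6), "TOP")
  expect_true(all(depth_derivative(const, 100) == 0))

  row <- depth_frame(matrix(c(1000L, 1010L, 1005L), 1, 3), "TOP")
  expect_equal(depth_derivative(row, 100)[1, ], c(0, 10, -5))

  spike <- depth_frame(matrix(c(1000L, 2000L), 1, 2), "TOP")
  expect_equal(depth_derivative(spike, 100)[1, ], c(0, 0))

  expect_error(depth_derivative(depth_frame(matrix(1L, 3, 1), "TOP"), 50),
               "width")
})

test_that("mirroring a frame negates and mirrors its derivative", {
  set.seed(13)
  v <- matrix(sample(1000:1100, 120, TRUE), 10, 12)  # gradients under cap
  f <- depth_frame(v, "TOP")
  fm <- depth_frame(v[, ncol(v):1], "TOP")
  g <- depth_derivative(f, 500)
  gm <- depth_derivative(fm, 500)
  # away from the padding column the identity is exact
  expect_equal(gm[, 2:12], -g[, 12:2])
})

test_that("channel stacks satisfy their invariants on random frames", {
  pp <- camera_preprocess(2500, c(3, 5, 16, 16), 2000, 150)
  zero <- depth_frame(matrix(0L, 30, 30), "ANGLED")
  expect_true(all(build_channel_stack(zero, pp) == 0))

  set.seed(99)
  for (i in 1:100) {
    f <- depth_frame(matrix(sample(0:4000, 900, TRUE), 30, 30), "ANGLED")
    st <- build_channel_stack(f, pp)
    expect_identical(dim(st), c(16L, 16L, 3L))
    expect_true(all(st[, , 1] >= 0 & st[, , 1] <= 1))
    expect_true(all(st[, , 2] %in% c(0, 1)))
    expect_true(all(abs(st[, , 3]) <= 150))
  }
  # deterministic and shape-stable
  f <- depth_frame(matrix(sample(0:4000, 900, TRUE), 30, 30), "ANGLED")
  expect_identical(build_channel_stack(f, pp), build_channel_stack(f, pp))
})

test_that("default crops follow the per-camera aspect convention", {
  pp <- default_preprocess_config()
  expect_equal(pp$ANGLED$crop[3], pp$ANGLED$crop[4])    # square
  expect_gt(pp$REAR$crop[3], pp$REAR$crop[4])           # taller than wide
  expect_lt(pp$TOP$crop[3], pp$TOP$crop[4])             # wider than tall
  sensor <- c(424L, 512L)
  for (cam in CAMERA_VIEWS) {
    w <- pp[[cam]]$crop
    expect_true(w[1] >= 1 && w[2] >= 1 &&
                  w[1] + w[3] - 1 <= sensor[1] &&
                  w[2] + w[4] - 1 <= sensor[2])
  }
})
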