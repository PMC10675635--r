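test_that("zero bone amplitude yields the exact smooth ellipsoid patch", {
  p <- cow_shape_params(2.50, bone_amplitude = 0, seed = 4L)
  surf <- generate_cow_surface(p, spacing = 0.03)
  ax <- 0.33; ay <- 0.85; az <- 0.38; cz <- 1.05
  r2 <- (surf[, 1] / ax)^2 + (surf[, 2] / ay)^2 + ((surf[, 3] - cz) / az)^2
  expect_lt(max(abs(r2 - 1)), 1e-9)
  # amplitude 0 is independent of the shape seed
  p2 <- cow_shape_params(3.25, bone_amplitude = 0, seed = 99L)
  expect_equal(unclass(generate_cow_surface(p2, spacing = 0.03)),
               unclass(surf), ignore_attr = TRUE)
})

test_that("surfaces are deterministic in the seed", {
  p <- cow_shape_params(2.00, seed = 11L)
  s1 <- generate_cow_surface(p)
  s2 <- generate_cow_surface(p)
  expect_identical(unclass(s1), unclass(s2))
  s3 <- generate_cow_surface(cow_shape_params(2.00, seed = 12L))
  expect_false(isTRUE(all.equal(unclass(s1), unclass(s3))))
})

test_that("bone amplitude decreases strictly with the score", {
  amps <- bone_amplitude_mm(bcs_grid())
  expect_true(all(diff(amps) < 0))
  expect_true(all(amps > 0))
})

test_that("a plane normal to the optical axis renders at its range", {
  cfg <- tiny_scene_config(noise_sd = 0)
  cfg$background <- FALSE
  pose <- default_camera_poses()$TOP
  g <- expand.grid(x = seq(-1, 1, by = 0.02), y = seq(-1.2, 1, by = 0.02))
  plane <- cbind(g$x, g$y, pose$position[3] - 2.0)  # 2000 mm below camera
  f <- render_depth(plane, pose, cfg)
  expect_true(all(f[f > 0] == 2000L))
  expect_gt(sum(f > 0), 200)
  # determinism without noise
  expect_identical(unclass(render_depth(plane, pose, cfg)), unclass(f))
})

test_that("occluders win the z-buffer exactly as a two-depth oracle", {
  cfg <- tiny_scene_config(noise_sd = 0)
  cfg$background <- FALSE
  pose <- default_camera_poses()$TOP
  g <- expand.grid(x = seq(-1, 1, by = 0.02), y = seq(-1.2, 1, by = 0.02))
  plane <- cbind(g$x, g$y, pose$position[3] - 2.0)
  bar_sel <- abs(g$x) < 0.15
  bar <- cbind(g$x[bar_sel], g$y[bar_sel], pose$position[3] - 1.7)
  both <- render_depth(rbind(plane, bar), pose, cfg)
  p_only <- render_depth(plane, pose, cfg)
  b_only <- render_depth(bar, pose, cfg)
  # analytic z-buffer: per-pixel minimum of covered depths
  pv <- unclass(p_only); bv <- unclass(b_only)
  oracle <- ifelse(bv > 0 & pv > 0, pmin(pv, bv), pmax(pv, bv))
  expect_equal(unclass(both), matrix(as.integer(oracle), nrow(oracle)),
               ignore_attr = TRUE)
  expect_true(all(both[bv > 0] == 1700L))
})

test_that("noisy renders are integer, bounded, and seed-deterministic", {
  cfg <- tiny_scene_config(noise_sd = 5)
  surf <- generate_cow_surface(cow_shape_params(2.25, seed = 2L),
                               spacing = 0.03)
  pose <- default_camera_poses()$ANGLED
  f1 <- render_depth(surf, pose, cfg, seed = 42L)
  f2 <- render_depth(surf, pose, cfg, seed = 42L)
  expect_identical(unclass(f1), unclass(f2))
  expect_true(all(f1 >= 0L & f1 <= 65535L))
  f3 <- render_depth(surf, pose, cfg, seed = 43L)
  expect_false(identical(unclass(f1), unclass(f3)))
})

test_that("a surface outside the frustum is an error", {
  cfg <- tiny_scene_config()
  pose <- default_camera_poses()$TOP
  behind <- cbind(0, 0, 5)  # above the camera
  expect_error(render_depth(behind, pose, cfg), "outside the camera frustum")
})

test_that("generated datasets have the right shape and are reproducible", {
  cfg <- tiny_scene_config(noise_sd = 0)
  d1 <- tempfile("scene_a_"); d2 <- tempfile("scene_b_")
  m1 <- generate_dataset(1L, cfg, seed = 9L, dir = d1)
  expect_equal(nrow(m1), 1L * 3L * 2L)  # cameras x frames
  expect_true(all(file.exists(file.path(d1, m1$frame_ref))))
  m2 <- generate_dataset(1L, cfg, seed = 9L, dir = d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "manifest.csv"))),
                   unname(tools::md5sum(file.path(d2, "manifest.csv"))))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the default class mix concentrates mass at BCS 2.50-3.00", {
  cfg <- tiny_scene_config()
  cfg$frames_per_cow <- c(1L, 1L)
  d <- tempfile("scene_mix_")
  m <- generate_dataset(400L, cfg, seed = 21L, dir = d, cameras = "TOP")
  unlink(d, recursive = TRUE)
  counts <- table(factor(m$bcs, levels = bcs_grid()))
  mid <- sum(counts[c("2.5", "2.75", "3")])
  expect_gt(mid / sum(counts), 0.5)
  expect_true(names(which.max(counts)) %in% c("2.5", "2.75", "3"))
  # edge classes are the rarest
  expect_lt(max(counts[c("1.75", "3.5")]), min(counts[c("2.5", "2.75")]))
  expect_error(scene_config(class_probs = rep(0, 8)), "positive mass")
})

test_that("thin cows show larger rendered surface gradients than fat cows", {
  bench <- benchmark_config()
  cfg <- bench$scene_config
  cfg$noise_sd <- 0
  pp <- bench$preprocess_config
  poses <- default_camera_poses()
  stat <- function(score, seed) {
    surf <- generate_cow_surface(cow_shape_params(score, seed = seed),
                                 spacing = 0.022)
    f <- render_depth(surf, poses$TOP, cfg)
    st <- build_channel_stack(f, pp$TOP)
    mean(abs(st[, , 3])[st[, , 2] == 1])
  }
  thin <- vapply(1:8, function(s) stat(1.75, s), numeric(1))
  fat <- vapply(1:8, function(s) stat(3.50, s), numeric(1))
  expect_gt(mean(thin), mean(fat))
})
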