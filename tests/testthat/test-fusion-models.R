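test_that("inverse-frequency weights satisfy the cost-sensitivity identity", {
  expect_equal(class_weights(c(10, 10, 10)), rep(1, 3))
  w <- class_weights(c(1, 2))
  expect_equal(w[1] / w[2], 2)

  herd <- c(320, 452, 1196, 1468, 2516, 1780, 368, 112)
  wh <- class_weights(herd)
  expect_equal(diff(range(wh * herd)), 0, tolerance = 1e-9)
  expect_equal(sum(wh * herd), sum(herd))

  wz <- class_weights(c(5, 0, 5))
  expect_equal(wz[2], 0)
  expect_equal(sum(wz * c(5, 0, 5)), 10)
  expect_error(class_weights(c(0, 0)), "positive")
})

shapes3 <- list(ANGLED = c(16L, 16L, 3L), REAR = c(16L, 16L, 3L),
                TOP = c(16L, 16L, 3L))

test_that("early fusion stacks three channels per camera into one input", {
  cfg <- backbone_config(shapes3, conv_filters = c(4L, 8L, 8L),
                         dense_units = 16L)
  m <- build_model("EARLY", CAMERA_VIEWS, cfg, seed = 1L)
  expect_equal(m$net$branches[[1L]][[1L]]$input_shape[3], 9L)
  m1 <- build_model("EARLY", "TOP", cfg, seed = 1L)
  expect_equal(m1$net$branches[[1L]][[1L]]$input_shape[3], 3L)
  expect_error(build_model("EARLY", character(0), cfg), "non-empty")
})

test_that("mid fusion concatenates one feature block per camera", {
  cfg <- backbone_config(shapes3, conv_filters = c(4L, 8L, 8L),
                         dense_units = 16L)
  m2 <- build_model("MID", c("ANGLED", "TOP"), cfg, seed = 1L)
  m1 <- build_model("MID", "ANGLED", cfg, seed = 1L)
  expect_length(m2$net$feature_widths, 2L)
  expect_equal(sum(m2$net$feature_widths), 2L * m1$net$feature_widths[[1L]])
  # the head consumes the concatenated width
  expect_equal(m2$net$head[[1L]]$input_shape, sum(m2$net$feature_widths))
})

test_that("late fusion with one member is exactly that member", {
  cfg <- backbone_config(shapes3, conv_filters = c(4L, 8L, 8L),
                         dense_units = 16L)
  late <- build_model("LATE", "TOP", cfg, seed = 3L)
  set.seed(1)
  x <- list(TOP = array(rnorm(16 * 16 * 3 * 5), c(16, 16, 3, 5)))
  pr <- predict(late, x)
  expect_equal(pr$prob, pr$member_prob$TOP)
  expect_equal(rowSums(pr$prob), rep(1, 5), tolerance = 1e-9)
})

test_that("ensemble averaging is an equal-weight mean with tie-breaks", {
  v <- c(0.5, 0.3, 0.2, rep(0, 5))
  same <- ensemble_average(list(v, v, v))
  expect_equal(as.numeric(same$prob), v)
  expect_equal(same$class, 0L)

  a <- c(1, rep(0, 7)); b <- c(0, 1, rep(0, 6))
  tie <- ensemble_average(list(a, b))
  expect_equal(as.numeric(tie$prob)[1:2], c(0.5, 0.5))
  expect_equal(tie$class, 0L)  # lowest index wins the tie

  set.seed(12)
  ps <- list(random_simplex(6), random_simplex(6), random_simplex(6))
  fused <- ensemble_average(ps)
  brute <- (ps[[1]] + ps[[2]] + ps[[3]]) / 3  # arithmetic oracle
  expect_equal(fused$prob, brute, tolerance = 1e-12)
  perm <- ensemble_average(ps[c(3, 1, 2)])
  expect_equal(perm$prob, fused$prob, tolerance = 1e-12)

  expect_error(ensemble_average(list(c(1, 0), c(1, 0, 0))), "shape")
  expect_error(ensemble_average(list(c(0.7, 0.7))), "summing to 1")
})

test_that("parameter and FLOP counts follow the closed forms", {
  ns <- asNamespace("bcsfusion")
  dense <- ns$init_layers(list(ns$layer_dense(8L)), 10L)
  expect_equal(ns$layer_param_count(dense), 10 * 8 + 8)
  conv <- ns$init_layers(list(ns$layer_conv(16L)), c(12L, 12L, 3L))
  expect_equal(ns$layer_param_count(conv), 3 * 3 * 3 * 16 + 16)
  expect_equal(ns$layer_flops(conv), 2 * 12 * 12 * 3 * 3 * 3 * 16)

  cfg <- backbone_config(shapes3, conv_filters = c(4L, 8L, 8L),
                         dense_units = 16L)
  all3 <- model_stats(build_model("LATE", CAMERA_VIEWS, cfg, seed = 1L))
  singles <- lapply(CAMERA_VIEWS, function(cam) {
    model_stats(build_model("LATE", cam, cfg, seed = 1L))
  })
  expect_equal(all3$parameters,
               sum(vapply(singles, `[[`, numeric(1), "parameters")))
  expect_equal(all3$flops, sum(vapply(singles, `[[`, numeric(1), "flops")))
})

test_that("a separable toy problem is learnt to perfection", {
  toy <- toy_separable_set(n_per_class = 20L, seed = 2L)
  cfg <- backbone_config(list(TOP = c(8L, 8L, 3L)),
                         conv_filters = c(4L, 8L, 8L), dense_units = 16L,
                         n_classes = 8L)
  model <- build_model("LATE", "TOP", cfg, seed = 7L)
  tc <- train_config(epochs = 20L, batch_size = 8L, seed = 5L)
  model <- train_model(model, toy, toy, tc)
  pred <- predict(model, toy$x)
  expect_equal(mean(pred$class == toy$y), 1)
  expect_true(is.data.frame(model$history$TOP))
  expect_equal(nrow(model$history$TOP), 20L)
})

test_that("training is deterministic under a fixed seed", {
  toy <- toy_separable_set(n_per_class = 10L, seed = 3L)
  cfg <- backbone_config(list(TOP = c(8L, 8L, 3L)),
                         conv_filters = c(4L, 4L, 4L), dense_units = 8L)
  tc <- train_config(epochs = 4L, batch_size = 8L, seed = 9L)
  run <- function() {
    m <- build_model("LATE", "TOP", cfg, seed = 4L)
    train_model(m, toy, toy, tc)$history$TOP
  }
  expect_identical(run(), run())
})

test_that("class weighting protects minority recall on an imbalanced toy", {
  set.seed(21)
  n_maj <- 45L; n_min <- 5L
  n <- n_maj + n_min
  x <- array(rnorm(8 * 8 * 3 * n, sd = 0.35), c(8, 8, 3, n))
  y <- rep(c(0L, 1L), c(n_maj, n_min))
  for (i in seq_len(n)) {
    if (y[i] == 0L) x[1:4, , 1, i] <- x[1:4, , 1, i] + 0.4
    else x[5:8, , 1, i] <- x[5:8, , 1, i] + 0.4
  }
  toy <- list(x = list(TOP = x), y = y)
  cfg <- backbone_config(list(TOP = c(8L, 8L, 3L)),
                         conv_filters = c(4L, 4L, 4L), dense_units = 8L)
  fit <- function(weighting) {
    m <- build_model("LATE", "TOP", cfg, seed = 6L)
    tc <- train_config(epochs = 8L, batch_size = 8L, seed = 6L,
                       class_weighting = weighting)
    predict(train_model(m, toy, toy, tc), toy$x)$class
  }
  recall_min <- function(cls) mean(cls[y == 1L] == 1L)
  expect_gte(recall_min(fit(TRUE)), recall_min(fit(FALSE)))
})
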