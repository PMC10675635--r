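test_that("tolerance relabelling follows the band rule", {
  expect_equal(relabel_within_tolerance(c(2L, 5L), c(3L, 1L), 0), c(3L, 1L))
  expect_equal(relabel_within_tolerance(4L, 5L, 1), 4L)
  expect_equal(relabel_within_tolerance(4L, 6L, 1), 6L)
  expect_equal(relabel_within_tolerance(4L, 6L, 2), 4L)
  expect_error(relabel_within_tolerance(1:3, 1:2, 1), "lengths differ")
})

test_that("accuracy is the correct percentage and rejects empty input", {
  expect_equal(accuracy_pct(1:5, 1:5), 100)
  expect_equal(accuracy_pct(rep(0:1, c(274, 274)), rep(0L, 548)), 50)
  expect_error(accuracy_pct(integer(0), integer(0)), "no predictions")
})

test_that("accuracy equals class-weighted recall on random predictions", {
  set.seed(44)
  for (i in 1:50) {
    n <- sample(50:300, 1)
    truth <- sample(0:7, n, TRUE)
    pred <- sample(0:7, n, TRUE)
    cm <- confusion_matrix(truth, pred)
    pc <- class_metrics(cm)
    expect_equal(weighted_metric(pc$recall, pc$n), accuracy_pct(truth, pred),
                 tolerance = 1e-9)
  }
})

test_that("per-class F1 reproduces published precision/recall pairs", {
  expect_equal(round(f1_score(23.08, 27.27), 2), 25.00)
  expect_equal(round(f1_score(100.0, 84.38), 2), 91.53)
  cm <- confusion_matrix(c(0L, 1L, 2L), c(0L, 1L, 2L), n_classes = 3L)
  pc <- class_metrics(cm)
  expect_true(all(pc$precision == 100 & pc$recall == 100 & pc$f1 == 100))
  # zero-denominator convention: an absent class scores 0, not NaN
  cm2 <- confusion_matrix(c(0L, 0L), c(0L, 0L), n_classes = 2L)
  pc2 <- class_metrics(cm2)
  expect_equal(pc2$f1[2], 0)
})

test_that("class-weighted averages reproduce the published herd summary", {
  test_counts <- c(16, 44, 64, 128, 164, 96, 32, 4)
  f1_exact <- c(0, 25.0, 6.06, 32.65, 35.58, 29.75, 12.5, 0)
  recall_exact <- c(0, 27.27, 4.69, 31.25, 35.37, 37.5, 12.5, 0)
  expect_equal(round(weighted_metric(f1_exact, test_counts), 2), 26.93)
  expect_equal(round(weighted_metric(recall_exact, test_counts), 2), 27.92)

  expect_equal(weighted_metric(c(10, 20, 30), rep(7, 3)), 20)  # uniform
  set.seed(10)
  for (i in 1:50) {
    met <- runif(8, 0, 100); cnt <- sample(0:50, 8)
    if (sum(cnt) == 0) cnt[1] <- 1
    expect_equal(weighted_metric(met, cnt),
                 sum(met * cnt) / sum(cnt), tolerance = 1e-12)
  }
  expect_error(weighted_metric(1:3, c(0, 0, 0)), "zero total")
})

test_that("F1 lies between precision and recall when both are positive", {
  set.seed(18)
  p <- runif(200, 1, 100); r <- runif(200, 1, 100)
  f <- f1_score(p, r)
  expect_true(all(f >= pmin(p, r) - 1e-9 & f <= pmax(p, r) + 1e-9))
})

test_that("band reports are complete, perfect on perfect input, monotone", {
  truth <- sample(0:7, 100, TRUE)
  rep_perfect <- evaluate_predictions(truth, truth)
  expect_named(rep_perfect, c("exact", "within_0.25", "within_0.5"))
  for (b in rep_perfect) expect_equal(b$accuracy, 100)

  set.seed(27)
  for (i in 1:100) {
    n <- sample(20:200, 1)
    tr <- sample(0:7, n, TRUE); pr <- sample(0:7, n, TRUE)
    r <- evaluate_predictions(tr, pr)
    acc <- vapply(r, `[[`, numeric(1), "accuracy")
    expect_true(all(diff(acc) >= 0))
    # internal consistency: weighted recall == accuracy per band
    for (b in r) {
      expect_equal(b$weighted$recall, b$accuracy, tolerance = 1e-9)
    }
  }
})

test_that("the camera-set report has the seven standard rows", {
  set.seed(9)
  n <- 40L
  truth <- sample(0:7, n, TRUE)
  member <- list(ANGLED = random_simplex(n), REAR = random_simplex(n),
                 TOP = random_simplex(n))
  rep7 <- evaluate_camera_sets(member, truth)
  tab <- report_accuracy_table(rep7)
  expect_equal(nrow(tab), 7L)
  expect_identical(tab$approach,
                   c("A", "R", "T", "A&R", "A&T", "T&R", "All"))
  expect_identical(names(tab), c("approach", "exact", "within_0.25",
                                 "within_0.5"))
  out <- tempfile(fileext = ".json")
  write_metrics_json(rep7, out)
  parsed <- jsonlite::read_json(out)
  expect_named(parsed, tab$approach)
  expect_named(parsed$All, c("exact", "within_0.25", "within_0.5"))
})

test_that("reports are reproducible bit for bit from fixed predictions", {
  set.seed(5)
  truth <- sample(0:7, 60, TRUE); pred <- sample(0:7, 60, TRUE)
  expect_identical(evaluate_predictions(truth, pred),
                   evaluate_predictions(truth, pred))
})
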