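test_that("width-height IoU matches the closed form and a raster oracle", {
  expect_equal(iou_wh(c(13, 29), c(13, 29)), 1.0)
  expect_equal(iou_wh(c(2, 2), c(4, 4)), 0.25)
  expect_error(iou_wh(c(0, 2), c(1, 1)), "positive")

  set.seed(3)
  for (rep in 1:20) {
    a <- sample(1:30, 2)
    b <- sample(1:30, 2)
    # raster oracle: corner-aligned boxes on a pixel grid
    big <- matrix(0, 32, 32)
    ra <- big; ra[seq_len(a[2]), seq_len(a[1])] <- 1
    rb <- big; rb[seq_len(b[2]), seq_len(b[1])] <- 1
    inter <- sum(ra & rb); union <- sum(ra | rb)
    expect_equal(iou_wh(a, b), inter / union)
    expect_equal(iou_wh(a, b), iou_wh(b, a))  # symmetry
  }
})

test_that("k-means collapses identical boxes to a single perfect anchor", {
  wh <- tibble::tibble(w = rep(37, 9), h = rep(21, 9))
  fit <- kmeans_anchors(wh, k = 1, seed = 0)
  expect_equal(c(fit$w, fit$h), c(37, 21))
  expect_equal(attr(fit, "avg_iou"), 1.0)
  expect_error(kmeans_anchors(wh, k = 10), "exceeds")
})

test_that("k-means recovers planted clusters within 2 * jitter_sd", {
  pop <- generate_box_population(list(c(20, 20), c(100, 100)),
                                 points_per_cluster = 50, jitter_sd = 2,
                                 seed = 4)
  fit <- kmeans_anchors(pop, k = 2, seed = 1)
  got <- as.matrix(fit[, c("w", "h")])
  expect_lt(max(abs(got[1, ] - c(20, 20))), 2 * 2)
  expect_lt(max(abs(got[2, ] - c(100, 100))), 2 * 2)
})

test_that("Lloyd with restarts matches exhaustive partition search on tiny instances", {
  wh <- generate_box_population(list(c(25, 20), c(90, 110)),
                                points_per_cluster = 4, jitter_sd = 4,
                                seed = 6)
  m <- as.matrix(wh[, c("w", "h")])
  # oracle: enumerate every 2-colouring, median centroids, best Avg IoU
  best <- 0
  for (mask in 1:(2^nrow(m) - 2)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(nrow(m)) - 1)))
    if (!any(sel) || all(sel)) next
    centers <- rbind(apply(m[sel, , drop = FALSE], 2, median),
                     apply(m[!sel, , drop = FALSE], 2, median))
    best <- max(best, avg_iou(wh, centers))
  }
  fits <- sapply(1:50, function(r) {
    attr(kmeans_anchors(wh, 2, seed = r), "avg_iou")
  })
  # a single Lloyd run attains the best of 50 restarts on this instance,
  # and no Lloyd solution can beat the exhaustive free-assignment bound
  expect_lt(abs(fits[1] - max(fits)), 1e-9)
  expect_lte(max(fits), best + 1e-9)
})

test_that("reported Avg IoU equals an independent recomputation", {
  pop <- generate_box_population(list(c(15, 18), c(40, 36), c(90, 70)),
                                 points_per_cluster = 30, jitter_sd = 5,
                                 seed = 2)
  for (k in c(2, 4)) {
    fit <- kmeans_anchors(pop, k, seed = 3)
    expect_equal(attr(fit, "avg_iou"), avg_iou(pop, fit))
  }
})

test_that("the Avg IoU curve is nondecreasing and saturates at k = n", {
  pop <- generate_box_population(list(c(20, 22), c(55, 50), c(120, 100)),
                                 points_per_cluster = 15, jitter_sd = 4,
                                 seed = 10)
  curve <- avg_iou_curve(pop, k_min = 2, k_max = 10, restarts = 10, seed = 1)
  expect_equal(curve$k, 2:10)
  expect_true(all(diff(curve$avg_iou) >= -1e-9))

  tiny <- pop[sample.int(nrow(pop), 6), ]
  fit <- kmeans_anchors(tiny, k = 6, seed = 1)
  expect_equal(attr(fit, "avg_iou"), 1.0)
})

test_that("more restarts never lower a curve value", {
  pop <- generate_box_population(list(c(20, 22), c(80, 75)),
                                 points_per_cluster = 12, jitter_sd = 6,
                                 seed = 5)
  c5 <- avg_iou_curve(pop, 2, 5, restarts = 5, seed = 2)
  c10 <- avg_iou_curve(pop, 2, 5, restarts = 10, seed = 2)
  expect_true(all(c10$avg_iou - c5$avg_iou >= -1e-12))
})

test_that("elbow selection finds the knee of the quality curve", {
  curve <- tibble::tibble(k = 2:5, avg_iou = c(0.50, 0.70, 0.74, 0.76))
  expect_equal(select_k_elbow(curve), 3L)
  linear <- tibble::tibble(k = 2:8, avg_iou = seq(0.3, 0.9, by = 0.1))
  expect_equal(select_k_elbow(linear), 3L)  # all slopes equal -> smallest admissible
  knee <- tibble::tibble(k = 2:9, avg_iou = c(0.2, 0.4, 0.6, 0.8, 0.82, 0.84,
                                              0.86, 0.88))
  expect_equal(select_k_elbow(knee), 5L)
  expect_error(select_k_elbow(curve[1:2, ]), "at least 3")
})

test_that("anchors rescale linearly between input resolutions", {
  a <- kmeans_anchors(tibble::tibble(w = c(46, 46), h = c(44, 44)), k = 1,
                      seed = 0, input_size = 1216)
  expect_equal(scale_anchors(a, 1216)$w, a$w)
  half <- scale_anchors(a, 608)
  expect_equal(c(half$w, half$h), c(23, 22))
  expect_equal(attr(half, "input_size"), 608L)
})

test_that("the shipped default anchors render darknet-style", {
  a <- citrus_anchors()
  expect_equal(attr(a, "k"), 5L)
  expect_equal(anchor_string(a), "23,22, 42,39, 64,62, 104,84, 165,141")
  expect_s3_class(tidy(a), "tbl_df")
  expect_equal(glance(a)$k, 5L)
})
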