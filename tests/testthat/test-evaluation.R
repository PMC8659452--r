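gt_boxes <- function(n, class = "flower") {
  boxes(xmin = (1:n) * 60, ymin = 10, xmax = (1:n) * 60 + 40, ymax = 50,
        class = class)
}

as_dets <- function(b, conf) {
  b$confidence <- conf
  b
}

test_that("matching follows the VOC protocol", {
  gts <- gt_boxes(3)
  perfect <- as_dets(gts, 1.0)
  mr <- match_detections(perfect, gts, 0.5)
  expect_equal(sum(mr$dets$tp), 3L)
  expect_equal(sum(!mr$dets$tp), 0L)
  expect_true(all(mr$gt_matched))

  none <- match_detections(perfect[0, ], gts, 0.5)
  expect_equal(sum(none$gt_matched), 0L)   # every ground truth missed

  # two detections on one object: the confident one wins, the other is FP
  one <- gt_boxes(1)
  dup <- as_dets(dplyr::bind_rows(one, one), c(0.9, 0.7))
  mr2 <- match_detections(dup, one, 0.5)
  expect_equal(mr2$dets$tp, c(TRUE, FALSE))
  expect_equal(mr2$dets$confidence, c(0.9, 0.7))
})

test_that("cumulative precision and recall follow Eqs. for TP/FP/FN", {
  # 2 TP + 1 FP against 3 ground truths -> final P = R = 2/3
  pr <- precision_recall(c(TRUE, TRUE, FALSE), n_gt = 3)
  expect_equal(pr$precision[3], 2 / 3)
  expect_equal(pr$recall[3], 2 / 3)
  expect_true(all(diff(pr$recall) >= 0))
  # all TP -> precision identically 1
  expect_true(all(precision_recall(rep(TRUE, 4), n_gt = 5)$precision == 1))
  # no detections
  expect_equal(nrow(precision_recall(logical(), n_gt = 4)), 0L)
})

test_that("average precision integrates the monotone envelope", {
  perfect <- precision_recall(rep(TRUE, 5), n_gt = 5)
  expect_equal(average_precision(perfect), 1)
  # envelope 2/3 up to recall 2/3, then zero -> 4/9
  pr <- precision_recall(c(FALSE, TRUE, TRUE), n_gt = 3)
  expect_equal(average_precision(pr), 4 / 9)
  expect_equal(average_precision(pr[0, ]), 0)
})

test_that("AP equals a brute-force step-integration oracle", {
  brute_ap <- function(tp, n_gt) {
    if (!length(tp) || n_gt == 0) return(0)
    prec <- cumsum(tp) / seq_along(tp)
    rec <- cumsum(tp) / n_gt
    total <- 0
    prev_r <- 0
    for (r in unique(rec)) {
      p_at <- max(c(0, prec[rec >= r]))   # best precision at recall >= r
      total <- total + (r - prev_r) * p_at
      prev_r <- r
    }
    total
  }
  set.seed(13)
  for (rep in 1:50) {
    n <- sample(1:12, 1)
    tp <- runif(n) < 0.6
    n_gt <- sum(tp) + sample(0:3, 1)
    if (n_gt == 0) next
    ours <- average_precision(precision_recall(tp, n_gt = n_gt))
    expect_equal(ours, brute_ap(tp, n_gt), tolerance = 1e-12)
  }
})

test_that("mAP is exactly the class mean and F1 the harmonic mean", {
  expect_equal(mean_ap(c(1.0, 0.5)), 0.75)
  expect_equal(f1_score(0.4, 0.4), 0.4)           # P = R -> F1 = P
  expect_equal(f1_score(0, 0), 0)
  # TP = 2, FP = 1, FN = 1: both printed forms give 2/3
  p <- 2 / 3; r <- 2 / 3
  expect_equal(f1_score(p, r), 2 * 2 / (2 * 2 + 1 + 1))
  set.seed(4)
  for (rep in 1:50) {
    tp <- sample(0:20, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
    if (tp + fp == 0 || tp + fn == 0) next
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    expect_equal(f1_score(p, r), 2 * tp / (2 * tp + fp + fn), tolerance = 1e-12)
  }
})

test_that("density stratification partitions exhaustively and counts pool", {
  mk <- function(id, n) {
    labeled_image(id, width = 640, height = 640,
                  boxes = gt_boxes(n))
  }
  imgs <- list(mk("a", 5), mk("b", 8), mk("c", 2), mk("d", 9))
  parts <- stratify_by_density(imgs, thresholds = c(4, 8))
  expect_equal(sapply(parts, length), c(few = 1L, middle = 2L, intensive = 1L))
  expect_equal(sum(lengths(parts)), length(imgs))

  dets <- dplyr::bind_rows(lapply(imgs, function(im) {
    d <- as_dets(im$boxes[seq_len(min(3, nrow(im$boxes))), ], 0.8)
    d$image_id <- im$image_id
    d
  }))
  whole <- evaluate_detections(dets, imgs, strata = c(4, 8))
  pooled <- Reduce(`+`, lapply(whole$strata, function(s) c(s$tp, s$fp, s$fn)))
  expect_equal(pooled, c(whole$tp, whole$fp, whole$fn))
})

test_that("corrupted synthetic detections recover the planted error rates", {
  set.seed(6)
  imgs <- lapply(1:12, function(i) {
    labeled_image(paste0("im", i), width = 640, height = 640,
                  boxes = gt_boxes(8, class = rep(c("flower", "bud"), 4)))
  })
  drop_rate <- 0.25
  dets <- dplyr::bind_rows(lapply(imgs, function(im) {
    b <- im$boxes[runif(8) > drop_rate, ]        # missed at rate d
    spurious <- boxes(500, 500, 560, 560, class = "flower")
    d <- as_dets(dplyr::bind_rows(b, spurious), 0.9)  # one FP per image
    d$image_id <- im$image_id
    d
  }))
  rep <- evaluate_detections(dets, imgs)
  n_gt <- 12 * 8
  expect_lt(abs(rep$recall - (1 - drop_rate)), 3 * sqrt(drop_rate * 0.75 / n_gt))
  expect_equal(rep$fp, 12)
})

test_that("evaluation reports expose tidy and visual summaries", {
  imgs <- list(labeled_image("a", width = 640, height = 640, boxes = gt_boxes(4)))
  dets <- as_dets(gt_boxes(3), c(0.9, 0.8, 0.7))
  dets$image_id <- "a"
  rep <- evaluate_detections(dets, imgs)
  expect_equal(glance(rep)$recall, 0.75)
  expect_equal(glance(rep)$precision, 1)
  expect_s3_class(tidy(rep), "tbl_df")
  expect_s3_class(autoplot(rep), "ggplot")
})
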