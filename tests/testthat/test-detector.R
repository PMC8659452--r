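# invert the decode equations to plant one box in a raw head tensor
encode_one_box <- function(s, stride, anchors, a, box, cls, nc = 2) {
  arr <- array(-20, dim = c(s, s, nrow(anchors) * (5 + nc)))
  cx <- (box[1] + box[3]) / 2; cy <- (box[2] + box[4]) / 2
  w <- box[3] - box[1]; h <- box[4] - box[2]
  col <- floor(cx / stride); row <- floor(cy / stride)
  off <- (a - 1) * (5 + nc)
  arr[row + 1, col + 1, off + 1] <- stats::qlogis(cx / stride - col)
  arr[row + 1, col + 1, off + 2] <- stats::qlogis(cy / stride - row)
  arr[row + 1, col + 1, off + 3] <- log(w / anchors[a, 1])
  arr[row + 1, col + 1, off + 4] <- log(h / anchors[a, 2])
  arr[row + 1, col + 1, off + 5] <- 10
  arr[row + 1, col + 1, off + 5 + cls] <- 10
  arr
}

toy_anchors <- function() {
  structure(tibble::tibble(w = c(10, 20, 30, 50, 80, 120),
                           h = c(12, 18, 32, 48, 84, 110)),
            class = c("anchor_set", class(tibble::tibble())),
            k = 6L, avg_iou = NA_real_, input_size = 160L)
}

test_that("decoding inverts a hand-encoded box within half a pixel", {
  anchors <- toy_anchors()
  chunks <- list(anchors[1:3, ], anchors[4:6, ])
  box <- c(40.5, 60.25, 90.5, 120.25)
  heads <- list(
    encode_one_box(5, 32, as.matrix(chunks[[2]]), 2, box, cls = 1),
    array(-20, dim = c(10, 10, 21))
  )
  dets <- decode_predictions(heads, anchors, conf_threshold = 0.5,
                             input_size = 160, image_id = "t")
  expect_equal(nrow(dets), 1L)
  expect_lt(max(abs(unlist(dets[1, 1:4]) - box)), 0.5)
  expect_equal(dets$class, "flower")
  expect_gt(dets$confidence, 0.99)
})

test_that("all-suppressed logits decode to zero detections", {
  heads <- list(array(-30, dim = c(5, 5, 21)), array(-30, dim = c(10, 10, 21)))
  dets <- decode_predictions(heads, toy_anchors(), 0.5, input_size = 160)
  expect_equal(nrow(dets), 0L)
})

test_that("detection count is nonincreasing in the confidence threshold", {
  set.seed(8)
  heads <- list(array(rnorm(5 * 5 * 21), dim = c(5, 5, 21)),
                array(rnorm(10 * 10 * 21), dim = c(10, 10, 21)))
  counts <- sapply(c(0, 0.25, 0.5, 0.99), function(th) {
    nrow(decode_predictions(heads, toy_anchors(), th, input_size = 160))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("NMS keeps the confident box among duplicates and spares disjoint ones", {
  d <- tibble::tibble(
    xmin = c(10, 10, 200), ymin = c(10, 10, 200),
    xmax = c(50, 50, 240), ymax = c(50, 50, 240),
    class = "flower", confidence = c(0.9, 0.8, 0.3)
  )
  out <- nms(d, 0.45)
  expect_equal(nrow(out), 2L)
  expect_setequal(out$confidence, c(0.9, 0.3))
  # different classes never suppress each other
  d$class <- c("flower", "bud", "flower")
  expect_equal(nrow(nms(d, 0.45)), 3L)
})

test_that("greedy NMS equals an exhaustive reference on random instances", {
  ref_nms <- function(d, thr) {
    d <- d[order(-d$confidence, d$xmin, d$ymin, d$xmax, d$ymax), ]
    keep <- rep(TRUE, nrow(d))
    for (i in seq_len(nrow(d))) {
      if (!keep[i]) next
      for (j in seq_len(nrow(d))) {
        if (j <= i || !keep[j] || d$class[j] != d$class[i]) next
        iou <- iou_boxes(d[i, ], unlist(d[j, c("xmin", "ymin", "xmax", "ymax")]))
        if (iou > thr) keep[j] <- FALSE
      }
    }
    d[keep, ]
  }
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(2:12, 1)
    x0 <- runif(n, 0, 80); y0 <- runif(n, 0, 80)
    d <- tibble::tibble(
      xmin = x0, ymin = y0,
      xmax = x0 + runif(n, 5, 40), ymax = y0 + runif(n, 5, 40),
      class = sample(c("flower", "bud"), n, TRUE),
      confidence = round(runif(n), 3)
    )
    thr <- sample(c(0.3, 0.45, 0.6), 1)
    got <- nms(d, thr)
    want <- ref_nms(d, thr)
    key <- function(x) sort(paste(x$xmin, x$ymin, x$class, x$confidence))
    expect_equal(key(got), key(want))
  }
})

test_that("flower counting tallies per image and is order invariant", {
  expect_equal(nrow(count_flowers(tibble::tibble())), 0L)
  d <- tibble::tibble(
    xmin = 1:4, ymin = 1:4, xmax = 11:14, ymax = 11:14,
    class = c("flower", "flower", "flower", "bud"),
    confidence = 0.9, image_id = "a"
  )
  r <- count_flowers(d)
  expect_equal(r$n_flower, 3L)
  expect_equal(r$n_bud, 1L)
  expect_equal(r$flower_share, 0.75)
  shuffled <- count_flowers(d[c(3, 1, 4, 2), ])
  expect_equal(as.data.frame(r), as.data.frame(shuffled))
})

test_that("cosine annealing starts at the initial rate and decays to near zero", {
  cfg <- train_config(iterations = 200, initial_lr = 0.01, input_size = 160,
                      batch_size = 2)
  expect_equal(cosine_lr(0, cfg), 0.01)
  expect_lt(cosine_lr(199, cfg), 0.01 * 0.01)
  expect_true(all(diff(cosine_lr(0:199, cfg)) < 0))
})

test_that("a short training run decreases the smoothed loss", {
  cfg <- easy_scene_config(seed = 5, size = 160)
  imgs <- lapply(1:12, function(i) {
    ci <- cfg; ci$seed <- cfg$seed + i * 31L
    s <- generate_scene(ci); s$image_id <- paste0("im", i); s
  })
  tc <- train_config(input_size = 160, batch_size = 2, iterations = 50,
                     initial_lr = 0.02, mosaic = FALSE, seed = 1)
  g <- build_architecture("yolov4_tiny_dw", num_classes = 2, input_size = 160)
  fit <- train_detector(g, imgs, tc, gains = c(box = 3, obj = 1, cls = 1))
  gl <- glance(fit)
  expect_lt(gl$final_loss, gl$initial_loss)
  expect_equal(nrow(fit$history), 50L)
  # same seed, same first-iteration loss
  fit2 <- train_detector(g, imgs, tc, gains = c(box = 3, obj = 1, cls = 1))
  expect_equal(fit2$history$loss[1], fit$history$loss[1])
})
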