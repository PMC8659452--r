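#' Training configuration
#'
#' Defaults follow the published protocol: 608 x 608 inputs, batches of 32,
#' 75,000 iterations, initial learning rate 0.001 with cosine annealing,
#' and Mosaic augmentation. Smoke-scale runs override the sizes.
#'
#' @param input_size Network input resolution (multiple of 32).
#' @param batch_size Images per iteration.
#' @param iterations Total training iterations.
#' @param initial_lr Initial learning rate.
#' @param lr_schedule Only `"cosine_annealing"` is implemented.
#' @param mosaic Use Mosaic composition when sampling batches.
#' @param seed Master seed for sampling and initialisation.
#' @param pretrained_weights Optional path to an RDS of runtime parameters
#'   used to warm-start matching nodes (transfer-learning hook).
#' @return A `train_config` list.
#' @export
train_config <- function(input_size = 608L, batch_size = 32L,
                         iterations = 75000L, initial_lr = 0.001,
                         lr_schedule = "cosine_annealing", mosaic = TRUE,
                         seed = 0L, pretrained_weights = NULL) {
  stopifnot(input_size %% 32 == 0, batch_size >= 1, iterations >= 1,
            initial_lr > 0)
  if (lr_schedule != "cosine_annealing") abort("unrecognised lr_schedule")
  structure(list(input_size = as.integer(input_size),
                 batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations),
                 initial_lr = initial_lr, lr_schedule = lr_schedule,
                 mosaic = mosaic, seed = as.integer(seed),
                 pretrained_weights = pretrained_weights),
            class = "train_config")
}

#' Cosine-annealed learning rate
#'
#' `lr(t) = initial * (1 + cos(pi * t / T)) / 2` for iteration
#' `t = 0, ..., T - 1`: starts at `initial_lr` and decays towards zero. A
#' short linear warmup (fraction `warmup` of the budget, default none) can
#' precede the cosine branch for stability at smoke scale.
#'
#' @param iteration 0-based iteration index (vectorised).
#' @param config A [train_config()].
#' @param warmup Fraction of the iteration budget ramped linearly first.
#' @return Learning rate(s).
#' @export
cosine_lr <- function(iteration, config, warmup = 0) {
  wu <- floor(warmup * config$iterations)
  base <- config$initial_lr * (1 + cos(pi * iteration / config$iterations)) / 2
  ifelse(iteration < wu, config$initial_lr * (iteration + 1) / wu, base)
}

# split a sorted anchor set into per-head chunks; finest grid (largest S)
# takes the smallest anchors
anchor_chunks <- function(anchors, n_heads) {
  m <- wh_matrix(anchors)
  a_per_head <- nrow(m) %/% n_heads
  if (a_per_head * n_heads != nrow(m)) {
    abort("anchor count is not a multiple of the number of heads")
  }
  lapply(seq_len(n_heads), function(i) {
    m[(i - 1) * a_per_head + seq_len(a_per_head), , drop = FALSE]
  })
}

#' Decode raw head outputs into detections
#'
#' Standard YOLO decoding: per grid cell and anchor, the centre offsets go
#' through a sigmoid and are added to the cell index, the sizes scale the
#' anchor by an exponential, and the score is
#' `sigmoid(objectness) * max(sigmoid(class))`. Anchors are sorted by area
#' and split evenly across heads, the finest grid taking the smallest
#' anchors; each head's stride is inferred from its grid size.
#'
#' @param head_outputs List of `S x S x (A * (5 + C))` arrays for one image
#'   (any head order; strides are inferred).
#' @param anchors An `anchor_set` (or `(w, h)` matrix) with
#'   `A * n_heads` rows, in input-resolution pixels.
#' @param conf_threshold Minimum score to keep a detection.
#' @param input_size Network input resolution in pixels.
#' @param class_names Class labels (length `C`).
#' @param image_id Id attached to the detections.
#' @return A detection tibble (`xmin, ymin, xmax, ymax, class, confidence,
#'   image_id`).
#' @export
decode_predictions <- function(head_outputs, anchors, conf_threshold = 0.5,
                               input_size = 608L,
                               class_names = c("flower", "bud"),
                               image_id = "image") {
  n_heads <- length(head_outputs)
  sizes <- map_int(head_outputs, ~ dim(.x)[1])
  ord <- order(sizes, decreasing = TRUE)     # finest first
  chunks <- anchor_chunks(anchors, n_heads)
  nc <- length(class_names)
  out <- list()
  for (pos in seq_len(n_heads)) {
    hi <- ord[pos]
    arr <- head_outputs[[hi]]
    s <- dim(arr)[1]
    a_per_head <- dim(arr)[3] %/% (5L + nc)
    if (a_per_head * (5L + nc) != dim(arr)[3]) {
      abort("head channel count does not match anchors * (5 + classes)")
    }
    if (nrow(chunks[[pos]]) != a_per_head) {
      abort("anchor count mismatch with head outputs")
    }
    stride <- input_size / s
    m <- matrix(arr, nrow = s * s)           # (cell, channel), col-major: row-index first
    rows <- (seq_len(s * s) - 1) %% s        # 0-based grid row (y)
    cols <- (seq_len(s * s) - 1) %/% s       # 0-based grid col (x)
    for (a in seq_len(a_per_head)) {
      off <- (a - 1) * (5 + nc)
      tx <- m[, off + 1]; ty <- m[, off + 2]
      tw <- m[, off + 3]; th <- m[, off + 4]
      obj <- stats::plogis(m[, off + 5])
      cls <- stats::plogis(m[, off + 5 + seq_len(nc), drop = FALSE])
      best <- max.col(cls, ties.method = "first")
      score <- obj * cls[cbind(seq_along(best), best)]
      keep <- which(score >= conf_threshold & score > 0)
      if (!length(keep)) next
      bx <- (cols[keep] + stats::plogis(tx[keep])) * stride
      by <- (rows[keep] + stats::plogis(ty[keep])) * stride
      bw <- chunks[[pos]][a, 1] * exp(pmin(tw[keep], 10))
      bh <- chunks[[pos]][a, 2] * exp(pmin(th[keep], 10))
      out[[length(out) + 1]] <- tibble(
        xmin = bx - bw / 2, ymin = by - bh / 2,
        xmax = bx + bw / 2, ymax = by + bh / 2,
        class = class_names[best[keep]],
        confidence = pmin(score[keep], 1),
        image_id = image_id
      )
    }
  }
  dets <- bind_rows(out)
  if (!nrow(dets)) {
    dets <- tibble(xmin = numeric(), ymin = numeric(), xmax = numeric(),
                   ymax = numeric(), class = character(),
                   confidence = numeric(), image_id = character())
  }
  dets
}

#' Greedy per-class non-maximum suppression
#'
#' Detections are processed per class in order of decreasing confidence
#' (ties broken lexicographically on the box coordinates); a detection is
#' suppressed when its corner-coordinate IoU with an already kept detection
#' of the same class exceeds the threshold. When an `image_id` column is
#' present suppression is additionally per image.
#'
#' @param dets A detection tibble.
#' @param iou_threshold Suppression threshold (default 0.45).
#' @return The surviving detections, in processing order.
#' @export
nms <- function(dets, iou_threshold = 0.45) {
  if (!nrow(dets)) return(dets)
  validate_boxes(dets, "detections")
  groups <- if ("image_id" %in% names(dets)) {
    split(dets, list(dets$image_id, dets$class), drop = TRUE)
  } else {
    split(dets, dets$class, drop = TRUE)
  }
  kept <- lapply(groups, function(g) {
    g <- arrange(g, desc(.data$confidence), .data$xmin, .data$ymin,
                 .data$xmax, .data$ymax)
    keep <- logical(nrow(g))
    for (i in seq_len(nrow(g))) {
      prior <- g[which(keep), , drop = FALSE]
      if (!nrow(prior) ||
          all(iou_boxes(prior, c(g$xmin[i], g$ymin[i], g$xmax[i], g$ymax[i])) <= iou_threshold)) {
        keep[i] <- TRUE
      }
    }
    g[keep, , drop = FALSE]
  })
  bind_rows(kept)
}

#' Per-image flower and bud counts
#'
#' Tallies detections (after NMS) into per-image counts and the flower
#' share `n_flower / (n_flower + n_bud)` — the toolkit's operational
#' flowering-rate statistic, reported as `NA` when an image has no
#' detections. The statistic is a package convention: published counts are
#' evaluated per object, and no closed-form flowering rate accompanies
#' them.
#'
#' @param dets Detection tibble with an `image_id` column.
#' @return A `count_report` tibble: `image_id`, `n_flower`, `n_bud`,
#'   `flower_share`.
#' @export
count_flowers <- function(dets) {
  if (!nrow(dets)) {
    out <- tibble(image_id = character(), n_flower = integer(),
                  n_bud = integer(), flower_share = numeric())
  } else {
    out <- dets %>%
      group_by(.data$image_id) %>%
      summarise(
        n_flower = sum(.data$class == "flower"),
        n_bud = sum(.data$class == "bud"),
        .groups = "drop"
      ) %>%
      mutate(flower_share = ifelse(.data$n_flower + .data$n_bud > 0,
                                   .data$n_flower / (.data$n_flower + .data$n_bud),
                                   NA_real_))
  }
  structure(out, class = c("count_report", class(out)))
}

#' Run detection over labeled images
#'
#' Resizes each image to the network input, runs the runtime model in
#' evaluation mode, decodes and suppresses, and maps boxes back to the
#' original image scale.
#'
#' @param model A `runtime_model`.
#' @param images List of [labeled_image()]s with pixels.
#' @param anchors Anchor set at the network input resolution.
#' @param conf_threshold Score threshold (default 0.5).
#' @param nms_iou NMS IoU threshold (default 0.45).
#' @param class_names Class labels.
#' @return A detection tibble over all images.
#' @export
detect_images <- function(model, images, anchors, conf_threshold = 0.5,
                          nms_iou = 0.45, class_names = c("flower", "bud")) {
  input_size <- attr(model$graph, "input_size")
  px <- lapply(images, function(im) resize_nearest(im$pixels, input_size, input_size))
  fwd <- forward_runtime(model, px, train = FALSE)
  dets <- map2(fwd$heads, images, function(heads, im) {
    d <- decode_predictions(heads, anchors, conf_threshold, input_size,
                            class_names, im$image_id)
    # back to original image coordinates
    d$xmin <- d$xmin * im$width / input_size
    d$xmax <- d$xmax * im$width / input_size
    d$ymin <- d$ymin * im$height / input_size
    d$ymax <- d$ymax * im$height / input_size
    d
  }) %>% bind_rows()
  if (nrow(dets)) {
    dets <- dets[dets$xmax > dets$xmin & dets$ymax > dets$ymin, , drop = FALSE]
    dets <- nms(dets, nms_iou)
  }
  dets
}
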