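#' Complete-IoU between two boxes in centre-size form
#'
#' `CIoU = IoU - d^2/c^2 - alpha * v`: IoU penalised by the normalised
#' centre distance and an aspect-ratio consistency term.
#'
#' @param a,b Numeric length-4 vectors `(cx, cy, w, h)`.
#' @return CIoU in `[-1, 1]`.
#' @export
ciou <- function(a, b) {
  ax0 <- a[1] - a[3] / 2; ax1 <- a[1] + a[3] / 2
  ay0 <- a[2] - a[4] / 2; ay1 <- a[2] + a[4] / 2
  bx0 <- b[1] - b[3] / 2; bx1 <- b[1] + b[3] / 2
  by0 <- b[2] - b[4] / 2; by1 <- b[2] + b[4] / 2
  iw <- max(0, min(ax1, bx1) - max(ax0, bx0))
  ih <- max(0, min(ay1, by1) - max(ay0, by0))
  inter <- iw * ih
  union <- a[3] * a[4] + b[3] * b[4] - inter
  iou <- if (union > 0) inter / union else 0
  cw <- max(ax1, bx1) - min(ax0, bx0)
  chh <- max(ay1, by1) - min(ay0, by0)
  c2 <- cw^2 + chh^2 + 1e-9
  d2 <- (a[1] - b[1])^2 + (a[2] - b[2])^2
  v <- 4 / pi^2 * (atan(b[3] / b[4]) - atan(a[3] / a[4]))^2
  alpha <- v / (1 - iou + v + 1e-9)
  iou - d2 / c2 - alpha * v
}

ciou_grad <- function(a, b) {
  # central differences; few positives per image make this cheap and robust
  g <- numeric(4)
  for (i in 1:4) {
    eps <- 1e-4 * max(1, abs(a[i]))
    ap <- a; ap[i] <- a[i] + eps
    am <- a; am[i] <- a[i] - eps
    g[i] <- (ciou(ap, b) - ciou(am, b)) / (2 * eps)
  }
  g
}

# assign each ground-truth box to its best anchor (over all heads) and cell
assign_targets <- function(gt, anchors_m, a_per_head, strides_by_chunk,
                           input_size) {
  if (!nrow(gt)) return(NULL)
  cx <- (gt$xmin + gt$xmax) / 2
  cy <- (gt$ymin + gt$ymax) / 2
  bw <- gt$xmax - gt$xmin
  bh <- gt$ymax - gt$ymin
  out <- list()
  for (i in seq_len(nrow(gt))) {
    sims <- iou_wh(anchors_m, c(bw[i], bh[i]))
    # the best anchor overall, plus every anchor that fits well (multi-scale)
    sel <- union(which.max(sims), which(sims >= 0.5))
    for (best in sel) {
      chunk <- (best - 1L) %/% a_per_head + 1L
      a <- best - (chunk - 1L) * a_per_head
      stride <- strides_by_chunk[chunk]
      s <- input_size / stride
      col <- min(max(floor(cx[i] / stride), 0), s - 1)
      row <- min(max(floor(cy[i] / stride), 0), s - 1)
      out[[length(out) + 1]] <- tibble(
        chunk = chunk, a = a, row = row, col = col,
        cx = cx[i], cy = cy[i], bw = bw[i], bh = bh[i],
        cls = gt$cls_idx[i]
      )
    }
  }
  tg <- bind_rows(out)
  # first assignment wins when two objects land on the same anchor cell
  tg[!duplicated(tg[, c("chunk", "a", "row", "col")]), , drop = FALSE]
}

# loss and gradient for one head of one image
yolo_head_grad <- function(arr, anchors_chunk, stride, tg, gt_boxes, nc,
                           gains = c(box = 1, obj = 1, cls = 1),
                           ignore_iou = 0.7) {
  s <- dim(arr)[1]
  a_per_head <- dim(arr)[3] %/% (5L + nc)
  m <- matrix(arr, nrow = s * s)
  dm <- matrix(0, nrow = s * s, ncol = ncol(m))
  rows <- (seq_len(s * s) - 1) %% s
  cols <- (seq_len(s * s) - 1) %/% s
  loss_box <- loss_obj <- loss_cls <- 0
  for (a in seq_len(a_per_head)) {
    off <- (a - 1) * (5 + nc)
    obj_logit <- m[, off + 5]
    obj_p <- stats::plogis(obj_logit)
    t_obj <- numeric(s * s)
    w_obj <- rep(1, s * s)
    # ignore confident predictions that already sit on an object
    if (nrow(gt_boxes)) {
      bx <- (cols + stats::plogis(m[, off + 1])) * stride
      by <- (rows + stats::plogis(m[, off + 2])) * stride
      bw <- anchors_chunk[a, 1] * exp(pmin(m[, off + 3], 10))
      bh <- anchors_chunk[a, 2] * exp(pmin(m[, off + 4], 10))
      pred <- tibble(xmin = bx - bw / 2, ymin = by - bh / 2,
                     xmax = bx + bw / 2, ymax = by + bh / 2)
      best_iou <- rep(0, s * s)
      for (gi in seq_len(nrow(gt_boxes))) {
        best_iou <- pmax(best_iou, iou_boxes(pred, as.numeric(gt_boxes[gi, c("xmin", "ymin", "xmax", "ymax")])))
      }
      w_obj[best_iou > ignore_iou] <- 0
    }
    pos <- if (is.null(tg) || !nrow(tg)) NULL else tg[tg$a == a, , drop = FALSE]
    if (!is.null(pos) && nrow(pos)) {
      idx <- pos$row + pos$col * s + 1L
      t_obj[idx] <- 1
      w_obj[idx] <- 1
      for (p in seq_len(nrow(pos))) {
        ii <- idx[p]
        tx <- m[ii, off + 1]; ty <- m[ii, off + 2]
        tw <- m[ii, off + 3]; th <- m[ii, off + 4]
        sx <- stats::plogis(tx); sy <- stats::plogis(ty)
        pw <- anchors_chunk[a, 1] * exp(min(tw, 10))
        ph <- anchors_chunk[a, 2] * exp(min(th, 10))
        px <- (pos$col[p] + sx) * stride
        py <- (pos$row[p] + sy) * stride
        pred_box <- c(px, py, pw, ph)
        gt_box <- c(pos$cx[p], pos$cy[p], pos$bw[p], pos$bh[p])
        cval <- ciou(pred_box, gt_box)
        loss_box <- loss_box + gains["box"] * (1 - cval)
        g <- -gains["box"] * ciou_grad(pred_box, gt_box)
        dm[ii, off + 1] <- dm[ii, off + 1] + g[1] * stride * sx * (1 - sx)
        dm[ii, off + 2] <- dm[ii, off + 2] + g[2] * stride * sy * (1 - sy)
        dm[ii, off + 3] <- dm[ii, off + 3] + g[3] * pw
        dm[ii, off + 4] <- dm[ii, off + 4] + g[4] * ph
        # class BCE on the positive cell
        for (ci in seq_len(nc)) {
          logit <- m[ii, off + 5 + ci]
          pr <- stats::plogis(logit)
          tcl <- as.numeric(ci == pos$cls[p])
          loss_cls <- loss_cls + gains["cls"] * bce(pr, tcl)
          dm[ii, off + 5 + ci] <- dm[ii, off + 5 + ci] + gains["cls"] * (pr - tcl)
        }
      }
    }
    w_obj[t_obj > 0] <- 3   # emphasise the rare positives
    loss_obj <- loss_obj + gains["obj"] * sum(w_obj * bce(obj_p, t_obj))
    dm[, off + 5] <- dm[, off + 5] + gains["obj"] * w_obj * (obj_p - t_obj)
  }
  list(darr = array(dm, dim = dim(arr)),
       loss = c(box = loss_box, obj = loss_obj, cls = loss_cls))
}

bce <- function(p, t) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -(t * log(p) + (1 - t) * log(1 - p))
}

#' Train a detector at smoke scale
#'
#' Gradient descent (Adam by default, momentum SGD as a switch) on the
#' package's native runtime: CIoU box loss on best-anchor-assigned
#' positives, binary cross-entropy objectness with an ignore band
#' (unassigned predictions overlapping an object above 0.7 IoU are neither
#' positives nor penalised), and binary cross-entropy class terms, under a
#' cosine-annealed learning rate with short warmup. Training ends with a
#' precise-batch-norm pass over the training images. The reference
#' protocol trains for 75,000 iterations at batch 32 on GPU hardware; this
#' implementation is intended for scaled-down runs that exercise the full
#' pipeline.
#'
#' @param graph An `arch_graph` (training currently requires grouped convs
#'   only of the depthwise kind, which covers all variants).
#' @param images List of [labeled_image()]s (the training split).
#' @param config A [train_config()].
#' @param anchors Optional anchor set at the network input resolution;
#'   computed from the training boxes by [kmeans_anchors()] when omitted.
#' @param class_names Class labels (order defines class indices).
#' @param optimizer `"adam"` (default; first/second-moment rates 0.9/0.999)
#'   or `"sgd"` with momentum.
#' @param momentum SGD momentum (default 0.9).
#' @param gains Named weights for the `box`, `obj` and `cls` loss terms.
#' @param warmup Fraction of iterations under linear learning-rate warmup.
#' @param verbose Print a line every 25 iterations.
#' @return A `train_result`: list with `model`, `history` (iteration, loss
#'   and components, lr), `anchors`, `config`.
#' @export
train_detector <- function(graph, images, config, anchors = NULL,
                           class_names = c("flower", "bud"),
                           optimizer = c("adam", "sgd"),
                           momentum = 0.9,
                           gains = c(box = 1, obj = 1, cls = 1),
                           warmup = 0.05, verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  input_size <- config$input_size
  if (attr(graph, "input_size") != input_size) {
    attr(graph, "input_size") <- input_size
  }
  n_heads <- sum(graph$head > 0L)
  a_per_head <- attr(graph, "anchors_per_head")
  nc <- attr(graph, "num_classes")
  stopifnot(nc == length(class_names))

  # images resized to the network input, boxes along
  prep <- lapply(images, function(im) {
    px <- resize_nearest(im$pixels, input_size, input_size)
    b <- im$boxes
    if (nrow(b)) {
      b$xmin <- b$xmin * input_size / im$width
      b$xmax <- b$xmax * input_size / im$width
      b$ymin <- b$ymin * input_size / im$height
      b$ymax <- b$ymax * input_size / im$height
      b$cls_idx <- match(b$class, class_names)
    } else {
      b$cls_idx <- integer()
    }
    list(px = px, boxes = b)
  })

  if (is.null(anchors)) {
    all_wh <- bind_rows(lapply(prep, function(p) {
      tibble(w = p$boxes$xmax - p$boxes$xmin, h = p$boxes$ymax - p$boxes$ymin)
    }))
    anchors <- kmeans_anchors(all_wh, k = n_heads * a_per_head,
                              seed = config$seed, input_size = input_size)
  }
  anchors_m <- wh_matrix(anchors)

  model <- build_runtime_model(graph, seed = config$seed)
  if (!is.null(config$pretrained_weights)) {
    pre <- readRDS(config$pretrained_weights)
    for (nm in intersect(names(pre), names(model$params))) {
      ok <- all(map_lgl(names(model$params[[nm]]), function(f) {
        identical(dim(pre[[nm]][[f]]), dim(model$params[[nm]][[f]])) &&
          length(pre[[nm]][[f]]) == length(model$params[[nm]][[f]])
      }))
      if (ok) model$params[[nm]] <- pre[[nm]]
    }
  }
  # start the heads pessimistic about objectness
  for (nm in head_node_names(graph)) {
    b <- model$params[[nm]]$b
    ch <- 5L + nc
    b[seq(5, length(b), by = ch)] <- -3
    model$params[[nm]]$b <- b
  }

  velocity <- lapply(model$params, function(p) lapply(p, function(x) x * 0))
  second <- if (optimizer == "adam") velocity else NULL
  history <- list()

  # head geometry: strides inferred once from a probe forward pass
  probe <- forward_runtime(model, list(array(0, dim = c(input_size, input_size, 3))))
  head_sizes <- map_int(probe$heads[[1]], ~ dim(.x)[1])
  ord <- order(head_sizes, decreasing = TRUE)  # chunk -> head position
  strides_by_chunk <- input_size / head_sizes[ord]
  chunks <- anchor_chunks(anchors_m, n_heads)

  for (t in seq_len(config$iterations) - 1L) {
    batch <- withr_seed(config$seed + t, {
      ids <- sample.int(length(prep), config$batch_size, replace = length(prep) < config$batch_size)
      lapply(ids, function(i) {
        p <- prep[[i]]
        if (runif(1) < 0.5) {   # horizontal mirror
          p$px <- p$px[, input_size:1, , drop = FALSE]
          if (nrow(p$boxes)) {
            xm <- input_size - p$boxes$xmax
            p$boxes$xmax <- input_size - p$boxes$xmin
            p$boxes$xmin <- xm
          }
        }
        if (config$mosaic && runif(1) < 0.5 && length(prep) >= 4) {
          js <- sample.int(length(prep), 4)
          mimgs <- lapply(js, function(j) {
            labeled_image("m", pixels = prep[[j]]$px,
                          boxes = prep[[j]]$boxes[, names(empty_boxes())])
          })
          mo <- mosaic(mimgs, out_size = input_size,
                       seed = (config$seed + t) %% 2147483647)
          mb <- mo$boxes
          mb$cls_idx <- match(mb$class, class_names)
          p <- list(px = mo$pixels, boxes = mb)
        }
        p
      })
    })

    fwd <- forward_runtime(model, lapply(batch, `[[`, "px"), train = TRUE)
    n_img <- length(batch)
    dheads <- vector("list", n_img)
    loss_parts <- c(box = 0, obj = 0, cls = 0)
    for (j in seq_len(n_img)) {
      gt <- batch[[j]]$boxes
      tg <- assign_targets(gt, anchors_m, a_per_head, strides_by_chunk, input_size)
      dlist <- vector("list", n_heads)
      for (chunk in seq_len(n_heads)) {
        hpos <- ord[chunk]
        tg_c <- if (is.null(tg)) NULL else tg[tg$chunk == chunk, , drop = FALSE]
        res <- yolo_head_grad(fwd$heads[[j]][[hpos]], chunks[[chunk]],
                              strides_by_chunk[chunk], tg_c, gt, nc, gains)
        dlist[[hpos]] <- res$darr / n_img
        loss_parts <- loss_parts + res$loss / n_img
      }
      dheads[[j]] <- dlist
    }
    grads <- backward_runtime(model, fwd, dheads)

    # global-norm gradient clip
    sq <- sum(map_dbl(grads, function(g) sum(map_dbl(g, function(x) sum(x^2)))))
    gnorm <- sqrt(sq)
    scale <- if (gnorm > 10) 10 / gnorm else 1

    lr <- cosine_lr(t, config, warmup)
    for (nm in names(grads)) {
      for (f in names(grads[[nm]])) {
        g <- scale * grads[[nm]][[f]]
        if (optimizer == "adam") {
          velocity[[nm]][[f]] <- 0.9 * velocity[[nm]][[f]] + 0.1 * g
          second[[nm]][[f]] <- 0.999 * second[[nm]][[f]] + 0.001 * g^2
          mhat <- velocity[[nm]][[f]] / (1 - 0.9^(t + 1))
          vhat <- second[[nm]][[f]] / (1 - 0.999^(t + 1))
          model$params[[nm]][[f]] <- model$params[[nm]][[f]] -
            lr * mhat / (sqrt(vhat) + 1e-8)
        } else {
          v <- momentum * velocity[[nm]][[f]] - lr * g
          velocity[[nm]][[f]] <- v
          model$params[[nm]][[f]] <- model$params[[nm]][[f]] + v
        }
      }
    }
    history[[t + 1]] <- tibble(iteration = t, loss = sum(loss_parts),
                               box = loss_parts["box"], obj = loss_parts["obj"],
                               cls = loss_parts["cls"], lr = lr)
    if (verbose && t %% 25 == 0) {
      message(sprintf("iter %4d  loss %.3f (box %.3f obj %.3f cls %.3f) lr %.5f",
                      t, sum(loss_parts), loss_parts["box"], loss_parts["obj"],
                      loss_parts["cls"], lr))
    }
  }
  # precise batch norm: replace lagged running statistics with aggregated
  # batch statistics over the training images
  refresh_bn_stats(model, lapply(prep, `[[`, "px"))
  structure(list(model = model, history = bind_rows(history),
                 anchors = anchors, config = config),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  h <- x$history
  cat(sprintf("<train_result> %d iterations, loss %.3f -> %.3f\n",
              nrow(h), h$loss[1], h$loss[nrow(h)]))
  invisible(x)
}

#' @export
tidy.train_result <- function(x, ...) x$history

#' @export
glance.train_result <- function(x, ...) {
  h <- x$history
  k <- min(10, nrow(h))
  tibble(iterations = nrow(h),
         initial_loss = mean(h$loss[seq_len(k)]),
         final_loss = mean(h$loss[nrow(h) - seq_len(k) + 1]))
}

#' @export
autoplot.train_result <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$iteration, y = .data$loss)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_smooth(se = FALSE, method = "loess", formula = y ~ x) +
    ggplot2::labs(x = "Iteration", y = "Loss")
}
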