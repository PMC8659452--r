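#' Match detections against ground truth (VOC protocol)
#'
#' Detections are processed in order of decreasing confidence; each one is
#' matched to the unmatched same-class, same-image ground-truth box of
#' highest IoU, and counts as a true positive when that IoU reaches the
#' threshold, otherwise as a false positive. Ground truths matched at most
#' once; leftovers are the false negatives. `TP` is the number of objects
#' predicted correctly, `FP` the number of spurious detections, `FN` the
#' number missed.
#'
#' @param dets Detection tibble (needs `confidence`; `image_id` optional —
#'   matching is per image when present).
#' @param gts Ground-truth box tibble (same columns, `confidence` ignored).
#' @param iou_threshold Match threshold (default 0.5).
#' @return A `match_result`: list with `dets` (ranked, with a logical `tp`
#'   column), `n_gt`, `gt_matched` and `iou_threshold`.
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  if (!"image_id" %in% names(dets)) dets$image_id <- "image"
  if (!"image_id" %in% names(gts)) gts$image_id <- "image"
  dets <- arrange(dets, desc(.data$confidence), .data$xmin, .data$ymin)
  matched <- logical(nrow(gts))
  tp <- logical(nrow(dets))
  for (i in seq_len(nrow(dets))) {
    cand <- which(!matched & gts$class == dets$class[i] &
                    gts$image_id == dets$image_id[i])
    if (!length(cand)) next
    ious <- iou_boxes(gts[cand, ],
                      c(dets$xmin[i], dets$ymin[i], dets$xmax[i], dets$ymax[i]))
    best <- which.max(ious)   # first index on ties -> lower gt index
    if (ious[best] >= iou_threshold) {
      tp[i] <- TRUE
      matched[cand[best]] <- TRUE
    }
  }
  dets$tp <- tp
  structure(list(dets = dets, n_gt = nrow(gts), gt_matched = matched,
                 iou_threshold = iou_threshold),
            class = "match_result")
}

#' Cumulative precision-recall curve
#'
#' Over the confidence-ranked detection list, `P = TP / (TP + FP)` and
#' `R = TP / (TP + FN)` are accumulated rank by rank; recall is
#' nondecreasing. With no detections the conventions are `R = 0` and
#' `P = 1` (precision at zero recall).
#'
#' @param matches A `match_result` (or logical TP vector in rank order).
#' @param n_gt Number of ground-truth objects (taken from `matches` when
#'   available).
#' @return A tibble with `rank`, `precision`, `recall`.
#' @export
precision_recall <- function(matches, n_gt = NULL) {
  if (inherits(matches, "match_result")) {
    tp <- matches$dets$tp
    n_gt <- n_gt %||% matches$n_gt
  } else {
    tp <- as.logical(matches)
    if (is.null(n_gt)) abort("n_gt is required when passing a raw TP vector")
  }
  if (!length(tp)) {
    return(tibble(rank = integer(), precision = numeric(), recall = numeric()))
  }
  cum_tp <- cumsum(tp)
  ranks <- seq_along(tp)
  tibble(
    rank = ranks,
    precision = cum_tp / ranks,
    recall = if (n_gt > 0) cum_tp / n_gt else rep(0, length(tp))
  )
}

#' Average precision as the area under the precision envelope
#'
#' All-point interpolation: precision is replaced by its monotone
#' (right-to-left running maximum) envelope and integrated over recall —
#' the plain integral `AP = \int P dR`. The VOC-2007 11-point variant is
#' available as a switch.
#'
#' @param pr A precision-recall tibble from [precision_recall()].
#' @param method `"all_point"` (default) or `"eleven_point"`.
#' @return AP in `[0, 1]`; 0 for an empty curve.
#' @export
average_precision <- function(pr, method = c("all_point", "eleven_point")) {
  method <- match.arg(method)
  if (!nrow(pr)) return(0)
  r <- c(0, pr$recall)
  p <- c(1, pr$precision)
  env <- rev(cummax(rev(p)))
  if (method == "eleven_point") {
    pts <- map_dbl(seq(0, 1, by = 0.1), function(rt) {
      ok <- which(r >= rt)
      if (length(ok)) max(env[ok]) else 0
    })
    return(mean(pts))
  }
  sum(diff(r) * env[-1])
}

#' Mean average precision over classes
#'
#' @param aps Numeric vector of per-class AP values.
#' @return Their arithmetic mean, `mAP = (1/C) * sum(AP_i)`.
#' @export
mean_ap <- function(aps) {
  if (!length(aps)) abort("mean_ap needs at least one class AP")
  mean(aps)
}

#' F1 score
#'
#' Harmonic mean of precision and recall, `2PR / (P + R)`, equivalently
#' `2TP / (2TP + FP + FN)`; defined as 0 when `P + R = 0`.
#'
#' @param precision,recall Fractions in `[0, 1]`.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Partition images by object density
#'
#' @param images List of [labeled_image()]s.
#' @param thresholds Two increasing counts `(t1, t2)`: images with at most
#'   `t1` ground-truth boxes are `few`, those with more than `t2` are
#'   `intensive`, the rest `middle`. Default `c(10, 30)`.
#' @return Named list of three image lists: `few`, `middle`, `intensive`.
#' @export
stratify_by_density <- function(images, thresholds = c(10, 30)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  n <- map_int(images, ~ nrow(.x$boxes))
  list(
    few = images[n <= thresholds[1]],
    middle = images[n > thresholds[1] & n <= thresholds[2]],
    intensive = images[n > thresholds[2]]
  )
}

#' Evaluate detections against labeled images
#'
#' Computes per-class PR curves and AP (at the given IoU threshold), their
#' mean (mAP), and per-class and aggregate F1 at the final operating point
#' of the ranked list. With `strata` thresholds the same report is also
#' produced per density stratum.
#'
#' @param dets Detection tibble (post-NMS) with `image_id`.
#' @param images List of [labeled_image()]s supplying ground truth.
#' @param iou_threshold Match threshold (default 0.5, i.e. mAP@0.5).
#' @param classes Classes to evaluate; defaults to those present in the
#'   ground truth.
#' @param strata Optional density thresholds passed to
#'   [stratify_by_density()].
#' @param ap_method Passed to [average_precision()].
#' @return An `eval_report`: list with `per_class` tibble (`class`, `ap`,
#'   `precision`, `recall`, `f1`, `n_gt`, `n_det`), `map`, `f1`,
#'   `pr_curves`, and optionally `strata`.
#' @export
evaluate_detections <- function(dets, images, iou_threshold = 0.5,
                                classes = NULL, strata = NULL,
                                ap_method = "all_point") {
  gts <- bind_rows(lapply(images, function(im) {
    b <- im$boxes
    b$image_id <- im$image_id
    b
  })) %||% empty_boxes()
  if (!nrow(gts)) abort("no ground-truth boxes to evaluate against")
  classes <- classes %||% sort(unique(gts$class))
  per_class <- list()
  curves <- list()
  tot_tp <- tot_fp <- tot_fn <- 0
  for (cl in classes) {
    d <- dets[dets$class == cl, , drop = FALSE]
    gt <- gts[gts$class == cl, , drop = FALSE]
    mr <- match_detections(d, gt, iou_threshold)
    pr <- precision_recall(mr)
    ap <- average_precision(pr, ap_method)
    tp <- sum(mr$dets$tp)
    fp <- nrow(d) - tp
    fn <- nrow(gt) - tp
    prec <- if (tp + fp > 0) tp / (tp + fp) else 1
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    per_class[[cl]] <- tibble(
      class = cl, ap = ap, precision = prec, recall = rec,
      f1 = f1_score(prec, rec), n_gt = nrow(gt), n_det = nrow(d)
    )
    if (nrow(pr)) curves[[cl]] <- mutate(pr, class = cl)
    tot_tp <- tot_tp + tp; tot_fp <- tot_fp + fp; tot_fn <- tot_fn + fn
  }
  per_class <- bind_rows(per_class)
  agg_p <- if (tot_tp + tot_fp > 0) tot_tp / (tot_tp + tot_fp) else 1
  agg_r <- if (tot_tp + tot_fn > 0) tot_tp / (tot_tp + tot_fn) else 0
  report <- list(
    per_class = per_class,
    map = mean_ap(per_class$ap),
    f1 = f1_score(agg_p, agg_r),
    precision = agg_p, recall = agg_r,
    tp = tot_tp, fp = tot_fp, fn = tot_fn,
    iou_threshold = iou_threshold,
    pr_curves = bind_rows(curves) %||% tibble()
  )
  if (!is.null(strata)) {
    parts <- stratify_by_density(images, strata)
    report$strata <- lapply(parts, function(part) {
      if (!length(part)) return(NULL)
      ids <- map_chr(part, "image_id")
      evaluate_detections(dets[dets$image_id %in% ids, , drop = FALSE],
                          part, iou_threshold, classes, strata = NULL,
                          ap_method = ap_method)
    })
  }
  structure(report, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> mAP@%.2g = %.4f, F1 = %.4f (TP %d / FP %d / FN %d)\n",
              x$iou_threshold, x$map, x$f1, x$tp, x$fp, x$fn))
  print(x$per_class)
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, ...) x$per_class

#' @export
glance.eval_report <- function(x, ...) {
  tibble(map = x$map, f1 = x$f1, precision = x$precision, recall = x$recall,
         tp = x$tp, fp = x$fp, fn = x$fn, iou_threshold = x$iou_threshold)
}

#' @export
autoplot.eval_report <- function(object, ...) {
  if (!nrow(object$pr_curves)) abort("no PR curves to plot")
  ggplot2::ggplot(object$pr_curves,
                  ggplot2::aes(x = .data$recall, y = .data$precision,
                               colour = .data$class)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision")
}
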