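#' K-means anchor clustering under IoU distance
#'
#' Clusters ground-truth box dimensions `(w, h)` with Lloyd iterations using
#' the distance `d = 1 - iou_wh`, the standard metric for anchor-box
#' optimisation: it is scale-aware where Euclidean distance on pixels is
#' not. Initialisation is k-means++ under the same distance; centroid
#' updates use the per-dimension median by default (robust to the long tail
#' of large boxes), with the mean available as a switch. Assignment ties
#' break toward the lowest anchor index; an emptied cluster is re-seeded
#' from the box farthest from its anchor.
#'
#' @param wh A tibble/matrix of box dimensions with columns `w`, `h`.
#' @param k Number of anchors; must not exceed the number of boxes.
#' @param seed Integer seed (initialisation only).
#' @param max_iter Maximum Lloyd iterations.
#' @param tol Stop when the mean best-IoU improves by less than this.
#' @param update `"median"` (default) or `"mean"` centroid update.
#' @param input_size Resolution the dimensions refer to (metadata).
#' @return An `anchor_set`: a tibble of `k` `(w, h)` anchors sorted by area,
#'   with attributes `k`, `avg_iou` and `input_size`.
#' @examples
#' pop <- generate_box_population(list(c(20, 20), c(100, 100)), 50, 2, seed = 1)
#' kmeans_anchors(pop, k = 2, seed = 1)
#' @export
kmeans_anchors <- function(wh, k, seed = 0L, max_iter = 100L, tol = 1e-8,
                           update = c("median", "mean"), input_size = 608L) {
  update <- match.arg(update)
  m <- wh_matrix(wh)
  n <- nrow(m)
  if (k < 1) abort("k must be >= 1")
  if (k > n) abort(sprintf("k = %d exceeds the number of boxes (%d)", k, n))
  if (any(m <= 0)) abort("box dimensions must be strictly positive")

  centers <- withr_seed(seed, kmeanspp_init(m, k))
  upd <- if (update == "median") {
    function(x) apply(x, 2, median)
  } else {
    function(x) colMeans(x)
  }
  prev_obj <- -Inf
  assign <- rep(1L, n)
  for (iter in seq_len(max_iter)) {
    sim <- iou_matrix(m, centers)              # n x k best-IoU similarities
    assign <- max.col(sim, ties.method = "first")
    for (j in seq_len(k)) {
      members <- m[assign == j, , drop = FALSE]
      if (!nrow(members)) {
        far <- which.min(sim[cbind(seq_len(n), assign)])
        centers[j, ] <- m[far, ]
        assign[far] <- j
        members <- m[far, , drop = FALSE]
      }
      centers[j, ] <- upd(members)
    }
    obj <- mean(apply(iou_matrix(m, centers), 1, max))
    if (obj - prev_obj < tol && iter > 1) break
    prev_obj <- obj
  }
  new_anchor_set(centers, m, input_size)
}

new_anchor_set <- function(centers, m, input_size) {
  ord <- order(centers[, 1] * centers[, 2])
  centers <- centers[ord, , drop = FALSE]
  avg_iou <- mean(apply(iou_matrix(m, centers), 1, max))
  out <- tibble(w = centers[, 1], h = centers[, 2])
  structure(out, class = c("anchor_set", class(out)),
            k = nrow(centers), avg_iou = avg_iou,
            input_size = as.integer(input_size))
}

# n x k matrix of iou_wh(box_i, center_j)
iou_matrix <- function(m, centers) {
  k <- nrow(centers)
  out <- matrix(0, nrow(m), k)
  for (j in seq_len(k)) out[, j] <- iou_wh(m, centers[j, ])
  out
}

kmeanspp_init <- function(m, k) {
  n <- nrow(m)
  centers <- m[sample.int(n, 1), , drop = FALSE]
  while (nrow(centers) < k) {
    d <- 1 - apply(iou_matrix(m, centers), 1, max)
    if (sum(d) <= 0) {
      cand <- sample.int(n, 1)
    } else {
      cand <- sample.int(n, 1, prob = d)
    }
    centers <- rbind(centers, m[cand, , drop = FALSE])
  }
  centers
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("<anchor_set> k = %d at %d px, Avg IoU = %s\n",
              attr(x, "k"), attr(x, "input_size"),
              formatC(attr(x, "avg_iou"), digits = 4, format = "f")))
  cat(" ", anchor_string(x), "\n")
  invisible(x)
}

#' Mean best IoU of a box population against an anchor set
#'
#' Independent recomputation of the clustering quality score: the mean over
#' boxes of the best `iou_wh` against any anchor.
#'
#' @param wh Box dimensions (columns `w`, `h`).
#' @param anchors An `anchor_set` or `(w, h)` matrix.
#' @return A fraction in `[0, 1]`.
#' @export
avg_iou <- function(wh, anchors) {
  mean(apply(iou_matrix(wh_matrix(wh), wh_matrix(anchors)), 1, max))
}

#' Avg-IoU curve over a range of k
#'
#' Runs [kmeans_anchors()] for each `k` in `k_min:k_max`, keeping the best
#' of `restarts` seeded restarts, and returns the quality curve used for
#' elbow-based selection of the anchor count.
#'
#' @inheritParams kmeans_anchors
#' @param k_min,k_max Inclusive range of cluster counts.
#' @param restarts Restarts per `k` (best Avg IoU kept).
#' @return An `avg_iou_curve` tibble with columns `k` and `avg_iou`.
#' @export
avg_iou_curve <- function(wh, k_min = 2L, k_max = 10L, restarts = 10L,
                          seed = 0L, input_size = 608L) {
  stopifnot(k_max >= k_min, k_min >= 1, restarts >= 1)
  entries <- map(k_min:k_max, function(k) {
    fits <- map(seq_len(restarts), function(r) {
      kmeans_anchors(wh, k, seed = seed + 1000L * r + k,
                     input_size = input_size)
    })
    best <- fits[[which.max(map_dbl(fits, ~ attr(.x, "avg_iou")))]]
    tibble(k = as.integer(k), avg_iou = attr(best, "avg_iou"))
  })
  out <- bind_rows(entries)
  structure(out, class = c("avg_iou_curve", class(out)))
}

#' Elbow selection of the anchor count
#'
#' On a concave quality curve the raw slope is always largest at the first
#' step, so "the point with the largest slope" is operationalised as the
#' knee: the `k` whose forward slope drops the most relative to the previous
#' step, i.e. `argmax_k (slope[k-1 -> k] - slope[k -> k+1])`. Ties break
#' toward the smaller `k`.
#'
#' @param curve An `avg_iou_curve` (or tibble with columns `k`, `avg_iou`);
#'   needs at least 3 entries.
#' @return The selected `k` (integer).
#' @examples
#' curve <- tibble::tibble(k = 2:5, avg_iou = c(0.50, 0.70, 0.74, 0.76))
#' select_k_elbow(curve) # 3
#' @export
select_k_elbow <- function(curve) {
  stopifnot(all(c("k", "avg_iou") %in% names(curve)))
  if (nrow(curve) < 3) abort("elbow selection needs at least 3 curve entries")
  if (any(diff(curve$k) <= 0)) abort("curve ks must be strictly increasing")
  slope <- diff(curve$avg_iou) / diff(curve$k)
  drop <- slope[-length(slope)] - slope[-1]
  # ties (within float noise) break toward the smaller k
  cand <- which(drop >= max(drop) - 1e-12)
  curve$k[min(cand) + 1L]
}

#' Rescale an anchor set to a different input resolution
#'
#' @param anchors An `anchor_set`.
#' @param target_size Target input resolution in pixels.
#' @return A rescaled `anchor_set` (dimensions rounded to whole pixels).
#' @export
scale_anchors <- function(anchors, target_size) {
  stopifnot(inherits(anchors, "anchor_set"), target_size > 0)
  f <- target_size / attr(anchors, "input_size")
  out <- tibble(w = round(anchors$w * f), h = round(anchors$h * f))
  structure(out, class = class(anchors),
            k = attr(anchors, "k"), avg_iou = attr(anchors, "avg_iou"),
            input_size = as.integer(target_size))
}

#' Default flower/bud anchors at 608 px
#'
#' The shipped default anchor configuration for the citrus-flower detector:
#' five anchors obtained by IoU k-means on the original training corpus at a
#' 608 x 608 input.
#'
#' @return An `anchor_set` with `k = 5` (no Avg IoU recorded).
#' @export
citrus_anchors <- function() {
  out <- tibble(w = c(23, 42, 64, 104, 165), h = c(22, 39, 62, 84, 141))
  structure(out, class = c("anchor_set", class(out)),
            k = 5L, avg_iou = NA_real_, input_size = 608L)
}

#' Darknet-style anchor string
#'
#' @param anchors An `anchor_set`.
#' @return A string like `"23,22, 42,39, 64,62, 104,84, 165,141"`.
#' @export
anchor_string <- function(anchors) {
  paste(sprintf("%d,%d", round(anchors$w), round(anchors$h)), collapse = ", ")
}

#' @export
tidy.anchor_set <- function(x, ...) {
  tibble(anchor = seq_len(nrow(x)), w = x$w, h = x$h, area = x$w * x$h)
}

#' @export
glance.anchor_set <- function(x, ...) {
  tibble(k = attr(x, "k"), avg_iou = attr(x, "avg_iou"),
         input_size = attr(x, "input_size"))
}

#' @export
autoplot.avg_iou_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$avg_iou)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$k) +
    ggplot2::labs(x = "k", y = "Avg IoU")
}
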