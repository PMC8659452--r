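#' Construct a bounding-box tibble
#'
#' Boxes live in image pixel coordinates with the origin at the top-left
#' corner and half-open extents, so that `width = xmax - xmin`. A box set is
#' an ordinary tibble with columns `xmin`, `ymin`, `xmax`, `ymax`, `class`
#' and `confidence` (`NA` for ground truth), which keeps every downstream
#' verb (`dplyr`, joins, plotting) available.
#'
#' @param xmin,ymin,xmax,ymax Numeric vectors of box corners in pixels.
#' @param class Character vector of class labels (default `"flower"`).
#' @param confidence Optional numeric vector in `[0, 1]`; `NA` marks ground
#'   truth.
#' @return A tibble with one row per box.
#' @examples
#' boxes(10, 10, 30, 40, class = "bud")
#' @export
boxes <- function(xmin = numeric(), ymin = numeric(), xmax = numeric(),
                  ymax = numeric(), class = "flower", confidence = NA_real_) {
  out <- tibble(
    xmin = as.numeric(xmin), ymin = as.numeric(ymin),
    xmax = as.numeric(xmax), ymax = as.numeric(ymax),
    class = as.character(class), confidence = as.numeric(confidence)
  )
  validate_boxes(out)
  out
}

empty_boxes <- function() {
  tibble(xmin = numeric(), ymin = numeric(), xmax = numeric(),
         ymax = numeric(), class = character(), confidence = numeric())
}

validate_boxes <- function(b, where = "boxes") {
  stopifnot(is.data.frame(b))
  need <- c("xmin", "ymin", "xmax", "ymax", "class")
  miss <- setdiff(need, names(b))
  if (length(miss)) {
    abort(sprintf("%s is missing columns: %s", where, paste(miss, collapse = ", ")))
  }
  if (nrow(b)) {
    if (any(b$xmax <= b$xmin) || any(b$ymax <= b$ymin)) {
      abort(sprintf("%s must have strictly positive width and height", where))
    }
    if ("confidence" %in% names(b)) {
      cf <- b$confidence[!is.na(b$confidence)]
      if (length(cf) && (any(cf < 0) || any(cf > 1))) {
        abort(sprintf("%s confidence must lie in [0, 1]", where))
      }
    }
  }
  invisible(b)
}

#' Clip boxes to image bounds
#'
#' Boxes are intersected with `[0, width] x [0, height]`; boxes left with
#' non-positive extent are dropped.
#'
#' @param b A box tibble (see [boxes()]).
#' @param width,height Image dimensions in pixels.
#' @return The clipped box tibble.
#' @export
clip_boxes <- function(b, width, height) {
  if (!nrow(b)) return(b)
  b$xmin <- pmax(0, pmin(b$xmin, width))
  b$xmax <- pmax(0, pmin(b$xmax, width))
  b$ymin <- pmax(0, pmin(b$ymin, height))
  b$ymax <- pmax(0, pmin(b$ymax, height))
  b[b$xmax > b$xmin & b$ymax > b$ymin, , drop = FALSE]
}

#' Corner-coordinate intersection over union
#'
#' IoU between positioned boxes, vectorised over the first argument.
#'
#' @param a A box tibble (or single-row tibble).
#' @param b A single box given as a one-row tibble or a numeric vector
#'   `c(xmin, ymin, xmax, ymax)`.
#' @return Numeric vector of IoU values in `[0, 1]`.
#' @export
iou_boxes <- function(a, b) {
  if (is.numeric(b)) b <- tibble(xmin = b[1], ymin = b[2], xmax = b[3], ymax = b[4])
  ix <- pmax(0, pmin(a$xmax, b$xmax) - pmax(a$xmin, b$xmin))
  iy <- pmax(0, pmin(a$ymax, b$ymax) - pmax(a$ymin, b$ymin))
  inter <- ix * iy
  ua <- (a$xmax - a$xmin) * (a$ymax - a$ymin) +
    (b$xmax - b$xmin) * (b$ymax - b$ymin) - inter
  ifelse(ua > 0, inter / ua, 0)
}

#' Width-height intersection over union
#'
#' The anchor-clustering metric: two rectangles are placed with coincident
#' top-left corners and their IoU is computed from the dimensions alone,
#' `min(w1,w2) * min(h1,h2) / (w1*h1 + w2*h2 - min*min)`. Both arguments are
#' recycled; either can be a two-column matrix/data frame of `(w, h)` pairs.
#'
#' @param a,b `(w, h)` pairs: numeric length-2 vectors, or matrices/tibbles
#'   with columns `w` and `h`.
#' @return Numeric vector of IoU values in `(0, 1]`.
#' @examples
#' iou_wh(c(2, 2), c(4, 4)) # 0.25
#' @export
iou_wh <- function(a, b) {
  a <- wh_matrix(a); b <- wh_matrix(b)
  if (any(a <= 0) || any(b <= 0)) abort("iou_wh requires strictly positive dimensions")
  iw <- pmin(a[, 1], b[, 1])
  ih <- pmin(a[, 2], b[, 2])
  inter <- iw * ih
  inter / (a[, 1] * a[, 2] + b[, 1] * b[, 2] - inter)
}

wh_matrix <- function(x) {
  if (is.data.frame(x)) x <- cbind(x$w, x$h)
  if (!is.matrix(x)) x <- matrix(x, ncol = 2, byrow = FALSE,
                                 nrow = max(1L, length(x) %/% 2L))
  storage.mode(x) <- "double"
  x
}
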