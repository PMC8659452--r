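#' Create a labeled image
#'
#' A labeled image bundles a pixel array with its ground-truth boxes. Pixels
#' are stored as an `height x width x 3` numeric array of intensities in
#' `[0, 255]`; boxes are a tibble as produced by [boxes()], clipped to the
#' image bounds on construction.
#'
#' @param image_id Character identifier.
#' @param pixels `H x W x 3` numeric array in `[0, 255]`, or `NULL` to keep
#'   an annotation-only image (as when reading VOC XML without pixel data).
#' @param boxes A box tibble; clipped to the image on construction.
#' @param width,height Image size in pixels; inferred from `pixels` when
#'   supplied.
#' @return An object of class `labeled_image`.
#' @export
labeled_image <- function(image_id, pixels = NULL, boxes = empty_boxes(),
                          width = NULL, height = NULL) {
  if (!is.null(pixels)) {
    stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3)
    height <- dim(pixels)[1]
    width <- dim(pixels)[2]
  }
  if (is.null(width) || is.null(height)) {
    abort("width and height are required when no pixel array is given")
  }
  validate_boxes(boxes)
  structure(
    list(
      image_id = as.character(image_id),
      width = as.integer(width), height = as.integer(height),
      pixels = pixels,
      boxes = clip_boxes(boxes, width, height)
    ),
    class = "labeled_image"
  )
}

#' @export
print.labeled_image <- function(x, ...) {
  cat(sprintf(
    "<labeled_image> %s  %dx%d px, %d box(es)%s\n",
    x$image_id, x$width, x$height, nrow(x$boxes),
    if (is.null(x$pixels)) " [no pixels]" else ""
  ))
  if (nrow(x$boxes)) print(dplyr::count(x$boxes, .data$class))
  invisible(x)
}

#' @rdname labeled_image
#' @param x A `labeled_image`.
#' @export
is_labeled_image <- function(x) inherits(x, "labeled_image")

#' Plot a labeled image with its boxes
#'
#' @param object A `labeled_image`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.labeled_image <- function(object, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(object$pixels)) {
    ras <- grDevices::as.raster(pmax(pmin(object$pixels / 255, 1), 0))
    p <- p + ggplot2::annotation_raster(ras, xmin = 0, xmax = object$width,
                                        ymin = -object$height, ymax = 0)
  }
  if (nrow(object$boxes)) {
    b <- object$boxes
    p <- p + ggplot2::geom_rect(
      data = b,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -.data$ymax, ymax = -.data$ymin,
                   colour = .data$class),
      fill = NA, linewidth = 0.4
    )
  }
  p + ggplot2::coord_fixed(xlim = c(0, object$width),
                           ylim = c(-object$height, 0), expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, title = object$image_id)
}
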