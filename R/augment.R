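#' Cutout occlusion augmentation
#'
#' Zeroes (or fills) one axis-aligned square patch of the image, simulating
#' a flower hidden behind foliage. The square's centre is uniform over the
#' whole image, so the patch may be clipped at the borders. Ground-truth
#' boxes are deliberately left untouched — even a fully covered object stays
#' annotated, which is what teaches a detector to find partially hidden
#' flowers.
#'
#' @param image A [labeled_image()] with pixels.
#' @param size Side of the square in pixels (default 100).
#' @param fill Fill intensity in `[0, 255]` (default 0).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return The augmented `labeled_image` (boxes identical).
#' @export
cutout <- function(image, size = 100L, fill = 0, seed = NULL) {
  stopifnot(is_labeled_image(image), !is.null(image$pixels))
  if (size < 1) abort("cutout size must be >= 1")
  if (fill < 0 || fill > 255) abort("cutout fill must lie in [0, 255]")
  run <- function() {
    cx <- runif(1, 0, image$width)
    cy <- runif(1, 0, image$height)
    x0 <- max(1L, ceiling(cx - size / 2 + 0.5))
    x1 <- min(image$width, floor(cx + size / 2 + 0.5))
    y0 <- max(1L, ceiling(cy - size / 2 + 0.5))
    y1 <- min(image$height, floor(cy + size / 2 + 0.5))
    if (x0 <= x1 && y0 <= y1) image$pixels[y0:y1, x0:x1, ] <- fill
    image
  }
  if (is.null(seed)) run() else withr_seed(seed, run())
}

#' Mosaic four-image composition
#'
#' Composites four images into one canvas split at a random point: each
#' input is scale-jittered, shifted in hue/saturation/value, resampled into
#' its quadrant, and its boxes are transformed along, clipped to the
#' quadrant, and dropped when the visible area falls below 20% of the
#' original.
#'
#' @param images A list of exactly four [labeled_image()]s with pixels.
#' @param out_size Side of the square output canvas in pixels.
#' @param seed Integer seed.
#' @return A `labeled_image` of size `out_size x out_size`.
#' @export
mosaic <- function(images, out_size = 608L, seed = 0L) {
  if (length(images) != 4 || !all(map_lgl(images, is_labeled_image))) {
    abort("mosaic requires exactly 4 labeled images")
  }
  withr_seed(seed, {
    sx <- round(runif(1, 0.3, 0.7) * out_size)
    sy <- round(runif(1, 0.3, 0.7) * out_size)
    canvas <- array(114, dim = c(out_size, out_size, 3))
    quads <- list(
      c(0, 0, sx, sy), c(sx, 0, out_size - sx, sy),
      c(0, sy, sx, out_size - sy), c(sx, sy, out_size - sx, out_size - sy)
    )
    all_boxes <- list()
    for (i in 1:4) {
      q <- quads[[i]]
      qw <- q[3]; qh <- q[4]
      img <- images[[i]]
      # jitter only upward so the resampled crop always covers its quadrant
      f <- runif(1, 1, 1.3) * max(qw / img$width, qh / img$height)
      px <- hsv_jitter(img$pixels,
                       dh = runif(1, -0.03, 0.03),
                       fs = runif(1, 0.8, 1.2),
                       fv = runif(1, 0.8, 1.2))
      px <- resize_nearest(px, ceiling(img$height * f), ceiling(img$width * f))
      ph <- dim(px)[1]; pw <- dim(px)[2]
      crop_h <- min(qh, ph); crop_w <- min(qw, pw)
      canvas[(q[2] + 1):(q[2] + crop_h), (q[1] + 1):(q[1] + crop_w), ] <-
        px[seq_len(crop_h), seq_len(crop_w), , drop = FALSE]
      b <- img$boxes
      if (nrow(b)) {
        orig_area <- (b$xmax - b$xmin) * (b$ymax - b$ymin) * f^2
        b$xmin <- b$xmin * f + q[1]; b$xmax <- b$xmax * f + q[1]
        b$ymin <- b$ymin * f + q[2]; b$ymax <- b$ymax * f + q[2]
        b$xmin <- pmax(b$xmin, q[1]); b$ymin <- pmax(b$ymin, q[2])
        b$xmax <- pmin(b$xmax, q[1] + crop_w); b$ymax <- pmin(b$ymax, q[2] + crop_h)
        keep <- b$xmax > b$xmin & b$ymax > b$ymin
        b <- b[keep, , drop = FALSE]
        if (nrow(b)) {
          vis <- (b$xmax - b$xmin) * (b$ymax - b$ymin)
          b <- b[vis >= 0.2 * orig_area[keep], , drop = FALSE]
        }
        all_boxes[[i]] <- b
      }
    }
    bb <- bind_rows(all_boxes)
    if (!nrow(bb)) bb <- empty_boxes()
    labeled_image(paste0("mosaic_", images[[1]]$image_id), pixels = canvas,
                  boxes = bb)
  })
}

#' Declare an augmentation plan
#'
#' An ordered list of operations with parameter ranges; realised parameters
#' are drawn when the plan is applied. Supported ops: `mirror` (horizontal
#' flip), `flip` (vertical flip), `rotate` (`angle` range in degrees),
#' `crop` (`fraction` range of retained extent), `translate` (`dx`, `dy`
#' pixel ranges), `brightness` (`gain` range), `noise` (`sd` range), and
#' `cutout` (`size`, `fill`).
#'
#' @param ... Named op entries, e.g.
#'   `augment_plan(mirror = list(), brightness = list(gain = c(0.8, 1.2)))`.
#'   Each value is a (possibly empty) list of parameter ranges.
#' @param seed Integer seed used when applying the plan.
#' @return An `augment_plan` object.
#' @export
augment_plan <- function(..., seed = 0L) {
  ops <- list(...)
  known <- c("mirror", "flip", "rotate", "crop", "translate", "brightness",
             "noise", "cutout")
  bad <- setdiff(names(ops), known)
  if (length(bad)) abort(sprintf("unknown augmentation ops: %s", paste(bad, collapse = ", ")))
  structure(list(ops = ops, seed = as.integer(seed)), class = "augment_plan")
}

#' Apply an augmentation plan to an image
#'
#' Operations are applied in the declared order; geometric ops transform
#' boxes consistently with the pixels, photometric ops leave boxes
#' untouched. Intensities stay clamped to `[0, 255]`.
#'
#' @param image A [labeled_image()] with pixels.
#' @param plan An [augment_plan()].
#' @param seed Optional seed overriding the plan's.
#' @return The augmented `labeled_image`.
#' @export
apply_plan <- function(image, plan, seed = NULL) {
  stopifnot(is_labeled_image(image), inherits(plan, "augment_plan"))
  seed <- seed %||% plan$seed
  withr_seed(seed, {
    for (i in seq_along(plan$ops)) {
      image <- apply_op(image, names(plan$ops)[i], plan$ops[[i]])
    }
    image
  })
}

apply_op <- function(image, op, pars) {
  px <- image$pixels
  b <- image$boxes
  W <- image$width; H <- image$height
  switch(op,
    mirror = {
      px <- px[, W:1, , drop = FALSE]
      if (nrow(b)) {
        new_xmin <- W - b$xmax; b$xmax <- W - b$xmin; b$xmin <- new_xmin
      }
    },
    flip = {
      px <- px[H:1, , , drop = FALSE]
      if (nrow(b)) {
        new_ymin <- H - b$ymax; b$ymax <- H - b$ymin; b$ymin <- new_ymin
      }
    },
    rotate = {
      rng <- pars$angle %||% c(-15, 15)
      th <- runif(1, rng[1], rng[2]) * pi / 180
      px <- rotate_nearest(px, th)
      if (nrow(b)) b <- rotate_boxes(b, th, W, H)
    },
    crop = {
      rng <- pars$fraction %||% c(0.7, 0.95)
      f <- runif(1, rng[1], rng[2])
      cw <- max(2L, round(W * f)); ch <- max(2L, round(H * f))
      x0 <- floor(runif(1, 0, W - cw)); y0 <- floor(runif(1, 0, H - ch))
      px <- px[(y0 + 1):(y0 + ch), (x0 + 1):(x0 + cw), , drop = FALSE]
      if (nrow(b)) {
        b$xmin <- b$xmin - x0; b$xmax <- b$xmax - x0
        b$ymin <- b$ymin - y0; b$ymax <- b$ymax - y0
      }
      W <- cw; H <- ch
    },
    translate = {
      dxr <- pars$dx %||% c(-W / 8, W / 8)
      dyr <- pars$dy %||% c(-H / 8, H / 8)
      dx <- round(runif(1, dxr[1], dxr[2])); dy <- round(runif(1, dyr[1], dyr[2]))
      out <- array(114, dim = dim(px))
      xs <- intersect(seq_len(W), seq_len(W) + dx)
      ys <- intersect(seq_len(H), seq_len(H) + dy)
      out[ys, xs, ] <- px[ys - dy, xs - dx, , drop = FALSE]
      px <- out
      if (nrow(b)) {
        b$xmin <- b$xmin + dx; b$xmax <- b$xmax + dx
        b$ymin <- b$ymin + dy; b$ymax <- b$ymax + dy
      }
    },
    brightness = {
      g <- runif(1, (pars$gain %||% c(0.7, 1.3))[1], (pars$gain %||% c(0.7, 1.3))[2])
      px <- px * g
    },
    noise = {
      sdv <- runif(1, (pars$sd %||% c(0, 8))[1], (pars$sd %||% c(0, 8))[2])
      if (sdv > 0) px <- px + array(rnorm(length(px), 0, sdv), dim = dim(px))
    },
    cutout = {
      image <- cutout(image, size = pars$size %||% 100L, fill = pars$fill %||% 0)
      px <- image$pixels
    },
    abort(sprintf("unknown op '%s'", op))
  )
  px <- pmax(pmin(px, 255), 0)
  labeled_image(image$image_id, pixels = px, boxes = b)
}

#' Balance a dataset by over-augmenting a minority class
#'
#' Images that contain the minority class receive `expansion_factor` times
#' as many augmented copies as the others, raising the minority share of
#' object instances.
#'
#' @param dataset A list of [labeled_image()]s.
#' @param minority Minority class name (default `"bud"`).
#' @param expansion_factor Multiplier (>= 1) for minority-containing images.
#' @param plan An [augment_plan()] applied to every copy.
#' @param base_copies Augmented copies per non-minority image (default 1).
#' @return A list: the originals followed by augmented copies whose ids are
#'   tagged `_augN`.
#' @export
balance_classes <- function(dataset, minority = "bud", expansion_factor = 3L,
                            plan = augment_plan(mirror = list(),
                                                brightness = list()),
                            base_copies = 1L) {
  stopifnot(expansion_factor >= 1, base_copies >= 0)
  has_minority <- map_lgl(dataset, ~ minority %in% .x$boxes$class)
  if (length(dataset) && !any(has_minority)) {
    warn(sprintf("minority class '%s' absent from every image; returning originals", minority))
    return(dataset)
  }
  out <- dataset
  for (i in seq_along(dataset)) {
    n_copies <- base_copies * if (has_minority[i]) expansion_factor else 1L
    for (j in seq_len(n_copies)) {
      aug <- apply_plan(dataset[[i]], plan, seed = plan$seed + i * 1000L + j)
      aug$image_id <- sprintf("%s_aug%d", dataset[[i]]$image_id, j)
      out[[length(out) + 1]] <- aug
    }
  }
  out
}

#' @importFrom purrr map_lgl
NULL

# ---- low-level raster helpers ----

resize_nearest <- function(px, new_h, new_w) {
  h <- dim(px)[1]; w <- dim(px)[2]
  new_h <- max(1L, new_h); new_w <- max(1L, new_w)
  ri <- pmin(h, pmax(1L, ceiling(seq_len(new_h) * h / new_h)))
  ci <- pmin(w, pmax(1L, ceiling(seq_len(new_w) * w / new_w)))
  px[ri, ci, , drop = FALSE]
}

rotate_nearest <- function(px, theta, fill = 114) {
  h <- dim(px)[1]; w <- dim(px)[2]
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  xs <- outer(rep(1, h), seq_len(w)) - cx
  ys <- outer(seq_len(h), rep(1, w)) - cy
  # inverse map: source = R(-theta) * dest
  sx <- round(cx + xs * cos(theta) + ys * sin(theta))
  sy <- round(cy - xs * sin(theta) + ys * cos(theta))
  valid <- sx >= 1 & sx <= w & sy >= 1 & sy <= h
  out <- array(fill, dim = dim(px))
  src_idx <- cbind(sy[valid], sx[valid])
  dst_idx <- which(valid, arr.ind = TRUE)
  for (ch in 1:3) {
    plane_src <- px[, , ch]
    plane <- matrix(fill, h, w)
    plane[dst_idx] <- plane_src[src_idx]
    out[, , ch] <- plane
  }
  out
}

rotate_boxes <- function(b, theta, W, H) {
  cx <- W / 2; cy <- H / 2
  rot <- function(x, y) {
    # forward rotation of annotation points (matches the raster's inverse map)
    list(x = cx + (x - cx) * cos(theta) - (y - cy) * sin(theta),
         y = cy + (x - cx) * sin(theta) + (y - cy) * cos(theta))
  }
  for (i in seq_len(nrow(b))) {
    xs <- c(b$xmin[i], b$xmax[i], b$xmin[i], b$xmax[i])
    ys <- c(b$ymin[i], b$ymin[i], b$ymax[i], b$ymax[i])
    p <- rot(xs, ys)
    b$xmin[i] <- min(p$x); b$xmax[i] <- max(p$x)
    b$ymin[i] <- min(p$y); b$ymax[i] <- max(p$y)
  }
  b
}

hsv_jitter <- function(px, dh = 0, fs = 1, fv = 1) {
  h <- dim(px)[1]; w <- dim(px)[2]
  m <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  m <- pmax(pmin(m, 255), 0)
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  hsv[1, ] <- (hsv[1, ] + dh) %% 1
  hsv[2, ] <- pmax(pmin(hsv[2, ] * fs, 1), 0)
  hsv[3, ] <- pmax(pmin(hsv[3, ] * fv, 1), 0)
  rgb <- hsv_to_rgb(hsv) * 255
  array(c(rgb[1, ], rgb[2, ], rgb[3, ]), dim = c(h, w, 3))
}

# vectorised HSV -> RGB (all values in [0, 1])
hsv_to_rgb <- function(hsv) {
  h6 <- hsv[1, ] * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  v <- hsv[3, ]; s <- hsv[2, ]
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  rbind(r, g, b)
}
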