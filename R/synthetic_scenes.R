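#' Configure a synthetic orchard scene
#'
#' The generator emulates the imaging conditions a flower detector faces in
#' an orchard: a green, optionally cluttered canopy background; bright
#' multi-lobed flower blobs; small compact bud blobs; partial occlusion by
#' foliage; and varying density and luminosity. Every rendered object gets
#' an exact ground-truth box, which makes all downstream modules testable
#' without field imagery.
#'
#' @param width,height Image size in pixels.
#' @param n_flowers,n_buds Object counts.
#' @param flower_size_range,bud_size_range Length-2 pixel ranges for the
#'   blob diameters.
#' @param occlusion_prob Per-object probability of drawing a foliage
#'   occluder over up to half of the blob (the box keeps the full extent).
#' @param background `"simple"` (flat canopy) or `"cluttered"` (leafy).
#' @param luminosity Multiplicative intensity scale in `(0, 1]`.
#' @param seed Integer seed; scenes are bit-reproducible per seed.
#' @param density Optional preset overriding the counts: `"sparse"`
#'   (<= 10 boxes), `"medium"` (11-30) or `"dense"` (> 30).
#' @return A `scene_config` list.
#' @export
scene_config <- function(width = 608, height = 608,
                         n_flowers = 8, n_buds = 4,
                         flower_size_range = c(40, 110),
                         bud_size_range = c(14, 34),
                         occlusion_prob = 0.2,
                         background = c("cluttered", "simple"),
                         luminosity = 1, seed = 0L,
                         density = NULL) {
  background <- match.arg(background)
  if (!is.null(density)) {
    density <- match.arg(density, c("sparse", "medium", "dense"))
    counts <- switch(density,
      sparse = c(4L, 2L),
      medium = c(14L, 7L),
      dense = c(26L, 12L)
    )
    n_flowers <- counts[1]
    n_buds <- counts[2]
  }
  stopifnot(
    width >= 32, height >= 32, n_flowers >= 0, n_buds >= 0,
    all(flower_size_range > 0), all(bud_size_range > 0),
    occlusion_prob >= 0, occlusion_prob <= 1,
    luminosity > 0, luminosity <= 1
  )
  structure(
    list(width = as.integer(width), height = as.integer(height),
         n_flowers = as.integer(n_flowers), n_buds = as.integer(n_buds),
         flower_size_range = flower_size_range, bud_size_range = bud_size_range,
         occlusion_prob = occlusion_prob, background = background,
         luminosity = luminosity, seed = as.integer(seed)),
    class = "scene_config"
  )
}

#' Generate a synthetic orchard scene
#'
#' Flowers render as five-petal white ellipse rosettes with a yellow centre,
#' buds as single small pale ellipses, both over a green canopy. The
#' ground-truth box of each object is the exact pixel extent of its rendered
#' blob (before any occluder), so boxes tightly bound the blobs; occluded
#' objects stay annotated.
#'
#' @param config A [scene_config()].
#' @return A [labeled_image()] with pixels and ground-truth boxes.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  withr_seed(config$seed, render_scene(config))
}

render_scene <- function(config) {
  w <- config$width; h <- config$height
  img <- render_background(w, h, config$background)

  n_total <- config$n_flowers + config$n_buds
  kinds <- c(rep("flower", config$n_flowers), rep("bud", config$n_buds))
  placed <- empty_boxes()
  for (i in seq_len(n_total)) {
    kind <- kinds[i]
    rng <- if (kind == "flower") config$flower_size_range else config$bud_size_range
    ok <- FALSE
    for (attempt in 1:40) {
      size <- runif(1, rng[1], rng[2])
      cx <- runif(1, size / 2 + 1, w - size / 2 - 1)
      cy <- runif(1, size / 2 + 1, h - size / 2 - 1)
      cand <- tibble(xmin = cx - size / 2, ymin = cy - size / 2,
                     xmax = cx + size / 2, ymax = cy + size / 2)
      if (!nrow(placed) || all(iou_boxes(placed, c(cand$xmin, cand$ymin, cand$xmax, cand$ymax)) < 0.45)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort(sprintf(
        "could not place all objects: %d of %d placed (image too crowded)",
        nrow(placed), n_total
      ))
    }
    blob <- if (kind == "flower") {
      draw_flower(img, cx, cy, size)
    } else {
      draw_bud(img, cx, cy, size)
    }
    img <- blob$img
    if (runif(1) < config$occlusion_prob) {
      img <- draw_occluder(img, blob$box)
    }
    placed <- bind_rows(placed, tibble(
      xmin = blob$box[1], ymin = blob$box[2],
      xmax = blob$box[3], ymax = blob$box[4],
      class = kind, confidence = NA_real_
    ))
  }
  img <- pmax(pmin(img * config$luminosity, 255), 0)
  labeled_image(sprintf("scene_%08d", config$seed), pixels = img, boxes = placed)
}

render_background <- function(w, h, background) {
  img <- array(0, dim = c(h, w, 3))
  base <- c(58, 108, 48)
  noise <- matrix(rnorm(h * w, 0, 6), h, w)
  for (ch in 1:3) img[, , ch] <- base[ch] + noise
  if (background == "cluttered") {
    n_leaves <- max(12L, (w * h) %/% 12000L)
    for (i in seq_len(n_leaves)) {
      cx <- runif(1, 1, w); cy <- runif(1, 1, h)
      a <- runif(1, w / 30, w / 8); b <- a * runif(1, 0.3, 0.7)
      th <- runif(1, 0, pi)
      shade <- runif(1, 0.55, 1.5)
      col <- pmin(base * shade + rnorm(3, 0, 4), 255)
      img <- paint_ellipse(img, cx, cy, a, b, th, col)
    }
  }
  pmax(pmin(img, 255), 0)
}

# paint an ellipse; returns the image (and extent when asked)
paint_ellipse <- function(img, cx, cy, a, b, theta, col, return_extent = FALSE) {
  h <- dim(img)[1]; w <- dim(img)[2]
  r <- max(a, b)
  x0 <- max(1L, floor(cx - r)); x1 <- min(w, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(h, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) {
    return(if (return_extent) list(img = img, extent = NULL) else img)
  }
  xs <- x0:x1; ys <- y0:y1
  # pixel centres at (x - 0.5, y - 0.5)
  dx <- outer(rep(1, length(ys)), xs - 0.5 - cx)
  dy <- outer(ys - 0.5 - cy, rep(1, length(xs)))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  mask <- (u / a)^2 + (v / b)^2 <= 1
  if (any(mask)) {
    for (ch in 1:3) {
      slab <- img[ys, xs, ch]
      slab[mask] <- col[ch]
      img[ys, xs, ch] <- slab
    }
  }
  if (return_extent) {
    if (!any(mask)) return(list(img = img, extent = NULL))
    idx <- which(mask, arr.ind = TRUE)
    list(img = img, extent = c(
      xmin = xs[min(idx[, 2])] - 1, ymin = ys[min(idx[, 1])] - 1,
      xmax = xs[max(idx[, 2])], ymax = ys[max(idx[, 1])]
    ))
  } else {
    img
  }
}

draw_flower <- function(img, cx, cy, size) {
  n_petals <- 5L
  petal_len <- size / 2 * 0.92
  petal_wid <- size / 2 * 0.42
  phase <- runif(1, 0, 2 * pi)
  extent <- NULL
  for (p in seq_len(n_petals)) {
    th <- phase + (p - 1) * 2 * pi / n_petals
    pcx <- cx + cos(th) * petal_len * 0.55
    pcy <- cy + sin(th) * petal_len * 0.55
    col <- c(1, 1, 1) * runif(1, 232, 252)
    res <- paint_ellipse(img, pcx, pcy, petal_len * 0.5, petal_wid * 0.5, th,
                         col, return_extent = TRUE)
    img <- res$img
    extent <- merge_extent(extent, res$extent)
  }
  res <- paint_ellipse(img, cx, cy, size * 0.13, size * 0.13, 0,
                       c(235, 205, 70), return_extent = TRUE)
  img <- res$img
  extent <- merge_extent(extent, res$extent)
  list(img = img, box = extent)
}

draw_bud <- function(img, cx, cy, size) {
  th <- runif(1, 0, pi)
  col <- c(228, 238, 205) + rnorm(3, 0, 4)
  res <- paint_ellipse(img, cx, cy, size / 2, size / 2 * runif(1, 0.65, 0.9),
                       th, col, return_extent = TRUE)
  list(img = res$img, box = res$extent)
}

draw_occluder <- function(img, box) {
  bw <- box[3] - box[1]; bh <- box[4] - box[2]
  # leaf-coloured ellipse over up to ~50% of the blob
  cx <- runif(1, box[1] + bw * 0.2, box[1] + bw * 0.8)
  cy <- runif(1, box[2] + bh * 0.2, box[2] + bh * 0.8)
  a <- bw / 2 * runif(1, 0.4, 0.7)
  b <- bh / 2 * runif(1, 0.4, 0.7)
  col <- c(52, 98, 44) + rnorm(3, 0, 3)
  paint_ellipse(img, cx, cy, a, b, runif(1, 0, pi), col)
}

merge_extent <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  c(xmin = min(a[1], b[1]), ymin = min(a[2], b[2]),
    xmax = max(a[3], b[3]), ymax = max(a[4], b[4]))
}

#' Generate a width-height box population with planted clusters
#'
#' Draws `points_per_cluster` boxes around each `(w, h)` centre with
#' isotropic Gaussian jitter truncated at 1 px — a controlled fixture for
#' anchor clustering.
#'
#' @param cluster_centers List (or 2-column matrix) of `(w, h)` centres.
#' @param points_per_cluster Points per centre.
#' @param jitter_sd Gaussian jitter standard deviation in pixels.
#' @param seed Integer seed.
#' @return A tibble with columns `w`, `h` and `cluster`.
#' @export
generate_box_population <- function(cluster_centers, points_per_cluster = 50,
                                    jitter_sd = 2, seed = 0L) {
  if (is.matrix(cluster_centers)) {
    cluster_centers <- split(cluster_centers, row(cluster_centers)[, 1])
  }
  stopifnot(points_per_cluster >= 1, jitter_sd >= 0)
  withr_seed(seed, {
    pop <- imap(cluster_centers, function(ctr, i) {
      stopifnot(length(ctr) == 2, all(ctr > 0))
      tibble(
        w = pmax(1, ctr[1] + rnorm(points_per_cluster, 0, jitter_sd)),
        h = pmax(1, ctr[2] + rnorm(points_per_cluster, 0, jitter_sd)),
        cluster = as.integer(i)
      )
    })
    bind_rows(pop)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_images` PNG scenes with VOC XML annotations and a manifest of
#' per-image seeds, then returns a 7:2:1 [split_dataset()] over the image
#' ids. Per-image seeds are derived deterministically from the config seed,
#' and per-image object counts jitter around the configured counts.
#'
#' @param config A [scene_config()]; its seed is the master seed.
#' @param n_images Number of images.
#' @param out_dir Output directory (created if needed).
#' @param ratios Split ratios (default 7:2:1).
#' @return A `dataset_split`; the images are in `out_dir/images`, the
#'   annotations in `out_dir/annotations`.
#' @export
generate_dataset <- function(config, n_images, out_dir,
                             ratios = c(0.7, 0.2, 0.1)) {
  stopifnot(inherits(config, "scene_config"), n_images >= 1)
  img_dir <- file.path(out_dir, "images")
  ann_dir <- file.path(out_dir, "annotations")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(ann_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- (config$seed + seq_len(n_images) * 131071L) %% 2147483647L
  jitters <- withr_seed(config$seed, runif(n_images, 0.7, 1.3))
  ids <- character(n_images)
  for (i in seq_len(n_images)) {
    cfg_i <- config
    cfg_i$seed <- seeds[i]
    cfg_i$n_flowers <- as.integer(round(config$n_flowers * jitters[i]))
    cfg_i$n_buds <- as.integer(round(config$n_buds * jitters[i]))
    scene <- generate_scene(cfg_i)
    scene$image_id <- sprintf("img_%04d", i)
    ids[i] <- scene$image_id
    png::writePNG(scene$pixels / 255, file.path(img_dir, paste0(scene$image_id, ".png")))
    write_voc_xml(scene, file.path(ann_dir, paste0(scene$image_id, ".xml")))
  }
  utils::write.csv(
    data.frame(image_id = ids, seed = seeds),
    file.path(out_dir, "manifest.csv"),
    row.names = FALSE
  )
  split <- split_dataset(ids, ratios, seed = config$seed)
  write_split_manifest(split, out_dir)
  split
}

#' Read a generated image and its annotation back
#'
#' @param out_dir Dataset directory produced by [generate_dataset()].
#' @param image_id Image id.
#' @return A [labeled_image()] with pixels.
#' @export
read_dataset_image <- function(out_dir, image_id) {
  ann <- read_voc_xml(file.path(out_dir, "annotations", paste0(image_id, ".xml")))
  px <- png::readPNG(file.path(out_dir, "images", paste0(image_id, ".png"))) * 255
  labeled_image(image_id, pixels = px, boxes = ann$boxes)
}
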