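#' Read a Pascal VOC XML annotation
#'
#' Parses LabelImg-style VOC XML. VOC stores 1-based inclusive pixel
#' coordinates; they are converted to the package's 0-based half-open
#' convention (`xmin0 = xmin - 1`, `xmax0 = xmax`) so that
#' `width = xmax - xmin`. Boxes are clipped to the image bounds; unknown
#' class names are kept verbatim.
#'
#' @param path Path to the XML file.
#' @return A [labeled_image()] without pixel data.
#' @export
read_voc_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(sprintf("malformed VOC XML in '%s': %s", path, conditionMessage(e)))
  })
  size <- xml2::xml_find_first(doc, ".//size")
  if (inherits(size, "xml_missing")) {
    abort(sprintf("VOC XML '%s' has no <size> element", path))
  }
  width <- as.numeric(xml2::xml_text(xml2::xml_find_first(size, "./width")))
  height <- as.numeric(xml2::xml_text(xml2::xml_find_first(size, "./height")))
  if (!isTRUE(width > 0) || !isTRUE(height > 0)) {
    abort(sprintf("VOC XML '%s' has an invalid <size> element", path))
  }
  fname <- xml2::xml_text(xml2::xml_find_first(doc, ".//filename"))
  if (is.na(fname) || !nzchar(fname)) {
    fname <- sub("\\.xml$", "", basename(path))
  }
  objs <- xml2::xml_find_all(doc, ".//object")
  if (length(objs)) {
    b <- map(objs, function(o) {
      bb <- xml2::xml_find_first(o, "./bndbox")
      num <- function(tag) as.numeric(xml2::xml_text(xml2::xml_find_first(bb, paste0("./", tag))))
      tibble(
        xmin = num("xmin") - 1, ymin = num("ymin") - 1,
        xmax = num("xmax"), ymax = num("ymax"),
        class = xml2::xml_text(xml2::xml_find_first(o, "./name")),
        confidence = NA_real_
      )
    }) %>% bind_rows()
  } else {
    b <- empty_boxes()
  }
  labeled_image(sub("\\.(png|jpg|jpeg)$", "", fname, ignore.case = TRUE),
                boxes = b, width = width, height = height)
}

#' Write a Pascal VOC XML annotation
#'
#' Inverse of [read_voc_xml()]: coordinates are serialised back to 1-based
#' inclusive integers, so that integer boxes round-trip exactly.
#'
#' @param image A [labeled_image()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_voc_xml <- function(image, path) {
  stopifnot(is_labeled_image(image))
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "images")
  xml2::xml_add_child(doc, "filename", paste0(image$image_id, ".png"))
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(image$width))
  xml2::xml_add_child(size, "height", as.character(image$height))
  xml2::xml_add_child(size, "depth", "3")
  xml2::xml_add_child(doc, "segmented", "0")
  if (nrow(image$boxes)) {
    for (i in seq_len(nrow(image$boxes))) {
      b <- image$boxes[i, ]
      obj <- xml2::xml_add_child(doc, "object")
      xml2::xml_add_child(obj, "name", b$class)
      xml2::xml_add_child(obj, "pose", "Unspecified")
      xml2::xml_add_child(obj, "truncated", "0")
      xml2::xml_add_child(obj, "difficult", "0")
      bb <- xml2::xml_add_child(obj, "bndbox")
      xml2::xml_add_child(bb, "xmin", as.character(round(b$xmin) + 1))
      xml2::xml_add_child(bb, "ymin", as.character(round(b$ymin) + 1))
      xml2::xml_add_child(bb, "xmax", as.character(round(b$xmax)))
      xml2::xml_add_child(bb, "ymax", as.character(round(b$ymax)))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read YOLO txt annotations
#'
#' Each line is `class_index cx cy w h` with values normalised to `[0, 1]`;
#' they are converted to absolute corner coordinates via
#' `xmin = (cx - w/2) * width`, etc.
#'
#' @param path Path to the txt file.
#' @param width,height Image dimensions in pixels.
#' @param class_names Ordered character vector mapping 0-based class indices
#'   to labels.
#' @return A box tibble.
#' @export
read_yolo_txt <- function(path, width, height, class_names = c("flower", "bud")) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_boxes())
  fields <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  if (ncol(fields) != 5) abort(sprintf("'%s': expected 5 fields per line", path))
  idx <- fields[, 1]
  if (any(idx != floor(idx)) || any(idx < 0) || any(idx >= length(class_names))) {
    abort(sprintf("'%s': class index outside class_names", path))
  }
  vals <- fields[, 2:5, drop = FALSE]
  if (any(vals < 0) || any(vals > 1)) {
    abort(sprintf("'%s': normalised values must lie in [0, 1]", path))
  }
  tibble(
    xmin = (fields[, 2] - fields[, 4] / 2) * width,
    ymin = (fields[, 3] - fields[, 5] / 2) * height,
    xmax = (fields[, 2] + fields[, 4] / 2) * width,
    ymax = (fields[, 3] + fields[, 5] / 2) * height,
    class = class_names[idx + 1],
    confidence = NA_real_
  )
}

#' Write YOLO txt annotations
#'
#' @param b A box tibble.
#' @param path Output file path.
#' @inheritParams read_yolo_txt
#' @return `path`, invisibly.
#' @export
write_yolo_txt <- function(b, path, width, height, class_names = c("flower", "bud")) {
  validate_boxes(b)
  idx <- match(b$class, class_names)
  if (nrow(b) && anyNA(idx)) {
    abort(sprintf("classes not in class_names: %s",
                  paste(unique(b$class[is.na(idx)]), collapse = ", ")))
  }
  lines <- sprintf(
    "%d %.8f %.8f %.8f %.8f",
    idx - 1L,
    (b$xmin + b$xmax) / 2 / width, (b$ymin + b$ymax) / 2 / height,
    (b$xmax - b$xmin) / width, (b$ymax - b$ymin) / height
  )
  writeLines(lines, path)
  invisible(path)
}

#' Split image ids into train / validation / test sets
#'
#' Ids are shuffled with the given seed and partitioned. Bucket sizes are
#' `floor(n * ratio)` with leftover items given to train first, then
#' validation — deterministic and exhaustive.
#'
#' @param image_ids Character vector of ids.
#' @param ratios Length-3 numeric vector summing to 1 (default `c(.7, .2, .1)`).
#' @param seed Integer seed for the shuffle.
#' @return A `dataset_split`: list with `train`, `val`, `test`, `ratios`, `seed`.
#' @examples
#' split_dataset(as.character(1:10), seed = 1)
#' @export
split_dataset <- function(image_ids, ratios = c(0.7, 0.2, 0.1), seed = 0L) {
  stopifnot(length(ratios) == 3)
  if (abs(sum(ratios) - 1) > 1e-9) abort("ratios must sum to 1")
  image_ids <- as.character(image_ids)
  n <- length(image_ids)
  shuffled <- if (n) withr_seed(seed, sample(image_ids)) else character()
  sizes <- floor(n * ratios)
  for (i in seq_len(n - sum(sizes))) {
    j <- if (i == 1) 1L else 2L  # leftovers: train first, then val
    sizes[j] <- sizes[j] + 1L
  }
  structure(
    list(
      train = shuffled[seq_len(sizes[1])],
      val = shuffled[seq_len(sizes[2]) + sizes[1]],
      test = shuffled[seq_len(sizes[3]) + sizes[1] + sizes[2]],
      ratios = ratios, seed = as.integer(seed)
    ),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train %d / val %d / test %d (seed %d)\n",
              length(x$train), length(x$val), length(x$test), x$seed))
  invisible(x)
}

#' Write / read a split as plain-text manifests
#'
#' One file per bucket (`train.txt`, `val.txt`, `test.txt`), one id per line.
#'
#' @param split A `dataset_split`.
#' @param dir Directory for the manifest files.
#' @return `write_split_manifest()` returns `dir`; `read_split_manifest()`
#'   returns a `dataset_split` with unknown ratios/seed metadata preserved
#'   only if present.
#' @export
write_split_manifest <- function(split, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (part in c("train", "val", "test")) {
    writeLines(split[[part]], file.path(dir, paste0(part, ".txt")))
  }
  invisible(dir)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(dir) {
  parts <- lapply(c(train = "train", val = "val", test = "test"), function(p) {
    f <- file.path(dir, paste0(p, ".txt"))
    if (file.exists(f)) readLines(f, warn = FALSE) else character()
  })
  structure(c(parts, list(ratios = NA, seed = NA_integer_)), class = "dataset_split")
}

# run expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
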