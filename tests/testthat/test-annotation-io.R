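test_that("VOC XML parses LabelImg fixtures field by field", {
  f <- withr::local_tempfile(fileext = ".xml")
  write_voc_fixture(f)
  im <- read_voc_xml(f)
  expect_s3_class(im, "labeled_image")
  expect_equal(im$width, 100L)
  expect_equal(im$height, 200L)
  expect_equal(nrow(im$boxes), 1L)
  # 1-based inclusive VOC coords become 0-based half-open internally
  expect_equal(im$boxes$xmin, 9)
  expect_equal(im$boxes$ymin, 9)
  expect_equal(im$boxes$xmax, 30)
  expect_equal(im$boxes$ymax, 40)
  expect_equal(im$boxes$class, "bud")
  expect_true(is.na(im$boxes$confidence))
})

test_that("VOC XML with no objects yields an empty box list", {
  f <- withr::local_tempfile(fileext = ".xml")
  write_voc_fixture(f, objects = FALSE)
  expect_equal(nrow(read_voc_xml(f)$boxes), 0L)
})

test_that("VOC errors name the file and the missing element", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines("<annotation><object></object>", f)
  expect_error(read_voc_xml(f), "malformed")
  writeLines("<annotation><object/></annotation>", f)
  expect_error(read_voc_xml(f), "<size>")
})

test_that("VOC write/read round-trips integer boxes exactly", {
  im <- labeled_image(
    "rt", width = 320, height = 240,
    boxes = boxes(c(5, 100), c(7, 30), c(55, 319), c(90, 239),
                  class = c("flower", "bud"))
  )
  f <- withr::local_tempfile(fileext = ".xml")
  write_voc_xml(im, f)
  txt <- paste(readLines(f), collapse = "")
  expect_match(txt, "flower")
  expect_match(txt, "bud")
  back <- read_voc_xml(f)
  expect_equal(back$boxes[, 1:5], im$boxes[, 1:5])
  # empty annotation writes no <object> elements
  f2 <- withr::local_tempfile(fileext = ".xml")
  write_voc_xml(labeled_image("e", width = 10, height = 10), f2)
  expect_false(grepl("<object>", paste(readLines(f2), collapse = "")))
})

test_that("YOLO txt converts normalised centre-size to corners", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("0 0.5 0.5 1.0 1.0", f)
  b <- read_yolo_txt(f, 608, 608)
  expect_equal(unlist(b[1, 1:4], use.names = FALSE), c(0, 0, 608, 608))
  expect_equal(b$class, "flower")
  # closed-form oracle: corners = (cx -/+ w/2) * W, (cy -/+ h/2) * H
  writeLines("1 0.25 0.25 0.1 0.2", f)
  b2 <- read_yolo_txt(f, 100, 200)
  expect_equal(unlist(b2[1, 1:4], use.names = FALSE), c(20, 30, 30, 70))
  expect_equal(b2$class, "bud")
})

test_that("YOLO txt validates class indices and value ranges", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("7 0.5 0.5 0.2 0.2", f)
  expect_error(read_yolo_txt(f, 100, 100), "class index")
  writeLines("0 1.5 0.5 0.2 0.2", f)
  expect_error(read_yolo_txt(f, 100, 100), "\\[0, 1\\]")
})

test_that("YOLO round-trip is lossless within half a pixel", {
  set.seed(1)
  for (rep in 1:5) {
    b <- boxes(
      xmin = runif(6, 0, 300), ymin = runif(6, 0, 200),
      xmax = runif(6, 301, 640), ymax = runif(6, 201, 480),
      class = sample(c("flower", "bud"), 6, TRUE)
    )
    f <- withr::local_tempfile(fileext = ".txt")
    write_yolo_txt(b, f, 640, 480)
    back <- read_yolo_txt(f, 640, 480)
    expect_lt(max(abs(as.matrix(back[, 1:4]) - as.matrix(b[, 1:4]))), 0.5)
  }
})

test_that("dataset split honours the 7:2:1 ratio with floor-then-distribute", {
  s <- split_dataset(as.character(1:10), seed = 4)
  expect_equal(lengths(s[c("train", "val", "test")]),
               c(train = 7L, val = 2L, test = 1L))
  big <- split_dataset(as.character(1:9610), seed = 0)
  expect_equal(lengths(big[c("train", "val", "test")]),
               c(train = 6727L, val = 1922L, test = 961L))
})

test_that("dataset split is deterministic, disjoint and exhaustive", {
  expect_identical(split_dataset(letters, seed = 9), split_dataset(letters, seed = 9))
  set.seed(2)
  for (rep in 1:20) {
    n <- sample(0:200, 1)
    ids <- as.character(seq_len(n))
    s <- split_dataset(ids, seed = sample.int(1e6, 1))
    all_ids <- c(s$train, s$val, s$test)
    expect_equal(sort(all_ids), sort(ids))
    expect_equal(anyDuplicated(all_ids), 0L)
    # realised sizes within one item of the request
    expect_true(all(abs(lengths(s[c("train", "val", "test")]) -
                          n * c(0.7, 0.2, 0.1)) <= 1))
  }
})

test_that("split manifests round-trip through plain text", {
  s <- split_dataset(as.character(1:10), seed = 1)
  d <- withr::local_tempdir()
  write_split_manifest(s, d)
  back <- read_split_manifest(d)
  expect_equal(back$train, s$train)
  expect_equal(back$test, s$test)
})
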