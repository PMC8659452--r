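test_that("cutout zeroes a 100x100 square and leaves annotations alone", {
  im <- flat_image(255, 608,
                   boxes = boxes(c(10, 300), c(20, 310), c(60, 380), c(80, 400),
                                 class = c("flower", "bud")))
  # seed chosen so the square lands fully interior
  out <- cutout(im, size = 100, fill = 0, seed = 1)
  zeros_per_channel <- sapply(1:3, function(ch) sum(out$pixels[, , ch] == 0))
  expect_equal(unname(zeros_per_channel), rep(10000, 3))
  expect_identical(out$boxes, im$boxes)

  one <- cutout(flat_image(200, 64), size = 1, seed = 2)
  expect_equal(sum(one$pixels != 200), 3)  # one pixel per channel
  expect_error(cutout(im, size = 0), ">= 1")
  expect_error(cutout(im, fill = 300), "\\[0, 255\\]")
})

test_that("cutout clips at borders instead of failing", {
  im <- flat_image(255, 64)
  out <- cutout(im, size = 200, fill = 7, seed = 3)  # covers everything
  expect_true(all(out$pixels == 7))
})

test_that("mosaic composes four images deterministically", {
  zero <- labeled_image("z", pixels = array(0, dim = c(64, 64, 3)))
  mz <- mosaic(list(zero, zero, zero, zero), out_size = 128, seed = 5)
  expect_true(all(mz$pixels == 0))
  expect_equal(dim(mz$pixels), c(128, 128, 3))

  scenes <- lapply(1:4, function(i) small_scene(seed = 40 + i))
  m1 <- mosaic(scenes, out_size = 256, seed = 11)
  m2 <- mosaic(scenes, out_size = 256, seed = 11)
  expect_identical(m1$pixels, m2$pixels)
  expect_identical(m1$boxes, m2$boxes)
  expect_error(mosaic(scenes[1:3], 256), "exactly 4")
})

test_that("mosaic boxes stay inside their quadrants", {
  one_box <- function(seed) {
    labeled_image(paste0("b", seed),
                  pixels = array(100, dim = c(64, 64, 3)),
                  boxes = boxes(20, 20, 44, 44))
  }
  for (seed in c(1, 9, 23)) {
    m <- mosaic(lapply(1:4, one_box), out_size = 128, seed = seed)
    expect_lte(nrow(m$boxes), 4)
    expect_true(all(m$boxes$xmin >= 0 & m$boxes$xmax <= 128))
    expect_true(all(m$boxes$ymin >= 0 & m$boxes$ymax <= 128))
  }
})

test_that("plan ops transform boxes consistently with pixels", {
  im <- small_scene(seed = 12)
  # double mirror is the identity
  twice <- apply_plan(im, augment_plan(mirror = list(), seed = 1)) |>
    apply_plan(augment_plan(mirror = list(), seed = 1))
  expect_equal(twice$pixels, im$pixels)
  expect_equal(twice$boxes, im$boxes)

  # fixed translation shifts every box by (dx, dy), then clips
  shifted <- apply_plan(im, augment_plan(
    translate = list(dx = c(10, 10), dy = c(-6, -6)), seed = 2
  ))
  expected <- im$boxes
  expected$xmin <- expected$xmin + 10; expected$xmax <- expected$xmax + 10
  expected$ymin <- expected$ymin - 6; expected$ymax <- expected$ymax - 6
  expected <- clip_boxes(expected, im$width, im$height)
  expect_equal(as.data.frame(shifted$boxes), as.data.frame(expected))

  # photometric identity
  ident <- apply_plan(im, augment_plan(brightness = list(gain = c(1, 1)),
                                       noise = list(sd = c(0, 0)), seed = 3))
  expect_equal(ident$pixels, im$pixels)
  expect_equal(ident$boxes, im$boxes)
})

test_that("geometric ops keep raster content and boxes aligned", {
  # a solid rectangle: its pixel extent must match the transformed box
  px <- array(0, dim = c(80, 80, 3))
  px[21:40, 11:30, ] <- 255   # rows 21..40 (y), cols 11..30 (x)
  im <- labeled_image("rect", pixels = px, boxes = boxes(10, 20, 30, 40))
  for (op in c("mirror", "flip")) {
    plan <- do.call(augment_plan, setNames(list(list()), op))
    out <- apply_plan(im, plan)
    hot <- which(out$pixels[, , 1] == 255, arr.ind = TRUE)
    b <- out$boxes
    expect_lte(abs(min(hot[, 2]) - 1 - b$xmin), 1)
    expect_lte(abs(max(hot[, 2]) - b$xmax), 1)
    expect_lte(abs(min(hot[, 1]) - 1 - b$ymin), 1)
    expect_lte(abs(max(hot[, 1]) - b$ymax), 1)
  }
})

test_that("pixel intensities and boxes stay within bounds after any plan", {
  im <- small_scene(seed = 33)
  plan <- augment_plan(rotate = list(angle = c(-30, 30)),
                       crop = list(fraction = c(0.6, 0.9)),
                       brightness = list(gain = c(0.5, 1.6)),
                       noise = list(sd = c(5, 10)),
                       cutout = list(size = 40), seed = 17)
  out <- apply_plan(im, plan)
  expect_true(all(out$pixels >= 0 & out$pixels <= 255))
  if (nrow(out$boxes)) {
    expect_true(all(out$boxes$xmin >= 0 & out$boxes$xmax <= out$width))
    expect_true(all(out$boxes$ymax <= out$height))
  }
})

test_that("class balancing expands minority images by the requested factor", {
  imgs <- lapply(1:10, function(i) {
    has_bud <- i <= 4
    labeled_image(paste0("im", i),
                  pixels = array(120, dim = c(32, 32, 3)),
                  boxes = boxes(2, 2, 20, 20,
                                class = if (has_bud) "bud" else "flower"))
  })
  out <- balance_classes(imgs, "bud", expansion_factor = 3,
                         plan = augment_plan(mirror = list(), seed = 1))
  expect_length(out, 10 + 4 * 3 + 6 * 1)  # originals + augmented copies

  share <- function(set) {
    cls <- unlist(lapply(set, function(x) x$boxes$class))
    mean(cls == "bud")
  }
  expect_gt(share(out), share(imgs))

  uniform <- balance_classes(imgs, "bud", expansion_factor = 1,
                             plan = augment_plan(mirror = list(), seed = 1))
  expect_length(uniform, 20)

  none <- lapply(imgs[5:10], identity)
  expect_warning(res <- balance_classes(none, "bud"), "absent")
  expect_identical(res, none)
})
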