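node_row <- function(kind, in_ch, out_ch, kernel = 0L, groups = 1L,
                     bias = FALSE, squeeze = NA_integer_) {
  tibble::tibble(name = "n", kind = kind, in_ch = in_ch, out_ch = out_ch,
                 kernel = kernel, stride = 1L, groups = groups, bias = bias,
                 activation = NA_character_, squeeze = squeeze,
                 inputs = list("x"), section = "panet", head = 0L)
}

test_that("per-node parameter counts follow the closed forms", {
  expect_equal(node_param_count(node_row("conv", 32L, 64L, 3L)), 9 * 32 * 64)
  # depthwise 3x3 + pointwise 1x1 replacing one 3x3 conv
  dw <- node_param_count(node_row("conv", 32L, 32L, 3L, groups = 32L))
  pw <- node_param_count(node_row("conv", 32L, 64L, 1L))
  expect_equal(dw, 288)
  expect_equal(pw, 2048)
  expect_equal(dw + pw, 2336)
  expect_equal(node_param_count(node_row("batchnorm", 64L, 64L)), 128)
  expect_equal(node_param_count(node_row("conv", 256L, 21L, 1L, bias = TRUE)),
               256 * 21 + 21)
  expect_equal(node_param_count(node_row("dense", 10L, 4L)), 44)
  expect_equal(node_param_count(node_row("maxpool", 64L, 64L)), 0)
  expect_error(node_param_count(node_row("warp", 1L, 1L)), "unknown")
})

test_that("all variants build as valid DAGs with consistent heads", {
  for (v in c("yolov4", "yolov4_dw", "yolov4_tiny", "yolov4_tiny_dw", "improved")) {
    g <- build_architecture(v, num_classes = 2)
    expect_silent(validate_graph(g))
    heads <- g[g$head > 0, ]
    expect_equal(nrow(heads), if (grepl("tiny", v)) 2L else 3L)
    expect_true(all(heads$out_ch == 3 * (5 + 2)))  # anchors * (5 + classes)
    rep <- count_parameters(g)
    expect_equal(sum(rep$by_section$params), rep$total)
    expect_equal(rep$weight_bytes_fp32, 4 * rep$total)
  }
  g5 <- build_architecture("yolov4", num_classes = 5, anchors_per_head = 4)
  expect_true(all(g5[g5$head > 0, ]$out_ch == 4 * 10))
})

test_that("the depthwise rewrite shrinks, scopes and idempotes", {
  g <- build_architecture("yolov4", num_classes = 2)
  t1 <- dw_separable_transform(g, scope = c("spp", "panet", "heads"))
  expect_lt(count_parameters(t1)$total, count_parameters(g)$total)
  # idempotent: depthwise nodes are never re-split
  t2 <- dw_separable_transform(t1, scope = c("spp", "panet", "heads"))
  expect_equal(count_parameters(t2)$total, count_parameters(t1)$total)
  expect_equal(nrow(t2), nrow(t1))
  # empty scope is the identity
  expect_equal(nrow(dw_separable_transform(g, character())), nrow(g))
  # backbone untouched
  bb <- function(gr) sum(count_parameters(gr)$ledger$params[
    count_parameters(gr)$ledger$section == "backbone"])
  expect_equal(bb(t1), bb(g))
  # no un-transformed 3x3 conv left in scope
  left <- t1[t1$kind == "conv" & t1$kernel == 3 & t1$groups == 1 &
               t1$section %in% c("spp", "panet", "heads"), ]
  expect_equal(nrow(left), 0L)
})

test_that("a 512-channel 3x3 conv separates to the expected weight count", {
  g <- build_architecture("yolov4", num_classes = 2)
  t1 <- dw_separable_transform(g, "spp")
  led <- count_parameters(t1)$ledger
  dwp <- led$params[led$name == "spp_pre2_dw"]
  pwp <- led$params[led$name == "spp_pre2"]
  expect_equal(dwp + pwp, 9 * 512 + 512 * 1024)  # 266,752 excluding BN
})

test_that("head predictors and final layers are never separated", {
  g <- build_architecture("yolov4_dw", num_classes = 2)
  preds <- g[g$head > 0, ]
  expect_true(all(preds$kernel == 1 & preds$bias & preds$groups == 1))
})

test_that("FLOP estimates follow symbolic spatial propagation", {
  g <- build_architecture("yolov4", num_classes = 2, input_size = 608)
  led <- tidy(count_parameters(g))
  expect_s3_class(led, "tbl_df")
  # first conv: 608 * 608 * 3 * 32 * 9 multiply-adds
  stem_only <- g[1:4, ]   # input, stem conv, bn, activation
  attr(stem_only, "input_size") <- 608L
  expect_equal(flops_estimate(stem_only), 608 * 608 * 3 * 32 * 9)
  # separable variant always costs fewer multiply-adds
  expect_lt(flops_estimate(build_architecture("yolov4_dw", num_classes = 2)),
            flops_estimate(g))
})

test_that("depthwise-separable cost ratio approaches 1/Do + 1/(Hk*Wk)", {
  hi <- 512; di <- 64; do <- 128; k <- 3
  std <- hi * hi * di * do * k * k
  sep <- hi * hi * di * k * k + hi * hi * di * do
  expect_equal(sep / std, 1 / do + 1 / k^2)
})

test_that("variant_table reproduces the published parameter inventory", {
  tab <- variant_table(c("yolov4", "yolov4_dw"), num_classes = 2)
  expect_equal(tab$params, c(63943071, 35690655))
})
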