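#' Declarative detector architecture graphs
#'
#' A detector architecture is represented as an ordered tibble of layer
#' nodes — a DAG in topological order — that fully determines both the
#' analytic parameter/FLOP accounting and the runtime model. Convolutions
#' followed by batch norm carry no bias (darknet convention); the final
#' 1x1 head predictors carry bias and no batch norm. Batch norm contributes
#' 2 trainable values per channel (scale and shift).
#'
#' @name arch_graph
NULL

new_graph_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env$names <- character()
  env$last <- NA_character_
  env$add <- function(name, kind, in_ch, out_ch, inputs = NULL,
                      kernel = 0L, stride = 1L, groups = 1L, bias = FALSE,
                      activation = NA_character_, squeeze = NA_integer_,
                      section = "backbone", head = 0L) {
    if (name %in% env$names) abort(sprintf("duplicate node name '%s'", name))
    if (is.null(inputs)) inputs <- if (is.na(env$last)) character() else env$last
    env$rows[[length(env$rows) + 1]] <- tibble(
      name = name, kind = kind,
      in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
      kernel = as.integer(kernel), stride = as.integer(stride),
      groups = as.integer(groups), bias = bias,
      activation = activation, squeeze = as.integer(squeeze),
      inputs = list(as.character(inputs)),
      section = section, head = as.integer(head)
    )
    env$names <- c(env$names, name)
    env$last <- name
    name
  }
  # conv + batchnorm + activation; returns the activation node's name
  env$cba <- function(name, in_ch, out_ch, kernel, stride = 1L,
                      act = "leaky_relu", section = "backbone",
                      inputs = NULL, groups = 1L) {
    env$add(name, "conv", in_ch, out_ch, inputs, kernel = kernel,
            stride = stride, groups = groups, section = section)
    env$add(paste0(name, "_bn"), "batchnorm", out_ch, out_ch, section = section)
    if (!is.na(act) && act != "linear") {
      env$add(paste0(name, "_act"), "activation", out_ch, out_ch,
              activation = act, section = section)
    }
    env$last
  }
  env
}

builder_graph <- function(env, variant, num_classes, anchors_per_head, input_size) {
  nodes <- bind_rows(env$rows)
  structure(nodes, class = c("arch_graph", class(nodes)),
            variant = variant, num_classes = as.integer(num_classes),
            anchors_per_head = as.integer(anchors_per_head),
            input_size = as.integer(input_size))
}

#' @export
print.arch_graph <- function(x, ...) {
  cat(sprintf("<arch_graph> %s: %d nodes, %d classes, %d anchors/head, input %d px\n",
              attr(x, "variant"), nrow(x), attr(x, "num_classes"),
              attr(x, "anchors_per_head"), attr(x, "input_size")))
  print(dplyr::count(as_tibble(x), .data$section, .data$kind))
  invisible(x)
}

# ---- backbones ----

csp_stage <- function(g, input, cin, cout, n_units, first = FALSE) {
  tag <- sprintf("csp%d", cout)
  split_ch <- if (first) cout else cout %/% 2L
  hid <- if (first) cout %/% 2L else split_ch
  down <- g$cba(paste0(tag, "_down"), cin, cout, 3L, 2L, "mish", inputs = input)
  route <- g$cba(paste0(tag, "_route"), cout, split_ch, 1L, act = "mish", inputs = down)
  x <- g$cba(paste0(tag, "_main"), cout, split_ch, 1L, act = "mish", inputs = down)
  for (u in seq_len(n_units)) {
    c1 <- g$cba(sprintf("%s_u%d_c1", tag, u), split_ch, hid, 1L, act = "mish", inputs = x)
    c2 <- g$cba(sprintf("%s_u%d_c2", tag, u), hid, split_ch, 3L, act = "mish", inputs = c1)
    x <- g$add(sprintf("%s_u%d_add", tag, u), "add", split_ch, split_ch,
               inputs = c(x, c2))
  }
  post <- g$cba(paste0(tag, "_post"), split_ch, split_ch, 1L, act = "mish", inputs = x)
  cat_n <- g$add(paste0(tag, "_cat"), "concat", 2L * split_ch, 2L * split_ch,
                 inputs = c(post, route))
  g$cba(paste0(tag, "_out"), 2L * split_ch, cout, 1L, act = "mish", inputs = cat_n)
}

backbone_cspdarknet53 <- function(g) {
  inp <- g$add("input", "input", 3L, 3L, inputs = character())
  stem <- g$cba("stem", 3L, 32L, 3L, act = "mish", inputs = inp)
  s1 <- csp_stage(g, stem, 32L, 64L, 1L, first = TRUE)
  s2 <- csp_stage(g, s1, 64L, 128L, 2L)
  p3 <- csp_stage(g, s2, 128L, 256L, 8L)
  p4 <- csp_stage(g, p3, 256L, 512L, 8L)
  p5 <- csp_stage(g, p4, 512L, 1024L, 4L)
  list(p3 = p3, p4 = p4, p5 = p5, ch = c(256L, 512L, 1024L))
}

tiny_body <- function(g, input, ch) {
  tag <- sprintf("tb%d", ch)
  c1 <- g$cba(paste0(tag, "_c1"), ch, ch, 3L, inputs = input)
  sl <- g$add(paste0(tag, "_slice"), "slice", ch, ch %/% 2L, inputs = c1)
  c2 <- g$cba(paste0(tag, "_c2"), ch %/% 2L, ch %/% 2L, 3L, inputs = sl)
  c3 <- g$cba(paste0(tag, "_c3"), ch %/% 2L, ch %/% 2L, 3L, inputs = c2)
  cat1 <- g$add(paste0(tag, "_cat1"), "concat", ch, ch, inputs = c(c3, c2))
  c4 <- g$cba(paste0(tag, "_c4"), ch, ch, 1L, inputs = cat1)
  cat2 <- g$add(paste0(tag, "_cat2"), "concat", 2L * ch, 2L * ch, inputs = c(c1, c4))
  pool <- g$add(paste0(tag, "_pool"), "maxpool", 2L * ch, 2L * ch,
                kernel = 2L, stride = 2L, inputs = cat2)
  list(out = pool, tap = c4)
}

backbone_tiny <- function(g) {
  inp <- g$add("input", "input", 3L, 3L, inputs = character())
  c1 <- g$cba("stem1", 3L, 32L, 3L, 2L, inputs = inp)
  c2 <- g$cba("stem2", 32L, 64L, 3L, 2L, inputs = c1)
  b1 <- tiny_body(g, c2, 64L)
  b2 <- tiny_body(g, b1$out, 128L)
  b3 <- tiny_body(g, b2$out, 256L)
  p5 <- g$cba("tail", 512L, 512L, 3L, inputs = b3$out)
  list(p4 = b3$tap, p5 = p5, ch = c(256L, 512L))
}

make_divisible <- function(v, divisor = 8L) {
  nv <- max(divisor, (floor(v + divisor / 2) %/% divisor) * divisor)
  if (nv < 0.9 * v) nv <- nv + divisor
  as.integer(nv)
}

mbv3_bneck <- function(g, input, idx, cin, exp, cout, kernel, stride, se, act) {
  tag <- sprintf("bneck%02d", idx)
  x <- input
  if (exp != cin) {
    x <- g$cba(paste0(tag, "_expand"), cin, exp, 1L, act = act, inputs = x)
  }
  x <- g$cba(paste0(tag, "_dw"), exp, exp, kernel, stride, act = act,
             inputs = x, groups = exp)
  if (se) {
    x <- g$add(paste0(tag, "_se"), "se_scale", exp, exp,
               squeeze = make_divisible(exp %/% 4L), inputs = x)
  }
  x <- g$cba(paste0(tag, "_project"), exp, cout, 1L, act = "linear", inputs = x)
  if (stride == 1L && cin == cout) {
    x <- g$add(paste0(tag, "_add"), "add", cout, cout, inputs = c(x, input))
  }
  x
}

backbone_mobilenetv3 <- function(g) {
  cfg <- list(
    list(16L, 16L, 16L, 3L, 1L, FALSE, "relu"),
    list(16L, 64L, 24L, 3L, 2L, FALSE, "relu"),
    list(24L, 72L, 24L, 3L, 1L, FALSE, "relu"),
    list(24L, 72L, 40L, 5L, 2L, TRUE, "relu"),
    list(40L, 120L, 40L, 5L, 1L, TRUE, "relu"),
    list(40L, 120L, 40L, 5L, 1L, TRUE, "relu"),
    list(40L, 240L, 80L, 3L, 2L, FALSE, "h_swish"),
    list(80L, 200L, 80L, 3L, 1L, FALSE, "h_swish"),
    list(80L, 184L, 80L, 3L, 1L, FALSE, "h_swish"),
    list(80L, 184L, 80L, 3L, 1L, FALSE, "h_swish"),
    list(80L, 480L, 112L, 3L, 1L, TRUE, "h_swish"),
    list(112L, 672L, 112L, 3L, 1L, TRUE, "h_swish"),
    list(112L, 672L, 160L, 5L, 2L, TRUE, "h_swish"),
    list(160L, 960L, 160L, 5L, 1L, TRUE, "h_swish"),
    list(160L, 960L, 160L, 5L, 1L, TRUE, "h_swish")
  )
  inp <- g$add("input", "input", 3L, 3L, inputs = character())
  x <- g$cba("stem", 3L, 16L, 3L, 2L, act = "h_swish", inputs = inp)
  taps <- list()
  for (i in seq_along(cfg)) {
    cc <- cfg[[i]]
    x <- mbv3_bneck(g, x, i, cc[[1]], cc[[2]], cc[[3]], cc[[4]], cc[[5]], cc[[6]], cc[[7]])
    if (i == 6L) taps$p3 <- x    # 40 ch, stride 8
    if (i == 12L) taps$p4 <- x   # 112 ch, stride 16
    if (i == 15L) taps$p5 <- x   # 160 ch, stride 32
  }
  c(taps, list(ch = c(40L, 112L, 160L)))
}

# ---- neck + heads ----

five_conv <- function(g, tag, input, in_ch, w, act = "leaky_relu",
                      section = "panet") {
  x <- g$cba(paste0(tag, "_c1"), in_ch, w, 1L, act = act, inputs = input,
             section = section)
  x <- g$cba(paste0(tag, "_c2"), w, 2L * w, 3L, act = act, inputs = x,
             section = section)
  x <- g$cba(paste0(tag, "_c3"), 2L * w, w, 1L, act = act, inputs = x,
             section = section)
  x <- g$cba(paste0(tag, "_c4"), w, 2L * w, 3L, act = act, inputs = x,
             section = section)
  g$cba(paste0(tag, "_c5"), 2L * w, w, 1L, act = act, inputs = x,
        section = section)
}

neck_yolov4 <- function(g, taps, num_classes, anchors_per_head) {
  pred_ch <- anchors_per_head * (5L + num_classes)
  ch <- taps$ch

  # SPP block around the P5 tap
  x <- g$cba("spp_pre1", ch[3], 512L, 1L, section = "spp", inputs = taps$p5)
  x <- g$cba("spp_pre2", 512L, 1024L, 3L, section = "spp", inputs = x)
  x <- g$cba("spp_pre3", 1024L, 512L, 1L, section = "spp", inputs = x)
  p5s <- map_chr(c(5L, 9L, 13L), function(k) {
    g$add(sprintf("spp_pool%d", k), "maxpool", 512L, 512L, kernel = k,
          stride = 1L, section = "spp", inputs = x)
  })
  x <- g$add("spp_cat", "concat", 2048L, 2048L, section = "spp",
             inputs = c(p5s[3], p5s[2], p5s[1], x))
  x <- g$cba("spp_post1", 2048L, 512L, 1L, section = "spp", inputs = x)
  x <- g$cba("spp_post2", 512L, 1024L, 3L, section = "spp", inputs = x)
  p5_mid <- g$cba("spp_post3", 1024L, 512L, 1L, section = "spp", inputs = x)

  # top-down path
  up1 <- g$cba("up1_conv", 512L, 256L, 1L, section = "panet", inputs = p5_mid)
  up1 <- g$add("up1", "upsample", 256L, 256L, section = "panet", inputs = up1)
  lat4 <- g$cba("lat_p4", ch[2], 256L, 1L, section = "panet", inputs = taps$p4)
  cat4 <- g$add("cat_p4", "concat", 512L, 512L, section = "panet",
                inputs = c(lat4, up1))
  p4_mid <- five_conv(g, "p4block", cat4, 512L, 256L)

  up2 <- g$cba("up2_conv", 256L, 128L, 1L, section = "panet", inputs = p4_mid)
  up2 <- g$add("up2", "upsample", 128L, 128L, section = "panet", inputs = up2)
  lat3 <- g$cba("lat_p3", ch[1], 128L, 1L, section = "panet", inputs = taps$p3)
  cat3 <- g$add("cat_p3", "concat", 256L, 256L, section = "panet",
                inputs = c(lat3, up2))
  p3_out <- five_conv(g, "p3block", cat3, 256L, 128L)

  # head P3
  h3 <- g$cba("head_p3_stem", 128L, 256L, 3L, section = "heads", inputs = p3_out)
  g$add("head_p3_pred", "conv", 256L, pred_ch, kernel = 1L, bias = TRUE,
        section = "heads", head = 1L, inputs = h3)

  # bottom-up path
  down4 <- g$cba("down_p4", 128L, 256L, 3L, 2L, section = "panet", inputs = p3_out)
  cat4b <- g$add("cat_p4b", "concat", 512L, 512L, section = "panet",
                 inputs = c(down4, p4_mid))
  p4_out <- five_conv(g, "p4block2", cat4b, 512L, 256L)
  h4 <- g$cba("head_p4_stem", 256L, 512L, 3L, section = "heads", inputs = p4_out)
  g$add("head_p4_pred", "conv", 512L, pred_ch, kernel = 1L, bias = TRUE,
        section = "heads", head = 2L, inputs = h4)

  down5 <- g$cba("down_p5", 256L, 512L, 3L, 2L, section = "panet", inputs = p4_out)
  cat5b <- g$add("cat_p5b", "concat", 1024L, 1024L, section = "panet",
                 inputs = c(down5, p5_mid))
  p5_out <- five_conv(g, "p5block2", cat5b, 1024L, 512L)
  h5 <- g$cba("head_p5_stem", 512L, 1024L, 3L, section = "heads", inputs = p5_out)
  g$add("head_p5_pred", "conv", 1024L, pred_ch, kernel = 1L, bias = TRUE,
        section = "heads", head = 3L, inputs = h5)
  invisible(NULL)
}

neck_tiny <- function(g, taps, num_classes, anchors_per_head) {
  pred_ch <- anchors_per_head * (5L + num_classes)
  p5c <- g$cba("neck_p5", 512L, 256L, 1L, section = "panet", inputs = taps$p5)
  h5 <- g$cba("head_p5_stem", 256L, 512L, 3L, section = "heads", inputs = p5c)
  g$add("head_p5_pred", "conv", 512L, pred_ch, kernel = 1L, bias = TRUE,
        section = "heads", head = 1L, inputs = h5)
  up <- g$cba("up1_conv", 256L, 128L, 1L, section = "panet", inputs = p5c)
  up <- g$add("up1", "upsample", 128L, 128L, section = "panet", inputs = up)
  cat4 <- g$add("cat_p4", "concat", 384L, 384L, section = "panet",
                inputs = c(taps$p4, up))
  fuse <- g$cba("fuse_p4", 384L, 256L, 3L, section = "panet", inputs = cat4)
  g$add("head_p4_pred", "conv", 256L, pred_ch, kernel = 1L, bias = TRUE,
        section = "heads", head = 2L, inputs = fuse)
  invisible(NULL)
}

#' Build a detector architecture graph
#'
#' Supported variants:
#' * `"yolov4"` — CSPDarknet53 backbone (Mish), SPP (5/9/13 max-pools),
#'   PANet and 3 detection heads (leaky ReLU in the neck).
#' * `"yolov4_dw"` — `"yolov4"` with every 3x3 convolution in the
#'   SPP/PANet/head-stem fusion network replaced by a depthwise-separable
#'   pair via [dw_separable_transform()]; the two upsample-branch 1x1
#'   convolutions are also rewritten as depthwise-separable blocks.
#' * `"yolov4_tiny"` — CSPDarknet53-tiny backbone with the standard
#'   two-head tiny neck.
#' * `"yolov4_tiny_dw"` — the tiny graph with the depthwise-separable
#'   rewrite over its fusion network.
#' * `"improved"` — MobileNetv3-Large backbone (width 1.0, squeeze-excite
#'   blocks, h-swish) tapped at 40/112/160 channels (strides 8/16/32, the
#'   final 160->960 expansion conv omitted), feeding the depthwise-separable
#'   SPP/PANet neck through 1x1 channel adapters; plain 1x1 upsample convs.
#'
#' @param variant One of the variants above.
#' @param num_classes Number of object classes (default 2: flower, bud).
#' @param anchors_per_head Anchors per detection head (default 3).
#' @param input_size Network input resolution (default 608).
#' @return An `arch_graph` tibble of layer nodes.
#' @examples
#' g <- build_architecture("yolov4_tiny", num_classes = 2)
#' count_parameters(g)$total
#' @export
build_architecture <- function(variant = c("yolov4", "yolov4_dw", "yolov4_tiny",
                                           "yolov4_tiny_dw", "improved"),
                               num_classes = 2L, anchors_per_head = 3L,
                               input_size = 608L) {
  variant <- match.arg(variant)
  stopifnot(num_classes >= 1, anchors_per_head >= 1, input_size %% 32 == 0)
  g <- new_graph_builder()
  graph <- switch(variant,
    yolov4 = , yolov4_dw = {
      taps <- backbone_cspdarknet53(g)
      neck_yolov4(g, taps, num_classes, anchors_per_head)
      builder_graph(g, variant, num_classes, anchors_per_head, input_size)
    },
    yolov4_tiny = , yolov4_tiny_dw = {
      taps <- backbone_tiny(g)
      neck_tiny(g, taps, num_classes, anchors_per_head)
      builder_graph(g, variant, num_classes, anchors_per_head, input_size)
    },
    improved = {
      taps <- backbone_mobilenetv3(g)
      neck_yolov4(g, taps, num_classes, anchors_per_head)
      builder_graph(g, variant, num_classes, anchors_per_head, input_size)
    }
  )
  if (variant %in% c("yolov4_dw", "improved")) {
    graph <- dw_separable_transform(graph, scope = c("spp", "panet", "heads"))
  }
  if (variant == "yolov4_dw") {
    # the lightweight fusion network also separates its upsample convs
    graph <- dw_rewrite_nodes(graph, c("up1_conv", "up2_conv"))
  }
  if (variant == "yolov4_tiny_dw") {
    graph <- dw_separable_transform(graph, scope = c("panet", "heads"))
  }
  validate_graph(graph)
  graph
}

#' Depthwise-separable rewrite of a graph's fusion network
#'
#' Every 3x3 standard convolution in the given sections is replaced by a
#' depthwise 3x3 convolution (groups = channels, batch-normalised and
#' activated) followed by the original convolution reduced to a 1x1
#' pointwise mixing layer. 1x1 convolutions, the biased head predictors and
#' the backbone are untouched; depthwise nodes are never re-split, so the
#' transform is idempotent.
#'
#' @param graph An `arch_graph`.
#' @param scope Character subset of `c("spp", "panet", "heads")`.
#' @return The transformed `arch_graph`.
#' @export
dw_separable_transform <- function(graph, scope = c("spp", "panet", "heads")) {
  if (!length(scope)) return(graph)
  stopifnot(all(scope %in% c("spp", "panet", "heads")))
  targets <- graph$name[graph$kind == "conv" & graph$kernel == 3L &
                          graph$groups == 1L & !graph$bias &
                          graph$section %in% scope]
  dw_rewrite_nodes(graph, targets)
}

# rewrite the named conv nodes into depthwise 3x3 + pointwise 1x1 pairs
dw_rewrite_nodes <- function(graph, names) {
  at <- attributes(graph)
  rows <- split_rows(graph)
  out <- list()
  for (row in rows) {
    if (row$name %in% names && row$kind == "conv") {
      di <- row$in_ch
      act <- find_conv_activation(graph, row$name)
      dw_name <- paste0(row$name, "_dw")
      out[[length(out) + 1]] <- modify_row(row, name = dw_name, out_ch = di,
                                           kernel = 3L, groups = di,
                                           stride = row$stride)
      out[[length(out) + 1]] <- modify_row(row, name = paste0(dw_name, "_bn"),
                                           kind = "batchnorm", out_ch = di,
                                           kernel = 0L, groups = 1L, stride = 1L,
                                           inputs = dw_name)
      out[[length(out) + 1]] <- modify_row(row, name = paste0(dw_name, "_act"),
                                           kind = "activation", out_ch = di,
                                           kernel = 0L, groups = 1L, stride = 1L,
                                           activation = act,
                                           inputs = paste0(dw_name, "_bn"))
      out[[length(out) + 1]] <- modify_row(row, kernel = 1L, stride = 1L,
                                           inputs = paste0(dw_name, "_act"))
    } else {
      out[[length(out) + 1]] <- row
    }
  }
  res <- bind_rows(out)
  attributes(res) <- c(attributes(res)[c("names", "row.names")],
                       at[setdiff(names(at), c("names", "row.names"))])
  res
}

split_rows <- function(graph) {
  lapply(seq_len(nrow(graph)), function(i) as_tibble(graph[i, ]))
}

modify_row <- function(row, ...) {
  ch <- list(...)
  for (nm in names(ch)) {
    row[[nm]] <- if (nm == "inputs") list(as.character(ch[[nm]])) else ch[[nm]]
  }
  row
}

find_conv_activation <- function(graph, conv_name) {
  downstream <- graph[map_lgl(graph$inputs, ~ conv_name %in% .x), ]
  if (nrow(downstream) && downstream$kind[1] == "batchnorm") {
    act <- graph[map_lgl(graph$inputs, ~ downstream$name[1] %in% .x) &
                   graph$kind == "activation", ]
    if (nrow(act)) return(act$activation[1])
  }
  "leaky_relu"
}

#' Validate an architecture graph
#'
#' Checks that the node list is a DAG in topological order with consistent
#' channels (concat inputs sum, grouped convs divide evenly), that spatial
#' strides are consistent at every merge, and that the detection heads have
#' the expected `anchors * (5 + classes)` output channels.
#'
#' @param graph An `arch_graph`.
#' @return `graph`, invisibly; aborts on an inconsistency.
#' @export
validate_graph <- function(graph) {
  seen <- character()
  stride_of <- setNames(numeric(nrow(graph)), graph$name)
  ch_of <- setNames(integer(nrow(graph)), graph$name)
  for (i in seq_len(nrow(graph))) {
    row <- graph[i, ]
    ins <- row$inputs[[1]]
    if (!all(ins %in% seen)) {
      abort(sprintf("node '%s' references undefined inputs: %s", row$name,
                    paste(setdiff(ins, seen), collapse = ", ")))
    }
    in_stride <- if (length(ins)) stride_of[ins] else 1
    if (length(ins) > 1 && length(unique(in_stride)) != 1) {
      abort(sprintf("node '%s' merges inputs at different strides", row$name))
    }
    s_in <- if (length(ins)) in_stride[1] else 1
    stride_of[row$name] <- s_in *
      (if (row$kind %in% c("conv", "maxpool") && row$stride > 1) row$stride else 1) *
      (if (row$kind == "upsample") 0.5 else 1)
    if (row$kind == "concat") {
      if (sum(ch_of[ins]) != row$in_ch) {
        abort(sprintf("concat '%s' channel mismatch: %d vs %d", row$name,
                      sum(ch_of[ins]), row$in_ch))
      }
    } else if (length(ins)) {
      if (any(ch_of[ins] != row$in_ch)) {
        abort(sprintf("node '%s' input channel mismatch", row$name))
      }
    }
    if (row$kind == "conv") {
      if (row$in_ch %% row$groups != 0 || row$out_ch %% row$groups != 0) {
        abort(sprintf("conv '%s': groups must divide channels", row$name))
      }
    }
    ch_of[row$name] <- row$out_ch
    seen <- c(seen, row$name)
  }
  heads <- graph[graph$head > 0L, ]
  expected_heads <- if (attr(graph, "variant") %in% c("yolov4_tiny", "yolov4_tiny_dw")) 2L else 3L
  if (nrow(heads) != expected_heads) {
    abort(sprintf("expected %d detection heads, found %d", expected_heads, nrow(heads)))
  }
  pred_ch <- attr(graph, "anchors_per_head") * (5L + attr(graph, "num_classes"))
  if (any(heads$out_ch != pred_ch)) abort("head predictor channels inconsistent")
  invisible(graph)
}
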