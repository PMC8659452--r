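#' Analytic per-node parameter count
#'
#' Trainable parameters only: convolution weights
#' `Hk * Wk * (Di / groups) * Do` (+ `Do` if biased), batch norm scale and
#' shift (`2 * Do`; running statistics are state, not parameters), dense
#' layers `Di * Do + Do`, and squeeze-excite scaling as its two biased
#' 1x1 projections. Activations, pools, upsampling, concat and add are free.
#'
#' @param node A single-row `arch_graph` slice (or an `arch_graph`, which is
#'   counted row-wise).
#' @return Integer-valued numeric vector of parameter counts.
#' @examples
#' g <- build_architecture("yolov4_tiny")
#' sum(node_param_count(g))
#' @export
node_param_count <- function(node) {
  kind <- node$kind
  p <- numeric(length(kind))
  is_conv <- kind == "conv"
  p[is_conv] <- node$kernel[is_conv]^2 *
    (node$in_ch[is_conv] / node$groups[is_conv]) * node$out_ch[is_conv] +
    ifelse(node$bias[is_conv], node$out_ch[is_conv], 0)
  p[kind == "batchnorm"] <- 2 * node$out_ch[kind == "batchnorm"]
  is_d <- kind == "dense"
  p[is_d] <- node$in_ch[is_d] * node$out_ch[is_d] + node$out_ch[is_d]
  is_se <- kind == "se_scale"
  p[is_se] <- 2 * node$in_ch[is_se] * node$squeeze[is_se] +
    node$squeeze[is_se] + node$in_ch[is_se]
  bad <- !kind %in% c("conv", "batchnorm", "dense", "se_scale", "activation",
                      "maxpool", "upsample", "concat", "add", "global_pool",
                      "slice", "input")
  if (any(bad)) abort(sprintf("unknown node kind: %s", paste(unique(kind[bad]), collapse = ", ")))
  p
}

#' Count the trainable parameters of an architecture
#'
#' @param graph An `arch_graph` from [build_architecture()].
#' @return A `param_report`: list with `total`, `by_section` (tibble),
#'   `weight_bytes_fp32` (`4 * total`) and the per-node `ledger` tibble.
#' @examples
#' count_parameters(build_architecture("yolov4_tiny"))$total
#' @export
count_parameters <- function(graph) {
  ledger <- as_tibble(graph)[, c("name", "kind", "section", "in_ch", "out_ch",
                                 "kernel", "groups", "bias")]
  ledger$params <- node_param_count(graph)
  by_section <- ledger %>%
    group_by(.data$section) %>%
    summarise(params = sum(.data$params), .groups = "drop")
  total <- sum(ledger$params)
  structure(
    list(total = total, by_section = by_section,
         weight_bytes_fp32 = 4 * total, ledger = ledger,
         variant = attr(graph, "variant")),
    class = "param_report"
  )
}

#' @export
print.param_report <- function(x, ...) {
  cat(sprintf("<param_report> %s: %s trainable parameters (%.1f MiB fp32)\n",
              x$variant, format(x$total, big.mark = ","),
              x$weight_bytes_fp32 / 2^20))
  print(x$by_section)
  invisible(x)
}

#' @export
tidy.param_report <- function(x, ...) x$ledger

#' @export
glance.param_report <- function(x, ...) {
  tibble(variant = x$variant, total = x$total,
         weight_mib_fp32 = x$weight_bytes_fp32 / 2^20)
}

#' Estimate multiply-add operations for a forward pass
#'
#' Spatial dimensions are propagated symbolically from the input size
#' through strides, pools and upsampling. Convolutions cost
#' `Ho * Wo * Hk * Wk * (Di / groups) * Do` multiply-adds; dense layers
#' `Di * Do`; squeeze-excite its two projections; normalisation,
#' activations and reshuffling ops are not counted. For a standard
#' convolution this is `Hi x Wi x Di x Do x Hk x Wk`; its
#' depthwise-separable replacement costs
#' `Hi x Wi x Di x Hk x Wk + Hi x Wi x Di x Do`, a ratio approaching
#' `1/Do + 1/(Hk x Wk)`.
#'
#' @param graph An `arch_graph`.
#' @return Total multiply-add count (numeric).
#' @export
flops_estimate <- function(graph) {
  size <- attr(graph, "input_size")
  hw <- setNames(vector("list", nrow(graph)), graph$name)
  total <- 0
  for (i in seq_len(nrow(graph))) {
    row <- graph[i, ]
    ins <- row$inputs[[1]]
    cur <- if (length(ins)) hw[[ins[1]]] else c(size, size)
    out_hw <- cur
    if (row$kind %in% c("conv", "maxpool") && row$stride > 1) {
      out_hw <- ceiling(cur / row$stride)
    }
    if (row$kind == "upsample") out_hw <- cur * 2
    if (row$kind %in% c("global_pool", "dense")) out_hw <- c(1, 1)
    hw[[row$name]] <- out_hw
    total <- total + switch(row$kind,
      conv = prod(out_hw) * row$kernel^2 * (row$in_ch / row$groups) * row$out_ch,
      dense = row$in_ch * row$out_ch,
      se_scale = 2 * row$in_ch * row$squeeze,
      0
    )
  }
  total
}

#' Tabulate the four published model variants
#'
#' Builds each requested variant and returns its exact trainable-parameter
#' total and fp32 weight size.
#'
#' @param variants Character vector of variants for [build_architecture()].
#' @param num_classes Classes per variant (recycled).
#' @return A tibble with columns `variant`, `num_classes`, `params`,
#'   `weight_mib_fp32`.
#' @export
variant_table <- function(variants = c("yolov4", "yolov4_dw", "yolov4_tiny_dw",
                                       "improved"),
                          num_classes = 2L) {
  num_classes <- rep_len(num_classes, length(variants))
  bind_rows(map2(variants, num_classes, function(v, nc) {
    rep <- count_parameters(build_architecture(v, num_classes = nc))
    tibble(variant = v, num_classes = nc, params = rep$total,
           weight_mib_fp32 = rep$weight_bytes_fp32 / 2^20)
  }))
}
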