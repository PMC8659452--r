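#' Build an executable runtime model from an architecture graph
#'
#' Materialises every trainable tensor declared by the graph (convolution
#' kernels, batch-norm scale/shift, squeeze-excite projections, head
#' biases), giving an independent runtime check of the analytic accountant:
#' the number of allocated weights must equal [count_parameters()]`$total`
#' exactly. The same object drives [forward_runtime()] and smoke-scale
#' [train_detector()].
#'
#' @param graph An `arch_graph` from [build_architecture()].
#' @param seed Integer seed for weight initialisation (He-normal).
#' @return A `runtime_model`.
#' @examples
#' m <- build_runtime_model(build_architecture("yolov4_tiny"), seed = 1)
#' runtime_param_total(m) == count_parameters(build_architecture("yolov4_tiny"))$total
#' @export
build_runtime_model <- function(graph, seed = 0L) {
  params <- list()
  state <- new.env(parent = emptyenv())  # running BN statistics, mutable
  withr_seed(seed, {
    for (i in seq_len(nrow(graph))) {
      row <- graph[i, ]
      nm <- row$name
      if (row$kind == "conv") {
        if (row$groups == 1L) {
          fan_in <- row$kernel^2 * row$in_ch
          w <- matrix(rnorm(row$out_ch * fan_in, 0, sqrt(2 / fan_in)),
                      nrow = row$out_ch)
          params[[nm]] <- if (row$bias) list(w = w, b = numeric(row$out_ch)) else list(w = w)
        } else if (row$groups == row$in_ch && row$in_ch == row$out_ch) {
          fan_in <- row$kernel^2
          params[[nm]] <- list(w = matrix(rnorm(fan_in * row$in_ch, 0, sqrt(2 / fan_in)),
                                          nrow = fan_in))
        } else {
          abort(sprintf("runtime supports groups = 1 or depthwise convs only ('%s')", nm))
        }
      } else if (row$kind == "batchnorm") {
        params[[nm]] <- list(gamma = rep(1, row$out_ch), beta = numeric(row$out_ch))
        state[[nm]] <- list(rm = numeric(row$out_ch), rv = rep(1, row$out_ch))
      } else if (row$kind == "dense") {
        params[[nm]] <- list(w = matrix(rnorm(row$out_ch * row$in_ch, 0, sqrt(2 / row$in_ch)),
                                        nrow = row$out_ch),
                             b = numeric(row$out_ch))
      } else if (row$kind == "se_scale") {
        sq <- row$squeeze
        params[[nm]] <- list(
          w1 = matrix(rnorm(sq * row$in_ch, 0, sqrt(2 / row$in_ch)), nrow = sq),
          b1 = numeric(sq),
          w2 = matrix(rnorm(row$in_ch * sq, 0, sqrt(2 / sq)), nrow = row$in_ch),
          b2 = numeric(row$in_ch)
        )
      }
    }
  })
  structure(list(graph = graph, params = params, state = state),
            class = "runtime_model")
}

#' Total trainable weights held by a runtime model
#'
#' @param model A `runtime_model`.
#' @return Numeric count of allocated trainable values.
#' @export
runtime_param_total <- function(model) {
  sum(map_dbl(model$params, ~ sum(map_dbl(.x, length))))
}

#' @export
print.runtime_model <- function(x, ...) {
  cat(sprintf("<runtime_model> %s: %s trainable weights\n",
              attr(x$graph, "variant"),
              format(runtime_param_total(x), big.mark = ",")))
  invisible(x)
}

head_node_names <- function(graph) graph$name[graph$head > 0L]

activation_fwd <- function(x, kind) {
  switch(kind,
    leaky_relu = x * (0.1 + 0.9 * (x > 0)),
    relu = pmax(x, 0),
    relu6 = pmin(pmax(x, 0), 6),
    mish = x * tanh(softplus(x)),
    h_swish = x * pmin(pmax(x + 3, 0), 6) / 6,
    h_sigmoid = pmin(pmax(x + 3, 0), 6) / 6,
    linear = x,
    abort(sprintf("unknown activation '%s'", kind))
  )
}

activation_bwd <- function(x, dy, kind) {
  switch(kind,
    leaky_relu = dy * (0.1 + 0.9 * (x > 0)),
    relu = dy * (x > 0),
    relu6 = dy * (x > 0 & x < 6),
    mish = {
      sp <- softplus(x); tsp <- tanh(sp)
      dy * (tsp + x * (1 - tsp^2) * stats::plogis(x))
    },
    h_swish = dy * ifelse(x <= -3, 0, ifelse(x >= 3, 1, (2 * x + 3) / 6)),
    h_sigmoid = dy * ifelse(x > -3 & x < 3, 1 / 6, 0),
    linear = dy,
    abort(sprintf("unknown activation '%s'", kind))
  )
}

softplus <- function(x) ifelse(x > 20, x, log1p(exp(pmin(x, 20))))

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  h <- d[1] %/% 2L; w <- d[2] %/% 2L
  out <- array(0, dim = c(h, w, d[3]))
  for (i in 0:1) for (j in 0:1) {
    out <- out + dy[seq_len(h) * 2 - i, seq_len(w) * 2 - j, , drop = FALSE]
  }
  out
}

#' Run a forward pass through a runtime model
#'
#' @param model A `runtime_model`.
#' @param images List of `H x W x 3` arrays with intensities in `[0, 255]`
#'   (they are scaled to `[0, 1]` internally).
#' @param train Logical; in training mode batch statistics drive the batch
#'   norms and every intermediate needed for [backward_runtime()] is kept.
#' @param bn_momentum Weight of the current batch in the running batch-norm
#'   statistics (training mode only).
#' @return A list with `heads` (per image: list of `S x S x Do` arrays, one
#'   per detection head) and, when `train = TRUE`, the forward `cache`.
#' @export
forward_runtime <- function(model, images, train = FALSE, bn_momentum = 0.03) {
  graph <- model$graph
  params <- model$params
  n_img <- length(images)
  values <- new.env(parent = emptyenv())
  cache <- if (train) new.env(parent = emptyenv()) else NULL
  assign("input", lapply(images, function(im) im / 255), envir = values)

  for (i in seq_len(nrow(graph))) {
    row <- graph[i, ]
    nm <- row$name
    if (row$kind == "input") next
    ins <- row$inputs[[1]]
    x <- get(ins[1], envir = values)
    out <- switch(row$kind,
      conv = {
        p <- params[[nm]]
        pad <- row$kernel %/% 2L
        if (row$groups == 1L) {
          b <- p$b %||% numeric(0)
          if (train) {
            res <- lapply(x, function(xx) {
              conv2d_fwd_cols_cpp(xx, p$w, b, row$kernel, row$stride, pad)
            })
            assign(nm, lapply(res, `[[`, "cols"), envir = cache)
            lapply(res, `[[`, "y")
          } else {
            lapply(x, function(xx) conv2d_fwd_cpp(xx, p$w, b, row$kernel, row$stride, pad))
          }
        } else {
          lapply(x, function(xx) dwconv_fwd_cpp(xx, p$w, row$kernel, row$stride, pad))
        }
      },
      batchnorm = {
        p <- params[[nm]]
        if (train) {
          res <- bn_train_fwd(x, p$gamma, p$beta)
          model$state[[nm]]$rm <- (1 - bn_momentum) * model$state[[nm]]$rm +
            bn_momentum * res$mu
          model$state[[nm]]$rv <- (1 - bn_momentum) * model$state[[nm]]$rv +
            bn_momentum * res$var
          assign(nm, res$cache, envir = cache)
          res$y
        } else {
          st <- model$state[[nm]]
          scale <- p$gamma / sqrt(st$rv + 1e-5)
          shift <- p$beta - st$rm * scale
          lapply(x, function(xx) sweep_channels(xx, scale, shift))
        }
      },
      activation = lapply(x, activation_fwd, kind = row$activation),
      maxpool = {
        pad <- if (row$stride == 1L) row$kernel %/% 2L else 0L
        res <- lapply(x, maxpool_fwd_cpp, k = row$kernel, stride = row$stride, pad = pad)
        if (train) assign(nm, lapply(res, `[[`, "idx"), envir = cache)
        lapply(res, `[[`, "y")
      },
      upsample = lapply(x, upsample2_fwd),
      concat = {
        branches <- lapply(ins, get, envir = values)
        lapply(seq_len(n_img), function(j) {
          parts <- lapply(branches, `[[`, j)
          d <- dim(parts[[1]])
          array(unlist(parts, use.names = FALSE),
                dim = c(d[1], d[2], sum(map_int(parts, ~ dim(.x)[3]))))
        })
      },
      add = {
        b2 <- get(ins[2], envir = values)
        lapply(seq_len(n_img), function(j) x[[j]] + b2[[j]])
      },
      slice = lapply(x, function(xx) {
        ch <- dim(xx)[3]
        xx[, , (ch %/% 2L + 1L):ch, drop = FALSE]
      }),
      se_scale = {
        p <- params[[nm]]
        res <- lapply(x, function(xx) se_fwd(xx, p))
        if (train) assign(nm, res, envir = cache)
        lapply(res, `[[`, "y")
      },
      global_pool = lapply(x, function(xx) {
        array(colMeans(matrix(xx, ncol = dim(xx)[3])), dim = c(1, 1, dim(xx)[3]))
      }),
      dense = {
        p <- params[[nm]]
        lapply(x, function(xx) {
          v <- as.vector(p$w %*% as.vector(xx) + p$b)
          array(v, dim = c(1, 1, length(v)))
        })
      },
      abort(sprintf("no forward rule for kind '%s'", row$kind))
    )
    assign(nm, out, envir = values)
  }
  heads <- lapply(head_node_names(graph), get, envir = values)
  list(
    heads = lapply(seq_len(n_img), function(j) lapply(heads, `[[`, j)),
    values = values, cache = cache
  )
}

sweep_channels <- function(x, scale, shift) {
  d <- dim(x)
  m <- matrix(x, ncol = d[3])
  m <- m * rep(scale, each = nrow(m)) + rep(shift, each = nrow(m))
  array(m, dim = d)
}

bn_train_fwd <- function(xs, gamma, beta, eps = 1e-5) {
  mats <- lapply(xs, function(x) matrix(x, ncol = dim(x)[3]))
  n <- sum(map_int(mats, nrow))
  mu <- Reduce(`+`, lapply(mats, colSums)) / n
  var <- Reduce(`+`, lapply(mats, function(m) colSums((m - rep(mu, each = nrow(m)))^2))) / n
  inv_sd <- 1 / sqrt(var + eps)
  xhat <- lapply(mats, function(m) (m - rep(mu, each = nrow(m))) * rep(inv_sd, each = nrow(m)))
  y <- map2(xs, xhat, function(x, xh) {
    array(xh * rep(gamma, each = nrow(xh)) + rep(beta, each = nrow(xh)), dim = dim(x))
  })
  list(y = y, mu = mu, var = var,
       cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma, n = n,
                    dims = lapply(xs, dim)))
}

bn_train_bwd <- function(cache, dys) {
  dmats <- map2(dys, cache$dims, function(dy, d) matrix(dy, ncol = d[3]))
  n <- cache$n
  dgamma <- Reduce(`+`, map2(dmats, cache$xhat, function(dm, xh) colSums(dm * xh)))
  dbeta <- Reduce(`+`, lapply(dmats, colSums))
  sum_dxhat <- Reduce(`+`, lapply(dmats, function(dm) colSums(dm))) * cache$gamma
  sum_dxhat_xhat <- Reduce(`+`, map2(dmats, cache$xhat, function(dm, xh) colSums(dm * xh))) * cache$gamma
  dxs <- map2(dmats, cache$xhat, function(dm, xh) {
    nr <- nrow(dm)
    dxhat <- dm * rep(cache$gamma, each = nr)
    dx <- (dxhat - rep(sum_dxhat / n, each = nr) -
             xh * rep(sum_dxhat_xhat / n, each = nr)) * rep(cache$inv_sd, each = nr)
    dx
  })
  list(dxs = map2(dxs, cache$dims, function(m, d) array(m, dim = d)),
       dgamma = dgamma, dbeta = dbeta)
}

se_fwd <- function(x, p) {
  d <- dim(x)
  s <- colMeans(matrix(x, ncol = d[3]))
  z1 <- pmax(as.vector(p$w1 %*% s + p$b1), 0)
  a2 <- as.vector(p$w2 %*% z1 + p$b2)
  g <- pmin(pmax(a2 + 3, 0), 6) / 6
  y <- sweep_channels(x, g, numeric(d[3]))
  list(y = y, s = s, z1 = z1, a2 = a2, g = g, x = x)
}

se_bwd <- function(cache, dy, p) {
  d <- dim(cache$x)
  hw <- d[1] * d[2]
  dym <- matrix(dy, ncol = d[3])
  xm <- matrix(cache$x, ncol = d[3])
  dg <- colSums(dym * xm)
  dx_direct <- dym * rep(cache$g, each = hw)
  da2 <- dg * ifelse(cache$a2 > -3 & cache$a2 < 3, 1 / 6, 0)
  dw2 <- outer(da2, cache$z1)
  db2 <- da2
  dz1 <- as.vector(t(p$w2) %*% da2) * (cache$z1 > 0)
  dw1 <- outer(dz1, cache$s)
  db1 <- dz1
  ds <- as.vector(t(p$w1) %*% dz1)
  dx <- array(dx_direct + rep(ds / hw, each = hw), dim = d)
  list(dx = dx, dw1 = dw1, db1 = db1, dw2 = dw2, db2 = db2)
}

#' Recompute running batch-norm statistics from a reference image set
#'
#' After a short training run the exponentially averaged statistics lag the
#' weights; this replaces them with equal-weighted batch statistics
#' aggregated over the given images (precise batch norm), which makes
#' inference-mode normalisation match what the network saw in training.
#'
#' @param model A `runtime_model`.
#' @param images List of `H x W x 3` arrays in `[0, 255]`.
#' @param chunk Images per forward pass.
#' @return The model, invisibly (statistics are updated in place).
#' @export
refresh_bn_stats <- function(model, images, chunk = 8L) {
  idx <- split(seq_along(images), ceiling(seq_along(images) / chunk))
  for (k in seq_along(idx)) {
    forward_runtime(model, images[idx[[k]]], train = TRUE,
                    bn_momentum = 1 / k)
  }
  invisible(model)
}

#' Back-propagate head gradients through a runtime model
#'
#' @param model A `runtime_model`.
#' @param fwd The result of `forward_runtime(..., train = TRUE)`.
#' @param dheads Per-image list of per-head gradient arrays (same shapes as
#'   the forward heads).
#' @return Named list of parameter gradients, in the structure of
#'   `model$params`.
#' @keywords internal
#' @export
backward_runtime <- function(model, fwd, dheads) {
  graph <- model$graph
  params <- model$params
  values <- fwd$values
  cache <- fwd$cache
  n_img <- length(dheads)
  grads <- list()
  dvals <- new.env(parent = emptyenv())

  hn <- head_node_names(graph)
  for (h in seq_along(hn)) {
    assign(hn[h], lapply(seq_len(n_img), function(j) dheads[[j]][[h]]), envir = dvals)
  }
  zero_like <- function(x) array(0, dim = dim(x))
  get_grad <- function(nm) {
    if (exists(nm, envir = dvals, inherits = FALSE)) {
      get(nm, envir = dvals)
    } else {
      lapply(get(nm, envir = values), zero_like)
    }
  }
  add_grad <- function(nm, g) {
    if (exists(nm, envir = dvals, inherits = FALSE)) {
      old <- get(nm, envir = dvals)
      assign(nm, map2(old, g, `+`), envir = dvals)
    } else {
      assign(nm, g, envir = dvals)
    }
  }

  for (i in rev(seq_len(nrow(graph)))) {
    row <- graph[i, ]
    nm <- row$name
    if (row$kind == "input") next
    if (!exists(nm, envir = dvals, inherits = FALSE)) next
    dy <- get(nm, envir = dvals)
    ins <- row$inputs[[1]]
    x <- get(ins[1], envir = values)
    switch(row$kind,
      conv = {
        p <- params[[nm]]
        pad <- row$kernel %/% 2L
        if (row$groups == 1L) {
          cols <- get(nm, envir = cache)
          res <- pmap(list(x, dy, cols), function(xx, dd, cc) {
            d <- dim(xx)
            conv2d_bwd_cols_cpp(cc, p$w, dd, row$kernel, row$stride, pad,
                                d[1], d[2], d[3], !is.null(p$b))
          })
          g <- list(w = Reduce(`+`, lapply(res, `[[`, "dw")))
          if (!is.null(p$b)) g$b <- Reduce(`+`, lapply(res, `[[`, "db"))
          grads[[nm]] <- g
          add_grad(ins[1], lapply(res, `[[`, "dx"))
        } else {
          res <- map2(x, dy, function(xx, dd) {
            dwconv_bwd_cpp(xx, p$w, dd, row$kernel, row$stride, pad)
          })
          grads[[nm]] <- list(w = Reduce(`+`, lapply(res, `[[`, "dw")))
          add_grad(ins[1], lapply(res, `[[`, "dx"))
        }
      },
      batchnorm = {
        res <- bn_train_bwd(get(nm, envir = cache), dy)
        grads[[nm]] <- list(gamma = res$dgamma, beta = res$dbeta)
        add_grad(ins[1], res$dxs)
      },
      activation = add_grad(ins[1], map2(x, dy, function(xx, dd) {
        activation_bwd(xx, dd, row$activation)
      })),
      maxpool = {
        idx <- get(nm, envir = cache)
        add_grad(ins[1], pmap(list(x, dy, idx), function(xx, dd, ii) {
          d <- dim(xx)
          maxpool_bwd_cpp(dd, ii, d[1], d[2], d[3])
        }))
      },
      upsample = add_grad(ins[1], lapply(dy, upsample2_bwd)),
      concat = {
        offsets <- cumsum(c(0, map_int(ins, function(b) {
          dim(get(b, envir = values)[[1]])[3]
        })))
        for (b in seq_along(ins)) {
          rng <- (offsets[b] + 1L):offsets[b + 1L]
          add_grad(ins[b], lapply(dy, function(dd) dd[, , rng, drop = FALSE]))
        }
      },
      add = {
        add_grad(ins[1], dy)
        add_grad(ins[2], dy)
      },
      slice = {
        add_grad(ins[1], map2(x, dy, function(xx, dd) {
          ch <- dim(xx)[3]
          out <- zero_like(xx)
          out[, , (ch %/% 2L + 1L):ch] <- dd
          out
        }))
      },
      se_scale = {
        p <- params[[nm]]
        caches <- get(nm, envir = cache)
        res <- map2(caches, dy, function(cc, dd) se_bwd(cc, dd, p))
        grads[[nm]] <- list(
          w1 = Reduce(`+`, lapply(res, `[[`, "dw1")),
          b1 = Reduce(`+`, lapply(res, `[[`, "db1")),
          w2 = Reduce(`+`, lapply(res, `[[`, "dw2")),
          b2 = Reduce(`+`, lapply(res, `[[`, "db2"))
        )
        add_grad(ins[1], lapply(res, `[[`, "dx"))
      },
      abort(sprintf("no backward rule for kind '%s'", row$kind))
    )
  }
  grads
}
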