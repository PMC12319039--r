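# Minimal CNN engine on BLAS matrix products.
#
# Networks are trees of plain-list nodes: every node has a `type`, a
# `params` list of numeric arrays, and (for containers) a `children` list.
# `nn_forward()` returns the output plus a cache tree; `nn_backward()`
# consumes the cache and returns the input gradient plus a gradient tree
# shaped exactly like the node tree, which `adam_update()` zips against the
# parameters. Activations are 4-d arrays (h, w, c, n) up to global pooling
# and (features, n) matrices after it.

nn_conv <- function(in_ch, out_ch, k, stride = 1L, pad = 0L, bias = TRUE) {
  fan_in <- k * k * in_ch
  W <- matrix(stats::rnorm(out_ch * fan_in, sd = sqrt(2 / fan_in)),
              nrow = out_ch)
  params <- list(W = W)
  if (bias) params$b <- numeric(out_ch)
  list(type = "conv", in_ch = in_ch, out_ch = out_ch, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad), params = params)
}

nn_dense <- function(in_dim, out_dim) {
  W <- matrix(stats::rnorm(out_dim * in_dim, sd = sqrt(2 / in_dim)),
              nrow = out_dim)
  list(type = "dense", params = list(W = W, b = numeric(out_dim)))
}

nn_relu <- function() list(type = "relu", params = list())
nn_sigmoid <- function() list(type = "sigmoid", params = list())
nn_gap <- function() list(type = "gap", params = list())
nn_dropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  list(type = "dropout", rate = rate, params = list())
}
nn_maxpool <- function(k = 2L, stride = k, pad = 0L) {
  list(type = "maxpool", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), params = list())
}

#' Squeeze-and-excitation layer constructor
#'
#' Channel attention: squeeze = per-channel global average; excitation = a
#' two-layer bottleneck MLP (`C -> C/r -> C`, rectifier then logistic) whose
#' outputs gate each channel multiplicatively in `(0, 1)`. Shape preserving.
#'
#' @param channels Number of input channels `C`.
#' @param reduction Bottleneck reduction ratio `r`; must divide `channels`.
#' @return An SE layer node usable in a network tree and with [se_block()].
#' @export
nn_se <- function(channels, reduction = 16L) {
  if (channels %% reduction != 0) {
    stop("channels (", channels, ") not divisible by reduction ratio (",
         reduction, ")")
  }
  mid <- channels %/% reduction
  list(type = "se", channels = channels, reduction = as.integer(reduction),
       pin_gates = FALSE,
       params = list(
         W1 = matrix(stats::rnorm(mid * channels, sd = sqrt(2 / channels)),
                     nrow = mid),
         b1 = numeric(mid),
         W2 = matrix(stats::rnorm(channels * mid, sd = sqrt(2 / mid)),
                     nrow = channels),
         b2 = numeric(channels)))
}

nn_seq <- function(...) {
  layers <- list(...)
  if (length(layers) == 1 && is.null(layers[[1]]$type)) layers <- layers[[1]]
  list(type = "seq", params = list(), children = layers)
}

# Residual unit: out = relu(body(x) + down(x)); `down` is NULL (identity
# skip) or a projection conv. The SE gate, when present, sits at the end of
# `body`, i.e. before the skip-addition.
nn_residual <- function(body, down = NULL) {
  list(type = "residual", params = list(),
       children = list(body = body, down = down))
}

# Batch normalization. Training mode normalizes with batch statistics;
# evaluation uses the stored running statistics (identity-initialized).
nn_bn <- function(channels, eps = 1e-5) {
  list(type = "bn", eps = eps,
       run_mean = numeric(channels), run_var = rep(1, channels),
       params = list(gamma = rep(1, channels), beta = numeric(channels)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- im2col ---------------------------------------------------------------

.im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(hp, wp, c, n, k, stride) {
  key <- paste(hp, wp, c, n, k, stride, sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  oh <- (hp - k) %/% stride + 1L
  ow <- (wp - k) %/% stride + 1L
  off <- as.vector(outer(1:k, (1:k - 1L) * hp, `+`))           # k*k
  off_c <- as.vector(outer(off, (0:(c - 1L)) * hp * wp, `+`))  # k*k*c
  start <- as.vector(outer(seq(1L, by = stride, length.out = oh),
                           (seq(0L, by = stride, length.out = ow)) * hp, `+`))
  start <- as.vector(outer(start, (0:(n - 1L)) * hp * wp * c, `+`))
  idx <- outer(off_c, start - 1L, `+`)  # 1-based linear indices
  storage.mode(idx) <- "integer"
  out <- list(idx = idx, oh = oh, ow = ow)
  # cache only moderate-sized index maps (repeated every minibatch)
  if (length(idx) <= 2e6) .im2col_cache[[key]] <- out
  out
}

pad_input <- function(x, pad, value = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(value, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[(pad + 1):(pad + d[1]), (pad + 1):(pad + d[2]), , ] <- x
  xp
}

# --- forward --------------------------------------------------------------

nn_forward <- function(node, x, train = FALSE) {
  switch(node$type,
    seq = {
      caches <- vector("list", length(node$children))
      for (i in seq_along(node$children)) {
        r <- nn_forward(node$children[[i]], x, train)
        x <- r$out
        caches[[i]] <- r$cache
      }
      list(out = x, cache = list(children = caches))
    },
    conv = {
      xp <- pad_input(x, node$pad)
      d <- dim(xp)
      ic <- im2col_index(d[1], d[2], d[3], d[4], node$k, node$stride)
      cols <- matrix(xp[ic$idx], nrow = node$k^2 * node$in_ch)
      out_mat <- node$params$W %*% cols
      if (!is.null(node$params$b)) out_mat <- out_mat + node$params$b
      out <- aperm(array(out_mat, c(node$out_ch, ic$oh, ic$ow, d[4])),
                   c(2, 3, 1, 4))
      list(out = out,
           cache = list(cols = cols, idx = ic$idx, dpad = d, dx_dim = dim(x)))
    },
    dense = {
      out <- node$params$W %*% x + node$params$b
      list(out = out, cache = list(x = x))
    },
    relu = {
      out <- x * (x > 0)
      list(out = out, cache = list(mask = x > 0))
    },
    sigmoid = {
      out <- sigmoid(x)
      list(out = out, cache = list(out = out))
    },
    gap = {
      d <- dim(x)
      out <- matrix(colMeans(matrix(x, nrow = d[1] * d[2])),
                    nrow = d[3], ncol = d[4])
      list(out = out, cache = list(d = d))
    },
    dropout = {
      if (!train || node$rate == 0) {
        list(out = x, cache = list(mask = NULL))
      } else {
        mask <- array(stats::runif(length(x)) >= node$rate, dim(x))
        list(out = x * mask / (1 - node$rate),
             cache = list(mask = mask))
      }
    },
    maxpool = {
      xp <- pad_input(x, node$pad, value = -Inf)
      d <- dim(xp)
      kk <- node$k^2
      ic <- im2col_index(d[1], d[2], d[3], d[4], node$k, node$stride)
      cols <- matrix(xp[ic$idx], nrow = kk * d[3])
      m <- matrix(array(cols, c(kk, d[3] * ncol(cols))), nrow = kk)
      am <- max.col(t(m), ties.method = "first")
      val <- m[cbind(am, seq_along(am))]
      # columns of m: channel fastest, then spatial/image position
      out <- aperm(array(val, c(d[3], ic$oh, ic$ow, d[4])), c(2, 3, 1, 4))
      list(out = out, cache = list(am = am, idx = ic$idx, dpad = d,
                                   dx_dim = dim(x), kk = kk))
    },
    bn = {
      d <- dim(x)
      xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
      if (train) {
        mu <- colMeans(xm)
        v <- colMeans(sweep(xm, 2, mu)^2)
      } else {
        mu <- node$run_mean
        v <- node$run_var
      }
      std <- sqrt(v + node$eps)
      xhat <- sweep(sweep(xm, 2, mu), 2, std, `/`)
      ym <- sweep(sweep(xhat, 2, node$params$gamma, `*`), 2,
                  node$params$beta, `+`)
      out <- aperm(array(ym, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
      list(out = out, cache = list(xhat = xhat, std = std, d = d))
    },
    se = {
      d <- dim(x)
      s <- matrix(colMeans(matrix(x, nrow = d[1] * d[2])),
                  nrow = d[3], ncol = d[4])
      z1 <- node$params$W1 %*% s + node$params$b1
      h1 <- z1 * (z1 > 0)
      g <- sigmoid(node$params$W2 %*% h1 + node$params$b2)
      if (isTRUE(node$pin_gates)) g[] <- 1
      gx <- array(rep(g, each = d[1] * d[2]), d)
      list(out = x * gx,
           cache = list(x = x, s = s, z1 = z1, h1 = h1, g = g, d = d))
    },
    residual = {
      body <- nn_forward(node$children$body, x, train)
      if (is.null(node$children$down)) {
        skip <- x
        down_cache <- NULL
      } else {
        r <- nn_forward(node$children$down, x, train)
        skip <- r$out
        down_cache <- r$cache
      }
      pre <- body$out + skip
      list(out = pre * (pre > 0),
           cache = list(body = body$cache, down = down_cache,
                        mask = pre > 0))
    },
    stop("unknown layer type: ", node$type)
  )
}

# --- backward -------------------------------------------------------------

nn_backward <- function(node, cache, dout) {
  switch(node$type,
    seq = {
      grads <- vector("list", length(node$children))
      for (i in rev(seq_along(node$children))) {
        r <- nn_backward(node$children[[i]], cache$children[[i]], dout)
        dout <- r$dx
        grads[[i]] <- r$grads
      }
      list(dx = dout, grads = list(children = grads))
    },
    conv = {
      n <- cache$dpad[4]
      dmat <- matrix(aperm(dout, c(3, 1, 2, 4)), nrow = node$out_ch)
      gW <- dmat %*% t(cache$cols)
      g <- list(W = gW)
      if (!is.null(node$params$b)) g$b <- rowSums(dmat)
      dcols <- crossprod(node$params$W, dmat)
      dxp <- col2im(dcols, cache$idx, prod(cache$dpad))
      dx <- unpad(dxp, cache$dpad, node$pad, cache$dx_dim)
      list(dx = dx, grads = list(params = g))
    },
    dense = {
      list(dx = crossprod(node$params$W, dout),
           grads = list(params = list(W = dout %*% t(cache$x),
                                      b = rowSums(dout))))
    },
    relu = list(dx = dout * cache$mask, grads = list()),
    sigmoid = list(dx = dout * cache$out * (1 - cache$out), grads = list()),
    gap = {
      d <- cache$d
      dx <- array(rep(dout / (d[1] * d[2]), each = d[1] * d[2]), d)
      list(dx = dx, grads = list())
    },
    dropout = {
      if (is.null(cache$mask)) list(dx = dout, grads = list())
      else list(dx = dout * cache$mask / (1 - node$rate), grads = list())
    },
    maxpool = {
      d <- cache$dpad
      dvec <- as.vector(aperm(dout, c(3, 1, 2, 4)))  # channel fastest
      kk <- cache$kk
      ncols_im2col <- dim(cache$idx)[2]
      # column j of the (kk, c*P) matrix maps to idx[(ch-1)*kk + am, p]
      j <- seq_along(cache$am)
      ch <- ((j - 1L) %% d[3]) + 1L
      p <- ((j - 1L) %/% d[3]) + 1L
      lin <- cache$idx[cbind((ch - 1L) * kk + cache$am, p)]
      dxp_vec <- numeric(prod(d))
      acc <- rowsum(dvec, group = lin)
      dxp_vec[as.integer(rownames(acc))] <- acc
      dxp <- array(dxp_vec, d)
      dx <- unpad(dxp, d, node$pad, cache$dx_dim)
      list(dx = dx, grads = list())
    },
    bn = {
      d <- cache$d
      dm <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = d[3])
      m <- nrow(dm)
      dgamma <- colSums(dm * cache$xhat)
      dbeta <- colSums(dm)
      dxhat <- sweep(dm, 2, node$params$gamma, `*`)
      dxm <- sweep(dxhat - matrix(colMeans(dxhat), m, d[3], byrow = TRUE) -
                     cache$xhat * matrix(colMeans(dxhat * cache$xhat),
                                         m, d[3], byrow = TRUE),
                   2, cache$std, `/`)
      dx <- aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
      list(dx = dx, grads = list(params = list(gamma = dgamma, beta = dbeta)))
    },
    se = {
      d <- cache$d
      hw <- d[1] * d[2]
      gx <- array(rep(cache$g, each = hw), d)
      dx1 <- dout * gx
      if (isTRUE(node$pin_gates)) {
        zero <- function(p) {p[] <- 0; p}
        return(list(dx = dx1,
                    grads = list(params = lapply(node$params, zero))))
      }
      dg <- matrix(colSums(matrix(dout * cache$x, nrow = hw)),
                   nrow = d[3], ncol = d[4])
      dz2 <- dg * cache$g * (1 - cache$g)
      gW2 <- dz2 %*% t(cache$h1)
      gb2 <- rowSums(dz2)
      dh1 <- crossprod(node$params$W2, dz2) * (cache$z1 > 0)
      gW1 <- dh1 %*% t(cache$s)
      gb1 <- rowSums(dh1)
      ds <- crossprod(node$params$W1, dh1)
      dx2 <- array(rep(ds / hw, each = hw), d)
      list(dx = dx1 + dx2,
           grads = list(params = list(W1 = gW1, b1 = gb1,
                                      W2 = gW2, b2 = gb2)))
    },
    residual = {
      dpre <- dout * cache$mask
      body <- nn_backward(node$children$body, cache$body, dpre)
      if (is.null(node$children$down)) {
        dskip <- dpre
        down_grads <- NULL
      } else {
        r <- nn_backward(node$children$down, cache$down, dpre)
        dskip <- r$dx
        down_grads <- r$grads
      }
      list(dx = body$dx + dskip,
           grads = list(children = list(body = body$grads,
                                        down = down_grads)))
    },
    stop("unknown layer type: ", node$type)
  )
}

col2im <- function(dcols, idx, total_len) {
  out <- numeric(total_len)
  # for a fixed kernel offset (row) every output position reads a distinct
  # input pixel, so each row can be scattered with a plain vectorized add
  for (r in seq_len(nrow(idx))) {
    ii <- idx[r, ]
    out[ii] <- out[ii] + dcols[r, ]
  }
  out
}

unpad <- function(dxp, dpad, pad, dx_dim) {
  dxp <- array(dxp, dpad)
  if (pad == 0L) return(array(dxp, dx_dim))
  dxp[(pad + 1):(pad + dx_dim[1]), (pad + 1):(pad + dx_dim[2]), , ,
      drop = FALSE]
}

# --- parameter updates ----------------------------------------------------

adam_init <- function(node) {
  st <- list()
  if (length(node$params) > 0) {
    st$params <- lapply(node$params, function(p) {
      list(m = array(0, dim(p) %||% length(p)),
           v = array(0, dim(p) %||% length(p)))
    })
  }
  if (!is.null(node$children)) {
    st$children <- lapply(node$children, function(ch) {
      if (is.null(ch)) NULL else adam_init(ch)
    })
  }
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_update <- function(node, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (length(node$params) > 0 && !is.null(grads$params)) {
    for (nm in names(node$params)) {
      g <- grads$params[[nm]]
      s <- state$params[[nm]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      mhat <- s$m / (1 - beta1^t)
      vhat <- s$v / (1 - beta2^t)
      upd <- node$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      dim(upd) <- dim(node$params[[nm]])  # keep plain vectors dimensionless
      node$params[[nm]] <- upd
      state$params[[nm]] <- s
    }
  }
  if (!is.null(node$children)) {
    for (nm in names(node$children) %||% seq_along(node$children)) {
      if (is.null(node$children[[nm]])) next
      r <- adam_update(node$children[[nm]], grads$children[[nm]],
                       state$children[[nm]], lr, t, beta1, beta2, eps)
      node$children[[nm]] <- r$node
      state$children[[nm]] <- r$state
    }
  }
  list(node = node, state = state)
}

sgd_update <- function(node, grads, state, lr, momentum = 0.9) {
  if (length(node$params) > 0 && !is.null(grads$params)) {
    for (nm in names(node$params)) {
      vel <- state$params[[nm]]$m
      vel <- momentum * vel - lr * grads$params[[nm]]
      upd <- node$params[[nm]] + vel
      dim(upd) <- dim(node$params[[nm]])
      node$params[[nm]] <- upd
      state$params[[nm]]$m <- vel
    }
  }
  if (!is.null(node$children)) {
    for (nm in names(node$children) %||% seq_along(node$children)) {
      if (is.null(node$children[[nm]])) next
      r <- sgd_update(node$children[[nm]], grads$children[[nm]],
                      state$children[[nm]], lr, momentum)
      node$children[[nm]] <- r$node
      state$children[[nm]] <- r$state
    }
  }
  list(node = node, state = state)
}

# element-wise sum of two gradient trees of identical shape
tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (!is.null(a$params)) {
    for (nm in names(a$params)) a$params[[nm]] <- a$params[[nm]] + b$params[[nm]]
  }
  if (!is.null(a$children)) {
    for (i in seq_along(a$children)) {
      a$children[[i]] <- tree_add(a$children[[i]], b$children[[i]])
    }
  }
  a
}

# walk a node tree, applying f to every node (f returns the modified node)
tree_map <- function(node, f) {
  node <- f(node)
  if (!is.null(node$children)) {
    node$children <- lapply(node$children, function(ch) {
      if (is.null(ch)) NULL else tree_map(ch, f)
    })
  }
  node
}

nn_count_params <- function(node) {
  n <- sum(vapply(node$params, length, 1L))
  if (!is.null(node$children)) {
    n <- n + sum(vapply(node$children, function(ch) {
      if (is.null(ch)) 0L else nn_count_params(ch)
    }, 1L))
  }
  n
}

#' Apply a squeeze-and-excitation block to a feature map
#'
#' Functional form of the SE layer: squeeze (global average per channel),
#' excite (two-layer bottleneck MLP with rectifier then logistic), and
#' channel-wise rescaling of the input by the resulting gates. With
#' `pin_gates = TRUE` every gate is forced to 1 and the block is the
#' identity.
#'
#' @param features `(h, w, c)` or `(h, w, c, n)` array.
#' @param layer An SE layer from [nn_se()]; `layer$channels` must equal the
#'   feature-map channel count.
#' @param pin_gates Force all gates to 1 (default `FALSE`).
#' @return Array of the same shape as `features`.
#' @export
se_block <- function(features, layer, pin_gates = FALSE) {
  d <- dim(features)
  squeeze3 <- length(d) == 3L
  if (squeeze3) {
    dim(features) <- c(d, 1L)
  }
  if (dim(features)[3] != layer$channels) {
    stop("feature map has ", dim(features)[3], " channels; SE layer expects ",
         layer$channels)
  }
  layer$pin_gates <- pin_gates
  out <- nn_forward(layer, features, train = FALSE)$out
  if (squeeze3) dim(out) <- d
  out
}
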