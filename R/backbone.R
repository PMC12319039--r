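# Embedding backbones. `se_resnet50` is the full-depth residual network
# with a squeeze-and-excitation gate at the end of every bottleneck body
# (applied before the skip-addition); `resnet50` is the same network with
# the SE layers removed. The `*_tiny` variants keep the architecture --
# stem, SE-gated bottleneck units, global pooling, two fully connected
# layers -- at a depth and width suited to small synthetic crops.

bottleneck_unit <- function(in_ch, mid_ch, out_ch, stride = 1L, se = FALSE,
                            reduction = 16L, use_bn = TRUE) {
  bias <- !use_bn
  layers <- list(nn_conv(in_ch, mid_ch, 1L, bias = bias))
  if (use_bn) layers <- c(layers, list(nn_bn(mid_ch)))
  layers <- c(layers, list(nn_relu(),
                           nn_conv(mid_ch, mid_ch, 3L, stride = stride,
                                   pad = 1L, bias = bias)))
  if (use_bn) layers <- c(layers, list(nn_bn(mid_ch)))
  layers <- c(layers, list(nn_relu(),
                           nn_conv(mid_ch, out_ch, 1L, bias = bias)))
  if (use_bn) layers <- c(layers, list(nn_bn(out_ch)))
  if (se) layers <- c(layers, list(nn_se(out_ch, reduction)))
  down <- NULL
  if (stride != 1L || in_ch != out_ch) {
    down <- nn_seq(list(nn_conv(in_ch, out_ch, 1L, stride = stride,
                                bias = bias)))
  }
  nn_residual(nn_seq(layers), down)
}

resnet_stage <- function(in_ch, mid_ch, out_ch, n_units, stride, se,
                         reduction, use_bn) {
  units <- vector("list", n_units)
  units[[1]] <- bottleneck_unit(in_ch, mid_ch, out_ch, stride, se,
                                reduction, use_bn)
  for (i in seq_len(n_units - 1)) {
    units[[i + 1]] <- bottleneck_unit(out_ch, mid_ch, out_ch, 1L, se,
                                      reduction, use_bn)
  }
  units
}

#' Build an embedding backbone
#'
#' Constructs the feature-extraction network of the Siamese scorer: a
#' convolutional stem, stacks of residual bottleneck units (with an SE gate
#' inside every unit for the `se_*` variants), global average pooling, and
#' two fully connected layers producing a fixed-length embedding. With all
#' SE gates pinned to 1 (see [pin_se_gates()]) the `se_*` forward pass is
#' numerically identical to the plain variant at the same weights.
#'
#' Weight initialization draws from the current RNG stream; seed it (e.g.
#' via [build_siamese()]) for reproducible models.
#'
#' @param cfg A [siamese_config()]; `cfg$backbone` selects among
#'   `"se_resnet50"`, `"resnet50"`, `"se_resnet_tiny"`, `"resnet_tiny"`.
#' @return A network node tree whose forward pass maps
#'   `(side, side, 3, n)` image batches to `(embedding_dim, n)` embeddings.
#' @export
build_backbone <- function(cfg) {
  se <- grepl("^se_", cfg$backbone)
  base <- sub("^se_", "", cfg$backbone)
  r <- cfg$reduction_ratio
  if (base == "resnet50") {
    stem <- list(nn_conv(3L, 64L, 7L, stride = 2L, pad = 3L, bias = FALSE),
                 nn_bn(64L), nn_relu(), nn_maxpool(3L, 2L, pad = 1L))
    stages <- c(
      resnet_stage(64L, 64L, 256L, 3L, 1L, se, r, TRUE),
      resnet_stage(256L, 128L, 512L, 4L, 2L, se, r, TRUE),
      resnet_stage(512L, 256L, 1024L, 6L, 2L, se, r, TRUE),
      resnet_stage(1024L, 512L, 2048L, 3L, 2L, se, r, TRUE)
    )
    feat_dim <- 2048L
    hidden <- 512L
  } else if (base == "resnet_tiny") {
    stem <- list(nn_conv(3L, 16L, 3L, pad = 1L), nn_relu(), nn_maxpool(2L))
    stages <- list(
      bottleneck_unit(16L, 8L, 32L, 2L, se, r, use_bn = FALSE),
      bottleneck_unit(32L, 12L, 48L, 2L, se, r, use_bn = FALSE)
    )
    feat_dim <- 48L
    hidden <- 64L
  } else {
    stop("unknown backbone: ", cfg$backbone)
  }
  nn_seq(c(stem, stages,
           list(nn_gap(), nn_dense(feat_dim, hidden), nn_relu(),
                nn_dense(hidden, cfg$embedding_dim))))
}

#' Pin every squeeze-and-excitation gate to 1
#'
#' Returns the network with all SE gates forced to unity, which reduces the
#' SE variant to its plain counterpart exactly.
#'
#' @param net A network node tree (or [build_siamese()] model).
#' @return The modified network/model.
#' @export
pin_se_gates <- function(net) {
  if (inherits(net, "siamese_model")) {
    net$backbone <- pin_se_gates(net$backbone)
    return(net)
  }
  tree_map(net, function(node) {
    if (node$type == "se") node$pin_gates <- TRUE
    node
  })
}

#' Remove squeeze-and-excitation layers from a network
#'
#' Drops SE layers wherever they occur, leaving every other layer and its
#' weights untouched: applied to an `se_resnet*` backbone this yields the
#' corresponding plain `resnet*` at identical weights.
#'
#' @param net A network node tree.
#' @return The network without SE layers.
#' @export
strip_se <- function(net) {
  if (net$type == "seq") {
    kept <- Filter(function(ch) ch$type != "se", net$children)
    net$children <- lapply(kept, strip_se)
  } else if (!is.null(net$children)) {
    net$children <- lapply(net$children, function(ch) {
      if (is.null(ch)) NULL else strip_se(ch)
    })
  }
  net
}
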