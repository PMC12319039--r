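#' Configuration of the Siamese similarity network
#'
#' Defaults follow the tuned verification setup: 105x105 inputs, dropout
#' 0.2 in the verification head, batch size 32, Adam with learning rate
#' 1e-3. The `*_tiny` backbones default to a narrower embedding and a
#' smaller SE reduction ratio so every channel count stays divisible.
#'
#' @param input_side Crop side length in pixels (default 105).
#' @param backbone One of `"se_resnet50"`, `"resnet50"`, `"se_resnet_tiny"`,
#'   `"resnet_tiny"`.
#' @param dropout_rate Dropout between the two head layers, in `[0, 1)`.
#' @param batch_size Pairs per optimization step.
#' @param learning_rate Optimizer step size.
#' @param optimizer `"adam"` or `"sgd"` (momentum 0.9).
#' @param momentum SGD momentum.
#' @param epochs Training epochs (>= 0).
#' @param embedding_dim Embedding length (default 256; 32 for tiny
#'   backbones).
#' @param reduction_ratio SE bottleneck ratio (default 16; 4 for tiny
#'   backbones).
#' @param head_hidden Width of the first verification-head layer.
#' @param seed Integer seed for weight init, shuffling and dropout.
#' @return An object of class `siamese_config`.
#' @export
siamese_config <- function(input_side = 105L, backbone = "se_resnet50",
                           dropout_rate = 0.2, batch_size = 32L,
                           learning_rate = 1e-3,
                           optimizer = c("adam", "sgd"), momentum = 0.9,
                           epochs = 10L, embedding_dim = NULL,
                           reduction_ratio = NULL, head_hidden = 64L,
                           seed = 1L) {
  optimizer <- match.arg(optimizer)
  tiny <- grepl("tiny", backbone)
  if (is.null(embedding_dim)) embedding_dim <- if (tiny) 32L else 256L
  if (is.null(reduction_ratio)) reduction_ratio <- if (tiny) 4L else 16L
  stopifnot(input_side >= 8, dropout_rate >= 0, dropout_rate < 1,
            batch_size >= 1, learning_rate > 0, epochs >= 0)
  structure(list(input_side = as.integer(input_side), backbone = backbone,
                 dropout_rate = dropout_rate,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 momentum = momentum, epochs = as.integer(epochs),
                 embedding_dim = as.integer(embedding_dim),
                 reduction_ratio = as.integer(reduction_ratio),
                 head_hidden = as.integer(head_hidden),
                 seed = as.integer(seed)),
            class = "siamese_config")
}

#' Build a Siamese similarity model
#'
#' The two branches are one shared network by construction (a single weight
#' tree applied to both inputs). The verification head is a logistic
#' classifier on the element-wise absolute difference of the two
#' embeddings: `dense -> relu -> dropout -> dense -> logistic`, so the
#' similarity score is symmetric in its two arguments by construction.
#'
#' @param cfg A [siamese_config()].
#' @return An object of class `siamese_model`.
#' @export
build_siamese <- function(cfg = siamese_config()) {
  stopifnot(inherits(cfg, "siamese_config"))
  with_seed(cfg$seed, {
    backbone <- build_backbone(cfg)
    head <- nn_seq(list(nn_dense(cfg$embedding_dim, cfg$head_hidden),
                        nn_relu(), nn_dropout(cfg$dropout_rate),
                        nn_dense(cfg$head_hidden, 1L)))
    structure(list(backbone = backbone, head = head, cfg = cfg),
              class = "siamese_model")
  })
}

#' @export
print.siamese_model <- function(x, ...) {
  cat(sprintf("<siamese_model> backbone %s, %d+%d parameters, input %dx%d\n",
              x$cfg$backbone, nn_count_params(x$backbone),
              nn_count_params(x$head), x$cfg$input_side, x$cfg$input_side))
  invisible(x)
}

stack_crops <- function(crops, side) {
  n <- length(crops)
  x <- array(0, c(side, side, 3L, n))
  for (i in seq_len(n)) {
    ci <- crops[[i]]
    if (!identical(dim(ci)[1:2], c(side, side))) {
      stop("crop ", i, " is ", paste(dim(ci)[1:2], collapse = "x"),
           "; model expects ", side, "x", side)
    }
    x[, , , i] <- ci
  }
  x
}

#' Embed crops with the shared backbone
#'
#' @param model A [build_siamese()] model.
#' @param crops List of `(side, side, 3)` crops.
#' @return `(embedding_dim, n)` matrix of embeddings.
#' @export
embed_crops <- function(model, crops) {
  x <- stack_crops(crops, model$cfg$input_side)
  nn_forward(model$backbone, x, train = FALSE)$out
}

head_scores <- function(model, diffs, train = FALSE) {
  logits <- nn_forward(model$head, diffs, train = train)$out
  as.numeric(sigmoid(logits))
}

#' Similarity score of two crops
#'
#' Logistic output of the verification head applied to `|e(a) - e(b)|`.
#' Exactly symmetric (`similarity(a, b) == similarity(b, a)`) and
#' deterministic in evaluation mode.
#'
#' @param model A [build_siamese()] model.
#' @param crop_a,crop_b `(side, side, 3)` crops at the configured input
#'   side.
#' @return Score in `[0, 1]`.
#' @export
similarity <- function(model, crop_a, crop_b) {
  e <- embed_crops(model, list(crop_a, crop_b))
  d <- abs(e[, 1] - e[, 2])
  head_scores(model, matrix(d, ncol = 1))
}

#' Pairwise similarity matrix between two detection sets
#'
#' Generic over the scorer. For a `siamese_model` the detections must carry
#' crops (see [attach_crops()]); each crop is embedded once and all
#' `|f| x |p|` pairs are scored through the head. For the identity oracle
#' ([oracle_similarity()]) scores come from the true pod identities.
#'
#' @param model Scorer: `siamese_model`, `oracle_model`, or a function
#'   `(crop_a, crop_b) -> score`.
#' @param front,rear [pod_set()]s of the two views (rear mirror-aligned).
#' @return `nrow(front) x nrow(rear)` matrix of scores in `[0, 1]`.
#' @export
similarity_matrix <- function(model, front, rear) {
  UseMethod("similarity_matrix")
}

#' @export
similarity_matrix.siamese_model <- function(model, front, rear) {
  cf <- attr(front, "crops")
  cr <- attr(rear, "crops")
  if (is.null(cf) || is.null(cr)) {
    stop("pod sets must carry crops; call attach_crops() first")
  }
  nf <- length(cf)
  np <- length(cr)
  if (nf == 0 || np == 0) return(matrix(numeric(0), nf, np))
  e <- embed_crops(model, c(cf, cr))
  ef <- e[, seq_len(nf), drop = FALSE]
  ep <- e[, nf + seq_len(np), drop = FALSE]
  d <- abs(ef[, rep(seq_len(nf), times = np), drop = FALSE] -
             ep[, rep(seq_len(np), each = nf), drop = FALSE])
  matrix(head_scores(model, d), nrow = nf, ncol = np)
}

#' @export
similarity_matrix.function <- function(model, front, rear) {
  cf <- attr(front, "crops")
  cr <- attr(rear, "crops")
  out <- matrix(0, length(cf), length(cr))
  for (i in seq_along(cf)) {
    for (j in seq_along(cr)) out[i, j] <- model(cf[[i]], cr[[j]])
  }
  out
}

#' Identity-oracle similarity scorer
#'
#' Test stand-in for a trained model: score 1 iff two detections share the
#' true pod identity, 0 otherwise. Isolates the matching stage from the
#' learned scorer.
#'
#' @return An object of class `oracle_model`.
#' @export
oracle_similarity <- function() {
  structure(list(), class = "oracle_model")
}

#' @export
similarity_matrix.oracle_model <- function(model, front, rear) {
  if (anyNA(front$pod_id) || anyNA(rear$pod_id)) {
    stop("oracle similarity needs pod identities on both pod sets")
  }
  outer(front$pod_id, rear$pod_id, `==`) * 1
}

#' Train the Siamese model on labeled crop pairs
#'
#' Minimizes binary cross-entropy of the similarity score against the
#' same-class label over seeded shuffled minibatches, updating the shared
#' backbone (gradients from both branches summed) and the head. Pair
#' accuracy is the fraction of pairs with `(score > 0.5) == label`.
#'
#' @param model A [build_siamese()] model.
#' @param crops List of crops indexed by `pairs$i` / `pairs$j`.
#' @param pairs Data frame from [sample_pairs()]: columns `i`, `j`,
#'   `label` in {0, 1}.
#' @param cfg Training configuration; defaults to `model$cfg`.
#' @param val_pairs Optional held-out pair data frame for per-epoch
#'   validation accuracy.
#' @param verbose Print one line per epoch.
#' @return List with the trained `model` and a `history` data frame
#'   (epoch, loss, train_acc, val_acc).
#' @export
train_pairs <- function(model, crops, pairs, cfg = model$cfg,
                        val_pairs = NULL, verbose = FALSE) {
  stopifnot(nrow(pairs) >= 1, all(pairs$label %in% 0:1))
  if (length(unique(pairs$label)) < 2) {
    warning("degenerate pair labels: only one class present")
  }
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     train_acc = numeric(0), val_acc = numeric(0))
  if (cfg$epochs == 0) return(list(model = model, history = hist))
  side <- cfg$input_side
  with_seed(cfg$seed, {
    st_b <- adam_init(model$backbone)
    st_h <- adam_init(model$head)
    t <- 0L
    for (ep in seq_len(cfg$epochs)) {
      perm <- sample.int(nrow(pairs))
      ep_loss <- 0
      ep_hits <- 0L
      for (b0 in seq(1, nrow(pairs), by = cfg$batch_size)) {
        bi <- perm[b0:min(b0 + cfg$batch_size - 1, nrow(pairs))]
        y <- pairs$label[bi]
        xa <- stack_crops(crops[pairs$i[bi]], side)
        xb <- stack_crops(crops[pairs$j[bi]], side)
        fa <- nn_forward(model$backbone, xa, train = TRUE)
        fb <- nn_forward(model$backbone, xb, train = TRUE)
        diff <- fa$out - fb$out
        d <- abs(diff)
        hd <- nn_forward(model$head, d, train = TRUE)
        p <- sigmoid(as.numeric(hd$out))
        eps <- 1e-12
        ep_loss <- ep_loss -
          sum(y * log(p + eps) + (1 - y) * log(1 - p + eps))
        ep_hits <- ep_hits + sum((p > 0.5) == (y == 1))
        dlogit <- matrix((p - y) / length(bi), nrow = 1)
        bh <- nn_backward(model$head, hd$cache, dlogit)
        dd <- bh$dx * sign(diff)
        ba <- nn_backward(model$backbone, fa$cache, dd)
        bb <- nn_backward(model$backbone, fb$cache, -dd)
        gb <- tree_add(ba$grads, bb$grads)
        t <- t + 1L
        if (cfg$optimizer == "adam") {
          ub <- adam_update(model$backbone, gb, st_b, cfg$learning_rate, t)
          uh <- adam_update(model$head, bh$grads, st_h, cfg$learning_rate, t)
        } else {
          ub <- sgd_update(model$backbone, gb, st_b, cfg$learning_rate,
                           cfg$momentum)
          uh <- sgd_update(model$head, bh$grads, st_h, cfg$learning_rate,
                           cfg$momentum)
        }
        model$backbone <- ub$node
        st_b <- ub$state
        model$head <- uh$node
        st_h <- uh$state
      }
      va <- if (is.null(val_pairs)) NA_real_ else
        pair_accuracy(model, crops, val_pairs)
      hist <- rbind(hist, data.frame(
        epoch = ep, loss = ep_loss / nrow(pairs),
        train_acc = ep_hits / nrow(pairs), val_acc = va))
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f train_acc %.3f val_acc %s",
                        ep, hist$loss[ep], hist$train_acc[ep],
                        ifelse(is.na(va), "-", sprintf("%.3f", va))))
      }
    }
  })
  list(model = model, history = hist)
}

#' Score labeled pairs and compute pair accuracy
#'
#' @inheritParams train_pairs
#' @return `pair_scores()`: numeric scores; `pair_accuracy()`: fraction of
#'   pairs classified correctly at the 0.5 threshold.
#' @export
pair_scores <- function(model, crops, pairs) {
  e <- embed_crops(model, crops)
  d <- abs(e[, pairs$i, drop = FALSE] - e[, pairs$j, drop = FALSE])
  head_scores(model, d)
}

#' @rdname pair_scores
#' @export
pair_accuracy <- function(model, crops, pairs) {
  s <- pair_scores(model, crops, pairs)
  mean((s > 0.5) == (pairs$label == 1))
}

#' Nearest-prototype confusion matrix over the four pod classes
#'
#' Each class contributes `n_ref` reference crops (seeded draw); every
#' remaining crop is assigned the class whose references it is most similar
#' to on average. Ties go to the lowest class index. Rows are true classes,
#' columns predictions, so row sums equal per-class query counts.
#'
#' @param model A `siamese_model` or a scorer function
#'   `(crop_a, crop_b) -> score`.
#' @param crops List of labeled crops.
#' @param labels True class per crop (1..4).
#' @param n_ref Reference crops per class (default 3).
#' @param seed Seed for the reference draw.
#' @return 4x4 integer matrix.
#' @export
evaluate_confusion <- function(model, crops, labels, n_ref = 3L, seed = 1L) {
  stopifnot(length(crops) == length(labels))
  by_class <- split(seq_along(labels), factor(labels, levels = 1:4))
  if (any(vapply(by_class, length, 1L) <= n_ref)) {
    stop("every class needs more than n_ref crops ",
         "(references plus at least one query)")
  }
  with_seed(seed, {
    refs <- lapply(by_class, function(ix) sample(ix, n_ref))
    query <- setdiff(seq_along(labels), unlist(refs))
    score_block <- function(qi, ri) {
      if (inherits(model, "siamese_model")) {
        e <- embed_crops(model, crops[c(qi, ri)])
        nq <- length(qi)
        eq <- e[, seq_len(nq), drop = FALSE]
        er <- e[, nq + seq_along(ri), drop = FALSE]
        d <- abs(eq[, rep(seq_len(nq), times = length(ri)), drop = FALSE] -
                   er[, rep(seq_along(ri), each = nq), drop = FALSE])
        matrix(head_scores(model, d), nrow = nq)
      } else {
        out <- matrix(0, length(qi), length(ri))
        for (a in seq_along(qi)) {
          for (b in seq_along(ri)) {
            out[a, b] <- model(crops[[qi[a]]], crops[[ri[b]]])
          }
        }
        out
      }
    }
    mean_sim <- sapply(1:4, function(cl) {
      rowMeans(score_block(query, refs[[cl]]))
    })
    mean_sim <- matrix(mean_sim, nrow = length(query))
    pred <- apply(mean_sim, 1, which.max)  # first max: lowest class wins ties
    cm <- matrix(0L, 4, 4,
                 dimnames = list(truth = pod_class_labels,
                                 predicted = pod_class_labels))
    for (q in seq_along(query)) {
      cm[labels[query[q]], pred[q]] <- cm[labels[query[q]], pred[q]] + 1L
    }
    cm
  })
}

#' Read a Siamese training configuration from YAML
#'
#' The YAML keys are the arguments of [siamese_config()].
#'
#' @param path YAML file.
#' @return A `siamese_config`.
#' @export
siamese_config_from_yaml <- function(path) {
  do.call(siamese_config, yaml::read_yaml(path))
}

#' Save / load a Siamese model checkpoint
#'
#' Checkpoints use R's native serialization (RDS).
#'
#' @param model A `siamese_model`.
#' @param path Checkpoint file path.
#' @return `path` invisibly; `load_siamese()` returns the model.
#' @export
save_siamese <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_siamese
#' @export
load_siamese <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "siamese_model"))
  model
}
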