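test_that("SE block matches a hand-rolled squeeze/excite computation", {
  set.seed(12)
  layer <- nn_se(8L, 2L)
  x <- array(stats::rnorm(5 * 6 * 8), c(5, 6, 8))
  out <- se_block(x, layer)
  # independent re-implementation with explicit loops
  s <- vapply(1:8, function(c) mean(x[, , c]), numeric(1))
  z1 <- as.vector(layer$params$W1 %*% s + layer$params$b1)
  h1 <- pmax(z1, 0)
  g <- 1 / (1 + exp(-(as.vector(layer$params$W2 %*% h1 + layer$params$b2))))
  expected <- x
  for (c in 1:8) expected[, , c] <- x[, , c] * g[c]
  expect_equal(out, expected)
  expect_true(all(g > 0 & g < 1))
  # constant channel scales to gate * value
  xc <- x
  xc[, , 3] <- 0.7
  oc <- se_block(xc, layer)
  expect_true(diff(range(oc[, , 3])) < 1e-12)
  # pinned gates give the identity
  expect_equal(se_block(x, layer, pin_gates = TRUE), x)
  expect_error(nn_se(8L, 3L), "divisible")
  expect_error(se_block(array(0, c(4, 4, 6)), layer), "channels")
})

test_that("backbones produce fixed-length embeddings with shared weights", {
  model <- tiny_model(seed = 6, side = 16)
  expect_equal(model$cfg$embedding_dim, 32L)
  crop <- const_crop(0.4)
  e <- embed_crops(model, list(crop, crop))
  expect_equal(dim(e), c(32L, 2L))
  # the two branches are one network: identical inputs embed identically
  expect_equal(e[, 1], e[, 2])
  expect_error(
    build_backbone(siamese_config(backbone = "resnet18", input_side = 16)),
    "unknown backbone")
})

test_that("pinning SE gates reduces the SE network to the plain one", {
  cfg <- siamese_config(backbone = "se_resnet_tiny", input_side = 16,
                        seed = 31)
  model <- build_siamese(cfg)
  set.seed(77)
  crops <- lapply(1:3, function(i) array(stats::runif(16 * 16 * 3),
                                         c(16, 16, 3)))
  pinned <- pin_se_gates(model)
  plain <- model
  plain$backbone <- strip_se(model$backbone)
  e1 <- embed_crops(pinned, crops)
  e2 <- embed_crops(plain, crops)
  expect_equal(max(abs(e1 - e2)), 0)
  # and the unpinned SE network genuinely differs
  e3 <- embed_crops(model, crops)
  expect_gt(max(abs(e3 - e2)), 0)
})

test_that("similarity is symmetric, self-constant, and 0.5 for a zero head", {
  model <- tiny_model(seed = 9)
  set.seed(3)
  crops <- lapply(1:4, function(i) array(stats::runif(16 * 16 * 3),
                                         c(16, 16, 3)))
  for (i in 1:3) {
    s_ab <- similarity(model, crops[[i]], crops[[i + 1]])
    s_ba <- similarity(model, crops[[i + 1]], crops[[i]])
    expect_identical(s_ab, s_ba)
    expect_true(s_ab >= 0 && s_ab <= 1)
  }
  # self-similarity is the head at the zero vector, the same for every crop
  selfs <- vapply(crops, function(cr) similarity(model, cr, cr), numeric(1))
  expect_equal(max(selfs) - min(selfs), 0)
  # zeroed head weights: logistic(0) = 0.5 for all pairs
  z <- model
  z$head$children[[4]]$params$W[] <- 0
  z$head$children[[4]]$params$b[] <- 0
  expect_equal(similarity(z, crops[[1]], crops[[2]]), 0.5)
  expect_error(similarity(model, const_crop(0.2, 32), const_crop(0.2, 32)),
               "expects")
})

test_that("training leaves the model untouched at 0 epochs and is seeded", {
  model <- tiny_model(seed = 2)
  crops <- c(lapply(1:4, function(i) const_crop(i / 5)),
             lapply(1:4, function(i) const_crop(i / 5 + 0.02)))
  labels <- rep(1:4, 2)
  pairs <- sample_pairs(labels, 12, 0.5, seed = 1)
  cfg0 <- model$cfg
  cfg0$epochs <- 0L
  fit0 <- train_pairs(model, crops, pairs, cfg0)
  expect_identical(fit0$model, model)
  expect_equal(nrow(fit0$history), 0)
  cfg2 <- model$cfg
  cfg2$epochs <- 2L
  fit_a <- train_pairs(model, crops, pairs, cfg2)
  fit_b <- train_pairs(model, crops, pairs, cfg2)
  expect_identical(fit_a$model, fit_b$model)
  expect_identical(fit_a$history, fit_b$history)
  expect_warning(
    train_pairs(model, crops, data.frame(i = c(1, 1), j = c(2, 3),
                                         label = c(1L, 1L)), cfg0),
    "degenerate")
})

test_that("training separates a trivially separable pair task", {
  # same-class crops are pixel-identical (difference vector exactly zero),
  # different-class crops differ strongly: the separable limit
  crops <- c(lapply(c(0.1, 0.4, 0.7, 0.95), const_crop),
             lapply(c(0.1, 0.4, 0.7, 0.95), const_crop))
  labels <- rep(1:4, 2)
  pairs <- sample_pairs(labels, 60, 0.5, seed = 3)
  cfg <- siamese_config(backbone = "se_resnet_tiny", input_side = 16,
                        epochs = 25, batch_size = 16, dropout_rate = 0,
                        seed = 8)
  fit <- train_pairs(build_siamese(cfg), crops, pairs, cfg)
  expect_equal(fit$history$train_acc[cfg$epochs], 1.0)
  expect_true(all(diff(fit$history$loss[c(1, cfg$epochs)]) < 0))
})

test_that("confusion matrix conserves queries and breaks ties low", {
  crops <- unlist(lapply(1:4, function(cl) {
    lapply(1:6, function(i) const_crop(cl / 5 + i / 1000))
  }), recursive = FALSE)
  labels <- rep(1:4, each = 6)
  # perfect oracle: score 1 iff the class-coding constants are close
  oracle <- function(a, b) as.numeric(abs(a[1, 1, 1] - b[1, 1, 1]) < 0.05)
  cm <- evaluate_confusion(oracle, crops, labels, n_ref = 3, seed = 5)
  expect_equal(cm, diag(3L, 4) + 0L, ignore_attr = TRUE)
  # all-constant similarity: every tie resolves to class one
  flat <- function(a, b) 0.5
  cm2 <- evaluate_confusion(flat, crops, labels, n_ref = 3, seed = 5)
  expect_equal(unname(colSums(cm2)), c(12, 0, 0, 0))
  expect_equal(unname(rowSums(cm2)), rep(3, 4))
  # row sums equal per-class query counts for a real model too
  model <- tiny_model(seed = 4)
  cm3 <- evaluate_confusion(model, crops, labels, n_ref = 3, seed = 5)
  expect_equal(unname(rowSums(cm3)), rep(3, 4))
  expect_error(evaluate_confusion(model, crops[1:10], labels[1:10],
                                  n_ref = 3),
               "class needs")
})

test_that("checkpoints and YAML configs round-trip", {
  model <- tiny_model(seed = 13)
  f <- tempfile(fileext = ".rds")
  save_siamese(model, f)
  back <- load_siamese(f)
  expect_identical(back, model)
  y <- tempfile(fileext = ".yaml")
  writeLines(c("backbone: se_resnet_tiny", "input_side: 16", "epochs: 3",
               "seed: 7"), y)
  cfg <- siamese_config_from_yaml(y)
  expect_s3_class(cfg, "siamese_config")
  expect_equal(cfg$epochs, 3L)
  expect_equal(cfg$reduction_ratio, 4L)
})
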