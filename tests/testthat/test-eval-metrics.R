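test_that("iou matches the pixel-set oracle and its closed forms", {
  b <- bounding_box(0, 0, 10, 10)
  expect_equal(iou(b, b), 1)
  expect_equal(iou(b, bounding_box(20, 20, 30, 30)), 0)
  expect_equal(iou(b, bounding_box(5, 0, 15, 10)), 1 / 3)

  # exhaustive over every box pair in a 4x4 grid
  grid <- 4
  boxes <- list()
  for (x0 in 0:(grid - 1)) for (x1 in (x0 + 1):grid) {
    for (y0 in 0:(grid - 1)) for (y1 in (y0 + 1):grid) {
      boxes[[length(boxes) + 1]] <- bounding_box(x0, y0, x1, y1)
    }
  }
  for (a in boxes) {
    for (b in boxes) {
      expect_equal(iou(a, b), pixel_iou(a, b))
    }
  }

  # random box pairs on a 20x20 grid
  set.seed(41)
  for (k in 1:300) {
    mk <- function() {
      x <- sort(sample(0:20, 2))
      y <- sort(sample(0:20, 2))
      if (x[1] == x[2]) x[2] <- x[2] + 1
      if (y[1] == y[2]) y[2] <- y[2] + 1
      bounding_box(x[1], y[1], x[2], y[2])
    }
    a <- mk()
    b <- mk()
    v <- iou(a, b)
    expect_equal(v, pixel_iou(a, b))
    expect_equal(v, iou(b, a))
    expect_true(v >= 0 && v <= 1)
  }
})

test_that("degenerate boxes are rejected", {
  expect_error(bounding_box(5, 0, 5, 10), "degenerate")
  expect_error(bounding_box(0, 0, Inf, 10), "finite")
})

test_that("TP/FP assignment follows the one-claim rule at IoU 0.5", {
  truth <- pod_set("p", "front", 0, 0, 10, 10, 1)
  # exact hit
  a <- assign_tp_fp(pod_set("p", "front", 0, 0, 10, 10, 1, 0.9), truth)
  expect_equal(c(a$tp, a$fp, a$fn), c(1, 0, 0))
  # duplicate detection of one truth: second is FP
  dets <- pod_set("p", "front", c(0, 1), c(0, 0), c(10, 11), c(10, 10),
                  c(1, 1), c(0.9, 0.8))
  a <- assign_tp_fp(dets, truth)
  expect_equal(c(a$tp, a$fp, a$fn), c(1, 1, 0))
  # IoU strictly below 0.5 is FP, truth stays FN
  low <- pod_set("p", "front", 0, 0, 10, 3, 1, 0.9)  # IoU 30/100 = 0.3
  a <- assign_tp_fp(low, truth)
  expect_equal(c(a$tp, a$fp, a$fn), c(0, 1, 1))
  # boundary: IoU exactly 0.5 counts as TP
  half <- pod_set("p", "front", 0, 0, 10, 5, 1, 0.9)  # 50/100
  a <- assign_tp_fp(half, truth)
  expect_equal(c(a$tp, a$fp, a$fn), c(1, 0, 0))
})

test_that("TP/FP assignment conserves counts on random inputs", {
  set.seed(7)
  for (k in 1:25) {
    nd <- sample(0:6, 1)
    nt <- sample(0:6, 1)
    mk <- function(n, view) {
      if (n == 0) return(pod_set("p", view))
      x0 <- sample(0:15, n, replace = TRUE)
      y0 <- sample(0:15, n, replace = TRUE)
      pod_set("p", view, x0, y0, x0 + sample(1:5, n, TRUE),
              y0 + sample(1:5, n, TRUE), rep(1, n), stats::runif(n))
    }
    a <- assign_tp_fp(mk(nd, "front"), mk(nt, "front"))
    expect_equal(a$tp + a$fp, nd)
    expect_equal(a$tp + a$fn, nt)
  }
})

test_that("average precision equals the rectangular-rule evaluation", {
  expect_equal(pr_ap(c("TP"), 1)$ap, 1)
  expect_equal(pr_ap(c("FP", "TP"), 1)$ap, 0.5)
  expect_equal(pr_ap(c("FP", "FP"), 2)$ap, 0)
  expect_equal(pr_ap(character(0), 0)$ap, 0)

  bf_ap <- function(labels, n_truth) {
    tp <- 0
    rec_prev <- 0
    s <- 0
    for (k in seq_along(labels)) {
      if (labels[k] == "TP") tp <- tp + 1
      prec <- tp / k
      rec <- tp / n_truth
      s <- s + prec * (rec - rec_prev)
      rec_prev <- rec
    }
    s
  }
  set.seed(13)
  for (k in 1:100) {
    n <- sample(1:10, 1)
    labels <- sample(c("TP", "FP"), n, replace = TRUE)
    n_truth <- sum(labels == "TP") + sample(0:3, 1)
    if (n_truth == 0) next
    expect_equal(pr_ap(labels, n_truth)$ap, bf_ap(labels, n_truth))
  }
})

test_that("mAP is the arithmetic mean over classes", {
  expect_equal(mean_ap(c(1, 1, 1, 1)), 1)
  expect_equal(mean_ap(c(0.2, 0.4, 0.6, 0.8)), 0.5)
  expect_equal(mean_ap(0.37), 0.37)
})

test_that("count metrics reproduce their closed forms", {
  m <- count_metrics(c(10, 20), c(12, 18))
  expect_equal(m$mae, 2)
  expect_equal(m$rmse, 2)
  expect_equal(m$r, 0.84)

  m <- count_metrics(c(3, 7, 9), c(3, 7, 9))
  expect_equal(unlist(m[c("mae", "rmse", "r")]),
               c(mae = 0, rmse = 0, r = 1))

  expect_warning(m <- count_metrics(5, 5), "constant")
  expect_equal(m$mae, 0)
  expect_true(is.na(m$r))

  # rmse is permutation invariant over paired samples; r can be negative
  set.seed(3)
  t <- sample(5:30, 8)
  c_ <- t + sample(-3:3, 8, TRUE)
  p <- sample(8)
  expect_equal(count_metrics(t, c_)$rmse, count_metrics(t[p], c_[p])$rmse)
  expect_lt(count_metrics(c(10, 11), c(30, -10))$r, 0)
})

test_that("count accuracy is unclamped and acc_mean averages 5 categories", {
  expect_equal(acc(10, 10), 1)
  expect_equal(acc(10, 8), 0.8)
  expect_equal(acc(10, 21), -0.1)
  expect_error(acc(0, 3), "undefined")
  expect_equal(acc_mean(c(1, 1, 1, 1, 0)), 0.8)
  expect_equal(acc_mean(rep(0.37, 5)), 0.37)
  expect_equal(acc_mean(c(0.1, 0.9, 0.5, 0.3, 0.7)),
               acc_mean(c(0.7, 0.3, 0.5, 0.9, 0.1)))
  expect_error(acc_mean(c(1, 1)), "five")
})

test_that("detection report stratifies by class and writes CSV", {
  truth <- pod_set("p", "front", c(0, 20, 40), c(0, 0, 0),
                   c(10, 30, 50), c(10, 10, 10), c(1, 2, 3))
  dets <- pod_set("p", "front", c(0, 20, 60), c(0, 0, 0),
                  c(10, 30, 70), c(10, 10, 10), c(1, 2, 4),
                  c(0.9, 0.8, 0.7))
  rep <- detection_report(dets, truth)
  expect_equal(rep$per_class$ap, c(1, 1, 0, 0))
  expect_equal(rep$map, 0.5)
  f <- tempfile(fileext = ".csv")
  write_detection_report(rep, f)
  back <- read.csv(f)
  expect_equal(back$ap, rep$per_class$ap)
  expect_equal(back$map, rep(0.5, 4))
})
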