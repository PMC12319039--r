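#' Intersection-over-union of two bounding boxes
#'
#' Boxes follow the package convention: 0-based, half-open pixel intervals
#' `[x_min, x_max) x [y_min, y_max)`, so the area of a box is
#' `(x_max - x_min) * (y_max - y_min)` and IoU is exact (a ratio of pixel
#' counts) whenever the coordinates are integers.
#'
#' @param a,b Bounding boxes as created by [bounding_box()] (any list or
#'   numeric vector with `x_min`, `y_min`, `x_max`, `y_max` works).
#' @return IoU in `[0, 1]`; 0 for disjoint boxes, 1 iff the boxes coincide.
#' @export
#' @examples
#' iou(bounding_box(0, 0, 10, 10), bounding_box(5, 0, 15, 10)) # 1/3
iou <- function(a, b) {
  a <- as_bounding_box(a)
  b <- as_bounding_box(b)
  ix <- max(0, min(a$x_max, b$x_max) - max(a$x_min, b$x_min))
  iy <- max(0, min(a$y_max, b$y_max) - max(a$y_min, b$y_min))
  inter <- ix * iy
  union <- box_area(a) + box_area(b) - inter
  inter / union
}

#' Assign true/false-positive labels to detections at an IoU threshold
#'
#' Detections (already restricted to one class and one image) are ranked by
#' confidence, descending. Each detection claims the unclaimed ground-truth
#' box of highest IoU; it is a true positive iff that IoU reaches `iou_min`,
#' otherwise a false positive. Each truth box can be claimed at most once,
#' so duplicate detections of the same pod count as false positives.
#' Unclaimed truths are false negatives.
#'
#' @param dets A [pod_set()] (or data frame of detections) for one class.
#' @param truths A [pod_set()] of ground-truth boxes for the same class.
#' @param iou_min Minimum IoU for a true positive (default 0.5).
#' @return A list with `labels` (character `"TP"`/`"FP"` per detection, in
#'   confidence-descending order), `confidence` (the ranked confidences),
#'   `order` (index of each ranked detection in the input), and counts
#'   `tp`, `fp`, `fn`, `n_truth`.
#' @export
assign_tp_fp <- function(dets, truths, iou_min = 0.5) {
  d <- as_detection_frame(dets)
  g <- as_detection_frame(truths)
  n_truth <- nrow(g)
  if (nrow(d) == 0L) {
    return(list(labels = character(0), confidence = numeric(0),
                order = integer(0), tp = 0L, fp = 0L, fn = n_truth,
                n_truth = n_truth))
  }
  ord <- order(-d$confidence, seq_len(nrow(d)))
  claimed <- logical(n_truth)
  labels <- character(nrow(d))
  for (r in seq_along(ord)) {
    i <- ord[r]
    best_iou <- -1
    best_j <- 0L
    for (j in seq_len(n_truth)) {
      if (claimed[j]) next
      v <- iou(d[i, , drop = FALSE], g[j, , drop = FALSE])
      if (v > best_iou) {
        best_iou <- v
        best_j <- j
      }
    }
    if (best_j > 0L && best_iou >= iou_min) {
      labels[r] <- "TP"
      claimed[best_j] <- TRUE
    } else {
      labels[r] <- "FP"
    }
  }
  tp <- sum(labels == "TP")
  list(labels = labels, confidence = d$confidence[ord], order = ord,
       tp = tp, fp = sum(labels == "FP"), fn = n_truth - tp,
       n_truth = n_truth)
}

#' Precision-recall curve and average precision
#'
#' Walks the confidence-ranked TP/FP labels and accumulates
#' `AP = sum_k Precision(k) * DeltaRecall(k)`, the rectangular (left) rule on
#' the raw curve with no interpolation. `DeltaRecall(k)` is nonzero only at
#' true positives, so false positives contribute nothing directly but lower
#' the precision of later true positives. With `interpolate = TRUE` the
#' precision envelope `max(Precision(k'), k' >= k)` is used instead
#' (VOC-style); the default is the raw rule.
#'
#' @param labels Character vector of `"TP"`/`"FP"` in confidence-descending
#'   order (as returned by [assign_tp_fp()]).
#' @param n_truth Number of ground-truth instances for the class.
#' @param interpolate Use the monotone precision envelope (default `FALSE`).
#' @return List with `precision`, `recall` (cumulative, per rank), and `ap`.
#' @export
pr_ap <- function(labels, n_truth, interpolate = FALSE) {
  stopifnot(n_truth >= 0)
  if (length(labels) == 0L || n_truth == 0L) {
    return(list(precision = numeric(0), recall = numeric(0), ap = 0))
  }
  is_tp <- labels == "TP"
  tp_cum <- cumsum(is_tp)
  k <- seq_along(labels)
  precision <- tp_cum / k
  recall <- tp_cum / n_truth
  prec_used <- precision
  if (interpolate) {
    prec_used <- rev(cummax(rev(precision)))
  }
  d_recall <- diff(c(0, recall))
  ap <- sum(prec_used * d_recall)
  list(precision = precision, recall = recall, ap = ap)
}

#' Mean average precision over classes
#'
#' @param aps Numeric vector of per-class average precisions.
#' @return Their arithmetic mean.
#' @export
mean_ap <- function(aps) {
  stopifnot(length(aps) >= 1)
  mean(aps)
}

#' Per-class detection evaluation report
#'
#' Stratifies detections and ground truths by pod class, assigns TP/FP/FN at
#' the IoU threshold, and computes Precision, Recall, F1 and AP per class
#' plus the overall mAP.
#'
#' @param dets Detections ([pod_set()] or detection data frame), all classes.
#' @param truths Ground truths, same image space.
#' @param iou_min IoU threshold for a true positive (default 0.5).
#' @param classes Class labels to evaluate (default 1:4).
#' @return A list with `per_class` (data frame: class, tp, fp, fn, precision,
#'   recall, f1, ap) and `map`.
#' @export
detection_report <- function(dets, truths, iou_min = 0.5, classes = 1:4) {
  d <- as_detection_frame(dets)
  g <- as_detection_frame(truths)
  rows <- lapply(classes, function(cl) {
    a <- assign_tp_fp(d[d$pod_class == cl, , drop = FALSE],
                      g[g$pod_class == cl, , drop = FALSE], iou_min)
    prec <- if (a$tp + a$fp > 0) a$tp / (a$tp + a$fp) else 0
    rec <- if (a$n_truth > 0) a$tp / a$n_truth else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    ap <- pr_ap(a$labels, a$n_truth)$ap
    data.frame(class = cl, tp = a$tp, fp = a$fp, fn = a$fn,
               precision = prec, recall = rec, f1 = f1, ap = ap)
  })
  per_class <- do.call(rbind, rows)
  list(per_class = per_class, map = mean_ap(per_class$ap))
}

#' Count-regression metrics: MAE, RMSE and coefficient of determination
#'
#' For truth counts `t` and predicted counts `c` over N plants:
#' `MAE = mean(|t - c|)`, `RMSE = sqrt(mean((t - c)^2))`, and
#' `R = 1 - sum((t - c)^2) / sum((t - mean(t))^2)`. `R` is the
#' coefficient-of-determination form and can be negative for predictions
#' worse than the truth mean; it equals 1 iff all residuals are zero. See
#' [pearson_r()] for the product-moment alternative.
#'
#' @param truth,pred Equal-length numeric vectors of counts.
#' @return List with `mae`, `rmse`, `r` (`r` is `NA` with a warning when
#'   `truth` is constant, where the denominator vanishes).
#' @export
#' @examples
#' count_metrics(c(10, 20), c(12, 18)) # mae 2, rmse 2, r 0.84
count_metrics <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) >= 1)
  res <- truth - pred
  mae <- mean(abs(res))
  rmse <- sqrt(mean(res^2))
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) {
    warning("truth vector is constant; R is undefined")
    r <- NA_real_
  } else {
    r <- 1 - sum(res^2) / ss_tot
  }
  list(mae = mae, rmse = rmse, r = r)
}

#' Pearson product-moment correlation between truth and prediction
#'
#' Companion to the coefficient-of-determination `r` of [count_metrics()].
#'
#' @inheritParams count_metrics
#' @return Pearson correlation.
#' @export
pearson_r <- function(truth, pred) {
  stats::cor(truth, pred)
}

#' Per-category count accuracy
#'
#' `Acc = 1 - |truth - predict| / truth`. Unclamped: over-prediction beyond
#' twice the truth gives a negative accuracy, reported as computed.
#'
#' @param truth True count (must be positive).
#' @param predict Predicted count.
#' @return Accuracy value (1 when exact; can be negative).
#' @export
#' @examples
#' acc(10, 8)  # 0.8
#' acc(10, 21) # -0.1
acc <- function(truth, predict) {
  if (any(truth <= 0)) stop("acc is undefined for truth <= 0")
  1 - abs(truth - predict) / truth
}

#' Mean count accuracy over the five categories
#'
#' The five categories are the four pod classes (one- to four-seed) plus the
#' total pod count.
#'
#' @param accs Numeric vector of exactly five per-category accuracies.
#' @return Their arithmetic mean.
#' @export
acc_mean <- function(accs) {
  if (length(accs) != 5L) {
    stop("acc_mean expects exactly five category accuracies, got ",
         length(accs))
  }
  mean(accs)
}

#' Write a per-class detection metrics table to CSV
#'
#' Columns mirror the usual detector benchmark layout: class, precision,
#' recall, F1, AP, and a repeated overall mAP column.
#'
#' @param report Output of [detection_report()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_detection_report <- function(report, path) {
  df <- report$per_class
  df$map <- report$map
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write count-regression metrics per category to CSV
#'
#' @param truth_df,pred_df Count tables (columns `plant_id`, `one`, `two`,
#'   `three`, `four`, `total`) with matching `plant_id`s.
#' @param path Output CSV path.
#' @return Data frame of R/MAE/RMSE per category, written to `path`.
#' @export
write_count_report <- function(truth_df, pred_df, path) {
  stopifnot(identical(truth_df$plant_id, pred_df$plant_id))
  cats <- c("one", "two", "three", "four", "total")
  rows <- lapply(cats, function(cat) {
    m <- count_metrics(truth_df[[cat]], pred_df[[cat]])
    data.frame(category = cat, r = m$r, mae = m$mae, rmse = m$rmse)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
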