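#' Configuration of the paired-scene generator
#'
#' Defines the study conditions the generator emulates: plants carry a
#' mixture of one- to four-seed pods whose class frequencies default to the
#' strongly imbalanced proportions observed in real mature plants
#' (two- and three-seed pods dominate), and each pod may be hidden in
#' exactly one of the two views, the single-side occlusion the cross-view
#' correction stage exists to fix.
#'
#' @param n_pods_range Integer interval `(min, max)` for the number of pods
#'   per plant (default 10..40).
#' @param class_probabilities Four nonnegative weights for pod classes 1..4;
#'   normalized to sum to 1. Default `(3078, 9805, 13896, 2955) / 29734`,
#'   the class tally of a large field survey of mature plants.
#' @param occlusion_rate Probability that a pod is hidden in exactly one
#'   view (which view is a fair coin); in `[0, 1)`. Default 0.2.
#' @param noise_level Salt-and-pepper pixel fraction applied to the rendered
#'   views, in `[0, 1]`. Default 0 (augmentation noise is applied at
#'   training time instead).
#' @param image_size `(width, height)` in pixels (default 400 x 300).
#' @param lobe_radius_range Per-pod lobe radius interval in pixels.
#' @param seed Integer seed; every draw of the generator derives from it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_pods_range = c(10L, 40L),
                         class_probabilities = c(3078, 9805, 13896, 2955),
                         occlusion_rate = 0.2,
                         noise_level = 0,
                         image_size = c(400L, 300L),
                         lobe_radius_range = c(5, 8),
                         seed = 1L) {
  stopifnot(length(n_pods_range) == 2, n_pods_range[1] >= 1,
            n_pods_range[2] >= n_pods_range[1],
            length(class_probabilities) == 4, all(class_probabilities >= 0),
            sum(class_probabilities) > 0,
            occlusion_rate >= 0, occlusion_rate < 1,
            noise_level >= 0, noise_level <= 1,
            length(image_size) == 2, all(image_size >= 1),
            lobe_radius_range[1] > 0,
            lobe_radius_range[2] >= lobe_radius_range[1])
  structure(list(
    n_pods_range = as.integer(n_pods_range),
    class_probabilities = class_probabilities / sum(class_probabilities),
    occlusion_rate = occlusion_rate,
    noise_level = noise_level,
    image_size = as.integer(image_size),
    lobe_radius_range = lobe_radius_range,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' Specification of a single synthetic pod
#'
#' @param pod_id Integer identity, shared across the two views.
#' @param pod_class Seeds per pod, in 1..4; equals the number of lobes.
#' @param center `(x, y)` center in pixels (front-view frame).
#' @param angle Pod axis angle in degrees.
#' @param lobe_radius Lobe semi-axis along the pod axis, pixels (> 0).
#' @param visible_front,visible_rear Visibility flags; a counted pod must be
#'   visible in at least one view.
#' @param color RGB triple in `[0, 1]` (default a tan pod color).
#' @return An object of class `pod_spec`.
#' @export
pod_spec <- function(pod_id, pod_class, center, angle, lobe_radius,
                     visible_front = TRUE, visible_rear = TRUE,
                     color = c(0.72, 0.60, 0.35)) {
  check_pod_class(pod_class)
  stopifnot(lobe_radius > 0, length(center) == 2, length(color) == 3)
  if (!visible_front && !visible_rear) {
    stop("a counted pod must be visible in at least one view")
  }
  structure(list(pod_id = as.integer(pod_id),
                 pod_class = as.integer(pod_class),
                 center = as.numeric(center), angle = as.numeric(angle),
                 lobe_radius = as.numeric(lobe_radius),
                 visible_front = visible_front, visible_rear = visible_rear,
                 color = as.numeric(color)),
            class = "pod_spec")
}

#' Paint a pod onto a canvas
#'
#' A class-k pod is a chain of k tangent ellipses (lobes) along the pod
#' axis: lobe semi-axes are `lobe_radius` along the axis and `0.78 *
#' lobe_radius` across it, with centers spaced `2 * lobe_radius` apart.
#' Each lobe gets a darker rim and a lighter center highlight so lobe count
#' is visible texture, not just extent. Painting is pure arithmetic, hence
#' deterministic.
#'
#' @param spec A [pod_spec()].
#' @param canvas `(h, w, 3)` array in `[0, 1]`.
#' @return List with `canvas` (pod painted) and `box` (tight
#'   [bounding_box()] of the painted pixels), or `box = NULL` if the pod
#'   falls entirely outside the canvas.
#' @export
render_pod <- function(spec, canvas) {
  check_pod_class(spec$pod_class)
  h <- dim(canvas)[1]
  w <- dim(canvas)[2]
  k <- spec$pod_class
  a <- spec$lobe_radius
  b <- 0.78 * a
  th <- spec$angle * pi / 180
  dir <- c(cos(th), sin(th))
  offs <- (seq_len(k) - (k + 1) / 2) * 2 * a
  lx <- spec$center[1] + offs * dir[1]
  ly <- spec$center[2] + offs * dir[2]
  # window of pixels that can possibly be painted
  half <- k * a + b + 1
  x0 <- max(0L, floor(spec$center[1] - half))
  x1 <- min(w - 1L, ceiling(spec$center[1] + half))
  y0 <- max(0L, floor(spec$center[2] - half))
  y1 <- min(h - 1L, ceiling(spec$center[2] + half))
  if (x1 < x0 || y1 < y0) return(list(canvas = canvas, box = NULL))
  xs <- x0:x1
  ys <- y0:y1
  px <- rep(xs + 0.5, each = length(ys))
  py <- rep(ys + 0.5, times = length(xs))
  q <- matrix(Inf, nrow = length(px), ncol = 1)
  for (i in seq_len(k)) {
    dx <- px - lx[i]
    dy <- py - ly[i]
    u <- (dx * dir[1] + dy * dir[2]) / a
    v <- (-dx * dir[2] + dy * dir[1]) / b
    q <- pmin(q, u^2 + v^2)
  }
  inside <- q <= 1
  if (!any(inside)) return(list(canvas = canvas, box = NULL))
  rim <- inside & q > 0.72
  core <- q <= 0.18
  shade <- numeric(length(px))
  shade[inside] <- 1
  shade[rim] <- 0.55       # darker seam/outline
  shade[core] <- 1.25      # seed bulge highlight
  idx <- which(inside)
  rowi <- ((idx - 1) %% length(ys)) + y0 + 1
  coli <- ((idx - 1) %/% length(ys)) + x0 + 1
  for (ch in 1:3) {
    lin <- rowi + (coli - 1) * h + (ch - 1) * h * w
    canvas[lin] <- clamp01(spec$color[ch] * shade[idx])
  }
  box <- bounding_box(min(coli) - 1, min(rowi) - 1, max(coli), max(rowi))
  list(canvas = canvas, box = box)
}

#' Generate a paired front/rear synthetic plant scene
#'
#' Pods are sampled from the configured class mixture and placed on a white
#' background. Each pod is hidden in exactly one view with probability
#' `occlusion_rate` (never in both), so the ideal fused count always equals
#' the true count. The rear view is rendered in mirrored camera geometry
#' (centers reflected across the vertical midline, axis angle negated),
#' which is what a camera sees after the plant is rotated 180 degrees; a
#' later [mirror_flip()] realigns it with the front frame. Per-pod
#' appearance (lobe radius, color, axis angle) is jittered between the two
#' views, seeded, so same-identity crops are similar but not identical.
#'
#' @param cfg A [synth_config()].
#' @param plant_id Identifier for the scene (default derived from the seed).
#' @return List with `front` and `rear` images (`(h, w, 3)` arrays) and
#'   `truth`, a `scene_truth` object: `pods` data frame (identity, class,
#'   geometry, visibility, per-view rendered boxes), `image_size`,
#'   `true_counts`, `seed`.
#' @export
generate_scene <- function(cfg, plant_id = sprintf("scene%04d", cfg$seed)) {
  stopifnot(inherits(cfg, "synth_config"))
  w <- cfg$image_size[1]
  h <- cfg$image_size[2]
  if (w < 1 || h < 1) stop("zero-area image")
  with_seed(cfg$seed, {
    n <- sample(cfg$n_pods_range[1]:cfg$n_pods_range[2], 1)
    cls <- sample(1:4, n, replace = TRUE, prob = cfg$class_probabilities)
    rmax <- cfg$lobe_radius_range[2]
    margin <- 4 * rmax + 2
    cx <- stats::runif(n, margin, w - margin)
    cy <- stats::runif(n, margin, h - margin)
    angle <- stats::runif(n, 0, 180)
    radius <- stats::runif(n, cfg$lobe_radius_range[1],
                           cfg$lobe_radius_range[2])
    base_col <- c(0.72, 0.60, 0.35)
    col <- t(vapply(seq_len(n), function(i) {
      clamp01(base_col + stats::runif(3, -0.08, 0.08))
    }, numeric(3)))
    hidden <- stats::runif(n) < cfg$occlusion_rate
    hidden_view <- ifelse(stats::runif(n) < 0.5, "front", "rear")
    visible_front <- !(hidden & hidden_view == "front")
    visible_rear <- !(hidden & hidden_view == "rear")
    # cross-view appearance jitter (same identity, not same pixels)
    rear_angle_jit <- stats::runif(n, -8, 8)
    rear_radius_scale <- stats::runif(n, 0.92, 1.08)
    noise_seeds <- sample.int(.Machine$integer.max, 2)

    front <- array(1, c(h, w, 3))
    rear <- array(1, c(h, w, 3))
    fb <- matrix(NA_real_, n, 4)
    rb <- matrix(NA_real_, n, 4)
    for (i in seq_len(n)) {
      if (visible_front[i]) {
        sp <- pod_spec(i, cls[i], c(cx[i], cy[i]), angle[i], radius[i],
                       color = col[i, ])
        res <- render_pod(sp, front)
        front <- res$canvas
        if (!is.null(res$box)) {
          fb[i, ] <- unlist(res$box[c("x_min", "y_min", "x_max", "y_max")])
        }
      }
      if (visible_rear[i]) {
        sp <- pod_spec(i, cls[i], c(w - cx[i], cy[i]),
                       180 - angle[i] + rear_angle_jit[i],
                       radius[i] * rear_radius_scale[i],
                       color = col[i, ])
        res <- render_pod(sp, rear)
        rear <- res$canvas
        if (!is.null(res$box)) {
          rb[i, ] <- unlist(res$box[c("x_min", "y_min", "x_max", "y_max")])
        }
      }
    }
    if (cfg$noise_level > 0) {
      front <- with_seed(noise_seeds[1], salt_pepper(front, cfg$noise_level))
      rear <- with_seed(noise_seeds[2], salt_pepper(rear, cfg$noise_level))
    }
    pods <- data.frame(
      pod_id = seq_len(n), pod_class = cls, cx = cx, cy = cy,
      angle = angle, lobe_radius = radius,
      visible_front = visible_front, visible_rear = visible_rear,
      r = col[, 1], g = col[, 2], b = col[, 3],
      front_x_min = fb[, 1], front_y_min = fb[, 2],
      front_x_max = fb[, 3], front_y_max = fb[, 4],
      rear_x_min = rb[, 1], rear_y_min = rb[, 2],
      rear_x_max = rb[, 3], rear_y_max = rb[, 4]
    )
    counts <- tabulate(cls, nbins = 4)
    truth <- structure(list(
      plant_id = plant_id, pods = pods, image_size = c(w, h),
      true_counts = c(one = counts[1], two = counts[2], three = counts[3],
                      four = counts[4], total = n),
      seed = cfg$seed
    ), class = "scene_truth")
    list(front = front, rear = rear, truth = truth)
  })
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> plant '%s', %d pods (%s), image %dx%d\n",
              x$plant_id, x$true_counts[["total"]],
              paste(x$true_counts[1:4], collapse = "/"),
              x$image_size[1], x$image_size[2]))
  invisible(x)
}

#' Oracle detections from a scene truth
#'
#' Stands in for an object detector: one detection per pod visible in the
#' requested view, with the rendered tight box, confidence 1, and the true
#' pod class and identity, ordered by pod id.
#'
#' @param truth A `scene_truth` from [generate_scene()].
#' @param view `"front"` or `"rear"` (rear boxes are in the rear image's own
#'   mirrored frame).
#' @return A [pod_set()].
#' @export
truth_to_detections <- function(truth, view = c("front", "rear")) {
  view <- match.arg(view)
  p <- truth$pods
  vis <- if (view == "front") p$visible_front else p$visible_rear
  pre <- paste0(view, "_")
  keep <- vis & !is.na(p[[paste0(pre, "x_min")]])
  p <- p[keep, , drop = FALSE]
  p <- p[order(p$pod_id), , drop = FALSE]
  pod_set(truth$plant_id, view,
          p[[paste0(pre, "x_min")]], p[[paste0(pre, "y_min")]],
          p[[paste0(pre, "x_max")]], p[[paste0(pre, "y_max")]],
          p$pod_class, rep(1, nrow(p)), p$pod_id)
}

#' Sample labeled crop pairs for similarity training
#'
#' Draws `n_pairs` index pairs from a class-labeled crop collection:
#' positive pairs (label 1) are two distinct crops of one class, negative
#' pairs (label 0) two crops of different classes. The realized number of
#' positives is `round(positive_fraction * n_pairs)`.
#'
#' @param labels Integer class label per crop.
#' @param n_pairs Number of pairs to draw.
#' @param positive_fraction Fraction of same-class pairs in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return Data frame with columns `i`, `j` (crop indices) and `label`.
#' @export
sample_pairs <- function(labels, n_pairs, positive_fraction = 0.5,
                         seed = NULL) {
  stopifnot(n_pairs >= 1, positive_fraction >= 0, positive_fraction <= 1)
  n_pos <- round(positive_fraction * n_pairs)
  by_class <- split(seq_along(labels), labels)
  pos_classes <- names(by_class)[vapply(by_class, length, 1L) >= 2]
  if (n_pos > 0 && length(pos_classes) == 0) {
    stop("positive pairs requested but no class has >= 2 crops")
  }
  if (n_pairs - n_pos > 0 && length(by_class) < 2) {
    stop("negative pairs requested but only one class present")
  }
  with_seed(seed, {
    pos <- if (n_pos > 0) {
      t(vapply(seq_len(n_pos), function(...) {
        cl <- sample(pos_classes, 1)
        sample(by_class[[cl]], 2)
      }, numeric(2)))
    } else matrix(numeric(0), 0, 2)
    neg <- if (n_pairs - n_pos > 0) {
      t(vapply(seq_len(n_pairs - n_pos), function(...) {
        cls <- sample(names(by_class), 2)
        c(sample(by_class[[cls[1]]], 1), sample(by_class[[cls[2]]], 1))
      }, numeric(2)))
    } else matrix(numeric(0), 0, 2)
    df <- data.frame(i = c(pos[, 1], neg[, 1]),
                     j = c(pos[, 2], neg[, 2]),
                     label = rep(c(1L, 0L), c(nrow(pos), nrow(neg))))
    df[sample.int(nrow(df)), , drop = FALSE]
  })
}

#' Extract labeled crops from one or more scenes
#'
#' Crops every visible pod in both views of each scene and labels it with
#' its pod class; the raw material for similarity training and the
#' confusion-matrix evaluation.
#'
#' @param scenes A scene (list from [generate_scene()]) or list of scenes.
#' @param pad,side Passed to [crop_and_resize()].
#' @return List with `crops` (list of arrays), `labels` (pod classes) and
#'   `pod_ids` (identities, unique within a scene only).
#' @export
scene_crops <- function(scenes, pad = 2, side = 105) {
  if (!is.null(scenes$truth)) scenes <- list(scenes)
  crops <- list()
  labels <- integer(0)
  ids <- integer(0)
  for (sc in scenes) {
    for (view in c("front", "rear")) {
      ps <- truth_to_detections(sc$truth, view)
      img <- sc[[view]]
      for (i in seq_len(nrow(ps))) {
        crops[[length(crops) + 1L]] <-
          crop_and_resize(img, ps[i, , drop = FALSE], pad = pad, side = side)
        labels <- c(labels, ps$pod_class[i])
        ids <- c(ids, ps$pod_id[i])
      }
    }
  }
  list(crops = crops, labels = labels, pod_ids = ids)
}

#' Serialize / restore a scene truth as JSON
#'
#' @param truth A `scene_truth`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_scene_truth()` returns the restored
#'   `scene_truth`.
#' @export
write_scene_truth <- function(truth, path) {
  obj <- list(plant_id = truth$plant_id, image_size = truth$image_size,
              true_counts = as.list(truth$true_counts), seed = truth$seed,
              pods = truth$pods)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_scene_truth
#' @export
read_scene_truth <- function(path) {
  j <- jsonlite::fromJSON(path)
  structure(list(plant_id = j$plant_id, pods = as.data.frame(j$pods),
                 image_size = as.integer(j$image_size),
                 true_counts = unlist(j$true_counts), seed = j$seed),
            class = "scene_truth")
}
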