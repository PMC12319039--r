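#' Bounding box in half-open pixel coordinates
#'
#' Boxes are 0-based with origin at the top-left and half-open extents
#' `[x_min, x_max) x [y_min, y_max)`: a box covering the single pixel (0,0)
#' is `bounding_box(0, 0, 1, 1)`. This makes areas and IoU integer-exact on
#' synthetic scenes.
#'
#' @param x_min,y_min,x_max,y_max Box edges in pixels; `x_max > x_min` and
#'   `y_max > y_min` are required.
#' @return An object of class `bounding_box`.
#' @export
bounding_box <- function(x_min, y_min, x_max, y_max) {
  if (!all(is.finite(c(x_min, y_min, x_max, y_max)))) {
    stop("bounding box coordinates must be finite")
  }
  if (x_max <= x_min || y_max <= y_min) {
    stop("degenerate bounding box: need x_max > x_min and y_max > y_min")
  }
  structure(list(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max),
            class = "bounding_box")
}

as_bounding_box <- function(b) {
  if (inherits(b, "bounding_box")) return(b)
  bounding_box(b$x_min, b$y_min, b$x_max, b$y_max)
}

box_area <- function(b) {
  (b$x_max - b$x_min) * (b$y_max - b$y_min)
}

#' A single pod detection
#'
#' @param box A [bounding_box()].
#' @param pod_class Integer in 1..4: seeds per pod.
#' @param confidence Detector confidence in `[0, 1]`.
#' @param view `"front"` or `"rear"`.
#' @param pod_id Optional true pod identity (synthetic scenes only).
#' @return An object of class `detection`.
#' @export
detection <- function(box, pod_class, confidence = 1, view = "front",
                      pod_id = NA_integer_) {
  box <- as_bounding_box(box)
  check_pod_class(pod_class)
  if (confidence < 0 || confidence > 1) {
    stop("confidence must lie in [0, 1]")
  }
  view <- match.arg(view, c("front", "rear"))
  structure(list(box = box, pod_class = as.integer(pod_class),
                 confidence = confidence, view = view,
                 pod_id = as.integer(pod_id)),
            class = "detection")
}

check_pod_class <- function(pod_class) {
  if (!all(pod_class %in% 1:4)) {
    stop("invalid pod class: must be in {1, 2, 3, 4}")
  }
  invisible(pod_class)
}

#' Ordered set of detections for one view of one plant
#'
#' The frontal and rear detection sets of a plant are the inputs of the
#' cross-view correction stage. Internally a data frame with one row per
#' detection; row order is the set order.
#'
#' @param plant_id Plant identifier.
#' @param view `"front"` or `"rear"`.
#' @param x_min,y_min,x_max,y_max Box edges (half-open pixel convention).
#' @param pod_class Integer vector in 1..4.
#' @param confidence Confidences in `[0, 1]` (default all 1).
#' @param pod_id Optional pod identities (synthetic truth).
#' @return An object of class `pod_set` (also a data frame).
#' @export
pod_set <- function(plant_id, view, x_min = numeric(0), y_min = numeric(0),
                    x_max = numeric(0), y_max = numeric(0),
                    pod_class = integer(0),
                    confidence = rep(1, length(x_min)),
                    pod_id = rep(NA_integer_, length(x_min))) {
  view <- match.arg(view, c("front", "rear"))
  check_pod_class(pod_class)
  stopifnot(all(confidence >= 0 & confidence <= 1))
  if (length(x_min) > 0) {
    stopifnot(all(is.finite(c(x_min, y_min, x_max, y_max))),
              all(x_max > x_min), all(y_max > y_min))
  }
  df <- data.frame(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                   x_max = as.numeric(x_max), y_max = as.numeric(y_max),
                   pod_class = as.integer(pod_class),
                   confidence = as.numeric(confidence),
                   pod_id = as.integer(pod_id))
  structure(df, plant_id = plant_id, view = view,
            class = c("pod_set", "data.frame"))
}

#' @export
print.pod_set <- function(x, ...) {
  cat(sprintf("<pod_set> plant '%s', %s view, %d detections\n",
              attr(x, "plant_id"), attr(x, "view"), nrow(x)))
  if (nrow(x) > 0) print.data.frame(x, ...)
  invisible(x)
}

as_detection_frame <- function(x) {
  if (inherits(x, "bounding_box")) {
    x <- data.frame(x_min = x$x_min, y_min = x$y_min,
                    x_max = x$x_max, y_max = x$y_max,
                    pod_class = NA_integer_, confidence = 1)
  }
  as.data.frame(x)
}

pod_class_labels <- c("one", "two", "three", "four")

label_to_class <- function(label, row = NULL) {
  idx <- match(as.character(label), pod_class_labels)
  num <- suppressWarnings(as.integer(as.character(label)))
  idx[is.na(idx)] <- ifelse(num[is.na(idx)] %in% 1:4, num[is.na(idx)], NA)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    where <- if (!is.null(row)) sprintf(" (row %d)", row[is.na(idx)][1]) else ""
    stop(sprintf("unknown pod class label '%s'%s", label[bad], where))
  }
  as.integer(idx)
}

#' Read a detection file into a pod set
#'
#' Two dialects are supported. `flat_csv` has the exact header
#' `plant_id,view,x_min,y_min,x_max,y_max,class,confidence` with class given
#' as `one`/`two`/`three`/`four` and boxes already half-open. `coco_json` is
#' a COCO-style JSON object (`images`, `annotations` with `[x, y, w, h]`
#' boxes, `categories` named one..four); boxes are converted to the
#' half-open convention via `x_max = x + w`, `y_max = y + h`.
#'
#' The file must describe a single (plant, view) pair. Malformed rows
#' (unknown class label, non-finite coordinates) raise an error naming the
#' offending row; an empty file yields an empty pod set.
#'
#' @param path File to read.
#' @param dialect `"flat_csv"` or `"coco_json"`.
#' @return A [pod_set()].
#' @export
read_detections <- function(path, dialect = c("flat_csv", "coco_json")) {
  dialect <- match.arg(dialect)
  if (dialect == "flat_csv") read_detections_csv(path) else
    read_detections_coco(path)
}

read_detections_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected <- c("plant_id", "view", "x_min", "y_min", "x_max", "y_max",
                "class", "confidence")
  if (!identical(names(df)[seq_along(expected)], expected)) {
    stop("flat_csv header must be: ", paste(expected, collapse = ","))
  }
  if (nrow(df) == 0) return(pod_set("unknown", "front"))
  one_plant_view(df$plant_id, df$view)
  coords <- as.matrix(df[, c("x_min", "y_min", "x_max", "y_max")])
  if (!all(is.finite(coords))) {
    stop("non-finite coordinates at row ",
         which(!apply(is.finite(coords), 1, all))[1])
  }
  cls <- label_to_class(df$class, row = seq_len(nrow(df)))
  pid <- if ("pod_id" %in% names(df)) df$pod_id else rep(NA_integer_, nrow(df))
  pod_set(df$plant_id[1], df$view[1], df$x_min, df$y_min, df$x_max, df$y_max,
          cls, df$confidence, pid)
}

read_detections_coco <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(j$annotations) || NROW(j$annotations) == 0) {
    pid <- if (NROW(j$images) >= 1) j$images$plant_id[1] else "unknown"
    vw <- if (NROW(j$images) >= 1) j$images$view[1] else "front"
    return(pod_set(pid, vw))
  }
  img <- j$images
  one_plant_view(img$plant_id, img$view)
  ann <- j$annotations
  bbox <- do.call(rbind, ann$bbox)
  if (!all(is.finite(bbox))) {
    stop("non-finite coordinates in annotation ",
         which(!apply(is.finite(bbox), 1, all))[1])
  }
  cat_names <- j$categories$name[match(ann$category_id, j$categories$id)]
  cls <- label_to_class(cat_names, row = seq_len(nrow(ann)))
  conf <- if (!is.null(ann$score)) ann$score else rep(1, nrow(ann))
  pid <- if (!is.null(ann$pod_id)) ann$pod_id else rep(NA_integer_, nrow(ann))
  pod_set(img$plant_id[1], img$view[1],
          bbox[, 1], bbox[, 2], bbox[, 1] + bbox[, 3], bbox[, 2] + bbox[, 4],
          cls, conf, pid)
}

one_plant_view <- function(plant_id, view) {
  if (length(unique(plant_id)) > 1 || length(unique(view)) > 1) {
    stop("detection file mixes plants or views; one (plant, view) per file")
  }
  invisible(NULL)
}

#' Write a pod set to a detection file
#'
#' Inverse of [read_detections()]; a round-trip through either dialect
#' reproduces the pod set exactly.
#'
#' @param podset A [pod_set()].
#' @param path Output file.
#' @param dialect `"flat_csv"` or `"coco_json"`.
#' @param image_size Optional `(width, height)` recorded in the COCO dialect.
#' @return `path`, invisibly.
#' @export
write_detections <- function(podset, path,
                             dialect = c("flat_csv", "coco_json"),
                             image_size = c(NA, NA)) {
  dialect <- match.arg(dialect)
  plant <- attr(podset, "plant_id")
  view <- attr(podset, "view")
  df <- as_detection_frame(podset)
  if (dialect == "flat_csv") {
    out <- data.frame(plant_id = rep(plant, nrow(df)),
                      view = rep(view, nrow(df)),
                      x_min = df$x_min, y_min = df$y_min,
                      x_max = df$x_max, y_max = df$y_max,
                      class = pod_class_labels[df$pod_class],
                      confidence = df$confidence,
                      pod_id = df$pod_id)
    if (nrow(out) == 0) {
      out <- out[0, c("plant_id", "view", "x_min", "y_min", "x_max", "y_max",
                      "class", "confidence", "pod_id")]
    }
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    obj <- list(
      images = list(list(id = 1L, file_name = paste0(plant, "_", view, ".png"),
                         width = image_size[1], height = image_size[2],
                         plant_id = plant, view = view)),
      annotations = lapply(seq_len(nrow(df)), function(i) {
        list(id = i, image_id = 1L,
             category_id = df$pod_class[i],
             bbox = c(df$x_min[i], df$y_min[i],
                      df$x_max[i] - df$x_min[i], df$y_max[i] - df$y_min[i]),
             score = df$confidence[i],
             pod_id = df$pod_id[i])
      }),
      categories = lapply(1:4, function(k) {
        list(id = k, name = pod_class_labels[k])
      })
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  }
  invisible(path)
}

#' Read / write an image
#'
#' Images are numeric arrays of dimension `(height, width, channels)` with
#' intensities in `[0, 1]`. PNG files go through the png package; other
#' formats (e.g. JPG) fall back to EBImage.
#'
#' @param path Image file.
#' @return `(h, w, c)` array in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
  } else {
    img <- aperm(as.array(EBImage::readImage(path)), c(2, 1, 3))
  }
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  img
}

#' @rdname read_image
#' @param image `(h, w, c)` array in `[0, 1]`.
#' @export
write_image <- function(image, path) {
  png::writePNG(clamp01(image), path)
  invisible(path)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Mirror-flip an image horizontally
#'
#' The rear photograph of a plant is taken after a 180-degree manual
#' rotation, so its geometry is the mirror image of the front view; flipping
#' it horizontally realigns the two coordinate frames. The operation is an
#' involution.
#'
#' @param image `(h, w)` or `(h, w, c)` array.
#' @return The horizontally reflected array.
#' @export
mirror_flip <- function(image) {
  d <- dim(image)
  if (is.null(d) || prod(d) == 0) stop("empty image")
  if (length(d) == 2L) {
    image[, rev(seq_len(d[2])), drop = FALSE]
  } else {
    image[, rev(seq_len(d[2])), , drop = FALSE]
  }
}

#' Reflect the boxes of a pod set across the vertical image midline
#'
#' Companion of [mirror_flip()] for box coordinates: under the half-open
#' convention a box maps to `x_min' = width - x_max`, `x_max' = width -
#' x_min`; rows, classes and confidences are untouched.
#'
#' @param podset A [pod_set()].
#' @param image_width Image width in pixels.
#' @return The reflected pod set.
#' @export
flip_boxes <- function(podset, image_width) {
  if (nrow(podset) > 0 &&
      (any(podset$x_min < 0) || any(podset$x_max > image_width))) {
    stop("box outside [0, image_width)")
  }
  new_min <- image_width - podset$x_max
  new_max <- image_width - podset$x_min
  podset$x_min <- new_min
  podset$x_max <- new_max
  podset
}

#' Crop a detection from an image and resize to the network input size
#'
#' The box is expanded by `pad` pixels on every side, clipped to the image,
#' cropped, bilinearly resized to `side x side`, and clamped to `[0, 1]`.
#'
#' @param image `(h, w, c)` array in `[0, 1]`.
#' @param det A [bounding_box()], [detection()], or one-row detection frame.
#' @param pad Context padding in pixels (default 2).
#' @param side Output side length in pixels (default 105, the similarity
#'   network input size).
#' @return `(side, side, c)` array.
#' @export
crop_and_resize <- function(image, det, pad = 2, side = 105) {
  b <- if (inherits(det, "detection")) det$box else as_bounding_box(det)
  h <- dim(image)[1]
  w <- dim(image)[2]
  x0 <- max(0, floor(b$x_min - pad))
  y0 <- max(0, floor(b$y_min - pad))
  x1 <- min(w, ceiling(b$x_max + pad))
  y1 <- min(h, ceiling(b$y_max + pad))
  if (x1 <= x0 || y1 <= y0) stop("box does not intersect the image")
  crop <- image[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
  out <- EBImage::resize(crop, w = side, h = side)
  clamp01(array(out, c(side, side, dim(image)[3])))
}

#' Attach normalized crops to a pod set
#'
#' Stores one `(side, side, c)` crop per detection as the `crops` attribute,
#' the form the similarity scorer consumes.
#'
#' @param podset A [pod_set()].
#' @param image The view image the detections refer to.
#' @inheritParams crop_and_resize
#' @return `podset` with a `crops` attribute (list of arrays).
#' @export
attach_crops <- function(podset, image, pad = 2, side = 105) {
  crops <- lapply(seq_len(nrow(podset)), function(i) {
    crop_and_resize(image, podset[i, , drop = FALSE], pad = pad, side = side)
  })
  attr(podset, "crops") <- crops
  podset
}

#' Augment a crop
#'
#' Applies the requested operations in the order given: `mirror` (horizontal
#' reflection), `salt_pepper` (each pixel independently set to black or
#' white with probability `p/2` each, all channels together), and
#' `rotate180` (reversal of both spatial axes, equal to two successive
#' mirror axes). With a seed the noise is reproducible byte-for-byte.
#'
#' @param crop `(h, w, c)` array.
#' @param ops Character vector, subset of
#'   `c("mirror", "salt_pepper", "rotate180")`, applied in the given order.
#' @param p Salt-and-pepper pixel flip probability in `[0, 1]` (default
#'   0.02).
#' @param seed Optional integer seed for the noise.
#' @return The augmented crop.
#' @export
augment <- function(crop, ops = character(0), p = 0.02, seed = NULL) {
  stopifnot(p >= 0, p <= 1,
            all(ops %in% c("mirror", "salt_pepper", "rotate180")))
  with_seed(seed, {
    for (op in ops) {
      crop <- switch(op,
        mirror = mirror_flip(crop),
        rotate180 = rotate180(crop),
        salt_pepper = salt_pepper(crop, p)
      )
    }
    crop
  })
}

rotate180 <- function(image) {
  d <- dim(image)
  image[rev(seq_len(d[1])), rev(seq_len(d[2])), , drop = FALSE]
}

salt_pepper <- function(image, p) {
  d <- dim(image)
  u <- stats::runif(d[1] * d[2])
  pepper <- u < p / 2
  salt <- u >= p / 2 & u < p
  for (ch in seq_len(d[3])) {
    plane <- image[, , ch]
    plane[pepper] <- 0
    plane[salt] <- 1
    image[, , ch] <- plane
  }
  image
}

#' Expand a crop set fourfold with the standard augmentations
#'
#' Each crop yields itself plus a mirrored, a salt-and-pepper, and a
#' 180-degree rotated copy, echoing the fourfold dataset expansion used for
#' training.
#'
#' @param crops List of crops.
#' @param labels Parallel label vector.
#' @param p Salt-and-pepper probability.
#' @param seed Integer seed.
#' @return List with expanded `crops` and `labels`.
#' @export
augment_dataset <- function(crops, labels, p = 0.02, seed = 1L) {
  out <- vector("list", 4L * length(crops))
  lab <- rep(labels, each = 4L)
  for (i in seq_along(crops)) {
    out[[4 * i - 3]] <- crops[[i]]
    out[[4 * i - 2]] <- augment(crops[[i]], "mirror")
    out[[4 * i - 1]] <- augment(crops[[i]], "salt_pepper", p = p,
                                seed = seed + i)
    out[[4 * i]] <- augment(crops[[i]], "rotate180")
  }
  list(crops = out, labels = lab)
}

#' Write a per-plant count table to CSV
#'
#' @param counts_df Data frame with columns `plant_id`, `one`, `two`,
#'   `three`, `four`, `total`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(counts_df, path) {
  utils::write.csv(counts_df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. A NULL seed runs `code` as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
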