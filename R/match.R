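#' Configuration of the cross-view correction matcher
#'
#' @param threshold Similarity threshold in `[0, 1]` (default 0.5). A
#'   frontal pod is matched only to a rear pod with similarity strictly
#'   greater than the threshold; equality does not match.
#' @param row_order Order in which frontal detections are processed:
#'   `"confidence_desc"` (default; ties by index) or `"index"`. Greedy
#'   matching is order-dependent, so the order is explicit.
#' @param class_conflict How to class a matched pair whose two views
#'   disagree: `"higher_confidence"` (default; ties go to the frontal
#'   detection) or `"frontal"`.
#' @return An object of class `match_config`.
#' @export
match_config <- function(threshold = 0.5,
                         row_order = c("confidence_desc", "index"),
                         class_conflict = c("higher_confidence", "frontal")) {
  stopifnot(threshold >= 0, threshold <= 1)
  structure(list(threshold = threshold,
                 row_order = match.arg(row_order),
                 class_conflict = match.arg(class_conflict)),
            class = "match_config")
}

#' Greedy cross-view matching of frontal and rear detections
#'
#' Implements the frontal/rear correction loop: frontal detections are
#' processed in `cfg$row_order`; each takes the most-similar remaining rear
#' detection (argmax over columns, ties to the lowest rear index). If that
#' similarity strictly exceeds the threshold the two are recorded as the
#' same pod and both leave their sets; otherwise the frontal detection is
#' recorded as front-only. Rear detections left over at the end are
#' rear-only pods (seen only from the back).
#'
#' Every frontal index ends up in exactly one of `pairs`/`front_only`, every
#' rear index in exactly one of `pairs`/`rear_only`.
#'
#' @param sim `|f| x |p|` similarity matrix, entries finite in `[0, 1]`
#'   (rows = frontal detections, columns = rear detections).
#' @param cfg A [match_config()].
#' @param row_confidence Optional frontal confidences for
#'   `row_order = "confidence_desc"`; index order is used when absent.
#' @return An object of class `match_result`: `pairs` (data frame `front`,
#'   `rear`, `similarity`; 1-based indices), `front_only`, `rear_only`
#'   (integer index vectors), and the `threshold` used.
#' @export
greedy_match <- function(sim, cfg = match_config(), row_confidence = NULL) {
  sim <- as.matrix(sim)
  if (length(sim) > 0 && !all(is.finite(sim))) {
    stop("similarity matrix contains non-finite entries")
  }
  nf <- nrow(sim)
  np <- ncol(sim)
  rows <- seq_len(nf)
  if (cfg$row_order == "confidence_desc" && !is.null(row_confidence)) {
    rows <- order(-row_confidence, seq_len(nf))
  }
  remaining <- seq_len(np)
  pairs <- data.frame(front = integer(0), rear = integer(0),
                      similarity = numeric(0))
  front_only <- integer(0)
  for (i in rows) {
    if (length(remaining) > 0) {
      s <- sim[i, remaining]
      j <- which.max(s)  # ties: lowest remaining rear index
      if (s[j] > cfg$threshold) {
        pairs <- rbind(pairs, data.frame(front = i, rear = remaining[j],
                                         similarity = s[j]))
        remaining <- remaining[-j]
        next
      }
    }
    front_only <- c(front_only, i)
  }
  structure(list(pairs = pairs, front_only = sort(front_only),
                 rear_only = remaining, threshold = cfg$threshold),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> %d pairs, %d front-only, %d rear-only (threshold %g)\n",
    nrow(x$pairs), length(x$front_only), length(x$rear_only), x$threshold))
  invisible(x)
}

#' Deduplicated per-class pod count from a match result
#'
#' Each matched pair is one pod; when its two views disagree on the class,
#' `cfg$class_conflict` picks the winner. Each front-only and rear-only
#' detection contributes one pod of its own class. The total is therefore
#' `|pairs| + |front_only| + |rear_only|`.
#'
#' @param result A [greedy_match()] result.
#' @param front,rear The [pod_set()]s the result indices refer to.
#' @param cfg A [match_config()].
#' @return An object of class `plant_count`: named counts `one`..`four`
#'   plus `total`.
#' @export
count_from_match <- function(result, front, rear, cfg = match_config()) {
  if (nrow(result$pairs) > 0 &&
      (max(result$pairs$front) > nrow(front) ||
       max(result$pairs$rear) > nrow(rear))) {
    stop("match result indices out of range for the pod sets")
  }
  if (length(result$front_only) > 0 && max(result$front_only) > nrow(front)) {
    stop("front_only index out of range")
  }
  if (length(result$rear_only) > 0 && max(result$rear_only) > nrow(rear)) {
    stop("rear_only index out of range")
  }
  classes <- integer(0)
  for (k in seq_len(nrow(result$pairs))) {
    fi <- result$pairs$front[k]
    ri <- result$pairs$rear[k]
    fc <- front$pod_class[fi]
    rc <- rear$pod_class[ri]
    cl <- if (fc == rc) {
      fc
    } else if (cfg$class_conflict == "higher_confidence" &&
               rear$confidence[ri] > front$confidence[fi]) {
      rc
    } else {
      fc
    }
    classes <- c(classes, cl)
  }
  classes <- c(classes, front$pod_class[result$front_only],
               rear$pod_class[result$rear_only])
  counts <- tabulate(classes, nbins = 4)
  structure(c(one = counts[1], two = counts[2], three = counts[3],
              four = counts[4], total = length(classes)),
            class = "plant_count")
}

#' Count a single view without cross-view correction
#'
#' The class histogram of one view's detections: what a detector alone
#' reports, with no occlusion supplement and no deduplication.
#'
#' @param podset A [pod_set()].
#' @return A `plant_count`.
#' @export
count_single_view <- function(podset) {
  counts <- tabulate(podset$pod_class, nbins = 4)
  structure(c(one = counts[1], two = counts[2], three = counts[3],
              four = counts[4], total = nrow(podset)),
            class = "plant_count")
}

#' Fuse the two views of one plant into a corrected count
#'
#' Builds the similarity matrix between the frontal and (mirror-aligned)
#' rear detection sets, runs the greedy matcher, and tallies the
#' deduplicated per-class counts. With the identity oracle on synthetic
#' scenes where every pod is visible in at least one view, the fused count
#' equals the true count exactly.
#'
#' @param front,rear [pod_set()]s of the same plant; rear boxes (and crops)
#'   must already be mirror-aligned to the front frame. For a
#'   `siamese_model` both sets must carry crops ([attach_crops()]).
#' @param model Similarity scorer (see [similarity_matrix()]).
#' @param cfg A [match_config()].
#' @return List with `match` (the [greedy_match()] result), `count` (the
#'   fused `plant_count`) and `similarity` (the matrix).
#' @export
fuse_plant <- function(front, rear, model = oracle_similarity(),
                       cfg = match_config()) {
  sim <- similarity_matrix(model, front, rear)
  m <- greedy_match(sim, cfg, row_confidence = front$confidence)
  cnt <- count_from_match(m, front, rear, cfg)
  list(match = m, count = cnt, similarity = sim)
}
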