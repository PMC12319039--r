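test_that("greedy matching follows the correction-loop contract", {
  cfg <- match_config(row_order = "index")
  # empty input
  m <- greedy_match(matrix(numeric(0), 0, 0), cfg)
  expect_equal(nrow(m$pairs), 0)
  expect_length(m$front_only, 0)
  expect_length(m$rear_only, 0)
  # strict threshold: similarity exactly 0.5 does not match
  m <- greedy_match(matrix(0.5, 1, 1), cfg)
  expect_equal(nrow(m$pairs), 0)
  expect_equal(m$front_only, 1L)
  expect_equal(m$rear_only, 1L)
  # hand trace: (1,1) pairs at 0.9; front 2's best remaining is 0.3 <= 0.5
  m <- greedy_match(matrix(c(0.9, 0.4, 0.2, 0.3), 2, 2), cfg)
  expect_equal(m$pairs$front, 1L)
  expect_equal(m$pairs$rear, 1L)
  expect_equal(m$pairs$similarity, 0.9)
  expect_equal(m$front_only, 2L)
  expect_equal(m$rear_only, 2L)
  expect_error(greedy_match(matrix(c(NA, 1), 1, 2), cfg), "non-finite")
})

test_that("greedy matching equals a naive trace of the correction loop", {
  set.seed(17)
  for (k in 1:200) {
    nf <- sample(0:6, 1)
    np <- sample(0:6, 1)
    sim <- matrix(round(stats::runif(nf * np), 3), nf, np)
    conf <- stats::runif(nf)
    for (order_mode in c("index", "confidence_desc")) {
      cfg <- match_config(row_order = order_mode)
      rows <- if (order_mode == "index") seq_len(nf) else
        order(-conf, seq_len(nf))
      m <- greedy_match(sim, cfg, row_confidence = conf)
      bf <- bf_greedy_trace(sim, 0.5, rows)
      expect_equal(nrow(m$pairs), nrow(bf$pairs))
      if (nrow(m$pairs) > 0) {
        mo <- m$pairs[order(m$pairs$front), ]
        bo <- bf$pairs[order(bf$pairs[, 1]), , drop = FALSE]
        expect_equal(mo$front, bo[, 1])
        expect_equal(mo$rear, bo[, 2])
      }
      expect_equal(m$front_only, as.integer(bf$front_only))
      expect_equal(sort(m$rear_only), sort(as.integer(bf$rear_only)))
      # partition invariants
      expect_equal(nrow(m$pairs) + length(m$front_only), nf)
      expect_equal(nrow(m$pairs) + length(m$rear_only), np)
      expect_true(all(m$pairs$similarity > 0.5))
    }
  }
})

test_that("fused totals obey their bounds and threshold monotonicity", {
  set.seed(23)
  for (k in 1:40) {
    nf <- sample(1:6, 1)
    np <- sample(1:6, 1)
    sim <- matrix(stats::runif(nf * np), nf, np)
    total_at <- function(th) {
      m <- greedy_match(sim, match_config(threshold = th))
      nrow(m$pairs) + length(m$front_only) + length(m$rear_only)
    }
    t05 <- total_at(0.5)
    expect_gte(t05, max(nf, np))
    expect_lte(t05, nf + np)
    # nothing strictly exceeds 1, so threshold 1 forbids all matches
    expect_equal(total_at(1.0), nf + np)
    # raising the threshold never decreases the fused total
    ths <- sort(stats::runif(4))
    expect_true(all(diff(vapply(ths, total_at, numeric(1))) >= 0))
    # an all-1 matrix collapses to the larger side
    m <- greedy_match(matrix(1, nf, np), match_config(threshold = 0.5))
    expect_equal(nrow(m$pairs) + length(m$front_only) + length(m$rear_only),
                 max(nf, np))
  }
})

test_that("counting applies the pairing and conflict rules", {
  cfg <- match_config()
  empty <- greedy_match(matrix(numeric(0), 0, 0), cfg)
  z <- count_from_match(empty, pod_set("p", "front"), pod_set("p", "rear"),
                        cfg)
  expect_equal(unclass(z), c(one = 0L, two = 0L, three = 0L, four = 0L,
                             total = 0L))
  # 1 pair (class 3) + 1 front-only class 1 + 1 rear-only class 2
  front <- pod_set("p", "front", c(0, 20), c(0, 0), c(10, 30), c(10, 10),
                   c(3, 1), c(0.9, 0.9))
  rear <- pod_set("p", "rear", c(0, 40), c(0, 0), c(10, 50), c(10, 10),
                  c(3, 2), c(0.8, 0.8))
  res <- list(pairs = data.frame(front = 1L, rear = 1L, similarity = 0.9),
              front_only = 2L, rear_only = 2L)
  cnt <- count_from_match(res, front, rear, cfg)
  expect_equal(unclass(cnt), c(one = 1L, two = 1L, three = 1L, four = 0L,
                               total = 3L))
  # class conflict: higher confidence wins; frontal wins ties or when told
  front2 <- pod_set("p", "front", 0, 0, 10, 10, 2, 0.9)
  rear2 <- pod_set("p", "rear", 0, 0, 10, 10, 3, 0.4)
  res2 <- list(pairs = data.frame(front = 1L, rear = 1L, similarity = 0.9),
               front_only = integer(0), rear_only = integer(0))
  expect_equal(count_from_match(res2, front2, rear2, cfg)[["two"]], 1L)
  rear3 <- pod_set("p", "rear", 0, 0, 10, 10, 3, 0.95)
  expect_equal(count_from_match(res2, front2, rear3, cfg)[["three"]], 1L)
  expect_equal(count_from_match(
    res2, front2, rear3, match_config(class_conflict = "frontal"))[["two"]],
    1L)
  bad <- list(pairs = data.frame(front = 5L, rear = 1L, similarity = 0.9),
              front_only = integer(0), rear_only = integer(0))
  expect_error(count_from_match(bad, front2, rear2, cfg), "out of range")
})

test_that("fusing with the identity oracle recovers the true counts", {
  sc <- cached_scene(44, occlusion_rate = 0.4)
  f <- truth_to_detections(sc$truth, "front")
  r <- flip_boxes(truth_to_detections(sc$truth, "rear"),
                  sc$truth$image_size[1])
  fr <- fuse_plant(f, r, oracle_similarity())
  expect_equal(unclass(fr$count)[1:4], sc$truth$true_counts[1:4])
  expect_equal(fr$count[["total"]], sc$truth$true_counts[["total"]])
  # empty rear set: pure single-view reduction
  empty_rear <- pod_set(sc$truth$plant_id, "rear")
  single <- fuse_plant(f, empty_rear, oracle_similarity())
  expect_equal(unclass(single$count), unclass(count_single_view(f)))
  # rear-only pods supplement the frontal count
  n_rear_only <- sum(!sc$truth$pods$visible_front)
  expect_equal(fr$count[["total"]],
               count_single_view(f)[["total"]] + n_rear_only)
})
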