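# Shared fixtures, built in code.

# a flat single-color crop; class-coded constants make oracle scorers easy
const_crop <- function(value, side = 16L) {
  array(value, c(side, side, 3L))
}

# brute-force pixel-set IoU oracle: enumerate covered pixels, count sets
pixel_iou <- function(a, b) {
  pix <- function(bx) {
    as.vector(outer(bx$x_min:(bx$x_max - 1), (bx$y_min:(bx$y_max - 1)) * 1e4,
                    `+`))
  }
  pa <- pix(a)
  pb <- pix(b)
  length(intersect(pa, pb)) / length(union(pa, pb))
}

# literal trace of the frontal/rear correction loop, kept deliberately
# naive: explicit index sets, setdiff removal, no shared code with the
# package matcher
bf_greedy_trace <- function(sim, threshold, row_order) {
  p_left <- seq_len(ncol(sim))
  pairs <- list()
  front_only <- integer(0)
  for (a in row_order) {
    if (length(p_left) > 0) {
      sims <- vapply(p_left, function(m) sim[a, m], numeric(1))
      best <- p_left[which.max(sims)]
      if (sim[a, best] > threshold) {
        pairs[[length(pairs) + 1]] <- c(a, best)
        p_left <- setdiff(p_left, best)
        next
      }
    }
    front_only <- c(front_only, a)
  }
  list(pairs = if (length(pairs)) do.call(rbind, pairs) else
         matrix(integer(0), 0, 2),
       front_only = sort(front_only), rear_only = p_left)
}

# small scene cache so multiple test files reuse the same renders
scene_cache <- new.env(parent = emptyenv())
cached_scene <- function(seed, occlusion_rate = 0.2, ...) {
  key <- paste0("s", seed, "_o", occlusion_rate)
  if (is.null(scene_cache[[key]])) {
    scene_cache[[key]] <- generate_scene(
      synth_config(seed = seed, occlusion_rate = occlusion_rate, ...))
  }
  scene_cache[[key]]
}

tiny_model <- function(seed = 3L, side = 16L, dropout = 0.2) {
  build_siamese(siamese_config(backbone = "se_resnet_tiny",
                               input_side = side, dropout_rate = dropout,
                               seed = seed))
}
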