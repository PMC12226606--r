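# Shared fixtures and independent oracles for the test suite.

ct_default <- scenediff::default_class_table()

# central-difference gradient of a scalar-valued function of a matrix
numeric_gradient <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x
    xp[i] <- xp[i] + eps
    xm <- x
    xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# brute-force relation predicate checker, coded independently of
# relation_between: explicit interval containment and centre offsets
oracle_relation <- function(a, b) {
  contains <- function(outer, inner) {
    inner[1] > outer[1] && inner[3] < outer[3] &&
      inner[2] > outer[2] && inner[4] < outer[4]
  }
  if (contains(b, a)) {
    return("inside")
  }
  if (contains(a, b)) {
    return("surrounding")
  }
  dx <- mean(a[c(1, 3)]) - mean(b[c(1, 3)])
  dy <- mean(a[c(2, 4)]) - mean(b[c(2, 4)])
  if (abs(dx) >= abs(dy)) {
    if (dx < 0) "left_of" else "right_of"
  } else {
    if (dy < 0) "above" else "below"
  }
}

random_box <- function() {
  x <- sort(stats::runif(2))
  y <- sort(stats::runif(2))
  c(x[1], y[1], x[2], y[2])
}

# pixel-membership IoU oracle on an integer lattice over the unit square
oracle_iou_pixels <- function(a, b, res = 600L) {
  xs <- (seq_len(res) - 0.5) / res
  inside <- function(box, px, py) {
    px >= box[1] & px < box[3] & py >= box[2] & py < box[4]
  }
  grid <- expand.grid(px = xs, py = xs)
  ia <- inside(a, grid$px, grid$py)
  ib <- inside(b, grid$px, grid$py)
  sum(ia & ib) / sum(ia | ib)
}

# permute graph nodes (edges reference node ids so stay valid)
permute_graph <- function(g, perm) {
  g$nodes <- g$nodes[perm, , drop = FALSE]
  rownames(g$nodes) <- NULL
  g
}

random_graph_from_seed <- function(seed, canvas = 64L) {
  sc <- scenediff::sample_scene(scenediff::scene_config(canvas = canvas), seed)
  scenediff::mask_to_graph(sc$mask, ct_default)
}

small_scene_set <- local({
  cache <- NULL
  function(n = 60L, seed = 2L) {
    if (is.null(cache)) {
      cache <<- scenediff:::render_scenes(n, scenediff::scene_config(), seed)
    }
    cache
  }
})
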