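test_that("node attributes match a brute-force pixel oracle", {
  # 8x8 square of class 3 with 0-based top-left pixel (28, 28) on 64x64
  m <- matrix(0L, 64, 64)
  m[29:36, 29:36] <- 3L
  g <- mask_to_graph(m, ct_default)
  expect_equal(nrow(g$nodes), 1L)
  expect_equal(g$nodes$cx, 0.5)
  expect_equal(g$nodes$cy, 0.5)
  expect_equal(g$nodes$w, 8 / 64)
  expect_equal(g$nodes$h, 8 / 64)
  expect_equal(g$nodes$area, 64 / 4096)

  # brute-force mean/extent on an irregular region
  m2 <- matrix(0L, 32, 32)
  px <- list(c(5, 7), c(5, 8), c(6, 7), c(9, 20), c(10, 21))
  for (p in px) m2[p[1], p[2]] <- 4L
  g2 <- mask_to_graph(m2, ct_default)
  cols <- vapply(px, `[[`, 0, 2)
  rows <- vapply(px, `[[`, 0, 1)
  expect_equal(g2$nodes$cx, mean(cols - 0.5) / 32)
  expect_equal(g2$nodes$cy, mean(rows - 0.5) / 32)
  expect_equal(g2$nodes$w, (max(cols) - min(cols) + 1) / 32)
  expect_equal(g2$nodes$area, length(px) / 1024)
})

test_that("empty masks yield empty graphs and unknown ids are rejected", {
  g0 <- mask_to_graph(matrix(0L, 16, 16), ct_default)
  expect_equal(nrow(g0$nodes), 0L)
  expect_equal(nrow(g0$edges), 0L)
  bad <- matrix(0L, 16, 16)
  bad[3, 3] <- 99L
  expect_error(mask_to_graph(bad, ct_default), "schema error")
})

test_that("relation assignment agrees with an independent predicate oracle", {
  expect_identical(
    relation_between(c(.4, .4, .6, .6), c(.1, .1, .9, .9)), "inside"
  )
  expect_identical(
    relation_between(c(.1, .1, .9, .9), c(.4, .4, .6, .6)), "surrounding"
  )
  expect_identical(
    relation_between(c(.1, .4, .3, .6), c(.7, .4, .9, .6)), "left_of"
  )
  expect_error(relation_between(c(.5, .5, .5, .6), c(0, 0, 1, 1)), "degenerate")
  set.seed(101)
  dual <- c(
    left_of = "right_of", right_of = "left_of", above = "below",
    below = "above", inside = "surrounding", surrounding = "inside"
  )
  pairs <- replicate(10000, list(a = random_box(), b = random_box()),
    simplify = FALSE
  )
  got <- vapply(pairs, function(p) relation_between(p$a, p$b), "")
  want <- vapply(pairs, function(p) oracle_relation(p$a, p$b), "")
  expect_identical(got, want)
  # reciprocal-pair consistency
  rev_got <- vapply(pairs, function(p) relation_between(p$b, p$a), "")
  expect_identical(rev_got, unname(dual[got]))
})

test_that("extracted graphs have all-pairs edges in the six-term vocabulary", {
  for (seed in 1:25) {
    g <- random_graph_from_seed(seed)
    n <- nrow(g$nodes)
    expect_equal(nrow(g$edges), n * (n - 1L))
    expect_true(all(g$edges$relation %in% scenediff:::RELATIONS))
  }
})

test_that("generator ground truth round-trips through extraction", {
  # class sets always match, whatever the occlusion structure
  cfg <- scene_config()
  for (seed in 1:20) {
    sc <- sample_scene(cfg, seed)
    g <- mask_to_graph(sc$mask, ct_default)
    expect_setequal(
      g$nodes$class_id,
      vapply(sc$objects, `[[`, 0L, "class_id")
    )
  }
  # centroid agreement is claimed only without cross-object occlusion:
  # anatomy-only scenes, where the concentric stack occludes symmetrically
  # about the shared centre
  cfg0 <- scene_config(
    tool_count_range = c(0L, 0L), misc_count_range = c(0L, 0L)
  )
  for (seed in 1:20) {
    sc <- sample_scene(cfg0, seed)
    g <- mask_to_graph(sc$mask, ct_default)
    for (obj in sc$objects) {
      nd <- g$nodes[g$nodes$class_id == obj$class_id, ]
      expect_lt(abs(nd$cx - obj$centroid[1]), 1 / cfg0$canvas)
      expect_lt(abs(nd$cy - obj$centroid[2]), 1 / cfg0$canvas)
    }
  }
})

test_that("feature rows unroll class one-hot plus geometry and permute with nodes", {
  g1 <- scenediff:::new_scene_graph(
    data.frame(
      id = 0L, class_id = 2L, cx = 0.5, cy = 0.25, w = 0.1, h = 0.2,
      area = 0.02
    ),
    NULL, c(64L, 64L)
  )
  ft <- graph_to_features(g1, 5L)
  expect_equal(
    as.numeric(ft$features),
    c(0, 0, 1, 0, 0, 0.5, 0.25, 0.1, 0.2, 0.02)
  )
  ft0 <- graph_to_features(
    scenediff:::new_scene_graph(NULL, NULL, c(64L, 64L)), 5L
  )
  expect_equal(dim(ft0$features), c(0L, 10L))
  set.seed(7)
  for (k in 1:10) {
    g <- random_graph_from_seed(200 + k)
    if (nrow(g$nodes) < 2) next
    perm <- sample(nrow(g$nodes))
    f1 <- graph_to_features(g, 10L)$features
    f2 <- graph_to_features(permute_graph(g, perm), 10L)$features
    expect_equal(f2, f1[perm, , drop = FALSE])
  }
})

test_that("edits rewrite nodes and recompute every edge", {
  g <- random_graph_from_seed(31)
  tools <- ct_default$class_id[ct_default$category == "tool"]
  tool_ids <- g$nodes$id[g$nodes$class_id %in% tools]
  skip_if(length(tool_ids) == 0) # seed chosen to contain tools
  # empty edit list: identity
  expect_identical(edit_graph(g, list()), g)
  # delete all tools
  g2 <- edit_graph(g, lapply(tool_ids, function(id) {
    list(op = "delete", node_id = id)
  }))
  expect_false(any(g2$nodes$class_id %in% tools))
  expect_false(any(g2$edges$src %in% tool_ids | g2$edges$dst %in% tool_ids))
  # a move across a static node flips left_of to right_of
  ga <- scenediff:::new_scene_graph(
    data.frame(
      id = 0:1, class_id = c(4L, 5L), cx = c(0.2, 0.5), cy = 0.5,
      w = 0.1, h = 0.1, area = 0.01
    ),
    NULL, c(64L, 64L)
  )
  ga$edges <- scenediff:::compute_edges(ga$nodes)
  rel_before <- ga$edges$relation[ga$edges$src == 0 & ga$edges$dst == 1]
  expect_identical(rel_before, "left_of")
  gb <- edit_graph(ga, list(list(op = "move", node_id = 0L, centroid = c(0.8, 0.5))))
  expect_identical(
    gb$edges$relation[gb$edges$src == 0 & gb$edges$dst == 1], "right_of"
  )
  expect_identical(
    gb$edges$relation[gb$edges$src == 0 & gb$edges$dst == 1],
    relation_between(
      c(0.75, 0.45, 0.85, 0.55), c(0.45, 0.45, 0.55, 0.55)
    )
  )
  # invalid edits
  expect_error(
    edit_graph(g, list(list(op = "retype", node_id = g$nodes$id[1], class_id = 0L))),
    "background"
  )
  expect_error(
    edit_graph(g, list(list(op = "move", node_id = 999L, centroid = c(.5, .5)))),
    "unknown node_id"
  )
})

test_that("scene graphs round-trip through JSON field-for-field", {
  for (seed in 1:40) {
    g <- random_graph_from_seed(seed, canvas = 32L)
    p <- withr::local_tempfile(fileext = ".json")
    save_graph(g, p)
    g2 <- load_graph(p)
    expect_equal(g2$nodes, g$nodes)
    expect_equal(g2$edges, g$edges)
    expect_equal(as.integer(g2$canvas), as.integer(g$canvas))
  }
  # empty graph round-trips
  p <- withr::local_tempfile(fileext = ".json")
  g0 <- scenediff:::new_scene_graph(NULL, NULL, c(16L, 16L))
  save_graph(g0, p)
  expect_equal(nrow(load_graph(p)$nodes), 0L)
  # edge to a missing node is a schema error
  bad <- jsonlite::read_json(save_graph(random_graph_from_seed(2), p))
  bad$edges[[1]]$src <- 999L
  jsonlite::write_json(bad, p, auto_unbox = TRUE, digits = NA)
  expect_error(load_graph(p), "schema error")
  bad$version <- 99L
  jsonlite::write_json(bad, p, auto_unbox = TRUE, digits = NA)
  expect_error(load_graph(p), "schema version")
})
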