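test_that("IoU matches a pixel-membership oracle and its axioms", {
  expect_equal(iou(c(0, 0, 10, 10), c(5, 5, 15, 15)), 25 / 175)
  expect_equal(iou(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(iou(c(0, 0, 1, 1), c(2, 2, 3, 3)), 0)
  expect_equal(iou(c(0, 0, 0, 1), c(0, 0, 1, 1)), 0) # degenerate box
  set.seed(61)
  for (i in 1:25) {
    a <- random_box()
    b <- random_box()
    expect_equal(iou(a, b), iou(b, a))
    expect_gte(iou(a, b), 0)
    expect_lte(iou(a, b), 1)
    expect_equal(iou(a, b), oracle_iou_pixels(a, b), tolerance = 0.03)
  }
})

test_that("the rule-based detector recovers rendered objects and equivaries under flips", {
  cfg <- scene_config()
  sc <- sample_scene(cfg, 21L)
  g <- mask_to_graph(sc$mask, ct_default)
  det <- detect_objects(sc$image, ct_default)
  rep <- coherence_score(list(det), list(g))
  expect_gte(rep$mean_iou, 0.9)
  expect_equal(rep$f1, 1.0)
  # blank (background-coloured) image: nothing detected
  blank <- array(rep(c(0.02, 0.02, 0.03), each = 64 * 64), c(64, 64, 3))
  expect_equal(nrow(detect_objects(blank, ct_default)), 0L)
  # horizontal flip: x-extents mirror, classes unchanged
  flipped <- sc$image[, dim(sc$image)[2]:1, ]
  det_f <- detect_objects(flipped, ct_default)
  ord <- order(det$class_id, det$xmin)
  ord_f <- order(det_f$class_id, -det_f$xmax)
  expect_equal(det_f$class_id[ord_f], det$class_id[ord])
  expect_equal(det_f$xmin[ord_f], 1 - det$xmax[ord], tolerance = 1e-9)
  expect_equal(det_f$xmax[ord_f], 1 - det$xmin[ord], tolerance = 1e-9)
  expect_equal(det_f$ymin[ord_f], det$ymin[ord])
})

test_that("coherence scoring handles the identity and empty cases", {
  g <- random_graph_from_seed(9)
  perfect <- scenediff:::graph_boxes(g)
  perfect$score <- 1.0
  rep1 <- coherence_score(list(perfect), list(g))
  expect_equal(rep1$f1, 1.0)
  expect_equal(rep1$mean_iou, 1.0)
  none <- coherence_score(
    list(perfect[0, ]), list(g)
  )
  expect_equal(none$f1, 0)
  expect_equal(none$mean_iou, 0)
  expect_error(coherence_score(list(perfect), list(g, g)), "per image")
})

test_that("greedy matching equals exhaustive optimal matching on a 3-node case", {
  g <- scenediff:::new_scene_graph(
    data.frame(
      id = 0:2, class_id = c(1L, 4L, 5L),
      cx = c(0.3, 0.6, 0.8), cy = c(0.3, 0.6, 0.2),
      w = c(0.2, 0.15, 0.1), h = c(0.2, 0.15, 0.1),
      area = c(0.04, 0.02, 0.01)
    ),
    NULL, c(64L, 64L)
  )
  det <- data.frame(
    class_id = c(1L, 7L, 5L), # one class mismatch (4 vs 7)
    xmin = c(0.21, 0.52, 0.78), ymin = c(0.21, 0.52, 0.18),
    xmax = c(0.41, 0.68, 0.88), ymax = c(0.41, 0.68, 0.28),
    score = 1.0
  )
  gt <- scenediff:::graph_boxes(g)
  m_greedy <- scenediff:::match_detections(det, gt)
  # exhaustive enumeration over all one-to-one same-class assignments
  best <- NULL
  best_total <- -1
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (p in perms) {
    total <- 0
    ok <- TRUE
    pairs <- list()
    for (d in 1:3) {
      gidx <- p[d]
      if (det$class_id[d] != gt$class_id[gidx]) next
      i <- iou(
        as.numeric(det[d, c("xmin", "ymin", "xmax", "ymax")]),
        as.numeric(gt[gidx, c("xmin", "ymin", "xmax", "ymax")])
      )
      total <- total + i
      pairs[[length(pairs) + 1]] <- c(d, gidx, i)
    }
    if (total > best_total) {
      best_total <- total
      best <- pairs
    }
  }
  expect_equal(sum(m_greedy$iou), best_total, tolerance = 1e-12)
  expect_equal(nrow(m_greedy), length(best))
})

test_that("coherence is order-invariant and degrades when a matched box drifts", {
  graphs <- lapply(c(3L, 8L, 15L), random_graph_from_seed)
  dets <- lapply(graphs, function(g) {
    b <- scenediff:::graph_boxes(g)
    b$score <- 1.0
    b
  })
  r1 <- coherence_score(dets, graphs)
  perm <- c(2L, 3L, 1L)
  r2 <- coherence_score(dets[perm], graphs[perm])
  expect_equal(r1$f1, r2$f1)
  expect_equal(r1$mean_iou, r2$mean_iou)
  # drift one matched detection below the threshold: F1 cannot increase
  d3 <- dets
  d3[[1]]$xmin[1] <- d3[[1]]$xmin[1] + 0.5
  d3[[1]]$xmax[1] <- d3[[1]]$xmax[1] + 0.5
  r3 <- coherence_score(d3, graphs)
  expect_lt(r3$f1, r1$f1)
  expect_lt(r3$mean_iou, r1$mean_iou)
})

test_that("diversity and fidelity proxies order image sets sensibly", {
  imgs <- lapply(1:5, function(i) sample_scene(scene_config(canvas = 32L), 70 + i)$image)
  expect_error(image_diversity(imgs[1]), "at least 2")
  # identical images: diversity exactly 0
  expect_equal(image_diversity(list(imgs[[1]], imgs[[1]])), 0)
  # inversion is farther than a tiny perturbation
  base <- imgs[[1]]
  d_inv <- image_diversity(list(base, 1 - base))
  d_noise <- image_diversity(list(base, pmin(pmax(base + 0.005, 0), 1)))
  expect_gt(d_inv, d_noise)
  # a set against itself: Frechet distance ~ 0
  fk <- fid_kid(imgs, imgs)
  expect_lt(abs(fk$fid), 1e-3)
  # disjoint colour distributions separate clearly
  dark <- lapply(imgs, function(x) x * 0.2)
  fk2 <- fid_kid(imgs, dark)
  expect_gt(fk2$fid, fk$fid + 0.1)
  expect_gt(fk2$kid, 0)
})
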