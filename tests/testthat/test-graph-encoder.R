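enc_cfg <- graph_encoder_config(
  num_layers = 3L, hidden_dim = 32L, out_dim = 16L, n_classes = 10L
)

test_that("graph embeddings are invariant to node permutation", {
  enc <- graph_encoder_init(enc_cfg, seed = 9L)
  checked <- 0L
  seed <- 0L
  while (checked < 50L) {
    seed <- seed + 1L
    g <- random_graph_from_seed(300 + seed)
    if (nrow(g$nodes) < 2L) next
    perm <- sample(nrow(g$nodes))
    d <- max(abs(encode_graph(enc, g) - encode_graph(enc, permute_graph(g, perm))))
    expect_lt(d, 1e-5)
    checked <- checked + 1L
  }
})

test_that("isolated nodes aggregate the zero message for every aggregation", {
  for (agg in c("mean", "sum", "max")) {
    cfg <- graph_encoder_config(
      num_layers = 1L, hidden_dim = 16L, out_dim = 8L,
      aggregation = agg, n_classes = 5L
    )
    enc <- graph_encoder_init(cfg, seed = 2L)
    x <- matrix(rnorm(10), 1, 10)
    out_iso <- gnn_layer(x, matrix(integer(), 2, 0), integer(), enc$params,
      layer = 1L, aggregation = agg
    )
    # by hand: tanh(W_self x + b) with zero neighbour term
    by_hand <- tanh(
      x %*% enc$params$self1_W + matrix(enc$params$self1_b, 1)
    )
    expect_equal(out_iso, by_hand, tolerance = 1e-12)
  }
})

test_that("star-graph hub output ignores leaf ordering", {
  set.seed(5)
  feats <- matrix(rnorm(5 * 10), 5, 10)
  ei <- rbind(2:5, rep(1L, 4)) # leaves -> hub
  et <- c(1L, 2L, 3L, 4L)
  for (agg in c("mean", "sum", "max")) {
    cfg <- graph_encoder_config(
      num_layers = 1L, hidden_dim = 16L, out_dim = 8L,
      aggregation = agg, n_classes = 5L
    )
    enc <- graph_encoder_init(cfg, seed = 3L)
    h1 <- gnn_layer(feats, ei, et, enc$params, aggregation = agg)
    perm <- c(3L, 1L, 4L, 2L)
    h2 <- gnn_layer(feats, rbind(ei[1, perm], ei[2, ]), et[perm], enc$params,
      aggregation = agg
    )
    expect_equal(h1[1, ], h2[1, ], tolerance = 1e-12)
  }
})

test_that("symmetric two-node graphs produce identical node updates", {
  enc <- graph_encoder_init(
    graph_encoder_config(num_layers = 1L, hidden_dim = 16L, out_dim = 8L, n_classes = 5L),
    seed = 4L
  )
  x <- matrix(rep(rnorm(10), 2), 2, 10, byrow = TRUE)
  ei <- rbind(c(1L, 2L), c(2L, 1L))
  h <- gnn_layer(x, ei, c(1L, 1L), enc$params)
  expect_equal(h[1, ], h[2, ], tolerance = 1e-12)
})

test_that("information propagates at most L hops on a path graph", {
  n_cls <- 6L
  path_graph_feats <- function(perturb_last = FALSE) {
    f <- matrix(0, 5, n_cls + 5)
    for (i in 1:5) f[i, i] <- 1
    f[, n_cls + 1] <- seq(0.1, 0.5, by = 0.1)
    if (perturb_last) f[5, n_cls + 2] <- 5
    f
  }
  # directed path 5 -> 4 -> 3 -> 2 -> 1; node 5 is 4 hops from node 1
  ei <- rbind(2:5, 1:4)
  et <- rep(1L, 4)
  run <- function(L, perturb) {
    cfg <- graph_encoder_config(
      num_layers = L, hidden_dim = 16L, out_dim = 8L, n_classes = n_cls
    )
    enc <- graph_encoder_init(cfg, seed = 6L)
    h <- path_graph_feats(perturb)
    for (l in seq_len(L)) {
      h <- gnn_layer(h, ei, et, enc$params, layer = l)
    }
    h[1, ]
  }
  # with L = 3 layers the perturbation at distance 4 cannot reach node 1
  expect_equal(run(3L, FALSE), run(3L, TRUE), tolerance = 1e-12)
  # with L = 4 it can
  expect_false(isTRUE(all.equal(run(4L, FALSE), run(4L, TRUE))))
})

test_that("null graphs embed to zero and class changes move the embedding", {
  enc <- graph_encoder_init(enc_cfg, seed = 9L)
  g0 <- mask_to_graph(matrix(0L, 16, 16), ct_default)
  expect_identical(encode_graph(enc, g0), numeric(16L))
  g <- random_graph_from_seed(12)
  tools <- ct_default$class_id[ct_default$category == "tool"]
  have <- g$nodes$id[g$nodes$class_id %in% tools]
  skip_if(length(have) == 0)
  free <- setdiff(tools, g$nodes$class_id)
  g2 <- edit_graph(g, list(list(op = "retype", node_id = have[1], class_id = free[1])))
  expect_gt(max(abs(encode_graph(enc, g) - encode_graph(enc, g2))), 1e-8)
})
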