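test_that("contrastive loss matches the printed formula", {
  set.seed(41)
  # no negatives: ratio is 1, loss exactly 0
  expect_identical(global_loss(rnorm(8), rnorm(8), list()), 0)
  # equal logits over 1 positive + 3 negatives: ln 4
  z <- rnorm(6)
  p <- rnorm(6)
  expect_equal(global_loss(z, p, list(p, p, p)), log(4), tolerance = 1e-12)
  # random vectors against a direct high-precision evaluation of the ratio
  for (i in 1:50) {
    z <- rnorm(12)
    pos <- rnorm(12)
    negs <- lapply(1:8, function(j) rnorm(12))
    direct <- {
      e_pos <- exp(sum(z * pos))
      e_negs <- vapply(negs, function(v) exp(sum(z * v)), numeric(1))
      -log(e_pos / (e_pos + sum(e_negs)))
    }
    expect_equal(global_loss(z, pos, negs), direct, tolerance = 1e-9)
  }
  # loss decreases monotonically as the positive logit grows
  z <- c(1, 0, 0)
  negs <- lapply(1:4, function(i) rnorm(3))
  losses <- vapply(seq(0, 30, by = 3), function(s) {
    global_loss(z, c(s, 0, 0), negs)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_lt(losses[length(losses)], 1e-6)
  # extreme logits stay finite via max-subtraction
  expect_true(is.finite(global_loss(c(1e3, 0), c(1e3, 0), list(c(-1e3, 0)))))
  expect_error(global_loss(rnorm(3), rnorm(4), list()), "dimension mismatch")
})

test_that("negative sampling is uniform, exclusive and rejects identical masks", {
  fake <- lapply(1:100, function(i) list(mask = matrix(i, 2, 2)))
  # k = |D| - 1 returns every other index exactly once
  all_others <- sample_negatives(fake, positive_index = 5L, k = 99L, seed = 1L)
  expect_setequal(all_others, setdiff(1:100, 5L))
  # positive never included; inclusion frequency uniform within 2 points
  counts <- numeric(100)
  n_draws <- 50000L
  for (i in seq_len(n_draws)) {
    idx <- sample_negatives(fake, positive_index = 7L, k = 4L, seed = i)
    counts[idx] <- counts[idx] + 1
  }
  expect_equal(counts[7], 0)
  incl <- counts[-7] / n_draws
  expect_true(all(abs(incl - 4 / 99) <= 0.02))
  # pixel-identical masks are redrawn
  dup <- lapply(1:10, function(i) list(mask = matrix(ifelse(i <= 2, 0, i), 2, 2)))
  for (s in 1:200) {
    idx <- sample_negatives(dup, positive_index = 1L, k = 5L, seed = s)
    expect_false(2L %in% idx) # mask 2 is identical to the positive's
  }
  expect_error(sample_negatives(fake, 1L, 100L, 1L), "too small")
})

test_that("mask projection pools latents exactly and normalizes when asked", {
  set.seed(43)
  Z <- matrix(rnorm(64 * 8), 64, 8)
  head <- list(W = diag(8), b = rep(0, 8), normalize = FALSE)
  expect_equal(project_mask_embedding(Z, head), colMeans(Z))
  # brute-force pooling oracle over all positions
  pooled <- numeric(8)
  for (i in seq_len(64)) pooled <- pooled + Z[i, ] / 64
  expect_equal(project_mask_embedding(Z, head), pooled)
  head$normalize <- TRUE
  v <- project_mask_embedding(Z, head)
  expect_equal(sum(v^2), 1)
  # identical masks project identically through a trained-shape head
  head2 <- list(W = matrix(rnorm(8 * 4), 8, 4), b = rnorm(4), normalize = TRUE)
  expect_identical(
    project_mask_embedding(Z, head2), project_mask_embedding(Z + 0, head2)
  )
})

test_that("global pre-training beats chance and never touches image pixels", {
  scenes <- small_scene_set()
  mcfg <- codec_config("mask",
    downsample_factor = 8L, codebook_size = 32L,
    code_dim = 16L, hidden_dim = 48L, epochs = 8L, batch_size = 8L,
    n_classes = nrow(ct_default)
  )
  codec_m <- train_codec(scenes, mcfg, seed = 5L)
  # alignment must rely on masks only: strip the images entirely
  masks_only <- lapply(scenes, function(s) list(mask = s$mask))
  ecfg <- graph_encoder_config(
    num_layers = 2L, hidden_dim = 32L, out_dim = 24L, n_classes = 10L
  )
  k <- 4L
  fit <- train_global(masks_only, codec_m, ecfg, k = k, seed = 3L, epochs = 6L)
  expect_lt(fit$heldout_loss, log(k + 1)) # better than a uniform softmax
  fit2 <- train_global(masks_only, codec_m, ecfg, k = k, seed = 3L, epochs = 6L)
  expect_identical(fit$trace, fit2$trace)
})
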