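#' Project a mask latent grid to the graph-embedding space
#'
#' Spatial mean pooling over all latent positions followed by a learned
#' linear head; optionally L2-normalized. These projections are the targets
#' the global graph encoder aligns to -- mask embeddings, deliberately not
#' image embeddings, so scenes sharing layout and instruments group
#' together regardless of texture.
#'
#' @param z_m a `latent_grid` from the mask codec, or an N x d matrix of
#'   latent positions.
#' @param head projection head: list with `W` (d x out), `b` (1 x out) and
#'   logical `normalize`.
#' @return numeric vector of length `out`.
#' @export
project_mask_embedding <- function(z_m, head) {
  Z <- if (inherits(z_m, "latent_grid")) latent_to_matrix(z_m) else z_m
  pooled <- matrix(colMeans(Z), 1L)
  out <- pooled %*% head$W + matrix(head$b, 1L)
  if (isTRUE(head$normalize)) {
    nrm <- sqrt(sum(out^2))
    if (nrm > 1e-12) out <- out / nrm
  }
  as.numeric(out)
}

#' Contrastive graph-mask alignment loss
#'
#' The softmax-style negative log ratio
#' `-log( exp(z_G . z_m+) / (exp(z_G . z_m+) + sum_i exp(z_G . z_mi-)) )`
#' over one compliant mask embedding and `k` negatives, evaluated with
#' log-sum-exp max-subtraction (numerically equivalent to the plain ratio).
#' With `k = 0` the ratio is 1 and the loss exactly 0.
#'
#' @param z_g numeric graph embedding.
#' @param pos numeric embedding of the compliant mask.
#' @param negs list (or row-matrix) of `k` negative mask embeddings.
#' @return scalar loss.
#' @export
#' @examples
#' global_loss(c(1, 0), c(1, 0), list()) # exactly 0
global_loss <- function(z_g, pos, negs) {
  if (is.matrix(negs)) negs <- asplit(negs, 1L)
  d <- length(z_g)
  if (length(pos) != d || any(vapply(negs, length, 0L) != d)) {
    stop("dimension mismatch")
  }
  if (length(negs) == 0L) {
    return(0)
  }
  logits <- c(
    sum(z_g * pos),
    vapply(negs, function(v) sum(z_g * v), numeric(1))
  )
  m <- max(logits)
  (m + log(sum(exp(logits - m)))) - logits[1]
}

#' Sample negative masks for contrastive training
#'
#' Draws `k` indices uniformly without replacement from the dataset,
#' excluding the positive; any draw whose mask is pixel-identical to the
#' positive's is rejected and redrawn.
#'
#' @param dataset list of scenes with `$mask`.
#' @param positive_index index of the compliant scene.
#' @param k number of negatives.
#' @param seed integer seed.
#' @return integer vector of `k` indices.
#' @export
sample_negatives <- function(dataset, positive_index, k, seed) {
  n <- length(dataset)
  if (n <= k) stop("dataset too small for k negatives")
  with_seed(seed, {
    pool <- setdiff(seq_len(n), positive_index)
    picked <- sample_k(pool, k)
    pos_mask <- dataset[[positive_index]]$mask
    for (j in seq_along(picked)) {
      tries <- 0L
      while (identical(dataset[[picked[j]]]$mask, pos_mask)) {
        cand <- setdiff(pool, picked)
        if (!length(cand)) break
        picked[j] <- sample_one(cand)
        tries <- tries + 1L
        if (tries > n) break
      }
    }
    picked
  })
}

#' Pre-train the global graph encoder
#'
#' Aligns graph embeddings with mask-codec embeddings by the contrastive
#' loss: for each scene the compliant mask is the positive and `k` random
#' other scenes' masks are negatives. The mask codec is frozen; the graph
#' encoder and the mask projection head train jointly. Embeddings are
#' L2-normalized before the dot product by default (`normalize = FALSE`
#' recovers the literal unnormalized formulation). The image codec is never
#' touched: alignment deliberately happens in mask-embedding space.
#'
#' @param dataset list of scenes.
#' @param codec_m trained mask `latent_codec`.
#' @param encoder_config a [graph_encoder_config()].
#' @param k number of negatives per sample.
#' @param seed integer seed.
#' @param epochs,lr training hyperparameters.
#' @param normalize L2-normalize embeddings before the dot product.
#' @param class_table scene [class_table()].
#' @param holdout_frac held-out fraction for the retrieval evaluation.
#' @return list with `encoder`, `head`, `trace`, `heldout_loss`,
#'   `retrieval_top1` (top-1 compliant-mask retrieval rate against 15
#'   negatives on the holdout) and `holdout_idx`.
#' @export
train_global <- function(dataset, codec_m, encoder_config, k = 8L, seed = 1L,
                         epochs = 25L, lr = 1e-3, normalize = TRUE,
                         class_table = default_class_table(),
                         holdout_frac = 0.1) {
  with_seed(derive_seed(seed, "pretrain_global"), {
    n <- length(dataset)
    pooled <- t(vapply(dataset, function(it) {
      colMeans(latent_to_matrix(codec_encode(codec_m, it$mask)))
    }, numeric(codec_m$config$code_dim)))
    fts <- lapply(dataset, function(it) {
      graph_to_features(
        mask_to_graph(it$mask, class_table), encoder_config$n_classes
      )
    })
    encoder <- graph_encoder_init(encoder_config, derive_seed(seed, "global_encoder"))
    head_lin <- with_seed(
      derive_seed(seed, "global_head"),
      nn_linear(codec_m$config$code_dim, encoder_config$out_dim, gain = 1)
    )
    params <- c(
      stats::setNames(encoder$params, paste0("E.", names(encoder$params))),
      list(H.W = head_lin$W, H.b = head_lin$b)
    )
    if (normalize) {
      # learnable inverse temperature (log-parameterised) sharpening the
      # softmax over unit-norm embeddings, as in CLIP-style alignment
      params$H.ls <- matrix(log(5), 1L, 1L)
    }
    opt <- adam_init(params)
    n_hold <- max(1L, round(holdout_frac * n))
    hold_idx <- sample.int(n, n_hold)
    train_idx <- setdiff(seq_len(n), hold_idx)

    # contrastive forward for one sample on a tape
    sample_loss_op <- function(tape, nodes, i, neg_idx) {
      enodes <- strip_prefix(nodes, "E.")
      ft <- fts[[i]]
      zg <- if (nrow(ft$features) == 0L) {
        ad_const(tape, matrix(0, 1L, encoder_config$out_dim))
      } else {
        encode_graph_op(
          enodes, tape, ft$features, ft$edge_index, ft$edge_type, encoder_config
        )
      }
      tgt <- ad_add(
        ad_matmul(ad_const(tape, pooled[c(i, neg_idx), , drop = FALSE]), nodes$H.W),
        nodes$H.b
      )
      if (normalize) {
        zg <- ad_l2norm_rows(zg)
        tgt <- ad_l2norm_rows(tgt)
      }
      logits <- ad_matmul(zg, ad_transpose(tgt)) # 1 x (k+1), positive first
      if (normalize) logits <- ad_mul(logits, ad_exp(nodes$H.ls))
      ad_sub(ad_logsumexp(logits), ad_entry(logits, 1L, 1L))
    }

    eval_ids <- function(i, neg_idx) {
      tape <- ad_tape()
      nodes <- ad_bind(tape, params)
      ad_value(sample_loss_op(tape, nodes, i, neg_idx))[1]
    }

    trace <- data.frame(epoch = integer(), train = numeric(), holdout = numeric())
    for (ep in seq_len(epochs)) {
      ord <- sample(train_idx)
      losses <- numeric(0)
      for (i in ord) {
        neg_idx <- sample_negatives(
          dataset, i, k,
          derive_seed(seed, paste0("neg_", ep, "_", i))
        )
        tape <- ad_tape()
        nodes <- ad_bind(tape, params)
        loss <- sample_loss_op(tape, nodes, i, neg_idx)
        grads <- ad_backward(tape, loss)
        step <- adam_step(params, ad_collect(grads, nodes), opt, lr = lr)
        params <- step$params
        opt <- step$state
        losses <- c(losses, ad_value(loss)[1])
      }
      hold_losses <- vapply(hold_idx, function(i) {
        eval_ids(i, sample_negatives(
          dataset, i, k, derive_seed(seed, paste0("negh_", ep, "_", i))
        ))
      }, numeric(1))
      trace <- rbind(trace, data.frame(
        epoch = ep, train = mean(losses), holdout = mean(hold_losses)
      ))
    }

    encoder$params <- strip_prefix(params, "E.")
    head <- list(W = params$H.W, b = params$H.b, normalize = normalize)

    # holdout retrieval: compliant mask ranked against 15 random negatives
    top1 <- vapply(hold_idx, function(i) {
      negs <- sample_negatives(
        dataset, i, min(15L, n - 1L), derive_seed(seed, paste0("retr_", i))
      )
      zg <- encode_graph_normed(encoder, fts[[i]], normalize)
      scores <- vapply(c(i, negs), function(j) {
        sum(zg * project_mask_embedding(matrix(pooled[j, ], 1L), head))
      }, numeric(1))
      as.numeric(which.max(scores) == 1L)
    }, numeric(1))

    list(
      encoder = encoder, head = head, trace = trace,
      heldout_loss = trace$holdout[nrow(trace)],
      retrieval_top1 = mean(top1), holdout_idx = hold_idx
    )
  })
}

encode_graph_normed <- function(encoder, ft, normalize) {
  z <- if (nrow(ft$features) == 0L) {
    numeric(encoder$config$out_dim)
  } else {
    tape <- ad_tape()
    nodes <- ad_bind(tape, encoder$params)
    as.numeric(ad_value(encode_graph_op(
      nodes, tape, ft$features, ft$edge_index, ft$edge_type, encoder$config
    )))
  }
  if (normalize) {
    nrm <- sqrt(sum(z^2))
    if (nrm > 1e-12) z <- z / nrm
  }
  z
}
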