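#' Rectangular class masking of an image
#'
#' Picks one of the mask's non-background classes uniformly at random and
#' replaces the image pixels inside that class's tight bounding box with a
#' fill colour (the segmentation mask itself is untouched). This is the
#' corruption the local pre-training task reconstructs from.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param mask H x W integer class-id matrix.
#' @param seed integer seed for the class draw.
#' @param class_table the scene's [class_table()].
#' @param fill length-3 fill colour; defaults to the image's per-channel
#'   mean so masked regions sit inside the codec's input distribution.
#' @return list with `x_r` (masked image), `masked_class`, and `masked_box`
#'   (pixel box `c(row_min, col_min, row_max, col_max)`, 1-based inclusive).
#' @export
mask_class_region <- function(image, mask, seed,
                              class_table = default_class_table(),
                              fill = NULL) {
  bg <- class_ids_of(class_table, "background")
  present <- setdiff(sort(unique(as.integer(mask))), bg)
  if (length(present) == 0L) {
    stop("no maskable class: mask contains only background")
  }
  with_seed(seed, {
    cid <- sample_one(present)
    idx <- which(mask == cid, arr.ind = TRUE)
    box <- c(min(idx[, 1]), min(idx[, 2]), max(idx[, 1]), max(idx[, 2]))
    if (is.null(fill)) fill <- apply(image, 3L, mean)
    x_r <- image
    for (ch in 1:3) {
      x_r[box[1]:box[3], box[2]:box[4], ch] <- fill[ch]
    }
    list(x_r = x_r, masked_class = cid, masked_box = box)
  })
}

#' Configuration for the masked-latent transformer decoder
#'
#' The decoder consumes the masked image's latent grid as a token sequence
#' (one token per spatial position), prepends the local graph embedding as
#' an extra token, adds learned positional embeddings, applies `depth`
#' blocks of single-head self-attention plus a two-layer MLP (both with
#' residual connections), and projects the image tokens back to latent
#' channels to predict the full image's latent grid.
#'
#' @param d_model token width.
#' @param depth number of attention blocks.
#' @param n_tokens number of latent positions (h * w of the latent grid).
#' @param d_latent latent channels per position.
#' @param graph_dim width of the incoming graph embedding.
#' @return a `local_decoder_config` list.
#' @export
local_decoder_config <- function(d_model = 64L, depth = 2L,
                                 n_tokens = 64L, d_latent = 16L,
                                 graph_dim = 128L) {
  structure(list(
    d_model = as.integer(d_model), depth = as.integer(depth),
    n_tokens = as.integer(n_tokens), d_latent = as.integer(d_latent),
    graph_dim = as.integer(graph_dim)
  ), class = "local_decoder_config")
}

local_decoder_init <- function(config, seed) {
  with_seed(seed, {
    p <- list()
    p <- nn_add(p, "embed", nn_linear(config$d_latent, config$d_model, gain = 1))
    p <- nn_add(p, "gproj", nn_linear(config$graph_dim, config$d_model, gain = 1))
    p$pos <- matrix(
      stats::rnorm((config$n_tokens + 1L) * config$d_model, sd = 0.02),
      config$n_tokens + 1L, config$d_model
    )
    for (l in seq_len(config$depth)) {
      for (nm in c("q", "k", "v", "o")) {
        p <- nn_add(p, paste0(nm, l), nn_linear(config$d_model, config$d_model, gain = 1))
      }
      p <- nn_add(p, paste0("m1_", l), nn_linear(config$d_model, 2L * config$d_model))
      p <- nn_add(p, paste0("m2_", l), nn_linear(2L * config$d_model, config$d_model, gain = 1))
    }
    p <- nn_add(p, "out", nn_linear(config$d_model, config$d_latent, gain = 1))
    structure(list(params = p, config = config), class = "local_decoder")
  })
}

# tape forward: z_r (P x d_latent matrix), zg (1 x graph_dim node or matrix)
local_decoder_op <- function(nodes, tape, z_r, zg, config) {
  x <- if (is_ad_node(z_r)) z_r else ad_const(tape, z_r)
  g <- if (is_ad_node(zg)) zg else ad_const(tape, zg)
  toks <- ad_rbind2(nn_affine(nodes, "gproj", g), nn_affine(nodes, "embed", x))
  h <- ad_add(toks, nodes$pos)
  sc <- 1 / sqrt(config$d_model)
  for (l in seq_len(config$depth)) {
    q <- nn_affine(nodes, paste0("q", l), h)
    k <- nn_affine(nodes, paste0("k", l), h)
    v <- nn_affine(nodes, paste0("v", l), h)
    attn <- ad_softmax_rows(ad_scale(ad_matmul(q, ad_transpose(k)), sc))
    h <- ad_add(h, nn_affine(nodes, paste0("o", l), ad_matmul(attn, v)))
    m <- ad_relu(nn_affine(nodes, paste0("m1_", l), h))
    h <- ad_add(h, nn_affine(nodes, paste0("m2_", l), m))
  }
  img_tok <- ad_rows(h, 1L + seq_len(config$n_tokens))
  nn_affine(nodes, "out", img_tok)
}

# plain-value decoder forward
local_decoder_predict <- function(decoder, z_r_mat, zg) {
  tape <- ad_tape()
  nodes <- ad_bind(tape, decoder$params)
  out <- local_decoder_op(
    nodes, tape, z_r_mat, matrix(zg, 1L), decoder$config
  )
  ad_value(out)
}

#' Masked-latent reconstruction loss
#'
#' Mean squared error between the full image's latent grid and the
#' decoder's prediction from the masked latent plus the local graph
#' embedding, averaged over all latent positions and channels.
#'
#' @param z_x full-image latent: a `latent_grid` or P x d matrix.
#' @param z_x_r masked-image latent of the same shape.
#' @param z_g_loc numeric local graph embedding.
#' @param decoder a `local_decoder`, or any function
#'   `(z_x_r_matrix, z_g_loc) -> P x d matrix`.
#' @return scalar loss.
#' @export
local_loss <- function(z_x, z_x_r, z_g_loc, decoder) {
  zx <- if (inherits(z_x, "latent_grid")) latent_to_matrix(z_x) else z_x
  zr <- if (inherits(z_x_r, "latent_grid")) latent_to_matrix(z_x_r) else z_x_r
  if (!identical(dim(zx), dim(zr))) stop("latent shape mismatch")
  pred <- if (is.function(decoder)) {
    decoder(zr, z_g_loc)
  } else {
    local_decoder_predict(decoder, zr, z_g_loc)
  }
  if (!identical(dim(pred), dim(zx))) stop("decoder output shape mismatch")
  mean((zx - pred)^2)
}

#' Pre-train the local graph encoder
#'
#' Jointly trains the local graph encoder and the transformer decoder to
#' reconstruct full-image latents from class-masked latents plus the scene
#' graph. The image codec is frozen. With `zero_graph = TRUE` the graph
#' embedding is replaced by zeros, giving the graph-ablated control run
#' used to demonstrate that the graph carries reconstructive information.
#'
#' @param dataset list of scenes (`$image`, `$mask`).
#' @param codec_x trained image `latent_codec`.
#' @param encoder_config a [graph_encoder_config()].
#' @param seed integer seed.
#' @param epochs,lr training hyperparameters.
#' @param d_model,depth decoder size.
#' @param class_table scene [class_table()].
#' @param zero_graph if `TRUE`, train the graph-ablated control.
#' @param holdout_frac fraction of scenes held out for the loss trace.
#' @return list with `encoder`, `decoder`, `trace` (per-epoch train and
#'   holdout loss), and `fill` (the dataset mean colour used for masking).
#' @export
train_local <- function(dataset, codec_x, encoder_config, seed,
                        epochs = 15L, lr = 1e-3, d_model = 64L, depth = 2L,
                        class_table = default_class_table(),
                        zero_graph = FALSE, holdout_frac = 0.1) {
  with_seed(derive_seed(seed, "pretrain_local"), {
    n <- length(dataset)
    fill <- c(0, 0, 0)
    for (it in dataset) fill <- fill + apply(it$image, 3L, mean) / n
    samples <- lapply(seq_len(n), function(i) {
      it <- dataset[[i]]
      mk <- mask_class_region(it$image, it$mask,
        seed = derive_seed(seed, paste0("maskreg_", i)),
        class_table = class_table, fill = fill
      )
      g <- mask_to_graph(it$mask, class_table)
      ft <- graph_to_features(g, encoder_config$n_classes)
      list(
        z_x = latent_to_matrix(codec_encode(codec_x, it$image)),
        z_r = latent_to_matrix(codec_encode(codec_x, mk$x_r)),
        ft = ft
      )
    })
    P <- nrow(samples[[1]]$z_x)
    d_lat <- ncol(samples[[1]]$z_x)
    dec_cfg <- local_decoder_config(
      d_model = d_model, depth = depth, n_tokens = P, d_latent = d_lat,
      graph_dim = encoder_config$out_dim
    )
    decoder <- local_decoder_init(dec_cfg, derive_seed(seed, "local_decoder"))
    encoder <- graph_encoder_init(encoder_config, derive_seed(seed, "local_encoder"))
    params <- c(
      stats::setNames(encoder$params, paste0("E.", names(encoder$params))),
      stats::setNames(decoder$params, paste0("D.", names(decoder$params)))
    )
    opt <- adam_init(params)
    n_hold <- max(1L, round(holdout_frac * n))
    hold_idx <- sample.int(n, n_hold)
    train_idx <- setdiff(seq_len(n), hold_idx)

    eval_loss <- function(idx) {
      mean(vapply(idx, function(i) {
        s <- samples[[i]]
        zg <- if (zero_graph) {
          numeric(encoder_config$out_dim)
        } else {
          encode_graph_like(params, "E.", s$ft, encoder_config)
        }
        dec <- strip_prefix(params, "D.")
        local_loss(s$z_x, s$z_r, zg, structure(
          list(params = dec, config = dec_cfg),
          class = "local_decoder"
        ))
      }, numeric(1)))
    }

    trace <- data.frame(epoch = integer(), train = numeric(), holdout = numeric())
    for (ep in seq_len(epochs)) {
      ord <- sample(train_idx)
      losses <- numeric(0)
      for (i in ord) {
        s <- samples[[i]]
        tape <- ad_tape()
        nodes <- ad_bind(tape, params)
        enodes <- strip_prefix(nodes, "E.")
        dnodes <- strip_prefix(nodes, "D.")
        zg <- if (zero_graph || nrow(s$ft$features) == 0L) {
          ad_const(tape, matrix(0, 1L, encoder_config$out_dim))
        } else {
          encode_graph_op(
            enodes, tape, s$ft$features, s$ft$edge_index, s$ft$edge_type,
            encoder_config
          )
        }
        pred <- local_decoder_op(dnodes, tape, s$z_r, zg, dec_cfg)
        loss <- ad_mse(pred, ad_const(tape, s$z_x))
        grads <- ad_backward(tape, loss)
        step <- adam_step(params, ad_collect(grads, nodes), opt, lr = lr)
        params <- step$params
        opt <- step$state
        losses <- c(losses, ad_value(loss)[1])
      }
      trace <- rbind(trace, data.frame(
        epoch = ep, train = mean(losses), holdout = eval_loss(hold_idx)
      ))
    }
    encoder$params <- strip_prefix(params, "E.")
    decoder$params <- strip_prefix(params, "D.")
    list(
      encoder = encoder, decoder = decoder, trace = trace, fill = fill,
      holdout_idx = hold_idx
    )
  })
}

strip_prefix <- function(x, prefix) {
  keep <- startsWith(names(x), prefix)
  out <- x[keep]
  names(out) <- substring(names(out), nchar(prefix) + 1L)
  out
}

# value-space encoder forward from a prefixed parameter list
encode_graph_like <- function(params, prefix, ft, config) {
  enc <- structure(
    list(params = strip_prefix(params, prefix), config = config),
    class = "graph_encoder"
  )
  if (nrow(ft$features) == 0L) {
    return(numeric(config$out_dim))
  }
  tape <- ad_tape()
  nodes <- ad_bind(tape, enc$params)
  as.numeric(ad_value(
    encode_graph_op(nodes, tape, ft$features, ft$edge_index, ft$edge_type, config)
  ))
}
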