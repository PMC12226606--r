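#' Configuration for a vector-quantised latent codec
#'
#' Two codecs back the pipeline: an image codec (`input_kind = "image"`,
#' RGB rasters) and a mask codec (`input_kind = "mask"`, one-hot class
#' channel stacks). Each maps non-overlapping `f x f` patches through a
#' shared encoder MLP to a `code_dim`-dimensional latent, quantises against
#' a learned codebook (EMA updates, dead-code re-seeding, straight-through
#' gradients), and decodes back to patches. The optional adversarial term
#' adds a per-patch discriminator for fidelity work; it is off by default
#' since the pipeline needs the codecs only as embedding providers.
#'
#' @param input_kind `"image"` or `"mask"`.
#' @param downsample_factor patch edge `f`, one of 2, 4, 8.
#' @param codebook_size number of codebook entries (>= 2).
#' @param code_dim latent channels per spatial position.
#' @param hidden_dim encoder/decoder hidden width.
#' @param commit_weight weight of the commitment term pulling encoder
#'   outputs toward their codes.
#' @param use_adversarial enable the patch discriminator.
#' @param n_classes one-hot width for mask codecs (background included).
#' @param epochs,batch_size,lr training hyperparameters.
#' @return a `codec_config` list.
#' @export
codec_config <- function(input_kind = c("image", "mask"),
                         downsample_factor = 4L,
                         codebook_size = 256L,
                         code_dim = 32L,
                         hidden_dim = 128L,
                         commit_weight = 0.25,
                         use_adversarial = FALSE,
                         n_classes = NULL,
                         epochs = 20L, batch_size = 16L, lr = 2e-3) {
  input_kind <- match.arg(input_kind)
  if (!downsample_factor %in% c(2L, 4L, 8L)) {
    stop("downsample_factor must be one of 2, 4, 8")
  }
  if (codebook_size < 2L) stop("codebook_size must be >= 2")
  if (input_kind == "mask" && is.null(n_classes)) {
    stop("mask codec needs n_classes")
  }
  structure(list(
    input_kind = input_kind,
    downsample_factor = as.integer(downsample_factor),
    codebook_size = as.integer(codebook_size),
    code_dim = as.integer(code_dim),
    hidden_dim = as.integer(hidden_dim),
    commit_weight = commit_weight,
    use_adversarial = isTRUE(use_adversarial),
    n_classes = if (is.null(n_classes)) NA_integer_ else as.integer(n_classes),
    epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    lr = lr
  ), class = "codec_config")
}

# raster <-> patch-matrix plumbing -------------------------------------------

as_channels <- function(x) {
  if (length(dim(x)) == 2L) array(x, c(dim(x), 1L)) else x
}

one_hot_mask <- function(mask, n_classes) {
  out <- array(0, c(nrow(mask), ncol(mask), n_classes))
  for (c_id in seq_len(n_classes) - 1L) {
    out[, , c_id + 1L] <- (mask == c_id) * 1
  }
  out
}

# rows ordered row-major over the patch grid: (py, px) with px fastest
to_patches <- function(arr, f) {
  arr <- as_channels(arr)
  H <- dim(arr)[1]
  W <- dim(arr)[2]
  C <- dim(arr)[3]
  stopifnot(H %% f == 0L, W %% f == 0L)
  hh <- H %/% f
  ww <- W %/% f
  out <- matrix(0, hh * ww, f * f * C)
  k <- 0L
  for (py in seq_len(hh)) {
    for (px in seq_len(ww)) {
      k <- k + 1L
      out[k, ] <- as.numeric(
        arr[((py - 1L) * f + 1L):(py * f), ((px - 1L) * f + 1L):(px * f), ,
          drop = FALSE
        ]
      )
    }
  }
  out
}

from_patches <- function(mat, f, H, W, C) {
  arr <- array(0, c(H, W, C))
  hh <- H %/% f
  ww <- W %/% f
  k <- 0L
  for (py in seq_len(hh)) {
    for (px in seq_len(ww)) {
      k <- k + 1L
      arr[((py - 1L) * f + 1L):(py * f), ((px - 1L) * f + 1L):(px * f), ] <-
        array(mat[k, ], c(f, f, C))
    }
  }
  arr
}

# vector quantisation ---------------------------------------------------------

#' Nearest-code quantisation against a codebook
#'
#' Assigns each spatial position the codebook entry with the smallest
#' Euclidean distance (ties break toward the lowest index) and reports the
#' commitment loss, the mean squared distance between `z` and its codes.
#' Training uses the straight-through convention: gradients of the
#' reconstruction loss pass to `z` as if quantisation were the identity.
#'
#' @param codebook K x d matrix of code vectors.
#' @param z latent values: an `h x w x d` array or an N x d matrix.
#' @return list with `z_q` (same shape as `z`), `codes` (integer, 1-based),
#'   and `commitment_loss`.
#' @export
vq_quantize <- function(codebook, z) {
  was_array <- length(dim(z)) == 3L
  zm <- if (was_array) matrix(z, dim(z)[1] * dim(z)[2], dim(z)[3]) else z
  if (anyNA(zm) || any(!is.finite(zm))) stop("numeric error: non-finite latent")
  # ||z - c||^2 up to the per-row constant ||z||^2, which argmin ignores
  d2 <- -2 * zm %*% t(codebook) +
    matrix(rowSums(codebook^2), nrow(zm), nrow(codebook), byrow = TRUE)
  codes <- max.col(-d2, ties.method = "first")
  z_q <- codebook[codes, , drop = FALSE]
  commitment <- mean((zm - z_q)^2)
  if (was_array) {
    z_q <- array(z_q, dim(z))
    codes <- matrix(codes, dim(z)[1], dim(z)[2])
  }
  list(z_q = z_q, codes = codes, commitment_loss = commitment)
}

codec_init_params <- function(D_in, config) {
  p <- list()
  p <- nn_add(p, "enc1", nn_linear(D_in, config$hidden_dim))
  p <- nn_add(p, "enc2", nn_linear(config$hidden_dim, config$code_dim, gain = 1))
  p <- nn_add(p, "dec1", nn_linear(config$code_dim, config$hidden_dim))
  p <- nn_add(p, "dec2", nn_linear(config$hidden_dim, D_in, gain = 1))
  p
}

codec_encode_op <- function(nodes, x) {
  h <- ad_relu(nn_affine(nodes, "enc1", x))
  nn_affine(nodes, "enc2", h)
}

codec_decode_op <- function(nodes, z) {
  h <- ad_relu(nn_affine(nodes, "dec1", z))
  nn_affine(nodes, "dec2", h)
}

codec_input_array <- function(codec_or_config, item) {
  cfg <- if (inherits(codec_or_config, "latent_codec")) {
    codec_or_config$config
  } else {
    codec_or_config
  }
  if (cfg$input_kind == "image") {
    as_channels(item$image)
  } else {
    one_hot_mask(item$mask, cfg$n_classes)
  }
}

#' Train a vector-quantised latent codec
#'
#' Optimises the patch encoder/decoder with Adam against reconstruction MSE
#' plus the commitment term; the codebook follows exponential-moving-average
#' updates with dead codes re-seeded from current encoder outputs after 100
#' unused steps. A 10% holdout split tracks generalisation.
#'
#' @param dataset list of scenes, each with `$image` (H x W x 3) and `$mask`
#'   (H x W integer matrix).
#' @param config a [codec_config()].
#' @param seed integer seed; fixes initialisation, batching and the holdout
#'   split.
#' @return a `latent_codec` with `$params`, `$codebook`, `$loss_trace`
#'   (per-epoch train/holdout MSE) and `$config`.
#' @export
train_codec <- function(dataset, config, seed) {
  stopifnot(length(dataset) >= 2L)
  with_seed(derive_seed(seed, paste0("codec_", config$input_kind)), {
    f <- config$downsample_factor
    pats <- lapply(dataset, function(it) to_patches(codec_input_array(config, it), f))
    D_in <- ncol(pats[[1]])
    n <- length(pats)
    n_hold <- max(1L, round(0.1 * n))
    hold_idx <- sample.int(n, n_hold)
    train_idx <- setdiff(seq_len(n), hold_idx)

    params <- codec_init_params(D_in, config)
    # codebook seeded from encoder outputs of a few training items
    seed_mat <- do.call(rbind, pats[train_idx[seq_len(min(8L, length(train_idx)))]])
    z0 <- codec_forward_values(params, seed_mat)
    codebook <- z0[sample.int(nrow(z0), config$codebook_size, replace = TRUE), ,
      drop = FALSE
    ] + matrix(stats::rnorm(config$codebook_size * config$code_dim, sd = 0.01),
      config$codebook_size
    )
    ema_size <- rep(1, config$codebook_size)
    ema_sum <- codebook
    unused <- rep(0L, config$codebook_size)

    disc <- NULL
    disc_opt <- NULL
    if (config$use_adversarial) {
      disc <- nn_add(nn_add(list(), "d1", nn_linear(D_in, 64L)),
        "d2", nn_linear(64L, 1L, gain = 1)
      )
      disc_opt <- adam_init(disc)
    }

    opt <- adam_init(params)
    decay <- 0.99
    trace <- data.frame(epoch = integer(), train_mse = numeric(), holdout_mse = numeric())

    holdout_mse <- function() {
      errs <- vapply(hold_idx, function(i) {
        X <- pats[[i]]
        z <- codec_forward_values(params, X)
        zq <- vq_quantize(codebook, z)$z_q
        mean((codec_backward_values(params, zq) - X)^2)
      }, numeric(1))
      mean(errs)
    }

    for (ep in seq_len(config$epochs)) {
      ord <- sample(train_idx)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_losses <- numeric(0)
      for (bi in batches) {
        X <- do.call(rbind, pats[bi])
        tape <- ad_tape()
        nodes <- ad_bind(tape, params)
        xn <- ad_const(tape, X)
        z_e <- codec_encode_op(nodes, xn)
        zv <- ad_value(z_e)
        vq <- vq_quantize(codebook, zv)
        # straight-through: decode z_e + (z_q - z_e) treated as constant
        z_st <- ad_add(z_e, ad_const(tape, vq$z_q - zv))
        recon <- codec_decode_op(nodes, z_st)
        loss <- ad_add(
          ad_mse(recon, xn),
          ad_scale(ad_mse(z_e, ad_const(tape, vq$z_q)), config$commit_weight)
        )
        if (config$use_adversarial) {
          dn <- ad_bind(tape, disc)
          d_fake <- ad_relu(nn_affine(dn, "d1", recon))
          d_fake <- nn_affine(dn, "d2", d_fake)
          loss <- ad_add(loss, ad_scale(ad_mean(d_fake), -0.05))
        }
        grads <- ad_backward(tape, loss)
        step <- adam_step(params, ad_collect(grads, nodes), opt, lr = config$lr)
        params <- step$params
        opt <- step$state
        ep_losses <- c(ep_losses, ad_value(loss)[1])

        # EMA codebook update with dead-code re-seeding
        counts <- tabulate(vq$codes, nbins = config$codebook_size)
        onehot_sum <- rowsum(zv, group = vq$codes)
        sums <- matrix(0, config$codebook_size, config$code_dim)
        sums[as.integer(rownames(onehot_sum)), ] <- onehot_sum
        ema_size <- decay * ema_size + (1 - decay) * counts
        ema_sum <- decay * ema_sum + (1 - decay) * sums
        codebook <- ema_sum / pmax(ema_size, 1e-5)
        unused <- ifelse(counts > 0L, 0L, unused + 1L)
        dead <- which(unused >= 100L)
        if (length(dead)) {
          repl <- zv[sample.int(nrow(zv), length(dead), replace = TRUE), ,
            drop = FALSE
          ]
          codebook[dead, ] <- repl
          ema_sum[dead, ] <- repl
          ema_size[dead] <- 1
          unused[dead] <- 0L
        }

        if (config$use_adversarial) {
          tape_d <- ad_tape()
          dn <- ad_bind(tape_d, disc)
          real_s <- ad_relu(nn_affine(dn, "d1", ad_const(tape_d, X)))
          real_s <- nn_affine(dn, "d2", real_s)
          fake_s <- ad_relu(nn_affine(dn, "d1", ad_const(tape_d, ad_value(recon))))
          fake_s <- nn_affine(dn, "d2", fake_s)
          d_loss <- ad_add(
            ad_mean(ad_relu(ad_sub(1, real_s))),
            ad_mean(ad_relu(ad_add(1, fake_s)))
          )
          dg <- ad_backward(tape_d, d_loss)
          dstep <- adam_step(disc, ad_collect(dg, dn), disc_opt, lr = config$lr)
          disc <- dstep$params
          disc_opt <- dstep$state
        }
      }
      trace <- rbind(trace, data.frame(
        epoch = ep, train_mse = mean(ep_losses), holdout_mse = holdout_mse()
      ))
    }

    structure(list(
      config = config, params = params, codebook = codebook,
      loss_trace = trace, discriminator = disc
    ), class = "latent_codec")
  })
}

# deterministic forward passes on plain matrices (no tape)
codec_forward_values <- function(params, X) {
  h <- pmax(sweep(X %*% params$enc1_W, 2L, as.numeric(params$enc1_b), "+"), 0)
  sweep(h %*% params$enc2_W, 2L, as.numeric(params$enc2_b), "+")
}

codec_backward_values <- function(params, Z) {
  h <- pmax(sweep(Z %*% params$dec1_W, 2L, as.numeric(params$dec1_b), "+"), 0)
  sweep(h %*% params$dec2_W, 2L, as.numeric(params$dec2_b), "+")
}

#' Encode a raster to a latent grid / decode a latent grid to a raster
#'
#' `codec_encode` is deterministic: the same raster always maps to the same
#' continuous latent values and quantised codes. `codec_decode` accepts any
#' latent grid of the right channel depth (quantised or continuous, e.g. a
#' diffusion sample) and returns a raster of the original shape; for mask
#' codecs the raster holds per-class scores (argmax for a hard labelling).
#'
#' @param codec a trained `latent_codec`.
#' @param raster H x W x 3 image, or H x W integer mask matrix.
#' @param grid a `latent_grid` as returned by `codec_encode`.
#' @return `codec_encode`: a `latent_grid` (list with `values` h x w x d,
#'   `codes` h x w, `source_kind`); `codec_decode`: a raster array.
#' @export
codec_encode <- function(codec, raster) {
  cfg <- codec$config
  f <- cfg$downsample_factor
  arr <- if (cfg$input_kind == "mask" && length(dim(raster)) == 2L) {
    one_hot_mask(raster, cfg$n_classes)
  } else {
    as_channels(raster)
  }
  H <- dim(arr)[1]
  W <- dim(arr)[2]
  if (H %% f != 0L || W %% f != 0L) {
    stop("raster dims must be divisible by the downsample factor")
  }
  X <- to_patches(arr, f)
  z <- codec_forward_values(codec$params, X)
  vq <- vq_quantize(codec$codebook, z)
  hh <- H %/% f
  ww <- W %/% f
  structure(list(
    values = aperm(array(z, c(ww, hh, cfg$code_dim)), c(2L, 1L, 3L)),
    codes = t(matrix(vq$codes, ww, hh)),
    source_kind = cfg$input_kind,
    H = H, W = W
  ), class = "latent_grid")
}

#' @rdname codec_encode
#' @export
codec_decode <- function(codec, grid) {
  cfg <- codec$config
  f <- cfg$downsample_factor
  Z <- latent_to_matrix(grid)
  X <- codec_backward_values(codec$params, Z)
  C <- if (cfg$input_kind == "image") 3L else cfg$n_classes
  out <- from_patches(X, f, grid$H, grid$W, C)
  if (cfg$input_kind == "image") out <- pmin(pmax(out, 0), 1)
  out
}

# latent grid rows in patch order (py, px) with px fastest -- matches to_patches
latent_to_matrix <- function(grid) {
  v <- grid$values
  matrix(aperm(v, c(2L, 1L, 3L)), dim(v)[1] * dim(v)[2], dim(v)[3])
}

matrix_to_latent <- function(Z, hh, ww, H, W, source_kind = "image") {
  structure(list(
    values = aperm(array(Z, c(ww, hh, ncol(Z))), c(2L, 1L, 3L)),
    codes = NULL, source_kind = source_kind, H = H, W = W
  ), class = "latent_grid")
}

# argmax labelling from a decoded mask-codec raster
decode_mask_labels <- function(scores) {
  hard <- apply(scores, c(1L, 2L), which.max) - 1L
  matrix(as.integer(hard), dim(scores)[1], dim(scores)[2])
}
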