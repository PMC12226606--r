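#' Noise schedule for the forward diffusion process
#'
#' Linear beta schedule from `beta_min` to `beta_max` over `T` steps with
#' `alpha_t = 1 - beta_t` and `alpha_bar_t` the running product, so the
#' closed-form forward marginal is
#' `x_t = sqrt(alpha_bar_t) x_0 + sqrt(1 - alpha_bar_t) eps`.
#'
#' @param T_steps number of diffusion steps.
#' @param beta_min,beta_max schedule range, `0 < beta_min <= beta_max < 1`.
#' @return a `noise_schedule` list with vectors `beta`, `alpha`, `alpha_bar`.
#' @export
#' @examples
#' sch <- make_schedule(1000)
#' all(diff(sch$alpha_bar) < 0)
make_schedule <- function(T_steps, beta_min = 1e-4, beta_max = 0.02) {
  if (!(beta_min >= 0 && beta_max < 1 && beta_min <= beta_max)) {
    stop("invalid schedule range")
  }
  beta <- if (T_steps == 1L) beta_min else seq(beta_min, beta_max, length.out = T_steps)
  alpha <- 1 - beta
  structure(
    list(
      T = as.integer(T_steps), beta = beta, alpha = alpha,
      alpha_bar = cumprod(alpha)
    ),
    class = "noise_schedule"
  )
}

#' Forward-process sample at step t
#'
#' Exact closed form `x_t = sqrt(alpha_bar_t) x_0 + sqrt(1-alpha_bar_t) eps`.
#'
#' @param x0 data (any numeric shape).
#' @param t integer step in `1..T`.
#' @param epsilon standard normal noise, same shape as `x0`.
#' @param schedule a [make_schedule()] result.
#' @return `x_t`, same shape as `x0`.
#' @export
q_sample <- function(x0, t, epsilon, schedule) {
  if (t < 1L || t > schedule$T) stop("t out of range")
  ab <- schedule$alpha_bar[t]
  sqrt(ab) * x0 + sqrt(1 - ab) * epsilon
}

#' Denoiser model: a time- and condition-modulated MLP
#'
#' The denoiser network is a residual two-hidden-layer MLP over the
#' flattened state, a sinusoidal timestep embedding and the fused graph
#' conditioning vector. Two parameterisations of the noise predictor
#' `eps(x_t, t, c)` are available: `"eps"` has the network output the noise
#' directly (natural for low-dimensional states), while `"x0"` has it
#' predict the clean state and derives
#' `eps = (x_t - sqrt(alpha_bar_t) x0_hat) / sqrt(1 - alpha_bar_t)`
#' analytically -- the appropriate form for high-dimensional latents, where
#' the near-identity map from `x_t` to `eps` at large `t` is carried by the
#' closed form rather than squeezed through the hidden bottleneck. Null
#' conditioning is the all-zero vector, shared with the classifier-free
#' guidance branch.
#'
#' @param dim flattened state width.
#' @param cond_dim conditioning width (0 for an unconditional model).
#' @param hidden hidden width.
#' @param time_dim sinusoidal embedding width (even).
#' @param seed integer seed.
#' @param parameterization `"eps"` or `"x0"`.
#' @param schedule the [make_schedule()] the model is trained against;
#'   required for the `"x0"` parameterisation.
#' @param arch `"mlp"` (one network over the flattened state) or `"token"`
#'   (a weight-shared network applied per latent grid position, each token
#'   seeing its own latent channels, Fourier features of its grid
#'   coordinates, the timestep embedding and the conditioning vector; the
#'   right bias when conditioning must *place* content spatially, and far
#'   fewer parameters than a flat network, so it generalises from a few
#'   hundred scenes).
#' @param latent_hw integer `c(h, w)` of the latent grid (token arch only).
#' @return a `denoiser` list with `$params` and shape metadata.
#' @export
denoiser_init <- function(dim, cond_dim, hidden = 256L, time_dim = 32L,
                          seed = 1L, parameterization = c("eps", "x0"),
                          schedule = NULL, arch = c("mlp", "token"),
                          latent_hw = NULL) {
  parameterization <- match.arg(parameterization)
  arch <- match.arg(arch)
  if (parameterization == "x0" && is.null(schedule)) {
    stop("x0 parameterisation needs the noise schedule")
  }
  with_seed(seed, {
    p <- list()
    if (arch == "token") {
      stopifnot(!is.null(latent_hw))
      P <- latent_hw[1] * latent_hw[2]
      stopifnot(dim %% P == 0L)
      td <- dim %/% P
      ffq <- token_coord_features(latent_hw)
      d_in <- td + ncol(ffq) + time_dim + cond_dim
      p <- nn_add(p, "in", nn_linear(d_in, hidden))
      p <- nn_add(p, "h1", nn_linear(hidden + time_dim + cond_dim, hidden))
      p <- nn_add(p, "out", nn_linear(hidden, td, gain = 0.1))
      model <- list(
        params = p, dim = as.integer(dim), cond_dim = as.integer(cond_dim),
        hidden = as.integer(hidden), time_dim = as.integer(time_dim),
        parameterization = parameterization, schedule = schedule,
        arch = arch, latent_hw = as.integer(latent_hw),
        token_dim = as.integer(td), coord_feats = ffq
      )
    } else {
      p <- nn_add(p, "in", nn_linear(dim + time_dim + cond_dim, hidden))
      # conditioning and timestep re-enter the second layer so the signal is
      # not diluted by the first projection
      p <- nn_add(p, "h1", nn_linear(hidden + time_dim + cond_dim, hidden))
      p <- nn_add(p, "out", nn_linear(hidden, dim, gain = 0.1))
      model <- list(
        params = p, dim = as.integer(dim), cond_dim = as.integer(cond_dim),
        hidden = as.integer(hidden), time_dim = as.integer(time_dim),
        parameterization = parameterization, schedule = schedule, arch = arch
      )
    }
    structure(model, class = "denoiser")
  })
}

# Fourier features of latent grid coordinates, rows in (py outer, px inner)
# token order matching latent_to_matrix()
token_coord_features <- function(latent_hw, n_freq = 4L) {
  hh <- latent_hw[1]
  ww <- latent_hw[2]
  px <- rep((seq_len(ww) - 0.5) / ww, times = hh)
  py <- rep((seq_len(hh) - 0.5) / hh, each = ww)
  ffq <- cbind(px, py)
  for (k in seq_len(n_freq)) {
    ffq <- cbind(
      ffq, sin(2 * pi * k * px), cos(2 * pi * k * px),
      sin(2 * pi * k * py), cos(2 * pi * k * py)
    )
  }
  unname(ffq)
}

# batch-rows <-> token-rows plumbing for the token architecture; latent
# rows are flattened column-major (token index fastest within a channel)
batch_to_tokens <- function(X, P, td) {
  do.call(rbind, lapply(seq_len(nrow(X)), function(b) matrix(X[b, ], P, td)))
}

tokens_to_batch <- function(Tm, B, P, td) {
  t(vapply(seq_len(B), function(b) {
    as.numeric(Tm[(b - 1L) * P + seq_len(P), , drop = FALSE])
  }, numeric(P * td)))
}

# raw network output on a tape (eps_hat or x0_hat depending on param).
# For the token architecture the returned node is token-major
# ((B*P) x token_dim); use tokens_to_batch on its value for batch-major form.
denoiser_core_op <- function(nodes, tape, model, x, t, cond, T_steps) {
  temb <- time_embedding(t, model$time_dim, T_steps)
  if (identical(model$arch, "token")) {
    X <- if (is_ad_node(x)) ad_value(x) else x
    B <- nrow(X)
    P <- model$latent_hw[1] * model$latent_hw[2]
    td <- model$token_dim
    Xtok <- batch_to_tokens(X, P, td)
    ffq <- model$coord_feats[rep(seq_len(P), times = B), , drop = FALSE]
    side <- cbind(ffq, temb[rep(seq_len(B), each = P), , drop = FALSE])
    if (model$cond_dim > 0L) {
      side <- cbind(side, cond[rep(seq_len(B), each = P), , drop = FALSE])
    }
    inp <- ad_const(tape, cbind(Xtok, side))
    h <- ad_relu(nn_affine(nodes, "in", inp))
    h2_in <- ad_cbind2(h, ad_const(tape, side[, -seq_len(ncol(ffq)), drop = FALSE]))
    h <- ad_add(h, ad_relu(nn_affine(nodes, "h1", h2_in)))
    return(nn_affine(nodes, "out", h))
  }
  temb <- ad_const(tape, temb)
  xin <- if (is_ad_node(x)) x else ad_const(tape, x)
  inp <- ad_cbind2(xin, temb)
  cn <- NULL
  if (model$cond_dim > 0L) {
    cn <- if (is_ad_node(cond)) cond else ad_const(tape, cond)
    inp <- ad_cbind2(inp, cn)
  }
  h <- ad_relu(nn_affine(nodes, "in", inp))
  h2_in <- ad_cbind2(h, temb)
  if (!is.null(cn)) h2_in <- ad_cbind2(h2_in, cn)
  h <- ad_add(h, ad_relu(nn_affine(nodes, "h1", h2_in)))
  nn_affine(nodes, "out", h)
}

# noise-prediction forward; x (B x dim), t integer vector length B. For the
# token architecture the returned node is token-major.
denoiser_op <- function(nodes, tape, model, x, t, cond, T_steps) {
  raw <- denoiser_core_op(nodes, tape, model, x, t, cond, T_steps)
  if (!identical(model$parameterization, "x0")) {
    return(raw)
  }
  ab <- model$schedule$alpha_bar[t]
  X <- if (is_ad_node(x)) ad_value(x) else x
  if (identical(model$arch, "token")) {
    P <- model$latent_hw[1] * model$latent_hw[2]
    Xr <- batch_to_tokens(X, P, model$token_dim)
    abr <- rep(ab, each = P)
  } else {
    Xr <- X
    abr <- ab
  }
  d <- ncol(ad_value(raw))
  num <- ad_sub(
    ad_const(tape, Xr),
    ad_mul(raw, ad_const(tape, matrix(sqrt(abr), nrow(Xr), d)))
  )
  ad_mul(num, ad_const(tape, matrix(1 / sqrt(pmax(1 - abr, 1e-12)), nrow(Xr), d)))
}

#' Evaluate the denoiser on plain values
#'
#' @param model a `denoiser`.
#' @param x B x dim matrix of noisy states.
#' @param t integer step vector (length 1 or B).
#' @param cond conditioning matrix (B x cond_dim), a single vector recycled
#'   over the batch, or `NULL` for the null (all-zero) conditioning.
#' @param T_steps schedule length used for the timestep embedding.
#' @return B x dim matrix of predicted noise.
#' @export
denoiser_predict <- function(model, x, t, cond = NULL, T_steps) {
  B <- nrow(x)
  if (length(t) == 1L) t <- rep(t, B)
  cm <- cond_matrix(model, cond, B)
  tape <- ad_tape()
  nodes <- ad_bind(tape, model$params)
  out <- ad_value(denoiser_op(nodes, tape, model, x, t, cm, T_steps))
  if (identical(model$arch, "token")) {
    P <- model$latent_hw[1] * model$latent_hw[2]
    out <- tokens_to_batch(out, B, P, model$token_dim)
  }
  out
}

cond_matrix <- function(model, cond, B) {
  if (model$cond_dim == 0L) {
    return(NULL)
  }
  if (is.null(cond)) {
    return(matrix(0, B, model$cond_dim))
  }
  if (is.matrix(cond)) {
    if (nrow(cond) == B) cond else matrix(cond[1, ], B, model$cond_dim, byrow = TRUE)
  } else {
    matrix(cond, B, model$cond_dim, byrow = TRUE)
  }
}

#' Denoising training loss with conditioning dropout
#'
#' Draws `t` uniform on `1..T` and `eps ~ N(0, I)` per row, forms `x_t` by
#' the closed-form forward process, and returns the mean squared error
#' between `eps` and the model's prediction. With probability
#' `cond_drop_prob` (per sample) the conditioning is replaced by the null
#' (zero) conditioning, so one network serves both guidance branches.
#'
#' @param model a `denoiser`, or any function `(x_t, t, cond) -> eps_hat`.
#' @param x0 B x dim data matrix.
#' @param cond conditioning (matrix, vector or `NULL`).
#' @param schedule a [make_schedule()].
#' @param seed integer seed for `t`, `eps` and the dropout draw.
#' @param cond_drop_prob conditioning dropout probability.
#' @return list with scalar `loss` and logical vector `dropped`.
#' @export
ddm_loss <- function(model, x0, cond, schedule, seed, cond_drop_prob = 0.2) {
  B <- nrow(x0)
  with_seed(seed, {
    t <- sample.int(schedule$T, B, replace = TRUE)
    eps <- matrix(stats::rnorm(length(x0)), B)
    dropped <- stats::runif(B) < cond_drop_prob
    ab <- schedule$alpha_bar[t]
    xt <- sqrt(ab) * x0 + sqrt(1 - ab) * eps
    if (is.function(model)) {
      cm <- cond
    } else {
      cm <- cond_matrix(model, cond, B)
    }
    if (!is.null(cm) && is.matrix(cm)) cm[dropped, ] <- 0
    pred <- if (is.function(model)) {
      model(xt, t, cm)
    } else {
      denoiser_predict(model, xt, t, cm, schedule$T)
    }
    list(loss = mean((eps - pred)^2), dropped = dropped, t = t)
  })
}

#' Classifier-free guided noise prediction
#'
#' `eps' = (1 + omega) * eps(x_t, t, c) - omega * eps(x_t, t)`, where the
#' unconditional branch evaluates the model under the null conditioning.
#' `omega = 0` recovers the conditional prediction and `omega = -1` the
#' unconditional one.
#'
#' @param model a `denoiser` or a function `(x_t, t, cond) -> eps_hat`.
#' @param x_t B x dim states.
#' @param t integer step (scalar or length B).
#' @param cond conditioning.
#' @param omega guidance scale (>= -1).
#' @param T_steps schedule length.
#' @return B x dim guided noise prediction.
#' @export
cfg_predict <- function(model, x_t, t, cond, omega, T_steps) {
  predict_fn <- if (is.function(model)) {
    model
  } else {
    function(x, tt, cc) denoiser_predict(model, x, tt, cc, T_steps)
  }
  e_cond <- predict_fn(x_t, t, cond)
  if (omega == 0) {
    return(e_cond)
  }
  e_unc <- predict_fn(x_t, t, NULL)
  (1 + omega) * e_cond - omega * e_unc
}

#' One ancestral (DDPM) reverse step
#'
#' Posterior mean from the guided noise prediction,
#' `mu = (x_t - beta_t / sqrt(1 - alpha_bar_t) * eps') / sqrt(alpha_t)`,
#' plus `sigma_t z` with `sigma_t^2 = (1 - alpha_bar_{t-1}) / (1 -
#' alpha_bar_t) * beta_t`; the `t = 1` step is deterministic.
#'
#' @param model a `denoiser` or prediction function.
#' @param x_t B x dim states at step `t`.
#' @param t integer step `>= 1`.
#' @param cond conditioning.
#' @param omega guidance scale.
#' @param schedule a [make_schedule()].
#' @param seed integer seed for the step noise.
#' @return B x dim states at step `t - 1`.
#' @export
p_sample_step <- function(model, x_t, t, cond, omega, schedule, seed) {
  stopifnot(t >= 1L)
  eps <- cfg_predict(model, x_t, t, cond, omega, schedule$T)
  a <- schedule$alpha[t]
  ab <- schedule$alpha_bar[t]
  mu <- (x_t - schedule$beta[t] / sqrt(1 - ab) * eps) / sqrt(a)
  if (t == 1L) {
    return(mu)
  }
  ab_prev <- schedule$alpha_bar[t - 1L]
  sigma <- sqrt((1 - ab_prev) / (1 - ab) * schedule$beta[t])
  with_seed(seed, mu + sigma * matrix(stats::rnorm(length(x_t)), nrow(x_t)))
}

#' Draw samples by iterating the reverse process
#'
#' Starts from `x_T ~ N(0, I)` and applies [p_sample_step()] from `t = T`
#' down to 1. When a codec is supplied, the terminal latents are decoded to
#' images (clipped to `[0, 1]`).
#'
#' @param model a `denoiser`.
#' @param cond conditioning vector/matrix or `NULL`.
#' @param omega guidance scale.
#' @param schedule a [make_schedule()].
#' @param n number of samples.
#' @param seed integer seed.
#' @param codec optional image `latent_codec` for decoding; needs `latent_hw`.
#' @param latent_hw integer `c(h, w)` of the latent grid when decoding.
#' @return without a codec: an `n x dim` matrix of terminal states; with a
#'   codec: a list of H x W x 3 images.
#' @export
diffusion_sample <- function(model, cond, omega, schedule, n, seed,
                             codec = NULL, latent_hw = NULL) {
  x <- with_seed(
    derive_seed(seed, "sample_init"),
    matrix(stats::rnorm(n * model$dim), n, model$dim)
  )
  for (t in seq(schedule$T, 1L)) {
    x <- p_sample_step(
      model, x, t, cond, omega, schedule,
      derive_seed(seed, paste0("step_", t))
    )
  }
  if (is.null(codec)) {
    return(x)
  }
  stopifnot(!is.null(latent_hw))
  f <- codec$config$downsample_factor
  lapply(seq_len(n), function(i) {
    grid <- matrix_to_latent(
      matrix(x[i, ], latent_hw[1] * latent_hw[2], model$dim %/% (latent_hw[1] * latent_hw[2])),
      latent_hw[1], latent_hw[2], latent_hw[1] * f, latent_hw[2] * f
    )
    codec_decode(codec, grid)
  })
}

#' Train the conditional denoising diffusion model
#'
#' Standard denoising training: per batch, uniform timesteps, Gaussian
#' noise, closed-form forward process, MSE on the noise prediction, with
#' per-sample conditioning dropout. Graph encoders are frozen; the
#' conditioning matrix rows are the fused (local, global) embeddings of
#' each scene's graph.
#'
#' @param x0 N x dim data matrix (latents or flattened pixels).
#' @param cond N x cond_dim conditioning matrix, or `NULL` for an
#'   unconditional model.
#' @param schedule a [make_schedule()].
#' @param seed integer seed.
#' @param epochs,batch_size,lr,hidden training hyperparameters.
#' @param cond_drop_prob conditioning dropout probability.
#' @param holdout_frac held-out fraction for the loss trace.
#' @param parameterization `"eps"` trains the noise-prediction MSE
#'   directly; `"x0"` trains the clean-state MSE, the per-timestep
#'   reweighting of the same objective that conditions well for
#'   high-dimensional latents.
#' @param arch,latent_hw denoiser architecture, see [denoiser_init()].
#' @param cond_groups optional list of column-index groups within `cond`
#'   (e.g. the local and global halves of a fused embedding). When given,
#'   each group is additionally dropped independently with
#'   `group_drop_prob`, so the one trained network can later be sampled
#'   under fused, single-group, or null conditioning.
#' @param group_drop_prob per-group independent dropout probability.
#' @return list with `model` (a `denoiser`) and `trace`.
#' @export
train_diffusion <- function(x0, cond, schedule, seed, epochs = 30L,
                            batch_size = 32L, lr = 1e-3, hidden = 256L,
                            cond_drop_prob = 0.2, holdout_frac = 0.1,
                            parameterization = c("eps", "x0"),
                            arch = c("mlp", "token"), latent_hw = NULL,
                            cond_groups = NULL, group_drop_prob = 0.1) {
  parameterization <- match.arg(parameterization)
  arch <- match.arg(arch)
  with_seed(derive_seed(seed, "train_diffusion"), {
    N <- nrow(x0)
    cond_dim <- if (is.null(cond)) 0L else ncol(cond)
    model <- denoiser_init(ncol(x0), cond_dim,
      hidden = hidden,
      seed = derive_seed(seed, "denoiser_init"),
      parameterization = parameterization, schedule = schedule,
      arch = arch, latent_hw = latent_hw
    )
    as_target <- function(M) {
      if (arch == "token") {
        batch_to_tokens(M, model$latent_hw[1] * model$latent_hw[2], model$token_dim)
      } else {
        M
      }
    }
    params <- model$params
    opt <- adam_init(params)
    n_hold <- max(1L, round(holdout_frac * N))
    hold_idx <- sample.int(N, n_hold)
    train_idx <- setdiff(seq_len(N), hold_idx)

    # held-out loss under the trained objective (noise MSE or clean-state MSE)
    eval_loss <- function(idx, s) {
      with_seed(s, {
        B <- length(idx)
        t <- sample.int(schedule$T, B, replace = TRUE)
        eps <- matrix(stats::rnorm(B * ncol(x0)), B)
        ab <- schedule$alpha_bar[t]
        xb <- x0[idx, , drop = FALSE]
        xt <- sqrt(ab) * xb + sqrt(1 - ab) * eps
        cm <- if (is.null(cond)) NULL else cond[idx, , drop = FALSE]
        tape <- ad_tape()
        nodes <- ad_bind(tape, params)
        if (parameterization == "x0") {
          raw <- denoiser_core_op(nodes, tape, model, xt, t, cm, schedule$T)
          mean((ad_value(raw) - as_target(xb))^2)
        } else {
          pred <- denoiser_op(nodes, tape, model, xt, t, cm, schedule$T)
          mean((ad_value(pred) - as_target(eps))^2)
        }
      })
    }

    trace <- data.frame(epoch = integer(), train = numeric(), holdout = numeric())
    for (ep in seq_len(epochs)) {
      ord <- sample(train_idx)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      losses <- numeric(0)
      for (bi in batches) {
        B <- length(bi)
        t <- sample.int(schedule$T, B, replace = TRUE)
        eps <- matrix(stats::rnorm(B * ncol(x0)), B)
        ab <- schedule$alpha_bar[t]
        xt <- sqrt(ab) * x0[bi, , drop = FALSE] + sqrt(1 - ab) * eps
        cm <- if (is.null(cond)) NULL else cond[bi, , drop = FALSE]
        if (!is.null(cm)) {
          dropped <- stats::runif(B) < cond_drop_prob
          cm[dropped, ] <- 0
          if (!is.null(cond_groups)) {
            for (grp in cond_groups) {
              gdrop <- stats::runif(B) < group_drop_prob
              cm[gdrop, grp] <- 0
            }
          }
        }
        tape <- ad_tape()
        nodes <- ad_bind(tape, params)
        loss <- if (parameterization == "x0") {
          raw <- denoiser_core_op(nodes, tape, model, xt, t, cm, schedule$T)
          ad_mse(raw, ad_const(tape, as_target(x0[bi, , drop = FALSE])))
        } else {
          pred <- denoiser_op(nodes, tape, model, xt, t, cm, schedule$T)
          ad_mse(pred, ad_const(tape, as_target(eps)))
        }
        grads <- ad_backward(tape, loss)
        step <- adam_step(params, ad_collect(grads, nodes), opt, lr = lr)
        params <- step$params
        opt <- step$state
        losses <- c(losses, ad_value(loss)[1])
      }
      trace <- rbind(trace, data.frame(
        epoch = ep, train = mean(losses),
        holdout = eval_loss(hold_idx, derive_seed(seed, paste0("hold_", ep)))
      ))
    }
    model$params <- params
    list(model = model, trace = trace, holdout_idx = hold_idx)
  })
}
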