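# Shared neural-network plumbing: initialisation and the Adam optimiser.

nn_linear <- function(n_in, n_out, gain = sqrt(2)) {
  list(
    W = matrix(stats::rnorm(n_in * n_out, sd = gain / sqrt(n_in)), n_in, n_out),
    b = matrix(0, 1L, n_out)
  )
}

# prefix a linear layer's matrices into a flat parameter list
nn_add <- function(params, name, layer) {
  params[[paste0(name, "_W")]] <- layer$W
  params[[paste0(name, "_b")]] <- layer$b
  params
}

# affine op on a tape from a flat bound-parameter list
nn_affine <- function(nodes, name, x) {
  ad_add(ad_matmul(x, nodes[[paste0(name, "_W")]]), nodes[[paste0(name, "_b")]])
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# sinusoidal timestep embedding, rows = timesteps (constant, not learned)
time_embedding <- function(t, dim, t_max) {
  stopifnot(dim %% 2L == 0L)
  half <- dim %/% 2L
  freq <- exp(-log(10000) * (seq_len(half) - 1L) / max(half - 1L, 1L))
  ang <- outer(t / t_max, freq * t_max)
  cbind(sin(ang), cos(ang))
}
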