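# Minimal tape-based reverse-mode automatic differentiation over R matrices.
#
# Every trainable component in the package (latent codecs, graph encoders,
# the masked-latent transformer decoder, the diffusion denoiser) expresses its
# forward pass through these ops; gradients come from a single reverse sweep
# over the tape. All node values are numeric matrices; scalars are 1x1.
# Gradient correctness is pinned by finite-difference checks in the test suite.

ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  class(e) <- "ad_tape"
  e
}

ad_push <- function(tape, value, parents = integer(0), backfn = NULL) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- list(value = value, parents = parents, backfn = backfn)
  tape$n <- n
  structure(list(tape = tape, id = n), class = "ad_node")
}

is_ad_node <- function(x) inherits(x, "ad_node")

# constants enter the tape as leaves; their gradients are computed but unused
ad_wrap <- function(tape, x) {
  if (is_ad_node(x)) {
    return(x)
  }
  if (!is.matrix(x)) x <- matrix(as.numeric(x), nrow = 1L)
  ad_push(tape, x)
}

ad_value <- function(x) {
  if (is_ad_node(x)) x$tape$nodes[[x$id]]$value else x
}

ad_const <- function(tape, x) ad_wrap(tape, x)
ad_param <- function(tape, x) ad_wrap(tape, x)

ad_matmul <- function(a, b) {
  tape <- a$tape
  b <- ad_wrap(tape, b)
  A <- ad_value(a)
  B <- ad_value(b)
  ad_push(tape, A %*% B, c(a$id, b$id), function(g) {
    list(g %*% t(B), t(A) %*% g)
  })
}

# addition with row-vector (bias) and scalar broadcasting
ad_add <- function(a, b) {
  tape <- if (is_ad_node(a)) a$tape else b$tape
  a <- ad_wrap(tape, a)
  b <- ad_wrap(tape, b)
  A <- ad_value(a)
  B <- ad_value(b)
  val <- if (identical(dim(A), dim(B))) {
    A + B
  } else if (nrow(B) == 1L && ncol(B) == ncol(A)) {
    sweep(A, 2L, as.numeric(B), "+")
  } else if (length(B) == 1L) {
    A + as.numeric(B)
  } else {
    stop("ad_add: incompatible shapes")
  }
  ad_push(tape, val, c(a$id, b$id), function(g) {
    gb <- if (identical(dim(A), dim(B))) {
      g
    } else if (nrow(B) == 1L && ncol(B) == ncol(A)) {
      matrix(colSums(g), 1L)
    } else {
      matrix(sum(g), 1L, 1L)
    }
    list(g, gb)
  })
}

ad_sub <- function(a, b) {
  tape <- if (is_ad_node(a)) a$tape else b$tape
  a <- ad_wrap(tape, a)
  b <- ad_wrap(tape, b)
  ad_add(a, ad_scale(b, -1))
}

# elementwise product; same shape or scalar operand
ad_mul <- function(a, b) {
  tape <- if (is_ad_node(a)) a$tape else b$tape
  a <- ad_wrap(tape, a)
  b <- ad_wrap(tape, b)
  A <- ad_value(a)
  B <- ad_value(b)
  val <- if (identical(dim(A), dim(B))) {
    A * B
  } else if (length(B) == 1L) {
    A * as.numeric(B)
  } else if (length(A) == 1L) {
    as.numeric(A) * B
  } else {
    stop("ad_mul: incompatible shapes")
  }
  ad_push(tape, val, c(a$id, b$id), function(g) {
    ga <- if (identical(dim(A), dim(B))) {
      g * B
    } else if (length(B) == 1L) {
      g * as.numeric(B)
    } else {
      matrix(sum(g * B), 1L, 1L)
    }
    gb <- if (identical(dim(A), dim(B))) {
      g * A
    } else if (length(B) == 1L) {
      matrix(sum(g * A), 1L, 1L)
    } else {
      as.numeric(A) * g
    }
    list(ga, gb)
  })
}

ad_scale <- function(a, k) {
  A <- ad_value(a)
  ad_push(a$tape, A * k, a$id, function(g) list(g * k))
}

ad_relu <- function(a) {
  A <- ad_value(a)
  ad_push(a$tape, pmax(A, 0), a$id, function(g) list(g * (A > 0)))
}

ad_tanh <- function(a) {
  V <- tanh(ad_value(a))
  ad_push(a$tape, V, a$id, function(g) list(g * (1 - V^2)))
}

ad_sigmoid <- function(a) {
  V <- 1 / (1 + exp(-ad_value(a)))
  ad_push(a$tape, V, a$id, function(g) list(g * V * (1 - V)))
}

ad_exp <- function(a) {
  V <- exp(ad_value(a))
  ad_push(a$tape, V, a$id, function(g) list(g * V))
}

ad_log <- function(a) {
  A <- ad_value(a)
  ad_push(a$tape, log(A), a$id, function(g) list(g / A))
}

ad_sum <- function(a) {
  A <- ad_value(a)
  ad_push(a$tape, matrix(sum(A), 1L, 1L), a$id, function(g) {
    list(matrix(as.numeric(g), nrow(A), ncol(A)))
  })
}

ad_mean <- function(a) {
  A <- ad_value(a)
  ad_push(a$tape, matrix(mean(A), 1L, 1L), a$id, function(g) {
    list(matrix(as.numeric(g) / length(A), nrow(A), ncol(A)))
  })
}

# column means -> 1 x d row (mean pooling over rows)
ad_mean_rows <- function(a) {
  A <- ad_value(a)
  n <- nrow(A)
  ad_push(a$tape, matrix(colMeans(A), 1L), a$id, function(g) {
    list(matrix(rep(as.numeric(g) / n, each = n), n, ncol(A)))
  })
}

ad_transpose <- function(a) {
  ad_push(a$tape, t(ad_value(a)), a$id, function(g) list(t(g)))
}

ad_cbind2 <- function(a, b) {
  tape <- if (is_ad_node(a)) a$tape else b$tape
  a <- ad_wrap(tape, a)
  b <- ad_wrap(tape, b)
  A <- ad_value(a)
  B <- ad_value(b)
  ka <- ncol(A)
  ad_push(tape, cbind(A, B), c(a$id, b$id), function(g) {
    list(g[, seq_len(ka), drop = FALSE], g[, -seq_len(ka), drop = FALSE])
  })
}

ad_cbind <- function(...) Reduce(ad_cbind2, list(...))

ad_rbind2 <- function(a, b) {
  tape <- if (is_ad_node(a)) a$tape else b$tape
  a <- ad_wrap(tape, a)
  b <- ad_wrap(tape, b)
  A <- ad_value(a)
  B <- ad_value(b)
  na <- nrow(A)
  ad_push(tape, rbind(A, B), c(a$id, b$id), function(g) {
    list(g[seq_len(na), , drop = FALSE], g[-seq_len(na), , drop = FALSE])
  })
}

# row gather with scatter-add backward; idx may repeat
ad_rows <- function(a, idx) {
  A <- ad_value(a)
  idx <- as.integer(idx)
  ad_push(a$tape, A[idx, , drop = FALSE], a$id, function(g) {
    Z <- matrix(0, nrow(A), ncol(A))
    gs <- rowsum(g, group = idx)
    Z[as.integer(rownames(gs)), ] <- gs
    list(Z)
  })
}

ad_softmax_rows <- function(a) {
  A <- ad_value(a)
  m <- apply(A, 1L, max)
  E <- exp(A - m)
  V <- E / rowSums(E)
  ad_push(a$tape, V, a$id, function(g) {
    s <- rowSums(g * V)
    list(V * (g - s))
  })
}

# log-sum-exp over all entries -> scalar, max-subtraction for stability
ad_logsumexp <- function(a) {
  A <- ad_value(a)
  m <- max(A)
  lse <- m + log(sum(exp(A - m)))
  W <- exp(A - lse)
  ad_push(a$tape, matrix(lse, 1L, 1L), a$id, function(g) {
    list(as.numeric(g) * W)
  })
}

ad_entry <- function(a, i, j) {
  A <- ad_value(a)
  ad_push(a$tape, matrix(A[i, j], 1L, 1L), a$id, function(g) {
    Z <- matrix(0, nrow(A), ncol(A))
    Z[i, j] <- as.numeric(g)
    list(Z)
  })
}

# rows rescaled to unit L2 norm (zero rows pass through unchanged)
ad_l2norm_rows <- function(a, eps = 1e-12) {
  A <- ad_value(a)
  r <- sqrt(rowSums(A^2))
  r <- pmax(r, eps)
  V <- A / r
  ad_push(a$tape, V, a$id, function(g) {
    s <- rowSums(g * V)
    list((g - V * s) / r)
  })
}

# per-dimension max over row segments; rows of `a` belong to groups 1..n_groups
# (empty groups yield 0). Backward routes each gradient entry to the argmax row.
ad_segment_max <- function(a, groups, n_groups) {
  A <- ad_value(a)
  d <- ncol(A)
  V <- matrix(0, n_groups, d)
  arg <- matrix(NA_integer_, n_groups, d)
  for (g in seq_len(n_groups)) {
    rows <- which(groups == g)
    if (length(rows)) {
      block <- A[rows, , drop = FALSE]
      j <- apply(block, 2L, which.max)
      arg[g, ] <- rows[j]
      V[g, ] <- block[cbind(j, seq_len(d))]
    }
  }
  ad_push(a$tape, V, a$id, function(g) {
    Z <- matrix(0, nrow(A), d)
    for (gg in seq_len(n_groups)) {
      if (!is.na(arg[gg, 1L])) {
        Z[cbind(arg[gg, ], seq_len(d))] <- Z[cbind(arg[gg, ], seq_len(d))] + g[gg, ]
      }
    }
    list(Z)
  })
}

ad_mse <- function(a, b) {
  d <- ad_sub(a, b)
  ad_mean(ad_mul(d, d))
}

# reverse sweep; loss must be 1x1. Returns per-node gradients (list by id).
ad_backward <- function(tape, loss) {
  stopifnot(is_ad_node(loss), length(ad_value(loss)) == 1L)
  grads <- vector("list", tape$n)
  grads[[loss$id]] <- matrix(1, 1L, 1L)
  for (i in seq(loss$id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    nd <- tape$nodes[[i]]
    if (is.null(nd$backfn)) next
    pg <- nd$backfn(g)
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[k]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  grads
}

# bind a flat named list of parameter matrices onto a tape; returns nodes
ad_bind <- function(tape, params) {
  lapply(params, function(p) ad_param(tape, p))
}

# collect gradients for bound parameter nodes (zero matrix when unused)
ad_collect <- function(grads, nodes) {
  out <- lapply(nodes, function(nd) {
    g <- grads[[nd$id]]
    if (is.null(g)) {
      v <- ad_value(nd)
      matrix(0, nrow(v), ncol(v))
    } else {
      g
    }
  })
  names(out) <- names(nodes)
  out
}
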