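#' Configuration for a stacked-GNN scene-graph encoder
#'
#' Each layer updates node representations from their in-neighbours,
#' `h_v <- update(h_v, aggregate_u msg(h_u, relation(u, v)))`, with a
#' permutation-invariant aggregation (`mean`, `sum` or `max`); messages are
#' relation-aware via a learned embedding per spatial relation concatenated
#' to the sender state. Final node states are mean-pooled into a
#' graph-level embedding; the empty graph maps to the zero vector.
#'
#' @param num_layers number of message-passing layers (L >= 1).
#' @param hidden_dim node state width.
#' @param out_dim pooled embedding width.
#' @param aggregation `"mean"`, `"sum"` or `"max"`.
#' @param relation_embed_dim width of the learned relation embeddings.
#' @param n_classes class count fixing the input feature width
#'   (`n_classes + 5`).
#' @return a `graph_encoder_config` list.
#' @export
graph_encoder_config <- function(num_layers = 3L,
                                 hidden_dim = 128L,
                                 out_dim = 128L,
                                 aggregation = c("mean", "sum", "max"),
                                 relation_embed_dim = 16L,
                                 n_classes = 10L) {
  aggregation <- match.arg(aggregation)
  stopifnot(num_layers >= 1L)
  structure(list(
    num_layers = as.integer(num_layers),
    hidden_dim = as.integer(hidden_dim),
    out_dim = as.integer(out_dim),
    aggregation = aggregation,
    relation_embed_dim = as.integer(relation_embed_dim),
    n_classes = as.integer(n_classes)
  ), class = "graph_encoder_config")
}

#' Initialise graph-encoder parameters
#'
#' @param config a [graph_encoder_config()].
#' @param seed integer seed for the random initialisation.
#' @return a `graph_encoder` list with `$params` and `$config`.
#' @export
graph_encoder_init <- function(config, seed) {
  with_seed(seed, {
    F_in <- config$n_classes + 5L
    p <- list()
    p$rel_embed <- matrix(
      stats::rnorm(length(RELATIONS) * config$relation_embed_dim, sd = 0.5),
      length(RELATIONS), config$relation_embed_dim
    )
    d_in <- F_in
    for (l in seq_len(config$num_layers)) {
      p <- nn_add(p, paste0("msg", l), nn_linear(d_in + config$relation_embed_dim, config$hidden_dim))
      p <- nn_add(p, paste0("self", l), nn_linear(d_in, config$hidden_dim))
      d_in <- config$hidden_dim
    }
    p <- nn_add(p, "readout", nn_linear(config$hidden_dim, config$out_dim, gain = 1))
    structure(list(params = p, config = config), class = "graph_encoder")
  })
}

#' One relation-aware message-passing layer
#'
#' `h_v' = tanh(W_self h_v + W_msg [aggregate_{u in N(v)} (h_u, e_rel(u,v))])`
#' where the aggregation runs over incoming edges and nodes without
#' in-neighbours aggregate the zero message. Exposed as a plain-matrix
#' operation; training runs the same computation on the autodiff tape.
#'
#' @param node_feats |V| x F matrix of node states.
#' @param edge_index 2 x |E| matrix of (src, dst) 1-based node rows.
#' @param edge_type length-|E| integer relation ids (1..6).
#' @param params layer parameters (`rel_embed`, `msgL_W/b`, `selfL_W/b`).
#' @param layer layer number within `params`.
#' @param aggregation `"mean"`, `"sum"` or `"max"`.
#' @return updated |V| x hidden matrix.
#' @export
gnn_layer <- function(node_feats, edge_index, edge_type, params, layer = 1L,
                      aggregation = "mean") {
  tape <- ad_tape()
  nodes <- ad_bind(tape, params)
  out <- gnn_layer_op(
    nodes, ad_const(tape, node_feats), edge_index, edge_type,
    layer, aggregation
  )
  ad_value(out)
}

# tape version shared by training paths
gnn_layer_op <- function(nodes, h, edge_index, edge_type, layer, aggregation) {
  n_v <- nrow(ad_value(h))
  hid <- ncol(ad_value(nodes[[paste0("self", layer, "_b")]]))
  self_term <- nn_affine(nodes, paste0("self", layer), h)
  if (length(edge_type) == 0L) {
    return(ad_tanh(self_term))
  }
  src <- edge_index[1L, ]
  dst <- edge_index[2L, ]
  h_src <- ad_rows(h, src)
  e_rel <- ad_rows(nodes$rel_embed, edge_type)
  msg_in <- ad_cbind2(h_src, e_rel)
  if (aggregation == "max") {
    # per-edge message, then per-dimension hard max over incoming edges
    msgs <- nn_affine(nodes, paste0("msg", layer), msg_in)
    agg <- ad_segment_max(msgs, dst, n_v)
  } else {
    w <- rep(1, length(dst))
    if (aggregation == "mean") {
      deg <- tabulate(dst, nbins = n_v)
      w <- 1 / pmax(deg[dst], 1)
    }
    A <- matrix(0, n_v, length(dst))
    A[cbind(dst, seq_along(dst))] <- w
    agg_in <- ad_matmul(ad_const(h$tape, A), msg_in)
    agg <- nn_affine(nodes, paste0("msg", layer), agg_in)
  }
  ad_tanh(ad_add(self_term, agg))
}

# full encoder forward on a tape; returns 1 x out_dim embedding node
encode_graph_op <- function(nodes, tape, feats, edge_index, edge_type, config) {
  if (nrow(feats) == 0L) {
    return(ad_const(tape, matrix(0, 1L, config$out_dim)))
  }
  h <- ad_const(tape, feats)
  for (l in seq_len(config$num_layers)) {
    h <- gnn_layer_op(nodes, h, edge_index, edge_type, l, config$aggregation)
  }
  nn_affine(nodes, "readout", ad_mean_rows(h))
}

#' Encode a scene graph into a pooled embedding
#'
#' Applies [graph_to_features()], `num_layers` message-passing layers and
#' mean pooling, then a linear readout. Permutation-invariant in node order
#' up to floating-point reduction order; the 0-node graph returns the zero
#' vector.
#'
#' @param encoder a `graph_encoder` from [graph_encoder_init()] (or trained).
#' @param graph a `scene_graph`.
#' @return numeric vector of length `out_dim`.
#' @export
encode_graph <- function(encoder, graph) {
  config <- encoder$config
  ft <- graph_to_features(graph, config$n_classes)
  if (nrow(ft$features) == 0L) {
    return(numeric(config$out_dim))
  }
  tape <- ad_tape()
  nodes <- ad_bind(tape, encoder$params)
  out <- encode_graph_op(nodes, tape, ft$features, ft$edge_index, ft$edge_type, config)
  as.numeric(ad_value(out))
}
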