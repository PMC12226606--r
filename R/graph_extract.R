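#' @title Scene graphs: spatial relations and containers
#' @description
#' A scene graph holds one node per non-background class present in a
#' segmentation mask -- with normalized centroid, bounding-box extents and
#' pixel-area fraction as node attributes -- and one directed edge per
#' ordered node pair carrying one of six spatial relations:
#' `left_of`, `right_of`, `above`, `below`, `inside`, `surrounding`.
#' @name scene_graph
NULL

RELATIONS <- c("left_of", "right_of", "above", "below", "inside", "surrounding")
GRAPH_SCHEMA_VERSION <- 1L

new_scene_graph <- function(nodes, edges, canvas) {
  if (is.null(nodes) || nrow(nodes) == 0L) {
    nodes <- data.frame(
      id = integer(), class_id = integer(), cx = numeric(), cy = numeric(),
      w = numeric(), h = numeric(), area = numeric()
    )
  }
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(src = integer(), dst = integer(), relation = character())
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(
    list(nodes = nodes, edges = edges, canvas = as.integer(canvas)),
    class = "scene_graph"
  )
}

#' @export
print.scene_graph <- function(x, ...) {
  cat(sprintf(
    "<scene_graph> %d nodes, %d edges, canvas %dx%d\n",
    nrow(x$nodes), nrow(x$edges), x$canvas[1], x$canvas[2]
  ))
  if (nrow(x$nodes)) print(x$nodes)
  invisible(x)
}

# nominal relation box: centroid-centred with the node's extents. The JSON
# schema carries centroid+size only, so relations are always computed from
# this box; serialization stays lossless and edits stay consistent.
node_box <- function(node) {
  c(
    node$cx - node$w / 2, node$cy - node$h / 2,
    node$cx + node$w / 2, node$cy + node$h / 2
  )
}

#' Spatial relation between two boxes
#'
#' Returns `inside` when `box_a` is strictly contained in `box_b`,
#' `surrounding` for the converse, and otherwise classifies by the dominant
#' centroid-displacement axis: `left_of`/`right_of` when `|dx| >= |dy|`
#' (ties resolve to the horizontal branch), else `above`/`below`.
#'
#' @param box_a,box_b numeric length-4 boxes `c(xmin, ymin, xmax, ymax)` in
#'   normalized coordinates (x rightward, y downward).
#' @return one of `"left_of"`, `"right_of"`, `"above"`, `"below"`,
#'   `"inside"`, `"surrounding"`.
#' @export
#' @examples
#' relation_between(c(.4, .4, .6, .6), c(.1, .1, .9, .9)) # "inside"
relation_between <- function(box_a, box_b) {
  if (box_a[1] >= box_a[3] || box_a[2] >= box_a[4] ||
    box_b[1] >= box_b[3] || box_b[2] >= box_b[4]) {
    stop("degenerate box: min must be < max on both axes")
  }
  a_in_b <- box_a[1] > box_b[1] && box_a[2] > box_b[2] &&
    box_a[3] < box_b[3] && box_a[4] < box_b[4]
  b_in_a <- box_b[1] > box_a[1] && box_b[2] > box_a[2] &&
    box_b[3] < box_a[3] && box_b[4] < box_a[4]
  if (a_in_b) {
    return("inside")
  }
  if (b_in_a) {
    return("surrounding")
  }
  dx <- (box_a[1] + box_a[3]) / 2 - (box_b[1] + box_b[3]) / 2
  dy <- (box_a[2] + box_a[4]) / 2 - (box_b[2] + box_b[4]) / 2
  if (abs(dx) >= abs(dy)) {
    if (dx < 0) "left_of" else "right_of"
  } else {
    if (dy < 0) "above" else "below"
  }
}

# one relation edge for every ordered node pair
compute_edges <- function(nodes) {
  n <- nrow(nodes)
  if (n < 2L) {
    return(data.frame(src = integer(), dst = integer(), relation = character()))
  }
  pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
  pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
  rel <- vapply(seq_len(nrow(pairs)), function(k) {
    relation_between(
      node_box(nodes[pairs$i[k], ]),
      node_box(nodes[pairs$j[k], ])
    )
  }, character(1))
  out <- data.frame(
    src = nodes$id[pairs$i], dst = nodes$id[pairs$j], relation = rel
  )
  out[order(out$src, out$dst), , drop = FALSE]
}

#' Extract a scene graph from a segmentation mask
#'
#' One node per non-background class present in the mask. Centroids are the
#' mean of that class's pixel-centre coordinates (0-based pixels + 0.5),
#' normalized by canvas width/height; `w`/`h` are the tight axis-aligned
#' bounding-box extents (half-open boxes); `area` is the class's pixel
#' fraction. Every ordered node pair receives exactly one relation edge via
#' [relation_between()].
#'
#' @param mask H x W integer matrix of class ids.
#' @param class_table a [class_table()]; mask values outside it are an error.
#' @return a `scene_graph`.
#' @export
mask_to_graph <- function(mask, class_table) {
  stopifnot(is.matrix(mask))
  H <- nrow(mask)
  W <- ncol(mask)
  present <- sort(unique(as.integer(mask)))
  if (!all(present %in% class_table$class_id)) {
    stop("schema error: mask contains ids absent from the class table")
  }
  bg <- class_ids_of(class_table, "background")
  present <- setdiff(present, bg)
  if (length(present) == 0L) {
    return(new_scene_graph(NULL, NULL, c(H, W)))
  }
  rows <- lapply(seq_along(present), function(k) {
    cid <- present[k]
    idx <- which(mask == cid, arr.ind = TRUE)
    px <- idx[, "col"] - 0.5 # 0-based pixel centres
    py <- idx[, "row"] - 0.5
    data.frame(
      id = k - 1L, class_id = cid,
      cx = mean(px) / W, cy = mean(py) / H,
      w = (max(idx[, "col"]) - min(idx[, "col"]) + 1L) / W,
      h = (max(idx[, "row"]) - min(idx[, "row"]) + 1L) / H,
      area = nrow(idx) / (H * W)
    )
  })
  nodes <- do.call(rbind, rows)
  new_scene_graph(nodes, compute_edges(nodes), c(H, W))
}

#' Tensorize a scene graph for the graph encoders
#'
#' Node features are the class one-hot concatenated with
#' `(cx, cy, w, h, area)`, so `F = n_classes + 5`. Edges are returned as a
#' 2 x |E| index matrix (1-based rows into the feature matrix) plus integer
#' relation ids into the six-element vocabulary.
#'
#' @param graph a `scene_graph`.
#' @param n_classes total number of classes in the class table (one-hot
#'   width; background included).
#' @return list with `features` (|V| x F matrix), `edge_index` (2 x |E|),
#'   `edge_type` (length |E| integer, 1..6).
#' @export
graph_to_features <- function(graph, n_classes) {
  nodes <- graph$nodes
  F_dim <- n_classes + 5L
  if (nrow(nodes) == 0L) {
    return(list(
      features = matrix(0, 0L, F_dim),
      edge_index = matrix(integer(), 2L, 0L),
      edge_type = integer()
    ))
  }
  feats <- matrix(0, nrow(nodes), F_dim)
  for (i in seq_len(nrow(nodes))) {
    feats[i, nodes$class_id[i] + 1L] <- 1
    feats[i, n_classes + 1:5] <- c(
      nodes$cx[i], nodes$cy[i], nodes$w[i], nodes$h[i], nodes$area[i]
    )
  }
  row_of <- match(graph$edges$src, nodes$id)
  col_of <- match(graph$edges$dst, nodes$id)
  list(
    features = feats,
    edge_index = rbind(row_of, col_of),
    edge_type = match(graph$edges$relation, RELATIONS)
  )
}

#' Edit a scene graph
#'
#' Supported edits: `move` (new centroid; the box translates rigidly),
#' `retype` (new class id), `delete`, and `add` (new node). After a
#' non-empty edit list, all edges are recomputed from the surviving nodes'
#' boxes; an empty edit list returns the graph unchanged.
#'
#' @param graph a `scene_graph`.
#' @param edits list of edits, each a list with `op` (`"move"`, `"retype"`,
#'   `"delete"`, `"add"`) and its fields: `node_id` plus `centroid` /
#'   `class_id` / `node` as appropriate.
#' @param class_table class table used to reject retypes/adds to the
#'   background class.
#' @return the edited `scene_graph`.
#' @export
#' @examples
#' g <- mask_to_graph(sample_scene(scene_config(), 1L)$mask, default_class_table())
#' edit_graph(g, list(list(op = "move", node_id = 0L, centroid = c(0.8, 0.5))))
edit_graph <- function(graph, edits, class_table = default_class_table()) {
  if (length(edits) == 0L) {
    return(graph)
  }
  bg <- class_ids_of(class_table, "background")
  nodes <- graph$nodes
  for (e in edits) {
    op <- e$op
    if (op %in% c("move", "retype", "delete")) {
      at <- which(nodes$id == e$node_id)
      if (length(at) != 1L) stop("invalid edit: unknown node_id ", e$node_id)
    }
    if (op == "move") {
      if (any(e$centroid < 0) || any(e$centroid > 1)) {
        stop("invalid edit: centroid outside [0,1]^2")
      }
      nodes$cx[at] <- e$centroid[1]
      nodes$cy[at] <- e$centroid[2]
    } else if (op == "retype") {
      if (e$class_id %in% bg) stop("invalid edit: cannot retype to background")
      if (!e$class_id %in% class_table$class_id) {
        stop("invalid edit: unknown class_id")
      }
      if (e$class_id %in% nodes$class_id[-at]) {
        stop("invalid edit: class already present (one node per class)")
      }
      nodes$class_id[at] <- as.integer(e$class_id)
    } else if (op == "delete") {
      nodes <- nodes[-at, , drop = FALSE]
    } else if (op == "add") {
      nd <- e$node
      if (nd$class_id %in% bg) stop("invalid edit: cannot add background node")
      if (nd$class_id %in% nodes$class_id) {
        stop("invalid edit: class already present (one node per class)")
      }
      new_id <- if (nrow(nodes)) max(nodes$id) + 1L else 0L
      nodes <- rbind(nodes, data.frame(
        id = new_id, class_id = as.integer(nd$class_id),
        cx = nd$centroid[1], cy = nd$centroid[2],
        w = nd$size[1], h = nd$size[2],
        area = if (is.null(nd$area)) nd$size[1] * nd$size[2] else nd$area
      ))
    } else {
      stop("invalid edit op: ", op)
    }
  }
  new_scene_graph(nodes, compute_edges(nodes), graph$canvas)
}

#' Serialize / deserialize scene graphs as JSON
#'
#' Schema: `{version, canvas:[H,W], nodes:[{id, class_id, centroid:[cx,cy],
#' size:[w,h], area}], edges:[{src, dst, relation}]}` with relations as
#' lowercase snake_case strings. `load_graph(save_graph(g)) == g`
#' field-for-field.
#'
#' @param graph a `scene_graph`.
#' @param path file path.
#' @return `save_graph` returns `path` invisibly; `load_graph` a `scene_graph`.
#' @export
save_graph <- function(graph, path) {
  nodes <- lapply(seq_len(nrow(graph$nodes)), function(i) {
    n <- graph$nodes[i, ]
    list(
      id = n$id, class_id = n$class_id,
      centroid = c(n$cx, n$cy), size = c(n$w, n$h), area = n$area
    )
  })
  edges <- lapply(seq_len(nrow(graph$edges)), function(i) {
    e <- graph$edges[i, ]
    list(src = e$src, dst = e$dst, relation = e$relation)
  })
  obj <- list(
    version = GRAPH_SCHEMA_VERSION,
    canvas = graph$canvas,
    nodes = nodes, edges = edges
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_graph
#' @export
load_graph <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$version) || obj$version != GRAPH_SCHEMA_VERSION) {
    stop("schema error: unknown scene-graph schema version")
  }
  nodes <- if (length(obj$nodes)) {
    do.call(rbind, lapply(obj$nodes, function(n) {
      data.frame(
        id = as.integer(n$id), class_id = as.integer(n$class_id),
        cx = as.numeric(n$centroid[[1]]), cy = as.numeric(n$centroid[[2]]),
        w = as.numeric(n$size[[1]]), h = as.numeric(n$size[[2]]),
        area = as.numeric(n$area)
      )
    }))
  } else {
    NULL
  }
  edges <- if (length(obj$edges)) {
    do.call(rbind, lapply(obj$edges, function(e) {
      data.frame(
        src = as.integer(e$src), dst = as.integer(e$dst),
        relation = as.character(e$relation)
      )
    }))
  } else {
    NULL
  }
  if (!is.null(edges)) {
    if (!all(edges$relation %in% RELATIONS)) {
      stop("schema error: unknown relation label")
    }
    ids <- if (is.null(nodes)) integer() else nodes$id
    if (!all(edges$src %in% ids) || !all(edges$dst %in% ids)) {
      stop("schema error: edge references a missing node")
    }
  }
  new_scene_graph(nodes, edges, unlist(obj$canvas))
}
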