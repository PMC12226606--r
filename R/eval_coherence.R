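#' Intersection over union of two boxes
#'
#' Boxes are `c(xmin, ymin, xmax, ymax)`. Degenerate (zero-area) boxes
#' score 0 by convention; disjoint boxes score 0.
#'
#' @param box_a,box_b numeric length-4 boxes.
#' @return IoU in `[0, 1]`.
#' @export
#' @examples
#' iou(c(0, 0, 10, 10), c(5, 5, 15, 15)) # 25/175
iou <- function(box_a, box_b) {
  if (box_a[1] >= box_a[3] || box_a[2] >= box_a[4] ||
    box_b[1] >= box_b[3] || box_b[2] >= box_b[4]) {
    return(0)
  }
  ix <- max(0, min(box_a[3], box_b[3]) - max(box_a[1], box_b[1]))
  iy <- max(0, min(box_a[4], box_b[4]) - max(box_a[2], box_b[2]))
  inter <- ix * iy
  area_a <- (box_a[3] - box_a[1]) * (box_a[4] - box_a[2])
  area_b <- (box_b[3] - box_b[1]) * (box_b[4] - box_b[2])
  inter / (area_a + area_b - inter)
}

#' Rule-based object detector for synthetic scenes
#'
#' Reverses the rendering convention: every pixel is classified to its
#' nearest class reference colour (Euclidean distance in RGB), each
#' non-background class's pixels are split into connected components, and
#' components above the area floor become detections with the component's
#' normalized bounding box, fixed score 1.0. This stands in for a learned
#' detector when scoring synthesized scenes against their conditioning
#' graphs.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param class_table the [class_table()] defining the colour palette.
#' @param min_area minimum component area as a fraction of the canvas;
#'   the default is about a third of the smallest object the generator
#'   draws, suppressing speckle while keeping every real object.
#' @return data.frame of detections: `class_id`, `xmin`, `ymin`, `xmax`,
#'   `ymax` (normalized), `score`.
#' @export
detect_objects <- function(image, class_table = default_class_table(),
                           min_area = 0.005) {
  H <- dim(image)[1]
  W <- dim(image)[2]
  cols <- class_colors(class_table)
  flat <- matrix(image, H * W, 3L)
  d2 <- -2 * flat %*% t(cols) +
    matrix(rowSums(cols^2), H * W, nrow(cols), byrow = TRUE)
  lab <- matrix(class_table$class_id[max.col(-d2, ties.method = "first")], H, W)
  bg <- class_ids_of(class_table, "background")
  out <- list()
  for (cid in setdiff(class_table$class_id, bg)) {
    bin <- lab == cid
    if (!any(bin)) next
    comp <- EBImage::bwlabel(EBImage::Image(bin * 1))
    cm <- EBImage::imageData(comp)
    for (k in seq_len(max(cm))) {
      idx <- which(cm == k, arr.ind = TRUE)
      if (nrow(idx) < min_area * H * W) next
      out[[length(out) + 1L]] <- data.frame(
        class_id = cid,
        xmin = (min(idx[, 2]) - 1) / W, ymin = (min(idx[, 1]) - 1) / H,
        xmax = max(idx[, 2]) / W, ymax = max(idx[, 1]) / H,
        score = 1.0
      )
    }
  }
  if (!length(out)) {
    return(data.frame(
      class_id = integer(), xmin = numeric(), ymin = numeric(),
      xmax = numeric(), ymax = numeric(), score = numeric()
    ))
  }
  do.call(rbind, out)
}

graph_boxes <- function(graph) {
  if (nrow(graph$nodes) == 0L) {
    return(data.frame(
      class_id = integer(), xmin = numeric(), ymin = numeric(),
      xmax = numeric(), ymax = numeric()
    ))
  }
  data.frame(
    class_id = graph$nodes$class_id,
    xmin = graph$nodes$cx - graph$nodes$w / 2,
    ymin = graph$nodes$cy - graph$nodes$h / 2,
    xmax = graph$nodes$cx + graph$nodes$w / 2,
    ymax = graph$nodes$cy + graph$nodes$h / 2
  )
}

# greedy same-class matching by descending IoU; each side used at most once
match_detections <- function(det, gt) {
  pairs <- list()
  if (nrow(det) && nrow(gt)) {
    cand <- expand.grid(d = seq_len(nrow(det)), g = seq_len(nrow(gt)))
    cand <- cand[det$class_id[cand$d] == gt$class_id[cand$g], , drop = FALSE]
    if (nrow(cand)) {
      cand$iou <- vapply(seq_len(nrow(cand)), function(r) {
        iou(
          as.numeric(det[cand$d[r], c("xmin", "ymin", "xmax", "ymax")]),
          as.numeric(gt[cand$g[r], c("xmin", "ymin", "xmax", "ymax")])
        )
      }, numeric(1))
      cand <- cand[order(-cand$iou), , drop = FALSE]
      used_d <- logical(nrow(det))
      used_g <- logical(nrow(gt))
      for (r in seq_len(nrow(cand))) {
        dd <- cand$d[r]
        gg <- cand$g[r]
        if (!used_d[dd] && !used_g[gg]) {
          used_d[dd] <- TRUE
          used_g[gg] <- TRUE
          pairs[[length(pairs) + 1L]] <- c(d = dd, g = gg, iou = cand$iou[r])
        }
      }
    }
  }
  if (!length(pairs)) {
    return(data.frame(d = integer(), g = integer(), iou = numeric()))
  }
  as.data.frame(do.call(rbind, pairs))
}

#' Coherence of detections with conditioning graphs
#'
#' For each image, detections are matched to the conditioning graph's
#' object boxes greedily over descending IoU among same-class pairs (each
#' detection and each graph node used at most once). Matched pairs with IoU
#' at or above the threshold are true positives; F1 = 2TP/(2TP+FP+FN) is
#' pooled over all images. `mean_iou` averages each graph node's matched
#' IoU (unmatched nodes contribute 0); `frac_iou_hit` reports the
#' alternative fraction-of-nodes-at-or-above-threshold reading.
#'
#' @param detections list of detection data.frames (one per image, as
#'   returned by [detect_objects()]).
#' @param graphs list of conditioning `scene_graph`s, same length.
#' @param iou_threshold matching threshold (default 0.5).
#' @return a `coherence_report`: list with `mean_iou`, `f1`,
#'   `frac_iou_hit`, `per_class` breakdown and `n_images`.
#' @export
coherence_score <- function(detections, graphs, iou_threshold = 0.5) {
  if (length(detections) != length(graphs)) {
    stop("one conditioning graph per image required")
  }
  tp <- 0L
  fp <- 0L
  fn <- 0L
  node_ious <- numeric(0)
  node_classes <- integer(0)
  image_ious <- numeric(length(graphs))
  for (i in seq_along(graphs)) {
    det <- detections[[i]]
    gt <- graph_boxes(graphs[[i]])
    m <- match_detections(det, gt)
    hit <- m[m$iou >= iou_threshold, , drop = FALSE]
    tp <- tp + nrow(hit)
    fp <- fp + nrow(det) - nrow(hit)
    fn <- fn + nrow(gt) - nrow(hit)
    per_node <- numeric(nrow(gt))
    if (nrow(m)) per_node[m$g] <- m$iou
    node_ious <- c(node_ious, per_node)
    node_classes <- c(node_classes, gt$class_id)
    image_ious[i] <- if (nrow(gt)) mean(per_node) else NA_real_
  }
  per_class <- if (length(node_ious)) {
    stats::aggregate(
      data.frame(mean_iou = node_ious),
      by = list(class_id = node_classes), FUN = mean
    )
  } else {
    data.frame(class_id = integer(), mean_iou = numeric())
  }
  structure(list(
    mean_iou = if (length(node_ious)) mean(node_ious) else 0,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0,
    frac_iou_hit = if (length(node_ious)) mean(node_ious >= iou_threshold) else 0,
    per_class = per_class,
    n_images = length(graphs),
    tp = tp, fp = fp, fn = fn,
    node_ious = node_ious, image_ious = image_ious
  ), class = "coherence_report")
}

#' @export
print.coherence_report <- function(x, ...) {
  cat(sprintf(
    "<coherence_report> n=%d  mean IoU %.3f  F1@0.5 %.3f  frac(IoU>=t) %.3f\n",
    x$n_images, x$mean_iou, x$f1, x$frac_iou_hit
  ))
  invisible(x)
}

#' Diversity and distributional-fidelity proxies
#'
#' `image_diversity` is the mean pairwise pixel-space L1 distance over all
#' image pairs -- a diversity proxy in the role a learned perceptual
#' distance plays at full scale (no pretrained perceptual network is
#' involved). `fid_kid` embeds each image with a fixed hand-crafted feature
#' map (mean-pooled 8x8 colour layout plus channel moments) and reports the
#' Frechet distance between Gaussian fits of the two sets plus an unbiased
#' polynomial-kernel MMD^2 in the role of FID/KID.
#'
#' @param images list of H x W x 3 arrays (>= 2).
#' @return `image_diversity`: scalar mean pairwise distance.
#' @export
image_diversity <- function(images) {
  n <- length(images)
  if (n < 2L) stop("need at least 2 images")
  tot <- 0
  cnt <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      tot <- tot + mean(abs(images[[i]] - images[[j]]))
      cnt <- cnt + 1L
    }
  }
  tot / cnt
}

image_features <- function(img, grid = 8L) {
  H <- dim(img)[1]
  W <- dim(img)[2]
  fy <- H %/% grid
  fx <- W %/% grid
  pooled <- vapply(1:3, function(ch) {
    m <- img[seq_len(grid * fy), seq_len(grid * fx), ch]
    as.numeric(rowsum(t(rowsum(m, rep(seq_len(grid), each = fy))),
      rep(seq_len(grid), each = fx)
    )) / (fx * fy)
  }, numeric(grid * grid))
  moments <- as.numeric(vapply(1:3, function(ch) {
    c(mean(img[, , ch]), stats::sd(img[, , ch]))
  }, numeric(2)))
  c(as.numeric(pooled), moments)
}

#' @rdname image_diversity
#' @param real_images,fake_images lists of H x W x 3 arrays.
#' @return `fid_kid`: list with `fid` (Frechet feature distance) and `kid`
#'   (polynomial-kernel MMD^2, unbiased).
#' @export
fid_kid <- function(real_images, fake_images) {
  stopifnot(length(real_images) >= 2L, length(fake_images) >= 2L)
  X <- t(vapply(real_images, image_features, numeric(198)))
  Y <- t(vapply(fake_images, image_features, numeric(198)))
  mu_x <- colMeans(X)
  mu_y <- colMeans(Y)
  eps <- 1e-6
  Sx <- stats::cov(X) + diag(eps, ncol(X))
  Sy <- stats::cov(Y) + diag(eps, ncol(Y))
  covmean <- Re(pracma::sqrtm(Sx %*% Sy)$B)
  fid <- sum((mu_x - mu_y)^2) + sum(diag(Sx + Sy - 2 * covmean))
  d <- ncol(X)
  kpoly <- function(A, B) (A %*% t(B) / d + 1)^3
  n <- nrow(X)
  m <- nrow(Y)
  kxx <- kpoly(X, X)
  kyy <- kpoly(Y, Y)
  kxy <- kpoly(X, Y)
  kid <- (sum(kxx) - sum(diag(kxx))) / (n * (n - 1)) +
    (sum(kyy) - sum(diag(kyy))) / (m * (m - 1)) -
    2 * mean(kxy)
  list(fid = fid, kid = kid)
}
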