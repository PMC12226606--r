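#' Generator settings for procedural surgical-style scenes
#'
#' Scenes emulate the layered structure of cataract-surgery frames: a
#' quasi-circular anatomy stack (outer sclera disk, iris annulus and pupil
#' disk sharing one jittered centre), 0--3 elongated instruments entering
#' from the frame border, and optional auxiliary border strips. Instruments
#' are always painted above anatomy, mirroring real scenes where tools
#' overlay tissue.
#'
#' @param canvas integer edge length in pixels (square canvas, >= 16).
#' @param class_table a [class_table()].
#' @param tool_count_range integer length-2, inclusive range of instrument
#'   counts per scene.
#' @param misc_count_range integer length-2, range of auxiliary strip counts.
#' @param noise_sd standard deviation of the additive Gaussian texture noise
#'   on the rendered image (flat per-class colour plus noise).
#' @return a `scene_config` list.
#' @export
scene_config <- function(canvas = 64L,
                         class_table = default_class_table(),
                         tool_count_range = c(0L, 3L),
                         misc_count_range = c(0L, 2L),
                         noise_sd = 0.03) {
  canvas <- as.integer(canvas)
  if (length(canvas) != 1L || is.na(canvas) || canvas < 16L) {
    stop("invalid config: canvas must be a single integer >= 16")
  }
  stopifnot(length(tool_count_range) == 2L, tool_count_range[1] <= tool_count_range[2])
  n_tools <- length(class_ids_of(class_table, "tool"))
  if (tool_count_range[2] > n_tools) {
    stop("tool_count_range exceeds number of tool classes")
  }
  n_misc <- length(class_ids_of(class_table, "misc"))
  if (misc_count_range[2] > n_misc) {
    stop("misc_count_range exceeds number of misc classes")
  }
  structure(list(
    canvas = canvas,
    class_table = class_table,
    tool_count_range = as.integer(tool_count_range),
    misc_count_range = as.integer(misc_count_range),
    noise_sd = noise_sd
  ), class = "scene_config")
}

# normalized pixel-centre coordinate grids (x rightward, y downward, origin
# top-left); rows index y, columns index x
pixel_grid <- function(S) {
  xs <- (seq_len(S) - 0.5) / S
  list(
    x = matrix(rep(xs, each = S), S, S),
    y = matrix(rep(xs, times = S), S, S)
  )
}

# boolean membership masks for the supported shapes, on pixel centres
shape_pixels <- function(obj, grid) {
  cx <- obj$centroid[1]
  cy <- obj$centroid[2]
  p <- obj$params
  switch(obj$shape,
    disk = {
      (grid$x - cx)^2 + (grid$y - cy)^2 <= p$radius^2
    },
    annulus = {
      d2 <- (grid$x - cx)^2 + (grid$y - cy)^2
      d2 <= p$r_out^2 & d2 > p$r_in^2
    },
    rotated_rect = {
      u <- (grid$x - cx) * cos(obj$angle) + (grid$y - cy) * sin(obj$angle)
      v <- -(grid$x - cx) * sin(obj$angle) + (grid$y - cy) * cos(obj$angle)
      abs(u) <= p$length / 2 & abs(v) <= p$width / 2
    },
    border_strip = {
      abs(grid$x - cx) <= obj$size[1] / 2 & abs(grid$y - cy) <= obj$size[2] / 2
    },
    stop("unknown shape: ", obj$shape)
  )
}

# sample() resolves a scalar first argument as 1:x; these avoid that trap
sample_one <- function(x) x[sample.int(length(x), 1L)]
sample_k <- function(x, k) x[sample.int(length(x), k)]

object_spec <- function(class_id, shape, centroid, size, angle = 0,
                        z_order = 0L, params = list()) {
  stopifnot(
    all(centroid >= 0 & centroid <= 1),
    all(size >= 0 & size <= 1)
  )
  list(
    class_id = as.integer(class_id), shape = shape,
    centroid = as.numeric(centroid), size = as.numeric(size),
    angle = as.numeric(angle), z_order = as.integer(z_order),
    params = params
  )
}

# draw the object list for one scene attempt; geometry only, no rasters
draw_objects <- function(config) {
  ct <- config$class_table
  anat <- class_ids_of(ct, "anatomy")
  objs <- list()
  z <- 0L

  # concentric anatomy: centre jitter and radii keep the sclera inside frame
  ctr <- 0.5 + stats::runif(2, -0.05, 0.05)
  r_scl <- stats::runif(1, 0.36, 0.42)
  r_iris <- stats::runif(1, 0.24, 0.30)
  r_pup <- stats::runif(1, 0.09, 0.14)
  objs[[length(objs) + 1L]] <- object_spec(
    anat[1], "disk", ctr, c(2 * r_scl, 2 * r_scl),
    z_order = z, params = list(radius = r_scl)
  )
  z <- z + 1L
  if (length(anat) >= 2L) {
    objs[[length(objs) + 1L]] <- object_spec(
      anat[2], "annulus", ctr, c(2 * r_iris, 2 * r_iris),
      z_order = z, params = list(r_out = r_iris, r_in = r_pup)
    )
    z <- z + 1L
  }
  if (length(anat) >= 3L) {
    objs[[length(objs) + 1L]] <- object_spec(
      anat[3], "disk", ctr, c(2 * r_pup, 2 * r_pup),
      z_order = z, params = list(radius = r_pup)
    )
    z <- z + 1L
  }

  # auxiliary border strips (tape/retractor style), above anatomy
  misc_ids <- class_ids_of(ct, "misc")
  n_misc <- sample_one(seq(config$misc_count_range[1], config$misc_count_range[2]))
  if (n_misc > 0L) {
    picked <- sample_k(misc_ids, n_misc)
    for (cid in picked) {
      side <- sample_one(1:4)
      thick <- stats::runif(1, 0.05, 0.09)
      len <- stats::runif(1, 0.30, 0.55)
      along <- stats::runif(1, 0.2, 0.8)
      if (side <= 2L) { # left/right
        cx <- if (side == 1L) thick / 2 else 1 - thick / 2
        objs[[length(objs) + 1L]] <- object_spec(
          cid, "border_strip", c(cx, along), c(thick, len), z_order = z
        )
      } else { # top/bottom
        cy <- if (side == 3L) thick / 2 else 1 - thick / 2
        objs[[length(objs) + 1L]] <- object_spec(
          cid, "border_strip", c(along, cy), c(len, thick), z_order = z
        )
      }
      z <- z + 1L
    }
  }

  # instruments: rotated rectangles entering from the border, painted last
  tool_ids <- class_ids_of(ct, "tool")
  rng <- config$tool_count_range
  n_tools <- sample_one(seq(rng[1], rng[2]))
  if (n_tools > 0L) {
    picked <- sample_k(tool_ids, n_tools)
    for (cid in picked) {
      side <- sample_one(1:4)
      along <- stats::runif(1, 0.2, 0.8)
      entry <- switch(side,
        c(0, along), c(1, along), c(along, 0), c(along, 1)
      )
      inward <- switch(side, 0, pi, pi / 2, -pi / 2)
      ang <- inward + stats::runif(1, -0.45, 0.45)
      len <- stats::runif(1, 0.35, 0.60)
      wid <- stats::runif(1, 0.05, 0.09)
      ctr_t <- entry + len / 2 * c(cos(ang), sin(ang))
      bw <- min(len * abs(cos(ang)) + wid * abs(sin(ang)), 1)
      bh <- min(len * abs(sin(ang)) + wid * abs(cos(ang)), 1)
      objs[[length(objs) + 1L]] <- object_spec(
        cid, "rotated_rect", pmin(pmax(ctr_t, 0), 1), c(bw, bh),
        angle = ang, z_order = z, params = list(length = len, width = wid)
      )
      z <- z + 1L
    }
  }
  objs
}

#' Sample one rendered scene
#'
#' Deterministically renders an (image, mask, ground-truth objects) triplet
#' from `(config, seed)`. Objects are painted in increasing `z_order`
#' (anatomy, then auxiliary strips, then instruments), so later objects
#' occlude earlier ones but never vice versa. The image is the per-class
#' reference colour plus Gaussian texture noise, clipped to `[0, 1]`.
#'
#' @param config a [scene_config()].
#' @param seed integer seed; the same `(config, seed)` pair always yields a
#'   bit-identical scene.
#' @return a `rendered_scene` list with `image` (H x W x 3 array in `[0,1]`),
#'   `mask` (H x W integer matrix of class ids), `objects` (list of object
#'   specs) and `seed`.
#' @export
#' @examples
#' sc <- sample_scene(scene_config(canvas = 32L), seed = 7L)
#' table(sc$mask)
sample_scene <- function(config, seed) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(seed, {
    S <- config$canvas
    grid <- pixel_grid(S)
    bg <- class_ids_of(config$class_table, "background")
    for (attempt in 1:20) {
      objs <- draw_objects(config)
      mask <- matrix(bg, S, S)
      for (obj in objs[order(vapply(objs, `[[`, 0L, "z_order"))]) {
        mask[shape_pixels(obj, grid)] <- obj$class_id
      }
      visible <- vapply(objs, function(o) any(mask == o$class_id), TRUE)
      if (all(visible)) break
    }
    if (!all(visible)) stop("could not render all objects visibly")
    cols <- class_colors(config$class_table)
    image <- array(0, c(S, S, 3L))
    for (ch in 1:3) {
      image[, , ch] <- matrix(cols[as.character(mask), ch], S, S)
    }
    image <- image + array(stats::rnorm(S * S * 3L, sd = config$noise_sd), c(S, S, 3L))
    image <- pmin(pmax(image, 0), 1)
    structure(
      list(image = image, mask = mask, objects = objs, seed = as.integer(seed)),
      class = "rendered_scene"
    )
  })
}

#' Generate and persist a scene dataset
#'
#' Writes `n` scenes under `out_dir`: 8-bit RGB PNG images, single-channel
#' PNG masks (pixel value = class id), per-scene ground-truth JSON, and an
#' `index.json` listing every entry. Scene `i` draws its seed from a
#' deterministic per-index substream of `seed`, so datasets are reproducible
#' and extensible.
#'
#' @param n number of scenes (>= 1).
#' @param config a [scene_config()].
#' @param seed integer base seed.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the index as a list.
#' @export
generate_dataset <- function(n, config, seed, out_dir) {
  stopifnot(n >= 1L)
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    si <- derive_seed(seed, paste0("scene_", i))
    sc <- sample_scene(config, si)
    img_path <- file.path("images", sprintf("scene_%05d.png", i))
    msk_path <- file.path("masks", sprintf("scene_%05d.png", i))
    tru_path <- file.path("truth", sprintf("scene_%05d.json", i))
    png::writePNG(sc$image, file.path(out_dir, img_path))
    png::writePNG(sc$mask / 255, file.path(out_dir, msk_path))
    truth <- lapply(sc$objects, function(o) {
      o$params <- NULL
      o
    })
    jsonlite::write_json(truth, file.path(out_dir, tru_path),
      auto_unbox = TRUE, digits = NA
    )
    entries[[i]] <- list(
      id = i, seed = si, image = img_path, mask = msk_path, truth = tru_path
    )
  }
  index <- list(
    n = n, canvas = config$canvas, base_seed = as.integer(seed),
    entries = entries
  )
  jsonlite::write_json(index, file.path(out_dir, "index.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(index)
}

#' Load a persisted scene dataset
#'
#' @param dir directory previously written by [generate_dataset()].
#' @return list with `index` and a `scenes` list of `(image, mask)` pairs.
#' @export
load_dataset <- function(dir) {
  index <- jsonlite::read_json(file.path(dir, "index.json"))
  scenes <- lapply(index$entries, function(e) {
    img <- png::readPNG(file.path(dir, e$image))
    msk <- png::readPNG(file.path(dir, e$mask))
    list(image = img, mask = matrix(as.integer(round(msk * 255)), nrow(msk), ncol(msk)))
  })
  list(index = index, scenes = scenes)
}

# in-memory dataset used by the training stages; avoids PNG round-trips
render_scenes <- function(n, config, seed) {
  lapply(seq_len(n), function(i) {
    sample_scene(config, derive_seed(seed, paste0("scene_", i)))
  })
}
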