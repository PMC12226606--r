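#' Experiment configuration for the end-to-end pipeline
#'
#' One nested configuration drives every stage: scene generation, the two
#' latent codecs, local and global graph-encoder pre-training, conditional
#' diffusion training, sampling, and coherence evaluation. Stage seeds are
#' deterministic substreams of the global seed.
#'
#' @param seed global integer seed.
#' @param n_train,n_eval training and held-out scene counts.
#' @param canvas scene edge length in pixels.
#' @param tool_count_range instruments per scene.
#' @param codec named list of codec settings (factor, code_dim, hidden,
#'   codebook, epochs).
#' @param encoder named list of graph-encoder settings.
#' @param local,global named lists for the two pre-training stages.
#' @param diffusion named list (T, epochs, batch_size, hidden, lr,
#'   cond_drop_prob).
#' @param omega guidance scale used at sampling time.
#' @param sample_n samples drawn per conditioning graph (1 for evaluation).
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(seed = 1L,
                              n_train = 512L, n_eval = 50L,
                              canvas = 64L,
                              tool_count_range = c(0L, 3L),
                              codec = list(),
                              encoder = list(),
                              local = list(),
                              global = list(),
                              diffusion = list(),
                              omega = 2.0,
                              sample_n = 1L) {
  # the image codec favours spatial resolution (factor 4, narrow codes) for
  # the diffusion latent; the mask codec favours channel capacity (factor 8,
  # wide codes) so its pooled embedding is a rich alignment target
  codec <- utils::modifyList(list(
    factor = 4L, code_dim = 8L, hidden = 96L, codebook = 128L,
    epochs = 25L, batch_size = 4L, lr = 2e-3,
    mask_factor = 8L, mask_code_dim = 32L, mask_epochs = 15L
  ), codec)
  encoder <- utils::modifyList(list(
    num_layers = 3L, hidden_dim = 64L, out_dim = 48L, aggregation = "mean",
    relation_embed_dim = 16L
  ), encoder)
  local <- utils::modifyList(list(
    epochs = 5L, d_model = 48L, depth = 1L, lr = 1e-3
  ), local)
  global <- utils::modifyList(list(
    k = 8L, epochs = 22L, lr = 1e-3, normalize = TRUE
  ), global)
  # beta_max scaled for T = 150 so alpha_bar_T ~ 1e-5 and the terminal
  # forward marginal matches the N(0, I) sampling prior
  diffusion <- utils::modifyList(list(
    T = 150L, beta_min = 1e-4, beta_max = 0.155, epochs = 50L,
    batch_size = 16L, hidden = 128L, lr = 1e-3, cond_drop_prob = 0.2
  ), diffusion)
  structure(list(
    seed = as.integer(seed), n_train = as.integer(n_train),
    n_eval = as.integer(n_eval), canvas = as.integer(canvas),
    tool_count_range = as.integer(tool_count_range),
    codec = codec, encoder = encoder, local = local, global = global,
    diffusion = diffusion, omega = omega, sample_n = as.integer(sample_n)
  ), class = "experiment_config")
}

#' Read / write experiment configurations as YAML
#'
#' @param path YAML file path.
#' @param config an [experiment_config()].
#' @return `read_experiment_config` returns an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(experiment_config, raw)
}

#' @rdname read_experiment_config
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

log_event <- function(out_root, stage, event, ...) {
  rec <- c(
    list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage = stage, event = event),
    list(...)
  )
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE),
    "\n",
    file = file.path(out_root, "events.jsonl"), append = TRUE, sep = ""
  )
}

# run one checkpointed stage: skip when its artifact exists
run_stage <- function(out_root, name, seed, fn) {
  path <- file.path(out_root, paste0(name, ".rds"))
  if (file.exists(path)) {
    log_event(out_root, name, "skipped")
    return(readRDS(path))
  }
  t0 <- Sys.time()
  log_event(out_root, name, "start", seed = seed)
  val <- fn()
  saveRDS(val, path)
  log_event(out_root, name, "done",
    seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2)
  )
  val
}

# fused conditioning row for one graph: c = (z_loc, z_glob)
fuse_conditioning <- function(graph, local_fit, global_fit, n_classes) {
  ft <- graph_to_features(graph, n_classes)
  z_loc <- encode_graph_like(
    stats::setNames(local_fit$encoder$params, paste0("E.", names(local_fit$encoder$params))),
    "E.", ft, local_fit$encoder$config
  )
  z_glob <- encode_graph_normed(
    global_fit$encoder, ft, global_fit$head$normalize
  )
  c(z_loc, z_glob)
}

#' Run the full pipeline
#'
#' Stages run in dependency order -- scene generation, image codec, mask
#' codec, local pre-training, global pre-training, conditional diffusion,
#' sampling from held-out graphs, coherence evaluation -- each checkpointed
#' under `out_root` and skipped when its checkpoint already exists. A
#' JSON-lines event log records per-stage seeds and durations.
#'
#' @param config an [experiment_config()].
#' @param out_root experiment directory (created if missing).
#' @return list with all stage artifacts, including the final
#'   `coherence_report` and its shuffled-conditioning null.
#' @export
run_pipeline <- function(config, out_root) {
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  ct <- default_class_table()
  n_classes <- nrow(ct)
  scfg <- scene_config(
    canvas = config$canvas, class_table = ct,
    tool_count_range = config$tool_count_range
  )

  data <- run_stage(out_root, "data", seed, function() {
    list(
      train = render_scenes(config$n_train, scfg, derive_seed(seed, "train_data")),
      eval = render_scenes(config$n_eval, scfg, derive_seed(seed, "eval_data"))
    )
  })

  codec_x <- run_stage(out_root, "codec_image", seed, function() {
    train_codec(data$train, codec_config("image",
      downsample_factor = config$codec$factor,
      codebook_size = config$codec$codebook, code_dim = config$codec$code_dim,
      hidden_dim = config$codec$hidden, epochs = config$codec$epochs,
      batch_size = config$codec$batch_size, lr = config$codec$lr
    ), seed)
  })

  codec_m <- run_stage(out_root, "codec_mask", seed, function() {
    train_codec(data$train, codec_config("mask",
      downsample_factor = config$codec$mask_factor,
      codebook_size = config$codec$codebook,
      code_dim = config$codec$mask_code_dim,
      hidden_dim = config$codec$hidden, epochs = config$codec$mask_epochs,
      batch_size = config$codec$batch_size, lr = config$codec$lr,
      n_classes = n_classes
    ), seed)
  })

  ecfg <- graph_encoder_config(
    num_layers = config$encoder$num_layers,
    hidden_dim = config$encoder$hidden_dim, out_dim = config$encoder$out_dim,
    aggregation = config$encoder$aggregation,
    relation_embed_dim = config$encoder$relation_embed_dim,
    n_classes = n_classes
  )

  local_fit <- run_stage(out_root, "pretrain_local", seed, function() {
    train_local(data$train, codec_x, ecfg,
      seed = seed,
      epochs = config$local$epochs, lr = config$local$lr,
      d_model = config$local$d_model, depth = config$local$depth,
      class_table = ct
    )
  })

  global_fit <- run_stage(out_root, "pretrain_global", seed, function() {
    train_global(data$train, codec_m, ecfg,
      k = config$global$k,
      seed = seed, epochs = config$global$epochs, lr = config$global$lr,
      normalize = config$global$normalize, class_table = ct
    )
  })

  diff_fit <- run_stage(out_root, "diffusion", seed, function() {
    x0 <- t(vapply(
      data$train,
      function(it) as.numeric(latent_to_matrix(codec_encode(codec_x, it$image))),
      numeric((config$canvas %/% config$codec$factor)^2 * config$codec$code_dim)
    ))
    cond <- t(vapply(data$train, function(it) {
      fuse_conditioning(
        mask_to_graph(it$mask, ct), local_fit, global_fit, n_classes
      )
    }, numeric(2L * config$encoder$out_dim)))
    sch <- make_schedule(config$diffusion$T, config$diffusion$beta_min, config$diffusion$beta_max)
    # standardise latents so the data scale matches the unit-variance prior,
    # and conditioning columns so the 2*out_dim embedding dims compete with
    # the high-dimensional state at the denoiser input
    latent_sd <- stats::sd(x0)
    x0 <- x0 / latent_sd
    cond_center <- colMeans(cond)
    cond_scale <- pmax(apply(cond, 2L, stats::sd), 1e-8)
    cond <- scale(cond, center = cond_center, scale = cond_scale)
    hh <- config$canvas %/% config$codec$factor
    fit <- train_diffusion(x0, cond, sch,
      seed = seed,
      epochs = config$diffusion$epochs, batch_size = config$diffusion$batch_size,
      lr = config$diffusion$lr, hidden = config$diffusion$hidden,
      cond_drop_prob = config$diffusion$cond_drop_prob,
      parameterization = "x0", arch = "token", latent_hw = c(hh, hh)
    )
    fit$schedule <- sch
    fit$latent_sd <- latent_sd
    fit$cond_center <- cond_center
    fit$cond_scale <- cond_scale
    fit
  })

  samples <- run_stage(out_root, "samples", seed, function() {
    graphs <- lapply(data$eval, function(it) mask_to_graph(it$mask, ct))
    cond <- t(vapply(
      graphs, fuse_conditioning, numeric(2L * config$encoder$out_dim),
      local_fit, global_fit, n_classes
    ))
    cond <- scale(cond, center = diff_fit$cond_center, scale = diff_fit$cond_scale)
    hh <- config$canvas %/% config$codec$factor
    imgs <- sample_latent_batch(
      diff_fit$model, cond, config$omega, diff_fit$schedule,
      derive_seed(seed, "sampling"), codec_x, c(hh, hh), diff_fit$latent_sd
    )
    list(graphs = graphs, images = imgs, conditioning = cond)
  })

  report <- run_stage(out_root, "evaluate", seed, function() {
    dets <- lapply(samples$images, detect_objects, class_table = ct)
    coh <- coherence_score(dets, samples$graphs)
    shuffle <- with_seed(
      derive_seed(seed, "shuffle_null"),
      sample(length(samples$graphs))
    )
    coh_null <- coherence_score(dets, samples$graphs[shuffle])
    fk <- fid_kid(lapply(data$eval, `[[`, "image"), samples$images)
    list(
      coherence = coh, null = coh_null,
      diversity = image_diversity(samples$images),
      fid = fk$fid, kid = fk$kid
    )
  })

  list(
    config = config, class_table = ct, scene_config = scfg,
    data = data, codec_x = codec_x, codec_m = codec_m,
    local_fit = local_fit, global_fit = global_fit,
    diffusion = diff_fit, samples = samples, report = report
  )
}

# batched reverse diffusion over per-row conditioning, decoded to images.
# Latents are standardised by the training-set latent scale during the
# reverse pass and rescaled before decoding.
sample_latent_batch <- function(model, cond, omega, schedule, seed, codec,
                                latent_hw, latent_sd = 1) {
  n <- nrow(cond)
  x <- with_seed(
    derive_seed(seed, "init"),
    matrix(stats::rnorm(n * model$dim), n, model$dim)
  )
  for (t in seq(schedule$T, 1L)) {
    x <- p_sample_step(
      model, x, t, cond, omega, schedule,
      derive_seed(seed, paste0("step_", t))
    )
  }
  hh <- latent_hw[1]
  ww <- latent_hw[2]
  f <- codec$config$downsample_factor
  lapply(seq_len(n), function(i) {
    Z <- matrix(x[i, ] * latent_sd, hh * ww, model$dim %/% (hh * ww))
    codec_decode(codec, matrix_to_latent(Z, hh, ww, hh * f, ww * f))
  })
}

#' Edit a conditioning graph and compare samples before and after
#'
#' Mirrors the interactive editing protocol: take a trained pipeline and a
#' conditioning graph, apply graph edits (move / retype / delete / add),
#' sample images under both the original and the edited conditioning, and
#' report detections and coherence for each against its own graph.
#'
#' @param pipeline result of [run_pipeline()].
#' @param graph a conditioning `scene_graph`.
#' @param edits edit list for [edit_graph()].
#' @param omega guidance scale.
#' @param n samples per condition.
#' @param seed integer seed.
#' @return list with `before`/`after` (images, detections, report) and the
#'   `edited_graph`.
#' @export
demo_edit_and_sample <- function(pipeline, graph, edits, omega = 2.0,
                                 n = 4L, seed = 1L) {
  ct <- pipeline$class_table
  cfg <- pipeline$config
  edited <- edit_graph(graph, edits, ct)
  hh <- cfg$canvas %/% cfg$codec$factor
  # both sides share one noise seed, so sample differences isolate the
  # conditioning change (an empty edit reproduces identical images)
  one_side <- function(g, tag) {
    raw <- fuse_conditioning(g, pipeline$local_fit, pipeline$global_fit, nrow(ct))
    raw <- (raw - pipeline$diffusion$cond_center) / pipeline$diffusion$cond_scale
    cond <- matrix(raw, n, 2L * cfg$encoder$out_dim, byrow = TRUE)
    imgs <- sample_latent_batch(
      pipeline$diffusion$model, cond, omega, pipeline$diffusion$schedule,
      derive_seed(seed, "demo"), pipeline$codec_x, c(hh, hh),
      pipeline$diffusion$latent_sd
    )
    dets <- lapply(imgs, detect_objects, class_table = ct)
    list(
      images = imgs, detections = dets,
      report = coherence_score(dets, rep(list(g), n))
    )
  }
  list(
    before = one_side(graph, "before"),
    after = one_side(edited, "after"),
    edited_graph = edited
  )
}
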