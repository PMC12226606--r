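test_that("scene generation is a pure function of (config, seed)", {
  cfg <- scene_config()
  a <- sample_scene(cfg, 42L)
  b <- sample_scene(cfg, 42L)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_identical(a$objects, b$objects)
  expect_false(identical(a$mask, sample_scene(cfg, 43L)$mask))
})

test_that("tool count range is honoured and tool regions are visible", {
  ct <- ct_default
  tools <- ct$class_id[ct$category == "tool"]
  cfg0 <- scene_config(tool_count_range = c(0L, 0L))
  sc0 <- sample_scene(cfg0, 3L)
  expect_false(any(unique(as.integer(sc0$mask)) %in% tools))

  cfg2 <- scene_config(tool_count_range = c(2L, 2L))
  for (seed in 1:150) {
    m <- sample_scene(cfg2, seed)$mask
    present <- intersect(unique(as.integer(m)), tools)
    expect_length(present, 2L)
    # brute-force pixel count: each tool class paints at least one pixel
    for (cid in present) expect_gte(sum(m == cid), 1L)
  }
})

test_that("anatomy appears in every scene and tools are reasonably frequent", {
  ct <- ct_default
  anat <- ct$class_id[ct$category == "anatomy"]
  tools <- ct$class_id[ct$category == "tool"]
  cfg <- scene_config()
  tool_hits <- setNames(numeric(length(tools)), tools)
  n <- 500L
  for (seed in seq_len(n)) {
    m <- sample_scene(cfg, seed)$mask
    present <- unique(as.integer(m))
    expect_true(all(anat %in% present))
    for (cid in intersect(present, tools)) {
      tool_hits[as.character(cid)] <- tool_hits[as.character(cid)] + 1
    }
  }
  expect_true(all(tool_hits / n >= 0.05))
})

test_that("painted area never exceeds the unoccluded analytic area", {
  cfg <- scene_config()
  S <- cfg$canvas
  for (seed in c(5L, 17L, 23L)) {
    sc <- sample_scene(cfg, seed)
    for (obj in sc$objects) {
      painted <- sum(sc$mask == obj$class_id)
      analytic <- switch(obj$shape,
        disk = pi * obj$params$radius^2,
        annulus = pi * (obj$params$r_out^2 - obj$params$r_in^2),
        rotated_rect = obj$params$length * obj$params$width,
        border_strip = obj$size[1] * obj$size[2]
      )
      # one pixel of slack for boundary rasterisation
      expect_lte(painted / S^2, analytic + 1 / S)
    }
  }
})

test_that("undersized canvases are rejected", {
  expect_error(scene_config(canvas = 8L), "invalid config")
})

test_that("persisted datasets are complete and reproducible", {
  cfg <- scene_config(canvas = 32L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  idx <- generate_dataset(10L, cfg, seed = 5L, out_dir = d1)
  expect_length(idx$entries, 10L)
  for (e in idx$entries) {
    expect_true(file.exists(file.path(d1, e$image)))
    expect_true(file.exists(file.path(d1, e$mask)))
    expect_true(file.exists(file.path(d1, e$truth)))
  }
  generate_dataset(10L, cfg, seed = 5L, out_dir = d2)
  expect_identical(
    unname(tools::md5sum(file.path(d1, "index.json"))),
    unname(tools::md5sum(file.path(d2, "index.json")))
  )
  expect_identical(
    unname(tools::md5sum(file.path(d1, idx$entries[[3]]$mask))),
    unname(tools::md5sum(file.path(d2, idx$entries[[3]]$mask)))
  )
  # masks round-trip through PNG with exact class ids
  ld <- load_dataset(d1)
  ref <- sample_scene(cfg, idx$entries[[1]]$seed)
  expect_identical(ld$scenes[[1]]$mask, ref$mask)
  # every anatomy class present in every rendered mask
  anat <- ct_default$class_id[ct_default$category == "anatomy"]
  hists <- vapply(
    ld$scenes,
    function(s) all(anat %in% unique(as.integer(s$mask))), TRUE
  )
  expect_true(all(hists))
})
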