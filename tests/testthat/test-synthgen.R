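test_that("scene specs enforce guard margins around class thresholds", {
  expect_s3_class(scene_spec(), "scene_spec")
  expect_error(scene_spec(filament_length_um = c(11.5, 15)), "exceed")
  expect_error(scene_spec(rod_length_um = c(3, 10.5)), "below")
  expect_error(scene_spec(punctum_radius_um = c(0.2, 0.55)), "below")
  expect_error(scene_spec(swollen_radius_um = c(0.62, 1.0)), "exceed")
  expect_error(scene_spec(spacing_um = 0.4, tube_width_um = 0.5), "exceed")
})

test_that("generated scenes carry exactly the requested ground truth", {
  spec <- scene_spec(shape = c(320L, 320L),
                     counts = c(filament = 2L, rod = 5L, punctum = 5L,
                                swollen = 5L), seed = 17L)
  sc <- generate_scene(spec)
  expect_equal(nrow(sc$truth), 17L)
  expect_equal(as.vector(table(factor(sc$truth$class,
                                      c("filament", "rod", "punctum",
                                        "swollen")))),
               c(2L, 5L, 5L, 5L))
  expect_equal(max(sc$truth_labels), 17L)
  expect_identical(dim(sc$stack$frames[[1L]]), c(320L, 320L))
  # planted objects are disjoint and labelled
  expect_equal(sum(sc$clean_mask), sum(sc$truth_labels > 0))
})

test_that("identical seeds give bit-identical scenes; seeds differ otherwise", {
  a <- generate_scene(small_scene_spec(seed = 5L))
  b <- generate_scene(small_scene_spec(seed = 5L))
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c_ <- generate_scene(small_scene_spec(seed = 6L))
  expect_false(identical(a$stack$frames[[1L]], c_$stack$frames[[1L]]))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(runif(1))
  invisible(generate_scene(small_scene_spec(seed = 2L)))
  after <- runif(2)
  expect_identical(before[2:3], after)
})

test_that("planted tube geodesics agree with measured skeleton extension", {
  sc <- generate_scene(scene_spec(shape = c(448L, 448L),
                                  counts = c(filament = 3L, rod = 4L,
                                             punctum = 0L, swollen = 0L),
                                  seed = 29L))
  obs <- objects_from_mask(sc$clean_mask, sc$stack$pixel_size)
  f <- measure_objects(obs, sc$stack$pixel_size)
  ev <- evaluate_against_truth(obs, classify_features(f, default_rules), sc)
  m <- ev$matches
  for (i in seq_len(nrow(m))) {
    planted <- sc$truth$length_um[sc$truth$id == m$truth_id[i]]
    expect_lt(abs(f$E[m$detection[i]] - planted) / planted, 0.05)
  }
})

test_that("a noise-free scene is recovered perfectly end to end", {
  spec <- small_scene_spec(seed = 13L, shot_gain = 0, add_noise_sd = 0)
  sc <- generate_scene(spec)
  res <- analyze_cell(z_project(sc$stack), sc$region, run_config())
  ev <- evaluate_against_truth(res$segments, res$objects$class, sc)
  expect_equal(unname(ev$recall), rep(1, 4L))
  expect_equal(ev$n_false_positive, 0L)
  expect_equal(ev$n_missed, 0L)
  expect_equal(sum(ev$confusion) - sum(diag(ev$confusion)), 0L)
})

test_that("truth matching counts misses, false positives and confusions", {
  sc <- generate_scene(small_scene_spec(seed = 19L))
  obs <- objects_from_mask(sc$clean_mask, sc$stack$pixel_size)
  f <- measure_objects(obs, sc$stack$pixel_size)
  cls <- classify_features(f, default_rules)
  # perfect detections -> identity confusion
  ev <- evaluate_against_truth(obs, cls, sc)
  expect_equal(sum(ev$confusion), nrow(sc$truth))
  expect_equal(sum(diag(ev$confusion)), nrow(sc$truth))

  # flip one rod call to filament: one off-diagonal entry
  i <- which(cls == "rod")[1L]
  cls2 <- cls; cls2[i] <- "filament"
  ev2 <- evaluate_against_truth(obs, cls2, sc)
  expect_equal(ev2$confusion["rod", "filament"], 1)
  n_rod <- sum(sc$truth$class == "rod")
  expect_equal(unname(ev2$recall["rod"]), 1 - 1 / n_rod)

  # empty detection set: everything missed
  ev3 <- evaluate_against_truth(list(), character(0L), sc)
  expect_equal(ev3$n_missed, nrow(sc$truth))
  expect_equal(sum(ev3$confusion), 0L)
})

test_that("scenes round-trip to disk with calibration in the sidecar", {
  sc <- generate_scene(small_scene_spec(seed = 23L))
  dir <- withr::local_tempdir()
  paths <- write_scene(sc, dir, name = "s1")
  expect_true(all(file.exists(paths)))
  meta <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(meta$pixel_size_um, sc$stack$pixel_size)
  expect_equal(nrow(meta$truth), nrow(sc$truth))
  st <- load_stack(paths[["image"]], pixel_size_override = meta$pixel_size_um)
  # 16-bit storage: counts round-trip within one grey level
  expect_lt(max(abs(st$frames[[1L]] * meta$intensity_scale -
                      sc$stack$frames[[1L]])), 1.01)
})

test_that("infeasible packing fails with a clear error", {
  spec <- scene_spec(shape = c(96L, 96L),
                     counts = c(filament = 30L, rod = 0L, punctum = 0L,
                                swollen = 0L), seed = 1L, max_attempts = 20L)
  expect_error(generate_scene(spec), "filament")
})
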