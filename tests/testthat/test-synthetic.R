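test_that("generated hierarchies have the requested shape and are reproducible", {
  sp <- synthetic_spec(n_animal = 2, n_artifact = 2, n_neutral = 1, side = 64)
  g <- generate_hierarchy(sp)
  expect_equal(n_labels(g), 5)
  expect_length(descendant_labels(g, "animal"), 2)
  expect_length(descendant_labels(g, "organism"), 2) # superordinate of animal
  g_again <- generate_hierarchy(sp)
  expect_identical(g$leaf_labels, g_again$leaf_labels)
  expect_identical(igraph::as_data_frame(g$graph), igraph::as_data_frame(g_again$graph))

  big <- generate_hierarchy(synthetic_spec(n_animal = 500, n_artifact = 500,
                                           n_neutral = 0, side = 64))
  expect_equal(n_labels(big), 1000)
  expect_error(synthetic_spec(n_animal = 0, n_artifact = 0, n_neutral = 0),
               class = "rapidcat_task_undefinable_error")
  expect_error(synthetic_spec(side = 100), class = "rapidcat_usage_error")
})

test_that("rendering is deterministic and validates its label", {
  sp <- spec64()
  img <- render_image("animal_1", sp, 42)
  expect_equal(dim(img), c(64, 64, 3))
  expect_true(all(img >= 0 & img <= 1))
  expect_identical(img, render_image("animal_1", sp, 42))
  expect_false(identical(img, render_image("animal_1", sp, 43)))
  expect_error(render_image("gnome_1", sp, 1), class = "rapidcat_missing_node_error")
})

test_that("branch cues separate in orientation statistics; no-signal mode does not", {
  sp1 <- spec64(cross_category_exclusion = 1)
  aniso <- function(img) {
    f <- orientation_features(img)
    sqrt(f[["c2"]]^2 + f[["s2"]]^2)
  }
  an <- vapply(1:40, function(i) aniso(render_image("animal_1", sp1, i)), numeric(1))
  ar <- vapply(1:40, function(i) aniso(render_image("artifact_1", sp1, 100 + i)), numeric(1))
  # vertical strokes are strongly oriented; rings are isotropic
  expect_gt(mean(ar), mean(an) + 0.2)

  sp0 <- spec64(signal = FALSE)
  e_an <- vapply(1:100, function(i) orientation_features(render_image("animal_1", sp0, i))["edge_energy"],
                 numeric(1))
  e_ar <- vapply(1:100, function(i) orientation_features(render_image("artifact_1", sp0, 1000 + i))["edge_energy"],
                 numeric(1))
  expect_gt(stats::t.test(e_an, e_ar)$p.value, 0.01)
})

test_that("sources are addressable, lazy, and capacity-checked", {
  sp <- synthetic_spec(n_animal = 2, n_artifact = 2, n_neutral = 1, side = 64)
  src <- make_source(sp, seed = 1, images_per_label = 10)
  expect_equal(length(src$labels) * src$n_per_label, 50)
  expect_identical(src$get("animal_2", 3), src$get("animal_2", 3))
  expect_error(src$get("animal_2", 11), class = "rapidcat_usage_error")

  g <- generate_hierarchy(sp)
  ok <- build_dataset(src, g, "animal", build_config(20, 8, 12, seed = 1))
  expect_equal(nrow(ok$manifest), 40)
  expect_error(build_dataset(src, g, "animal", build_config(2000, 800, 1200)),
               class = "rapidcat_capacity_error")
})

test_that("a linear probe solves the default task but not the no-signal control", {
  src <- make_source(spec64(), seed = 7, images_per_label = 60)
  g <- generate_hierarchy(spec64())
  ds <- build_dataset(src, g, "animal", small_config())
  expect_gte(linear_probe(ds)$accuracy, 0.9)

  sp0 <- spec64(signal = FALSE)
  src0 <- make_source(sp0, seed = 7, images_per_label = 60)
  ds0 <- build_dataset(src0, generate_hierarchy(sp0), "animal", small_config())
  expect_lt(abs(linear_probe(ds0)$accuracy - 0.5), 0.1)
})

test_that("probe accuracy rises with cue contrast (discriminability dial)", {
  accs <- vapply(c(0.05, 0.3, 1), function(cc) {
    sp <- spec64(cue_contrast = cc)
    src <- make_source(sp, seed = 7, images_per_label = 40)
    ds <- build_dataset(src, generate_hierarchy(sp), "animal",
                        build_config(120, 40, 80, seed = 11))
    linear_probe(ds)$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) >= -0.02)) # monotone up to sampling noise
  expect_gt(accs[3], accs[1])
})

test_that("rotating test images breaks the probe only for anisotropic cues", {
  rotated_probe_acc <- function(rotation_invariant) {
    sp <- spec64(rotation_invariant = rotation_invariant)
    src <- make_source(sp, seed = 7, images_per_label = 60)
    ds <- build_dataset(src, generate_hierarchy(sp), "animal", small_config())
    pr <- linear_probe(ds)
    te <- load_split_images(ds, "test")
    rot <- transform_spec("rotation", angle = 90)
    x <- t(sapply(te$images, function(im) orientation_features(apply_transform(im, rot))))
    p <- stats::predict(pr$fit, newdata = as.data.frame(x), type = "response")
    c(plain = pr$accuracy, rotated = mean((p > 0.5) == (te$labels == 1)))
  }
  sens <- rotated_probe_acc(FALSE)
  inv <- rotated_probe_acc(TRUE)
  # vertical-stroke cue: 90-degree rotation sends artifact energy into the
  # wrong orientation bin and accuracy collapses
  expect_lt(sens["rotated"], sens["plain"] - 0.15)
  # orientation-free cues survive rotation
  expect_gt(inv["rotated"], inv["plain"] - 0.1)
})
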