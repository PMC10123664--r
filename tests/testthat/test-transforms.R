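test_that("transform identities hold bit-exactly", {
  img <- render_image("animal_2", spec64(), 17)
  expect_identical(apply_transform(img, transform_spec("identity")), img)
  expect_identical(apply_transform(img, transform_spec("rotation", angle = 0)), img)
  hf <- transform_spec("hflip"); vf <- transform_spec("vflip")
  expect_identical(apply_transform(apply_transform(img, hf), hf), img)
  expect_identical(apply_transform(apply_transform(img, vf), vf), img)
  # full-frame patch shuffle is the identity (single patch)
  expect_identical(apply_transform(img, transform_spec("patch_shuffle", patch = 64)), img)
  # rotating twice by 180 degrees returns the original
  r180 <- transform_spec("rotation", angle = 180)
  expect_identical(apply_transform(apply_transform(img, r180), r180), img)
  # four quarter turns are the identity
  r90 <- transform_spec("rotation", angle = 90)
  out <- img
  for (k in 1:4) out <- apply_transform(out, r90)
  expect_identical(out, img)
})

test_that("cardinal rotations are lossless and consistent with resampling", {
  img <- render_image("artifact_2", spec64(), 23)
  for (a in c(-180, -90, 90, 180)) {
    exact <- apply_transform(img, transform_spec("rotation", angle = a))
    near <- rapidcat:::affine_warp(img, rapidcat:::rotation_matrix(a),
                                   interpolation = "nearest")
    expect_identical(exact, near)
  }
  # non-cardinal angles resample and lose the corners to the fill value
  r45 <- apply_transform(img, transform_spec("rotation", angle = 45))
  expect_equal(r45[1, 1, ], c(0, 0, 0))
  expect_error(transform_spec("rotation", angle = 200), class = "rapidcat_usage_error")
  expect_error(transform_spec("swirl"), class = "rapidcat_usage_error")
})

test_that("patch shuffle permutes patches and conserves pixel content", {
  img <- render_image("animal_1", spec64(), 29)
  ps <- apply_transform(img, transform_spec("patch_shuffle", patch = 16, seed = 3))
  expect_false(identical(ps, img))
  expect_identical(sort(as.vector(ps)), sort(as.vector(img)))
  # per-channel histograms conserved
  for (ch in 1:3) {
    expect_identical(sort(as.vector(ps[, , ch])), sort(as.vector(img[, , ch])))
  }
  # determinism under the permutation seed
  ps2 <- apply_transform(img, transform_spec("patch_shuffle", patch = 16, seed = 3))
  expect_identical(ps, ps2)
  expect_error(apply_transform(img, transform_spec("patch_shuffle", patch = 17)),
               class = "rapidcat_usage_error")
})

test_that("grayscale collapses the channels onto luminance", {
  img <- render_image("animal_1", spec64(), 31)
  gs <- apply_transform(img, transform_spec("grayscale"))
  expect_identical(gs[, , 1], gs[, , 2])
  expect_identical(gs[, , 2], gs[, , 3])
  expect_equal(gs[, , 1], 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
})

test_that("sweep harnesses report one row per condition with identity checks", {
  # cheap deterministic scorer: oriented-energy anisotropy read-out
  scorer <- function(img) {
    f <- orientation_features(img)
    min(1, sqrt(f[["c2"]]^2 + f[["s2"]]^2))
  }
  attr(scorer, "task") <- "animal"
  sp <- spec64()
  src <- make_source(sp, seed = 7, images_per_label = 10)
  ds <- build_dataset(src, generate_hierarchy(sp), "animal",
                      build_config(4, 2, 20, seed = 51))
  te <- load_split_images(ds, "test")

  base_acc <- evaluate(scorer, te)$accuracy
  rs <- rotation_sweep(scorer, te, angles = 0)
  expect_equal(nrow(rs), 1)
  expect_equal(rs$accuracy, base_acc)

  rs3 <- rotation_sweep(scorer, te, angles = c(-90, 0, 90))
  expect_equal(nrow(rs3), 3)
  expect_true(all(rs3$accuracy >= 0 & rs3$accuracy <= 1))
  expect_error(rotation_sweep(scorer, te, angles = numeric(0)),
               class = "rapidcat_usage_error")
  expect_error(rotation_sweep(scorer, te, angles = 270),
               class = "rapidcat_usage_error")

  ss <- shuffle_sweep(scorer, te, patch_sizes = c(64, 16), n_reps = 1, seed = 1)
  expect_equal(ss$condition, c(64, 16))
  expect_equal(ss$sd, c(0, 0)) # single rep: no spread; size 64 is identity
  expect_equal(ss$accuracy[1], base_acc)
  ss3 <- shuffle_sweep(scorer, te, patch_sizes = 8, n_reps = 3, seed = 2)
  expect_equal(ss3$n, 3)
  expect_error(shuffle_sweep(scorer, te, patch_sizes = 7),
               class = "rapidcat_usage_error")

  p <- withr::local_tempfile(fileext = ".csv")
  write_sweep(ss, p)
  expect_identical(utils::read.csv(p)$condition, c(64L, 16L))
})

test_that("timed prediction reports decisions and positive wall-clock stats", {
  m <- replace_head(make_backbone(small_backbone_config(K = 2), seed = 1), 1, seed = 2)
  imgs <- lapply(1:10, function(i) render_image("animal_1", spec64(), i))
  tp <- timed_predict(m, imgs)
  expect_length(tp$decisions, 10)
  expect_true(all(tp$decisions %in% c("target", "distractor")))
  expect_gt(tp$mean_seconds, 0)
  expect_true(is.finite(tp$sd_seconds) && tp$sd_seconds >= 0)
  expect_error(timed_predict(m, list()), class = "rapidcat_usage_error")

  # pruning strictly reduces the parameter count (the speed proxy)
  big <- make_backbone(backbone_config(), seed = 1)
  expect_lt(n_parameters(prune_conv_layers(big, 6, seed = 1)), n_parameters(big))
})
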