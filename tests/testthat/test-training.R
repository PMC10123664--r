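test_that("the five protocols map to their weight/freeze/augmentation settings", {
  expect_equal(unclass(protocol("SLS"))[c("origin", "trainable", "augmentation")],
               list(origin = "random", trainable = "all", augmentation = "none"))
  expect_equal(unclass(protocol("TLC"))[c("origin", "trainable", "augmentation")],
               list(origin = "pretrained", trainable = "head_only", augmentation = "none"))
  expect_equal(unclass(protocol("TLA"))[c("origin", "trainable", "augmentation")],
               list(origin = "pretrained", trainable = "all", augmentation = "none"))
  expect_equal(unclass(protocol("TLDA"))[c("origin", "trainable", "augmentation")],
               list(origin = "pretrained", trainable = "head_only", augmentation = "custom"))
  expect_equal(unclass(protocol("TLAA"))[c("origin", "trainable", "augmentation")],
               list(origin = "pretrained", trainable = "head_only", augmentation = "auto"))
  expect_error(protocol("XXX"), class = "rapidcat_usage_error")
})

test_that("hyperparameters are validated and default to the study settings", {
  hp <- hyperparams()
  expect_equal(hp$batch_size, 8L)
  expect_equal(hp$lr, 5e-5)
  expect_equal(hp$momentum, 0.99)
  expect_equal(hp$epochs, 25L)
  expect_equal(hp$threshold, 0.5)
  expect_error(hyperparams(batch_size = 0), class = "rapidcat_usage_error")
  expect_error(hyperparams(lr = -1), class = "rapidcat_usage_error")
  expect_error(hyperparams(momentum = 1), class = "rapidcat_usage_error")
  expect_error(hyperparams(threshold = 0), class = "rapidcat_usage_error")
})

test_that("augmentation policies are identity, stochastic chain, and catalogue", {
  img <- render_image("artifact_1", spec64(), 5)
  expect_identical(augment(img, "none"), img)
  expect_error(augment(img, "sepia"), class = "rapidcat_usage_error")

  # deterministic under seed
  a1 <- augment(img, "auto", seed = 11)
  a2 <- augment(img, "auto", seed = 11)
  expect_identical(a1, a2)
  outs <- vapply(1:20, function(s) sum(augment(img, "auto", seed = s)), numeric(1))
  expect_gt(length(unique(round(outs, 10))), 1)

  # per-op probabilities of the custom chain: flips and grayscale fire with
  # p = 0.5, rotation always (binomial check, 3 sd)
  small <- img[1:16, 1:16, , drop = FALSE]
  n <- 2000
  applied <- lapply(seq_len(n), function(s) attr(augment(small, "custom", seed = s), "applied"))
  for (op in c("hflip", "vflip", "grayscale")) {
    freq <- mean(vapply(applied, function(a) op %in% a, logical(1)))
    expect_lt(abs(freq - 0.5), 3 * sqrt(0.25 / n))
  }
  expect_true(all(vapply(applied, function(a) "rotation" %in% a, logical(1))))
})

test_that("transfer learning solves the separable task and freezes what it claims", {
  tlc <- get_tlc()
  res <- tlc$result
  ev <- evaluate(res$model, tlc$splits)
  expect_gte(ev$accuracy, 0.9)
  # loss decreases over training
  expect_lt(res$history$loss[nrow(res$history)], res$history$loss[1])
  expect_equal(nrow(res$history), 25)
  expect_equal(res$best_val_accuracy, max(res$history$val_accuracy))
  # frozen parameters are bit-unchanged
  before <- flatten_params_list(set_trainable(replace_head(
    tlc$fixture$pretrain$model, 1, seed = 9), "head_only"))
  after <- flatten_params_list(res$final_model)
  last <- length(res$final_model$classifier)
  for (nm in names(before)) {
    if (grepl(paste0("fc", last), nm)) next
    expect_identical(after[[nm]], before[[nm]], info = nm)
  }
})

test_that("nothing is learnable when labels are independent of pixels", {
  fx <- get_pretrained()
  sp0 <- spec64(signal = FALSE)
  src0 <- make_source(sp0, seed = 7, images_per_label = 60)
  dsr <- build_random_task(src0, generate_hierarchy(sp0), n_labels = 10,
                           config = small_config())
  det <- replace_head(fx$pretrain$model, 1, seed = 9)
  res <- train(det, dsr, protocol("TLC"), hyperparams(seed = 13))
  expect_lt(abs(evaluate(res$model, dsr)$accuracy - 0.5), 0.1)
})

test_that("train validates its inputs", {
  fx <- get_pretrained()
  ds <- build_dataset(fx$source, fx$graph, "animal", build_config(8, 2, 2, seed = 1))
  expect_error(train(fx$pretrain$model, ds, protocol("TLC")),
               class = "rapidcat_usage_error")
})

test_that("the sweep varies one parameter at a time and records the argmax", {
  fx <- get_pretrained()
  ds <- build_dataset(fx$source, fx$graph, "animal", build_config(40, 16, 16, seed = 31))
  factory <- function() replace_head(fx$pretrain$model, 1, seed = 9)
  hp0 <- hyperparams(epochs = 3, seed = 41)

  single <- sweep(factory, ds, protocol("TLC"), list(batch_size = 8), hp0)
  expect_equal(nrow(single$table), 1)
  expect_equal(single$best$batch_size, 8)

  two <- sweep(factory, ds, protocol("TLC"), list(lr = c(1e-2, 5e-5)), hp0)
  expect_equal(nrow(two$table), 2)
  expect_true(two$best$lr %in% c(1e-2, 5e-5))
  expect_equal(two$best$lr,
               two$table$value[which.max(two$table$val_accuracy)])

  two_again <- sweep(factory, ds, protocol("TLC"), list(lr = c(1e-2, 5e-5)), hp0)
  expect_identical(two$table, two_again$table)
  expect_error(sweep(factory, ds, protocol("TLC"), list(), hp0),
               class = "rapidcat_usage_error")
})
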