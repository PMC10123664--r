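test_that("default build yields balanced disjoint 2000/800/1200 splits", {
  sp <- synthetic_spec(n_animal = 4, n_artifact = 4, n_neutral = 2, side = 64)
  g <- generate_hierarchy(sp)
  src <- fake_source(g$leaf_labels, n_per_label = 500)
  ds <- build_dataset(src, g, "animal", build_config(seed = 3))
  man <- ds$manifest
  tab <- table(man$split, man$class)
  expect_equal(unname(tab["train", ]), c(1000, 1000))
  expect_equal(unname(tab["val", ]), c(400, 400))
  expect_equal(unname(tab["test", ]), c(600, 600))
  # image-level disjointness across the whole build
  expect_false(anyDuplicated(man$address) > 0)
  # class membership follows the hierarchy
  desc <- descendant_labels(g, "animal")
  expect_true(all(man$leaf_label[man$class == "target"] %in% desc))
  expect_false(any(man$leaf_label[man$class == "distractor"] %in% desc))
})

test_that("degenerate pools and seeded determinism behave as contracted", {
  g <- shepherd_graph()
  src <- fake_source(g$leaf_labels, n_per_label = 10)
  ds <- build_dataset(src, g, "animal", build_config(4, 2, 2, seed = 5))
  man <- ds$manifest
  expect_equal(sum(man$class == "target"), 4)
  expect_true(all(man$leaf_label[man$class == "target"] == "shepherd"))

  ds2 <- build_dataset(src, g, "animal", build_config(4, 2, 2, seed = 5))
  expect_identical(ds$manifest, ds2$manifest)
  ds3 <- build_dataset(src, g, "animal", build_config(4, 2, 2, seed = 6))
  expect_false(identical(ds$manifest$address, ds3$manifest$address))
  expect_equal(table(ds3$manifest$split), table(ds$manifest$split))

  expect_error(build_config(5, 2, 2), class = "rapidcat_usage_error")
  # every leaf is a kind of root, so no distractor pool remains
  expect_error(build_dataset(src, g, "root", build_config(4, 2, 2)),
               class = "rapidcat_task_undefinable_error")
})

test_that("capacity errors report the shortfall", {
  g <- shepherd_graph()
  src <- fake_source(g$leaf_labels, n_per_label = 3)
  err <- tryCatch(build_dataset(src, g, "animal", build_config(8, 2, 2, seed = 1)),
                  error = function(e) e)
  expect_s3_class(err, "rapidcat_capacity_error")
  expect_match(conditionMessage(err), "short by")
})

test_that("the random control splits labels half and half", {
  K <- 8
  g <- star_graph(K)
  src <- fake_source(g$leaf_labels, n_per_label = 20)
  ds <- build_random_task(src, g, n_labels = 4, config = build_config(8, 4, 4, seed = 2))
  expect_length(ds$target_pool, 2)
  expect_length(ds$distractor_pool, 2)
  expect_equal(ds$synset, "random")
  expect_error(build_random_task(src, g, n_labels = 10, config = build_config(4, 2, 2)),
               class = "rapidcat_capacity_error")

  big <- star_graph(1000)
  bsrc <- fake_source(big$leaf_labels, n_per_label = 5)
  dr <- build_random_task(bsrc, big, config = build_config(4, 2, 2, seed = 9))
  expect_equal(length(dr$target_pool) + length(dr$distractor_pool), 500)
  expect_length(intersect(dr$target_pool, dr$distractor_pool), 0)
})

test_that("strict datasets ban the excluded synset from the distractor pool", {
  g <- load_hierarchy(c("dog animal", "animal root", "hammer artifact",
                        "artifact root", "cloud root"),
                      c("dog", "hammer", "cloud"))
  src <- fake_source(g$leaf_labels, n_per_label = 20)
  ds <- build_strict_dataset(src, g, "animal", excluded = "artifact",
                             config = build_config(8, 2, 2, seed = 4))
  expect_true(all(ds$manifest$leaf_label[ds$manifest$class == "distractor"] == "cloud"))
  # brute-force pool recomputation
  pool <- setdiff(setdiff(g$leaf_labels, brute_descendants(
    data.frame(hyponym = c("dog", "animal", "hammer", "artifact", "cloud"),
               hypernym = c("animal", "root", "artifact", "root", "root")),
    g$leaf_labels, "animal")), "hammer")
  expect_setequal(ds$distractor_pool, pool)
  # strict pool is a subset of the plain pool
  plain <- build_dataset(src, g, "animal", build_config(8, 2, 2, seed = 4))
  expect_true(all(ds$distractor_pool %in% plain$distractor_pool))

  expect_error(build_strict_dataset(src, g, "animal", excluded = "nonexistent",
                                    config = build_config(8, 2, 2)),
               class = "rapidcat_missing_node_error")
  expect_error(build_strict_dataset(src, g, "animal", excluded = "root",
                                    config = build_config(8, 2, 2)),
               class = "rapidcat_task_undefinable_error")
})

test_that("excluded labels leave both pools", {
  sp <- synthetic_spec(n_animal = 3, n_artifact = 2, n_neutral = 1, side = 64)
  g <- generate_hierarchy(sp)
  src <- fake_source(g$leaf_labels, n_per_label = 20)
  ds <- build_dataset(src, g, "animal",
                      build_config(8, 2, 2, seed = 1,
                                   exclude_labels = c("animal_2", "neutral_1")))
  expect_false("animal_2" %in% ds$target_pool)
  expect_false("neutral_1" %in% ds$distractor_pool)
  expect_false(any(c("animal_2", "neutral_1") %in% ds$manifest$leaf_label))
})

test_that("written datasets round-trip through the manifest", {
  sp <- synthetic_spec(n_animal = 1, n_artifact = 1, n_neutral = 0, side = 32)
  g <- generate_hierarchy(sp)
  src <- make_source(sp, seed = 2, images_per_label = 6)
  ds <- build_dataset(src, g, "animal", build_config(4, 2, 2, seed = 1))
  root <- withr::local_tempdir()
  man <- write_dataset(ds, root)
  expect_true(file.exists(file.path(root, "manifest.csv")))
  expect_true(all(file.exists(man$path)))
  back <- png::readPNG(man$path[1])
  orig <- src$get(man$leaf_label[1], man$image_index[1])
  expect_lt(max(abs(back - orig)), 1 / 255) # 8-bit quantization only
})
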