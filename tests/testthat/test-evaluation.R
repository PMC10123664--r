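test_that("accuracy is the correct ratio and survives label swapping", {
  expect_equal(accuracy(confusion_counts(tp = 3, tn = 2, fp = 1, fn = 0)), 5 / 6)
  expect_equal(accuracy(confusion_counts(tp = 0, tn = 0, fp = 5, fn = 5)), 0)
  expect_error(accuracy(confusion_counts()), class = "rapidcat_validation_error")
  expect_error(confusion_counts(tp = -1), class = "rapidcat_validation_error")

  withr::with_seed(61, {
    for (k in 1:5) {
      c4 <- as.list(stats::rpois(4, 20))
      a <- accuracy(confusion_counts(c4[[1]], c4[[2]], c4[[3]], c4[[4]]))
      swapped <- accuracy(confusion_counts(c4[[2]], c4[[1]], c4[[4]], c4[[3]]))
      expect_equal(a, swapped)
    }
  })
})

test_that("accuracy equals a per-record recount on random response sets", {
  withr::with_seed(62, {
    truth <- sample(c("target", "distractor"), 500, replace = TRUE)
    dec <- ifelse(stats::runif(500) < 0.7, truth,
                  ifelse(truth == "target", "distractor", "target"))
    counts <- confusion_counts(
      tp = sum(dec == "target" & truth == "target"),
      tn = sum(dec == "distractor" & truth == "distractor"),
      fp = sum(dec == "target" & truth == "distractor"),
      fn = sum(dec == "distractor" & truth == "target"))
    expect_equal(accuracy(counts), mean(dec == truth))
    expect_equal(counts$total, 500)
  })
})

test_that("evaluate applies the threshold rule and counts consistently", {
  # fake test set whose images encode their class in their mean
  imgs <- c(lapply(1:10, function(i) array(0.9, c(4, 4, 3))),
            lapply(1:10, function(i) array(0.1, c(4, 4, 3))))
  ts <- list(images = imgs, labels = rep(c(1L, 0L), each = 10))
  perfect <- function(img) mean(img)
  ev <- evaluate(perfect, ts)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$counts$fp + ev$counts$fn, 0)

  constant <- function(img) 0.5 # exactly at threshold: always "distractor"
  ev2 <- evaluate(constant, ts)
  expect_equal(ev2$accuracy, 0.5)
  expect_true(all(ev2$records$decision == "distractor"))

  ev3 <- evaluate(perfect, ts, invert = TRUE)
  expect_equal(ev3$accuracy, 0)
  expect_equal(ev2$counts$total, nrow(ev2$records))
})

test_that("the cross-task matrix scores own tasks directly and off-tasks by absence", {
  fx <- get_pretrained()
  ds <- build_dataset(fx$source, fx$graph, "animal", build_config(8, 2, 20, seed = 71))
  lut <- lut_scorer(fx$pretrain$model, fx$graph, "animal")
  ct <- cross_task_matrix(list(animal = lut), list(animal = ds))
  expect_equal(dim(ct), c(1, 1))
  expect_equal(unclass(ct)[1, 1], evaluate(lut, ds)$accuracy)
  expect_equal(attr(ct, "direct")[1, 1], unclass(ct)[1, 1]) # same task: direct

  dsa <- build_dataset(fx$source, fx$graph, "artifact", build_config(8, 2, 20, seed = 72))
  ct2 <- cross_task_matrix(list(animal = lut), list(artifact = dsa))
  expect_equal(unclass(ct2)[1, 1], 1 - attr(ct2, "direct")[1, 1])
})

test_that("agreement is the fraction of identical correctness, symmetric, aligned", {
  rec <- function(id, truth, dec) data.frame(image_id = id, truth = truth,
                                             decision = dec, stringsAsFactors = FALSE)
  a <- rec(1:10, rep("target", 10), rep("target", 10))
  expect_equal(agreement(a, a)$agreement, 1)
  expect_equal(unname(agreement(a, a)$taxonomy["both_correct"]), 10)

  b <- rec(1:10, rep("target", 10), rep("distractor", 10))
  ab <- agreement(a, b)
  expect_equal(ab$agreement, 0)
  expect_equal(unname(ab$taxonomy["a_only"]), 10)

  # two responders with accuracy p on disjoint error sets agree on 2p - 1
  n <- 100; p <- 0.8
  truth <- rep("target", n)
  dec_a <- c(rep("target", 80), rep("distractor", 20))
  dec_b <- c(rep("distractor", 20), rep("target", 80))
  g <- agreement(rec(1:n, truth, dec_a), rec(1:n, truth, dec_b))
  expect_equal(g$agreement, 2 * p - 1)
  # symmetry (taxonomy roles swap)
  g2 <- agreement(rec(1:n, truth, dec_b), rec(1:n, truth, dec_a))
  expect_equal(g$agreement, g2$agreement)
  expect_equal(unname(g$taxonomy["a_only"]), unname(g2$taxonomy["b_only"]))
  # order of rows must not matter
  perm <- withr::with_seed(73, sample(n))
  g3 <- agreement(rec(1:n, truth, dec_a), rec(perm, truth[perm], dec_b[perm]))
  expect_equal(g3$agreement, g$agreement)

  err <- tryCatch(agreement(a, rec(2:11, rep("target", 10), rep("target", 10))),
                  error = function(e) e)
  expect_s3_class(err, "rapidcat_alignment_error")
  expect_match(conditionMessage(err), "1")
})

test_that("external response files round-trip into agreement analyses", {
  p <- withr::local_tempfile(fileext = ".csv")
  d <- data.frame(image_id = c("im1", "im2"), truth = c("target", "distractor"),
                  decision = c("target", "target"), score = c(0.9, 0.7))
  utils::write.csv(d, p, row.names = FALSE)
  r <- read_responses(p)
  expect_equal(r$decision, c("target", "target"))
  expect_equal(agreement(r, r)$agreement, 1)
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d[, 1:2], p2, row.names = FALSE)
  expect_error(read_responses(p2), class = "rapidcat_usage_error")
})
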