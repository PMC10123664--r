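#' Confusion counts
#'
#' @param tp,tn,fp,fn nonnegative integer counts.
#' @return a `confusion_counts` list with a `total` field.
#' @export
confusion_counts <- function(tp = 0, tn = 0, fp = 0, fn = 0) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop_valid("confusion counts must be nonnegative integers")
  }
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn, total = sum(counts)),
            class = "confusion_counts")
}

#' Accuracy from confusion counts
#'
#' The ratio of true positives plus true negatives over all evaluated
#' samples.
#'
#' @param counts a [confusion_counts()].
#' @return accuracy in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  if (counts$total == 0) stop_valid("accuracy is undefined on zero evaluated samples")
  (counts$tp + counts$tn) / counts$total
}

# -- scorers -----------------------------------------------------------------

#' Per-image detection scores
#'
#' Generic over scorer types: a `K = 1` `backbone_model` (sigmoid of its
#' logit — the predicted probability that the target synset is present), a
#' [lut_scorer()] (softmax over leaf scores summed over the synset's
#' descendants), or a plain `function(image) -> score`.
#'
#' @param object the scorer.
#' @param images list of images or 4-d array.
#' @param ... passed on (e.g. `batch_size`).
#' @return numeric vector of scores in `[0, 1]`.
#' @export
image_score <- function(object, images, ...) UseMethod("image_score")

#' @export
image_score.backbone_model <- function(object, images, ...) {
  if (object$config$K != 1) {
    stop_usage("model outputs K > 1 scores; wrap it in lut_scorer() to evaluate")
  }
  as.numeric(sigmoid(predict_scores(object, images, ...)))
}

#' @export
image_score.lut_scorer <- function(object, images, ...) {
  sc <- predict_scores(object$model, images, ...)
  apply(sc, 1, function(z) lut_probability(softmax(z), object$synset, object$graph))
}

#' @export
image_score.function <- function(object, images, ...) {
  if (is.array(images) && length(dim(images)) == 4) {
    images <- lapply(seq_len(dim(images)[4]), function(i) images[, , , i])
  }
  vapply(images, object, numeric(1))
}

#' @export
image_score.train_result <- function(object, images, ...) {
  image_score(object$model, images, ...)
}

scorer_task <- function(object) {
  if (inherits(object, "train_result")) return(object$task)
  if (inherits(object, "lut_scorer")) return(object$synset)
  if (inherits(object, "backbone_model")) return(object$task)
  attr(object, "task", exact = TRUE)
}

# normalize the many accepted test-set forms into list(images, labels, ids)
as_testset <- function(testset, split = "test") {
  if (inherits(testset, "dataset_splits")) testset <- load_split_images(testset, split)
  if (!is.list(testset) || is.null(testset$images) || is.null(testset$labels)) {
    stop_usage("testset must be a dataset_splits or a load_split_images() result")
  }
  ids <- if (!is.null(testset$manifest)) testset$manifest$image_id else
    as.character(seq_along(testset$images))
  list(images = testset$images, labels = testset$labels, ids = ids)
}

#' Evaluate a scorer on a test set
#'
#' Applies the strict `score > threshold` decision rule per image and
#' accumulates confusion counts. Optionally applies a deterministic
#' [transform_spec()] to every image first (the robustness harness).
#'
#' @param object a scorer (see [image_score()]).
#' @param testset a `dataset_splits` (its test split) or a
#'   [load_split_images()] result.
#' @param threshold decision threshold (default 0.5).
#' @param transform optional [transform_spec()] applied to each image.
#' @param invert if `TRUE` the complemented decision is scored — the scorer
#'   is read as a detector of its synset's absence (used for cross-task
#'   cells; see [cross_task_matrix()]).
#' @param ... passed to [image_score()].
#' @return list with `records` (image_id, truth, decision, score), `counts`
#'   (a [confusion_counts()]) and `accuracy`.
#' @export
evaluate <- function(object, testset, threshold = 0.5, transform = NULL,
                     invert = FALSE, ...) {
  ts <- as_testset(testset)
  imgs <- ts$images
  if (!is.null(transform)) imgs <- lapply(imgs, apply_transform, spec = transform)
  score <- image_score(object, imgs, ...)
  dec <- ifelse(score > threshold, "target", "distractor")
  if (invert) dec <- ifelse(dec == "target", "distractor", "target")
  truth <- ifelse(ts$labels == 1, "target", "distractor")
  records <- data.frame(image_id = ts$ids, truth = truth, decision = dec,
                        score = score, stringsAsFactors = FALSE)
  counts <- confusion_counts(
    tp = sum(dec == "target" & truth == "target"),
    tn = sum(dec == "distractor" & truth == "distractor"),
    fp = sum(dec == "target" & truth == "distractor"),
    fn = sum(dec == "distractor" & truth == "target"))
  list(records = records, counts = counts, accuracy = accuracy(counts))
}

#' Cross-task accuracy matrix
#'
#' Evaluates each model on each dataset (rows = models, columns = datasets).
#' A model evaluated on the task it was trained for (or whenever either side
#' is the random control) is scored directly. For genuinely different tasks
#' the model is read as a detector of its own synset's *absence*: within
#' anti-correlated category pairs, "no animal in this scene" is the
#' informative prediction for "artifact present", which is exactly the
#' dataset-composition bias this matrix quantifies. The direct accuracies
#' are kept in the `direct` attribute.
#'
#' @param models named list of scorers (each carrying its training task; see
#'   [image_score()]).
#' @param datasets named list of `dataset_splits`.
#' @param threshold decision threshold.
#' @return a numeric matrix with attribute `direct` (the uncomplemented
#'   accuracies) and class `cross_task_table`.
#' @export
cross_task_matrix <- function(models, datasets, threshold = 0.5) {
  stopifnot(length(names(models)) == length(models),
            length(names(datasets)) == length(datasets))
  out <- matrix(NA_real_, length(models), length(datasets),
                dimnames = list(names(models), names(datasets)))
  direct <- out
  loaded <- lapply(datasets, load_split_images, split = "test")
  for (i in seq_along(models)) {
    task_m <- scorer_task(models[[i]])
    for (j in seq_along(datasets)) {
      task_d <- datasets[[j]]$synset
      same <- is.null(task_m) || task_m == task_d ||
        task_m == "random" || task_d == "random"
      ev_direct <- evaluate(models[[i]], loaded[[j]], threshold = threshold)
      direct[i, j] <- ev_direct$accuracy
      out[i, j] <- if (same) ev_direct$accuracy else 1 - ev_direct$accuracy
    }
  }
  attr(out, "direct") <- direct
  class(out) <- c("cross_task_table", class(out))
  out
}

#' @export
print.cross_task_table <- function(x, ...) {
  cat("<cross_task_table> rows: trained models, columns: evaluation datasets\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Frame-by-frame agreement between two responders
#'
#' The fraction of images on which the two responders have identical
#' correctness (both correct or both wrong), plus the four-way outcome
#' taxonomy. Symmetric in its arguments.
#'
#' @param records_a,records_b `records` data frames as returned by
#'   [evaluate()] (or read from a responses CSV with [read_responses()]):
#'   columns image_id, truth, decision.
#' @return list with `agreement` and `taxonomy` (named counts: both_correct,
#'   a_only, b_only, both_wrong).
#' @export
agreement <- function(records_a, records_b) {
  ids_a <- records_a$image_id; ids_b <- records_b$image_id
  if (!setequal(ids_a, ids_b) || anyDuplicated(ids_a) || anyDuplicated(ids_b)) {
    diff <- union(setdiff(ids_a, ids_b), setdiff(ids_b, ids_a))
    stop_rapidcat(paste0("responder image sets differ: ",
                         paste(utils::head(diff, 10), collapse = ", ")),
                  "rapidcat_alignment_error")
  }
  b <- records_b[match(ids_a, ids_b), ]
  ok_a <- records_a$decision == records_a$truth
  ok_b <- b$decision == b$truth
  taxonomy <- c(both_correct = sum(ok_a & ok_b),
                a_only = sum(ok_a & !ok_b),
                b_only = sum(!ok_a & ok_b),
                both_wrong = sum(!ok_a & !ok_b))
  list(agreement = mean(ok_a == ok_b), taxonomy = taxonomy)
}

#' Read an external responses CSV
#'
#' Ingests per-image responses (e.g. a psychophysics export) with columns
#' `image_id`, `truth`, `decision` (and optionally `score`) so
#' [agreement()] runs on them without bespoke parsing.
#'
#' @param path CSV path.
#' @return a records data frame.
#' @export
read_responses <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "truth", "decision")
  if (!all(need %in% names(d))) {
    stop_usage(paste0("responses CSV needs columns: ", paste(need, collapse = ", ")))
  }
  d
}
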