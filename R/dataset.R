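#' Dataset build configuration
#'
#' Split sizes follow the study defaults: 2000 train, 800 validation and 1200
#' test images, each split half targets and half distractors.
#'
#' @param train,val,test split sizes in images (each must be even and >= 2).
#' @param seed integer seed; the manifest is a pure function of (source,
#'   graph, synset, config).
#' @param excluded_synset optional synset whose descendants are additionally
#'   banned from the distractor pool (the "strictly" datasets).
#' @param exclude_labels labels removed from the build entirely (e.g.
#'   human-depicting labels, which are conventionally not counted as animal
#'   targets).
#' @return a `build_config` list.
#' @export
build_config <- function(train = 2000, val = 800, test = 1200, seed = 1,
                         excluded_synset = NULL, exclude_labels = character()) {
  sizes <- c(train = train, val = val, test = test)
  if (any(sizes < 2)) stop_usage("every split needs at least 2 images")
  if (any(sizes %% 2 != 0)) stop_usage("split sizes must be even (balanced halves)")
  structure(list(sizes = sizes, seed = seed, excluded_synset = excluded_synset,
                 exclude_labels = exclude_labels),
            class = "build_config")
}

# core sampler shared by the three dataset constructors: two-stage sampling
# (label uniform from pool, then an unused image uniform from that label),
# image-level disjointness enforced globally across splits
build_from_pools <- function(source, graph, target_pool, distractor_pool,
                             config, task_synset) {
  if (length(target_pool) == 0) stop_task("target label pool is empty")
  if (length(distractor_pool) == 0) stop_task("distractor label pool is empty")
  stopifnot(all(c(target_pool, distractor_pool) %in% source$labels))

  capacity <- function(pool) length(pool) * source$n_per_label
  need_half <- sum(config$sizes) / 2
  short_t <- need_half - capacity(target_pool)
  short_d <- need_half - capacity(distractor_pool)
  if (short_t > 0 || short_d > 0) {
    stop_capacity(sprintf(
      "insufficient images: need %d per class; target pool short by %d, distractor pool short by %d",
      need_half, max(0, short_t), max(0, short_d)))
  }

  used <- new.env(parent = emptyenv())
  for (l in unique(c(target_pool, distractor_pool))) assign(l, integer(0), envir = used)

  draw <- function(pool, n) {
    lab <- character(n); idx <- integer(n)
    for (i in seq_len(n)) {
      open <- pool[vapply(pool, function(l) length(get(l, envir = used)) < source$n_per_label,
                          logical(1))]
      l <- if (length(open) == 1) open else sample(open, 1)
      taken <- get(l, envir = used)
      free <- setdiff(seq_len(source$n_per_label), taken)
      j <- if (length(free) == 1) free else sample(free, 1)
      assign(l, c(taken, j), envir = used)
      lab[i] <- l; idx[i] <- j
    }
    list(label = lab, index = idx)
  }

  manifest <- withr::with_seed(as.integer(config$seed), {
    rows <- list()
    for (split in c("train", "val", "test")) {
      n_half <- config$sizes[[split]] / 2
      for (cls in c("target", "distractor")) {
        pool <- if (cls == "target") target_pool else distractor_pool
        d <- draw(pool, n_half)
        rows[[paste(split, cls)]] <- data.frame(
          split = split, class = cls, leaf_label = d$label, image_index = d$index,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })
  rownames(manifest) <- NULL
  manifest$task_synset <- task_synset
  manifest$seed <- config$seed
  manifest$address <- paste0(manifest$leaf_label, "/", manifest$image_index)
  manifest$image_id <- paste(manifest$split, manifest$class,
                             seq_len(nrow(manifest)), sep = "_")

  structure(
    list(manifest = manifest, source = source, graph = graph,
         synset = task_synset, config = config,
         target_pool = target_pool, distractor_pool = distractor_pool),
    class = "dataset_splits"
  )
}

#' @export
print.dataset_splits <- function(x, ...) {
  tab <- table(x$manifest$split, x$manifest$class)
  cat(sprintf("<dataset_splits> task '%s', %d images\n", x$synset, nrow(x$manifest)))
  print(tab)
  invisible(x)
}

#' Build balanced target/distractor splits for a synset task
#'
#' Targets are drawn from leaves subsumed by `synset` (its descendants),
#' distractors from the remaining leaves. Sampling is two-stage — a label
#' uniformly from the pool, then an unused image uniformly from that label —
#' so large classes do not dominate, and no image appears in more than one
#' split.
#'
#' @param source an `image_source`.
#' @param graph a [synset_graph()].
#' @param synset the task synset (the "keyword").
#' @param config a [build_config()].
#' @return a `dataset_splits` object whose `manifest` records address, leaf
#'   label, split, class, task synset and seed for every image.
#' @export
build_dataset <- function(source, graph, synset, config = build_config()) {
  check_node(graph, synset)
  desc <- descendant_labels(graph, synset)
  keep <- setdiff(graph$leaf_labels, config$exclude_labels)
  target_pool <- intersect(desc, keep)
  distractor_pool <- setdiff(keep, desc)
  if (!is.null(config$excluded_synset)) {
    check_node(graph, config$excluded_synset)
    distractor_pool <- setdiff(distractor_pool,
                               descendant_labels(graph, config$excluded_synset))
  }
  if (length(target_pool) == 0) {
    stop_task(paste0("no leaf label is a descendant of '", synset, "'"))
  }
  if (length(distractor_pool) == 0) {
    stop_task(paste0("no leaf label remains for the distractor pool of '", synset, "'"))
  }
  build_from_pools(source, graph, target_pool, distractor_pool, config, synset)
}

#' Build the "strictly" variant of a synset task
#'
#' As [build_dataset()], except distractor labels are descendants of neither
#' `synset` nor `excluded` — e.g. a strictly-animal task whose distractors,
#' in addition to not being animals, are not artifacts either.
#'
#' @inheritParams build_dataset
#' @param excluded the synset whose descendants are banned from the
#'   distractor pool.
#' @export
build_strict_dataset <- function(source, graph, synset, excluded,
                                 config = build_config()) {
  check_node(graph, excluded)
  config$excluded_synset <- excluded
  splits <- build_dataset(source, graph, synset, config)
  splits$synset <- synset
  splits
}

#' Build the random-label control task
#'
#' Draws `n_labels` leaves uniformly without replacement and splits them
#' half/half into pseudo-target and pseudo-distractor label sets; the split
#' machinery is then identical to [build_dataset()]. With an image source in
#' which labels carry signal this task is still learnable only through the
#' accidental semantics of the drawn labels; with a no-signal source it is
#' chance-level by construction.
#'
#' @inheritParams build_dataset
#' @param n_labels even number of leaves to draw (study default 500).
#' @export
build_random_task <- function(source, graph, n_labels = 500,
                              config = build_config()) {
  if (!is_count(n_labels) || n_labels < 2 || n_labels %% 2 != 0) {
    stop_usage("n_labels must be a positive even integer")
  }
  if (n_labels > length(graph$leaf_labels)) {
    stop_capacity(sprintf("n_labels = %d exceeds the %d leaves of the hierarchy",
                          n_labels, length(graph$leaf_labels)))
  }
  pools <- withr::with_seed(as.integer(derive_seed(config$seed, "random-task")), {
    chosen <- sample(graph$leaf_labels, n_labels)
    list(target = chosen[seq_len(n_labels / 2)],
         distractor = chosen[(n_labels / 2 + 1):n_labels])
  })
  build_from_pools(source, graph, pools$target, pools$distractor, config,
                   task_synset = "random")
}

#' Materialize the images of one split
#'
#' Loads (or renders) every image of a split into memory once, in manifest
#' order — used by training and by the sweep harnesses so repeated transforms
#' do not re-render.
#'
#' @param splits a `dataset_splits`.
#' @param split one of "train", "val", "test".
#' @return list with `images` (list of arrays), `labels` (0/1 integer,
#'   1 = target) and `manifest` rows of the split.
#' @export
load_split_images <- function(splits, split = "test") {
  man <- splits$manifest[splits$manifest$split == split, ]
  if (nrow(man) == 0) stop_usage(paste0("split '", split, "' is empty"))
  imgs <- lapply(seq_len(nrow(man)),
                 function(i) splits$source$get(man$leaf_label[i], man$image_index[i]))
  list(images = imgs, labels = as.integer(man$class == "target"), manifest = man)
}

#' Write a dataset to disk
#'
#' Layout `<root>/<split>/<target|distractor>/<n>.png` plus `manifest.csv`
#' with columns path, split, class, leaf_label, task_synset, seed.
#'
#' @param splits a `dataset_splits`.
#' @param root output directory.
#' @return invisibly, the manifest with the `path` column filled in.
#' @export
write_dataset <- function(splits, root) {
  man <- splits$manifest
  man$path <- NA_character_
  for (split in unique(man$split)) {
    for (cls in c("target", "distractor")) {
      sel <- which(man$split == split & man$class == cls)
      dir.create(file.path(root, split, cls), recursive = TRUE, showWarnings = FALSE)
      for (k in seq_along(sel)) {
        i <- sel[k]
        p <- file.path(root, split, cls, paste0(k, ".png"))
        png::writePNG(splits$source$get(man$leaf_label[i], man$image_index[i]), p)
        man$path[i] <- p
      }
    }
  }
  utils::write.csv(
    man[, c("path", "split", "class", "leaf_label", "task_synset", "seed")],
    file.path(root, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
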