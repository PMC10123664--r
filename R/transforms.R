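#' Deterministic image transform specification
#'
#' @param kind one of "identity", "rotation", "hflip", "vflip", "grayscale",
#'   "patch_shuffle".
#' @param angle rotation angle in degrees, in `[-180, 180]`. At exact
#'   multiples of 90 the rotation is a lossless grid operation; otherwise the
#'   image is resampled (`interpolation`) with out-of-frame regions set to
#'   `fill`.
#' @param patch patch side in pixels for `patch_shuffle`; must divide the
#'   image side.
#' @param seed permutation seed for `patch_shuffle`.
#' @param interpolation "bilinear" (default) or "nearest".
#' @param fill fill value for out-of-frame pixels (default 0, black).
#' @return a `transform_spec`.
#' @export
transform_spec <- function(kind = c("identity", "rotation", "hflip", "vflip",
                                    "grayscale", "patch_shuffle"),
                           angle = 0, patch = NULL, seed = 1,
                           interpolation = "bilinear", fill = 0) {
  kinds <- c("identity", "rotation", "hflip", "vflip", "grayscale", "patch_shuffle")
  if (!(kind[1] %in% kinds)) stop_usage(paste0("unknown transform kind: ", kind[1]))
  kind <- kind[1]
  if (kind == "rotation" && (angle < -180 || angle > 180)) {
    stop_usage("rotation angle must lie in [-180, 180] degrees")
  }
  if (kind == "patch_shuffle" && is.null(patch)) {
    stop_usage("patch_shuffle needs a patch size")
  }
  structure(list(kind = kind, angle = angle, patch = patch, seed = seed,
                 interpolation = interpolation, fill = fill),
            class = "transform_spec")
}

#' Apply a deterministic transform to one image
#'
#' Rotation is about the image centre; horizontal/vertical flips mirror the
#' pixel grid exactly; grayscale maps to luminance replicated across
#' channels; patch shuffle partitions the image into a `(side/patch)^2` grid
#' and applies a uniformly random patch permutation under the spec's seed
#' (conserving the multiset of patch contents).
#'
#' @param img `H x W x 3` array.
#' @param spec a [transform_spec()].
#' @return the transformed image, same shape.
#' @export
apply_transform <- function(img, spec) {
  switch(spec$kind,
    identity = img,
    hflip = img[, rev(seq_len(dim(img)[2])), , drop = FALSE],
    vflip = img[rev(seq_len(dim(img)[1])), , , drop = FALSE],
    grayscale = to_grayscale(img),
    rotation = {
      a <- ((spec$angle %% 360) + 360) %% 360
      if (a %% 90 == 0) {
        rotate_exact90(img, a / 90)
      } else {
        affine_warp(img, rotation_matrix(spec$angle),
                    interpolation = spec$interpolation, fill = spec$fill)
      }
    },
    patch_shuffle = {
      side <- dim(img)[1]
      s <- spec$patch
      if (is.null(s) || side %% s != 0 || dim(img)[2] != side) {
        stop_usage(sprintf("patch size %s must divide the image side %d",
                           as.character(s), side))
      }
      g <- side / s
      n_p <- g * g
      perm <- withr::with_seed(as.integer(spec$seed), sample.int(n_p))
      out <- img
      for (k in seq_len(n_p)) {
        src <- perm[k]
        r_d <- (k - 1) %% g; c_d <- (k - 1) %/% g
        r_s <- (src - 1) %% g; c_s <- (src - 1) %/% g
        out[r_d * s + seq_len(s), c_d * s + seq_len(s), ] <-
          img[r_s * s + seq_len(s), c_s * s + seq_len(s), ]
      }
      out
    })
}

sweep_row <- function(condition, accs) {
  data.frame(condition = condition, accuracy = mean(accs),
             sd = if (length(accs) > 1) stats::sd(accs) else 0,
             n = length(accs))
}

#' Accuracy as a function of rotation angle
#'
#' Rotates every test image about its centre by each angle and evaluates the
#' model(s); the default grid covers -180..180 in 45-degree steps, including
#' all cardinal angles. With several models (replicate training seeds) the
#' per-angle mean and standard deviation across models are reported.
#'
#' @param models a scorer or list of scorers.
#' @param testset a `dataset_splits` or [load_split_images()] result.
#' @param angles numeric vector of angles in degrees within `[-180, 180]`.
#' @param threshold decision threshold.
#' @param interpolation passed to [transform_spec()].
#' @return a `sweep_result` data frame: condition (angle), accuracy (mean
#'   across models), sd, n.
#' @export
rotation_sweep <- function(models, testset,
                           angles = seq(-180, 180, by = 45),
                           threshold = 0.5, interpolation = "bilinear") {
  if (length(angles) == 0) stop_usage("at least one angle is required")
  if (any(angles < -180 | angles > 180)) {
    stop_usage("angles must lie in [-180, 180]")
  }
  if (!is.list(models) || inherits(models, c("backbone_model", "lut_scorer", "train_result"))) {
    models <- list(models)
  }
  ts <- load_if_splits(testset)
  rows <- lapply(angles, function(a) {
    tf <- transform_spec("rotation", angle = a, interpolation = interpolation)
    accs <- vapply(models, function(m) {
      evaluate(m, ts, threshold = threshold, transform = tf)$accuracy
    }, numeric(1))
    sweep_row(a, accs)
  })
  res <- do.call(rbind, rows)
  class(res) <- c("sweep_result", class(res))
  res
}

#' Accuracy as a function of patch-shuffle scale
#'
#' For each patch size, shuffles the test images `n_reps` times with
#' different permutation seeds and reports mean and standard deviation of
#' the accuracy across repetitions. A patch size equal to the image side is
#' the identity.
#'
#' @param model a scorer.
#' @param testset a `dataset_splits` or [load_split_images()] result.
#' @param patch_sizes sizes in pixels, each dividing the image side; default
#'   `c(256, 128, 64, 32, 16, 8)` intersected with the divisors of the side.
#' @param n_reps permutation repetitions per size.
#' @param seed master seed for the permutations.
#' @param threshold decision threshold.
#' @return a `sweep_result` data frame: condition (patch size), accuracy,
#'   sd, n.
#' @export
shuffle_sweep <- function(model, testset, patch_sizes = NULL, n_reps = 3,
                          seed = 1, threshold = 0.5) {
  ts <- load_if_splits(testset)
  side <- dim(ts$images[[1]])[1]
  if (is.null(patch_sizes)) {
    patch_sizes <- c(256, 128, 64, 32, 16, 8)
    patch_sizes <- patch_sizes[side %% patch_sizes == 0 & patch_sizes <= side]
  }
  if (any(side %% patch_sizes != 0)) {
    stop_usage(sprintf("patch sizes must divide the image side %d", side))
  }
  rows <- lapply(patch_sizes, function(s) {
    accs <- vapply(seq_len(n_reps), function(r) {
      tf <- transform_spec("patch_shuffle", patch = s,
                           seed = derive_seed(seed, "shuffle", s, r))
      evaluate(model, ts, threshold = threshold, transform = tf)$accuracy
    }, numeric(1))
    sweep_row(s, accs)
  })
  res <- do.call(rbind, rows)
  class(res) <- c("sweep_result", class(res))
  res
}

load_if_splits <- function(testset, split = "test") {
  if (inherits(testset, "dataset_splits")) load_split_images(testset, split) else testset
}

#' Timed prediction
#'
#' Scores a batch image-by-image, reporting the decisions and the wall-clock
#' mean and standard deviation of seconds per image. Timings are
#' hardware-dependent and are reported, never asserted against reference
#' values; the qualitative expectation is that pruned (shallower) networks
#' are faster.
#'
#' @param model a scorer.
#' @param images list of images (non-empty).
#' @param threshold decision threshold.
#' @return list with `decisions`, `mean_seconds`, `sd_seconds`.
#' @export
timed_predict <- function(model, images, threshold = 0.5) {
  if (is.array(images) && length(dim(images)) == 3) images <- list(images)
  if (length(images) == 0) stop_usage("timed_predict needs a non-empty batch")
  times <- numeric(length(images))
  scores <- numeric(length(images))
  for (i in seq_along(images)) {
    t0 <- proc.time()[["elapsed"]]
    scores[i] <- image_score(model, images[i])
    times[i] <- proc.time()[["elapsed"]] - t0
  }
  list(decisions = decide(scores, threshold),
       mean_seconds = mean(times),
       sd_seconds = if (length(times) > 1) stats::sd(times) else 0)
}

#' Serialize a sweep result
#'
#' @param result a `sweep_result`.
#' @param path CSV output path.
#' @return the path, invisibly.
#' @export
write_sweep <- function(result, path) {
  utils::write.csv(result, path, row.names = FALSE)
  invisible(path)
}
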