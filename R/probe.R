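#' Hand-crafted orientation-energy features
#'
#' A fixed, training-free image description used to ground the
#' discriminability of the procedural generator independently of any
#' convolutional network: a gradient-orientation energy histogram plus
#' summary statistics.
#'
#' Features: 8 orientation bins (gradient energy by orientation mod 180
#' degrees, normalized), the two signed components of the second circular
#' harmonic (`c2`, `s2` — the resultant of the doubled angles), and mean
#' gradient magnitude (edge energy, which discriminates cue-bearing textures
#' from smooth clutter). The description is deliberately *equivariant*, not
#' invariant, under rotation: a 90-degree rotation permutes the bins and
#' negates `c2`, so a probe fitted on upright images keys on oriented energy
#' and loses its cue when the image rotates — the property the rotation
#' experiments are built on. (The rotation-invariant modulus
#' `sqrt(c2^2 + s2^2)` would hide exactly that.)
#'
#' @param img `side x side x 3` array in `[0, 1]`.
#' @param n_bins number of orientation bins (default 8).
#' @return named numeric vector of length `n_bins + 3`.
#' @export
orientation_features <- function(img, n_bins = 8) {
  lum <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  n <- nrow(lum)
  gx <- lum[c(2:n, n), ] - lum[c(1, 1:(n - 1)), ]
  gy <- lum[, c(2:n, n)] - lum[, c(1, 1:(n - 1))]
  m <- sqrt(gx^2 + gy^2)
  phi <- atan2(gy, gx) %% pi
  bins <- pmin(floor(phi / pi * n_bins) + 1, n_bins)
  e <- as.vector(m^2)
  hist <- vapply(seq_len(n_bins), function(b) sum(e[bins == b]), numeric(1))
  tot <- sum(hist) + 1e-12
  resultant <- sum(e * exp(2i * as.vector(phi))) / tot
  out <- c(hist / tot, Re(resultant), Im(resultant), mean(m))
  names(out) <- c(paste0("ori", seq_len(n_bins)), "c2", "s2", "edge_energy")
  out
}

#' Linear probe on orientation features
#'
#' Fits a logistic regression of target-vs-distractor on
#' [orientation_features()] over the train split of a dataset and reports its
#' accuracy on the test split. Used as a model-free check that the task a
#' dataset defines is (or, for no-signal controls, is not) linearly solvable
#' from first-order oriented energy.
#'
#' @param splits a `dataset_splits` object.
#' @param seed seed (the probe itself is deterministic; reserved).
#' @return list with `accuracy` (test) and `fit` (the glm).
#' @export
linear_probe <- function(splits, seed = 1) {
  feat_of <- function(split) {
    man <- splits$manifest[splits$manifest$split == split, ]
    x <- t(sapply(seq_len(nrow(man)),
                  function(i) orientation_features(
                    splits$source$get(man$leaf_label[i], man$image_index[i]))))
    list(x = as.data.frame(x), y = as.integer(man$class == "target"))
  }
  tr <- feat_of("train")
  te <- feat_of("test")
  dat <- cbind(tr$x, y = tr$y)
  fit <- suppressWarnings(stats::glm(y ~ ., data = dat, family = stats::binomial()))
  p <- stats::predict(fit, newdata = te$x, type = "response")
  acc <- mean((p > 0.5) == (te$y == 1))
  list(accuracy = acc, fit = fit)
}
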