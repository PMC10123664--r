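# General affine warp used by augmentation and rotation: maps output pixel
# coordinates through the inverse of the 2x2 matrix A about the image centre
# plus translation t (in pixels); bilinear or nearest sampling, `fill`
# outside the frame.
affine_warp <- function(img, A, t = c(0, 0), interpolation = "bilinear", fill = 0) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  cx <- (H + 1) / 2; cy <- (W + 1) / 2
  Ainv <- solve(A)
  xo <- rep(seq_len(H) - cx, times = W)
  yo <- rep(seq_len(W) - cy, each = H)
  xs <- Ainv[1, 1] * (xo - t[1]) + Ainv[1, 2] * (yo - t[2]) + cx
  ys <- Ainv[2, 1] * (xo - t[1]) + Ainv[2, 2] * (yo - t[2]) + cy
  out <- array(fill, d)
  if (interpolation == "nearest") {
    xr <- round(xs); yr <- round(ys)
    ok <- xr >= 1 & xr <= H & yr >= 1 & yr <= W
    idx <- xr[ok] + (yr[ok] - 1) * H
    for (ch in seq_len(d[3])) {
      plane <- matrix(fill, H, W)
      src <- img[, , ch]
      plane[ok] <- src[idx]
      out[, , ch] <- plane
    }
  } else {
    x0 <- floor(xs); y0 <- floor(ys)
    fx <- xs - x0; fy <- ys - y0
    ok <- x0 >= 1 & x0 + 1 <= H & y0 >= 1 & y0 + 1 <= W
    i00 <- x0[ok] + (y0[ok] - 1) * H
    for (ch in seq_len(d[3])) {
      src <- img[, , ch]
      v <- src[i00] * (1 - fx[ok]) * (1 - fy[ok]) +
        src[i00 + 1] * fx[ok] * (1 - fy[ok]) +
        src[i00 + H] * (1 - fx[ok]) * fy[ok] +
        src[i00 + H + 1] * fx[ok] * fy[ok]
      plane <- matrix(fill, H, W)
      plane[ok] <- v
      out[, , ch] <- plane
    }
  }
  out
}

rotation_matrix <- function(angle_deg) {
  th <- angle_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

# exact grid rotations at multiples of 90 degrees (interpolation-free); one
# quarter turn matches affine_warp with a 90-degree rotation matrix on square
# images, but without any resampling loss
rotate_exact90 <- function(img, quarter_turns) {
  q <- ((quarter_turns %% 4) + 4) %% 4
  if (q == 0) return(img)
  d <- dim(img)
  out <- img
  for (ch in seq_len(d[3])) {
    m <- img[, , ch]
    if (q == 1) m <- t(m)[rev(seq_len(d[2])), , drop = FALSE]
    if (q == 2) m <- m[rev(seq_len(d[1])), rev(seq_len(d[2])), drop = FALSE]
    if (q == 3) m <- t(m)[, rev(seq_len(d[1])), drop = FALSE]
    out[, , ch] <- m
  }
  out
}

to_grayscale <- function(img) {
  lum <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  array(rep(lum, 3), dim(img))
}

# the 16-operation auto-augmentation catalogue; each op takes (img, m) with
# magnitude m in [0, 1] and returns an image
auto_ops <- list(
  rotation     = function(img, m) affine_warp(img, rotation_matrix((2 * m - 1) * 30)),
  shear_x      = function(img, m) affine_warp(img, matrix(c(1, (2 * m - 1) * 0.3, 0, 1), 2, 2)),
  shear_y      = function(img, m) affine_warp(img, matrix(c(1, 0, (2 * m - 1) * 0.3, 1), 2, 2)),
  translate_x  = function(img, m) affine_warp(img, diag(2), t = c((2 * m - 1) * 0.2 * dim(img)[1], 0)),
  translate_y  = function(img, m) affine_warp(img, diag(2), t = c(0, (2 * m - 1) * 0.2 * dim(img)[2])),
  scale        = function(img, m) affine_warp(img, diag(2) * (0.75 + 0.5 * m)),
  hflip        = function(img, m) img[, rev(seq_len(dim(img)[2])), , drop = FALSE],
  vflip        = function(img, m) img[rev(seq_len(dim(img)[1])), , , drop = FALSE],
  contrast     = function(img, m) clamp01(0.5 + (0.5 + m) * (img - 0.5)),
  brightness   = function(img, m) clamp01(img + (2 * m - 1) * 0.3),
  sharpness    = function(img, m) {
    blur <- img
    for (ch in 1:3) {
      p <- img[, , ch]
      blur[, , ch] <- (p +
        p[c(1, seq_len(nrow(p) - 1)), ] + p[c(2:nrow(p), nrow(p)), ] +
        p[, c(1, seq_len(ncol(p) - 1))] + p[, c(2:ncol(p), ncol(p))]) / 5
    }
    clamp01(blur + (0.5 + m) * (img - blur))
  },
  posterize    = function(img, m) {
    levels <- 2^max(2, round(8 - 5 * m))
    floor(img * (levels - 1) + 0.5) / (levels - 1)
  },
  solarize     = function(img, m) {
    thr <- 1 - 0.5 * m
    ifelse(img >= thr, 1 - img, img)
  },
  grayscale    = function(img, m) to_grayscale(img),
  cutout       = function(img, m) {
    side <- dim(img)[1]
    s <- max(2, round(side * 0.2 * (0.5 + m)))
    x0 <- sample.int(side - s + 1, 1); y0 <- sample.int(side - s + 1, 1)
    img[x0:(x0 + s - 1), y0:(y0 + s - 1), ] <- 0.5
    img
  },
  identity     = function(img, m) img
)

#' Stochastic training-time augmentation
#'
#' Three policies:
#' * `none` — identity.
#' * `custom` — the fixed chain: random horizontal flip (p = 0.5), random
#'   vertical flip (p = 0.5), a random rotation (p = 1, angle uniform in
#'   -180..180 degrees), random grayscale (p = 0.5), applied in that order.
#' * `auto` — one of a fixed catalogue of 16 affine/photometric operations
#'   (rotation, shears, translations, scale, flips, contrast, brightness,
#'   sharpness, posterize, solarize, grayscale, cutout, identity), drawn with
#'   a random magnitude per call.
#'
#' Deterministic under `seed`; with `seed = NULL` the current RNG stream is
#' used (the training loop derives a per-image seed).
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param policy "none", "custom" or "auto".
#' @param seed optional integer seed.
#' @return the augmented image, same shape, with attribute `applied` naming
#'   the operations that fired (policies other than `none`).
#' @export
augment <- function(image, policy = c("none", "custom", "auto"), seed = NULL) {
  if (!(policy[1] %in% c("none", "custom", "auto"))) {
    stop_usage(paste0("unknown augmentation policy: ", policy[1]))
  }
  policy <- policy[1]
  if (policy == "none") return(image)
  run <- function() {
    applied <- character(0)
    if (policy == "custom") {
      if (stats::runif(1) < 0.5) {
        image <- image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
        applied <- c(applied, "hflip")
      }
      if (stats::runif(1) < 0.5) {
        image <- image[rev(seq_len(dim(image)[1])), , , drop = FALSE]
        applied <- c(applied, "vflip")
      }
      angle <- stats::runif(1, -180, 180)
      image <- affine_warp(image, rotation_matrix(angle))
      applied <- c(applied, "rotation")
      if (stats::runif(1) < 0.5) {
        image <- to_grayscale(image)
        applied <- c(applied, "grayscale")
      }
    } else {
      op <- sample(length(auto_ops), 1)
      m <- stats::runif(1)
      image <- auto_ops[[op]](image, m)
      applied <- names(auto_ops)[op]
    }
    attr(image, "applied") <- applied
    image
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}
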