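#' Specification of the procedural image generator
#'
#' The generator stands in for a photographic image provider: it emits
#' procedural textures whose statistics carry the same kind of structure the
#' categorization analysis assumes in natural scenes. Leaves live under three
#' superordinate branches:
#'
#' * `animal`-like leaves render curved, isotropic contours (rings/arcs),
#' * `artifact`-like leaves render rectilinear strokes (long straight lines,
#'   vertically oriented by default, so the cue is orientation-anisotropic),
#' * `neutral` leaves render background clutter only.
#'
#' Both cue families share the same stroke profile, so below the cue scale
#' their local statistics match and only the arrangement (curved vs straight)
#' distinguishes them. Nuisance variation covers element position, element
#' scale and per-channel colour gain. With probability `1 -
#' cross_category_exclusion` an animal (artifact) image additionally carries a
#' superimposed artifact (animal) cue, emulating the anti-correlation of the
#' two categories within one photograph. With `signal = FALSE` the rendered
#' content is independent of the label (the "random" control regime).
#'
#' @param n_animal,n_artifact,n_neutral leaves per branch.
#' @param side image side in pixels; must be divisible by 32 so patch-shuffle
#'   grids at the standard sizes exist.
#' @param cue_scale characteristic cue size in pixels: ring diameter and the
#'   length scale of straight strokes.
#' @param cue_contrast cue stroke amplitude relative to the clutter level;
#'   the discriminability dial.
#' @param clutter amplitude of the smooth background clutter.
#' @param stroke_sd Gaussian stroke half-width in pixels.
#' @param density expected number of cue elements per `cue_scale^2` patch of
#'   image area (scaled to an element count internally).
#' @param scale_range 2-vector, multiplicative range of per-element scale.
#' @param jitter fraction of the side by which the whole element cloud is
#'   offset (position nuisance).
#' @param rotation_invariant if `TRUE`, straight strokes take a uniformly
#'   random orientation per element, making the artifact cue
#'   orientation-isotropic (rotation of the image then leaves the class
#'   statistics unchanged); if `FALSE` (default) strokes are vertical.
#' @param cross_category_exclusion probability that an image carries only its
#'   own branch's cue.
#' @param signal if `FALSE`, labels are independent of pixel content.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_animal = 4, n_artifact = 4, n_neutral = 2,
                           side = 256, cue_scale = 48,
                           cue_contrast = 1, clutter = 0.35,
                           stroke_sd = NULL, density = 0.75,
                           scale_range = c(0.8, 1.25), jitter = 0.15,
                           rotation_invariant = FALSE,
                           cross_category_exclusion = 0.9,
                           signal = TRUE) {
  if (n_animal + n_artifact + n_neutral < 1) {
    stop_task("the hierarchy needs at least one leaf in some branch")
  }
  if (side %% 32 != 0) stop_usage("side must be divisible by 32")
  if (cross_category_exclusion < 0 || cross_category_exclusion > 1) {
    stop_valid("cross_category_exclusion must lie in [0, 1]")
  }
  if (is.null(stroke_sd)) stroke_sd <- max(1, cue_scale / 16)
  structure(
    list(
      n_animal = n_animal, n_artifact = n_artifact, n_neutral = n_neutral,
      side = side, cue_scale = cue_scale, cue_contrast = cue_contrast,
      clutter = clutter, stroke_sd = stroke_sd, density = density,
      scale_range = scale_range, jitter = jitter,
      rotation_invariant = rotation_invariant,
      cross_category_exclusion = cross_category_exclusion,
      signal = signal
    ),
    class = "synthetic_spec"
  )
}

branch_sizes <- function(spec) {
  c(animal = spec$n_animal, artifact = spec$n_artifact, neutral = spec$n_neutral)
}

synthetic_leaves <- function(spec) {
  sizes <- branch_sizes(spec)
  unlist(lapply(names(sizes), function(b) {
    if (sizes[[b]] == 0) return(character(0))
    paste0(b, "_", seq_len(sizes[[b]]))
  }), use.names = FALSE)
}

leaf_branch <- function(label) sub("_[0-9]+$", "", label)

#' Generate the toy hyperonym hierarchy
#'
#' Builds the deterministic hierarchy that matches a [synthetic_spec()]:
#' leaves under the three branch synsets, with `animal` under `organism`,
#' `artifact` under `object`, and everything under the root `entity` — so
#' hyperonym paths have realistic depth and a superordinate synset
#' (`organism`) strictly above the task synset exists.
#'
#' @param spec a `synthetic_spec`.
#' @param seed unused (the hierarchy is a pure function of `spec`); kept so
#'   generator calls share one signature.
#' @return a [synset_graph()] whose leaf order is animal, artifact, neutral
#'   leaves.
#' @export
generate_hierarchy <- function(spec, seed = 0) {
  leaves <- synthetic_leaves(spec)
  if (length(leaves) == 0) stop_task("no leaves in any branch")
  edges <- data.frame(hyponym = character(0), hypernym = character(0))
  for (lf in leaves) {
    edges <- rbind(edges, data.frame(hyponym = lf, hypernym = leaf_branch(lf)))
  }
  branches <- unique(leaf_branch(leaves))
  upper <- list(animal = "organism", artifact = "object", neutral = "entity")
  for (b in branches) {
    edges <- rbind(edges, data.frame(hyponym = b, hypernym = upper[[b]]))
  }
  if ("animal" %in% branches) edges <- rbind(edges, data.frame(hyponym = "organism", hypernym = "entity"))
  if ("artifact" %in% branches) edges <- rbind(edges, data.frame(hyponym = "object", hypernym = "entity"))
  edges <- unique(edges)
  synset_graph(edges, leaves)
}

# -- rendering ---------------------------------------------------------------

# smooth background clutter: bilinearly upsampled coarse Gaussian noise
render_clutter <- function(side, amplitude) {
  coarse_n <- max(4, side %/% 16)
  g <- matrix(stats::rnorm(coarse_n^2), coarse_n, coarse_n)
  # bilinear upsample to side x side
  src <- seq(1, coarse_n, length.out = side)
  i0 <- pmin(floor(src), coarse_n - 1)
  fr <- src - i0
  a <- g[i0, , drop = FALSE] * (1 - fr) + g[i0 + 1, , drop = FALSE] * fr
  a <- a[, i0, drop = FALSE] * rep(1 - fr, each = side) +
    a[, i0 + 1, drop = FALSE] * rep(fr, each = side)
  amplitude * a / stats::sd(a)
}

# add a Gaussian-profile ring of radius r centred at (cx, cy)
draw_ring <- function(canvas, cx, cy, r, sd, amp) {
  side <- nrow(canvas)
  w <- ceiling(r + 3 * sd)
  xlo <- max(1, floor(cx - w)); xhi <- min(side, ceiling(cx + w))
  ylo <- max(1, floor(cy - w)); yhi <- min(side, ceiling(cy + w))
  if (xlo > xhi || ylo > yhi) return(canvas)
  xs <- xlo:xhi; ys <- ylo:yhi
  d <- sqrt(outer((xs - cx)^2, (ys - cy)^2, "+"))
  canvas[xs, ys] <- canvas[xs, ys] + amp * exp(-(d - r)^2 / (2 * sd^2))
  canvas
}

# add a Gaussian-profile straight stroke of half-length L/2, orientation theta
# (theta = 0 is vertical: the stroke runs along the y axis)
draw_stroke <- function(canvas, cx, cy, len, theta, sd, amp) {
  side <- nrow(canvas)
  w <- ceiling(len / 2 + 3 * sd)
  xlo <- max(1, floor(cx - w)); xhi <- min(side, ceiling(cx + w))
  ylo <- max(1, floor(cy - w)); yhi <- min(side, ceiling(cy + w))
  if (xlo > xhi || ylo > yhi) return(canvas)
  xs <- xlo:xhi; ys <- ylo:yhi
  dx <- outer(xs - cx, rep(1, length(ys)))
  dy <- outer(rep(1, length(xs)), ys - cy)
  # along-stroke and perpendicular coordinates
  along <- dx * sin(theta) + dy * cos(theta)
  perp <- dx * cos(theta) - dy * sin(theta)
  ends <- pmax(abs(along) - len / 2, 0)
  canvas[xs, ys] <- canvas[xs, ys] +
    amp * exp(-(perp^2 + ends^2) / (2 * sd^2))
  canvas
}

# leaf_frac in [0, 1] places the leaf within its branch's subordinate cue
# continuum (ring size for animal-like leaves, stroke length for
# artifact-like ones) — subordinate classes differ, as leaf labels do in
# photographic collections, which is what makes leaf-level pre-training a
# non-trivial task
draw_cue <- function(canvas, branch, spec, leaf_frac = 0.5) {
  side <- spec$side
  n_el <- max(3, round(spec$density * (side / spec$cue_scale)^2))
  off <- stats::runif(2, -spec$jitter, spec$jitter) * side
  leaf_mod <- 0.55 + 0.75 * leaf_frac
  for (i in seq_len(n_el)) {
    sc <- stats::runif(1, spec$scale_range[1], spec$scale_range[2])
    cx <- stats::runif(1, 1, side) + off[1]
    cy <- stats::runif(1, 1, side) + off[2]
    amp <- spec$cue_contrast * stats::runif(1, 0.8, 1.2)
    if (branch == "animal") {
      r <- leaf_mod * sc * spec$cue_scale / 2
      canvas <- draw_ring(canvas, cx, cy, r, spec$stroke_sd, amp)
    } else if (branch == "artifact") {
      theta <- if (spec$rotation_invariant) stats::runif(1, 0, pi) else 0
      len <- leaf_mod * sc * spec$cue_scale * 2.2
      canvas <- draw_stroke(canvas, cx, cy, len, theta, spec$stroke_sd, amp)
    }
  }
  canvas
}

leaf_frac_of <- function(label, spec) {
  branch <- leaf_branch(label)
  n <- branch_sizes(spec)[[branch]]
  i <- as.integer(sub("^.*_", "", label))
  if (n <= 1) 0.5 else (i - 1) / (n - 1)
}

#' Render one procedural image
#'
#' Deterministic in `(label, spec, seed)`: the same triple yields the same
#' pixels. See [synthetic_spec()] for the generative model.
#'
#' @param label a leaf of the hierarchy generated from `spec`.
#' @param spec a `synthetic_spec`.
#' @param seed integer seed for this image.
#' @return numeric array `side x side x 3` with values in `[0, 1]`.
#' @export
render_image <- function(label, spec, seed) {
  leaves <- synthetic_leaves(spec)
  if (!(label %in% leaves)) {
    stop_missing(paste0("label '", label, "' is not a leaf of this generator"))
  }
  withr::with_seed(as.integer(seed %% 2147483647), {
    side <- spec$side
    canvas <- render_clutter(side, spec$clutter)
    if (spec$signal) {
      branch <- leaf_branch(label)
      canvas <- draw_cue(canvas, branch, spec, leaf_frac_of(label, spec))
      other <- c(animal = "artifact", artifact = "animal")[branch]
      if (!is.na(other) &&
          stats::runif(1) > spec$cross_category_exclusion) {
        canvas <- draw_cue(canvas, other, spec, stats::runif(1))
      }
    }
    # standardize luminance so mean level and global contrast carry no class
    # information; classes differ in spatial arrangement only
    canvas <- (canvas - mean(canvas)) / (stats::sd(canvas) + 1e-8)
    lum <- clamp01(0.5 + 0.12 * canvas)
    gains <- stats::runif(3, 0.85, 1.15)
    img <- array(0, c(side, side, 3))
    for (ch in 1:3) img[, , ch] <- clamp01(0.5 + gains[ch] * (lum - 0.5))
    img
  })
}

#' Lazily rendering image source
#'
#' Wraps the generator as an addressable image provider satisfying the
#' dataset builder's contract: every leaf exposes `images_per_label` images,
#' addressable by `(label, index)`, rendered on demand with a per-image seed
#' derived from `(seed, label, index)` — so the pixel content of image `i` of
#' a label does not depend on enumeration order.
#'
#' @param spec a `synthetic_spec`.
#' @param seed master seed.
#' @param images_per_label images available per leaf.
#' @return an object of class `image_source` with fields `labels`,
#'   `n_per_label`, `side` and a `get(label, index)` function.
#' @export
make_source <- function(spec, seed, images_per_label) {
  if (!is_count(images_per_label) || images_per_label < 1) {
    stop_usage("images_per_label must be a positive integer")
  }
  labels <- synthetic_leaves(spec)
  get <- function(label, index) {
    if (!(label %in% labels)) {
      stop_missing(paste0("label '", label, "' is not in this source"))
    }
    if (index < 1 || index > images_per_label) {
      stop_usage(sprintf("image index %d out of range 1..%d", index, images_per_label))
    }
    render_image(label, spec, derive_seed(seed, label, index))
  }
  structure(
    list(labels = labels, n_per_label = images_per_label, side = spec$side,
         get = get, spec = spec, seed = seed),
    class = "image_source"
  )
}

#' @export
print.image_source <- function(x, ...) {
  cat(sprintf("<image_source> %d labels x %d images, side %d px\n",
              length(x$labels), x$n_per_label, x$side))
  invisible(x)
}

#' Image source over a directory of PNG files
#'
#' Reads `<root>/<label>/*.png`, resizing to `side` if needed; the on-disk
#' counterpart of [make_source()] for externally supplied images.
#'
#' @param root directory containing one sub-directory per leaf label.
#' @param side side length images are resized to (default 256).
#' @return an `image_source`.
#' @export
image_dir_source <- function(root, side = 256) {
  labels <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(labels) == 0) stop_usage(paste0("no label directories under ", root))
  files <- lapply(labels, function(l) {
    sort(list.files(file.path(root, l), pattern = "\\.png$", full.names = TRUE))
  })
  names(files) <- labels
  n_min <- min(vapply(files, length, integer(1)))
  if (n_min == 0) stop_usage("every label directory needs at least one png")
  get <- function(label, index) {
    if (!(label %in% labels)) stop_missing(paste0("label '", label, "' not in source"))
    f <- files[[label]]
    if (index < 1 || index > length(f)) stop_usage("image index out of range")
    img <- png::readPNG(f[index])
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    if (dim(img)[3] > 3) img <- img[, , 1:3]
    if (dim(img)[1] != side || dim(img)[2] != side) img <- resize_bilinear(img, side)
    img
  }
  structure(
    list(labels = labels, n_per_label = n_min, side = side, get = get),
    class = "image_source"
  )
}

# bilinear resize of an H x W x C array to side x side
resize_bilinear <- function(img, side) {
  d <- dim(img)
  src_r <- seq(1, d[1], length.out = side)
  src_c <- seq(1, d[2], length.out = side)
  r0 <- pmin(floor(src_r), d[1] - 1); fr <- src_r - r0
  c0 <- pmin(floor(src_c), d[2] - 1); fc <- src_c - c0
  if (d[1] == 1) { r0 <- rep(1, side); fr <- rep(0, side) }
  if (d[2] == 1) { c0 <- rep(1, side); fc <- rep(0, side) }
  out <- array(0, c(side, side, d[3]))
  for (ch in seq_len(d[3])) {
    m <- img[, , ch]
    a <- m[r0, , drop = FALSE] * (1 - fr) + m[pmin(r0 + 1, d[1]), , drop = FALSE] * fr
    out[, , ch] <- a[, c0, drop = FALSE] * rep(1 - fc, each = side) +
      a[, pmin(c0 + 1, d[2]), drop = FALSE] * rep(fc, each = side)
  }
  out
}
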