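#' VGG-style backbone configuration
#'
#' The default mirrors the classical 16-layer architecture's convolutional
#' stage: 13 3x3 convolutional layers organized into 5 blocks (2,2,3,3,3
#' layers wide 64,128,256,512,512 channels), 2x2 max pooling between blocks,
#' adaptive average pooling to a constant 7x7 spatial side, and a fully
#' connected classifier. Because the pooled side is constant, the classifier
#' architecture is independent of input resolution and of how many
#' convolutional layers survive pruning.
#'
#' @param channels per-block channel widths.
#' @param convs convolutional layers per block; `sum(convs)` is the depth.
#' @param pooled_side adaptive-pooling output side.
#' @param hidden classifier hidden widths.
#' @param K output dimension (1000 for a leaf classifier; 1 for the binary
#'   detection head).
#' @param in_channels input channels (3 for RGB).
#' @return a `backbone_config`.
#' @export
backbone_config <- function(channels = c(64, 128, 256, 512, 512),
                            convs = c(2, 2, 3, 3, 3),
                            pooled_side = 7,
                            hidden = c(4096, 4096),
                            K = 1000,
                            in_channels = 3) {
  if (length(channels) != length(convs)) {
    stop_usage("channels and convs must have one entry per block")
  }
  if (any(channels < 1) || any(convs < 1)) stop_usage("widths and depths must be positive")
  if (!is_count(K) || K < 1) stop_usage("K must be a positive integer")
  structure(list(channels = channels, convs = convs, pooled_side = pooled_side,
                 hidden = hidden, K = K, in_channels = in_channels),
            class = "backbone_config")
}

#' Small backbone preset for desk-scale experiments
#'
#' Three blocks of one 3x3 convolution each (8, 16, 32 channels), adaptive
#' pooling to 4x4, one hidden classifier layer of 64 units.
#'
#' @param K output dimension.
#' @param hidden classifier hidden widths.
#' @return a `backbone_config`.
#' @export
small_backbone_config <- function(K = 1, hidden = c(64)) {
  backbone_config(channels = c(8, 16, 32), convs = c(1, 1, 1),
                  pooled_side = 4, hidden = hidden, K = K)
}

new_conv_layer <- function(in_ch, out_ch) {
  sd <- sqrt(2 / (in_ch * 9))
  list(type = "conv", in_ch = in_ch, out_ch = out_ch,
       W = matrix(stats::rnorm(out_ch * in_ch * 9, sd = sd), out_ch, in_ch * 9),
       b = rep(0, out_ch), trainable = TRUE)
}

new_linear_layer <- function(n_in, n_out, final = FALSE) {
  sd <- if (final) sqrt(1 / n_in) else sqrt(2 / n_in)
  list(type = "linear", n_in = n_in, n_out = n_out,
       W = matrix(stats::rnorm(n_out * n_in, sd = sd), n_out, n_in),
       b = rep(0, n_out), trainable = TRUE, final = final)
}

#' Construct a backbone model
#'
#' Initialization is deterministic under `seed` (He-style normal weights).
#' Externally supplied weights may be injected when their shapes match the
#' architecture; a mismatch raises a weight-mismatch error listing the
#' offending layers.
#'
#' @param config a [backbone_config()].
#' @param seed integer seed for initialization.
#' @param weights optional named list of parameter arrays in the layout of
#'   `flatten_params()` (names like `conv1.W`, `fc2.b`).
#' @param preprocess list with per-channel `mean` and `sd` applied to inputs
#'   after scaling to `[0, 1]`; identity by default.
#' @return a `backbone_model`.
#' @export
make_backbone <- function(config = backbone_config(), seed = 1, weights = NULL,
                          preprocess = list(mean = c(0, 0, 0), sd = c(1, 1, 1))) {
  model <- withr::with_seed(as.integer(seed), {
    features <- list()
    in_ch <- config$in_channels
    for (blk in seq_along(config$channels)) {
      for (k in seq_len(config$convs[blk])) {
        features[[length(features) + 1]] <- new_conv_layer(in_ch, config$channels[blk])
        in_ch <- config$channels[blk]
      }
      features[[length(features) + 1]] <- list(type = "maxpool")
    }
    n_in <- config$channels[length(config$channels)] * config$pooled_side^2
    widths <- c(config$hidden, config$K)
    classifier <- list()
    for (i in seq_along(widths)) {
      classifier[[i]] <- new_linear_layer(n_in, widths[i], final = i == length(widths))
      n_in <- widths[i]
    }
    structure(list(config = config, features = features, classifier = classifier,
                   preprocess = preprocess, task = NULL),
              class = "backbone_model")
  })
  if (!is.null(weights)) model <- inject_weights(model, weights)
  model
}

#' Inject externally supplied weights
#'
#' @param model a `backbone_model`.
#' @param weights named list of arrays; names as in `flatten_params()`.
#' @return the model with matching parameters replaced.
#' @export
inject_weights <- function(model, weights) {
  current <- flatten_params(model)
  unknown <- setdiff(names(weights), names(current))
  bad <- character(0)
  for (nm in intersect(names(weights), names(current))) {
    if (!identical(dim1(current[[nm]]), dim1(weights[[nm]]))) bad <- c(bad, nm)
  }
  if (length(unknown) > 0 || length(bad) > 0) {
    stop_rapidcat(paste0(
      "weight mismatch: ",
      if (length(bad) > 0) paste0("shape differs for [", paste(bad, collapse = ", "), "]"),
      if (length(unknown) > 0) paste0(" unknown layers [", paste(unknown, collapse = ", "), "]")),
      "rapidcat_weight_mismatch_error")
  }
  ci <- 0; fi <- 0
  for (i in seq_along(model$features)) {
    if (model$features[[i]]$type != "conv") next
    ci <- ci + 1
    for (part in c("W", "b")) {
      nm <- paste0("conv", i, ".", part)
      if (nm %in% names(weights)) model$features[[i]][[part]] <- weights[[nm]]
    }
  }
  for (i in seq_along(model$classifier)) {
    for (part in c("W", "b")) {
      nm <- paste0("fc", i, ".", part)
      if (nm %in% names(weights)) model$classifier[[i]][[part]] <- weights[[nm]]
    }
  }
  model
}

dim1 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' @export
print.backbone_model <- function(x, ...) {
  nconv <- sum(vapply(x$features, function(l) l$type == "conv", logical(1)))
  cat(sprintf("<backbone_model> %d conv layers, pooled side %d, classifier %s -> K = %d\n",
              nconv, x$config$pooled_side,
              paste(x$config$hidden, collapse = "-"), x$config$K))
  invisible(x)
}

#' Number of convolutional layers
#' @param model a `backbone_model`.
#' @return integer count.
#' @export
conv_depth <- function(model) {
  sum(vapply(model$features, function(l) l$type == "conv", logical(1)))
}

#' Count parameters
#' @param model a `backbone_model`.
#' @param trainable_only count only trainable parameters.
#' @return integer count.
#' @export
n_parameters <- function(model, trainable_only = FALSE) {
  tot <- 0
  all_layers <- c(model$features, model$classifier)
  for (ly in all_layers) {
    if (is.null(ly$W)) next
    if (trainable_only && !isTRUE(ly$trainable)) next
    tot <- tot + length(ly$W) + length(ly$b)
  }
  tot
}

#' Replace the classification head
#'
#' Re-instantiates only the final classifier layer with output width `K_new`
#' (freshly initialized under `seed`); every other parameter is untouched.
#' This is the step that turns a K-class leaf classifier into a single-output
#' detector ("is the synset present?").
#'
#' @param model a `backbone_model`.
#' @param K_new new output dimension (>= 1).
#' @param seed seed for the fresh layer.
#' @return the modified model.
#' @export
replace_head <- function(model, K_new = 1, seed = 1) {
  if (!is_count(K_new) || K_new < 1) stop_usage("K_new must be a positive integer")
  i <- length(model$classifier)
  n_in <- model$classifier[[i]]$n_in
  model$classifier[[i]] <- withr::with_seed(as.integer(seed),
                                            new_linear_layer(n_in, K_new, final = TRUE))
  model$config$K <- as.integer(K_new)
  model$task <- NULL
  model
}

#' Prune the deepest convolutional layers
#'
#' Removes the `n_removed` deepest convolutional layers (and the pooling
#' stage of any block left empty). Because adaptive pooling keeps the
#' classifier's spatial input constant, the classifier remains usable; its
#' first layer is re-instantiated to match the surviving channel width.
#' Surviving convolutional parameters are bit-unchanged, and `n_removed = 0`
#' returns the model unmodified.
#'
#' @param model a `backbone_model`.
#' @param n_removed number of deepest conv layers to remove,
#'   `0 <= n_removed <= depth - 1`.
#' @param seed seed for the re-instantiated classifier layer.
#' @return the pruned model.
#' @export
prune_conv_layers <- function(model, n_removed, seed = 1) {
  depth <- conv_depth(model)
  if (!is_count(n_removed) || n_removed < 0 || n_removed >= depth) {
    stop_usage(sprintf("n_removed must lie in 0..%d", depth - 1))
  }
  if (n_removed == 0) return(model)

  keep <- depth - n_removed
  convs_per_block <- model$config$convs
  surv <- integer(length(convs_per_block))
  left <- keep
  for (b in seq_along(convs_per_block)) {
    surv[b] <- min(convs_per_block[b], max(0L, left))
    left <- left - convs_per_block[b]
  }
  conv_layers <- Filter(function(l) l$type == "conv", model$features)
  features <- list()
  ci <- 0
  for (b in seq_along(surv)) {
    if (surv[b] == 0) break
    for (k in seq_len(surv[b])) {
      ci <- ci + 1
      features[[length(features) + 1]] <- conv_layers[[ci]]
    }
    features[[length(features) + 1]] <- list(type = "maxpool")
  }
  last_ch <- features[[length(features) - 1]]$out_ch
  model$features <- features
  model$config$channels <- model$config$channels[surv > 0]
  model$config$channels[sum(surv > 0)] <- last_ch
  model$config$convs <- surv[surv > 0]

  n_in <- last_ch * model$config$pooled_side^2
  old_first <- model$classifier[[1]]
  model$classifier[[1]] <- withr::with_seed(
    as.integer(seed),
    new_linear_layer(n_in, old_first$n_out, final = isTRUE(old_first$final)))
  model
}

#' Set which parameters train
#'
#' `head_only` marks exactly the final classifier layer trainable (the
#' transfer-learning freeze); `all` and `none` are self-describing.
#'
#' @param model a `backbone_model`.
#' @param policy one of "head_only", "all", "none".
#' @return the model with trainability flags set.
#' @export
set_trainable <- function(model, policy = c("head_only", "all", "none")) {
  if (!(policy[1] %in% c("head_only", "all", "none"))) {
    stop_usage(paste0("unknown trainability policy: ", policy[1]))
  }
  policy <- policy[1]
  for (i in seq_along(model$features)) {
    if (model$features[[i]]$type == "conv") {
      model$features[[i]]$trainable <- policy == "all"
    }
  }
  for (i in seq_along(model$classifier)) {
    model$classifier[[i]]$trainable <-
      policy == "all" || (policy == "head_only" && i == length(model$classifier))
  }
  model
}

# -- forward / backward ------------------------------------------------------

# stack a list of H x W x 3 images into an H x W x 3 x N array
stack_images <- function(images) {
  if (is.array(images) && length(dim(images)) == 4) return(images)
  if (is.array(images) && length(dim(images)) == 3) images <- list(images)
  d <- dim(images[[1]])
  x <- array(0, c(d, length(images)))
  for (i in seq_along(images)) x[, , , i] <- images[[i]]
  x
}

preprocess_batch <- function(model, x) {
  mu <- model$preprocess$mean; sd <- model$preprocess$sd
  if (all(mu == 0) && all(sd == 1)) return(x)
  for (ch in 1:3) x[, , ch, ] <- (x[, , ch, ] - mu[ch]) / sd[ch]
  x
}

# forward pass; with cache = TRUE returns intermediates needed by backward
forward_backbone <- function(model, x, cache = FALSE) {
  x <- preprocess_batch(model, x)
  acts <- list(); pools <- list()
  for (i in seq_along(model$features)) {
    ly <- model$features[[i]]
    if (ly$type == "conv") {
      if (cache) acts[[i]] <- x
      x <- cpp_conv3x3_forward(x, ly$W, ly$b, TRUE)
    } else {
      if (dim(x)[1] >= 2 && dim(x)[2] >= 2) {
        if (cache) acts[[i]] <- dim(x)
        p <- cpp_maxpool2(x)
        x <- p$y
        if (cache) pools[[i]] <- p$idx
      } else if (cache) acts[[i]] <- NA # pooling skipped on degenerate side
    }
  }
  pre_pool_dim <- dim(x)
  x <- cpp_adaptive_avgpool(x, model$config$pooled_side)
  n <- dim(x)[4]
  f <- matrix(x, ncol = n) # (S*S*C) x N
  fcs <- list()
  for (i in seq_along(model$classifier)) {
    ly <- model$classifier[[i]]
    if (cache) fcs[[i]] <- f
    z <- ly$W %*% f + ly$b
    f <- if (isTRUE(ly$final)) z else pmax(z, 0)
  }
  scores <- t(f) # N x K
  if (!cache) return(scores)
  list(scores = scores, acts = acts, pools = pools, fcs = fcs,
       pre_pool_dim = pre_pool_dim, last_f = f)
}

# backward pass from dscores (N x K); returns list of gradients for trainable
# layers, keyed like flatten_params(). Backpropagation stops below the
# shallowest trainable layer.
backward_backbone <- function(model, fwd, dscores) {
  grads <- list()
  df <- t(dscores) # K x N
  n_cls <- length(model$classifier)
  conv_trainable <- vapply(model$features,
                           function(l) l$type == "conv" && isTRUE(l$trainable),
                           logical(1))
  lowest_trainable_feature <- if (any(conv_trainable)) min(which(conv_trainable)) else Inf
  for (i in rev(seq_len(n_cls))) {
    ly <- model$classifier[[i]]
    f_in <- fwd$fcs[[i]]
    if (!isTRUE(ly$final)) {
      # df arrives w.r.t. post-relu output; mask by the layer's own output
      out <- ly$W %*% f_in + ly$b
      df <- df * (out > 0)
    }
    if (isTRUE(ly$trainable)) {
      grads[[paste0("fc", i, ".W")]] <- df %*% t(f_in)
      grads[[paste0("fc", i, ".b")]] <- rowSums(df)
    }
    need_lower <- i > 1 || is.finite(lowest_trainable_feature)
    if (!need_lower) return(grads)
    df <- t(ly$W) %*% df
  }
  # back through adaptive pooling
  S <- model$config$pooled_side
  dpool <- array(df, c(S, S, fwd$pre_pool_dim[3], fwd$pre_pool_dim[4]))
  dx <- cpp_adaptive_avgpool_backward(dpool, as.integer(fwd$pre_pool_dim), S)
  for (i in rev(seq_along(model$features))) {
    ly <- model$features[[i]]
    if (ly$type == "maxpool") {
      if (!is.null(fwd$pools[[i]]) && length(fwd$pools[[i]]) > 0) {
        dx <- cpp_maxpool2_backward(dx, fwd$pools[[i]], as.integer(fwd$acts[[i]]))
      }
    } else {
      y_i <- NULL
      need_dx <- i > lowest_trainable_feature
      if (!isTRUE(ly$trainable) && !need_dx) break
      # recompute layer output cheaply from cached input for the relu mask
      y_out <- cpp_conv3x3_forward(fwd$acts[[i]], ly$W, ly$b, TRUE)
      g <- cpp_conv3x3_backward(fwd$acts[[i]], y_out, ly$W, dx, TRUE, need_dx)
      if (isTRUE(ly$trainable)) {
        grads[[paste0("conv", i, ".W")]] <- g$dW
        grads[[paste0("conv", i, ".b")]] <- g$db
      }
      if (!need_dx) break
      dx <- g$dx
    }
  }
  grads
}

#' Raw network scores for a batch of images
#'
#' @param model a `backbone_model`.
#' @param images a list of images or an `H x W x 3 x N` array.
#' @param batch_size forward-pass batch size.
#' @return `N x K` matrix of scores (logits).
#' @export
predict_scores <- function(model, images, batch_size = 32) {
  x <- stack_images(images)
  n <- dim(x)[4]
  out <- NULL
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1)
    s <- forward_backbone(model, x[, , , idx, drop = FALSE])
    out <- rbind(out, s)
  }
  out
}
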