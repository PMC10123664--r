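#' The five (re-)training protocols
#'
#' * `SLS`  — supervised learning from scratch: random weights, all layers
#'   trainable, no augmentation (the control for the value of pre-training).
#' * `TLC`  — transfer learning on the classification layer: pre-trained
#'   backbone, only the final layer trains, no augmentation.
#' * `TLA`  — transfer learning on all layers: pre-trained start, everything
#'   trains, no augmentation.
#' * `TLDA` — TLC plus the custom augmentation chain (flips, rotation,
#'   grayscale).
#' * `TLAA` — TLC plus the 16-operation auto-augmentation catalogue.
#'
#' @param name one of "SLS", "TLC", "TLA", "TLDA", "TLAA".
#' @return a `protocol` with fields `name`, `origin` (random/pretrained),
#'   `trainable` (all/head_only) and `augmentation` (none/custom/auto).
#' @export
protocol <- function(name = c("TLC", "TLA", "TLDA", "TLAA", "SLS")) {
  name <- toupper(name[1])
  spec <- switch(name,
    SLS  = list(origin = "random",     trainable = "all",       augmentation = "none"),
    TLC  = list(origin = "pretrained", trainable = "head_only", augmentation = "none"),
    TLA  = list(origin = "pretrained", trainable = "all",       augmentation = "none"),
    TLDA = list(origin = "pretrained", trainable = "head_only", augmentation = "custom"),
    TLAA = list(origin = "pretrained", trainable = "head_only", augmentation = "auto"),
    stop_usage(paste0("unknown protocol: ", name))
  )
  structure(c(list(name = name), spec), class = "protocol")
}

#' Training hyperparameters
#'
#' Defaults are the values retained after the one-at-a-time validation sweep
#' of the study conditions: batch size 8, learning rate 5e-5, momentum 0.99,
#' 25 epochs, decision threshold 0.5.
#'
#' @param batch_size mini-batch size (>= 1).
#' @param lr learning rate (> 0).
#' @param momentum SGD momentum in `[0, 1)`.
#' @param epochs training epochs.
#' @param threshold decision threshold in (0, 1).
#' @param seed master seed for shuffling, augmentation and initialization.
#' @return a `hyperparams` list.
#' @export
hyperparams <- function(batch_size = 8, lr = 0.00005, momentum = 0.99,
                        epochs = 25, threshold = 0.5, seed = 1) {
  if (batch_size < 1) stop_usage("batch_size must be >= 1")
  if (lr <= 0) stop_usage("lr must be positive")
  if (momentum < 0 || momentum >= 1) stop_usage("momentum must lie in [0, 1)")
  if (threshold <= 0 || threshold >= 1) stop_usage("threshold must lie in (0, 1)")
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 momentum = momentum, epochs = as.integer(epochs),
                 threshold = threshold, seed = as.integer(seed)),
            class = "hyperparams")
}

# one SGD-with-momentum step (v <- mu v + g ; w <- w - lr v) over the named
# gradient list; state is an environment holding velocities
sgd_step <- function(model, grads, hp, state) {
  for (nm in names(grads)) {
    v <- if (!is.null(state$v[[nm]])) state$v[[nm]] else 0
    v <- hp$momentum * v + grads[[nm]]
    state$v[[nm]] <- v
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    where <- parts[1]; part <- parts[2]
    if (grepl("^conv", where)) {
      i <- as.integer(sub("conv", "", where))
      model$features[[i]][[part]] <- model$features[[i]][[part]] - hp$lr * v
    } else {
      i <- as.integer(sub("fc", "", where))
      model$classifier[[i]][[part]] <- model$classifier[[i]][[part]] - hp$lr * v
    }
  }
  model
}

bce_with_logits <- function(z, y) {
  # numerically stable binary cross entropy on raw scores
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

#' Train a binary detector
#'
#' Optimizes the sigmoid-linked binary cross entropy (targets coded 1,
#' distractors 0) with momentum SGD over shuffled mini-batches. The
#' trainability policy and augmentation policy come from the protocol;
#' parameters frozen by the policy are bit-unchanged afterwards. Validation
#' accuracy is computed each epoch with the 0.5-threshold rule and the
#' best-epoch parameters are retained.
#'
#' When the protocol freezes everything below the head and does not augment
#' (TLC), the penultimate features are computed once and only the head is
#' iterated — mathematically identical, much faster.
#'
#' @param model a `backbone_model` with `K = 1` (apply [replace_head()]
#'   first).
#' @param splits a `dataset_splits`.
#' @param protocol a [protocol()].
#' @param hp a [hyperparams()].
#' @return a `train_result`: `model` (best epoch), `final_model`, `history`
#'   (epoch, loss, val_accuracy), `best_epoch`, `best_val_accuracy`,
#'   `protocol`, `hp`.
#' @export
train <- function(model, splits, protocol, hp = hyperparams()) {
  if (model$config$K != 1) {
    stop_usage("train() expects a K = 1 detection head; call replace_head() first")
  }
  model <- set_trainable(model, protocol$trainable)
  tr <- load_split_images(splits, "train")
  va <- load_split_images(splits, "val")
  if (length(tr$images) == 0 || length(va$images) == 0) {
    stop_capacity("empty train or validation split")
  }

  head_only_fast <- protocol$trainable == "head_only" &&
    protocol$augmentation == "none" && length(model$classifier) >= 1

  n <- length(tr$images)
  y <- tr$labels
  state <- new.env(parent = emptyenv()); state$v <- list()
  history <- data.frame(epoch = integer(0), loss = numeric(0), val_accuracy = numeric(0))
  best <- list(acc = -Inf, epoch = NA, model = model)

  if (head_only_fast) {
    feats_tr <- penultimate_features(model, tr$images)
    feats_va <- penultimate_features(model, va$images)
    i_head <- length(model$classifier)
    for (epoch in seq_len(hp$epochs)) {
      ord <- withr::with_seed(derive_seed(hp$seed, "shuffle", epoch), sample.int(n))
      losses <- numeric(0)
      for (start in seq(1, n, by = hp$batch_size)) {
        idx <- ord[start:min(n, start + hp$batch_size - 1)]
        f <- feats_tr[, idx, drop = FALSE]
        head <- model$classifier[[i_head]]
        z <- as.numeric(head$W %*% f + head$b)
        losses <- c(losses, bce_with_logits(z, y[idx]))
        dz <- matrix((sigmoid(z) - y[idx]) / length(idx), nrow = 1)
        grads <- list()
        grads[[paste0("fc", i_head, ".W")]] <- dz %*% t(f)
        grads[[paste0("fc", i_head, ".b")]] <- rowSums(dz)
        model <- sgd_step(model, grads, hp, state)
      }
      head <- model$classifier[[i_head]]
      zv <- as.numeric(head$W %*% feats_va + head$b)
      acc <- mean((sigmoid(zv) > hp$threshold) == (va$labels == 1))
      history <- rbind(history, data.frame(epoch = epoch, loss = mean(losses),
                                           val_accuracy = acc))
      if (acc > best$acc) best <- list(acc = acc, epoch = epoch, model = model)
    }
  } else {
    for (epoch in seq_len(hp$epochs)) {
      ord <- withr::with_seed(derive_seed(hp$seed, "shuffle", epoch), sample.int(n))
      losses <- numeric(0)
      for (start in seq(1, n, by = hp$batch_size)) {
        idx <- ord[start:min(n, start + hp$batch_size - 1)]
        imgs <- lapply(seq_along(idx), function(k) {
          augment(tr$images[[idx[k]]], protocol$augmentation,
                  seed = derive_seed(hp$seed, "aug", epoch, idx[k]))
        })
        x <- stack_images(imgs)
        fwd <- forward_backbone(model, x, cache = TRUE)
        z <- as.numeric(fwd$scores)
        losses <- c(losses, bce_with_logits(z, y[idx]))
        dsc <- matrix((sigmoid(z) - y[idx]) / length(idx), ncol = 1)
        grads <- backward_backbone(model, fwd, dsc)
        model <- sgd_step(model, grads, hp, state)
      }
      ev <- evaluate(model, va, threshold = hp$threshold)
      acc <- ev$accuracy
      history <- rbind(history, data.frame(epoch = epoch, loss = mean(losses),
                                           val_accuracy = acc))
      if (acc > best$acc) best <- list(acc = acc, epoch = epoch, model = model)
    }
  }

  best$model$task <- splits$synset
  model$task <- splits$synset
  structure(list(model = best$model, final_model = model, history = history,
                 best_epoch = best$epoch, best_val_accuracy = best$acc,
                 protocol = protocol, hp = hp, task = splits$synset),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("<train_result> %s on task '%s': best val accuracy %.3f (epoch %d/%d)\n",
              x$protocol$name, x$task, x$best_val_accuracy, x$best_epoch,
              nrow(x$history)))
  invisible(x)
}

# activations entering the final classifier layer, as a (p x N) matrix
penultimate_features <- function(model, images, batch_size = 32) {
  x <- stack_images(images)
  n <- dim(x)[4]
  cols <- list()
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1)
    xb <- preprocess_batch(model, x[, , , idx, drop = FALSE])
    for (ly in model$features) {
      if (ly$type == "conv") {
        xb <- cpp_conv3x3_forward(xb, ly$W, ly$b, TRUE)
      } else if (dim(xb)[1] >= 2 && dim(xb)[2] >= 2) {
        xb <- cpp_maxpool2(xb)$y
      }
    }
    xb <- cpp_adaptive_avgpool(xb, model$config$pooled_side)
    f <- matrix(xb, ncol = length(idx))
    for (i in seq_len(length(model$classifier) - 1)) {
      ly <- model$classifier[[i]]
      f <- pmax(ly$W %*% f + ly$b, 0)
    }
    cols[[length(cols) + 1]] <- f
  }
  do.call(cbind, cols)
}

#' Train a K-class leaf classifier
#'
#' Softmax cross-entropy over all leaves of an image source; the desk-scale
#' analogue of large-scale pre-training, producing the "pretrained" weights
#' the transfer protocols start from and the K-class model the LUT scorer
#' needs.
#'
#' @param model a `backbone_model` whose `K` equals the number of source
#'   labels.
#' @param source an `image_source`.
#' @param images_per_label images drawn per leaf (train; a further 20% block
#'   is used for monitoring).
#' @param hp a [hyperparams()]; all layers train.
#' @return a `train_result` (history columns: epoch, loss, val_accuracy =
#'   leaf-classification accuracy).
#' @export
train_multiclass <- function(model, source, images_per_label = 30,
                             hp = hyperparams(lr = 0.01, momentum = 0.9, epochs = 15)) {
  K <- length(source$labels)
  if (model$config$K != K) {
    stop_usage(sprintf("model K = %d but the source has %d labels", model$config$K, K))
  }
  n_val <- max(1, round(images_per_label * 0.2))
  if (images_per_label + n_val > source$n_per_label) {
    stop_capacity(sprintf("source holds %d images per label; %d needed",
                          source$n_per_label, images_per_label + n_val))
  }
  model <- set_trainable(model, "all")
  tr_imgs <- list(); tr_y <- integer(0)
  va_imgs <- list(); va_y <- integer(0)
  for (li in seq_along(source$labels)) {
    l <- source$labels[li]
    for (j in seq_len(images_per_label)) {
      tr_imgs[[length(tr_imgs) + 1]] <- source$get(l, j)
      tr_y <- c(tr_y, li)
    }
    for (j in images_per_label + seq_len(n_val)) {
      va_imgs[[length(va_imgs) + 1]] <- source$get(l, j)
      va_y <- c(va_y, li)
    }
  }
  n <- length(tr_imgs)
  state <- new.env(parent = emptyenv()); state$v <- list()
  history <- data.frame(epoch = integer(0), loss = numeric(0), val_accuracy = numeric(0))
  best <- list(acc = -Inf, epoch = NA, model = model)
  va_x <- stack_images(va_imgs)
  for (epoch in seq_len(hp$epochs)) {
    ord <- withr::with_seed(derive_seed(hp$seed, "mc-shuffle", epoch), sample.int(n))
    losses <- numeric(0)
    for (start in seq(1, n, by = hp$batch_size)) {
      idx <- ord[start:min(n, start + hp$batch_size - 1)]
      x <- stack_images(tr_imgs[idx])
      fwd <- forward_backbone(model, x, cache = TRUE)
      p <- t(apply(fwd$scores, 1, softmax)) # N x K
      yy <- tr_y[idx]
      losses <- c(losses, -mean(log(pmax(p[cbind(seq_along(idx), yy)], 1e-12))))
      dsc <- p
      dsc[cbind(seq_along(idx), yy)] <- dsc[cbind(seq_along(idx), yy)] - 1
      dsc <- dsc / length(idx)
      grads <- backward_backbone(model, fwd, dsc)
      model <- sgd_step(model, grads, hp, state)
    }
    sc <- predict_scores(model, va_x)
    acc <- mean(max.col(sc) == va_y)
    history <- rbind(history, data.frame(epoch = epoch, loss = mean(losses),
                                         val_accuracy = acc))
    if (acc > best$acc) best <- list(acc = acc, epoch = epoch, model = model)
  }
  structure(list(model = best$model, final_model = model, history = history,
                 best_epoch = best$epoch, best_val_accuracy = best$acc,
                 protocol = NULL, hp = hp, task = "leaf-classification"),
            class = "train_result")
}

#' One-at-a-time hyperparameter sweep
#'
#' Varies one hyperparameter over its candidate list while the others stay at
#' their defaults (not a full factorial), trains once per setting, and
#' reports the validation accuracy per setting plus the argmax per parameter.
#'
#' @param model_factory zero-argument function returning a fresh `K = 1`
#'   model (called once per setting).
#' @param splits a `dataset_splits`.
#' @param protocol a [protocol()].
#' @param grid named list, e.g. `list(lr = c(1e-2, 5e-5), batch_size = c(8, 32))`.
#' @param hp_defaults baseline [hyperparams()].
#' @return list with `table` (parameter, value, val_accuracy) and `best`
#'   (hyperparams with each swept parameter at its argmax).
#' @export
sweep <- function(model_factory, splits, protocol, grid,
                  hp_defaults = hyperparams()) {
  if (length(grid) == 0 || any(vapply(grid, length, integer(1)) == 0)) {
    stop_usage("sweep grid must provide a non-empty value list per parameter")
  }
  rows <- list()
  best <- hp_defaults
  for (param in names(grid)) {
    accs <- numeric(0)
    for (value in grid[[param]]) {
      hp <- hp_defaults
      hp[[param]] <- value
      res <- train(model_factory(), splits, protocol, hp)
      accs <- c(accs, res$best_val_accuracy)
      rows[[length(rows) + 1]] <- data.frame(parameter = param, value = value,
                                             val_accuracy = res$best_val_accuracy)
    }
    best[[param]] <- grid[[param]][which.max(accs)]
  }
  list(table = do.call(rbind, rows), best = best)
}
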