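#' @useDynLib rapidcat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Classed conditions so callers can distinguish failure modes programmatically.
stop_rapidcat <- function(message, class, call. = FALSE) {
  cond <- structure(
    class = c(class, "rapidcat_error", "error", "condition"),
    list(message = message, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cond)
}

stop_usage    <- function(msg) stop_rapidcat(msg, "rapidcat_usage_error")
stop_missing  <- function(msg) stop_rapidcat(msg, "rapidcat_missing_node_error")
stop_format   <- function(msg) stop_rapidcat(msg, "rapidcat_hierarchy_format_error")
stop_capacity <- function(msg) stop_rapidcat(msg, "rapidcat_capacity_error")
stop_task     <- function(msg) stop_rapidcat(msg, "rapidcat_task_undefinable_error")
stop_valid    <- function(msg) stop_rapidcat(msg, "rapidcat_validation_error")

#' Derive a reproducible child seed
#'
#' Mixes a master seed with any number of integer/character tokens into a
#' 31-bit seed, so per-image or per-epoch random streams are independent of
#' the order in which they are consumed.
#'
#' @param seed master seed (single integer).
#' @param ... integer or character tokens identifying the child stream.
#' @return an integer in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, ...) {
  tokens <- list(...)
  h <- as.double(seed) %% 2147483647
  for (tok in tokens) {
    if (is.character(tok)) {
      tok <- sum(utf8ToInt(paste(tok, collapse = ""))) %% 2147483647
    }
    for (t in as.double(tok)) {
      # 31-bit multiply-add hash; constants from Park-Miller family
      h <- (h * 48271 + (t %% 2147483647) + 11) %% 2147483647
      h <- (h * 16807 + 17) %% 2147483647
    }
  }
  as.integer(h)
}

# Sum-based digest of all parameters; exact equality of the unlisted vector is
# used in tests, this is a cheap human-readable fingerprint.
#' Checksum of all model parameters
#'
#' @param model a `backbone_model`.
#' @return a single numeric, the sum of all weights and biases.
#' @export
param_checksum <- function(model) {
  sum(vapply(flatten_params(model), function(p) sum(p), numeric(1)))
}

# All parameter arrays of a model as a flat named list.
flatten_params <- function(model) {
  out <- list()
  for (i in seq_along(model$features)) {
    ly <- model$features[[i]]
    if (ly$type == "conv") {
      out[[paste0("conv", i, ".W")]] <- ly$W
      out[[paste0("conv", i, ".b")]] <- ly$b
    }
  }
  for (i in seq_along(model$classifier)) {
    ly <- model$classifier[[i]]
    out[[paste0("fc", i, ".W")]] <- ly$W
    out[[paste0("fc", i, ".b")]] <- ly$b
  }
  out
}

#' Numerically stable softmax
#'
#' @param z numeric vector of scores (logits).
#' @return a probability vector of the same length summing to 1.
#' @export
softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Clamp helper used by renderers and transforms.
clamp01 <- function(x) pmin(pmax(x, 0), 1)

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) && x == floor(x)
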