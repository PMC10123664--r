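#' Look-up-table probability of a superordinate synset
#'
#' Given the post-softmax class probabilities of a K-class leaf classifier,
#' the probability assigned to a superordinate synset is the sum of the
#' probabilities of the leaf labels whose hyperonym path contains that synset
#' (its descendants). Inputs must already be normalized: raw scores are
#' rejected, not silently renormalized.
#'
#' @param probs numeric vector of length K, nonnegative, summing to 1 within
#'   `1e-6`, indexed in the leaf order of `graph`.
#' @param synset a node of `graph`.
#' @param graph a [synset_graph()].
#' @return a scalar score in `[0, 1]`.
#' @export
lut_probability <- function(probs, synset, graph) {
  K <- length(graph$leaf_labels)
  if (length(probs) != K) {
    stop_valid(sprintf("probs has length %d but the hierarchy has K = %d leaves",
                       length(probs), K))
  }
  if (any(probs < 0)) stop_valid("probabilities must be nonnegative")
  if (abs(sum(probs) - 1) > 1e-6) {
    stop_valid("probabilities must sum to 1 (within 1e-6); apply softmax first")
  }
  check_node(graph, synset)
  desc <- descendant_labels(graph, synset)
  score <- sum(probs[match(desc, graph$leaf_labels)])
  min(max(score, 0), 1)
}

#' Threshold decision
#'
#' An image is called a target when its score strictly exceeds the threshold
#' (a score exactly at the threshold is a distractor).
#'
#' @param score scalar (or vector) in `[0, 1]`.
#' @param threshold decision threshold, default 0.5.
#' @return character "target"/"distractor", vectorized over `score`.
#' @export
decide <- function(score, threshold = 0.5) {
  if (any(score < 0 | score > 1)) stop_valid("scores must lie in [0, 1]")
  ifelse(score > threshold, "target", "distractor")
}

#' LUT scorer over a K-class backbone
#'
#' Wraps a leaf classifier and a hierarchy into a scorer whose per-image
#' score is the LUT probability of `synset`: softmax over the K leaf scores,
#' summed over the synset's descendants. Usable anywhere a trained binary
#' detector is (e.g. [evaluate()], [rotation_sweep()]).
#'
#' @param model a `backbone_model` with `K > 1` (leaf classifier).
#' @param graph the [synset_graph()] whose leaf order indexed the training.
#' @param synset the superordinate synset to score.
#' @return an object of class `lut_scorer`.
#' @export
lut_scorer <- function(model, graph, synset) {
  check_node(graph, synset)
  if (model$config$K != length(graph$leaf_labels)) {
    stop_usage(sprintf("model K = %d does not match the %d leaf labels",
                       model$config$K, length(graph$leaf_labels)))
  }
  structure(list(model = model, graph = graph, synset = synset, task = synset),
            class = "lut_scorer")
}

#' @export
print.lut_scorer <- function(x, ...) {
  cat(sprintf("<lut_scorer> synset '%s' over K = %d leaves\n",
              x$synset, length(x$graph$leaf_labels)))
  invisible(x)
}
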