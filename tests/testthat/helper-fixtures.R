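# shared fixtures; heavy ones (trained models) are built once per test run
# and cached in this environment
.fix <- new.env(parent = emptyenv())

# the worked example hierarchy: a German-Shepherd-style 5-edge graph
shepherd_graph <- function() {
  load_hierarchy(c("shepherd dog", "dog animal", "animal root",
                   "hammer artifact", "artifact root"),
                 c("shepherd", "hammer"))
}

# standard desk-scale generator settings: 64-px images, 16-px cue scale
spec64 <- function(...) synthetic_spec(side = 64, cue_scale = 16, ...)

small_config <- function(seed = 11) build_config(200, 80, 120, seed = seed)

centered_pp <- function() list(mean = rep(0.5, 3), sd = rep(0.25, 3))

flatten_params_list <- function(m) rapidcat:::flatten_params(m)

# image source whose pixels are irrelevant (manifest-level dataset tests);
# images encode their (label, index) so leakage checks could decode them
fake_source <- function(labels, n_per_label, side = 8) {
  get <- function(label, index) {
    val <- (match(label, labels) * 1000 + index) / (length(labels) * 1000 + n_per_label)
    array(val, c(side, side, 3))
  }
  structure(list(labels = labels, n_per_label = n_per_label, side = side, get = get),
            class = "image_source")
}

# a star hierarchy: K leaves all under 'root'; optional subset under 'mid'
star_graph <- function(K, mid_leaves = integer(0)) {
  leaves <- sprintf("leaf%02d", seq_len(K))
  edges <- data.frame(hyponym = leaves, hypernym = "root")
  if (length(mid_leaves) > 0) {
    edges <- rbind(data.frame(hyponym = leaves[mid_leaves], hypernym = "mid"),
                   data.frame(hyponym = setdiff(leaves, leaves[mid_leaves]),
                              hypernym = "root"),
                   data.frame(hyponym = "mid", hypernym = "root"))
  }
  synset_graph(edges, leaves)
}

# random DAG generator for property tests: nodes n1..n_nodes, edges only from
# lower to higher id (acyclic by construction); the lowest `n_leaves` ids are
# the leaf labels, each wired to at least one higher node
random_dag <- function(n_nodes, n_leaves, n_extra, seed) {
  withr::with_seed(seed, {
    nodes <- sprintf("n%02d", seq_len(n_nodes))
    edges <- data.frame(hyponym = nodes[seq_len(n_nodes - 1)],
                        hypernym = nodes[pmin(n_nodes,
                                              seq_len(n_nodes - 1) +
                                                sample(n_nodes, n_nodes - 1, replace = TRUE))])
    edges$hypernym <- ifelse(edges$hypernym == edges$hyponym, nodes[n_nodes], edges$hypernym)
    for (k in seq_len(n_extra)) {
      i <- sample(n_nodes - 1, 1)
      j <- sample((i + 1):n_nodes, 1)
      edges <- rbind(edges, data.frame(hyponym = nodes[i], hypernym = nodes[j]))
    }
    list(edges = unique(edges), leaves = nodes[seq_len(n_leaves)], nodes = nodes)
  })
}

# independent brute-force path enumeration over a raw edge data frame (no
# igraph): all maximal hyponym->hypernym walks starting at `from`
brute_paths <- function(edges, from) {
  out <- list()
  walk <- function(path) {
    nxt <- edges$hypernym[edges$hyponym == path[length(path)]]
    if (length(nxt) == 0) {
      out[[length(out) + 1]] <<- path
    } else {
      for (n in nxt) walk(c(path, n))
    }
  }
  walk(from)
  out
}

# brute-force descendant computation from paths
brute_descendants <- function(edges, leaves, synset) {
  keep <- vapply(leaves, function(l) {
    any(vapply(brute_paths(edges, l), function(p) synset %in% p, logical(1)))
  }, logical(1))
  leaves[keep]
}

# cached pretrained leaf classifier over the standard generator settings
get_pretrained <- function(rotation_invariant = FALSE) {
  key <- if (rotation_invariant) "pre_ri" else "pre_std"
  if (!is.null(.fix[[key]])) return(.fix[[key]])
  spec <- spec64(rotation_invariant = rotation_invariant)
  g <- generate_hierarchy(spec)
  src <- make_source(spec, seed = 7, images_per_label = 120)
  base <- make_backbone(small_backbone_config(K = length(g$leaf_labels)),
                        seed = 3, preprocess = centered_pp())
  pt <- train_multiclass(base, src, images_per_label = 30,
                         hp = hyperparams(lr = 0.01, momentum = 0.9,
                                          epochs = 15, seed = 5))
  .fix[[key]] <- list(spec = spec, graph = g, source = src, pretrain = pt)
  .fix[[key]]
}

# cached TLC detector on the standard animal task
get_tlc <- function() {
  if (!is.null(.fix$tlc)) return(.fix$tlc)
  fx <- get_pretrained()
  ds <- build_dataset(fx$source, fx$graph, "animal", small_config())
  det <- replace_head(fx$pretrain$model, 1, seed = 9)
  res <- train(det, ds, protocol("TLC"), hyperparams(seed = 13))
  .fix$tlc <- list(fixture = fx, splits = ds, result = res)
  .fix$tlc
}
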