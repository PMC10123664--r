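#' Synset hierarchies
#'
#' A `synset_graph` represents a hyperonym ("is a kind of") hierarchy over
#' semantic synsets: a directed acyclic graph whose edges point from hyponym
#' to hypernym (e.g. `shepherd -> dog -> animal -> entity`). A designated
#' ordered subset of nodes, the leaf labels, are the image-class labels; their
#' order fixes the index `0..K-1` used by class-probability vectors.
#'
#' @param edges a two-column data frame (or matrix) of `hyponym`, `hypernym`
#'   node names.
#' @param leaf_labels character vector of leaf label names, in index order.
#' @return an object of class `synset_graph` with elements `graph` (an
#'   [igraph::graph]), `nodes`, `leaf_labels`.
#' @export
synset_graph <- function(edges, leaf_labels) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2) stop_format("edge list must have two columns (hyponym, hypernym)")
  names(edges)[1:2] <- c("hyponym", "hypernym")
  edges$hyponym <- as.character(edges$hyponym)
  edges$hypernym <- as.character(edges$hypernym)
  leaf_labels <- as.character(leaf_labels)

  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = TRUE)
  if (!igraph::is_dag(g)) {
    stop_format("hierarchy contains a cycle; hyperonym relations must be acyclic")
  }
  nodes <- igraph::V(g)$name
  missing <- setdiff(leaf_labels, nodes)
  if (length(missing) > 0) {
    stop_missing(paste0("leaf label(s) not present in the hierarchy: ",
                        paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(leaf_labels)) stop_format("leaf labels must be unique")
  if (length(leaf_labels) == 0) stop_format("at least one leaf label is required")

  roots <- nodes[igraph::degree(g, mode = "out") == 0]
  # every leaf must reach a root; in a finite DAG every node reaches some sink,
  # so this holds by construction, but we keep the roots for path enumeration
  structure(
    list(graph = g, nodes = nodes, roots = roots, leaf_labels = leaf_labels),
    class = "synset_graph"
  )
}

#' @export
print.synset_graph <- function(x, ...) {
  cat(sprintf("<synset_graph> %d nodes, %d edges, K = %d leaf labels, root(s): %s\n",
              length(x$nodes), igraph::ecount(x$graph), length(x$leaf_labels),
              paste(x$roots, collapse = ", ")))
  invisible(x)
}

#' Number of leaf labels
#' @param graph a `synset_graph`.
#' @return integer K.
#' @export
n_labels <- function(graph) length(graph$leaf_labels)

#' Load a hierarchy from an edge-list file
#'
#' The file format is two whitespace-separated columns, `hyponym hypernym`,
#' one edge per line; `#` starts a comment. Leaf labels may be given as a
#' character vector or as the path of a file with one label per line (order
#' fixes the class index).
#'
#' @param edge_file path to the edge-list file, or a character vector of its
#'   lines.
#' @param leaf_labels character vector of leaf names, or path to a one-name-
#'   per-line file.
#' @return a [synset_graph()].
#' @export
load_hierarchy <- function(edge_file, leaf_labels) {
  lines <- if (length(edge_file) == 1 && file.exists(edge_file)) {
    readLines(edge_file)
  } else {
    as.character(edge_file)
  }
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop_format("edge list is empty")
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- vapply(parts, length, integer(1)) != 2
  if (any(bad)) {
    stop_format(paste0("malformed edge line(s): ",
                       paste(lines[bad][seq_len(min(3, sum(bad)))], collapse = "; ")))
  }
  edges <- data.frame(
    hyponym = vapply(parts, `[`, character(1), 1),
    hypernym = vapply(parts, `[`, character(1), 2),
    stringsAsFactors = FALSE
  )
  if (length(leaf_labels) == 1 && file.exists(leaf_labels)) {
    leaf_labels <- trimws(readLines(leaf_labels))
    leaf_labels <- leaf_labels[nzchar(leaf_labels)]
  }
  synset_graph(edges, leaf_labels)
}

check_node <- function(graph, node) {
  if (!(node %in% graph$nodes)) {
    stop_missing(paste0("unknown synset: '", node, "'"))
  }
  invisible(node)
}

#' Enumerate hyperonym paths of a leaf label
#'
#' Returns every maximal walk from `label` up the hyponym-to-hypernym edges to
#' a root, each path once. With multiple hypernyms (the graph is a DAG, not a
#' tree) a leaf can have several paths.
#'
#' @param graph a `synset_graph`.
#' @param label a leaf label of `graph`.
#' @return a list of character vectors, each from `label` to a root.
#' @export
hyperonym_paths <- function(graph, label) {
  check_node(graph, label)
  if (!(label %in% graph$leaf_labels)) {
    stop_usage(paste0("'", label, "' is not a leaf label of the hierarchy"))
  }
  paths <- list()
  for (r in graph$roots) {
    if (label == r) {
      paths <- c(paths, list(label))
      next
    }
    ps <- igraph::all_simple_paths(graph$graph, from = label, to = r, mode = "out")
    paths <- c(paths, lapply(ps, function(p) igraph::V(graph$graph)$name[p]))
  }
  unique(paths)
}

#' Leaf labels subsumed by a synset
#'
#' The leaf labels whose hyperonym path contains `synset` — i.e. the labels
#' that are "a kind of" the synset. Their complement within the leaf set is
#' the distractor label pool for a task built on `synset`. A leaf is a
#' descendant of itself.
#'
#' @param graph a `synset_graph`.
#' @param synset a node of `graph`.
#' @return character vector of leaf labels, in leaf index order.
#' @export
descendant_labels <- function(graph, synset) {
  check_node(graph, synset)
  reach <- igraph::subcomponent(graph$graph, synset, mode = "in")
  reach <- igraph::V(graph$graph)$name[reach]
  graph$leaf_labels[graph$leaf_labels %in% reach]
}
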