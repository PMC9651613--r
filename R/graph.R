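#' Construct a DNA-protein interaction graph
#'
#' An interaction graph is a homogeneous undirected graph whose vertices are
#' DNA sequences and proteins (distinguished by a class label, not by
#' relation type) and whose edges are experimentally supported bindings.
#' There is a single relation type; binding is symmetric, so edges are stored
#' undirected and traversed in both directions by the path engines.
#'
#' @param nodes Character vector of unique node identifiers.
#' @param node_class Character vector parallel to `nodes` with values
#'   `"DNA"` or `"PROTEIN"`.
#' @param edges A two-column matrix or data.frame of node identifiers (or a
#'   zero-row object for an edgeless graph). Self-loops and duplicate edges
#'   are rejected.
#' @return An object of class `interaction_graph` with components `nodes`
#'   (character), `class` (character, parallel to nodes), and `edges`
#'   (integer matrix, one row per undirected edge, columns are node indices
#'   with the smaller index first).
#' @examples
#' g <- interaction_graph(c("d1", "d2", "p1"), c("DNA", "DNA", "PROTEIN"),
#'                        rbind(c("d1", "p1"), c("d2", "p1")))
#' n_edges(g)
#' @export
interaction_graph <- function(nodes, node_class, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node ids: ",
    paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  node_class <- as.character(node_class)
  if (length(node_class) != length(nodes))
    stop("node_class must be given for every node")
  bad <- !node_class %in% c("DNA", "PROTEIN")
  if (any(bad)) stop("node classes must be 'DNA' or 'PROTEIN', got: ",
    paste(unique(node_class[bad]), collapse = ", "))

  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("edges must have two columns")
    if (is.character(edges)) {
      i <- match(edges[, 1L], nodes)
      j <- match(edges[, 2L], nodes)
      if (anyNA(i) || anyNA(j))
        stop("edge endpoint not among nodes: ",
             paste(unique(c(edges[, 1L][is.na(i)], edges[, 2L][is.na(j)])),
                   collapse = ", "))
    } else {
      i <- as.integer(edges[, 1L]); j <- as.integer(edges[, 2L])
      if (any(i < 1L | i > length(nodes) | j < 1L | j > length(nodes)))
        stop("edge endpoint index out of range")
    }
    if (any(i == j)) stop("self-loops are not allowed")
    em <- cbind(pmin(i, j), pmax(i, j))
    key <- (em[, 1L] - 1) * length(nodes) + em[, 2L]
    if (anyDuplicated(key)) stop("duplicate edges are not allowed")
    em <- em[order(key), , drop = FALSE]
  }
  structure(list(nodes = nodes, class = node_class, edges = em),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat("Interaction graph: ", length(x$nodes), " nodes (",
      sum(x$class == "DNA"), " DNA, ", sum(x$class == "PROTEIN"),
      " protein), ", nrow(x$edges), " binding edges\n", sep = "")
  invisible(x)
}

#' Number of nodes / edges of an interaction graph
#' @param graph An `interaction_graph`.
#' @return Integer count.
#' @export
n_nodes <- function(graph) length(graph$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(graph) nrow(graph$edges)

# resolve node ids to internal dense indices (stable within a run)
node_index <- function(graph, ids) {
  idx <- match(as.character(ids), graph$nodes)
  if (anyNA(idx))
    stop("unknown node id: ", paste(unique(ids[is.na(idx)]), collapse = ", "))
  idx
}

#' Incident edges and neighbors of a node
#'
#' Returns the set of edges incident to `u` together with the opposite
#' endpoints, i.e. E(u) and N(u).
#'
#' @param graph An `interaction_graph`.
#' @param u A node identifier.
#' @return A data.frame with columns `edge` (row index into `graph$edges`)
#'   and `neighbor` (node id). Zero rows for an isolated node.
#' @export
neighbors <- function(graph, u) {
  ui <- node_index(graph, u)
  if (length(ui) != 1L) stop("u must be a single node id")
  hit1 <- graph$edges[, 1L] == ui
  hit2 <- graph$edges[, 2L] == ui
  edge <- c(which(hit1), which(hit2))
  nb <- c(graph$edges[hit1, 2L], graph$edges[hit2, 1L])
  ord <- order(edge)
  data.frame(edge = edge[ord], neighbor = graph$nodes[nb[ord]],
             stringsAsFactors = FALSE)
}

# "i|j" keys (i < j, internal indices) for fast membership tests
edge_keys <- function(graph) {
  if (nrow(graph$edges) == 0L) return(character(0))
  paste(graph$edges[, 1L], graph$edges[, 2L], sep = "|")
}

pair_keys <- function(graph, u, v) {
  ui <- node_index(graph, u); vi <- node_index(graph, v)
  paste(pmin(ui, vi), pmax(ui, vi), sep = "|")
}

#' Read an edge-list TSV of DNA-protein interactions
#'
#' The file must be tab-separated with header
#' `node_a  class_a  node_b  class_b  label`; classes are `DNA`/`PROTEIN`
#' and labels 0/1. Rows with label 1 become graph edges; every row becomes a
#' link example (labelled pair), so the file carries both the observed graph
#' and the positive/negative training samples.
#'
#' @param path Path to the TSV file.
#' @param on_duplicate What to do when two label-1 rows name the same pair:
#'   `"error"` (default) or `"dedup"` (keep a single edge).
#' @return A list with components `graph` (an [interaction_graph()]) and
#'   `examples` (data.frame with columns `u`, `v`, `label`).
#' @export
read_edge_tsv <- function(path, on_duplicate = c("error", "dedup")) {
  on_duplicate <- match.arg(on_duplicate)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          check.names = TRUE)
  need <- c("node_a", "class_a", "node_b", "class_b", "label")
  if (!all(need %in% names(df)))
    stop("edge TSV must have columns: ", paste(need, collapse = ", "))
  lab <- suppressWarnings(as.integer(df$label))
  for (i in seq_len(nrow(df))) {   # line numbers: +1 for the header
    line <- i + 1L
    if (is.na(lab[i]) || !lab[i] %in% c(0L, 1L))
      stop(sprintf("line %d: label must be 0 or 1, got '%s'", line, df$label[i]))
    if (!df$class_a[i] %in% c("DNA", "PROTEIN") ||
        !df$class_b[i] %in% c("DNA", "PROTEIN"))
      stop(sprintf("line %d: classes must be DNA or PROTEIN", line))
    if (df$node_a[i] == df$node_b[i])
      stop(sprintf("line %d: self-loop row (%s)", line, df$node_a[i]))
  }
  ids <- c(rbind(df$node_a, df$node_b))     # first-appearance order
  cls <- c(rbind(df$class_a, df$class_b))
  keep <- !duplicated(ids)
  nodes <- ids[keep]; node_class <- cls[keep]
  conflict <- tapply(cls, ids, function(z) length(unique(z)) > 1L)
  if (any(conflict))
    stop("node with conflicting classes: ",
         paste(names(conflict)[conflict], collapse = ", "))

  pos <- lab == 1L
  epairs <- cbind(df$node_a[pos], df$node_b[pos])
  if (nrow(epairs) > 0L) {
    i <- match(epairs[, 1L], nodes); j <- match(epairs[, 2L], nodes)
    key <- paste(pmin(i, j), pmax(i, j), sep = "|")
    if (anyDuplicated(key)) {
      if (on_duplicate == "error")
        stop("duplicate edge rows (set on_duplicate='dedup' to collapse): ",
             paste(unique(key[duplicated(key)]), collapse = ", "))
      epairs <- epairs[!duplicated(key), , drop = FALSE]
    }
  }
  graph <- interaction_graph(nodes, node_class, epairs)
  examples <- data.frame(u = df$node_a, v = df$node_b, label = lab,
                         stringsAsFactors = FALSE)
  list(graph = graph, examples = examples)
}

#' Write an edge-list TSV
#'
#' Inverse of [read_edge_tsv()]: writes one row per link example with node
#' classes taken from the graph.
#'
#' @param graph An `interaction_graph`.
#' @param examples Data.frame with columns `u`, `v`, `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_tsv <- function(graph, examples, path) {
  ci <- graph$class[node_index(graph, examples$u)]
  cj <- graph$class[node_index(graph, examples$v)]
  out <- data.frame(node_a = examples$u, class_a = ci,
                    node_b = examples$v, class_b = cj,
                    label = as.integer(examples$label))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Corrupt one entity of a positive pair to build a negative sample
#'
#' Negative examples are generated by replacing exactly one endpoint of a
#' known positive pair with another node of the same class, chosen uniformly
#' among replacements that do not produce a known positive pair. The side to
#' corrupt (DNA vs protein endpoint) is chosen by a fair coin; if the chosen
#' side has no admissible replacement the other side is used.
#'
#' @param graph An `interaction_graph`.
#' @param u,v Endpoints of the positive pair.
#' @param forbidden Character vector of internal `"i|j"` pair keys that must
#'   not be emitted; defaults to the graph's edge set. Pass the full
#'   positive set (e.g. including held-out positives) to avoid sampling
#'   them as negatives.
#' @return A one-row data.frame `u`, `v`, `label = 0` with exactly one
#'   endpoint replaced.
#' @export
corrupt_negative <- function(graph, u, v, forbidden = NULL) {
  if (is.null(forbidden)) forbidden <- edge_keys(graph)
  ui <- node_index(graph, u); vi <- node_index(graph, v)
  if (ui == vi) stop("positive pair must have distinct endpoints")

  candidates_for <- function(fix_i, rep_i) {
    cand <- which(graph$class == graph$class[rep_i])
    cand <- cand[cand != rep_i & cand != fix_i]
    if (length(cand) == 0L) return(integer(0))
    key <- paste(pmin(fix_i, cand), pmax(fix_i, cand), sep = "|")
    cand[!key %in% forbidden]
  }
  side_first <- if (stats::runif(1) < 0.5) 1L else 2L
  for (side in c(side_first, 3L - side_first)) {
    fix <- if (side == 1L) vi else ui    # side 1 corrupts u, keeps v
    rep_ <- if (side == 1L) ui else vi
    cand <- candidates_for(fix, rep_)
    if (length(cand) > 0L) {
      pick <- cand[sample.int(length(cand), 1L)]
      uu <- if (side == 1L) graph$nodes[pick] else u
      vv <- if (side == 1L) v else graph$nodes[pick]
      return(data.frame(u = uu, v = vv, label = 0L, stringsAsFactors = FALSE))
    }
  }
  stop("corruption exhausted: every same-class replacement of either ",
       "endpoint yields a known positive pair")
}

#' Stratified k-fold split of link examples
#'
#' Splits labelled pairs into k folds for cross-validation, stratified by
#' label so that each test fold holds the same positive/negative balance
#' within one example. Splits operate on examples (links), not nodes: the
#' setting is transductive. Callers must remove each fold's test-positive
#' edges from the message-passing graph before training (see
#' [remove_edges()] and [cross_validate()]).
#'
#' @param examples Data.frame with columns `u`, `v`, `label`.
#' @param k Number of folds (>= 2).
#' @return A list of k splits, each a list with `train`, `test` (data.frames)
#'   and `fold_index`.
#' @export
kfold_split <- function(examples, k) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  n <- nrow(examples)
  if (k > n) stop("k exceeds the number of examples")
  fold <- integer(n)
  for (lab in unique(examples$label)) {
    idx <- which(examples$label == lab)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(i) {
    list(train = examples[fold != i, , drop = FALSE],
         test = examples[fold == i, , drop = FALSE],
         fold_index = i)
  })
}

#' Remove edges from an interaction graph
#'
#' Used to drop test-fold positive edges from the message-passing graph so a
#' model never sees the links it is asked to predict.
#'
#' @param graph An `interaction_graph`.
#' @param pairs Data.frame with columns `u`, `v` (order irrelevant).
#' @return A new `interaction_graph` on the same node set.
#' @export
remove_edges <- function(graph, pairs) {
  if (NROW(pairs) == 0L) return(graph)
  drop <- pair_keys(graph, pairs$u, pairs$v)
  keep <- !(edge_keys(graph) %in% drop)
  interaction_graph(graph$nodes, graph$class,
                    graph$edges[keep, , drop = FALSE])
}
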