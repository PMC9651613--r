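#' Define a semiring for the generalized Bellman-Ford engine
#'
#' A semiring supplies a commutative aggregation operator `plus` with
#' identity `zero` and a multiplication operator `times` with identity `one`,
#' with `times` distributing over `plus`. Different choices recover the
#' classical path-based link-prediction scores: sum-product gives Katz-style
#' walk sums, min-plus gives graph distance, max-min the widest path,
#' max-product the most reliable path.
#'
#' `times` is not required to be commutative (the engine multiplies edge
#' values in walk order), though all built-in instantiations are.
#'
#' @param plus,times Binary functions of two scalars.
#' @param zero,one The identities of `plus` and `times`.
#' @param name Label used in printing.
#' @return An object of class `semiring`.
#' @examples
#' sr <- semiring(`+`, `*`, 0, 1, "sum-product")
#' sr$plus(2, 3)
#' @export
semiring <- function(plus, times, zero, one, name = "custom") {
  stopifnot(is.function(plus), is.function(times))
  structure(list(plus = plus, times = times, zero = zero, one = one,
                 name = name), class = "semiring")
}

#' @export
print.semiring <- function(x, ...) {
  cat("Semiring <", x$name, ">: zero = ", format(x$zero),
      ", one = ", format(x$one), "\n", sep = "")
  invisible(x)
}

#' Built-in semirings
#'
#' `sr_sum_product()` (walk counting / Katz / PageRank), `sr_min_plus()`
#' (graph distance), `sr_max_min()` (widest path), `sr_max_product()`
#' (most reliable path).
#' @return A [semiring()].
#' @export
sr_sum_product <- function() semiring(`+`, `*`, 0, 1, "sum-product")

#' @rdname sr_sum_product
#' @export
sr_min_plus <- function() semiring(min, `+`, Inf, 0, "min-plus")

#' @rdname sr_sum_product
#' @export
sr_max_min <- function() semiring(max, min, -Inf, Inf, "max-min")

#' @rdname sr_sum_product
#' @export
sr_max_product <- function() semiring(max, `*`, 0, 1, "max-product")

# Directed arc expansion of an undirected graph: arcs 1..nE run edges[,1] ->
# edges[,2], arcs nE+1..2nE the reverse. Edge values of length nE are
# recycled over both directions; length 2nE gives per-arc values.
arc_values <- function(graph, edge_values) {
  nE <- nrow(graph$edges)
  if (length(edge_values) == 1L) edge_values <- rep(edge_values, nE)
  if (length(edge_values) == nE) return(rep(edge_values, 2L))
  if (length(edge_values) == 2L * nE) return(edge_values)
  stop("edge_values must have length 1, n_edges, or 2*n_edges")
}

arc_ends <- function(graph) {
  cbind(c(graph$edges[, 1L], graph$edges[, 2L]),
        c(graph$edges[, 2L], graph$edges[, 1L]))
}

#' Generalized Bellman-Ford over a semiring
#'
#' Computes, for a fixed source u and every node v, the semiring aggregation
#' over all walks u to v of length at most `iterations` of the
#' `times`-product of edge values along the walk. The boundary condition sets
#' h0(u,v) to the `times`-identity iff v = u and the `plus`-identity
#' otherwise; each iteration aggregates incoming messages
#' h(x) times w(x,v) over the incident edges of v and re-adds the boundary
#' term, exploiting distributivity so the cost is linear in the edge count
#' per iteration rather than exponential in walk length.
#'
#' @param graph An `interaction_graph`.
#' @param source Source node id.
#' @param sr A [semiring()].
#' @param edge_values Numeric: a scalar, one value per undirected edge, or
#'   one per directed arc (length `2 * n_edges(graph)`, forward direction
#'   first).
#' @param iterations Number of Bellman-Ford iterations T >= 0 (walks of
#'   length at most T are aggregated).
#' @return An object of class `path_score_vector`: list with `source`,
#'   `values` (named numeric over all nodes), `iteration`.
#' @examples
#' g <- interaction_graph(c("a", "b", "c"), c("DNA", "PROTEIN", "DNA"),
#'                        rbind(c("a", "b"), c("b", "c")))
#' generalized_bellman_ford(g, "a", sr_sum_product(), 0.5, 2)
#' @export
generalized_bellman_ford <- function(graph, source, sr, edge_values,
                                     iterations) {
  if (!inherits(sr, "semiring")) stop("sr must be a semiring")
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 0L)
    stop("iterations must be a nonnegative integer")
  if (anyNA(edge_values)) stop("missing edge value")
  w <- arc_values(graph, edge_values)
  ends <- arc_ends(graph)
  V <- n_nodes(graph)
  si <- node_index(graph, source)
  by_dst <- split(seq_len(nrow(ends)), factor(ends[, 2L], levels = seq_len(V)))

  h0 <- rep(sr$zero, V); h0[si] <- sr$one
  h <- h0
  t <- 0L
  while (t < iterations) {
    hn <- h0
    for (v in seq_len(V)) {
      acc <- h0[v]
      for (a in by_dst[[v]]) {
        acc <- sr$plus(acc, sr$times(h[ends[a, 1L]], w[a]))
      }
      hn[v] <- acc
    }
    h <- hn
    t <- t + 1L
  }
  structure(list(source = graph$nodes[si],
                 values = stats::setNames(h, graph$nodes),
                 iteration = iterations),
            class = "path_score_vector")
}

#' @export
print.path_score_vector <- function(x, ...) {
  cat("Path scores from '", x$source, "' after ", x$iteration,
      " iterations:\n", sep = "")
  print(x$values, ...)
  invisible(x)
}

#' Brute-force walk enumeration oracle
#'
#' Explicitly enumerates every walk from `u` to `v` of length at most
#' `max_len`, multiplies the edge values along each walk with the semiring's
#' `times`, and aggregates across walks with `plus`. Exponential in
#' `max_len`; refuses `max_len > 8`. This is the independent reference the
#' Bellman-Ford recursion is checked against: the two must agree at
#' `iterations = max_len`.
#'
#' The empty walk (length 0) contributes the `times`-identity when `u == v`,
#' matching the Bellman-Ford boundary condition.
#'
#' @inheritParams generalized_bellman_ford
#' @param u,v Source and target node ids.
#' @param max_len Maximum walk length (0..8).
#' @return A scalar path score.
#' @export
enumerate_path_score <- function(graph, u, v, sr, edge_values, max_len) {
  max_len <- as.integer(max_len)
  if (is.na(max_len) || max_len < 0L) stop("max_len must be nonnegative")
  if (max_len > 8L)
    stop("max_len capped at 8: walk enumeration is exponential")
  w <- arc_values(graph, edge_values)
  ends <- arc_ends(graph)
  V <- n_nodes(graph)
  ui <- node_index(graph, u); vi <- node_index(graph, v)
  by_src <- split(seq_len(nrow(ends)), factor(ends[, 1L], levels = seq_len(V)))

  total <- sr$zero
  recurse <- function(node, len, prod) {
    if (node == vi) total <<- sr$plus(total, prod)
    if (len == max_len) return(invisible(NULL))
    for (a in by_src[[node]]) {
      recurse(ends[a, 2L], len + 1L, sr$times(prod, w[a]))
    }
    invisible(NULL)
  }
  recurse(ui, 0L, sr$one)
  total
}

#' Classical path-based link-prediction scores
#'
#' Dispatches the generalized Bellman-Ford engine with the semiring and
#' edge-value transform of a classical method:
#' \describe{
#'   \item{katz}{sum-product semiring with uniform edge value `beta`
#'     (truncated Katz index; converges to the resolvent series when
#'     `beta` is below the inverse spectral radius).}
#'   \item{graph_distance}{min-plus semiring over edge lengths
#'     (default 1).}
#'   \item{widest_path}{max-min semiring over edge capacities.}
#'   \item{most_reliable_path}{max-product semiring over edge
#'     probabilities in \[0, 1\].}
#'   \item{personalized_pagerank}{damped degree-normalized sum-product
#'     iteration: arc value `damping / degree(x)` for arc x -> v, with the
#'     final vector scaled by `1 - damping` so that the truncated series
#'     equals `(1-damping) * sum_t damping^t (D^-1 A)^t` applied to the
#'     source indicator.}
#' }
#'
#' @inheritParams generalized_bellman_ford
#' @param method One of `"katz"`, `"personalized_pagerank"`,
#'   `"graph_distance"`, `"widest_path"`, `"most_reliable_path"`.
#' @param beta Katz damping factor.
#' @param damping PageRank damping (restart probability is `1 - damping`).
#' @param edge_values Edge lengths/capacities/probabilities where the method
#'   uses them; ignored by katz and personalized PageRank.
#' @return A `path_score_vector`.
#' @export
classic_link_score <- function(graph, method = c("katz",
                               "personalized_pagerank", "graph_distance",
                               "widest_path", "most_reliable_path"),
                               source, iterations,
                               beta = 0.1, damping = 0.85,
                               edge_values = NULL) {
  method <- match.arg(method)
  V <- n_nodes(graph)
  deg <- tabulate(c(graph$edges[, 1L], graph$edges[, 2L]), V)
  switch(method,
    katz = {
      if (beta <= 0) stop("beta must be positive")
      if (length(deg) > 0L && beta * max(deg) >= 1)
        warning("beta * max degree >= 1: truncated Katz may not converge")
      generalized_bellman_ford(graph, source, sr_sum_product(), beta,
                               iterations)
    },
    graph_distance = {
      ev <- if (is.null(edge_values)) 1 else edge_values
      generalized_bellman_ford(graph, source, sr_min_plus(), ev, iterations)
    },
    widest_path = {
      if (is.null(edge_values)) stop("widest_path needs edge capacities")
      generalized_bellman_ford(graph, source, sr_max_min(), edge_values,
                               iterations)
    },
    most_reliable_path = {
      if (is.null(edge_values)) stop("most_reliable_path needs edge probabilities")
      ev <- arc_values(graph, edge_values)
      if (any(ev < 0 | ev > 1))
        stop("most_reliable_path requires edge values in [0, 1]")
      generalized_bellman_ford(graph, source, sr_max_product(), edge_values,
                               iterations)
    },
    personalized_pagerank = {
      if (damping <= 0 || damping >= 1) stop("damping must be in (0, 1)")
      nE <- nrow(graph$edges)
      # per-arc value damping / deg(src); arcs are forward then reverse
      src <- c(graph$edges[, 1L], graph$edges[, 2L])
      ev <- damping / pmax(deg[src], 1)
      res <- generalized_bellman_ford(graph, source, sr_sum_product(), ev,
                                      iterations)
      res$values <- res$values * (1 - damping)
      res
    })
}
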