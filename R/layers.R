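# Neural parametrization of the generalized Bellman-Ford iteration.
#
# The boundary condition becomes a learned indicator (query embedding at the
# source row), the edge-value product becomes a message function (DistMult /
# TransE / RotatE against a learned per-layer edge representation), and the
# semiring aggregation becomes sum / mean / max over incoming messages plus
# the boundary term, followed by a learned linear mixing. All forward passes
# have matching hand-written backward passes (no autodiff is available);
# these are validated against finite differences in the test suite.

# Precomputed arc traversal structure for a graph. Arcs are the directed
# expansion of undirected edges (forward rows first). `cls` indexes the
# relation variant per arc: a single shared variant by default, or one per
# ordered endpoint-class pair when edge representations are class-specialized.
arc_workspace <- function(graph, edge_by_class = FALSE) {
  V <- n_nodes(graph)
  src <- c(graph$edges[, 1L], graph$edges[, 2L])
  dst <- c(graph$edges[, 2L], graph$edges[, 1L])
  n_arc <- length(src)
  if (edge_by_class && n_arc > 0L) {
    lab <- paste(graph$class[src], graph$class[dst], sep = ">")
    levs <- sort(unique(lab))
    cls <- match(lab, levs)
  } else {
    levs <- "all"
    cls <- rep(1L, n_arc)
  }
  list(V = V, src = src, dst = dst, n_arc = n_arc,
       cnt = tabulate(dst, V),
       by_dst = split(seq_len(n_arc), factor(dst, levels = seq_len(V))),
       cls = cls, cls_levels = levs)
}

# rowsum() scattered back to a fixed number of rows
scatter_rowsum <- function(M, group, V) {
  out <- matrix(0, V, ncol(M))
  if (nrow(M) == 0L) return(out)
  rs <- rowsum(M, group)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# per-arc messages; H is V x d, returns n_arc x d
msg_forward <- function(H, w_cls, aw, kind) {
  Hm <- H[aw$src, , drop = FALSE]
  Wa <- w_cls[aw$cls, , drop = FALSE]
  switch(kind,
    distmult = Hm * Wa,
    transe = Hm + Wa,
    rotate = {
      d <- ncol(H)
      odd <- seq(1L, d, by = 2L); even <- odd + 1L
      a <- Hm[, odd, drop = FALSE]; b <- Hm[, even, drop = FALSE]
      ca <- cos(Wa); sa <- sin(Wa)
      M <- matrix(0, nrow(Hm), d)
      M[, odd] <- a * ca - b * sa
      M[, even] <- a * sa + b * ca
      M
    },
    stop("unknown message kind: ", kind))
}

# gradients of messages wrt node states and edge representation
msg_backward <- function(dM, H, w_cls, aw, kind) {
  Hm <- H[aw$src, , drop = FALSE]
  Wa <- w_cls[aw$cls, , drop = FALSE]
  switch(kind,
    distmult = {
      dHm <- dM * Wa
      dw <- scatter_rowsum(dM * Hm, aw$cls, nrow(w_cls))
      list(dH = scatter_rowsum(dHm, aw$src, aw$V), dw = dw)
    },
    transe = {
      dw <- scatter_rowsum(dM, aw$cls, nrow(w_cls))
      list(dH = scatter_rowsum(dM, aw$src, aw$V), dw = dw)
    },
    rotate = {
      d <- ncol(H)
      odd <- seq(1L, d, by = 2L); even <- odd + 1L
      a <- Hm[, odd, drop = FALSE]; b <- Hm[, even, drop = FALSE]
      ca <- cos(Wa); sa <- sin(Wa)
      dMo <- dM[, odd, drop = FALSE]; dMe <- dM[, even, drop = FALSE]
      dHm <- matrix(0, nrow(Hm), d)
      dHm[, odd] <- dMo * ca + dMe * sa
      dHm[, even] <- -dMo * sa + dMe * ca
      dTheta <- dMo * (-a * sa - b * ca) + dMe * (a * ca - b * sa)
      list(dH = scatter_rowsum(dHm, aw$src, aw$V),
           dw = scatter_rowsum(dTheta, aw$cls, nrow(w_cls)))
    },
    stop("unknown message kind: ", kind))
}

# aggregate messages with the boundary term (the union in the iteration is
# realized as one extra element per node): returns V x d plus argmax cache
# for max aggregation (0 = boundary won)
agg_forward <- function(M, H0, aw, kind) {
  V <- aw$V; d <- ncol(H0)
  switch(kind,
    sum = list(S = scatter_rowsum(M, aw$dst, V) + H0, amax = NULL),
    mean = list(S = (scatter_rowsum(M, aw$dst, V) + H0) / (aw$cnt + 1),
                amax = NULL),
    max = {
      S <- H0
      amax <- matrix(0L, V, d)
      for (v in seq_len(V)) {
        arcs <- aw$by_dst[[v]]
        if (length(arcs) == 0L) next
        cand <- rbind(H0[v, ], M[arcs, , drop = FALSE])
        pick <- apply(cand, 2L, which.max)
        S[v, ] <- cand[cbind(pick, seq_len(d))]
        amax[v, ] <- ifelse(pick == 1L, 0L, arcs[pick - 1L])
      }
      list(S = S, amax = amax)
    },
    stop("unknown aggregate kind: ", kind))
}

agg_backward <- function(dS, aw, kind, amax, n_arc_rows) {
  V <- aw$V; d <- ncol(dS)
  switch(kind,
    sum = list(dM = dS[aw$dst, , drop = FALSE], dH0 = dS),
    mean = {
      sc <- dS / (aw$cnt + 1)
      list(dM = sc[aw$dst, , drop = FALSE], dH0 = sc)
    },
    max = {
      dM <- matrix(0, n_arc_rows, d)
      dH0 <- matrix(0, V, d)
      for (v in seq_len(V)) {
        for (j in seq_len(d)) {
          a <- amax[v, j]
          if (a == 0L) dH0[v, j] <- dH0[v, j] + dS[v, j]
          else dM[a, j] <- dM[a, j] + dS[v, j]
        }
      }
      list(dM = dM, dH0 = dH0)
    },
    stop("unknown aggregate kind: ", kind))
}

# one NBFnet layer: aggregate(message(...)) followed by learned linear mixing
layer_forward <- function(H, H0, lay, aw, kinds) {
  M <- msg_forward(H, lay$w, aw, kinds$message)
  ag <- agg_forward(M, H0, aw, kinds$aggregate)
  list(H_out = ag$S %*% lay$W + matrix(lay$b, aw$V, length(lay$b),
                                       byrow = TRUE),
       cache = list(H_in = H, S = ag$S, amax = ag$amax))
}

layer_backward <- function(dH_out, cache, lay, aw, kinds) {
  dS <- dH_out %*% t(lay$W)
  dW <- t(cache$S) %*% dH_out
  db <- colSums(dH_out)
  ab <- agg_backward(dS, aw, kinds$aggregate, cache$amax, aw$n_arc)
  mb <- msg_backward(ab$dM, cache$H_in, lay$w, aw, kinds$message)
  list(dH_in = mb$dH, dH0 = ab$dH0, dw = mb$dw, dW = dW, db = db)
}

#' Indicator function: source-conditioned boundary state
#'
#' The neural analogue of the Bellman-Ford boundary condition: the source
#' row receives the learned query embedding, every other row the zero
#' vector.
#'
#' @param graph An `interaction_graph`.
#' @param u Source node id.
#' @param q Numeric query embedding of length d.
#' @return An object of class `pair_state`: list with `source`, `states`
#'   (|V| x d matrix with node-id rownames), `layer = 0`.
#' @export
indicator <- function(graph, u, q) {
  ui <- node_index(graph, u)
  H <- matrix(0, n_nodes(graph), length(q),
              dimnames = list(graph$nodes, NULL))
  H[ui, ] <- q
  structure(list(source = graph$nodes[ui], states = H, layer = 0L),
            class = "pair_state")
}

#' @export
print.pair_state <- function(x, ...) {
  cat("Pair state from '", x$source, "' at layer ", x$layer, ": ",
      nrow(x$states), " nodes x ", ncol(x$states), " dims\n", sep = "")
  invisible(x)
}

#' Message function between a node state and an edge representation
#'
#' `distmult` is the elementwise product, `transe` the translation `h + w`,
#' `rotate` treats consecutive coordinate pairs of `h` as complex numbers
#' and rotates each by a phase angle; for `rotate`, `w` holds the d/2 phase
#' angles (unit modulus by construction) and d must be even.
#'
#' @param h Node state vector (length d).
#' @param w Edge representation (length d, or d/2 angles for `rotate`).
#' @param kind `"distmult"`, `"transe"` or `"rotate"`.
#' @return Message vector of length d.
#' @examples
#' nbf_message(c(1, 2), c(3, 4), "distmult")  # c(3, 8)
#' nbf_message(c(1, 0), pi / 2, "rotate")     # quarter turn -> c(0, 1)
#' @export
nbf_message <- function(h, w, kind = c("distmult", "transe", "rotate")) {
  kind <- match.arg(kind)
  d <- length(h)
  if (kind == "rotate") {
    if (d %% 2L != 0L) stop("rotate requires an even state dimension")
    if (length(w) != d / 2L)
      stop("rotate takes d/2 phase angles as the edge representation")
  } else if (length(w) != d) {
    stop("state and edge representation dimensions differ")
  }
  H <- matrix(h, nrow = 1L)
  aw <- list(src = 1L, dst = 1L, n_arc = 1L, V = 1L, cls = 1L)
  drop(msg_forward(H, matrix(w, nrow = 1L), aw, kind))
}

#' Aggregate messages with the boundary term
#'
#' Reduces the multiset of incoming messages together with the node's
#' boundary state (the union term of the Bellman-Ford iteration) by sum,
#' mean, or coordinatewise max. With no incident edges the boundary vector
#' is returned unchanged.
#'
#' @param messages A list of message vectors, or a matrix with one message
#'   per row; may be empty.
#' @param boundary The node's boundary state h0(v) (length d).
#' @param kind `"sum"`, `"mean"` or `"max"`.
#' @return Aggregated vector of length d.
#' @export
nbf_aggregate <- function(messages, boundary, kind = c("sum", "mean", "max")) {
  kind <- match.arg(kind)
  if (missing(boundary) || is.null(boundary))
    stop("boundary state is required (the aggregation union includes h0)")
  if (is.list(messages)) {
    messages <- if (length(messages) == 0L)
      matrix(numeric(0), 0L, length(boundary))
    else do.call(rbind, messages)
  }
  if (NCOL(messages) != length(boundary) && nrow(messages) > 0L)
    stop("message dimension does not match the boundary state")
  stack <- rbind(messages, boundary)
  switch(kind,
    sum = colSums(stack),
    mean = colMeans(stack),
    max = apply(stack, 2L, max))
}

#' NBFnet forward pass
#'
#' Runs T neural Bellman-Ford layers from the source `u`: the indicator
#' initializes the state, each layer sends messages along every (directed)
#' edge against that layer's learned edge representation, aggregates them
#' with the boundary term, and applies a learned linear transform. With
#' d = 1, DistMult messages, sum aggregation, identity linear transforms and
#' fixed scalar edge representations this reproduces the sum-product
#' semiring engine exactly.
#'
#' @param graph An `interaction_graph`.
#' @param u Source node id.
#' @param params List with `q` (query embedding, length d) and `layers`, a
#'   list of per-layer parameter lists `w` (edge representation matrix,
#'   one row per relation variant), `W` (d x d), `b` (length d).
#' @param message,aggregate Kinds, see [nbf_message()] and
#'   [nbf_aggregate()].
#' @param edge_by_class Specialize edge representations by ordered
#'   endpoint-class pair instead of sharing one per layer.
#' @return A list of `pair_state` objects for t = 0..T.
#' @export
nbfnet_forward <- function(graph, u, params,
                           message = c("distmult", "transe", "rotate"),
                           aggregate = c("sum", "mean", "max"),
                           edge_by_class = FALSE) {
  kinds <- list(message = match.arg(message), aggregate = match.arg(aggregate))
  d <- length(params$q)
  if (kinds$message == "rotate" && d %% 2L != 0L)
    stop("rotate requires an even state dimension")
  aw <- arc_workspace(graph, edge_by_class)
  st0 <- indicator(graph, u, params$q)
  H0 <- st0$states
  out <- vector("list", length(params$layers) + 1L)
  out[[1L]] <- st0
  H <- H0
  for (t in seq_along(params$layers)) {
    lay <- params$layers[[t]]
    if (ncol(lay$W) != d || nrow(lay$W) != d)
      stop("layer ", t, ": linear transform dimension mismatch")
    fw <- layer_forward(H, H0, lay, aw, kinds)
    H <- fw$H_out
    rownames(H) <- graph$nodes
    out[[t + 1L]] <- structure(list(source = st0$source, states = H,
                                    layer = t), class = "pair_state")
  }
  out
}
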