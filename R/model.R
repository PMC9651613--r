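# The full architecture: three feature-extraction modules (NBFnet layers +
# leaky ReLU + SortPooling), three AlphaMEX global poolings, an addition
# module, and a fully connected head (256/64/2) with a joint log-softmax.
#
# Graph-level pooling alone would lose the identity of the target node v, so
# the pooling is computed over the enclosing context of the pair (nodes
# within two hops of u or v) and the pooled summary is concatenated with the
# source-conditioned state h(u,v) of the target before the FC stack.

#' Leaky rectified linear unit
#' @param x Numeric input.
#' @param slope Negative-branch slope (default 0.2).
#' @return `x` where positive, `slope * x` elsewhere.
#' @export
leaky_relu <- function(x, slope = 0.2) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  x
}

lrelu_grad <- function(x, slope = 0.2) {
  g <- rep(1, length(x))
  g[x <= 0] <- slope
  if (is.matrix(x)) dim(g) <- dim(x)
  g
}

#' Initialize model parameters
#'
#' Builds the full learnable parameter set: the query embedding, per-layer
#' NBFnet parameters (edge representation, linear mixing, bias) for the
#' three feature modules, the three AlphaMEX sharpness parameters, and the
#' fully connected head with 256, 64 and 2 neurons.
#'
#' Initialization starts the network at the classical path-counting
#' operating point so that the untrained forward pass already behaves like a
#' damped Katz walk count, which gradient descent then refines: linear
#' mixings are identity plus small noise, DistMult edge representations are
#' positive with mean `1 / (mean degree + 1)` (so sum aggregation neither
#' explodes nor vanishes across the default six layers), TransE offsets are
#' small, RotatE phases are small angles, and biases start at zero. The FC
#' head uses Glorot-style scaling.
#'
#' @param d Hidden dimension (default 32; even values required for RotatE).
#' @param K SortPooling output rows (default 10).
#' @param depths Integer vector: NBFnet layers per feature module
#'   (default `c(2, 2, 2)`, six layers total, the saturation depth).
#' @param message,aggregate Message and aggregation kinds.
#' @param edge_by_class Learn one edge representation per ordered
#'   endpoint-class pair instead of a shared one.
#' @param alpha_init Initial AlphaMEX alpha (in (0.5, 1), default 0.9).
#' @param leak Leaky ReLU slope (default 0.2).
#' @param graph Optional `interaction_graph` used to scale the edge
#'   representation initialization by mean degree.
#' @return An object of class `nbf_params`.
#' @export
init_model_params <- function(d = 32L, K = 10L, depths = c(2L, 2L, 2L),
                              message = c("distmult", "transe", "rotate"),
                              aggregate = c("sum", "mean", "max"),
                              edge_by_class = FALSE, alpha_init = 0.9,
                              leak = 0.2, graph = NULL) {
  message <- match.arg(message); aggregate <- match.arg(aggregate)
  d <- as.integer(d)
  if (message == "rotate" && d %% 2L != 0L)
    stop("rotate requires an even hidden dimension")
  n_cls <- 1L
  if (edge_by_class) {
    if (is.null(graph)) stop("edge_by_class requires the graph at init time")
    n_cls <- length(arc_workspace(graph, TRUE)$cls_levels)
  }
  mean_deg <- if (!is.null(graph) && n_edges(graph) > 0L)
    2 * n_edges(graph) / n_nodes(graph) else 3
  w_mu <- 1 / (mean_deg + 1)
  wdim <- if (message == "rotate") d %/% 2L else d
  mk_layer <- function() {
    w <- switch(message,
      distmult = matrix(stats::rnorm(n_cls * wdim, w_mu, w_mu / 2),
                        n_cls, wdim),
      transe = matrix(stats::rnorm(n_cls * wdim, 0, 0.1), n_cls, wdim),
      rotate = matrix(stats::runif(n_cls * wdim, -pi / 4, pi / 4),
                      n_cls, wdim))
    list(w = w,
         W = diag(d) + matrix(stats::rnorm(d * d, 0, 0.1 / sqrt(d)), d, d),
         b = numeric(d))
  }
  fc_dims <- c(2L * d, 256L, 64L, 2L)
  fc <- list()
  for (i in 1:3) {
    nin <- fc_dims[i]; nout <- fc_dims[i + 1L]
    fc[[paste0("W", i)]] <- matrix(stats::rnorm(nin * nout, 0,
                                                sqrt(2 / (nin + nout))),
                                   nin, nout)
    fc[[paste0("b", i)]] <- numeric(nout)
  }
  structure(list(
    q = stats::rnorm(d),
    layers = replicate(sum(depths), mk_layer(), simplify = FALSE),
    thetas = rep(theta_from_alpha(alpha_init), 3L),
    fc = fc,
    meta = list(d = d, K = as.integer(K), depths = as.integer(depths),
                message = message, aggregate = aggregate,
                edge_by_class = edge_by_class, leak = leak,
                n_cls = n_cls)),
    class = "nbf_params")
}

#' @export
print.nbf_params <- function(x, ...) {
  m <- x$meta
  cat("DPB-NBFnet parameters: d =", m$d, ", K =", m$K,
      ", depths =", paste(m$depths, collapse = "+"),
      ", message =", m$message, ", aggregate =", m$aggregate, "\n")
  cat("  ", length(flatten_params(x)), "learnable values\n")
  invisible(x)
}

# ---- parameter <-> flat vector plumbing (optimizer, gradient checks) ----

param_leaves <- function(p) {
  out <- list(q = p$q)
  for (i in seq_along(p$layers)) {
    out[[paste0("layer", i, ".w")]] <- p$layers[[i]]$w
    out[[paste0("layer", i, ".W")]] <- p$layers[[i]]$W
    out[[paste0("layer", i, ".b")]] <- p$layers[[i]]$b
  }
  out$thetas <- p$thetas
  for (nm in names(p$fc)) out[[paste0("fc.", nm)]] <- p$fc[[nm]]
  out
}

#' Flatten model parameters to a numeric vector (and back)
#'
#' Used by the optimizer and the finite-difference gradient checks; the
#' layout is stable for a given architecture.
#' @param params,skeleton An `nbf_params` object (the skeleton supplies the
#'   architecture when unflattening).
#' @param x Numeric vector as produced by `flatten_params`.
#' @return A numeric vector / an `nbf_params` object.
#' @export
flatten_params <- function(params) {
  unlist(param_leaves(params), use.names = FALSE)
}

#' @rdname flatten_params
#' @export
unflatten_params <- function(x, skeleton) {
  leaves <- param_leaves(skeleton)
  pos <- 0L
  for (nm in names(leaves)) {
    n <- length(leaves[[nm]])
    val <- x[pos + seq_len(n)]
    if (is.matrix(leaves[[nm]])) dim(val) <- dim(leaves[[nm]])
    leaves[[nm]] <- val
    pos <- pos + n
  }
  stopifnot(pos == length(x))
  out <- skeleton
  out$q <- leaves$q
  for (i in seq_along(out$layers)) {
    out$layers[[i]]$w <- leaves[[paste0("layer", i, ".w")]]
    out$layers[[i]]$W <- leaves[[paste0("layer", i, ".W")]]
    out$layers[[i]]$b <- leaves[[paste0("layer", i, ".b")]]
  }
  out$thetas <- leaves$thetas
  for (nm in names(out$fc)) out$fc[[nm]] <- leaves[[paste0("fc.", nm)]]
  out
}

zero_grads <- function(params) {
  unflatten_params(numeric(length(flatten_params(params))), params)
}

# ---- forward / backward over one source and many targets ----

# 2-hop context of the pair (u, v): the node set pooled over
pair_context <- function(nb, ui, vi, hops = 2L) {
  ctx <- unique(c(ui, vi))
  for (h in seq_len(hops)) ctx <- unique(c(ctx, unlist(nb[ctx])))
  sort(ctx)
}

arc_neighbors <- function(aw) {
  split(aw$src, factor(aw$dst, levels = seq_len(aw$V)))
}

# Runs the three-module chain once for source ui, then the per-pair head for
# every target in vi_vec. Returns log-probability rows c(pos, neg) plus the
# caches the backward pass needs.
forward_source <- function(aw, nb, params, ui, vi_vec, keep_cache = TRUE) {
  m <- params$meta
  kinds <- list(message = m$message, aggregate = m$aggregate)
  d <- m$d; leak <- m$leak
  V <- aw$V
  H0 <- matrix(0, V, d); H0[ui, ] <- params$q
  H <- H0
  caches <- vector("list", length(params$layers))
  pre <- vector("list", 3L); S <- vector("list", 3L)
  li <- 0L
  for (mod in 1:3) {
    for (t in seq_len(m$depths[mod])) {
      li <- li + 1L
      fw <- layer_forward(H, H0, params$layers[[li]], aw, kinds)
      caches[[li]] <- fw$cache
      H <- fw$H_out
    }
    pre[[mod]] <- H
    H <- leaky_relu(H, leak)
    S[[mod]] <- H
  }
  alphas <- alpha_from_theta(params$thetas)
  fc <- params$fc
  n <- length(vi_vec)
  logp <- matrix(NA_real_, n, 2L)
  pair_caches <- if (keep_cache) vector("list", n) else NULL
  for (j in seq_len(n)) {
    vi <- vi_vec[j]
    ctx <- pair_context(nb, ui, vi)
    P <- vector("list", 3L); idx <- vector("list", 3L)
    zsum <- numeric(d)
    for (mod in 1:3) {
      pm <- sort_pooling(S[[mod]][ctx, , drop = FALSE], m$K)
      P[[mod]] <- pm
      idx[[mod]] <- attr(pm, "indices")
      zsum <- zsum + alphamex(pm, alphas[mod])
    }
    feat <- c(zsum, S[[3L]][vi, ])
    pre1 <- drop(feat %*% fc$W1) + fc$b1
    h1 <- leaky_relu(pre1, leak)
    pre2 <- drop(h1 %*% fc$W2) + fc$b2
    h2 <- leaky_relu(pre2, leak)
    logits <- drop(h2 %*% fc$W3) + fc$b3
    mx <- max(logits)
    logp[j, ] <- logits - (mx + log(sum(exp(logits - mx))))
    if (keep_cache)
      pair_caches[[j]] <- list(vi = vi, ctx = ctx, P = P, idx = idx,
                               feat = feat, pre1 = pre1, h1 = h1,
                               pre2 = pre2, h2 = h2)
  }
  list(logp = logp, caches = caches, pre = pre, S = S, H0 = H0,
       pair_caches = pair_caches, alphas = alphas, ui = ui)
}

# Accumulates parameter gradients for one source batch given upstream
# gradients dlogp (n x 2) on the log-probabilities.
backward_source <- function(aw, fwd, params, dlogp) {
  m <- params$meta
  kinds <- list(message = m$message, aggregate = m$aggregate)
  d <- m$d; leak <- m$leak; V <- aw$V
  g <- zero_grads(params)
  fc <- params$fc
  dS <- lapply(1:3, function(i) matrix(0, V, d))
  dalpha <- numeric(3L)
  for (j in seq_len(nrow(dlogp))) {
    pc <- fwd$pair_caches[[j]]
    p <- exp(fwd$logp[j, ])
    dlogits <- dlogp[j, ] - p * sum(dlogp[j, ])
    g$fc$W3 <- g$fc$W3 + outer(pc$h2, dlogits)
    g$fc$b3 <- g$fc$b3 + dlogits
    dh2 <- drop(fc$W3 %*% dlogits)
    dpre2 <- dh2 * lrelu_grad(pc$pre2, leak)
    g$fc$W2 <- g$fc$W2 + outer(pc$h1, dpre2)
    g$fc$b2 <- g$fc$b2 + dpre2
    dh1 <- drop(fc$W2 %*% dpre2)
    dpre1 <- dh1 * lrelu_grad(pc$pre1, leak)
    g$fc$W1 <- g$fc$W1 + outer(pc$feat, dpre1)
    g$fc$b1 <- g$fc$b1 + dpre1
    dfeat <- drop(fc$W1 %*% dpre1)
    dz <- dfeat[seq_len(d)]
    dS[[3L]][pc$vi, ] <- dS[[3L]][pc$vi, ] + dfeat[d + seq_len(d)]
    for (mod in 1:3) {
      amb <- alphamex_backward(pc$P[[mod]], fwd$alphas[mod], dz)
      dalpha[mod] <- dalpha[mod] + amb$dalpha
      sel <- !is.na(pc$idx[[mod]])
      rows <- pc$ctx[pc$idx[[mod]][sel]]
      if (any(sel))
        dS[[mod]][rows, ] <- dS[[mod]][rows, ] +
          amb$dstates[which(sel), , drop = FALSE]
    }
  }
  # alpha = 0.5 + 0.5 * plogis(theta)
  sg <- stats::plogis(params$thetas)
  g$thetas <- dalpha * 0.5 * sg * (1 - sg)

  dH0_acc <- matrix(0, V, d)
  dH <- dS[[3L]]
  li <- length(params$layers)
  for (mod in 3:1) {
    dH <- dH * lrelu_grad(fwd$pre[[mod]], leak)
    for (t in seq_len(m$depths[mod])) {
      lb <- layer_backward(dH, fwd$caches[[li]], params$layers[[li]], aw,
                           kinds)
      g$layers[[li]]$w <- g$layers[[li]]$w + lb$dw
      g$layers[[li]]$W <- g$layers[[li]]$W + lb$dW
      g$layers[[li]]$b <- g$layers[[li]]$b + lb$db
      dH0_acc <- dH0_acc + lb$dH0
      dH <- lb$dH_in
      li <- li - 1L
    }
    if (mod > 1L) dH <- dH + dS[[mod - 1L]]
  }
  dH0_acc <- dH0_acc + dH
  g$q <- dH0_acc[fwd$ui, ]
  g
}

#' One feature-extraction module
#'
#' Applies a block of NBFnet layers to a source-conditioned state, a leaky
#' ReLU, and SortPooling over a context node set. The state output feeds the
#' next module; the pooled K x d matrix feeds a global pooling layer.
#'
#' @param graph An `interaction_graph`.
#' @param state_in A `pair_state` (see [indicator()]).
#' @param layers List of per-layer parameter lists (`w`, `W`, `b`).
#' @param boundary The boundary `pair_state` (layer-0 indicator state), also
#'   aggregated at every layer.
#' @param K SortPooling rows.
#' @param message,aggregate Kinds.
#' @param leak Leaky ReLU slope.
#' @param context Node ids pooled over (default: all nodes).
#' @param edge_by_class Class-specialized edge representations.
#' @return List with `state_out` (a `pair_state`) and `pooled` (K x d).
#' @export
feature_module <- function(graph, state_in, layers, boundary, K = 10L,
                           message = "distmult", aggregate = "sum",
                           leak = 0.2, context = NULL,
                           edge_by_class = FALSE) {
  aw <- arc_workspace(graph, edge_by_class)
  kinds <- list(message = message, aggregate = aggregate)
  H <- state_in$states
  H0 <- boundary$states
  lay_n <- state_in$layer
  for (lay in layers) {
    H <- layer_forward(H, H0, lay, aw, kinds)$H_out
    lay_n <- lay_n + 1L
  }
  H <- leaky_relu(H, leak)
  rownames(H) <- graph$nodes
  ctx <- if (is.null(context)) seq_len(n_nodes(graph))
         else node_index(graph, context)
  pooled <- sort_pooling(H[ctx, , drop = FALSE], K)
  list(state_out = structure(list(source = state_in$source, states = H,
                                  layer = lay_n), class = "pair_state"),
       pooled = pooled)
}

#' Full forward pass for one candidate pair
#'
#' Chains the three feature modules from the indicator state of `u`, pools
#' each module's output over the pair context with SortPooling then
#' AlphaMEX, sums the three pooled vectors (addition module), concatenates
#' the target state h(u, v), and applies the FC head with a joint
#' log-softmax.
#'
#' @param graph An `interaction_graph`.
#' @param u,v Candidate pair endpoints.
#' @param params An `nbf_params` object.
#' @return An object of class `prediction_pair`: list with `log_p_pos`,
#'   `log_p_neg` (their exponentials sum to 1).
#' @export
model_forward <- function(graph, u, v, params) {
  aw <- arc_workspace(graph, params$meta$edge_by_class)
  nb <- arc_neighbors(aw)
  ui <- node_index(graph, u); vi <- node_index(graph, v)
  fwd <- forward_source(aw, nb, params, ui, vi, keep_cache = FALSE)
  structure(list(log_p_pos = fwd$logp[1L, 1L], log_p_neg = fwd$logp[1L, 2L]),
            class = "prediction_pair")
}

#' @export
print.prediction_pair <- function(x, ...) {
  cat(sprintf("P(bind) = %.4f  (log p+ = %.4f, log p- = %.4f)\n",
              exp(x$log_p_pos), x$log_p_pos, x$log_p_neg))
  invisible(x)
}

#' Negative log-likelihood loss
#'
#' The mean over samples of `-(l * log p+ + (1 - l) * log p-)`: zero iff
#' every prediction assigns probability one to its true class.
#'
#' @param log_p_pos,log_p_neg Numeric vectors of log-probabilities (or pass
#'   a list of `prediction_pair` objects as `log_p_pos`).
#' @param labels Binary labels.
#' @return Scalar loss.
#' @export
nll_loss <- function(log_p_pos, log_p_neg = NULL, labels) {
  if (is.list(log_p_pos) && is.null(log_p_neg)) {
    preds <- log_p_pos
    log_p_pos <- vapply(preds, function(p) p$log_p_pos, numeric(1))
    log_p_neg <- vapply(preds, function(p) p$log_p_neg, numeric(1))
  }
  k <- length(labels)
  if (k < 1L) stop("at least one sample is required")
  if (length(log_p_pos) != k || length(log_p_neg) != k)
    stop("prediction and label lengths differ")
  # selecting by label avoids 0 * -Inf when the other class has log prob -Inf
  -mean(ifelse(labels == 1, log_p_pos, log_p_neg))
}
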