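# Training loop (Adam + entity-corruption negative sampling), evaluation
# metrics (precision/recall/accuracy/MCC from confusion counts, trapezoidal
# AUROC), and stratified k-fold cross-validation with leakage control.

adam_state <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, theta, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(state = state, theta = theta - lr * mhat / (sqrt(vhat) + eps))
}

#' Training configuration
#'
#' Collects every tunable of the training loop. The seed fixes all random
#' draws in a run (initialization, negative corruption, batching order); a
#' single CPU is sufficient and runs are bit-reproducible.
#'
#' @param epochs Training epochs (default 20; the loss trace plateaus well
#'   within this budget on the synthetic benchmarks studied).
#' @param lr Adam learning rate (default 1e-3).
#' @param negatives_per_positive Fresh corrupted negatives drawn per positive
#'   per epoch (default 1).
#' @param seed Master seed.
#' @param k Cross-validation folds (default 4).
#' @param d,K,depths,message,aggregate,edge_by_class,alpha_init Architecture
#'   settings, see [init_model_params()].
#' @param verbose Print per-epoch loss.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 20L, lr = 1e-3,
                         negatives_per_positive = 1L, seed = 1L, k = 4L,
                         d = 32L, K = 10L, depths = c(2L, 2L, 2L),
                         message = "distmult", aggregate = "sum",
                         edge_by_class = FALSE, alpha_init = 0.9,
                         verbose = FALSE) {
  stopifnot(epochs >= 0, lr >= 0, negatives_per_positive >= 1, k >= 2)
  structure(list(epochs = as.integer(epochs), lr = lr,
                 negatives_per_positive = as.integer(negatives_per_positive),
                 seed = as.integer(seed), k = as.integer(k),
                 d = as.integer(d), K = as.integer(K),
                 depths = as.integer(depths), message = message,
                 aggregate = aggregate, edge_by_class = edge_by_class,
                 alpha_init = alpha_init, verbose = isTRUE(verbose)),
            class = "train_config")
}

# Orient a pair so the source is the DNA endpoint (falls back to the first
# endpoint when both share a class). A stable convention lets examples that
# share a source share one Bellman-Ford forward pass.
orient_pairs <- function(graph, examples) {
  ui <- node_index(graph, examples$u)
  vi <- node_index(graph, examples$v)
  swap <- graph$class[ui] != "DNA" & graph$class[vi] == "DNA"
  data.frame(src = ifelse(swap, vi, ui), dst = ifelse(swap, ui, vi),
             label = as.integer(examples$label))
}

# log-probability matrix (n x 2) for oriented examples, batched by source
predict_logp <- function(graph, params, oriented) {
  aw <- arc_workspace(graph, params$meta$edge_by_class)
  nb <- arc_neighbors(aw)
  out <- matrix(NA_real_, nrow(oriented), 2L)
  for (s in unique(oriented$src)) {
    rows <- which(oriented$src == s)
    fwd <- forward_source(aw, nb, params, s, oriented$dst[rows],
                          keep_cache = FALSE)
    out[rows, ] <- fwd$logp
  }
  out
}

#' Train the model on one cross-validation split
#'
#' Minimizes the negative log-likelihood by Adam over batches grouped by
#' source node: each step takes one source's training positives plus freshly
#' corrupted negatives (entity corruption, fair-coin side choice, uniform
#' among admissible same-class replacements). The message-passing graph
#' excludes the split's test-fold positive edges, so no test link is ever
#' seen during training. Within each batch the batch's own positive query
#' edges are also dropped from the message graph: otherwise the model can
#' read the answer off the direct edge and never learns the multi-hop
#' structure that generalizes to unseen pairs, whose edges are absent at
#' evaluation time.
#'
#' @param graph The full `interaction_graph` (test positives are removed
#'   internally).
#' @param split A split from [kfold_split()]: list with `train`, `test`.
#' @param config A [train_config()].
#' @param params Optional warm-start `nbf_params`.
#' @return List with `params` (trained `nbf_params`), `trace` (per-epoch
#'   mean loss), `graph_msg` (the message-passing graph used).
#' @export
train <- function(graph, split, config = train_config(), params = NULL) {
  train_pos <- split$train[split$train$label == 1L, , drop = FALSE]
  if (nrow(train_pos) == 0L) stop("training fold has no positive examples")
  set.seed(config$seed)
  test_pos <- split$test[split$test$label == 1L, , drop = FALSE]
  graph_msg <- remove_edges(graph, test_pos)
  # every known positive (either fold) is off-limits as a negative
  all_pos <- rbind(split$train, split$test)
  forbidden <- unique(c(edge_keys(graph),
                        pair_keys(graph, all_pos$u[all_pos$label == 1L],
                                  all_pos$v[all_pos$label == 1L])))
  if (is.null(params))
    params <- init_model_params(d = config$d, K = config$K,
                                depths = config$depths,
                                message = config$message,
                                aggregate = config$aggregate,
                                edge_by_class = config$edge_by_class,
                                alpha_init = config$alpha_init,
                                graph = graph_msg)
  theta <- flatten_params(params)
  opt <- adam_state(length(theta))
  trace <- numeric(config$epochs)

  for (ep in seq_len(config$epochs)) {
    negs <- do.call(rbind, lapply(seq_len(nrow(train_pos)), function(i) {
      do.call(rbind, lapply(seq_len(config$negatives_per_positive),
        function(r) corrupt_negative(graph, train_pos$u[i], train_pos$v[i],
                                     forbidden)))
    }))
    batch_ex <- rbind(train_pos, negs)
    oriented <- orient_pairs(graph_msg, batch_ex)
    sources <- unique(oriented$src)
    sources <- sources[sample.int(length(sources))]
    ep_loss <- 0; ep_n <- 0L
    for (s in sources) {
      rows <- which(oriented$src == s)
      lab <- oriented$label[rows]
      pos_rows <- rows[lab == 1L]
      g_batch <- remove_edges(graph_msg,
        data.frame(u = graph_msg$nodes[oriented$src[pos_rows]],
                   v = graph_msg$nodes[oriented$dst[pos_rows]]))
      aw <- arc_workspace(g_batch, params$meta$edge_by_class)
      nb <- arc_neighbors(aw)
      fwd <- forward_source(aw, nb, params, s, oriented$dst[rows])
      n <- length(rows)
      loss <- -mean(lab * fwd$logp[, 1L] + (1 - lab) * fwd$logp[, 2L])
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", ep,
             ", source ", graph_msg$nodes[s])
      dlogp <- cbind(-lab, -(1 - lab)) / n
      g <- backward_source(aw, fwd, params, dlogp)
      st <- adam_step(opt, theta, flatten_params(g), config$lr)
      opt <- st$state; theta <- st$theta
      params <- unflatten_params(theta, params)
      ep_loss <- ep_loss + loss * n; ep_n <- ep_n + n
    }
    trace[ep] <- ep_loss / ep_n
    if (config$verbose)
      cat(sprintf("epoch %3d  loss %.4f\n", ep, trace[ep]))
  }
  list(params = params, trace = trace, graph_msg = graph_msg)
}

#' Score candidate pairs with a trained model
#'
#' @param graph The message-passing `interaction_graph` (use the training
#'   graph of the fold being evaluated, not the full graph).
#' @param params Trained `nbf_params`.
#' @param examples Data.frame with columns `u`, `v` (a `label` column is
#'   carried through if present).
#' @return The examples with a `score` column: predicted probability that
#'   the pair binds.
#' @export
score_pairs <- function(graph, params, examples) {
  oriented <- orient_pairs(graph, data.frame(u = examples$u, v = examples$v,
                                             label = 0L))
  logp <- predict_logp(graph, params, oriented)
  out <- examples
  out$score <- exp(logp[, 1L])
  out
}

#' Confusion counts at a probability threshold
#'
#' A pair is predicted to bind iff its positive-class probability is at
#' least `threshold` (default 0.5).
#'
#' @param scores Positive-class probabilities (or a list of
#'   `prediction_pair` objects).
#' @param labels Binary labels.
#' @param threshold Decision threshold.
#' @return Named integer vector `TrP`, `TrN`, `FaP`, `FaN`.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  if (is.list(scores))
    scores <- vapply(scores, function(p) exp(p$log_p_pos), numeric(1))
  if (length(scores) == 0L) stop("no predictions to tally")
  if (length(scores) != length(labels))
    stop("prediction and label lengths differ")
  pred <- scores >= threshold
  c(TrP = sum(pred & labels == 1L), TrN = sum(!pred & labels == 0L),
    FaP = sum(pred & labels == 0L), FaN = sum(!pred & labels == 1L))
}

#' Area under the ROC curve (trapezoidal)
#'
#' Sweeps all score thresholds, accumulating the ROC curve from (0,0) to
#' (1,1), and integrates by the trapezoid rule; tied scores move the curve
#' diagonally, so ties contribute half credit.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels Binary labels.
#' @return AUROC in \[0, 1\], or `NA` if only one class is present.
#' @export
auroc <- function(scores, labels) {
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0L || N == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  tp <- cumsum(l == 1L); fp <- cumsum(l == 0L)
  keep <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tie group
  tpr <- c(0, tp[keep] / P); fpr <- c(0, fp[keep] / N)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Classification metrics from confusion counts
#'
#' Precision `TrP/(TrP+FaP)`, recall `TrP/(TrP+FaN)`, accuracy, the Matthews
#' correlation coefficient
#' `(TrP*TrN - FaP*FaN) / sqrt((TrP+FaP)(TrP+FaN)(TrN+FaP)(TrN+FaN))`, and
#' trapezoidal AUROC. Metrics with a degenerate denominator are reported as
#' `NA` (a distinct marker), never silently as 0.
#'
#' @param counts Confusion counts from [confusion()].
#' @param scores Positive-class probabilities (for AUROC; optional).
#' @param labels Binary labels (for AUROC; optional).
#' @return A list of class `binding_metrics`: counts plus `PR`, `RE`, `AC`,
#'   `MCC`, `auroc`.
#' @export
compute_metrics <- function(counts, scores = NULL, labels = NULL) {
  TrP <- counts[["TrP"]]; TrN <- counts[["TrN"]]
  FaP <- counts[["FaP"]]; FaN <- counts[["FaN"]]
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(prod(c(TrP + FaP, TrP + FaN, TrN + FaP, TrN + FaN)))
  structure(list(
    TrP = TrP, TrN = TrN, FaP = FaP, FaN = FaN,
    PR = safe_div(TrP, TrP + FaP),
    RE = safe_div(TrP, TrP + FaN),
    AC = safe_div(TrP + TrN, TrP + TrN + FaP + FaN),
    MCC = if (mcc_den == 0) NA_real_ else (TrP * TrN - FaP * FaN) / mcc_den,
    auroc = if (is.null(scores)) NA_real_ else auroc(scores, labels)),
    class = "binding_metrics")
}

#' @export
print.binding_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
  cat(sprintf("counts: TrP=%d TrN=%d FaP=%d FaN=%d\n",
              x$TrP, x$TrN, x$FaP, x$FaN))
  cat(sprintf("PR=%s RE=%s AC=%s MCC=%s AUROC=%s\n", fmt(x$PR), fmt(x$RE),
              fmt(x$AC), fmt(x$MCC), fmt(x$auroc)))
  invisible(x)
}

#' k-fold cross-validation of the full pipeline
#'
#' Stratified k-fold split of the labelled examples; per fold, trains on the
#' training examples (with the fold's test-positive edges removed from the
#' message-passing graph) and evaluates on the held-out fold. Per-fold seeds
#' are derived from the master seed plus the fold index.
#'
#' @param graph An `interaction_graph`.
#' @param examples Data.frame `u`, `v`, `label`.
#' @param config A [train_config()].
#' @return A list of class `cv_result`: `folds` (per-fold
#'   `binding_metrics`), `mean` (named vector of fold-averaged metrics),
#'   `traces` (per-fold loss traces), `scores` (per-fold scored test
#'   examples).
#' @export
cross_validate <- function(graph, examples, config = train_config()) {
  set.seed(config$seed)
  splits <- kfold_split(examples, config$k)
  folds <- list(); traces <- list(); scored <- list()
  for (i in seq_along(splits)) {
    cfg <- config
    cfg$seed <- config$seed + i
    fit <- train(graph, splits[[i]], cfg)
    te <- splits[[i]]$test
    sc <- score_pairs(fit$graph_msg, fit$params, te)
    cm <- confusion(sc$score, te$label)
    folds[[i]] <- compute_metrics(cm, sc$score, te$label)
    traces[[i]] <- fit$trace
    scored[[i]] <- sc
  }
  keys <- c("PR", "RE", "AC", "MCC", "auroc")
  avg <- vapply(keys, function(k2)
    mean(vapply(folds, function(f) f[[k2]], numeric(1)), na.rm = TRUE),
    numeric(1))
  structure(list(folds = folds, mean = avg, traces = traces,
                 scores = scored, config = config), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(length(x$folds), "-fold cross-validation (seed ", x$config$seed,
      ")\n", sep = "")
  for (i in seq_along(x$folds)) {
    f <- x$folds[[i]]
    cat(sprintf("fold %d: ", i)); print(f)
  }
  cat("mean:  ", paste(sprintf("%s=%.4f", names(x$mean), x$mean),
                       collapse = " "), "\n")
  invisible(x)
}
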