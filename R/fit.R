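#' Fit a DPB-NBFnet binding predictor
#'
#' The front-door modelling interface: trains the full architecture (three
#' neural Bellman-Ford feature modules with SortPooling and AlphaMEX global
#' pooling, an addition module and a 256/64/2 fully connected head) on a
#' labelled set of DNA-protein pairs over an interaction graph, minimizing
#' the negative log-likelihood with entity-corruption negative sampling.
#'
#' For honest performance estimates use [cross_validate()], which removes
#' each test fold's positive edges from the message-passing graph;
#' `nbf_fit` trains on everything it is given.
#'
#' @param graph An [interaction_graph()].
#' @param examples Data.frame with columns `u`, `v`, `label` (at least one
#'   positive). Defaults to the graph's edges as positives.
#' @param config A [train_config()]; individual settings can also be passed
#'   via `...` (e.g. `epochs = 10`, `message = "rotate"`).
#' @param ... Overrides for [train_config()] fields.
#' @return An object of class `dpb_nbfnet` with components `params`,
#'   `trace`, `config`, `graph`, `examples`, `call`.
#' @examples
#' \donttest{
#' dat <- generate_binding_graph(30, 30, density = 0.1, seed = 7)
#' fit <- nbf_fit(dat$graph, dat$examples, epochs = 3, d = 8)
#' head(predict(fit, dat$heldout))
#' }
#' @export
nbf_fit <- function(graph, examples = NULL, config = NULL, ...) {
  if (is.null(examples))
    examples <- data.frame(u = graph$nodes[graph$edges[, 1L]],
                           v = graph$nodes[graph$edges[, 2L]], label = 1L)
  if (is.null(config)) config <- train_config(...)
  else {
    dots <- list(...)
    for (nm in names(dots)) config[[nm]] <- dots[[nm]]
  }
  split <- list(train = examples, test = examples[0, , drop = FALSE],
                fold_index = 0L)
  fit <- train(graph, split, config)
  structure(list(params = fit$params, trace = fit$trace, config = config,
                 graph = graph, examples = examples,
                 call = match.call()),
            class = "dpb_nbfnet")
}

#' @export
print.dpb_nbfnet <- function(x, ...) {
  cat("DPB-NBFnet binding predictor\n")
  print(x$graph)
  m <- x$params$meta
  cat("  architecture: d =", m$d, ", modules =",
      paste(m$depths, collapse = "+"), "layers,", m$message, "messages,",
      m$aggregate, "aggregation, K =", m$K, "\n")
  if (length(x$trace))
    cat(sprintf("  final training loss: %.4f (%d epochs)\n",
                x$trace[length(x$trace)], length(x$trace)))
  invisible(x)
}

#' @export
summary.dpb_nbfnet <- function(object, ...) {
  sc <- score_pairs(object$graph, object$params, object$examples)
  cm <- confusion(sc$score, object$examples$label)
  met <- compute_metrics(cm, sc$score, object$examples$label)
  out <- list(fit = object, train_metrics = met,
              n_params = length(flatten_params(object$params)),
              alphas = alpha_from_theta(object$params$thetas))
  class(out) <- "summary.dpb_nbfnet"
  out
}

#' @export
print.summary.dpb_nbfnet <- function(x, ...) {
  print(x$fit)
  cat("  learnable values:", x$n_params, "\n")
  cat("  AlphaMEX alphas:", paste(sprintf("%.3f", x$alphas), collapse = ", "),
      "\n")
  cat("  training-set metrics (optimistic; use cross_validate):\n  ")
  print(x$train_metrics)
  invisible(x)
}

#' Predict binding probabilities for new pairs
#'
#' @param object A fitted `dpb_nbfnet`.
#' @param newdata Data.frame with columns `u`, `v` (defaults to the training
#'   examples).
#' @param ... Unused.
#' @return `newdata` with a `score` column of binding probabilities.
#' @export
predict.dpb_nbfnet <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$examples
  score_pairs(object$graph, object$params, newdata)
}

#' @export
coef.dpb_nbfnet <- function(object, ...) {
  list(query = object$params$q,
       layers = object$params$layers,
       alphas = alpha_from_theta(object$params$thetas),
       fc = object$params$fc)
}

#' @export
plot.dpb_nbfnet <- function(x, ...) {
  plot(seq_along(x$trace), x$trace, type = "b", pch = 16,
       xlab = "epoch", ylab = "mean NLL", main = "Training loss", ...)
  invisible(x)
}

#' @export
residuals.dpb_nbfnet <- function(object, ...) {
  sc <- predict(object)
  sc$label - sc$score
}

#' Simulate labels from a fitted binding predictor
#'
#' Draws Bernoulli labels for candidate pairs from the model's predicted
#' binding probabilities.
#'
#' @param object A fitted `dpb_nbfnet`.
#' @param nsim Number of simulated label vectors.
#' @param seed Optional seed.
#' @param newdata Data.frame `u`, `v` (defaults to training examples).
#' @param ... Unused.
#' @return A data.frame with one column per simulation.
#' @export
simulate.dpb_nbfnet <- function(object, nsim = 1, seed = NULL,
                                newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sc <- predict(object, newdata)
  out <- as.data.frame(replicate(nsim,
    as.integer(stats::runif(nrow(sc)) < sc$score)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
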