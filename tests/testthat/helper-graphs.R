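# Shared fixtures: small deterministic graphs and a random-graph generator
# used by the property-style tests. All fixtures are built in code.

# path a - b - c
path_graph <- function() {
  interaction_graph(c("a", "b", "c"), c("DNA", "PROTEIN", "DNA"),
                    rbind(c("a", "b"), c("b", "c")))
}

# triangle with edge values a-b = 1, a-c = 3, b-c = 1 (edge rows are stored
# sorted: (a,b), (a,c), (b,c))
triangle_graph <- function() {
  interaction_graph(c("a", "b", "c"), c("DNA", "PROTEIN", "DNA"),
                    rbind(c("a", "b"), c("b", "c"), c("a", "c")))
}
triangle_lengths <- c(1, 3, 1)

# random graph with <= n_max nodes and <= e_max edges, both classes present
random_interaction_graph <- function(n_max = 8L, e_max = 12L) {
  n <- sample(4:n_max, 1L)
  cls <- c("DNA", "PROTEIN",
           sample(c("DNA", "PROTEIN"), n - 2L, replace = TRUE))
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(n, 2L))
  m <- min(sample(3:e_max, 1L), nrow(pairs))
  sel <- pairs[sample.int(nrow(pairs), m), , drop = FALSE]
  interaction_graph(ids, cls, matrix(ids[sel], ncol = 2L))
}

# the five classical semirings with edge values appropriate to each
classic_semiring_cases <- function(n_edges) {
  list(
    list(name = "katz-sum-product", sr = sr_sum_product(),
         ev = rep(0.1, n_edges), integer_valued = FALSE),
    list(name = "graph-distance", sr = sr_min_plus(),
         ev = sample(1:5, n_edges, replace = TRUE), integer_valued = TRUE),
    list(name = "widest-path", sr = sr_max_min(),
         ev = sample(1:9, n_edges, replace = TRUE), integer_valued = TRUE),
    list(name = "most-reliable", sr = sr_max_product(),
         ev = round(runif(n_edges, 0.1, 0.9), 3), integer_valued = FALSE),
    list(name = "pagerank-normalized", sr = sr_sum_product(),
         ev = round(runif(n_edges, 0.05, 0.3), 3), integer_valued = FALSE))
}

# tiny trained-model parameter set for forward/backward tests
tiny_params <- function(graph, d = 4L, K = 3L, depths = c(1L, 1L, 1L),
                        message = "distmult", aggregate = "sum",
                        seed = 7L) {
  set.seed(seed)
  init_model_params(d = d, K = K, depths = depths, message = message,
                    aggregate = aggregate, graph = graph)
}

expect_all_equal <- function(x, y, tol = 1e-9) {
  expect_lt(max(abs(x - y)), tol)
}

# run the CLI in-process, swallowing its console output
capture_status <- function(argv) {
  st <- NULL
  utils::capture.output(
    st <- suppressWarnings(suppressMessages(nbfbind_main(argv))))
  st
}
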