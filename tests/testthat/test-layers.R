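test_that("indicator marks exactly the source row", {
  g <- triangle_graph()
  st <- indicator(g, "a", c(1, 1))
  expect_equal(st$states["a", ], c(1, 1))
  expect_equal(unname(st$states["b", ]), c(0, 0))
  expect_equal(unname(st$states["c", ]), c(0, 0))
  st2 <- indicator(g, "b", c(1, 1))
  expect_equal(st2$states["b", ], c(1, 1))
  expect_equal(sum(st2$states != 0), 2L)
  expect_error(indicator(g, "zz", c(1, 1)), "unknown")
  # degenerate all-zero query is legal
  expect_true(all(indicator(g, "a", c(0, 0))$states == 0))
})

test_that("message functions implement DistMult, TransE and RotatE", {
  expect_equal(nbf_message(c(1, 2), c(3, 4), "distmult"), c(3, 8))
  expect_equal(nbf_message(c(1, 2), c(3, 4), "transe"), c(4, 6))
  # quarter-turn rotation of 1 + 0i
  expect_equal(nbf_message(c(1, 0), pi / 2, "rotate"), c(0, 1),
               tolerance = 1e-12)
  expect_error(nbf_message(c(1, 2, 3), pi, "rotate"), "even")
  expect_error(nbf_message(c(1, 2), c(1, 2, 3), "distmult"), "dimension")
})

test_that("aggregation reduces messages together with the boundary term", {
  expect_equal(nbf_aggregate(list(c(1, 2), c(3, 4)), c(0, 0), "sum"),
               c(4, 6))
  expect_equal(nbf_aggregate(list(c(1, 5), c(3, 4)), c(0, 0), "max"),
               c(3, 5))
  expect_equal(nbf_aggregate(list(), c(7, 8), "mean"), c(7, 8))
  expect_equal(nbf_aggregate(list(c(1, 2)), c(3, 4), "mean"), c(2, 3))
  expect_error(nbf_aggregate(list(c(1, 2)), NULL, "sum"), "boundary")
})

test_that("NBFnet with unit DistMult weights counts walks", {
  g <- path_graph()
  params <- list(q = 1, layers = replicate(2, list(
    w = matrix(1, 1, 1), W = matrix(1, 1, 1), b = 0), simplify = FALSE))
  states <- nbfnet_forward(g, "a", params)
  expect_length(states, 3L)           # t = 0, 1, 2
  expect_equal(unname(states[[1]]$states["a", 1]), 1)
  expect_equal(unname(states[[3]]$states["c", 1]), 1)  # one walk a-b-c
  expect_equal(unname(states[[3]]$states["b", 1]), 1)  # a-b only
  expect_equal(unname(states[[3]]$states["a", 1]), 2)  # empty walk + a-b-a
  # T = 0: just the indicator
  p0 <- list(q = 1, layers = list())
  expect_equal(nbfnet_forward(g, "a", p0)[[1]]$states[, 1],
               c(a = 1, b = 0, c = 0))
})

test_that("disconnected components stay at zero under DistMult + sum", {
  g <- interaction_graph(c("a", "b", "c", "d"),
                         c("DNA", "PROTEIN", "DNA", "PROTEIN"),
                         rbind(c("a", "b")))
  params <- list(q = c(1, -2), layers = replicate(3, list(
    w = matrix(c(0.5, 2), 1, 2), W = diag(2), b = c(0, 0)),
    simplify = FALSE))
  states <- nbfnet_forward(g, "a", params)
  final <- states[[4]]$states
  expect_equal(unname(final["c", ]), c(0, 0))
  expect_equal(unname(final["d", ]), c(0, 0))
  expect_false(all(final["b", ] == 0))
})

test_that("NBFnet with scalar states reproduces the sum-product engine", {
  set.seed(70)
  for (rep in 1:10) {
    g <- random_interaction_graph(8L, 12L)
    w_e <- round(runif(1, 0.2, 0.8), 3)
    T <- 3L
    params <- list(q = 1, layers = replicate(T, list(
      w = matrix(w_e, 1, 1), W = matrix(1, 1, 1), b = 0),
      simplify = FALSE))
    nn <- nbfnet_forward(g, g$nodes[1], params)[[T + 1L]]$states[, 1]
    en <- generalized_bellman_ford(g, g$nodes[1], sr_sum_product(), w_e,
                                   T)$values
    expect_all_equal(unname(nn), unname(en), tol = 1e-9)
  }
})

test_that("node relabeling permutes the pair state rows identically", {
  set.seed(80)
  g <- random_interaction_graph(7L, 10L)
  perm <- sample(n_nodes(g))
  g2 <- interaction_graph(g$nodes[perm], g$class[perm],
                          matrix(g$nodes[g$edges], ncol = 2L))
  d <- 3L
  set.seed(81)
  params <- list(q = rnorm(d), layers = replicate(2, list(
    w = matrix(rnorm(d), 1, d), W = diag(d), b = numeric(d)),
    simplify = FALSE))
  s1 <- nbfnet_forward(g, g$nodes[1], params)[[3]]$states
  s2 <- nbfnet_forward(g2, g$nodes[1], params)[[3]]$states
  expect_equal(s1[g$nodes, ], s2[g$nodes, ], tolerance = 1e-12)
})

test_that("gradients flow to the query and edge representations", {
  g <- path_graph()
  set.seed(90)
  params <- tiny_params(g, d = 2L, depths = c(1L, 1L, 1L))
  aw <- nbfbind:::arc_workspace(g, FALSE)
  nb <- nbfbind:::arc_neighbors(aw)
  fwd <- nbfbind:::forward_source(aw, nb, params, 1L, 3L)
  grads <- nbfbind:::backward_source(aw, fwd, params, matrix(c(-1, 0), 1))
  expect_true(all(is.finite(flatten_params(grads))))
  expect_gt(sum(abs(grads$q)), 0)
  expect_gt(sum(abs(grads$layers[[1]]$w)), 0)

  # finite-difference agreement on the query embedding
  lossfn <- function(p) {
    f <- nbfbind:::forward_source(aw, nb, p, 1L, 3L, keep_cache = FALSE)
    -f$logp[1, 1]
  }
  for (i in seq_along(params$q)) {
    e <- 1e-5
    pp <- params; pp$q[i] <- pp$q[i] + e
    pm <- params; pm$q[i] <- pm$q[i] - e
    expect_equal(grads$q[i], (lossfn(pp) - lossfn(pm)) / (2 * e),
                 tolerance = 1e-4)
  }
})

test_that("full-model backward matches finite differences for every kind", {
  set.seed(91)
  dat <- generate_binding_graph(8, 8, f = 3, density = 0.25,
                                heldout_frac = 0, seed = 3)
  g <- dat$graph
  aw <- nbfbind:::arc_workspace(g, FALSE)
  nb <- nbfbind:::arc_neighbors(aw)
  ui <- 1L; vis <- c(10L, 12L); lab <- c(1, 0)
  for (msg in c("distmult", "transe", "rotate")) {
    for (agg in c("sum", "mean", "max")) {
      params <- tiny_params(g, d = 4L, depths = c(1L, 1L, 1L),
                            message = msg, aggregate = agg)
      theta <- flatten_params(params)
      lossfn <- function(th) {
        p <- unflatten_params(th, params)
        f <- nbfbind:::forward_source(aw, nb, p, ui, vis, keep_cache = FALSE)
        -mean(lab * f$logp[, 1] + (1 - lab) * f$logp[, 2])
      }
      fwd <- nbfbind:::forward_source(aw, nb, params, ui, vis)
      ga <- flatten_params(nbfbind:::backward_source(
        aw, fwd, params, cbind(-lab, -(1 - lab)) / 2))
      idx <- sort(sample.int(length(theta), 25))
      gn <- vapply(idx, function(i) {
        e <- 1e-5
        tp <- theta; tp[i] <- tp[i] + e
        tm <- theta; tm[i] <- tm[i] - e
        (lossfn(tp) - lossfn(tm)) / (2 * e)
      }, numeric(1))
      expect_lt(max(abs(ga[idx] - gn) / pmax(1, abs(gn))), 1e-6)
    }
  }
})
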