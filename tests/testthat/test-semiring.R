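test_that("built-in semirings satisfy the semiring laws on sampled values", {
  set.seed(1)
  srs <- list(sr_sum_product(), sr_min_plus(), sr_max_min(),
              sr_max_product())
  for (sr in srs) {
    vals <- switch(sr$name,
                   "sum-product" = runif(6, -2, 2),
                   "min-plus" = sample(0:9, 6, TRUE),
                   "max-min" = sample(0:9, 6, TRUE),
                   "max-product" = runif(6, 0, 1))
    for (i in 1:20) {
      abc <- sample(vals, 3, TRUE)
      a <- abc[1]; b <- abc[2]; c <- abc[3]
      expect_equal(sr$plus(a, b), sr$plus(b, a))
      expect_equal(sr$plus(sr$plus(a, b), c), sr$plus(a, sr$plus(b, c)))
      expect_equal(sr$times(sr$times(a, b), c), sr$times(a, sr$times(b, c)))
      # distributivity of times over plus
      expect_equal(sr$times(a, sr$plus(b, c)),
                   sr$plus(sr$times(a, b), sr$times(a, c)))
      expect_equal(sr$plus(a, sr$zero), a)
      expect_equal(sr$times(a, sr$one), a)
      expect_equal(sr$times(a, sr$zero), sr$zero)
    }
  }
})

test_that("T = 0 gives the boundary condition", {
  g <- triangle_graph()
  for (sr in list(sr_sum_product(), sr_min_plus())) {
    r <- generalized_bellman_ford(g, "b", sr, 1, 0)
    expect_equal(unname(r$values[g$nodes == "b"]), sr$one)
    expect_equal(unname(r$values[g$nodes != "b"]), rep(sr$zero, 2))
  }
})

test_that("min-plus on the triangle finds the two-hop shortcut", {
  g <- triangle_graph()
  r <- generalized_bellman_ford(g, "a", sr_min_plus(), triangle_lengths, 2)
  expect_equal(unname(r$values["c"]), 2)  # a-b-c beats the direct a-c = 3
  expect_equal(unname(r$values["b"]), 1)
  expect_equal(unname(r$values["a"]), 0)
})

test_that("sum-product walk sums on the path match hand enumeration", {
  g <- path_graph()
  r <- generalized_bellman_ford(g, "a", sr_sum_product(), 0.5, 2)
  expect_equal(unname(r$values["c"]), 0.25)  # single walk a-b-c
  expect_equal(unname(r$values["b"]), 0.5)   # single walk a-b
  expect_equal(unname(r$values["a"]), 1.25)  # empty walk + a-b-a
})

test_that("walk enumeration boundary conventions match the recursion", {
  g <- path_graph()
  sr <- sr_sum_product()
  expect_equal(enumerate_path_score(g, "a", "a", sr, 0.5, 0), sr$one)
  gi <- interaction_graph(c("x", "y", "z"), rep("DNA", 3),
                          rbind(c("x", "y")))
  expect_equal(enumerate_path_score(gi, "x", "z", sr, 1, 4), sr$zero)
  expect_error(enumerate_path_score(g, "a", "c", sr, 1, 9), "capped")
})

test_that("Bellman-Ford equals brute-force walk enumeration on random graphs", {
  set.seed(20)
  for (rep in 1:20) {
    g <- random_interaction_graph(8L, 12L)
    cases <- classic_semiring_cases(n_edges(g))
    T <- 3L
    for (cs in cases) {
      bf <- generalized_bellman_ford(g, g$nodes[1], cs$sr, cs$ev, T)
      for (v in g$nodes) {
        en <- enumerate_path_score(g, g$nodes[1], v, cs$sr, cs$ev, T)
        if (cs$integer_valued) expect_identical(unname(bf$values[v]), en)
        else expect_equal(unname(bf$values[v]), en, tolerance = 1e-9)
      }
    }
  }
})

test_that("min-plus and max-min stabilize after |V| - 1 iterations", {
  set.seed(30)
  for (rep in 1:5) {
    g <- random_interaction_graph(7L, 10L)
    V <- n_nodes(g)
    ev <- sample(1:5, n_edges(g), TRUE)
    for (sr in list(sr_min_plus(), sr_max_min())) {
      vals <- lapply(0:(V + 1L), function(t)
        generalized_bellman_ford(g, g$nodes[1], sr, ev, t)$values)
      # monotone in T (improving in the plus order) and fixed after V - 1
      for (t in seq_len(V + 1L)) {
        cmp <- mapply(sr$plus, vals[[t]], vals[[t + 1L]])
        expect_equal(unname(cmp), unname(vals[[t + 1L]]))
      }
      expect_identical(vals[[V]], vals[[V + 2L]])
    }
  }
})

test_that("truncated Katz converges to the matrix resolvent", {
  set.seed(40)
  for (rep in 1:3) {
    g <- random_interaction_graph(6L, 9L)
    V <- n_nodes(g)
    A <- matrix(0, V, V); A[g$edges] <- 1; A <- A + t(A)
    beta <- 0.1
    closed <- solve(diag(V) - beta * A) - diag(V)
    kz <- classic_link_score(g, "katz", source = g$nodes[1],
                             iterations = 20, beta = beta)
    # engine includes the empty walk (score 1 at the source); the resolvent
    # series I + bA + (bA)^2 + ... minus I drops it
    got <- unname(kz$values) - as.numeric(seq_len(V) == 1L)
    expect_all_equal(got, closed[1, ], tol = 1e-6)
  }
})

test_that("personalized PageRank matches the damped power-series oracle", {
  set.seed(50)
  g <- random_interaction_graph(7L, 10L)
  V <- n_nodes(g)
  A <- matrix(0, V, V); A[g$edges] <- 1; A <- A + t(A)
  deg <- pmax(rowSums(A), 1)
  M <- A %*% diag(1 / deg)        # column-normalized walk matrix
  damp <- 0.85; T <- 15L
  h0 <- as.numeric(seq_len(V) == 2L)
  oracle <- numeric(V); P <- diag(V)
  for (t in 0:T) { oracle <- oracle + P %*% h0; P <- damp * M %*% P }
  oracle <- (1 - damp) * oracle
  pr <- classic_link_score(g, "personalized_pagerank", source = g$nodes[2],
                           iterations = T, damping = damp)
  expect_all_equal(unname(pr$values), as.numeric(oracle), tol = 1e-9)
})

test_that("widest path takes the max-min route", {
  # a-b capacity 5, b-c capacity 3, a-c capacity 2: best a->c width is 3
  g <- interaction_graph(c("a", "b", "c"), c("DNA", "PROTEIN", "DNA"),
                         rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  # stored edge order: (a,b), (a,c), (b,c)
  r <- classic_link_score(g, "widest_path", source = "a", iterations = 3,
                          edge_values = c(5, 2, 3))
  expect_equal(unname(r$values["c"]), 3)
})

test_that("scores are independent of edge insertion order", {
  set.seed(60)
  ids <- sprintf("n%d", 1:6)
  cls <- rep(c("DNA", "PROTEIN"), 3)
  ep <- rbind(c("n1", "n2"), c("n2", "n3"), c("n3", "n4"), c("n4", "n5"),
              c("n5", "n6"), c("n1", "n6"), c("n2", "n5"))
  g1 <- interaction_graph(ids, cls, ep)
  perm <- sample(nrow(ep))
  g2 <- interaction_graph(ids, cls, ep[perm, ])
  expect_identical(g1$edges, g2$edges)  # canonical storage
  r1 <- generalized_bellman_ford(g1, "n1", sr_sum_product(), 0.3, 4)
  r2 <- generalized_bellman_ford(g2, "n1", sr_sum_product(), 0.3, 4)
  expect_identical(r1$values, r2$values)
})

test_that("engine validates its inputs", {
  g <- path_graph()
  expect_error(generalized_bellman_ford(g, "a", sr_sum_product(), 1, -1),
               "nonnegative")
  expect_error(generalized_bellman_ford(g, "a", sr_sum_product(),
                                        c(1, NA), 2), "missing")
  expect_error(generalized_bellman_ford(g, "a", sr_sum_product(),
                                        c(1, 2, 3), 2), "length")
  expect_error(classic_link_score(g, "nope", source = "a", iterations = 1))
  expect_warning(classic_link_score(g, "katz", source = "a",
                                    iterations = 2, beta = 0.9),
                 "converge")
  expect_error(classic_link_score(g, "most_reliable_path", source = "a",
                                  iterations = 2, edge_values = c(0.5, 1.2)),
               "\\[0, 1\\]")
})
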