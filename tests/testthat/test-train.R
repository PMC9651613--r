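test_that("confusion counts match the definitions", {
  expect_equal(confusion(c(0.9, 0.2), c(1, 0)),
               c(TrP = 1L, TrN = 1L, FaP = 0L, FaN = 0L))
  expect_equal(confusion(c(0.9, 0.8), c(1, 0)),
               c(TrP = 1L, TrN = 0L, FaP = 1L, FaN = 0L))
  expect_equal(unname(confusion(c(0.99, 0.8), c(1, 0), threshold = 1)),
               c(0L, 1L, 0L, 1L))
  expect_error(confusion(numeric(0), integer(0)), "no predictions")
})

test_that("metrics and AUROC agree with the double-loop oracle", {
  set.seed(200)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    cc <- confusion(scores, labels)
    expect_identical(cc, oracle_confusion(scores, labels, 0.5))
    met <- compute_metrics(cc, scores, labels)
    expect_equal(met$auroc, oracle_auroc(scores, labels), tolerance = 1e-9)
    if (!is.na(met$PR)) expect_equal(met$PR, cc[["TrP"]] /
                                       (cc[["TrP"]] + cc[["FaP"]]))
    expect_equal(met$AC, (cc[["TrP"]] + cc[["TrN"]]) / n)
  }
})

test_that("MCC hits its corners and degenerate metrics are NA", {
  expect_equal(compute_metrics(c(TrP = 9, TrN = 0, FaP = 1, FaN = 0))$PR,
               0.9)
  expect_equal(compute_metrics(c(TrP = 25, TrN = 25, FaP = 25,
                                 FaN = 25))$MCC, 0)
  expect_equal(compute_metrics(c(TrP = 10, TrN = 10, FaP = 0,
                                 FaN = 0))$MCC, 1)
  expect_equal(compute_metrics(c(TrP = 0, TrN = 0, FaP = 10,
                                 FaN = 10))$MCC, -1)
  m <- compute_metrics(c(TrP = 0, TrN = 5, FaP = 0, FaN = 5))
  expect_true(is.na(m$PR))   # no predicted positives: PR undefined, not 0
  expect_equal(m$RE, 0)
  # MCC symmetric under simultaneous label/prediction flip
  a <- compute_metrics(c(TrP = 7, TrN = 3, FaP = 2, FaN = 4))$MCC
  b <- compute_metrics(c(TrP = 3, TrN = 7, FaP = 4, FaN = 2))$MCC
  expect_equal(a, b)
  expect_equal(auroc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  expect_true(is.na(auroc(c(0.9, 0.8), c(1, 1))))
})

test_that("zero learning rate leaves parameters unchanged", {
  dat <- generate_binding_graph(8, 8, f = 2, density = 0.25,
                                heldout_frac = 0, seed = 6)
  set.seed(6)
  sp <- kfold_split(dat$examples, 2)[[1]]
  set.seed(7)
  init <- init_model_params(d = 4, K = 3, depths = c(1, 1, 1),
                            graph = dat$graph)
  fit <- train(dat$graph, sp, train_config(epochs = 1, lr = 0, seed = 8,
                                           d = 4, K = 3,
                                           depths = c(1, 1, 1)),
               params = init)
  expect_identical(flatten_params(fit$params), flatten_params(init))
})

test_that("training is deterministic and decreases the loss on a toy graph", {
  dat <- generate_binding_graph(12, 12, f = 2, density = 0.3,
                                heldout_frac = 0, scale = 12, seed = 9)
  set.seed(9)
  sp <- kfold_split(dat$examples, 3)[[1]]
  cfg <- train_config(epochs = 6, seed = 10, d = 8, K = 4,
                      depths = c(1, 1, 1))
  f1 <- train(dat$graph, sp, cfg)
  f2 <- train(dat$graph, sp, cfg)
  expect_identical(f1$trace, f2$trace)     # bitwise-identical loss traces
  expect_lt(f1$trace[length(f1$trace)], f1$trace[1])
  expect_error(train(dat$graph, list(train = sp$train[sp$train$label == 0, ],
                                     test = sp$test),
                     cfg), "no positive")
})

test_that("cross-validation reports per-fold and mean metrics without leakage", {
  dat <- generate_binding_graph(10, 10, f = 2, density = 0.3,
                                heldout_frac = 0, seed = 12)
  cfg <- train_config(epochs = 1, seed = 13, k = 4, d = 4, K = 3,
                      depths = c(1, 1, 1))
  res <- cross_validate(dat$graph, dat$examples, cfg)
  expect_length(res$folds, 4L)
  expect_named(res$mean, c("PR", "RE", "AC", "MCC", "auroc"))
  for (i in seq_along(res$folds)) {
    f <- res$folds[[i]]
    expect_equal(f$TrP + f$TrN + f$FaP + f$FaN, nrow(res$scores[[i]]))
  }

  # leakage: per fold, the message graph must not contain test positives and
  # train/test example sets must be disjoint
  set.seed(cfg$seed)
  splits <- kfold_split(dat$examples, cfg$k)
  for (sp in splits) {
    cfg0 <- cfg; cfg0$epochs <- 0L
    fit <- train(dat$graph, sp, cfg0)
    gm_keys <- nbfbind:::edge_keys(fit$graph_msg)
    tp <- sp$test[sp$test$label == 1, ]
    tp_keys <- nbfbind:::pair_keys(fit$graph_msg, tp$u, tp$v)
    expect_length(intersect(gm_keys, tp_keys), 0L)
    expect_length(intersect(paste(sp$train$u, sp$train$v),
                            paste(sp$test$u, sp$test$v)), 0L)
  }
})

test_that("a perfect scorer yields perfect metrics and a random one ~0.5 AUROC", {
  set.seed(210)
  labels <- rbinom(400, 1, 0.5)
  perfect <- ifelse(labels == 1, 0.9, 0.1)
  met <- compute_metrics(confusion(perfect, labels), perfect, labels)
  expect_equal(met$AC, 1); expect_equal(met$MCC, 1)
  expect_equal(met$auroc, 1)
  rnd <- runif(400)
  met2 <- compute_metrics(confusion(rnd, labels), rnd, labels)
  expect_lt(abs(met2$auroc - 0.5), 0.12)
})

test_that("the S3 modelling interface fits, predicts and summarizes", {
  dat <- generate_binding_graph(10, 10, f = 2, density = 0.3,
                                heldout_frac = 0.1, seed = 14)
  fit <- nbf_fit(dat$graph, dat$examples, epochs = 2, d = 4, K = 3,
                 depths = c(1, 1, 1), seed = 15)
  expect_s3_class(fit, "dpb_nbfnet")
  expect_output(print(fit), "DPB-NBFnet")
  sm <- summary(fit)
  expect_s3_class(sm$train_metrics, "binding_metrics")
  pr <- predict(fit, dat$heldout)
  expect_true(all(pr$score >= 0 & pr$score <= 1))
  expect_length(residuals(fit), nrow(dat$examples))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(nrow(dat$examples), 2L))
  expect_type(coef(fit)$alphas, "double")
})
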