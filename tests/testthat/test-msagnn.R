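# Propagation operators, forward passes, gradients, training behavior.

toy_graph <- function(n = 6, seed = 33, d = 8) {
  tbl <- make_test_table(n, seed = seed, spread = 0.03)
  list(table = tbl, graph = build_fixed_graph(tbl, d = d, theta = 5))
}

test_that("normalized propagation matches hand and dense-algebra oracles", {
  # single node: the operator is the identity at every hop order
  single <- matrix(0, 1, 1)
  for (k in 1:3) expect_equal(normalized_propagation(single, k), matrix(1, 1, 1))

  # two nodes, one unit-weight edge, k = 1: all entries 0.5
  W2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(normalized_propagation(W2, 1), matrix(0.5, 2, 2))

  # k = 2 equals normalizing the explicit matrix square
  set.seed(14)
  tg <- toy_graph(8, seed = 14)
  Wg <- tg$graph$weights
  P2 <- (Wg + diag(8)) %*% (Wg + diag(8))
  Dm <- diag(1 / sqrt(rowSums(P2)))
  expect_equal(normalized_propagation(Wg, 2), Dm %*% P2 %*% Dm,
               tolerance = 1e-12)

  # symmetric, spectral radius <= 1, at every hop order
  for (k in 1:3) {
    S <- normalized_propagation(Wg, k)
    expect_equal(S, t(S))
    expect_lte(max(abs(eigen(S, only.values = TRUE)$values)), 1 + 1e-10)
  }
})

test_that("multi-scale convolution has the contracted shapes and zero/identity limits", {
  tg <- toy_graph(5)
  cfg <- msagnn_config(hidden_dim = 4, seed = 1)
  set.seed(2)
  params <- soilgnn:::init_params(cfg, 7)
  H0 <- matrix(rnorm(35), 5, 7)
  H <- msgcn_forward(H0, tg$graph, params, cfg)
  expect_equal(dim(H), c(5, 12))  # 3 branches x hidden_dim
  expect_true(all(H >= 0))

  # all-zero input stays zero (no bias terms in the branches)
  expect_equal(msgcn_forward(H0 * 0, tg$graph, params, cfg),
               matrix(0, 5, 12))

  # single node with identity weights: S_k = 1, output is ReLU([H0|H0|H0])
  one <- make_test_table(2, seed = 3)[1:2, ]
  one$latitude <- c(0, 0); one$longitude <- c(0, 90)
  g1 <- build_fixed_graph(one, d = 1, theta = 5)  # repair edge, weight ~0
  cfg1 <- msagnn_config(hidden_dim = 3, seed = 1)
  p1 <- soilgnn:::init_params(cfg1, 3)
  p1$W1 <- p1$W2 <- p1$W3 <- diag(3)
  X1 <- matrix(c(1, -2, 3, -1, 2, -3), 2, 3, byrow = TRUE)
  g_iso <- g1; g_iso$weights <- matrix(0, 2, 2); g_iso$adjacency <- matrix(0, 2, 2)
  out <- msgcn_forward(X1, g_iso, p1, cfg1)
  expect_equal(out, pmax(cbind(X1, X1, X1), 0), ignore_attr = TRUE)
})

test_that("attention rows are a softmax over the self-inclusive neighborhood", {
  tg <- toy_graph(7, seed = 41)
  cfg <- msagnn_config(use_msgcn = FALSE, attention_dim = 5, seed = 4)
  set.seed(4)
  params <- soilgnn:::init_params(cfg, 6)
  H <- matrix(rnorm(42), 7, 6)
  res <- agnn_forward(H, tg$graph, params, cfg)
  expect_equal(rowSums(res$alpha), rep(1, 7), tolerance = 1e-6)
  mask <- tg$graph$adjacency > 0 | diag(7) > 0
  expect_true(all(res$alpha[!mask] == 0))

  # two neighbors with identical features receive identical weights
  H2 <- H
  H2[2, ] <- H2[3, ]
  g <- tg$graph
  g$adjacency <- matrix(0, 7, 7)
  g$adjacency[1, 2] <- g$adjacency[2, 1] <- 1
  g$adjacency[1, 3] <- g$adjacency[3, 1] <- 1
  res2 <- agnn_forward(H2, g, params, cfg)
  expect_equal(res2$alpha[1, 2], res2$alpha[1, 3], tolerance = 1e-12)
})

test_that("attention output matches a per-edge brute-force oracle", {
  tg <- toy_graph(4, seed = 52, d = 30)
  cfg <- msagnn_config(use_msgcn = FALSE, attention_dim = 3,
                       leaky_relu_slope = 0.2, seed = 9)
  set.seed(9)
  params <- soilgnn:::init_params(cfg, 5)
  H <- matrix(rnorm(20), 4, 5)
  res <- agnn_forward(H, tg$graph, params, cfg)

  lrelu <- function(x) ifelse(x > 0, x, 0.2 * x)
  P <- H %*% params$Wa
  mask <- tg$graph$adjacency > 0 | diag(4) > 0
  expected <- matrix(0, 4, 3)
  for (i in 1:4) {
    nb <- which(mask[i, ])
    scores <- vapply(nb, function(j) {
      lrelu(sum(params$a1 * P[i, ]) + sum(params$a2 * P[j, ]))
    }, numeric(1))
    alpha <- exp(scores - max(scores))
    alpha <- alpha / sum(alpha)
    for (t in seq_along(nb)) {
      expected[i, ] <- expected[i, ] + alpha[t] * P[nb[t], ]
    }
    expect_equal(res$alpha[i, nb], alpha, tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_equal(res$h, expected, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  tg <- toy_graph(5, seed = 66)
  cfg <- msagnn_config(hidden_dim = 3, attention_dim = 3, seed = 5,
                       target = "cd")
  set.seed(5)
  X <- matrix(rnorm(20), 5, 4)
  y <- rnorm(5)
  ops <- soilgnn:::graph_operators(tg$graph, cfg)
  params <- soilgnn:::init_params(cfg, 4)
  batch <- c(1, 3, 4)

  loss_fn <- function(p) {
    cache <- soilgnn:::forward_cache(p, cfg, X, ops)
    mean((cache$yhat[batch] - y[batch])^2)
  }
  cache <- soilgnn:::forward_cache(params, cfg, X, ops)
  dyhat <- numeric(5)
  dyhat[batch] <- 2 * (cache$yhat[batch] - y[batch]) / length(batch)
  grads <- soilgnn:::backward_pass(params, cfg, ops, cache, dyhat)

  eps <- 1e-6
  for (name in names(grads)) {
    g_num <- params[[name]] * 0
    for (idx in seq_along(params[[name]])) {
      up <- params; up[[name]][idx] <- up[[name]][idx] + eps
      dn <- params; dn[[name]][idx] <- dn[[name]][idx] - eps
      g_num[idx] <- (loss_fn(up) - loss_fn(dn)) / (2 * eps)
    }
    expect_equal(grads[[name]], g_num, tolerance = 1e-4, label = name)
  }
})

test_that("the full forward pass is permutation equivariant", {
  tg <- toy_graph(9, seed = 71)
  cfg <- msagnn_config(hidden_dim = 4, epochs = 5, seed = 6)
  model <- train_msagnn(tg$table, tg$graph, 1:9, cfg)
  pred <- model_forward(model, tg$table, tg$graph)

  set.seed(1)
  perm <- sample(9)
  tbl_p <- tg$table[perm, ]
  g_p <- build_fixed_graph(tbl_p, d = 8, theta = 5)
  pred_p <- model_forward(model, tbl_p, g_p)
  expect_equal(pred_p, pred[perm], tolerance = 1e-6)
})

test_that("head-only degenerate forms and checkpoint identity hold", {
  tg <- toy_graph(6, seed = 81)
  cfg <- msagnn_config(hidden_dim = 3, epochs = 3, seed = 7)
  model <- train_msagnn(tg$table, tg$graph, 1:6, cfg)

  # zero-weight head: every prediction is the (de-standardized) head bias
  zero_model <- model
  zero_model$params$w_out <- zero_model$params$w_out * 0
  pred <- model_forward(zero_model, tg$table, tg$graph)
  expect_equal(pred, rep(zero_model$params$b_out[1, 1] * zero_model$y_scale +
                         zero_model$y_center, 6))

  # save/load gives bit-identical predictions
  path <- withr::local_tempfile(fileext = ".rds")
  save_msagnn(model, path)
  reloaded <- load_msagnn(path)
  expect_identical(model_forward(reloaded, tg$table, tg$graph),
                   model_forward(model, tg$table, tg$graph))

  # a duplicated node (same features, same neighbors) predicts identically
  tbl <- tg$table
  dup <- tbl[c(1:6, 3), ]
  dup$sample_id <- as.character(1:7)
  g7 <- build_fixed_graph(dup, d = 8, theta = 5)
  p7 <- model_forward(model, dup, g7)
  expect_equal(p7[7], p7[3], tolerance = 1e-10)

  expect_error(msagnn_config(use_msgcn = FALSE, use_agnn = FALSE),
               "configuration error")
})

test_that("training reduces loss, fits recoverable signal, and is reproducible", {
  set.seed(100)
  tbl <- make_test_table(50, seed = 100, spread = 0.05)
  graph <- build_fixed_graph(tbl, d = 10, theta = 5)

  # constant targets: loss falls and predictions approach the constant
  tbl_const <- tbl
  tbl_const$cd <- rep(3, 50)
  cfg <- msagnn_config(hidden_dim = 8, epochs = 40, seed = 11)
  m_const <- train_msagnn(tbl_const, graph, 1:40, cfg)
  expect_lt(utils::tail(m_const$history$train_mse, 1),
            m_const$history$train_mse[1])
  pred <- model_forward(m_const, tbl_const, graph)
  expect_lt(max(abs(pred - 3)), 1.5)

  # a node-local linear target is recovered with high training R^2 on the
  # self-only graph (neighbor averaging would blur a purely local signal)
  tbl_lin <- tbl
  tbl_lin$cd <- 2 + 0.5 * scale(tbl$ph)[, 1] - 0.8 * scale(tbl$cec)[, 1]
  g_self <- identity_graph(tbl_lin)
  cfg_lin <- msagnn_config(hidden_dim = 8, epochs = 150, seed = 12)
  m_lin <- train_msagnn(tbl_lin, g_self, 1:50, cfg_lin)
  fit <- model_forward(m_lin, tbl_lin, g_self)
  expect_gt(regression_metrics(fit, tbl_lin$cd)$r2, 0.9)

  # same seed, same data: bit-identical loss histories
  m_a <- train_msagnn(tbl_lin, graph, 1:40, cfg)
  m_b <- train_msagnn(tbl_lin, graph, 1:40, cfg)
  expect_identical(m_a$history, m_b$history)

  # non-finite training targets are rejected
  tbl_na <- tbl
  tbl_na$cd[2] <- NA
  expect_error(train_msagnn(tbl_na, graph, 1:10, cfg), "non-finite target")
})
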