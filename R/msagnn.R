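# The multi-scale attention graph regressor: configuration, normalized
# multi-hop propagation operators, multi-scale graph convolution, softmax
# attention aggregation, training (mini-batch Adam) and prediction.

#' Model configuration
#'
#' @param hidden_dim Width of each graph-convolution branch (default 8,
#'   sized for surveys of a few hundred sites; wider branches overfit
#'   node-local noise at this scale).
#' @param attention_dim Width of the attention projection (default 8).
#' @param leaky_relu_slope Negative slope of the attention score activation
#'   (default 0.2, the usual attention-network convention).
#' @param use_msgcn,use_agnn Ablation flags; at least one must be `TRUE`.
#'   With `use_msgcn = FALSE` the attention layer reads the raw encoded
#'   features; with `use_agnn = FALSE` the merged convolution output feeds
#'   the head directly.
#' @param merge How the three branch outputs are merged: `"concat"`
#'   (default) or `"sum"`.
#' @param learning_rate Adam learning rate (default 0.001).
#' @param epochs Training epochs (default 100).
#' @param batch_size Nodes per mini-batch (default 8); each step still
#'   propagates over the full graph, the loss is restricted to the batch.
#' @param seed Seed controlling initialization and batch shuffling.
#' @param target Target column, `"cd"` or `"pb"` (one model per metal).
#' @return Object of class `msagnn_config`.
#' @export
msagnn_config <- function(hidden_dim = 8, attention_dim = 8,
                          leaky_relu_slope = 0.2,
                          use_msgcn = TRUE, use_agnn = TRUE,
                          merge = c("concat", "sum"),
                          learning_rate = 0.001, epochs = 100,
                          batch_size = 8, seed = 1L,
                          target = c("cd", "pb")) {
  merge <- match.arg(merge)
  target <- match.arg(target)
  stopifnot(hidden_dim >= 1, attention_dim >= 1, epochs >= 1, batch_size >= 1,
            learning_rate > 0)
  if (!use_msgcn && !use_agnn) {
    stop("configuration error: at least one of use_msgcn/use_agnn must be TRUE")
  }
  structure(
    list(hidden_dim = hidden_dim, attention_dim = attention_dim,
         leaky_relu_slope = leaky_relu_slope,
         use_msgcn = use_msgcn, use_agnn = use_agnn, merge = merge,
         learning_rate = learning_rate, epochs = epochs,
         batch_size = batch_size, seed = as.integer(seed), target = target),
    class = "msagnn_config"
  )
}

#' Symmetrically normalized k-hop propagation operator
#'
#' With self-looped weighted adjacency `Ahat = A_w + I`, forms
#' `P_k = Ahat^k` and returns `S_k = D_k^(-1/2) P_k D_k^(-1/2)` where
#' `D_k` holds the row sums of `P_k`. `S_k` is symmetric with spectral
#' radius at most 1; k = 1, 2, 3 give the small, medium and large
#' receptive fields of the multi-scale convolution.
#'
#' @param weights Symmetric non-negative weighted adjacency (zero diagonal).
#' @param k Hop order (1, 2 or 3).
#' @return The n x n operator `S_k`.
#' @export
normalized_propagation <- function(weights, k) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights),
            k %in% 1:3, all(weights >= 0))
  n <- nrow(weights)
  ahat <- weights + diag(n)
  P <- ahat
  if (k >= 2) for (i in seq_len(k - 1)) P <- P %*% ahat
  deg <- rowSums(P)
  if (any(deg <= 0)) stop("zero row sum in propagation operator")  # impossible with self-loops
  inv_sqrt <- 1 / sqrt(deg)
  S <- P * (inv_sqrt %o% inv_sqrt)
  (S + t(S)) / 2  # enforce exact symmetry against fp drift
}

leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)

init_params <- function(config, n_features) {
  h <- config$hidden_dim
  q <- config$attention_dim
  glorot <- function(nr, nc) {
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
  }
  params <- list()
  att_in <- n_features
  if (config$use_msgcn) {
    for (k in 1:3) params[[paste0("W", k)]] <- glorot(n_features, h)
    att_in <- if (config$merge == "concat") 3L * h else h
  }
  head_in <- att_in
  if (config$use_agnn) {
    params$Wa <- glorot(att_in, q)
    # small attention vectors: early passes are near-uniform averaging
    params$a1 <- matrix(stats::rnorm(q, sd = 0.1), q, 1)
    params$a2 <- matrix(stats::rnorm(q, sd = 0.1), q, 1)
    head_in <- q
  }
  params$w_out <- matrix(stats::rnorm(head_in, sd = sqrt(1 / head_in)), head_in, 1)
  params$b_out <- matrix(0, 1, 1)
  params
}

# Graph-dependent operators used by every forward pass.
graph_operators <- function(graph, config) {
  S_list <- NULL
  if (config$use_msgcn) {
    S_list <- lapply(1:3, function(k) normalized_propagation(graph$weights, k))
  }
  mask <- (graph$adjacency > 0) | diag(graph$n) > 0  # attention N~(i) = N(i) U {i}
  list(S_list = S_list, mask = mask)
}

#' Multi-scale graph convolution forward pass
#'
#' Computes the three branch outputs `H_k = S_k H0 W_k` for hop orders
#' k = 1..3, merges them (concatenation by default) and applies a ReLU:
#' the multi-scale feature map.
#'
#' @param H0 Node feature matrix (rows aligned with graph nodes).
#' @param graph A `soil_graph` (or a precomputed operator list).
#' @param params Parameter list with `W1`, `W2`, `W3`.
#' @param config A `msagnn_config`.
#' @return Matrix of width `3 * hidden_dim` (concat) or `hidden_dim` (sum).
#' @export
msgcn_forward <- function(H0, graph, params, config) {
  ops <- if (inherits(graph, "soil_graph")) graph_operators(graph, config) else graph
  fwd <- msgcn_forward_cache(H0, ops$S_list, params, config)
  fwd$H_ms
}

msgcn_forward_cache <- function(H0, S_list, params, config) {
  SX <- lapply(1:3, function(k) S_list[[k]] %*% H0)
  Z <- lapply(1:3, function(k) SX[[k]] %*% params[[paste0("W", k)]])
  M <- if (config$merge == "concat") do.call(cbind, Z) else Z[[1]] + Z[[2]] + Z[[3]]
  list(H_ms = pmax(M, 0), M = M, SX = SX)
}

#' Attention aggregation forward pass
#'
#' For each node i and its self-inclusive neighborhood, scores
#' `e_ij = LeakyReLU(a^T [W h_i || W h_j])` are softmax-normalized into
#' attention weights `alpha_ij` (each row sums to 1) and the new node
#' feature is the attention-weighted sum of the projected neighbor
#' features `sum_j alpha_ij W h_j`.
#'
#' @param H Node feature matrix.
#' @param graph A `soil_graph` (or precomputed operator list).
#' @param params Parameter list with `Wa`, `a1`, `a2` (the two halves of
#'   the attention vector acting on the target and neighbor projections).
#' @param config A `msagnn_config`.
#' @return List with `h` (aggregated features) and `alpha` (the attention
#'   matrix; zero outside the self-inclusive neighborhood).
#' @export
agnn_forward <- function(H, graph, params, config) {
  ops <- if (inherits(graph, "soil_graph")) graph_operators(graph, config) else graph
  fwd <- agnn_forward_cache(H, ops$mask, params, config)
  list(h = fwd$O, alpha = fwd$alpha)
}

agnn_forward_cache <- function(H, mask, params, config) {
  P <- H %*% params$Wa
  u <- drop(P %*% params$a1)
  v <- drop(P %*% params$a2)
  n <- nrow(P)
  s <- matrix(u, n, n) + matrix(v, n, n, byrow = TRUE)
  e <- leaky_relu(s, config$leaky_relu_slope)
  e_masked <- ifelse(mask, e, -Inf)
  row_max <- apply(e_masked, 1, max)
  ex <- exp(e_masked - row_max)
  ex[!mask] <- 0
  alpha <- ex / rowSums(ex)
  O <- alpha %*% P
  list(O = O, alpha = alpha, P = P, s = s)
}

forward_cache <- function(params, config, X, ops) {
  cache <- list(X = X)
  H <- X
  if (config$use_msgcn) {
    cache$ms <- msgcn_forward_cache(X, ops$S_list, params, config)
    H <- cache$ms$H_ms
  }
  cache$H <- H
  if (config$use_agnn) {
    cache$ag <- agnn_forward_cache(H, ops$mask, params, config)
    O <- cache$ag$O
  } else {
    O <- H
  }
  cache$O <- O
  cache$yhat <- drop(O %*% params$w_out) + params$b_out[1, 1]
  cache
}

backward_pass <- function(params, config, ops, cache, dyhat) {
  grads <- list()
  dyhat <- matrix(dyhat, ncol = 1)
  grads$w_out <- t(cache$O) %*% dyhat
  grads$b_out <- matrix(sum(dyhat), 1, 1)
  dO <- dyhat %*% t(params$w_out)
  if (config$use_agnn) {
    ag <- cache$ag
    P <- ag$P; alpha <- ag$alpha
    dalpha <- dO %*% t(P)
    dP <- t(alpha) %*% dO
    ds <- alpha * (dalpha - rowSums(alpha * dalpha))
    ds <- ds * ifelse(ag$s > 0, 1, config$leaky_relu_slope)
    du <- rowSums(ds)
    dv <- colSums(ds)
    grads$a1 <- t(P) %*% matrix(du, ncol = 1)
    grads$a2 <- t(P) %*% matrix(dv, ncol = 1)
    dP <- dP + du %o% drop(params$a1) + dv %o% drop(params$a2)
    grads$Wa <- t(cache$H) %*% dP
    dH <- dP %*% t(params$Wa)
  } else {
    dH <- dO
  }
  if (config$use_msgcn) {
    ms <- cache$ms
    dM <- dH * (ms$M > 0)
    h <- config$hidden_dim
    for (k in 1:3) {
      dMk <- if (config$merge == "concat") {
        dM[, ((k - 1) * h + 1):(k * h), drop = FALSE]
      } else {
        dM
      }
      grads[[paste0("W", k)]] <- t(ms$SX[[k]]) %*% dMk
    }
  }
  grads
}

#' Full model forward pass
#'
#' Encodes the table with the model's fitted encoder, runs the configured
#' stages (multi-scale convolution, attention, linear head) over the graph
#' and returns per-node predictions on the original mg/kg scale.
#'
#' @param model A fitted `msagnn_model`.
#' @param table Sample table whose rows align with the graph nodes.
#' @param graph A `soil_graph` over those nodes.
#' @param detail If `TRUE`, also return the attention matrix and hidden
#'   feature maps.
#' @return Numeric vector of predictions, or (with `detail`) a list with
#'   `prediction`, `alpha`, `h_ms`.
#' @export
model_forward <- function(model, table, graph, detail = FALSE) {
  stopifnot(inherits(model, "msagnn_model"))
  X <- encode_features(model$encoder, table)
  ops <- graph_operators(graph, model$config)
  cache <- forward_cache(model$params, model$config, X, ops)
  pred <- cache$yhat * model$y_scale + model$y_center
  if (!detail) return(pred)
  list(prediction = pred,
       alpha = if (model$config$use_agnn) cache$ag$alpha else NULL,
       h_ms = if (model$config$use_msgcn) cache$ms$H_ms else NULL)
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (name in names(grads)) {
    g <- grads[[name]]
    state$m[[name]] <- beta1 * state$m[[name]] + (1 - beta1) * g
    state$v[[name]] <- beta2 * state$v[[name]] + (1 - beta2) * g^2
    mhat <- state$m[[name]] / (1 - beta1^t)
    vhat <- state$v[[name]] / (1 - beta2^t)
    params[[name]] <- params[[name]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the graph regressor
#'
#' Mini-batch training: per epoch the training nodes are shuffled
#' (seeded) and partitioned into batches of `batch_size`; each step runs a
#' full-graph forward pass, takes the mean squared error over the batch
#' nodes (targets standardized internally on the training nodes) and
#' applies an Adam update. With a fixed seed and single-threaded BLAS the
#' loss history is bit-reproducible.
#'
#' @param table Sample table containing the target column.
#' @param graph `soil_graph` over the table rows.
#' @param train_index Training node indices; their targets must be finite.
#' @param config A [msagnn_config()].
#' @param encoder Optional pre-fitted encoder; by default one is fitted on
#'   the training rows only.
#' @return Object of class `msagnn_model`: parameters, encoder, target
#'   scaling, config and `history` (per-epoch training MSE on the
#'   standardized scale).
#' @export
train_msagnn <- function(table, graph, train_index, config, encoder = NULL) {
  stopifnot(inherits(config, "msagnn_config"))
  y_raw <- table[[config$target]]
  if (is.null(y_raw)) stop("target column '", config$target, "' missing")
  if (any(!is.finite(y_raw[train_index]))) {
    stop("non-finite target values among training nodes")
  }
  if (is.null(encoder)) encoder <- fit_feature_encoder(table, train_index)
  X <- encode_features(encoder, table)
  y_center <- mean(y_raw[train_index])
  y_scale <- stats::sd(y_raw[train_index])
  if (!is.finite(y_scale) || y_scale < 1e-8) y_scale <- 1
  y <- (y_raw - y_center) / y_scale

  ops <- graph_operators(graph, config)
  set.seed(config$seed)
  params <- init_params(config, ncol(X))
  state <- list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0)
  )
  t_step <- 0L
  n_train <- length(train_index)
  history <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    order_idx <- train_index[sample.int(n_train)]
    batches <- split(order_idx, ceiling(seq_len(n_train) / config$batch_size))
    for (b in seq_along(batches)) {
      batch <- batches[[b]]
      cache <- forward_cache(params, config, X, ops)
      resid <- cache$yhat[batch] - y[batch]
      loss <- mean(resid^2)
      if (!is.finite(loss)) {
        stop("non-finite loss at epoch ", epoch, ", batch ", b)
      }
      dyhat <- numeric(graph$n)
      dyhat[batch] <- 2 * resid / length(batch)
      grads <- backward_pass(params, config, ops, cache, dyhat)
      t_step <- t_step + 1L
      upd <- adam_step(params, grads, state, config$learning_rate, t_step)
      params <- upd$params
      state <- upd$state
    }
    cache <- forward_cache(params, config, X, ops)
    history[epoch] <- mean((cache$yhat[train_index] - y[train_index])^2)
  }
  structure(
    list(config = config, encoder = encoder, params = params,
         y_center = y_center, y_scale = y_scale,
         n_features = ncol(X),
         history = data.frame(epoch = seq_len(config$epochs),
                              train_mse = history)),
    class = "msagnn_model"
  )
}

#' @export
print.msagnn_model <- function(x, ...) {
  cat(sprintf(
    "Graph regressor for %s: msgcn=%s agnn=%s hidden=%d, %d epochs, final train MSE %.4g\n",
    x$config$target, x$config$use_msgcn, x$config$use_agnn,
    x$config$hidden_dim, x$config$epochs, utils::tail(x$history$train_mse, 1)))
  invisible(x)
}

#' Predict with a fitted model
#'
#' @param object A `msagnn_model`.
#' @param table Sample table aligned with `graph` nodes.
#' @param graph A `soil_graph`.
#' @param ... Unused.
#' @return Numeric vector of per-node predictions (mg/kg).
#' @export
predict.msagnn_model <- function(object, table, graph, ...) {
  model_forward(object, table, graph)
}

#' Save / load a model checkpoint
#'
#' A single-file native-serialization checkpoint holding the parameters,
#' encoder, target scaling and configuration; reloading gives bit-identical
#' predictions.
#'
#' @param model A `msagnn_model`.
#' @param path Checkpoint path.
#' @return `path` invisibly (save); the model (load).
#' @export
save_msagnn <- function(model, path) {
  stopifnot(inherits(model, "msagnn_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_msagnn
#' @export
load_msagnn <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "msagnn_model")) stop("not a model checkpoint: ", path)
  model
}

#' Write the per-epoch training loss as CSV
#'
#' @param model A fitted `msagnn_model`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_training_log_csv <- function(model, path) {
  utils::write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}
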