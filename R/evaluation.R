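# Evaluation protocol: regression metrics, repeated random splits, nested
# cross-validation, ablation runner, permutation feature importance, and
# prediction at new locations.

#' Regression metrics: MAE, RMSE, R-squared
#'
#' `mae = mean(|P - O|)`, `rmse = sqrt(mean((O - P)^2))` and the standard
#' coefficient of determination `r2 = 1 - SSE/SST` with
#' `SST = sum((O - mean(O))^2)`. `r2_form = "printed"` substitutes
#' `sum((P - mean(O))^2)` for the SSE numerator — a nonstandard variant
#' kept only for comparison.
#'
#' @param predicted,observed Equal-length finite numeric vectors, n >= 2.
#' @param r2_form `"standard"` (default) or `"printed"`.
#' @return List with `mae`, `rmse`, `r2` and `r2_defined` (`FALSE`, with
#'   `r2 = NA`, when the observations have zero variance).
#' @export
regression_metrics <- function(predicted, observed,
                               r2_form = c("standard", "printed")) {
  r2_form <- match.arg(r2_form)
  stopifnot(length(predicted) == length(observed), length(observed) >= 2)
  if (any(!is.finite(predicted)) || any(!is.finite(observed))) {
    stop("predictions and observations must be finite")
  }
  err <- observed - predicted
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) {
    return(list(mae = mae, rmse = rmse, r2 = NA_real_, r2_defined = FALSE))
  }
  num <- if (r2_form == "standard") sum(err^2) else sum((predicted - mean(observed))^2)
  list(mae = mae, rmse = rmse, r2 = 1 - num / sst, r2_defined = TRUE)
}

resolve_graph <- function(table, graph_params) {
  if (isTRUE(graph_params$identity)) return(identity_graph(table))
  d <- if (is.null(graph_params$d)) 10 else graph_params$d
  theta <- if (is.null(graph_params$theta)) 5 else graph_params$theta
  if (!is.null(graph_params$labels)) {
    build_parent_material_graph(table, d = d, theta = theta,
                                labels = graph_params$labels)
  } else {
    build_fixed_graph(table, d = d, theta = theta)
  }
}

split_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

new_eval_report <- function(splits, protocol, target) {
  agg <- data.frame(
    metric = c("mae", "rmse", "r2"),
    mean = c(mean(splits$mae), mean(splits$rmse), mean(splits$r2)),
    sd = c(stats::sd(splits$mae), stats::sd(splits$rmse), stats::sd(splits$r2))
  )
  structure(list(splits = splits, aggregate = agg, protocol = protocol,
                 target = target),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation (", x$protocol, ", target ", x$target, "):\n", sep = "")
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}

#' Repeated random train/test splits
#'
#' For each repeat (seeded from `seed`) the nodes are split 80/20 by
#' default, the encoder and model are fitted on the training nodes only,
#' and MAE/RMSE/R-squared are measured on the held-out nodes. The graph is
#' built once over all sites (positions carry no target information);
#' splits with fewer than 2 test nodes are redrawn.
#'
#' @param table Sample table with the target column.
#' @param graph_params List with `d`, `theta`, optional `labels`
#'   (environmental-type masking) or `identity = TRUE` (covariate-only
#'   baseline); ignored when `graph` is supplied.
#' @param config A [msagnn_config()].
#' @param n_repeats Number of independent splits (default 100).
#' @param train_fraction Training fraction (default 0.8).
#' @param seed Master seed for the whole protocol.
#' @param graph Optional prebuilt `soil_graph`.
#' @return An `eval_report` with per-split records and mean/sd aggregates.
#' @export
repeated_random_splits <- function(table, graph_params = list(), config,
                                   n_repeats = 100, train_fraction = 0.8,
                                   seed = 1L, graph = NULL) {
  if (is.null(graph)) graph <- resolve_graph(table, graph_params)
  n <- nrow(table)
  seeds <- split_seeds(seed, n_repeats)
  rows <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    set.seed(seeds[r])
    repeat {
      train_index <- sort(sample.int(n, round(train_fraction * n)))
      test_index <- setdiff(seq_len(n), train_index)
      if (length(test_index) >= 2 && length(train_index) >= 2) break
      message("degenerate split redrawn (repeat ", r, ")")
    }
    cfg <- config
    cfg$seed <- seeds[r]
    model <- train_msagnn(table, graph, train_index, cfg)
    pred <- model_forward(model, table, graph)
    m <- regression_metrics(pred[test_index], table[[config$target]][test_index])
    rows[[r]] <- data.frame(split = r, seed = seeds[r], mae = m$mae,
                            rmse = m$rmse, r2 = m$r2,
                            n_test = length(test_index))
  }
  new_eval_report(do.call(rbind, rows),
                  protocol = sprintf("%d repeats, %.0f/%.0f split", n_repeats,
                                     100 * train_fraction,
                                     100 * (1 - train_fraction)),
                  target = config$target)
}

make_folds <- function(n, k) {
  idx <- sample.int(n)
  split(idx, rep_len(seq_len(k), n)[order(seq_len(n))])  # balanced fold sizes
}

#' Nested cross-validation with inner hyperparameter selection
#'
#' Outer folds are each held out once; within every outer training set,
#' inner folds score every grid cell (`hidden_dim`, graph radius `d`) by
#' mean inner RMSE, the winning configuration is refitted on the full
#' outer training set, and test metrics are pooled over the outer folds.
#'
#' @param table Sample table.
#' @param graph_params Base graph parameters (theta, labels); `d` comes
#'   from the grid.
#' @param config Base model configuration.
#' @param outer_k,inner_k Fold counts (defaults 10 and 3).
#' @param grid Data.frame of candidate settings with columns `hidden_dim`
#'   and `d`; default `expand.grid(hidden_dim = c(32, 64), d = c(5, 10, 20))`.
#' @param seed Master seed.
#' @return An `eval_report`; per-fold records carry the selected
#'   hyperparameters, and `pooled` holds metrics over the concatenated
#'   outer-fold predictions.
#' @export
nested_cross_validation <- function(table, graph_params = list(), config,
                                    outer_k = 10, inner_k = 3,
                                    grid = expand.grid(hidden_dim = c(32, 64),
                                                       d = c(5, 10, 20)),
                                    seed = 1L) {
  if (is.null(grid) || nrow(grid) == 0) stop("configuration error: empty grid")
  n <- nrow(table)
  stopifnot(n >= outer_k)
  theta <- if (is.null(graph_params$theta)) 5 else graph_params$theta
  graph_for_d <- local({
    cache <- list()
    function(d) {
      key <- as.character(d)
      if (is.null(cache[[key]])) {
        gp <- graph_params
        gp$d <- d
        gp$theta <- theta
        cache[[key]] <<- resolve_graph(table, gp)
      }
      cache[[key]]
    }
  })
  set.seed(seed)
  outer_folds <- make_folds(n, outer_k)
  fold_seeds <- sample.int(.Machine$integer.max - 1L, outer_k)
  rows <- vector("list", outer_k)
  pooled_pred <- pooled_obs <- numeric(0)
  for (f in seq_len(outer_k)) {
    test_index <- sort(outer_folds[[f]])
    outer_train <- setdiff(seq_len(n), test_index)
    set.seed(fold_seeds[f])
    inner_folds <- make_folds(length(outer_train), min(inner_k, length(outer_train)))
    grid_rmse <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      graph <- graph_for_d(grid$d[g])
      inner_scores <- numeric(length(inner_folds))
      for (i in seq_along(inner_folds)) {
        val_index <- outer_train[inner_folds[[i]]]
        fit_index <- setdiff(outer_train, val_index)
        cfg <- config
        cfg$hidden_dim <- grid$hidden_dim[g]
        cfg$seed <- fold_seeds[f]
        model <- train_msagnn(table, graph, fit_index, cfg)
        pred <- model_forward(model, table, graph)
        inner_scores[i] <- regression_metrics(
          pred[val_index], table[[config$target]][val_index])$rmse
      }
      grid_rmse[g] <- mean(inner_scores)
    }
    best <- which.min(grid_rmse)
    graph <- graph_for_d(grid$d[best])
    cfg <- config
    cfg$hidden_dim <- grid$hidden_dim[best]
    cfg$seed <- fold_seeds[f]
    model <- train_msagnn(table, graph, outer_train, cfg)
    pred <- model_forward(model, table, graph)
    m <- regression_metrics(pred[test_index], table[[config$target]][test_index])
    rows[[f]] <- data.frame(split = f, seed = fold_seeds[f], mae = m$mae,
                            rmse = m$rmse, r2 = m$r2,
                            n_test = length(test_index),
                            hidden_dim = grid$hidden_dim[best],
                            d = grid$d[best])
    pooled_pred <- c(pooled_pred, pred[test_index])
    pooled_obs <- c(pooled_obs, table[[config$target]][test_index])
  }
  report <- new_eval_report(
    do.call(rbind, rows),
    protocol = sprintf("nested CV, %d outer x %d inner folds", outer_k, inner_k),
    target = config$target)
  report$pooled <- regression_metrics(pooled_pred, pooled_obs)
  report
}

#' Ablation runner: full model vs single-component variants
#'
#' Evaluates the full model, the convolution-only variant (attention
#' ablated) and the attention-only variant (multi-scale convolution
#' ablated) under an identical split schedule — the same master seed drives
#' every arm, so per-split records are paired.
#'
#' @param table Sample table.
#' @param graph_params Graph parameters as in [repeated_random_splits()].
#' @param config Base configuration (its ablation flags are overridden).
#' @param n_repeats Splits per arm (default 20).
#' @param seed Master seed shared by the arms.
#' @return List with `summary` (variant x mean metrics), `reports` (one
#'   `eval_report` per variant) and `per_split` (long data.frame).
#' @export
run_ablation <- function(table, graph_params = list(), config,
                         n_repeats = 20, seed = 1L) {
  variants <- list(
    full = c(msgcn = TRUE, agnn = TRUE),
    msgcn_only = c(msgcn = TRUE, agnn = FALSE),
    agnn_only = c(msgcn = FALSE, agnn = TRUE)
  )
  graph <- resolve_graph(table, graph_params)
  reports <- lapply(names(variants), function(v) {
    cfg <- config
    cfg$use_msgcn <- unname(variants[[v]]["msgcn"])
    cfg$use_agnn <- unname(variants[[v]]["agnn"])
    repeated_random_splits(table, config = cfg, n_repeats = n_repeats,
                           seed = seed, graph = graph)
  })
  names(reports) <- names(variants)
  summary <- do.call(rbind, lapply(names(reports), function(v) {
    agg <- reports[[v]]$aggregate
    data.frame(variant = v, mae = agg$mean[agg$metric == "mae"],
               rmse = agg$mean[agg$metric == "rmse"],
               r2 = agg$mean[agg$metric == "r2"])
  }))
  per_split <- do.call(rbind, lapply(names(reports), function(v) {
    cbind(variant = v, reports[[v]]$splits)
  }))
  list(summary = summary, reports = reports, per_split = per_split)
}

#' Permutation feature importance
#'
#' For each original predictor, its values are permuted over the
#' evaluation nodes (a categorical column's one-hot block moves jointly,
#' since the permutation happens before encoding), the model's RMSE on
#' those nodes is recomputed, and the raw importance is the mean RMSE
#' increase over `n_permutations` draws. Negative raw importances are
#' clipped to zero and the weights normalized to sum to 1. The graph is
#' held fixed: importance measures the feature pathway, not graph
#' rewiring.
#'
#' @param model Fitted `msagnn_model`.
#' @param table Sample table aligned with `graph`.
#' @param graph The `soil_graph` used for prediction.
#' @param eval_index Nodes to evaluate on (>= 2).
#' @param n_permutations Permutations per feature (default 10).
#' @param seed Seed for the permutation draws.
#' @return Object of class `importance_report`: data.frame `importance`
#'   (feature, raw, weight) sorted by weight, plus `baseline_rmse`,
#'   `n_permutations`, `seed` and `normalized` flag.
#' @export
permutation_importance <- function(model, table, graph, eval_index,
                                   n_permutations = 10, seed = 1L) {
  if (length(eval_index) < 2) stop("need at least 2 evaluation nodes")
  obs <- table[[model$config$target]][eval_index]
  base_pred <- model_forward(model, table, graph)
  baseline <- regression_metrics(base_pred[eval_index], obs)$rmse
  features <- predictor_columns()
  set.seed(seed)
  raw <- numeric(length(features))
  names(raw) <- features
  for (f in features) {
    deltas <- numeric(n_permutations)
    for (p in seq_len(n_permutations)) {
      perm_table <- table
      perm_table[[f]][eval_index] <- sample(table[[f]][eval_index])
      pred <- model_forward(model, perm_table, graph)
      deltas[p] <- regression_metrics(pred[eval_index], obs)$rmse - baseline
    }
    raw[f] <- mean(deltas)
  }
  clipped <- pmax(raw, 0)
  total <- sum(clipped)
  weights <- if (total > 0) clipped / total else clipped
  imp <- data.frame(feature = features, raw = unname(raw),
                    weight = unname(weights))
  imp <- imp[order(-imp$weight), ]
  rownames(imp) <- NULL
  structure(
    list(importance = imp, baseline_rmse = baseline,
         n_permutations = n_permutations, seed = seed,
         normalized = total > 0),
    class = "importance_report"
  )
}

#' @export
print.importance_report <- function(x, ...) {
  cat("Permutation importance (baseline RMSE ",
      sprintf("%.4g", x$baseline_rmse), "):\n", sep = "")
  print(utils::head(x$importance, 10), row.names = FALSE)
  invisible(x)
}

#' Predict heavy-metal concentrations at new locations
#'
#' Builds a joint graph over the training and new sites with the same
#' rules (radius neighborhoods, optional type masking, connectivity
#' repair, Gaussian weights), runs the fitted model forward, and returns
#' predictions for the new sites only, with their coordinates for gridded
#' mapping.
#'
#' @param model Fitted `msagnn_model`.
#' @param train_table The table the model was trained on.
#' @param new_table Table of new sites carrying coordinates and all 15
#'   predictors (targets not required).
#' @param graph_params List with `d`, `theta` and optional `labels` for
#'   the joint sites (training labels first).
#' @return Data.frame with `sample_id`, `longitude`, `latitude`,
#'   `prediction` (mg/kg) for the new sites; empty input gives an empty
#'   frame.
#' @export
predict_at_locations <- function(model, train_table, new_table,
                                 graph_params = list()) {
  if (nrow(new_table) == 0) {
    return(data.frame(sample_id = character(0), longitude = numeric(0),
                      latitude = numeric(0), prediction = numeric(0)))
  }
  missing_cols <- setdiff(predictor_columns(), names(new_table))
  if (length(missing_cols)) {
    stop("new sites missing predictor column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- !stats::complete.cases(new_table[, predictor_columns()])
  if (any(bad)) {
    stop("new site row(s) with missing predictor values: ",
         paste(which(bad), collapse = ", "))
  }
  keep <- c("sample_id", predictor_columns())
  joint <- rbind(
    cbind(train_table[, keep], .role = "train"),
    cbind(new_table[, keep], .role = "new")
  )
  joint$sample_id <- make.unique(as.character(joint$sample_id))
  graph <- resolve_graph(joint, graph_params)
  pred <- model_forward(model, joint, graph)
  new_rows <- which(joint$.role == "new")
  data.frame(
    sample_id = as.character(new_table$sample_id),
    longitude = new_table$longitude, latitude = new_table$latitude,
    prediction = pred[new_rows]
  )
}

#' Write an evaluation report to JSON and/or CSV
#'
#' @param report An `eval_report`.
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_eval_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(protocol = report$protocol, target = report$target,
           aggregate = report$aggregate, splits = report$splits),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(report$splits, csv_path, row.names = FALSE)
  }
  invisible(c(json_path, csv_path))
}
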