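# Metrics, split protocols, ablation, importance, new-site prediction.

fast_config <- function(...) {
  msagnn_config(hidden_dim = 4, attention_dim = 4, epochs = 5, ...)
}

test_that("regression metrics evaluate their definitions", {
  perfect <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r2, 1)

  m <- regression_metrics(c(0, 2), c(1, 1))
  expect_equal(m$mae, 1)
  expect_equal(m$rmse, 1)
  expect_false(m$r2_defined)  # zero variance in the observations
  expect_true(is.na(m$r2))

  # the constant mean predictor scores exactly zero
  obs <- c(1, 4, 2, 8)
  expect_equal(regression_metrics(rep(mean(obs), 4), obs)$r2, 0)

  # hand case: P=(1,2,4), O=(2,2,5): mae=2/3, rmse=sqrt(2/3), r2=1-2/6
  h <- regression_metrics(c(1, 2, 4), c(2, 2, 5))
  expect_equal(h$mae, 2 / 3)
  expect_equal(h$rmse, sqrt(2 / 3))
  expect_equal(h$r2, 1 - 2 / 6)

  # the printed variant differs from the standard form in general
  p <- regression_metrics(c(1, 2, 4), c(2, 2, 5), r2_form = "printed")
  expect_equal(p$r2, 1 - sum((c(1, 2, 4) - 3)^2) / 6)
  expect_error(regression_metrics(c(1, NA), c(1, 2)), "finite")
})

test_that("MAE never exceeds RMSE", {
  set.seed(17)
  for (i in 1:200) {
    n <- sample(2:40, 1)
    m <- regression_metrics(rnorm(n), rnorm(n))
    expect_lte(m$mae, m$rmse + 1e-12)
  }
})

test_that("repeated splits are reproducible and shuffle-consistent", {
  sv <- simulate_survey(synthetic_config(
    n_sites = 30, zone_counts = c(6, 6, 6, 6, 6), seed = 2))
  cfg <- fast_config(target = "cd")
  r1 <- repeated_random_splits(sv$table, list(d = 15), cfg,
                               n_repeats = 3, seed = 99)
  expect_equal(nrow(r1$splits), 3)
  expect_named(r1$splits, c("split", "seed", "mae", "rmse", "r2", "n_test"))
  expect_true(all(r1$splits$n_test == 6))
  expect_true(all(r1$splits$mae <= r1$splits$rmse))
  # aggregates recompute from the per-split records
  expect_equal(r1$aggregate$mean[r1$aggregate$metric == "mae"],
               mean(r1$splits$mae))

  r2 <- repeated_random_splits(sv$table, list(d = 15), cfg,
                               n_repeats = 3, seed = 99)
  expect_identical(r1$splits, r2$splits)
})

test_that("a memorizable feature yields high held-out split R^2", {
  # covariate-only construction: the target is a visible feature, so the
  # self-only graph makes the signal recoverable by the training loop; the
  # unregularized network still spends some capacity on spurious feature
  # directions, which caps held-out R^2 below the noise-free ideal
  tbl <- make_test_table(100, seed = 123, spread = 0.05)
  tbl$cd <- 1 + 2 * scale(tbl$organic_matter)[, 1]
  cfg <- msagnn_config(hidden_dim = 8, epochs = 100, target = "cd")
  rep <- repeated_random_splits(tbl, list(identity = TRUE), cfg,
                                n_repeats = 2, seed = 5)
  expect_gt(mean(rep$splits$r2), 0.75)
})

test_that("nested CV with a one-cell grid is plain outer cross-validation", {
  sv <- simulate_survey(synthetic_config(
    n_sites = 24, zone_counts = c(5, 5, 5, 5, 4), seed = 3))
  cfg <- fast_config(target = "cd")
  grid <- data.frame(hidden_dim = 4, d = 15)
  out <- nested_cross_validation(sv$table, list(theta = 5), cfg,
                                 outer_k = 4, inner_k = 2, grid = grid,
                                 seed = 21)
  expect_equal(nrow(out$splits), 4)
  expect_true(all(out$splits$hidden_dim == 4))
  expect_true(all(out$splits$d == 15))
  # every site lands in exactly one outer test fold
  expect_equal(sum(out$splits$n_test), 24)
  expect_true(is.finite(out$pooled$rmse))
  expect_error(nested_cross_validation(sv$table, list(), cfg,
                                       grid = data.frame()), "empty grid")
})

test_that("ablation arms share the split schedule and report three variants", {
  sv <- simulate_survey(synthetic_config(
    n_sites = 30, zone_counts = c(6, 6, 6, 6, 6), seed = 4))
  cfg <- fast_config(target = "cd")
  ab <- run_ablation(sv$table, list(d = 15), cfg, n_repeats = 2, seed = 8)
  expect_equal(ab$summary$variant, c("full", "msgcn_only", "agnn_only"))
  expect_equal(nrow(ab$per_split), 6)
  # paired: identical split seeds across arms
  seeds_by_variant <- split(ab$per_split$seed, ab$per_split$variant)
  expect_identical(seeds_by_variant$full, seeds_by_variant$msgcn_only)
  expect_identical(seeds_by_variant$full, seeds_by_variant$agnn_only)

  ab2 <- run_ablation(sv$table, list(d = 15), cfg, n_repeats = 2, seed = 8)
  expect_identical(ab$summary, ab2$summary)
})

test_that("permutation importance is normalized and finds the only signal", {
  tbl <- make_test_table(80, seed = 140, spread = 0.05)
  tbl$cd <- 1 + 3 * scale(tbl$ph)[, 1]  # ph is the sole informative feature
  graph <- identity_graph(tbl)  # node-local signal: self-only neighborhoods
  cfg <- msagnn_config(hidden_dim = 8, epochs = 120, target = "cd",
                       use_agnn = FALSE, seed = 3)
  model <- train_msagnn(tbl, graph, 1:80, cfg)
  imp <- permutation_importance(model, tbl, graph, eval_index = 1:80,
                                n_permutations = 5, seed = 9)
  expect_equal(sum(imp$importance$weight), 1, tolerance = 1e-9)
  expect_true(all(imp$importance$weight >= 0))
  expect_equal(imp$importance$feature[1], "ph")
  expect_gt(imp$importance$weight[imp$importance$feature == "ph"], 0.3)

  expect_error(permutation_importance(model, tbl, graph, eval_index = 1),
               "at least 2")
})

test_that("a one-feature toy concentrates all importance on that feature", {
  # every other predictor is constant, so permuting it cannot change the
  # prediction and the single positive raw importance normalizes to 1
  tbl <- make_test_table(30, seed = 141)
  for (col in setdiff(predictor_columns(),
                      c("ph", "pollution_type", "crop"))) {
    tbl[[col]] <- rep(tbl[[col]][1], 30)
  }
  tbl$sand_pct <- rep(40, 30); tbl$clay_pct <- rep(30, 30)
  tbl$silt_pct <- rep(30, 30)
  tbl$pollution_type <- "background"
  tbl$crop <- "rice"
  tbl$cd <- 1 + 2 * scale(tbl$ph)[, 1]
  graph <- identity_graph(tbl)
  cfg <- msagnn_config(hidden_dim = 4, epochs = 80, target = "cd",
                       use_agnn = FALSE, seed = 5)
  model <- suppressWarnings(train_msagnn(tbl, graph, 1:30, cfg))
  imp <- suppressWarnings(
    permutation_importance(model, tbl, graph, eval_index = 1:30,
                           n_permutations = 3, seed = 2))
  expect_equal(imp$importance$weight[imp$importance$feature == "ph"], 1)
})

test_that("new-location prediction respects structure and empty input", {
  tbl <- make_test_table(15, seed = 150, spread = 0.03)
  graph <- build_fixed_graph(tbl, d = 10, theta = 5)
  cfg <- fast_config(target = "cd", seed = 2)
  model <- train_msagnn(tbl, graph, 1:15, cfg)

  empty <- predict_at_locations(model, tbl, tbl[0, ], list(d = 10))
  expect_equal(nrow(empty), 0)

  # a new site duplicating a training site predicts that site's value
  new_site <- tbl[4, ]
  new_site$sample_id <- "NEW"
  out <- predict_at_locations(model, tbl, new_site, list(d = 10))
  expect_equal(nrow(out), 1)
  joint <- rbind(tbl, new_site)
  g_joint <- build_fixed_graph(joint, d = 10, theta = 5)
  joint_pred <- model_forward(model, joint, g_joint)
  expect_equal(out$prediction, joint_pred[4], tolerance = 1e-8)

  missing <- new_site
  missing$ph <- NULL
  expect_error(predict_at_locations(model, tbl, missing, list(d = 10)), "ph")
  na_row <- new_site
  na_row$cec <- NA
  expect_error(predict_at_locations(model, tbl, na_row, list(d = 10)),
               "missing predictor values")
})

test_that("predictions at grid points recover a known spatial surface", {
  cfg_gen <- synthetic_config(n_sites = 60, zone_counts = c(12, 12, 12, 12, 12),
                              sigma2_s = 1, range_km = 15, noise_sd = 0.05,
                              log_link = FALSE, intercepts = c(cd = 8, pb = 110),
                              beta = c(organic_matter = 0.1), seed = 31)
  sv <- simulate_survey(cfg_gen)
  graph <- build_fixed_graph(sv$table, d = 15, theta = 5)
  cfg <- msagnn_config(hidden_dim = 16, epochs = 100, target = "cd", seed = 7)
  model <- train_msagnn(sv$table, graph, seq_len(60), cfg)
  fit <- model_forward(model, sv$table, graph)
  # the fitted surface correlates with the generating one
  expect_gt(stats::cor(fit, sv$truth$noiseless_log_cd), 0.5)
})
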