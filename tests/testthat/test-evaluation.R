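test_that("metric report matches the hand-computed oracle", {
  m <- compute_metrics(c(100, 110, 120), c(110, 100, 130))
  expect_equal(m$mae, 10)
  expect_equal(m$mse, 100)
  expect_equal(m$rmse, 10)
  expect_equal(m$msd, -10 / 3)
  expect_equal(m$r2, 1 - 300 / (4200 / 9))  # SS_tot about mean 340/3
  expect_equal(m$mape, mean(c(10 / 110, 10 / 100, 10 / 130)))

  ident <- compute_metrics(c(5, 9, 30), c(5, 9, 30))
  expect_equal(unlist(ident[c("r2", "mae", "mse", "rmse", "msd", "mape")]),
               c(r2 = 1, mae = 0, mse = 0, rmse = 0, msd = 0, mape = 0))
})

test_that("degenerate metric inputs are signaled, not silently propagated", {
  expect_error(compute_metrics(1:3, 1:4), class = "bud_dimension_error")
  expect_error(compute_metrics(1, 1), class = "bud_dimension_error")
  expect_warning(m <- compute_metrics(c(1, 2, 3), c(7, 7, 7)),
                 regexp = "constant")
  expect_true(is.na(m$r2))
  expect_false(is.na(m$rmse))
  expect_warning(m0 <- compute_metrics(c(1, 2), c(0, 4)), regexp = "MAPE")
  expect_true(is.na(m0$mape))
  expect_false(is.na(m0$mae))
})

test_that("metric identities hold on random series", {
  set.seed(404)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    o <- runif(n, 10, 500)
    p <- o + rnorm(n, 0, 30)
    m <- compute_metrics(p, o)
    expect_equal(m$rmse^2, m$mse)
    expect_lte(m$mae, m$rmse + 1e-12)
    expect_true(m$msd >= -m$mae - 1e-12 && m$msd <= m$mae + 1e-12)
    expect_lte(m$r2, 1)
    k <- runif(1, 0.1, 10)  # MAPE is scale-invariant
    expect_equal(compute_metrics(k * p, k * o)$mape, m$mape)
  }
})

test_that("family comparison covers the seven families deterministically", {
  ds <- fixture_ds()
  cmp <- compare_families(ds, seed = 5)
  expect_identical(cmp$family, model_families())
  expect_true(all(is.na(cmp$error)))
  expect_identical(compare_families(ds, seed = 5), cmp)
})

test_that("single-family comparison equals the direct fit/predict/metrics chain", {
  ds <- fixture_ds()
  cmp <- compare_families(ds, seed = 9, families = "tree_ensemble_regression")
  sp <- fit_test_split(seed = 9)
  m <- suppressWarnings(compute_metrics(predict_bud(sp$model, sp$parts$test)$bud_days,
                                        sp$parts$test$bud_days))
  expect_equal(cmp$r2, m$r2)
  expect_equal(cmp$rmse, m$rmse)
  expect_equal(cmp$mape, m$mape)
})

test_that("noise-free linear structure is learnable to r2 = 1 by regression families", {
  # BUD an exact function of LogP on a repeated grid: test rows duplicate
  # training design points, so tree regressors can interpolate exactly.
  truth <- ground_truth_spec(logp_effect = -10, noise_sd = 0,
                             excipient_offsets = setNames(rep(0, 6),
                               c("lactose", "silica", "cellulose", "mannitol",
                                 "sucrose", "hpmc")),
                             temperature_effect = 0, content_effect = 0)
  apis <- generate_apis(5, seed = 2)
  feats <- featurize_dataset(generate_stability_dataset(
    200, truth, seed = 2, n_apis = 5))
  parts <- linear_partition(feats, 0.8)
  m <- fit_bud_model(parts$train, seed = 2)
  p <- predict_bud(m, parts$test)
  r2 <- suppressWarnings(compute_metrics(p$bud_days, parts$test$bud_days)$r2)
  expect_gte(r2, 0.99)
})

test_that("correlation screen agrees with the textbook Pearson formula", {
  set.seed(11)
  n <- 50
  feats <- tibble::as_tibble(setNames(
    as.data.frame(matrix(rnorm(n * 27), n, 27)), feature_schema()))
  pred <- rnorm(n)
  scr <- correlation_screen(feats, pred)
  expect_identical(nrow(scr), 27L)
  manual <- vapply(feature_schema(),
                   function(col) oracle_pearson(feats[[col]], pred), numeric(1))
  expect_equal(scr$r, unname(manual), tolerance = 1e-12)
  # p-values from the t distribution with n - 2 df
  tstat <- scr$r * sqrt((n - 2) / (1 - scr$r^2))
  expect_equal(scr$p, 2 * stats::pt(-abs(tstat), n - 2), tolerance = 1e-12)
})

test_that("correlation screen handles exact linearity and zero variance", {
  feats <- tibble::as_tibble(setNames(
    as.data.frame(matrix(1, 3, 27)), feature_schema()))
  feats$logp <- c(1, 2, 3)
  scr <- correlation_screen(feats, c(2, 4, 6))
  expect_equal(scr$r[scr$parameter == "logp"], 1)
  expect_lt(scr$p[scr$parameter == "logp"], 1e-8)
  expect_true(is.na(scr$r[scr$parameter == "mw"]))  # zero-variance column
  expect_error(correlation_screen(feats[1:2, ], c(1, 2)),
               class = "bud_dimension_error")
})

test_that("fixture-pipeline screen matches the LogP trend of the observed data", {
  sp <- fit_test_split(seed = 1)
  feats <- rbind(sp$parts$train, sp$parts$test)
  pred <- predict_bud(sp$model, feats)$bud_days
  scr <- correlation_screen(feats, pred)
  expect_identical(nrow(scr), 27L)
  # the model's LogP trend reproduces the sign of the raw-data association
  expect_identical(sign(scr$r[scr$parameter == "logp"]),
                   sign(cor(feats$logp, feats$bud_days)))
  expect_true(all(abs(scr$r[!is.na(scr$r)]) <= 1))
})
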