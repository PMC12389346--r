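# Model evaluation: the six-metric report, the seven-family comparison
# table, and the descriptor/prediction correlation screen.

#' Six-metric evaluation report
#'
#' Computes the standard regression scores used throughout the package:
#' coefficient of determination (R^2), mean absolute error (MAE, days), mean
#' squared error (MSE, days^2), root mean squared error (RMSE, days), mean
#' signed difference (MSD, days; sign convention `mean(predicted - observed)`)
#' and mean absolute percentage error (MAPE, reported as a proportion).
#'
#' With a constant observed series R^2 is undefined and returned as `NA` with
#' a warning; with any observed value equal to zero MAPE is `NA` with a
#' warning (the remaining metrics are still returned).
#'
#' @param predicted,observed Equal-length numeric vectors (length >= 2) of
#'   predicted and experimental BUDs in days.
#' @return A list of class `metric_report` with elements `r2`, `mae`, `mse`,
#'   `rmse`, `msd`, `mape`.
#' @export
#' @examples
#' compute_metrics(c(100, 110, 120), c(110, 100, 130))
compute_metrics <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    abort("predicted and observed series differ in length",
          class = "bud_dimension_error")
  }
  if (length(observed) < 2) {
    abort("need at least 2 observations", class = "bud_dimension_error")
  }
  err <- predicted - observed
  mse <- mean(err^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    warn("observed series is constant; R^2 is undefined")
    r2 <- NA_real_
  } else {
    r2 <- 1 - sum(err^2) / ss_tot
  }
  if (any(observed == 0)) {
    warn("observed series contains zero; MAPE is undefined")
    mape <- NA_real_
  } else {
    mape <- mean(abs(err) / abs(observed))
  }
  structure(list(r2 = r2, mae = mean(abs(err)), mse = mse, rmse = sqrt(mse),
                 msd = mean(err), mape = mape),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "R2 %.4g | MAE %.4g d | MSE %.4g d^2 | RMSE %.4g d | MSD %.4g d | MAPE %.4g\n",
    x$r2, x$mae, x$mse, x$rmse, x$msd, x$mape))
  invisible(x)
}

#' Compare the seven model families on a linear 80/20 split
#'
#' Featurizes the dataset, takes the linear train/test partition, fits each
#' family with the same seed, and scores the held-out rows with
#' [compute_metrics()]. Families that fail to fit or predict are kept in the
#' table with `NA` metrics and the error message in the `error` column.
#'
#' @param ds A `curated_dataset`.
#' @param seed Integer RNG seed shared by all families.
#' @param train_fraction Proportion of rows (in file order) used for
#'   training; default 0.8.
#' @param families Model families to fit; default all seven.
#' @param ... Hyperparameters forwarded to [fit_bud_model()].
#' @return Tibble with one row per family: `family`, the six metrics, and
#'   `error` (`NA` on success).
#' @export
compare_families <- function(ds, seed = 42L, train_fraction = 0.8,
                             families = model_families(), ...) {
  feats <- featurize_dataset(ds)
  parts <- linear_partition(feats, train_fraction)
  rows <- lapply(families, function(fam) {
    res <- tryCatch({
      model <- fit_bud_model(parts$train, family = fam, seed = seed, ...)
      pred <- predict_bud(model, parts$test)
      m <- suppressWarnings(compute_metrics(pred$bud_days, parts$test$bud_days))
      c(m, list(error = NA_character_))
    }, error = function(e) {
      list(r2 = NA_real_, mae = NA_real_, mse = NA_real_, rmse = NA_real_,
           msd = NA_real_, mape = NA_real_, error = conditionMessage(e))
    })
    tibble::tibble(family = fam, r2 = res$r2, mae = res$mae, mse = res$mse,
                   rmse = res$rmse, msd = res$msd, mape = res$mape,
                   error = res$error)
  })
  dplyr::bind_rows(rows)
}

#' Correlation screen between feature columns and predicted BUDs
#'
#' For each of the 27 feature columns, computes the Pearson correlation with
#' the predicted BUD series and its two-sided p-value from the t distribution
#' with n-2 degrees of freedom, flagging parameters with `p < 0.05`.
#' Zero-variance parameters are reported with `NA` correlation.
#'
#' @param features Feature rows (the 27 [feature_schema()] columns; a
#'   `bud_days` column, if present, is ignored).
#' @param predicted Numeric predicted BUDs, one per feature row.
#' @param alpha Significance threshold for the `significant` flag.
#' @return Tibble with columns `parameter`, `r`, `p`, `significant`.
#' @export
correlation_screen <- function(features, predicted, alpha = 0.05) {
  cols <- intersect(feature_schema(), names(features))
  if (length(cols) == 0) {
    abort("features must contain feature-schema columns", class = "bud_domain_error")
  }
  if (nrow(features) != length(predicted)) {
    abort("features and predicted series differ in length",
          class = "bud_dimension_error")
  }
  if (nrow(features) < 3) {
    abort("correlation screen needs at least 3 rows", class = "bud_dimension_error")
  }
  rows <- lapply(cols, function(col) {
    xc <- features[[col]]
    ok <- !is.na(xc)
    if (sum(ok) < 3 || sd(xc[ok]) == 0 || sd(predicted[ok]) == 0) {
      return(tibble::tibble(parameter = col, r = NA_real_, p = NA_real_,
                            significant = NA))
    }
    ct <- cor.test(xc[ok], predicted[ok], method = "pearson")
    tibble::tibble(parameter = col, r = unname(ct$estimate),
                   p = ct$p.value, significant = ct$p.value < alpha)
  })
  dplyr::bind_rows(rows)
}
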