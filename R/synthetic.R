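# Synthetic data with a known ground-truth BUD function, so every pipeline
# stage is testable without external downloads and parameter recovery can be
# asserted against the generating model.

#' Ground-truth specification for the synthetic BUD generator
#'
#' The generating model is linear with per-excipient offsets:
#' `bud = intercept + logp_effect * LogP + sum(excipient offsets)
#' + temperature_effect * (T - 25) + content_effect * content + N(0, noise_sd)`,
#' clipped below at 1 day. The default effect directions follow the
#' qualitative structure reported for compounded oral solids: lower LogP,
#' lower temperature and lower content extend stability; cellulose, silica,
#' sucrose and mannitol stabilize while lactose and HPMC destabilize.
#'
#' @param intercept_days Baseline BUD in days at LogP 0, 25 degC, content 0.
#' @param logp_effect Days per LogP unit (default -10).
#' @param excipient_offsets Named numeric vector of offsets in days for the
#'   six excipients.
#' @param temperature_effect Days per degC relative to 25 degC.
#' @param content_effect Days per content percent.
#' @param noise_sd Gaussian noise standard deviation in days (>= 0).
#' @return List of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(intercept_days = 180,
                              logp_effect = -10,
                              excipient_offsets = c(lactose = -15, silica = 15,
                                                    cellulose = 20, mannitol = 10,
                                                    sucrose = 10, hpmc = -20),
                              temperature_effect = -1,
                              content_effect = -0.5,
                              noise_sd = 5) {
  stopifnot(is.numeric(noise_sd), noise_sd >= 0,
            all(EXCIPIENT_LEVELS %in% names(excipient_offsets)))
  structure(list(intercept_days = intercept_days, logp_effect = logp_effect,
                 excipient_offsets = excipient_offsets[EXCIPIENT_LEVELS],
                 temperature_effect = temperature_effect,
                 content_effect = content_effect, noise_sd = noise_sd),
            class = "ground_truth_spec")
}

#' Deterministic closed-form BUD under a ground truth (noise excluded)
#'
#' @param truth A [ground_truth_spec()].
#' @param logp LogP values.
#' @param excipients List of character vectors (excipients per record).
#' @param temperature_c,content_pct Storage conditions.
#' @return Noise-free BUDs in days, clipped at 1.
#' @export
true_bud <- function(truth, logp, excipients, temperature_c, content_pct) {
  offsets <- vapply(excipients, function(e) sum(truth$excipient_offsets[e]),
                    numeric(1))
  pmax(1, truth$intercept_days + truth$logp_effect * logp + offsets +
         truth$temperature_effect * (temperature_c - 25) +
         truth$content_effect * content_pct)
}

#' Generate synthetic API descriptor records
#'
#' Molecular weight is log-uniform over 12.01-1461.43 g/mol and LogP uniform
#' over -12.01 to 17.16 (the descriptor ranges of the large screening set);
#' count descriptors are small non-negative integers; polar surface area is
#' gamma-distributed. Deterministic under `seed`.
#'
#' @param n Number of APIs (>= 1).
#' @param seed Integer RNG seed.
#' @return Tibble with the API descriptor columns of `load_dataset()`.
#' @export
generate_apis <- function(n, seed = 1L) {
  if (!is.numeric(n) || n < 1) {
    abort("n must be >= 1", class = "bud_domain_error")
  }
  n <- as.integer(n)
  set.seed(as.integer(seed))
  tibble::tibble(
    name = sprintf("SYN-API-%04d", seq_len(n)),
    smiles = sprintf("SYN-SMILES-%04d", seq_len(n)),
    mw = exp(runif(n, log(12.01), log(1461.43))),
    logp = runif(n, -12.01, 17.16),
    rb = rpois(n, 4),
    ps = rgamma(n, shape = 2, scale = 45),
    hbd = rpois(n, 2),
    hba = rpois(n, 4),
    ar = rpois(n, 1),
    mc_printed = NA_real_,
    msc_printed = NA_real_
  )
}

#' Generate a synthetic stability dataset with known ground truth
#'
#' Samples formulations (one or two excipients, content level, storage
#' temperature, packaging) for synthetic APIs and assigns each record the
#' ground-truth BUD plus Gaussian noise, clipped at 1 day. The result is a
#' fully valid `curated_dataset`, interchangeable with the packaged fixture.
#'
#' @param n_records Number of stability records.
#' @param truth A [ground_truth_spec()].
#' @param seed Integer RNG seed.
#' @param n_apis Number of distinct APIs; default scales with `n_records`.
#' @return A `curated_dataset` whose records carry a `.true_bud` attribute
#'   (noise-free BUDs) for oracle checks.
#' @export
generate_stability_dataset <- function(n_records, truth = ground_truth_spec(),
                                       seed = 1L, n_apis = NULL) {
  stopifnot(inherits(truth, "ground_truth_spec"))
  if (!is.numeric(n_records) || n_records < 1) {
    abort("n_records must be >= 1", class = "bud_domain_error")
  }
  n_records <- as.integer(n_records)
  if (is.null(n_apis)) n_apis <- max(3L, min(100L, ceiling(n_records / 10)))
  seed <- as.integer(seed)
  apis <- generate_apis(n_apis, seed = seed)
  excipients <- load_dataset()$excipients

  set.seed(seed + 1L)
  api_idx <- sample.int(n_apis, n_records, replace = TRUE)
  n_exc <- sample(1:2, n_records, replace = TRUE)
  exc_sets <- lapply(n_exc, function(k) sample(EXCIPIENT_LEVELS, k))
  content <- round(runif(n_records, 0.5, 99.5), 1)
  temperature <- sample(c(4, 25, 40), n_records, replace = TRUE)
  packaging <- sample(PACKAGING_LEVELS, n_records, replace = TRUE)
  dose <- round(runif(n_records, 1, 500), 1)

  base <- true_bud(truth, apis$logp[api_idx], exc_sets, temperature, content)
  bud <- pmax(1, base + rnorm(n_records, 0, truth$noise_sd))

  pack_display <- c(glass = "G", plastic = "Pl", paper = "P")[packaging]
  records <- tibble::tibble(
    api_name = apis$name[api_idx],
    main_excipient = vapply(exc_sets, `[`, character(1), 1),
    other_excipient = vapply(exc_sets, function(e)
      if (length(e) > 1) e[2] else "NONE", character(1)),
    main_excipient_display = vapply(exc_sets, `[`, character(1), 1),
    other_excipient_display = vapply(exc_sets, function(e)
      if (length(e) > 1) e[2] else "-", character(1)),
    packaging = packaging,
    packaging_display = unname(pack_display),
    dose_mg = dose,
    content_pct = content,
    temperature_c = as.numeric(temperature),
    bud_days = bud
  )
  validate_records(records, apis)
  ds <- new_curated_dataset(apis, excipients, records)
  attr(ds$records, ".true_bud") <- base
  ds
}

#' Parameter-recovery report on synthetic data
#'
#' Generates a synthetic dataset under `truth`, trains the tree-ensemble
#' regressor on the linear 80/20 split, and reports how well the generating
#' structure is recovered: held-out metrics, the sign of the predicted-BUD
#' versus LogP trend, and the rank agreement between per-excipient predicted
#' effects and the true offsets.
#'
#' @param truth A [ground_truth_spec()].
#' @param n_records Number of synthetic records.
#' @param seed Integer RNG seed (generation and model fit).
#' @param train_fraction Linear partition fraction.
#' @return List with `metrics` (a `metric_report` on the held-out rows),
#'   `logp_trend` (Pearson correlation of held-out predictions with LogP),
#'   `logp_sign_recovered` (logical), `excipient_rank_cor` (Spearman
#'   correlation of predicted pure-excipient BUDs with the true offsets) and
#'   `n_test`.
#' @export
recovery_report <- function(truth = ground_truth_spec(), n_records = 500,
                            seed = 1L, train_fraction = 0.8) {
  ds <- generate_stability_dataset(n_records, truth, seed = seed)
  feats <- featurize_dataset(ds)
  parts <- linear_partition(feats, train_fraction)
  model <- fit_bud_model(parts$train, family = "tree_ensemble_regression",
                         seed = seed)
  pred <- predict_bud(model, parts$test)
  metrics <- suppressWarnings(compute_metrics(pred$bud_days, parts$test$bud_days))

  logp_trend <- if (sd(parts$test$logp) > 0 && sd(pred$bud_days) > 0) {
    cor(parts$test$logp, pred$bud_days)
  } else NA_real_
  sign_recovered <- !is.na(logp_trend) && truth$logp_effect != 0 &&
    sign(logp_trend) == sign(truth$logp_effect)

  # pure-excipient probe at fixed mid-grid conditions, one spec per excipient
  probe <- enumerate_formulations(ds$apis$name[1], contents = 10,
                                  temperatures = 25, packagings = "plastic",
                                  excipient_mode = "pure")
  probe_pred <- predict_grid(model, probe, ds)
  rank_cor <- suppressWarnings(cor(
    probe_pred$bud_days,
    unname(truth$excipient_offsets[probe_pred$excipient_1]),
    method = "spearman"))

  list(metrics = metrics, logp_trend = logp_trend,
       logp_sign_recovered = sign_recovered,
       excipient_rank_cor = rank_cor, n_test = nrow(parts$test))
}
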