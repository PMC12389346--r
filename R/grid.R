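# Formulation design-space enumeration, batch BUD prediction over the grid,
# and BUD-range frequency histograms.

excipient_settings <- function(mode = c("both", "pure", "binary")) {
  mode <- match.arg(mode)
  pure <- tibble::tibble(excipient_1 = EXCIPIENT_LEVELS,
                         excipient_2 = NA_character_)
  pairs <- utils::combn(EXCIPIENT_LEVELS, 2)
  binary <- tibble::tibble(excipient_1 = pairs[1, ], excipient_2 = pairs[2, ])
  switch(mode,
         pure = pure,
         binary = binary,
         both = dplyr::bind_rows(pure, binary))
}

#' Enumerate formulation scenarios
#'
#' Builds the full cross of APIs, excipient settings (6 pure excipients
#' and/or the 15 unordered binary combinations), content levels, storage
#' temperatures and packaging types, in deterministic order (excipient
#' settings in canonical order within each API/content/temperature/packaging
#' cell).
#'
#' @param apis Character vector of API names.
#' @param contents Numeric API content levels in percent; default the
#'   standard 1/10/50/90 study levels.
#' @param temperatures Numeric storage temperatures in degC; default
#'   `c(4, 25, 40)`.
#' @param packagings Packaging types; default `"plastic"`.
#' @param excipient_mode `"pure"` (6 settings), `"binary"` (15) or `"both"`
#'   (21).
#' @return Tibble of formulation specs with columns `api_name`,
#'   `excipient_1`, `excipient_2` (`NA` for pure formulations),
#'   `content_pct`, `temperature_c`, `packaging`.
#' @export
#' @examples
#' nrow(enumerate_formulations("Melatonin", contents = 10,
#'                             temperatures = 25, packagings = "plastic"))
enumerate_formulations <- function(apis,
                                   contents = c(1, 10, 50, 90),
                                   temperatures = c(4, 25, 40),
                                   packagings = "plastic",
                                   excipient_mode = "both") {
  if (length(apis) == 0 || length(contents) == 0 ||
      length(temperatures) == 0 || length(packagings) == 0) {
    abort("all grid dimensions must be non-empty", class = "bud_enumeration_error")
  }
  exc <- excipient_settings(excipient_mode)
  grid <- expand.grid(setting = seq_len(nrow(exc)),
                      packaging = packagings,
                      temperature_c = sort(temperatures),
                      content_pct = sort(contents),
                      api_name = apis,
                      stringsAsFactors = FALSE)
  tibble::tibble(
    api_name = grid$api_name,
    excipient_1 = exc$excipient_1[grid$setting],
    excipient_2 = exc$excipient_2[grid$setting],
    content_pct = grid$content_pct,
    temperature_c = grid$temperature_c,
    packaging = grid$packaging
  )
}

#' Batch BUD prediction over a formulation grid
#'
#' Featurizes every formulation spec against the dataset the model was
#' trained on and predicts its BUD with standard error. APIs or excipients
#' outside the training codebook receive deterministic new label codes
#' (appearance order past the training codes).
#'
#' @param model A fitted `bud_model` (trained on [featurize_dataset()]
#'   output).
#' @param specs Formulation specs from [enumerate_formulations()].
#' @param ds The `curated_dataset` providing API descriptors and the
#'   label-encoding codebook. Every `api_name` in `specs` must resolve in
#'   `ds$apis`.
#' @return `specs` with `bud_days` and `stderr_days` columns appended.
#' @export
predict_grid <- function(model, specs, ds) {
  stopifnot(inherits(model, "bud_model"), inherits(ds, "curated_dataset"))
  i <- match(specs$api_name, ds$apis$name)
  if (anyNA(i)) {
    abort(sprintf("grid spec row %d: api_name '%s' not found in dataset",
                  which(is.na(i))[1], specs$api_name[which(is.na(i))[1]]),
          class = "bud_reference_error")
  }
  codebook <- build_codebook(ds)
  codebook$main_excipient <- extend_codes(codebook$main_excipient,
                                          specs$excipient_1)
  other <- ifelse(is.na(specs$excipient_2), "NONE", specs$excipient_2)
  feats <- assemble_features(ds$apis[i, ], specs$excipient_1, other,
                             specs$packaging, specs$content_pct,
                             specs$temperature_c, codebook)
  pred <- predict_bud(model, feats)
  out <- specs
  out$bud_days <- pred$bud_days
  out$stderr_days <- pred$stderr_days
  out
}

#' BUD-range frequency histogram
#'
#' Bins predicted BUDs into half-open ranges `[e_i, e_{i+1})` given strictly
#' increasing day edges, with explicit underflow/overflow bins for values
#' outside `[e_1, e_last)`, and reports per-group counts and percentages.
#' The default edges are the standard reporting categories 80-120, 120-140,
#' 140-150, 150-160 and 160-170 days.
#'
#' @param predictions Prediction table with a `bud_days` column (e.g. from
#'   [predict_grid()]).
#' @param edges Strictly increasing numeric day boundaries (>= 2 values).
#' @param group_cols Columns of `predictions` to group by; defaults to
#'   whichever of `excipient_1`, `excipient_2`, `content_pct`,
#'   `temperature_c` are present. Use `character(0)` for a single overall
#'   group.
#' @return Tidy tibble with the group columns plus `bin` (ordered factor),
#'   `count` and `percent`; per group the percentages sum to 100 and the
#'   counts to the group size.
#' @export
bud_histogram <- function(predictions, edges = c(80, 120, 140, 150, 160, 170),
                          group_cols = NULL) {
  if (length(edges) < 2 || any(diff(edges) <= 0)) {
    abort("edges must be >= 2 strictly increasing day boundaries",
          class = "bud_domain_error")
  }
  if (!"bud_days" %in% names(predictions)) {
    abort("predictions must have a bud_days column", class = "bud_domain_error")
  }
  if (is.null(group_cols)) {
    group_cols <- intersect(c("excipient_1", "excipient_2", "content_pct",
                              "temperature_c"), names(predictions))
  }
  labels <- c(sprintf("<%g", edges[1]),
              sprintf("[%g,%g)", edges[-length(edges)], edges[-1]),
              sprintf(">=%g", edges[length(edges)]))
  bin_of <- cut(predictions$bud_days, breaks = c(-Inf, edges, Inf),
                labels = labels, right = FALSE)
  df <- predictions[, group_cols, drop = FALSE]
  df$bin <- bin_of
  out <- df |>
    dplyr::count(dplyr::across(dplyr::all_of(c(group_cols, "bin"))),
                 name = "count", .drop = FALSE) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::mutate(percent = 100 * .data$count / sum(.data$count)) |>
    dplyr::ungroup()
  tibble::as_tibble(out)
}
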