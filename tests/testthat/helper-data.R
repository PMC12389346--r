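# Shared fixtures and independent oracles used across the suite.

fixture_ds <- function() load_dataset()

fixture_paths <- function() {
  list(stability = bud_example("stability_records.csv"),
       api = bud_example("api_descriptors.csv"),
       excipient = bud_example("excipients.csv"))
}

write_lines_tmp <- function(lines) {
  p <- tempfile(fileext = ".csv")
  writeLines(lines, p)
  p
}

# Stability CSV with selected data lines (1-based, excluding header) edited
# through `fn(line)`; returns the temp path.
edited_stability <- function(rows, fn) {
  lines <- readLines(fixture_paths()$stability)
  for (i in rows) lines[i + 1] <- fn(lines[i + 1])
  write_lines_tmp(lines)
}

# Independent class-assignment oracle: linear scan over the explicit list of
# bin lower edges rather than arithmetic on the step.
oracle_class <- function(values, scheme) {
  edges <- scheme$lower + scheme$step * (0:(scheme$class_count - 2))
  vapply(values, function(v) min(scheme$class_count, 1L + sum(v >= edges)),
         numeric(1))
}

# Independent Pearson correlation (textbook formula).
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

fit_test_split <- function(seed = 42, family = "tree_ensemble_regression") {
  feats <- featurize_dataset(fixture_ds())
  parts <- linear_partition(feats, 0.8)
  model <- fit_bud_model(parts$train, family = family, seed = seed)
  list(parts = parts, model = model)
}
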