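# Data model, validation and CSV I/O for the curated stability database:
# API descriptor table, excipient table, and stability records.

STABILITY_COLUMNS <- c("api_name", "main_excipient", "other_excipient",
                       "packaging", "dose_mg", "content_pct",
                       "temperature_c", "bud_days")
API_COLUMNS <- c("name", "smiles", "mw", "logp", "rb", "ps",
                 "hbd", "hba", "ar")
EXCIPIENT_COLUMNS <- c("name", "mw", "logp", "rb", "ps", "hbd", "hba", "ar",
                       "functional_roles", "solid_form", "shelf_life_years")

SENTINELS <- c("ND", "-", "")

read_raw_csv <- function(path, required, what) {
  if (!file.exists(path)) {
    abort(sprintf("%s file not found: %s", what, path), class = "bud_io_error")
  }
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("%s file '%s' is missing required column(s): %s",
                  what, path, paste(missing, collapse = ", ")),
          class = "bud_schema_error")
  }
  tbl
}

# Numeric parser with sentinel handling; errors carry row and column.
parse_numeric <- function(x, column, what, allow_missing = FALSE) {
  x <- trimws(ifelse(is.na(x), "", x))
  is_missing <- x %in% SENTINELS
  out <- suppressWarnings(as.numeric(x))
  bad <- !is_missing & is.na(out)
  if (any(bad)) {
    abort(sprintf("%s: non-numeric value '%s' in column '%s' (row %d)",
                  what, x[which(bad)[1]], column, which(bad)[1]),
          class = "bud_parse_error")
  }
  if (!allow_missing && any(is_missing)) {
    abort(sprintf("%s: missing value in required numeric column '%s' (row %d)",
                  what, column, which(is_missing)[1]),
          class = "bud_parse_error")
  }
  out[is_missing] <- NA_real_
  out
}

check_count_field <- function(x, column, what) {
  bad <- is.na(x) | x < 0 | x != floor(x)
  if (any(bad)) {
    abort(sprintf("%s: column '%s' must hold non-negative integers (row %d)",
                  what, column, which(bad)[1]),
          class = "bud_validation_error")
  }
  as.integer(x)
}

canonicalize_excipient <- function(x) {
  y <- tolower(trimws(x))
  y[y %in% tolower(SENTINELS)] <- NA_character_
  y
}

canonicalize_packaging <- function(x) {
  y <- tolower(trimws(x))
  map <- c(g = "glass", glass = "glass",
           pl = "plastic", pi = "plastic", plastic = "plastic",
           p = "paper", paper = "paper")
  out <- unname(map[y])
  out[y %in% tolower(SENTINELS)] <- "UNKNOWN"
  if (any(is.na(out))) {
    abort(sprintf("unrecognized packaging value '%s' (row %d)",
                  x[which(is.na(out))[1]], which(is.na(out))[1]),
          class = "bud_validation_error")
  }
  out
}

new_curated_dataset <- function(apis, excipients, records) {
  structure(list(apis = apis, excipients = excipients, records = records),
            class = "curated_dataset")
}

#' Load the curated stability dataset from its three CSV tables
#'
#' Reads and cross-validates the stability records, API descriptor table and
#' excipient table. Sentinel strings (`"ND"`, `"-"`) in the stability file are
#' mapped to `UNKNOWN` (categorical fields) or `NA` (numeric fields), never to
#' zero. Excipient and packaging names are canonicalized to lowercase; the
#' printed display strings are retained in `*_display` columns so that a
#' load/save/load round trip is lossless.
#'
#' @param stability_path,api_path,excipient_path Paths to UTF-8 CSV files with
#'   the documented headers. Defaults are the packaged fixture tables.
#' @return A `curated_dataset`: a list with tibbles `apis`, `excipients` and
#'   `records` (record order is file order).
#' @export
#' @examples
#' ds <- load_dataset()
#' nrow(ds$records)
load_dataset <- function(stability_path = bud_example("stability_records.csv"),
                         api_path = bud_example("api_descriptors.csv"),
                         excipient_path = bud_example("excipients.csv")) {
  apis <- read_raw_csv(api_path, API_COLUMNS, "API descriptor")
  excipients <- read_raw_csv(excipient_path, EXCIPIENT_COLUMNS, "excipient")
  records <- read_raw_csv(stability_path, STABILITY_COLUMNS, "stability")

  apis <- tibble::tibble(
    name = apis$name,
    smiles = apis$smiles,
    mw  = parse_numeric(apis$mw, "mw", "API descriptor"),
    logp = parse_numeric(apis$logp, "logp", "API descriptor"),
    rb  = check_count_field(parse_numeric(apis$rb, "rb", "API descriptor"), "rb", "API descriptor"),
    ps  = parse_numeric(apis$ps, "ps", "API descriptor"),
    hbd = check_count_field(parse_numeric(apis$hbd, "hbd", "API descriptor"), "hbd", "API descriptor"),
    hba = check_count_field(parse_numeric(apis$hba, "hba", "API descriptor"), "hba", "API descriptor"),
    ar  = check_count_field(parse_numeric(apis$ar, "ar", "API descriptor"), "ar", "API descriptor"),
    mc_printed = if ("mc_printed" %in% names(apis))
      parse_numeric(apis$mc_printed, "mc_printed", "API descriptor", allow_missing = TRUE) else NA_real_,
    msc_printed = if ("msc_printed" %in% names(apis))
      parse_numeric(apis$msc_printed, "msc_printed", "API descriptor", allow_missing = TRUE) else NA_real_
  )
  if (any(apis$mw <= 0)) {
    abort("API descriptor: mw must be > 0", class = "bud_validation_error")
  }
  if (any(apis$ps < 0)) {
    abort("API descriptor: ps must be >= 0", class = "bud_validation_error")
  }
  if (anyDuplicated(apis$name)) {
    abort("API descriptor: duplicated API name", class = "bud_validation_error")
  }

  exc_name <- canonicalize_excipient(excipients$name)
  bad_exc <- !exc_name %in% EXCIPIENT_LEVELS
  if (any(bad_exc) || anyNA(exc_name)) {
    abort(sprintf("excipient table: name '%s' is not one of {%s}",
                  excipients$name[which(bad_exc | is.na(exc_name))[1]],
                  paste(EXCIPIENT_LEVELS, collapse = ", ")),
          class = "bud_validation_error")
  }
  excipients <- tibble::tibble(
    name = exc_name,
    display_name = if ("display_name" %in% names(excipients))
      excipients$display_name else excipients$name,
    mw  = parse_numeric(excipients$mw, "mw", "excipient"),
    logp = parse_numeric(excipients$logp, "logp", "excipient"),
    rb  = check_count_field(parse_numeric(excipients$rb, "rb", "excipient"), "rb", "excipient"),
    ps  = parse_numeric(excipients$ps, "ps", "excipient"),
    hbd = check_count_field(parse_numeric(excipients$hbd, "hbd", "excipient"), "hbd", "excipient"),
    hba = check_count_field(parse_numeric(excipients$hba, "hba", "excipient"), "hba", "excipient"),
    ar  = check_count_field(parse_numeric(excipients$ar, "ar", "excipient"), "ar", "excipient"),
    mc_printed = if ("mc_printed" %in% names(excipients))
      parse_numeric(excipients$mc_printed, "mc_printed", "excipient", allow_missing = TRUE) else NA_real_,
    msc_printed = if ("msc_printed" %in% names(excipients))
      parse_numeric(excipients$msc_printed, "msc_printed", "excipient", allow_missing = TRUE) else NA_real_,
    functional_roles = excipients$functional_roles,
    solid_form = tolower(excipients$solid_form),
    shelf_life_years = parse_numeric(excipients$shelf_life_years, "shelf_life_years", "excipient")
  )
  if (any(!excipients$solid_form %in% c("crystalline", "amorphous", "mixed"))) {
    abort("excipient table: solid_form must be crystalline, amorphous or mixed",
          class = "bud_validation_error")
  }
  if (any(excipients$shelf_life_years <= 0)) {
    abort("excipient table: shelf_life_years must be > 0",
          class = "bud_validation_error")
  }

  main <- canonicalize_excipient(records$main_excipient)
  other <- canonicalize_excipient(records$other_excipient)
  records_out <- tibble::tibble(
    api_name = records$api_name,
    main_excipient = ifelse(is.na(main), "UNKNOWN", main),
    other_excipient = ifelse(is.na(other), "NONE", other),
    main_excipient_display = records$main_excipient,
    other_excipient_display = records$other_excipient,
    packaging = canonicalize_packaging(records$packaging),
    packaging_display = records$packaging,
    dose_mg = parse_numeric(records$dose_mg, "dose_mg", "stability", allow_missing = TRUE),
    content_pct = parse_numeric(records$content_pct, "content_pct", "stability", allow_missing = TRUE),
    temperature_c = parse_numeric(records$temperature_c, "temperature_c", "stability"),
    bud_days = parse_numeric(records$bud_days, "bud_days", "stability")
  )

  validate_records(records_out, apis)
  new_curated_dataset(apis, excipients, records_out)
}

validate_records <- function(records, apis) {
  if (nrow(records) == 0) return(invisible(records))
  bad_api <- !records$api_name %in% apis$name
  if (any(bad_api)) {
    i <- which(bad_api)[1]
    abort(sprintf("stability row %d: api_name '%s' not found in API table",
                  i, records$api_name[i]),
          class = "bud_reference_error")
  }
  for (col in c("main_excipient", "other_excipient")) {
    vals <- records[[col]]
    ok <- vals %in% c(EXCIPIENT_LEVELS, "UNKNOWN", "NONE")
    if (any(!ok)) {
      i <- which(!ok)[1]
      abort(sprintf("stability row %d: %s '%s' is not a known excipient",
                    i, col, vals[i]),
            class = "bud_reference_error")
    }
  }
  both <- records$main_excipient != "UNKNOWN" & records$other_excipient != "NONE"
  clash <- both & records$main_excipient == records$other_excipient
  if (any(clash)) {
    abort(sprintf("stability row %d: main and other excipient are identical",
                  which(clash)[1]),
          class = "bud_validation_error")
  }
  if (any(records$bud_days <= 0 | is.na(records$bud_days))) {
    abort("stability records: bud_days must be > 0", class = "bud_validation_error")
  }
  cp <- records$content_pct
  if (any(!is.na(cp) & (cp <= 0 | cp > 100))) {
    abort("stability records: content_pct must lie in (0, 100] when present",
          class = "bud_validation_error")
  }
  invisible(records)
}

#' Write a curated dataset back to its three CSV tables
#'
#' Emits CSVs that reproduce the load-time representation: display strings and
#' sentinels (`ND`, `-`) are restored so that `load_dataset()` on the written
#' files returns a dataset identical to `ds`.
#'
#' @param ds A `curated_dataset`.
#' @param stability_path,api_path,excipient_path Output file paths.
#' @return Invisibly, the three paths.
#' @export
write_dataset <- function(ds, stability_path, api_path, excipient_path) {
  stopifnot(inherits(ds, "curated_dataset"))
  num_chr <- function(x, sentinel = "-") ifelse(is.na(x), sentinel, sprintf("%.15g", x))
  api_out <- ds$apis
  api_out$mc_printed <- num_chr(api_out$mc_printed, "ND")
  api_out$msc_printed <- num_chr(api_out$msc_printed, "ND")
  readr::write_csv(api_out, api_path, progress = FALSE)
  exc_out <- ds$excipients
  exc_out$mc_printed <- num_chr(exc_out$mc_printed, "ND")
  exc_out$msc_printed <- num_chr(exc_out$msc_printed, "ND")
  readr::write_csv(exc_out, excipient_path, progress = FALSE)
  rec <- ds$records
  rec_out <- tibble::tibble(
    api_name = rec$api_name,
    main_excipient = rec$main_excipient_display,
    other_excipient = rec$other_excipient_display,
    packaging = rec$packaging_display,
    dose_mg = num_chr(rec$dose_mg),
    content_pct = num_chr(rec$content_pct),
    temperature_c = num_chr(rec$temperature_c),
    bud_days = num_chr(rec$bud_days)
  )
  readr::write_csv(rec_out, stability_path, progress = FALSE)
  invisible(c(stability = stability_path, api = api_path,
              excipient = excipient_path))
}

#' Summarize a curated dataset
#'
#' Counts records, APIs, excipients and known packaging types, and reports the
#' `[min, max]` ranges of temperature, content and BUD over non-missing values.
#'
#' @param ds A `curated_dataset`.
#' @return A list of class `dataset_summary` with elements `n_records`,
#'   `n_apis`, `n_excipients`, `packaging` (named count vector over known
#'   types), and numeric ranges `temperature_range`, `content_range`,
#'   `bud_range`.
#' @export
#' @examples
#' dataset_summary(load_dataset())
dataset_summary <- function(ds) {
  stopifnot(inherits(ds, "curated_dataset"))
  rec <- ds$records
  rng <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) c(NA_real_, NA_real_) else c(min(x), max(x))
  }
  known_pack <- rec$packaging[rec$packaging != "UNKNOWN"]
  out <- list(
    n_records = nrow(rec),
    n_apis = nrow(ds$apis),
    n_excipients = nrow(ds$excipients),
    packaging = table(factor(known_pack, levels = PACKAGING_LEVELS)),
    temperature_range = rng(rec$temperature_c),
    content_range = rng(rec$content_pct),
    bud_range = rng(rec$bud_days)
  )
  class(out) <- "dataset_summary"
  out
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat(sprintf("Curated stability dataset: %d records, %d APIs, %d excipients\n",
              x$n_records, x$n_apis, x$n_excipients))
  cat("  packaging (known): ",
      paste(sprintf("%s=%d", names(x$packaging), as.integer(x$packaging)),
            collapse = ", "), "\n", sep = "")
  fmt <- function(r) if (anyNA(r)) "n/a" else sprintf("[%g, %g]", r[1], r[2])
  cat(sprintf("  temperature %s degC; content %s %%; BUD %s days\n",
              fmt(x$temperature_range), fmt(x$content_range), fmt(x$bud_range)))
  invisible(x)
}

#' @export
print.curated_dataset <- function(x, ...) {
  cat(sprintf("<curated_dataset> %d stability records, %d APIs, %d excipients\n",
              nrow(x$records), nrow(x$apis), nrow(x$excipients)))
  invisible(x)
}
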