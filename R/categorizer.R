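# Descriptor categorization framework: per-descriptor class assignment,
# composite indices (molecule class MC, molecular structure class MSC,
# storage class), the 7-position excipient indicator, and assembly of the
# 27-feature row consumed by the regressors.

#' Construct a binning scheme
#'
#' A scheme maps any finite real value to a class index `1..class_count`.
#' Class 1 is the open lower class (`value < lower`); interior classes are
#' half-open intervals `[lower + step*(k-2), lower + step*(k-1))`; the top
#' class is open above.
#'
#' @param name Scheme name.
#' @param class_count Number of classes (>= 2).
#' @param lower Value below which class 1 applies.
#' @param step Bin width (> 0).
#' @return An object of class `bin_scheme`.
#' @export
bin_scheme <- function(name, class_count, lower, step) {
  stopifnot(is.numeric(class_count), class_count >= 2,
            is.numeric(lower), is.numeric(step), step > 0)
  structure(list(name = name, class_count = as.integer(class_count),
                 lower = lower, step = step),
            class = "bin_scheme")
}

#' Default binning schemes of the categorization framework
#'
#' Scheme cardinalities: MW 25 classes (50 g/mol steps from below 50),
#' LogP 46 (0.5 steps from below -10), RB/HBD/HBA/AR 8 each (steps of 3 from
#' below 3), PS 21 (50 A^2 steps from below 50), content 10 (10% steps from
#' below 10), temperature 15 (5 degC steps from below -15). Packaging is a
#' fixed 3-level code (glass=1, plastic=2, paper=3; unknown contributes 0).
#'
#' @return Named list of `bin_scheme` objects with elements `mw`, `logp`,
#'   `rb`, `ps`, `hbd`, `hba`, `ar`, `content`, `temperature`.
#' @export
default_schemes <- function() {
  list(
    mw = bin_scheme("mw", 25, 50, 50),
    logp = bin_scheme("logp", 46, -10, 0.5),
    rb = bin_scheme("rb", 8, 3, 3),
    ps = bin_scheme("ps", 21, 50, 50),
    hbd = bin_scheme("hbd", 8, 3, 3),
    hba = bin_scheme("hba", 8, 3, 3),
    ar = bin_scheme("ar", 8, 3, 3),
    content = bin_scheme("content", 10, 10, 10),
    temperature = bin_scheme("temperature", 15, -15, 5)
  )
}

#' Assign a class index under a binning scheme
#'
#' Vectorized over `value`. A tiny relative tolerance (1e-9 of the step)
#' guards bin edges against floating-point representation error.
#'
#' @param value Finite numeric vector.
#' @param scheme A [bin_scheme()].
#' @return Integer class indices in `1..scheme$class_count`.
#' @export
#' @examples
#' assign_class(94.12, default_schemes()$mw)   # class 2
#' assign_class(25, default_schemes()$temperature)  # class 10
assign_class <- function(value, scheme) {
  stopifnot(inherits(scheme, "bin_scheme"))
  if (any(!is.finite(value))) {
    abort(sprintf("assign_class(%s): value must be finite", scheme$name),
          class = "bud_domain_error")
  }
  k <- floor((value - scheme$lower) / scheme$step + 1e-9) + 2L
  k[value < scheme$lower] <- 1L
  as.integer(pmin(pmax(k, 1L), scheme$class_count))
}

packaging_class <- function(packaging) {
  cls <- match(packaging, PACKAGING_LEVELS)  # glass=1, plastic=2, paper=3
  cls[packaging == "UNKNOWN"] <- 0L
  if (anyNA(cls)) {
    abort("packaging must be glass, plastic, paper or UNKNOWN",
          class = "bud_domain_error")
  }
  as.integer(cls)
}

content_class <- function(content_pct, schemes = default_schemes()) {
  out <- rep(0L, length(content_pct))  # MISSING contributes class 0
  ok <- !is.na(content_pct)
  out[ok] <- assign_class(content_pct[ok], schemes$content)
  out
}

#' Encode an excipient set as the 7-position binary indicator
#'
#' Positions are (lactose, silica, cellulose, mannitol, sucrose, hpmc,
#' reserved); the reserved slot is always 0. Order-insensitive: any ordering
#' of the same set yields the same indicator.
#'
#' @param excipients Character vector of 0-2 canonical excipient names.
#' @return Named integer vector of length 7 with values in `{0, 1}`.
#' @export
#' @examples
#' encode_excipients("lactose")
#' encode_excipients(c("lactose", "cellulose"))
encode_excipients <- function(excipients) {
  excipients <- unique(excipients[!is.na(excipients) &
                                    !excipients %in% c("UNKNOWN", "NONE")])
  bad <- setdiff(excipients, EXCIPIENT_LEVELS)
  if (length(bad) > 0) {
    abort(sprintf("unknown excipient name(s): %s", paste(bad, collapse = ", ")),
          class = "bud_domain_error")
  }
  ind <- as.integer(EXCIPIENT_LEVELS %in% excipients)
  setNames(c(ind, 0L), c(EXCIPIENT_LEVELS, "reserved"))
}

#' Pack an excipient indicator into a single integer feature
#'
#' Bit-packs the 7-position indicator (lactose = bit 1 ... hpmc = bit 6,
#' reserved = bit 7) so it occupies one column of the 27-feature row.
#'
#' @param indicator Result of [encode_excipients()].
#' @return Single integer in `0..127`.
#' @export
pack_indicator <- function(indicator) {
  stopifnot(length(indicator) == 7, all(indicator %in% c(0L, 1L)))
  as.integer(sum(indicator * 2^(seq_len(7) - 1)))
}

indicator_code <- function(main, other) {
  # vectorized over parallel main/other vectors
  vapply(seq_along(main), function(i) {
    pack_indicator(encode_excipients(c(main[i], other[i])))
  }, integer(1))
}

#' Composite molecule class (MC)
#'
#' MC is the sum of the MW, LogP and rotatable-bond class indices.
#'
#' @param api A data frame (or one-row tibble) with columns `mw`, `logp`,
#'   `rb`; vectorized over rows.
#' @param schemes Binning schemes, by default [default_schemes()].
#' @return Integer MC values.
#' @export
#' @examples
#' ds <- load_dataset()
#' molecule_class(ds$apis[ds$apis$name == "Melatonin", ])  # 31
molecule_class <- function(api, schemes = default_schemes()) {
  assign_class(api$mw, schemes$mw) +
    assign_class(api$logp, schemes$logp) +
    assign_class(api$rb, schemes$rb)
}

#' Composite molecular structure class (MSC)
#'
#' MSC is the sum of the polar-surface, H-bond-donor, H-bond-acceptor and
#' aromatic-ring class indices (donor and acceptor counts each contribute
#' their own class).
#'
#' @inheritParams molecule_class
#' @param api A data frame with columns `ps`, `hbd`, `hba`, `ar`.
#' @return Integer MSC values.
#' @export
molecular_structure_class <- function(api, schemes = default_schemes()) {
  assign_class(api$ps, schemes$ps) +
    assign_class(api$hbd, schemes$hbd) +
    assign_class(api$hba, schemes$hba) +
    assign_class(api$ar, schemes$ar)
}

#' Composite storage class
#'
#' Sum of the packaging class (glass=1, plastic=2, paper=3, UNKNOWN=0), the
#' content class (10-level scheme; missing content contributes 0) and the
#' temperature class (15-level scheme).
#'
#' @param packaging Character vector over
#'   `{glass, plastic, paper, UNKNOWN}`.
#' @param content_pct Numeric content percentages; `NA` = missing.
#' @param temperature_c Finite storage temperatures in degC.
#' @param schemes Binning schemes.
#' @return Integer storage class values.
#' @export
#' @examples
#' storage_class("glass", 4, 25)  # 1 + 1 + 10 = 12
storage_class <- function(packaging, content_pct, temperature_c,
                          schemes = default_schemes()) {
  packaging_class(packaging) +
    content_class(content_pct, schemes) +
    assign_class(temperature_c, schemes$temperature)
}

# The excipient pair is a set: featurization is insensitive to which member
# was recorded as "main". Canonical order (EXCIPIENT_LEVELS) decides which
# one carries the main-excipient code.
canonical_pair <- function(main, other) {
  known <- lapply(seq_along(main), function(i) {
    e <- c(main[i], other[i])
    e <- e[e %in% EXCIPIENT_LEVELS]
    e[order(match(e, EXCIPIENT_LEVELS))]
  })
  list(
    main = vapply(known, function(e) if (length(e) >= 1) e[1] else "UNKNOWN",
                  character(1)),
    other = vapply(known, function(e) if (length(e) >= 2) e[2] else "NONE",
                   character(1))
  )
}

# Label-encoding codebook: APIs and SMILES by first appearance in the API
# table (file order); main excipients by first appearance in the records
# (after canonicalizing the excipient pair).
build_codebook <- function(ds) {
  mains <- canonical_pair(ds$records$main_excipient,
                          ds$records$other_excipient)$main
  main_levels <- unique(mains[mains != "UNKNOWN"])
  list(
    name = setNames(seq_along(ds$apis$name), ds$apis$name),
    smiles = setNames(seq_along(ds$apis$smiles), ds$apis$smiles),
    main_excipient = setNames(seq_along(main_levels), main_levels),
    packaging = setNames(seq_along(PACKAGING_LEVELS), PACKAGING_LEVELS)
  )
}

# Deterministically extend a code map with unseen labels (appearance order).
extend_codes <- function(codes, labels) {
  new <- setdiff(unique(labels[!is.na(labels)]), names(codes))
  if (length(new) > 0) {
    codes <- c(codes, setNames(length(codes) + seq_along(new), new))
  }
  codes
}

lookup_code <- function(codes, labels, unknown = c("UNKNOWN", "NONE")) {
  out <- unname(codes[labels])
  out[labels %in% unknown] <- 0L
  if (anyNA(out)) {
    abort(sprintf("no label code for '%s'", labels[which(is.na(out))[1]]),
          class = "bud_domain_error")
  }
  as.integer(out)
}

FEATURE_SCHEMA <- c(
  "name_code", "smiles_code", "mw", "mw_class", "logp", "logp_class",
  "rb", "rb_class", "ps", "ps_class", "hbd", "hbd_class", "hba", "hba_class",
  "ar", "ar_class", "mc", "msc",
  "main_excipient_code", "excipient_indicator", "content_pct", "content_class",
  "packaging_code", "packaging_class", "temperature_c", "temperature_class",
  "storage_class"
)

#' Ordered names of the 27 feature columns
#'
#' 18 API descriptors, 4 formulation descriptors and 5 conditioning/storage
#' descriptors, in fixed order.
#'
#' @return Character vector of length 27.
#' @export
feature_schema <- function() FEATURE_SCHEMA

# Core feature assembly shared by featurize_dataset() and the grid module.
assemble_features <- function(api_rows, main_excipient, other_excipient,
                              packaging, content_pct, temperature_c,
                              codebook, schemes = default_schemes()) {
  mwc <- assign_class(api_rows$mw, schemes$mw)
  lpc <- assign_class(api_rows$logp, schemes$logp)
  rbc <- assign_class(api_rows$rb, schemes$rb)
  psc <- assign_class(api_rows$ps, schemes$ps)
  hdc <- assign_class(api_rows$hbd, schemes$hbd)
  hac <- assign_class(api_rows$hba, schemes$hba)
  arc <- assign_class(api_rows$ar, schemes$ar)
  cc <- content_class(content_pct, schemes)
  pc <- packaging_class(packaging)
  tc <- assign_class(temperature_c, schemes$temperature)
  pair <- canonical_pair(main_excipient, other_excipient)
  main_excipient <- pair$main
  other_excipient <- pair$other
  tibble::tibble(
    name_code = lookup_code(codebook$name, api_rows$name, unknown = character()),
    smiles_code = lookup_code(codebook$smiles, api_rows$smiles, unknown = character()),
    mw = api_rows$mw, mw_class = mwc,
    logp = api_rows$logp, logp_class = lpc,
    rb = as.numeric(api_rows$rb), rb_class = rbc,
    ps = api_rows$ps, ps_class = psc,
    hbd = as.numeric(api_rows$hbd), hbd_class = hdc,
    hba = as.numeric(api_rows$hba), hba_class = hac,
    ar = as.numeric(api_rows$ar), ar_class = arc,
    mc = mwc + lpc + rbc,
    msc = psc + hdc + hac + arc,
    main_excipient_code = lookup_code(codebook$main_excipient, main_excipient),
    excipient_indicator = indicator_code(main_excipient, other_excipient),
    content_pct = content_pct,
    content_class = cc,
    packaging_code = lookup_code(codebook$packaging, packaging),
    packaging_class = pc,
    temperature_c = temperature_c,
    temperature_class = tc,
    storage_class = pc + cc + tc
  )
}

#' Encode all stability records of a dataset as 27-feature rows
#'
#' Builds the full feature table consumed by the regressors: 18 API
#' descriptors (raw values, their class indices, and the composite MC/MSC),
#' 4 formulation descriptors (main-excipient code, bit-packed excipient
#' indicator, content and content class) and 5 conditioning/storage
#' descriptors (packaging code/class, temperature and class, storage class),
#' plus the `bud_days` target. Name, SMILES and main-excipient codes are
#' label-encoded by first appearance order in `ds`.
#'
#' @param ds A `curated_dataset`.
#' @param schemes Binning schemes.
#' @return Tibble with the 27 [feature_schema()] columns plus `bud_days`,
#'   one row per stability record in file order.
#' @export
#' @examples
#' feats <- featurize_dataset(load_dataset())
#' ncol(feats)  # 27 features + bud_days
featurize_dataset <- function(ds, schemes = default_schemes()) {
  stopifnot(inherits(ds, "curated_dataset"))
  rec <- ds$records
  if (nrow(rec) == 0) {
    abort("dataset has no stability records to featurize",
          class = "bud_domain_error")
  }
  codebook <- build_codebook(ds)
  api_rows <- ds$apis[match(rec$api_name, ds$apis$name), ]
  out <- assemble_features(api_rows, rec$main_excipient, rec$other_excipient,
                           rec$packaging, rec$content_pct, rec$temperature_c,
                           codebook, schemes)
  out$bud_days <- rec$bud_days
  out
}

#' Encode a single stability record
#'
#' @param record One-row data frame with the stability-record fields
#'   (`api_name`, `main_excipient`, `other_excipient`, `packaging`,
#'   `content_pct`, `temperature_c`, optionally `bud_days`).
#' @param ds The `curated_dataset` that `record` resolves against (defines
#'   the label-encoding codebook).
#' @param schemes Binning schemes.
#' @return One-row tibble with the 27 feature columns (plus `bud_days` when
#'   present in `record`).
#' @export
featurize <- function(record, ds, schemes = default_schemes()) {
  stopifnot(is.data.frame(record), nrow(record) == 1)
  codebook <- build_codebook(ds)
  i <- match(record$api_name, ds$apis$name)
  if (is.na(i)) {
    abort(sprintf("api_name '%s' not found in dataset", record$api_name),
          class = "bud_reference_error")
  }
  out <- assemble_features(ds$apis[i, ], record$main_excipient,
                           record$other_excipient, record$packaging,
                           record$content_pct, record$temperature_c,
                           codebook, schemes)
  if ("bud_days" %in% names(record)) out$bud_days <- record$bud_days
  out
}

#' Computed-versus-printed composite class report
#'
#' For every API (and excipient, when descriptor rows carry printed values)
#' compares the MC/MSC computed under the package's binning convention with
#' the reference values stored in the fixture, reporting the deltas. Rows of
#' the source tables whose printed values disagree with any single consistent
#' convention are flagged rather than matched.
#'
#' @param ds A `curated_dataset`.
#' @param schemes Binning schemes.
#' @return Tibble with columns `name`, `mc_computed`, `mc_printed`,
#'   `mc_delta`, `msc_computed`, `msc_printed`, `msc_delta`, `consistent`.
#' @export
class_delta_report <- function(ds, schemes = default_schemes()) {
  apis <- ds$apis
  mc <- molecule_class(apis, schemes)
  msc <- molecular_structure_class(apis, schemes)
  tibble::tibble(
    name = apis$name,
    mc_computed = mc,
    mc_printed = apis$mc_printed,
    mc_delta = mc - apis$mc_printed,
    msc_computed = msc,
    msc_printed = apis$msc_printed,
    msc_delta = msc - apis$msc_printed,
    consistent = (mc - apis$mc_printed == 0) & (msc - apis$msc_printed == 0)
  )
}
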