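test_that("class assignment matches the edge-scan oracle on spot values", {
  s <- default_schemes()
  expect_identical(assign_class(94.12, s$mw), 2L)
  expect_identical(assign_class(-10.5, s$logp), 1L)
  expect_identical(assign_class(13.0, s$logp), 46L)
  expect_identical(assign_class(25, s$temperature), 10L)
  expect_error(assign_class(NaN, s$mw), class = "bud_domain_error")
  expect_error(assign_class(Inf, s$temperature), class = "bud_domain_error")
})

test_that("scheme cardinalities match the categorization framework exactly", {
  s <- default_schemes()
  counts <- vapply(s, function(x) x$class_count, integer(1))
  expect_identical(
    counts[c("mw", "logp", "rb", "ps", "hbd", "hba", "ar", "content",
             "temperature")],
    c(mw = 25L, logp = 46L, rb = 8L, ps = 21L, hbd = 8L, hba = 8L, ar = 8L,
      content = 10L, temperature = 15L))
  # packaging: fixed 3-level code
  expect_identical(storage_class(c("glass", "plastic", "paper"), NA, -100) -
                     storage_class("UNKNOWN", NA, -100), 1:3)
})

test_that("every scheme partitions the reals and is monotone (dense-grid scan)", {
  for (scheme in default_schemes()) {
    K <- scheme$class_count
    grid <- seq(scheme$lower - 3 * scheme$step,
                scheme$lower + (K + 1) * scheme$step,
                by = scheme$step / 4)
    got <- assign_class(grid, scheme)
    expect_equal(as.numeric(got), oracle_class(grid, scheme),
                 info = scheme$name)
    expect_true(all(got >= 1 & got <= K))
    expect_true(all(diff(got) >= 0))          # monotone in the value
    expect_setequal(unique(got), 1:K)          # every class reachable
  }
})

test_that("excipient indicator encoding is exact, order-insensitive and idempotent", {
  expect_identical(unname(encode_excipients("lactose")),
                   c(1L, 0L, 0L, 0L, 0L, 0L, 0L))
  expect_identical(unname(encode_excipients(c("lactose", "cellulose"))),
                   c(1L, 0L, 1L, 0L, 0L, 0L, 0L))
  expect_identical(unname(encode_excipients(character(0))), rep(0L, 7))
  expect_identical(encode_excipients(c("silica", "lactose")),
                   encode_excipients(c("lactose", "silica")))
  expect_identical(encode_excipients(c("hpmc", "hpmc")),
                   encode_excipients("hpmc"))
  ind <- encode_excipients(c("mannitol", "sucrose"))
  expect_identical(sum(ind), 2L)
  expect_identical(unname(ind["reserved"]), 0L)
  expect_error(encode_excipients("lactulose"), class = "bud_domain_error")
  expect_identical(pack_indicator(encode_excipients("lactose")), 1L)
  expect_identical(pack_indicator(encode_excipients(c("lactose", "hpmc"))), 33L)
})

test_that("composite classes reproduce the verified reference rows", {
  apis <- fixture_ds()$apis
  one <- function(n) apis[apis$name == n, ]
  expect_identical(molecule_class(one("Melatonin")), 31L)
  expect_identical(molecular_structure_class(one("Melatonin")), 6L)
  expect_identical(molecule_class(one("Menadione")), 30L)
  expect_identical(molecular_structure_class(one("Menadione")), 4L)
  expect_identical(molecule_class(one("Captopril")), 29L)
  expect_identical(molecular_structure_class(one("Captopril")), 6L)
  expect_identical(molecule_class(one("4-Aminopyridine")), 24L)
  expect_identical(molecule_class(one("Clonidine hydrochloride")), 33L)
  expect_identical(molecule_class(one("Midazolam hydrochloride")), 38L)
  # minimal API: every component in its open bottom class
  tiny <- tibble::tibble(mw = 10, logp = -11, rb = 0L, ps = 0, hbd = 0L,
                         hba = 0L, ar = 0L)
  expect_identical(molecule_class(tiny), 3L)
  expect_identical(molecular_structure_class(tiny), 4L)
})

test_that("the delta report flags printed values that no single convention fits", {
  dr <- class_delta_report(fixture_ds())
  con <- dr[dr$name %in% c("Melatonin", "Menadione", "Captopril",
                           "4-Aminopyridine", "Clonidine hydrochloride",
                           "Midazolam hydrochloride"), ]
  expect_true(all(con$consistent))
  inc <- dr[dr$name %in% c("Acetylsalicylic acid", "Atenolol", "Naltrexone",
                           "Nifedipine", "Hydrocortisone", "Erythromycin"), ]
  expect_true(all(!inc$consistent))
  expect_true(all(abs(c(inc$mc_delta, inc$msc_delta)) <= 4))
})

test_that("storage class sums its packaging, content and temperature components", {
  expect_identical(storage_class("glass", 4, 25), 12L)
  expect_identical(storage_class("glass", 5, -20), 3L)
  expect_identical(storage_class("UNKNOWN", NA, 25), 10L)
})

test_that("featurized fixture rows satisfy the composite conservation laws", {
  ds <- fixture_ds()
  f <- featurize_dataset(ds)
  expect_identical(ncol(f), 28L)  # 27 features + target
  expect_identical(setdiff(names(f), "bud_days"), feature_schema())
  expect_identical(f$mc, f$mw_class + f$logp_class + f$rb_class)
  expect_identical(f$msc,
                   f$ps_class + f$hbd_class + f$hba_class + f$ar_class)
  expect_identical(f$storage_class,
                   f$packaging_class + f$content_class + f$temperature_class)
  # missing content contributes class 0, not an imputed class
  expect_true(all(f$content_class[is.na(f$content_pct)] == 0L))
  # recompute component classes independently from raw descriptor values
  s <- default_schemes()
  expect_equal(as.numeric(f$mw_class), oracle_class(f$mw, s$mw))
  expect_equal(as.numeric(f$logp_class), oracle_class(f$logp, s$logp))
  expect_equal(as.numeric(f$temperature_class),
               oracle_class(f$temperature_c, s$temperature))
})

test_that("featurize resolves a single record and honors excipient set semantics", {
  ds <- fixture_ds()
  rec <- ds$records[ds$records$api_name == "Melatonin" &
                      ds$records$other_excipient == "hpmc", ][1, ]
  row <- featurize(rec, ds)
  expect_identical(row$excipient_indicator,
                   pack_indicator(encode_excipients(c("lactose", "hpmc"))))
  expect_identical(row$mc, 31L)
  expect_identical(row$msc, 6L)
  # swapping which member of the pair is "main" leaves the row unchanged
  swapped <- rec
  swapped$main_excipient <- rec$other_excipient
  swapped$other_excipient <- rec$main_excipient
  expect_identical(featurize(swapped, ds), row)
})
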