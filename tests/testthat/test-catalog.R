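test_that("symbol harmonization maps aliases and rejects empty input", {
  expect_equal(harmonize_symbol("C10ORF90", c(C10ORF90 = "C10orf90")),
               "C10orf90")
  expect_equal(harmonize_symbol("VHL", character()), "VHL")
  expect_equal(
    harmonize_symbol(c("A", "B"), tibble::tibble(alias = "A", symbol = "Z")),
    c("Z", "B"))
  expect_error(harmonize_symbol("", c(X = "Y")), "non-empty")
})

test_that("per-source sub-scores follow the four printed rules", {
  expect_equal(score_source(source_record("X", "GE", lit_validated = TRUE)), 2L)
  expect_equal(score_source(source_record("X", "GE", lit_validated = FALSE)), 1L)
  expect_equal(
    score_source(source_record("X", "UBIHUB", function_text = "RING E3 ligase")),
    2L)
  # "E3" must match as a token, not as a substring of another symbol
  expect_equal(
    score_source(source_record("X", "UBIHUB",
                               function_text = "UBE3A-like HECT domain")),
    1L)
  expect_equal(
    score_source(source_record("X", "UBIHUB", function_text = "e3 ligase")),
    2L)
  # "over 5" is strict: exactly 5 curated ESIs score 1
  expect_equal(score_source(source_record("X", "UBIBROWSER", esi_count = 5L)), 1L)
  expect_equal(score_source(source_record("X", "UBIBROWSER", esi_count = 6L)), 2L)
})

test_that("confidence is the sum over present sources, 1 to 6", {
  all_max <- list(
    source_record("VHL", "GE", lit_validated = TRUE),
    source_record("VHL", "UBIHUB", function_text = "E3 ubiquitin ligase"),
    source_record("VHL", "UBIBROWSER", esi_count = 12L))
  expect_equal(confidence_score(all_max), 6L)
  expect_equal(
    confidence_score(list(source_record("X", "GE", lit_validated = FALSE))), 1L)
  expect_equal(
    confidence_score(list(
      source_record("X", "GE", lit_validated = TRUE),
      source_record("X", "UBIHUB", function_text = "kinase adaptor"))),
    3L)
  expect_error(confidence_score(list()), "cannot enter")
  expect_error(confidence_score(list(
    source_record("X", "GE", lit_validated = TRUE),
    source_record("Y", "GE", lit_validated = TRUE))), "same symbol")
})

test_that("catalog assembly unions sources with deterministic order", {
  src <- tiny_sources()
  cat_tbl <- assemble_catalog(src$ge, src$ubihub, src$ubibrowser,
                              co_opted_config(c("VHL", "CRBN"), c("VHL")))
  # oracle: plain set union of harmonized symbols
  expect_equal(cat_tbl$symbol,
               sort(Reduce(union, lapply(src, `[[`, "symbol"))))
  vhl <- cat_tbl[cat_tbl$symbol == "VHL", ]
  expect_equal(vhl$confidence, 6)
  # AAA1: GE predicted (1) + esi_count 5 (1) = 2
  expect_equal(cat_tbl$confidence[cat_tbl$symbol == "AAA1"], 2)
  expect_true(all(cat_tbl$confidence >= 1 & cat_tbl$confidence <= 6))
  expect_true(vhl$co_opted && vhl$clinical)
  expect_false(cat_tbl$co_opted[cat_tbl$symbol == "AAA1"])
  # idempotence
  expect_identical(
    cat_tbl,
    assemble_catalog(src$ge, src$ubihub, src$ubibrowser,
                     co_opted_config(c("VHL", "CRBN"), c("VHL"))))
})

test_that("adding a source never decreases confidence (monotonicity)", {
  src <- tiny_sources()
  base <- assemble_catalog(src$ge, src$ubihub[0, ], src$ubibrowser,
                           co_opted_config("VHL", character()))
  full <- assemble_catalog(src$ge, src$ubihub, src$ubibrowser,
                           co_opted_config("VHL", character()))
  shared <- intersect(base$symbol, full$symbol)
  expect_true(all(
    full$confidence[match(shared, full$symbol)] >=
      base$confidence[match(shared, base$symbol)]))
  # three-source members score at least 3
  three <- full$symbol[full$n_sources == 3]
  expect_true(all(full$confidence[full$symbol %in% three] >= 3))
})

test_that("within-source duplicates keep the max sub-score and IAPs collapse", {
  ge <- tibble::tibble(symbol = c("XIAP", "XIAP", "BIRC3"),
                       lit_validated = c(FALSE, TRUE, TRUE))
  src <- tiny_sources()
  expect_message(
    cat_tbl <- assemble_catalog(ge, src$ubihub[0, ], src$ubibrowser[0, ],
                                co_opted_config("XIAP", character())),
    "duplicate")
  expect_equal(cat_tbl$score_ge[cat_tbl$symbol == "XIAP"], 2L)
  # BIRC3 is represented by BIRC2/XIAP, so it is dropped from the catalog
  expect_false("BIRC3" %in% cat_tbl$symbol)
})

test_that("co-opted symbols absent from all sources warn and are not added", {
  src <- tiny_sources()
  expect_warning(
    cat_tbl <- assemble_catalog(src$ge, src$ubihub, src$ubibrowser,
                                co_opted_config(c("VHL", "GHOST9"), character())),
    "GHOST9")
  expect_false("GHOST9" %in% cat_tbl$symbol)
})

test_that("co-opted config validates the clinical subset", {
  expect_error(co_opted_config("VHL", "CRBN"), "subset")
  cfg <- co_opted_config()
  expect_true(all(cfg$clinical_symbols %in% cfg$co_opted_symbols))
})
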