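test_that("per-source retention filters apply the printed cutoffs", {
  string_tbl <- tibble::tibble(
    protein1 = "VHL", protein2 = c("T1", "T2", "T3"),
    combined_score = c(701, 700, 999), species = "9606")
  got <- load_source_edges(string_tbl, "STRING")
  expect_equal(got$b, c("T1", "T3"))
  expect_true(all(got$score > 700))

  ub <- tibble::tibble(
    ligase = "VHL", substrate = c("S1", "S2", "S3", "S4"),
    evidence = c("predicted", "predicted", "literature", "predicted"),
    confidence = c(0.70, 0.71, NA, 0.99), organism = "Homo sapiens")
  got <- load_source_edges(ub, "UBIBROWSER")
  expect_setequal(got$b, c("S2", "S3", "S4"))   # 0.70 dropped, literature kept
  expect_equal(got$source[got$b == "S3"], "UBIBROWSER_LIT")

  bg <- tibble::tibble(
    symbol_a = "VHL", symbol_b = c("T1", "T2"),
    organism_a = "9606", organism_b = c("9606", "10090"),
    method = c("Two-hybrid", "Two-hybrid"))
  got <- load_source_edges(bg, "BIOGRID")
  expect_equal(got$b, "T1")                      # non-human dropped
  expect_true(got$physical)                      # Y2H is physical evidence

  huri <- tibble::tibble(symbol_a = "VHL", symbol_b = "T9")
  expect_true(load_source_edges(huri, "HURI")$physical)

  re <- tibble::tibble(symbol_a = "VHL", symbol_b = "T1",
                       species = "Homo sapiens")
  expect_false(load_source_edges(re, "REACTOME")$physical)
})

test_that("malformed rows are skipped with a warning", {
  bad <- tibble::tibble(symbol_a = c("VHL", ""), symbol_b = c("T1", "T2"),
                        organism_a = "9606", organism_b = "9606")
  expect_warning(got <- load_source_edges(bad, "INTACT"), "malformed")
  expect_equal(nrow(got), 1L)
})

test_that("edge merging matches the set-semantics oracle", {
  raw <- tibble::tibble(
    a = c("VHL", "EGFR", "VHL", "X", "A", "B", "A", "VHL", "KRAS", "Q"),
    b = c("EGFR", "VHL", "EGFR", "X", "B", "A", "B", "KRAS", "VHL", "R"),
    source = c("STRING", "BIOGRID", "INTACT", "HURI", "REACTOME",
               "STRING", "HURI", "HURI", "STRING", "INTACT"),
    score = NA_real_, physical = FALSE)
  merged <- merge_edges(raw)
  oracle <- dedup_pairs_oracle(raw$a, raw$b)
  expect_equal(paste(merged$a, merged$b, sep = "|"), oracle)
  vhl_egfr <- merged[merged$a == "EGFR" & merged$b == "VHL", ]
  expect_equal(vhl_egfr$n_sources, 3L)
  expect_false(any(merged$a == merged$b))        # self-loop removed
  # idempotent and order-invariant
  expect_identical(merged,
                   merge_edges(raw[sample.int(nrow(raw)), ]))
  re_raw <- tibble::tibble(a = merged$a, b = merged$b,
                           source = "STRING", score = NA_real_,
                           physical = merged$physical)
  expect_equal(nrow(merge_edges(re_raw)), nrow(merged))
})

test_that("physical flag is OR across sources", {
  raw <- tibble::tibble(a = c("L", "T"), b = c("T", "L"),
                        source = c("STRING", "HURI"),
                        score = NA_real_, physical = c(FALSE, TRUE))
  expect_true(merge_edges(raw)$physical)
})

test_that("target space is monotone in the ligase set", {
  raw <- tibble::tibble(
    a = c("E1", "E1", "E2", "E2", "E3"),
    b = c("T1", "T2", "T2", "E3", "T3"),
    source = "HURI", score = NA_real_, physical = TRUE)
  edges <- merge_edges(raw)
  e3s <- c("E1", "E2", "E3")
  expect_equal(target_space(edges, "E1"), c("T1", "T2"))
  s1 <- target_space(edges, c("E1"), exclude_e3 = FALSE)
  s2 <- target_space(edges, c("E1", "E2"), exclude_e3 = FALSE)
  expect_true(all(s1 %in% s2))
  # E2-E3 edge: E3 excluded as a target when it is in the ligase set
  expect_equal(target_space(edges, e3s), c("T1", "T2", "T3"))
  expect_equal(target_space(edges, character()), character())
  expect_equal(target_space(edges[0, ], "E1"), character())
})

test_that("percent increase follows the printed reporting convention", {
  expect_equal(percent_increase(10930, 19248), 76.1)
  expect_equal(percent_increase(100, 100), 0.0)
  expect_equal(percent_increase(100, 250), 150.0)
  expect_error(percent_increase(0, 10), "positive")
  # closed-form roundtrip on rationals whose inverse is exact at one decimal
  expect_equal(percent_increase(100, 200),
               -percent_increase(200, 100) / (100 / 200))
})

test_that("E3-per-target counts include zeros only with an explicit universe", {
  raw <- tibble::tibble(
    a = c("E1", "E2", "E3", "E1"),
    b = c("T1", "T1", "T1", "T2"),
    source = "HURI", score = NA_real_, physical = TRUE)
  edges <- merge_edges(raw)
  e3s <- c("E1", "E2", "E3")
  res <- e3_per_target(edges, e3s)
  expect_equal(res$counts$n_e3[res$counts$target == "T1"], 3L)
  expect_equal(res$median, 2)                     # counts 3 and 1
  with_univ <- e3_per_target(edges, e3s, targets = c("T1", "T2", "T3", "T4"))
  expect_equal(with_univ$counts$n_e3,
               c(3L, 1L, 0L, 0L))
  expect_equal(with_univ$median, 0.5)
  expect_equal(e3_per_target(edges, e3s, targets = character())$median,
               NA_real_)
})

test_that("tractability sets expose union and overlap", {
  tr <- tractability_sets(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(tr$overlap, c("B", "C"))
  expect_equal(tr$union, c("A", "B", "C", "D"))
})
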