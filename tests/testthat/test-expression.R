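test_that("bulk tissue level is the per-tissue median", {
  mat <- rbind(G1 = c(3, 4, 5, 3, 5), G2 = c(7.2, 7.5, 8, 1, 1))
  colnames(mat) <- paste0("S", 1:5)
  meta <- tibble::tibble(sample = paste0("S", 1:5),
                         tissue = c("A", "A", "A", "B", "B"))
  expect_equal(bulk_tissue_level(mat, meta, "G1", "A"), 4.0)  # odd length
  expect_equal(bulk_tissue_level(mat, meta, "G1", "B"), 4.0)  # even midpoint
  expect_equal(bulk_tissue_level(mat[, 1, drop = FALSE],
                                 meta[1, ], "G2", "A"), 7.2)  # single sample
  expect_error(bulk_tissue_level(mat, meta, "G1", "Z"), "no samples")
  calls <- bulk_tissue_calls(mat, meta)
  expect_equal(nrow(calls), 4L)
  expect_equal(calls$call[calls$symbol == "G2" & calls$tissue == "A"], "High")
})

test_that("bulk High is strictly above 4 and monotone", {
  expect_equal(classify_bulk(4.0), "Low")
  expect_equal(classify_bulk(4.01), "High")
  expect_equal(classify_bulk(0), "Low")
  lv <- sort(runif(50, 0, 8))
  calls <- classify_bulk(lv)
  expect_true(all(diff(calls == "High") >= 0))  # monotone non-decreasing
})

test_that("staining High needs >= 20% medium/high samples by default", {
  expect_equal(classify_hpa(c(rep("high", 10), "low")), "High")      # 10 of 11
  expect_equal(classify_hpa(c("medium", rep("low", 9))), "Low")      # 10%
  expect_equal(classify_hpa(c(rep("high", 11), "low")), "High")      # 11 of 12
  on_boundary <- c(rep("medium", 2), rep("not_detected", 8))         # 20%
  expect_equal(classify_hpa(on_boundary), "High")
  expect_equal(classify_hpa(on_boundary, strict = TRUE), "Low")
  expect_error(classify_hpa(character()), "no staining")
  expect_error(classify_hpa("strong"), "vocabulary")
})

test_that("single-cell thresholds scale the reference pattern linearly", {
  thr <- derive_sc_thresholds(17, 3.1, 0.75)
  expect_identical(thr$frac_pct_threshold, 12.75)
  expect_identical(thr$mean_threshold, 2.325)
  id <- derive_sc_thresholds(9, 2.2, 1.0)
  expect_equal(c(id$frac_pct_threshold, id$mean_threshold), c(9, 2.2))
  half <- derive_sc_thresholds(10, 2, 0.5)
  expect_equal(c(half$frac_pct_threshold, half$mean_threshold), c(5, 1))
  dbl <- derive_sc_thresholds(10, 2, 1.0)
  expect_equal(dbl$frac_pct_threshold, 2 * half$frac_pct_threshold)
  expect_equal(dbl$mean_threshold, 2 * half$mean_threshold)
  expect_error(derive_sc_thresholds(0, 3.1, 0.75), "positive")
})

test_that("single-cell High needs both fraction and non-zero mean, strictly", {
  thr <- derive_sc_thresholds()
  expect_equal(classify_sc_tissue(c(rep(2.4, 13), rep(0, 87)), thr), "High")
  # exactly 12.75% non-zero is Low (strict)
  on_frac <- c(rep(3, 51), rep(0, 349))
  expect_equal(100 * mean(on_frac != 0), 12.75)
  expect_equal(classify_sc_tissue(on_frac, thr), "Low")
  # fraction fine but non-zero mean too low
  expect_equal(classify_sc_tissue(c(rep(2.0, 50), rep(0, 50)), thr), "Low")
  # non-zero mean exactly 2.325 is Low (strict)
  expect_equal(classify_sc_tissue(c(rep(2.325, 60), rep(0, 340)), thr), "Low")
  expect_error(classify_sc_tissue(numeric(), thr), "no cells")
})

test_that("low-in-majority uses an inclusive 70% rule", {
  expect_true(low_in_majority(c(rep("Low", 7), rep("High", 3))))
  expect_false(low_in_majority(c(rep("Low", 6), rep("High", 4))))
  expect_true(low_in_majority(rep("Low", 5)))
  expect_warning(res <- low_in_majority(character()), "empty")
  expect_false(res)
})

test_that("tumor selectivity is the conjunction of the four dataset flags", {
  hi <- c("High", rep("Low", 4)); lo <- rep("Low", 10)
  expect_true(tumor_selectivity(hi, hi, lo, lo))
  expect_false(tumor_selectivity(rep("High", 5), hi, rep("High", 10), lo))
  expect_false(tumor_selectivity(lo, hi, lo, lo))   # no tumor High in bulk
  expect_warning(res <- tumor_selectivity(hi, character(), lo, lo), "missing")
  expect_false(res)
  # oracle: direct recomputation of the conjunction on random profiles
  set.seed(99)
  for (i in 1:20) {
    tc <- sample(c("High", "Low"), 6, TRUE); hp <- sample(c("High", "Low"), 6, TRUE)
    gt <- sample(c("High", "Low"), 10, TRUE); tb <- sample(c("High", "Low"), 10, TRUE)
    expect_equal(
      tumor_selectivity(tc, hp, gt, tb),
      any(tc == "High") && any(hp == "High") &&
        mean(gt == "Low") >= 0.7 && mean(tb == "Low") >= 0.7)
  }
})

test_that("tumor single-cell composition reproduces printed-style ratios", {
  # group sizes and expressing counts as in the malignant-specific example
  grp <- rep(c("malignant", "immune", "other"), c(4099, 241, 35))
  expr <- c(rep(1, 2448), rep(0, 4099 - 2448),
            rep(1, 25), rep(0, 241 - 25),
            rep(1, 5), rep(0, 35 - 5))
  comp <- sc_tumor_composition(expr, grp)
  mal <- comp[comp$group == "malignant", ]
  expect_equal(mal$pct_of_expressing, 98.8)
  expect_equal(mal$pct_within_group, 59.7)
  expect_equal(comp$pct_within_group[comp$group == "immune"], 10.4)
  expect_equal(comp$pct_within_group[comp$group == "other"], 14.3)
  expect_lte(abs(sum(comp$pct_of_expressing) - 100), 0.1)
  # all expressing cells in one group
  one <- sc_tumor_composition(c(1, 1, 0, 0), c("m", "m", "i", "i"))
  expect_equal(one$pct_of_expressing[one$group == "m"], 100.0)
  # zero expressing cells are flagged
  none <- sc_tumor_composition(c(0, 0), c("m", "i"))
  expect_true(attr(none, "flagged"))
  expect_true(all(is.na(none$pct_of_expressing)))
})

test_that("reporting rounding is half-up at one decimal", {
  expect_equal(round_half_up(0.25 * 100, 1), 25.0)
  expect_equal(round_half_up(98.75, 1), 98.8)
  expect_equal(round_half_up(1.116, 1), 1.1)
  expect_equal(percent_of(275, 1075), 25.6)
  expect_equal(percent_of(12, 1075), 1.1)
})
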