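test_that("identical seeds give byte-identical bundles", {
  cfg <- sim_config(seed = 7, n_ligases = 12, n_targets = 150,
                    n_tumor_types = 3, n_normal_tissues = 3,
                    samples_per_tissue = 5, cells_per_tissue = 40,
                    n_co_opted = 3, n_clinical = 1, n_case1_passers = 1)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_bundle(cfg, d1)
  generate_bundle(cfg, d2)
  expect_identical(readLines(file.path(d1, "checksums.txt")),
                   readLines(file.path(d2, "checksums.txt")))
  # a different seed changes the bundle
  d3 <- withr::local_tempdir()
  generate_bundle(sim_config(seed = 8, n_ligases = 12, n_targets = 150,
                             n_tumor_types = 3, n_normal_tissues = 3,
                             samples_per_tissue = 5, cells_per_tissue = 40,
                             n_co_opted = 3, n_clinical = 1,
                             n_case1_passers = 1), d3)
  expect_false(identical(readLines(file.path(d1, "checksums.txt")),
                         readLines(file.path(d3, "checksums.txt"))))
})

test_that("the bundle parses under the pipeline readers without warnings", {
  sb <- small_bundle()
  expect_no_warning(suppressMessages(build_atlas(sb$dir)))
})

test_that("the pipeline reproduces the truth manifest on the small bundle", {
  sb <- small_bundle()
  tr <- sb$manifest$per_ligase
  s <- sb$atlas$summary[match(tr$symbol, sb$atlas$summary$symbol), ]
  expect_equal(s$symbol, tr$symbol)
  for (col in c("confidence", "co_opted", "clinical", "tier", "has_drug",
                "has_chem", "has_cova", "n_categories", "n_unique_ligands",
                "n_tcga_high", "n_hpa_high", "n_gtex_high", "n_tabula_high",
                "tumor_high_any_tcga", "tumor_high_any_hpa",
                "normal_low_majority_gtex", "normal_low_majority_tabula",
                "tumor_selective", "n_ppi", "essential_crispr",
                "essential_rnai", "in_cytoplasm", "in_nucleus", "n_pdb",
                "afdb_available", "n_interfaces")) {
    expect_equal(unname(unlist(s[[col]])), unname(unlist(tr[[col]])),
                 info = col)
  }
})

test_that("planted dark ligases have no ligand rows in the bundle", {
  sb <- small_bundle()
  dark <- sb$manifest$per_ligase$symbol[sb$manifest$per_ligase$tier == "E3dark"]
  if (length(dark) > 0) {
    chembl <- readr::read_tsv(file.path(sb$dir, "chembl.tsv"),
                              show_col_types = FALSE)
    drugs <- readr::read_tsv(file.path(sb$dir, "drugs.tsv"),
                             show_col_types = FALSE)
    cova <- readr::read_tsv(file.path(sb$dir, "covalent.tsv"),
                            show_col_types = FALSE)
    expect_false(any(dark %in% chembl$target_symbol))
    expect_false(any(dark %in% drugs$target_symbol))
    expect_false(any(dark %in% cova$symbol))
  }
})

test_that("network statistics on the bundle match the planted truth", {
  sb <- small_bundle()
  m <- sb$manifest
  at <- sb$atlas
  co <- at$catalog$symbol[at$catalog$co_opted]
  expect_equal(sort(co), sort(m$co_opted_symbols))
  expect_equal(length(target_space(at$edges, co)), m$co_opted_target_space_n)
  expect_equal(length(at$tractability$overlap), m$tractable_overlap_n)
  res_co <- e3_per_target(at$edges, co, targets = at$tractability$union)
  expect_equal(res_co$median, m$tractable_median_co_opted)
  res_all <- e3_per_target(at$edges, at$catalog$symbol,
                           targets = at$tractability$union)
  expect_equal(res_all$median, m$tractable_median_all)
})

test_that("tumor single-cell composition matches the planted marker counts", {
  sb <- small_bundle()
  stopifnot(!is.null(sb$atlas$tumor_sc))
  counts <- sb$atlas$tumor_sc$counts
  meta <- sb$atlas$tumor_sc$cell_meta
  for (mk in sb$manifest$tumor_sc_markers) {
    comp <- sc_tumor_composition(counts[mk$gene, ], meta$group)
    for (g in mk$groups) {
      row <- comp[comp$group == g$group, ]
      expect_equal(row$n_cells, g$n_cells)
      expect_equal(row$n_expressing, g$n_expressing)
    }
  }
})

test_that("config validation rejects impossible plants", {
  expect_error(sim_config(n_ligases = 0), "positive")
  expect_error(plant_case1_passers(sim_config(), 1000), "\\[0, n_ligases\\]")
  cfg <- plant_case1_passers(sim_config(n_ligases = 10, n_targets = 50,
                                        n_co_opted = 3, n_clinical = 1), 2)
  expect_error(generate_bundle(cfg, withr::local_tempdir()), "infeasible")
  expect_error(sim_config(n_co_opted = 5, n_clinical = 6), "n_clinical")
})

test_that("boundary fixtures sit exactly on the printed thresholds", {
  fx <- make_boundary_fixtures()
  expect_equal(fx$chembl$pchembl, c(5.0, 4.99))
  expect_equal(100 * mean(fx$sc_fraction_on != 0), 12.75)
  nz <- fx$sc_mean_on[fx$sc_mean_on != 0]
  expect_equal(mean(nz), 2.325)
  expect_equal(unname(fx$esi_counts), c(5L, 6L))
  expect_equal(nrow(fx$expected), 10L)
})
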