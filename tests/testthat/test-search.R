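test_that("ligase profile joins every dimension and rejects unknown symbols", {
  sb <- small_bundle()
  tr <- sb$manifest$per_ligase
  sym <- tr$symbol[5]
  prof <- ligase_profile(sb$atlas, sym)
  expect_s3_class(prof, "ligase_profile")
  expect_equal(prof$summary$confidence, tr$confidence[5])
  expect_equal(prof$summary$tier, tr$tier[5])
  expect_equal(prof$summary$n_ppi, tr$n_ppi[5])
  expect_equal(length(prof$partners), tr$n_ppi[5])
  dark <- tr$symbol[tr$tier == "E3dark"][1]
  if (!is.na(dark)) {
    expect_equal(ligase_profile(sb$atlas, dark)$summary$tier, "E3dark")
  }
  expect_error(ligase_profile(sb$atlas, "NOSUCHGENE"), "not in catalog")
})

test_that("all switches off returns the full catalog in deterministic order", {
  sb <- small_bundle()
  res <- general_search(sb$atlas, candidate_query())
  expect_equal(sort(res$symbol), sb$atlas$catalog$symbol)
  ord <- order(-res$confidence, -res$n_unique_ligands, res$symbol)
  expect_equal(ord, seq_len(nrow(res)))
})

test_that("filters use the printed strict comparisons", {
  sb <- small_bundle()
  s <- sb$atlas$summary
  res <- general_search(sb$atlas, candidate_query(min_confidence = 3))
  expect_true(all(res$confidence > 3))
  expect_true(any(s$confidence == 3))  # boundary ligase exists and is excluded
  expect_false(any(res$confidence == 3))
  # inclusive variant for sensitivity analysis
  res_inc <- general_search(sb$atlas,
                            candidate_query(min_confidence = 3, strict = FALSE))
  expect_true(any(res_inc$confidence == 3))
  # contradictory query: empty result, no error
  expect_equal(nrow(general_search(sb$atlas, candidate_query(min_confidence = 7))),
               0L)
})

test_that("tightening any slider never adds results (anti-monotonicity)", {
  sb <- small_bundle()
  loose <- general_search(sb$atlas, candidate_query(min_confidence = 2))
  for (q in list(candidate_query(min_confidence = 4),
                 candidate_query(min_confidence = 2, require_ligand = TRUE),
                 candidate_query(min_confidence = 2, min_ppi = 50),
                 candidate_query(min_confidence = 2, gtex_high_max_frac = 0.3),
                 candidate_query(min_confidence = 2, tcga_high_min = 1,
                                 require_structure = TRUE))) {
    expect_true(all(general_search(sb$atlas, q)$symbol %in% loose$symbol))
  }
})

test_that("target search restricts the general result and ranks by specificity", {
  sb <- small_bundle()
  edges <- sb$atlas$edges
  # pick a target interacting with several ligases
  tgt_counts <- table(c(edges$a, edges$b)[grepl("^TGT", c(edges$a, edges$b))])
  tgt <- names(tgt_counts)[which.max(tgt_counts)]
  q <- candidate_query()
  res <- search_by_target(sb$atlas, tgt, query = q)
  expect_gt(nrow(res), 1)
  expect_true(all(res$symbol %in% general_search(sb$atlas, q)$symbol))
  # every hit actually interacts with the target
  partners <- target_space(edges, tgt, exclude_e3 = FALSE)
  expect_true(all(res$symbol %in% partners))
  # within ties on (confidence, ligand count), lower PPI degree leads
  key <- paste(res$confidence, res$n_unique_ligands)
  for (kk in unique(key[duplicated(key)])) {
    expect_false(is.unsorted(res$n_ppi[key == kk]))
  }
  expect_equal(nrow(search_by_target(sb$atlas, "NOSUCHTARGET")), 0L)
})

test_that("cancer-type restriction requires a High call in that tumor type", {
  sb <- small_bundle()
  edges <- sb$atlas$edges
  tgt_counts <- table(c(edges$a, edges$b)[grepl("^TGT", c(edges$a, edges$b))])
  tgt <- names(tgt_counts)[which.max(tgt_counts)]
  ct <- sb$atlas$calls$tcga$tissue[1]
  res <- search_by_target(sb$atlas, tgt, cancer_type = ct, datasets = "TCGA")
  hi <- sb$atlas$calls$tcga
  hi_syms <- hi$symbol[hi$tissue == ct & hi$call == "High"]
  expect_true(all(res$symbol %in% hi_syms))
  expect_true(all(res$symbol %in%
                    search_by_target(sb$atlas, tgt)$symbol))
})

test_that("query constructor validates fractions", {
  expect_error(candidate_query(gtex_high_max_frac = 1.5), "\\[0, 1\\]")
})

test_that("hypergeometric enrichment matches the frozen enumeration example", {
  # N = 10, K = 4, n = 5, k = 4: C(4,4) C(6,1) / C(10,5) = 6/252
  universe <- paste0("g", 1:10)
  term <- list(T1 = universe[1:4])
  gene_set <- universe[c(1:4, 10)]
  res <- enrich_partners(gene_set, term, universe)
  expect_equal(res$p, 6 / 252, tolerance = 1e-12)
  expect_equal(res$p, enum_hyper_tail(10, 4, 5, 4), tolerance = 1e-12)
  expect_equal(res$p_adj, res$p)                    # single term: BH identity
  expect_true(res$significant)
  # zero-size term: k = 0, p = 1
  res0 <- enrich_partners(gene_set, list(T0 = character()), universe)
  expect_equal(res0$p, 1)
  expect_false(res0$significant)
  expect_equal(nrow(enrich_partners(character(), term, universe)), 0L)
  expect_error(enrich_partners("zzz", term, universe), "subset")
})

test_that("partner enrichment runs on the atlas edge universe", {
  sb <- small_bundle()
  sym <- sb$atlas$catalog$symbol[1]
  universe <- sort(unique(c(sb$atlas$edges$a, sb$atlas$edges$b)))
  terms <- list(A = universe[1:50], B = universe[30:120])
  res <- enrich_ligase_partners(sb$atlas, sym, terms)
  expect_equal(nrow(res), 2L)
  expect_true(all(res$p_adj >= res$p))
  expect_true(all(res$p_adj <= 1))
})
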