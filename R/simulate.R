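# Synthetic input bundles with planted ground truth.
#
# The generator emits every table the pipeline readers expect, in the same
# dialects, together with a truth manifest recording each planted derived
# quantity. The manifest is computed from the planted plan, not by running
# the pipeline, so a full pipeline run over the bundle is an end-to-end
# oracle test. Planted values keep a safety margin around every decision
# boundary (medians at least 0.5 away from 4, staining fractions well away
# from 20%, single-cell fractions away from 12.75%), so classification is
# guaranteed; boundary behaviour is exercised separately by
# make_boundary_fixtures().

bind_or_schema <- function(pieces, cols) {
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0) {
    out <- tibble::as_tibble(stats::setNames(rep(list(character()),
                                                 length(cols)), cols))
  }
  out
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Configuration for a synthetic bundle
#'
#' Sizes default to a desk-scale study: 200 ligases, 1000 candidate targets,
#' 10 tumor types, 10 normal tissues, 20 bulk samples per tissue, 500 cells
#' per normal tissue (~5000 cells), 12 protein-staining samples per tumor
#' type, 20 dependency-screen cell lines in 2 lineages.
#'
#' @param n_ligases,n_targets,n_tumor_types,n_normal_tissues Bundle sizes.
#' @param samples_per_tissue Bulk samples per tissue/tumor type.
#' @param cells_per_tissue Cells per normal tissue in the single-cell atlas.
#' @param hpa_samples_per_type Staining samples per tumor type.
#' @param n_cell_lines Dependency-screen cell lines (split into 2 lineages).
#' @param n_co_opted,n_clinical Planted co-opted / clinical ligase counts.
#' @param n_case1_passers How many ligases are planted to pass the
#'   worked-example search preset ([case1_query()]); every other ligase is
#'   forced to violate at least one of its criteria.
#' @param seed Master seed; each table derives its own stream from it by
#'   table name, so adding a table never perturbs the others.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_ligases = 200, n_targets = 1000, n_tumor_types = 10,
                       n_normal_tissues = 10, samples_per_tissue = 20,
                       cells_per_tissue = 500, hpa_samples_per_type = 12,
                       n_cell_lines = 20, n_co_opted = 12, n_clinical = 2,
                       n_case1_passers = 5, seed = 1L) {
  cfg <- list(n_ligases = n_ligases, n_targets = n_targets,
              n_tumor_types = n_tumor_types,
              n_normal_tissues = n_normal_tissues,
              samples_per_tissue = samples_per_tissue,
              cells_per_tissue = cells_per_tissue,
              hpa_samples_per_type = hpa_samples_per_type,
              n_cell_lines = n_cell_lines, n_co_opted = n_co_opted,
              n_clinical = n_clinical, n_case1_passers = n_case1_passers,
              seed = as.integer(seed))
  if (any(unlist(cfg[1:9]) <= 0)) stop("all counts must be positive", call. = FALSE)
  if (n_clinical > n_co_opted || n_co_opted > n_ligases) {
    stop("need n_clinical <= n_co_opted <= n_ligases", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Set the number of planted preset passers
#'
#' Marks `k` ligases whose planted properties satisfy every criterion of the
#' worked-example preset and guarantees all others violate at least one.
#'
#' @param config A [sim_config()].
#' @param k Number of passers, `0 <= k <= n_ligases`.
#' @return The updated config.
#' @export
plant_case1_passers <- function(config, k) {
  stopifnot(inherits(config, "sim_config"))
  if (k < 0 || k > config$n_ligases) {
    stop("k must lie in [0, n_ligases]", call. = FALSE)
  }
  config$n_case1_passers <- as.integer(k)
  config
}

# Draw sub-scores for a ligase given a target confidence band.
draw_scores <- function(min_conf = 1, max_conf = 6) {
  repeat {
    n_src <- sample(1:3, 1)
    srcs <- sample(c("GE", "UBIHUB", "UBIBROWSER"), n_src)
    scores <- sample(1:2, n_src, replace = TRUE)
    if (sum(scores) >= min_conf && sum(scores) <= max_conf) {
      return(stats::setNames(scores, srcs))
    }
  }
}

# The planted plan: one row per ligase with every derived quantity fixed.
plan_ligases <- function(config) {
  n <- config$n_ligases
  nt <- config$n_tumor_types
  nn <- config$n_normal_tissues
  k <- config$n_case1_passers
  gtex_cap <- ceiling(0.3 * nn) - 1L       # max High tissues for frac < 0.3
  low_majority_cap <- floor((1 - 0.7) * nn) # max High tissues for >= 70% Low

  if (config$n_targets < 111) {
    stop("bundle infeasible: the preset's PPI criterion (> 100 partners) ",
         "needs at least 111 candidate targets", call. = FALSE)
  }
  symbols <- sprintf("E3L%04d", seq_len(n))
  passer_idx <- if (k > 0) sort(sample.int(n, k)) else integer()
  is_passer <- seq_len(n) %in% passer_idx
  nonpass <- setdiff(seq_len(n), passer_idx)
  # one near-passer sits exactly on the confidence boundary (score 3, all
  # other criteria satisfied) to exercise the strict > 3 filter end-to-end
  boundary_idx <- if (length(nonpass) > 0) nonpass[1] else integer()
  modes <- c("confidence", "dark", "tcga", "gtex", "ppi")

  plan <- vector("list", n)
  for (i in seq_len(n)) {
    passer <- is_passer[i]
    mode <- if (passer) "pass"
      else if (i %in% boundary_idx) "confidence_boundary"
      else sample(modes, 1)

    scores <- switch(mode,
      pass = draw_scores(4, 6),
      confidence_boundary = stats::setNames(c(1L, 1L, 1L),
                                            c("GE", "UBIHUB", "UBIBROWSER")),
      confidence = draw_scores(1, 3),
      draw_scores(1, 6)
    )

    tier <- if (mode %in% c("pass", "confidence_boundary")) {
      sample(c("E3drug", "E3chem", "E3cova"), 1, prob = c(0.3, 0.3, 0.4))
    } else if (mode == "dark") {
      "E3dark"
    } else {
      sample(c("E3drug", "E3chem", "E3cova", "E3dark"), 1,
             prob = c(0.15, 0.15, 0.3, 0.4))
    }
    has_drug <- tier == "E3drug"
    has_chem <- tier == "E3chem" || (has_drug && stats::runif(1) < 0.5)
    has_cova <- tier == "E3cova" ||
      ((has_drug || has_chem) && stats::runif(1) < 0.5)

    n_chem <- if (has_chem) sample(1:3, 1) else 0L
    n_drug <- if (has_drug) sample(1:2, 1) else 0L
    n_cova <- if (has_cova) sample(1:2, 1) else 0L
    share <- has_drug && has_chem && stats::runif(1) < 0.4
    n_unique <- n_chem + n_drug + n_cova - as.integer(share)

    n_tcga_high <- if (mode %in% c("pass", "confidence_boundary")) sample(1:nt, 1)
      else if (mode == "tcga") 0L
      else sample(0:nt, 1)
    n_hpa_high <- sample(0:nt, 1)
    n_gtex_high <- if (mode %in% c("pass", "confidence_boundary")) {
      sample(0:gtex_cap, 1)
    } else if (mode == "gtex") {
      sample(seq(gtex_cap + 1L, nn), 1)
    } else {
      sample(0:nn, 1, prob = (nn:0 + 1)^2)
    }
    n_tabula_high <- sample(0:nn, 1, prob = (nn:0 + 1)^2)

    degree <- if (mode %in% c("pass", "confidence_boundary")) {
      sample(110:min(160L, config$n_targets), 1)
    } else if (mode == "ppi") {
      sample(c(3:min(80L, config$n_targets), min(100L, config$n_targets)), 1)
    } else {
      sample(3:min(150L, config$n_targets), 1)
    }

    # means kept in [0.2, 0.8] so the +/-0.2 per-line spread stays in [0, 1]
    mean_crispr <- if (stats::runif(1) < 0.25) stats::runif(1, 0.6, 0.8)
      else stats::runif(1, 0.2, 0.4)
    mean_rnai <- if (stats::runif(1) < 0.15) stats::runif(1, 0.6, 0.8)
      else stats::runif(1, 0.2, 0.4)

    in_cyt <- stats::runif(1) < 0.6
    in_nuc <- stats::runif(1) < 0.5
    n_pdb <- sample(0:5, 1, prob = c(0.45, 0.2, 0.15, 0.1, 0.06, 0.04))
    in_afdb <- n_pdb == 0 && stats::runif(1) < 0.8
    n_interfaces <- sample(0:5, 1)

    plan[[i]] <- tibble::tibble(
      symbol = symbols[i], is_passer = passer, mode = mode,
      score_ge = unname(scores["GE"]), score_ubihub = unname(scores["UBIHUB"]),
      score_ubibrowser = unname(scores["UBIBROWSER"]),
      confidence = sum(scores), n_sources = length(scores),
      tier = tier, has_drug = has_drug, has_chem = has_chem,
      has_cova = has_cova, n_chem = n_chem, n_drug = n_drug, n_cova = n_cova,
      share = share, n_unique_ligands = n_unique,
      n_tcga_high = n_tcga_high, n_hpa_high = n_hpa_high,
      n_gtex_high = n_gtex_high, n_tabula_high = n_tabula_high,
      ppi_degree = degree, mean_crispr = mean_crispr, mean_rnai = mean_rnai,
      in_cytoplasm = in_cyt, in_nucleus = in_nuc,
      n_pdb = n_pdb, afdb_available = in_afdb, n_interfaces = n_interfaces
    )
  }
  plan <- dplyr::bind_rows(plan)

  co_idx <- sample.int(n, config$n_co_opted)
  plan$co_opted <- seq_len(n) %in% co_idx
  clin <- co_idx[seq_len(config$n_clinical)]
  plan$clinical <- seq_len(n) %in% clin

  # high/low tissue assignment per dataset
  pick <- function(n_high, labels) {
    sample(labels, n_high)
  }
  tumor_types <- sprintf("TT%02d", seq_len(nt))
  tissues <- sprintf("NT%02d", seq_len(nn))
  plan$tcga_high_types <- lapply(plan$n_tcga_high, pick, labels = tumor_types)
  plan$hpa_high_types <- lapply(plan$n_hpa_high, pick, labels = tumor_types)
  plan$gtex_high_tissues <- lapply(plan$n_gtex_high, pick, labels = tissues)
  plan$tabula_high_tissues <- lapply(plan$n_tabula_high, pick, labels = tissues)

  # interaction partners
  targets <- sprintf("TGT%04d", seq_len(config$n_targets))
  plan$partners <- lapply(plan$ppi_degree, function(d) sample(targets, d))

  validate_plan(plan)
  attr(plan, "tumor_types") <- tumor_types
  attr(plan, "tissues") <- tissues
  attr(plan, "targets") <- targets
  plan
}

validate_plan <- function(plan) {
  bad_tier <- (plan$tier == "E3drug" & !plan$has_drug) |
    (plan$tier == "E3chem" & (plan$has_drug | !plan$has_chem)) |
    (plan$tier == "E3cova" & (plan$has_drug | plan$has_chem | !plan$has_cova)) |
    (plan$tier == "E3dark" & (plan$has_drug | plan$has_chem | plan$has_cova))
  if (any(bad_tier)) {
    stop("inconsistent planted spec: tier disagrees with ligand categories",
         call. = FALSE)
  }
  if (any(lengths(plan$partners) != plan$ppi_degree)) {
    stop("inconsistent planted spec: partner list length != degree", call. = FALSE)
  }
  invisible(plan)
}

# log-normal sample around a forced exact median (multiplicative shift keeps
# positivity and makes the median order statistic exact)
bulk_values <- function(n, med, sdlog = 0.25) {
  v <- med * exp(stats::rnorm(n, 0, sdlog))
  v * (med / stats::median(v))
}

write_bulk_dataset <- function(plan, tissue_labels, high_of, samples_per,
                               prefix, dir, seed) {
  with_seed(seed, {
    samples <- as.vector(vapply(tissue_labels, function(ts) {
      sprintf("%s_S%02d", ts, seq_len(samples_per))
    }, character(samples_per)))
    meta <- tibble::tibble(sample = samples,
                           tissue = rep(tissue_labels, each = samples_per))
    mat <- matrix(0, nrow = nrow(plan), ncol = length(samples),
                  dimnames = list(plan$symbol, samples))
    for (i in seq_len(nrow(plan))) {
      high <- high_of[[i]]
      for (ts in tissue_labels) {
        med <- if (ts %in% high) stats::runif(1, 4.5, 7.5)
               else stats::runif(1, 0.5, 3.5)
        idx <- meta$sample[meta$tissue == ts]
        mat[i, idx] <- bulk_values(samples_per, med)
      }
    }
    write_tsv_file(
      dplyr::bind_cols(tibble::tibble(symbol = rownames(mat)),
                       tibble::as_tibble(mat)),
      file.path(dir, paste0(prefix, "_expr.tsv")))
    write_tsv_file(meta, file.path(dir, paste0(prefix, "_samples.tsv")))
  })
}

write_sc_dataset <- function(plan, tissues, cells_per, dir, seed) {
  with_seed(seed, {
    cell_ids <- as.vector(vapply(tissues, function(ts) {
      sprintf("%s_C%04d", ts, seq_len(cells_per))
    }, character(cells_per)))
    cell_meta <- tibble::tibble(
      cell_id = cell_ids,
      tissue = rep(tissues, each = cells_per),
      cell_type = sample(c("epithelial", "T cell", "B cell", "fibroblast",
                           "endothelial"), length(cell_ids), replace = TRUE)
    )
    ii <- list(); jj <- list(); xx <- list()
    for (i in seq_len(nrow(plan))) {
      high <- plan$tabula_high_tissues[[i]]
      for (t_idx in seq_along(tissues)) {
        ts <- tissues[t_idx]
        if (ts %in% high) {
          frac <- stats::runif(1, 0.18, 0.35)
          m <- stats::runif(1, 2.9, 3.6)
        } else if (stats::runif(1) < 0.5) {
          frac <- stats::runif(1, 0.02, 0.10)   # too few expressing cells
          m <- stats::runif(1, 1.5, 3.5)
        } else {
          frac <- stats::runif(1, 0.18, 0.30)   # enough cells, mean too low
          m <- stats::runif(1, 0.6, 1.6)
        }
        n_nz <- round(frac * cells_per)
        if (ts %in% high) n_nz <- max(n_nz, ceiling(0.14 * cells_per))
        if (n_nz == 0) next
        cells <- sample.int(cells_per, n_nz) + (t_idx - 1L) * cells_per
        v <- 0.3 + stats::rexp(n_nz)
        v <- v * (m / mean(v))                  # exact non-zero mean
        ii[[length(ii) + 1L]] <- rep(i, n_nz)
        jj[[length(jj) + 1L]] <- cells
        xx[[length(xx) + 1L]] <- v
      }
    }
    counts <- Matrix::sparseMatrix(
      i = unlist(ii), j = unlist(jj), x = unlist(xx),
      dims = c(nrow(plan), length(cell_ids)))
    Matrix::writeMM(counts, file.path(dir, "tabula_counts.mtx"))
    write_tsv_file(tibble::tibble(symbol = plan$symbol),
                   file.path(dir, "tabula_genes.tsv"))
    write_tsv_file(cell_meta, file.path(dir, "tabula_cells.tsv"))
  })
}

write_tumor_sc_dataset <- function(plan, dir, seed) {
  with_seed(seed, {
    sizes <- c(malignant = 400L, immune = 150L, other = 50L)
    group <- rep(names(sizes), sizes)
    cell_meta <- tibble::tibble(
      cell_id = sprintf("TUM_C%04d", seq_along(group)),
      tissue = "BRCA_like",
      cell_type = ifelse(group == "malignant", "malignant cell",
                         ifelse(group == "immune", "T cell", "stromal cell")),
      group = group,
      malignant = group == "malignant"
    )
    offsets <- c(malignant = 0L, immune = sizes[["malignant"]],
                 other = sizes[["malignant"]] + sizes[["immune"]])
    ii <- list(); jj <- list(); xx <- list()
    expressing <- matrix(0L, nrow(plan), 3,
                         dimnames = list(plan$symbol, names(sizes)))
    for (i in seq_len(nrow(plan))) {
      fr <- c(malignant = stats::runif(1, 0.1, 0.7),
              immune = stats::runif(1, 0.02, 0.3),
              other = stats::runif(1, 0.02, 0.3))
      for (g in names(sizes)) {
        n_nz <- round(fr[[g]] * sizes[[g]])
        expressing[i, g] <- n_nz
        if (n_nz == 0) next
        cells <- sample.int(sizes[[g]], n_nz) + offsets[[g]]
        ii[[length(ii) + 1L]] <- rep(i, n_nz)
        jj[[length(jj) + 1L]] <- cells
        xx[[length(xx) + 1L]] <- 0.5 + stats::rexp(n_nz)
      }
    }
    counts <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                                   x = unlist(xx),
                                   dims = c(nrow(plan), length(group)))
    Matrix::writeMM(counts, file.path(dir, "tumor_sc_counts.mtx"))
    write_tsv_file(tibble::tibble(symbol = plan$symbol),
                   file.path(dir, "tumor_sc_genes.tsv"))
    write_tsv_file(cell_meta, file.path(dir, "tumor_sc_cells.tsv"))
    list(sizes = sizes, expressing = expressing)
  })
}

write_ppi_tables <- function(plan, dir, seed) {
  with_seed(seed, {
    tags <- c("UBIBROWSER_LIT", "UBIBROWSER_PRED", "BIOGRID", "INTACT",
              "REACTOME", "STRING", "HURI")
    rows <- list()
    for (i in seq_len(nrow(plan))) {
      partners <- plan$partners[[i]]
      if (length(partners) == 0) next
      n_src <- sample(1:2, length(partners), replace = TRUE, prob = c(0.8, 0.2))
      for (j in seq_along(partners)) {
        for (tag in sample(tags, n_src[j])) {
          rows[[length(rows) + 1L]] <- c(plan$symbol[i], partners[j], tag)
        }
      }
    }
    m <- do.call(rbind, rows)
    edf <- tibble::tibble(a = m[, 1], b = m[, 2], tag = m[, 3])

    methods_pool <- c("Affinity Capture-MS", "Two-hybrid",
                      "Biochemical Activity", "Co-fractionation")
    sub <- function(tag) edf[edf$tag == tag, , drop = FALSE]

    ub_lit <- sub("UBIBROWSER_LIT")
    ub_pred <- sub("UBIBROWSER_PRED")
    decoy_pred <- tibble::tibble(
      a = sample(plan$symbol, 15, replace = TRUE),
      b = sprintf("DEC%04d", 1:15))
    ubibrowser <- dplyr::bind_rows(
      tibble::tibble(ligase = ub_lit$a, substrate = ub_lit$b,
                     evidence = "literature", confidence = NA_real_,
                     organism = "Homo sapiens"),
      tibble::tibble(ligase = ub_pred$a, substrate = ub_pred$b,
                     evidence = "predicted",
                     confidence = round(stats::runif(nrow(ub_pred), 0.71, 0.99), 3),
                     organism = "Homo sapiens"),
      tibble::tibble(ligase = decoy_pred$a, substrate = decoy_pred$b,
                     evidence = "predicted",
                     confidence = c(0.7, round(stats::runif(14, 0.1, 0.7), 3)),
                     organism = "Homo sapiens")
    )
    write_tsv_file(ubibrowser, file.path(dir, "ppi_ubibrowser.tsv"))

    bg <- sub("BIOGRID")
    biogrid <- dplyr::bind_rows(
      tibble::tibble(symbol_a = bg$a, symbol_b = bg$b,
                     organism_a = "9606", organism_b = "9606",
                     method = sample(methods_pool, nrow(bg), replace = TRUE)),
      # non-human and self-loop decoys, dropped on load/merge
      tibble::tibble(symbol_a = sample(plan$symbol, 10),
                     symbol_b = sprintf("DEC%04d", 16:25),
                     organism_a = "9606", organism_b = "10090",
                     method = "Two-hybrid"),
      tibble::tibble(symbol_a = plan$symbol[1:3], symbol_b = plan$symbol[1:3],
                     organism_a = "9606", organism_b = "9606",
                     method = "Two-hybrid")
    )
    write_tsv_file(biogrid, file.path(dir, "ppi_biogrid.tsv"))

    it <- sub("INTACT")
    write_tsv_file(
      tibble::tibble(symbol_a = it$a, symbol_b = it$b,
                     taxid_a = "9606", taxid_b = "9606",
                     method = sample(methods_pool, nrow(it), replace = TRUE)),
      file.path(dir, "ppi_intact.tsv"))

    re <- sub("REACTOME")
    write_tsv_file(
      tibble::tibble(symbol_a = re$a, symbol_b = re$b, species = "Homo sapiens"),
      file.path(dir, "ppi_reactome.tsv"))

    st <- sub("STRING")
    string <- dplyr::bind_rows(
      tibble::tibble(protein1 = st$a, protein2 = st$b,
                     combined_score = sample(701:999, nrow(st), replace = TRUE),
                     species = "9606"),
      tibble::tibble(protein1 = sample(plan$symbol, 12, replace = TRUE),
                     protein2 = sprintf("DEC%04d", 26:37),
                     combined_score = c(700L, sample(100:700, 11, replace = TRUE)),
                     species = "9606")
    )
    write_tsv_file(string, file.path(dir, "ppi_string.tsv"))

    hu <- sub("HURI")
    write_tsv_file(tibble::tibble(symbol_a = hu$a, symbol_b = hu$b),
                   file.path(dir, "ppi_huri.tsv"))
  })
}

write_ligand_tables <- function(plan, dir, seed) {
  with_seed(seed, {
    chembl <- list(); drugs <- list(); cova <- list()
    for (i in seq_len(nrow(plan))) {
      sym <- plan$symbol[i]
      chem_ids <- if (plan$n_chem[i] > 0) {
        sprintf("CHEMBL%s%03d", gsub("E3L", "", sym), seq_len(plan$n_chem[i]))
      } else character()
      if (plan$n_chem[i] > 0) {
        chembl[[length(chembl) + 1L]] <- tibble::tibble(
          ligand_id = chem_ids, chembl_id = chem_ids, smiles = NA_character_,
          target_symbol = sym,
          pchembl = round(stats::runif(length(chem_ids), 5.5, 9), 2))
        # inactive decoy record, dropped by the activity filter
        if (stats::runif(1) < 0.3) {
          chembl[[length(chembl) + 1L]] <- tibble::tibble(
            ligand_id = paste0(chem_ids[1], "X"),
            chembl_id = paste0(chem_ids[1], "X"), smiles = NA_character_,
            target_symbol = sym, pchembl = round(stats::runif(1, 1, 4.5), 2))
        }
      }
      if (plan$n_drug[i] > 0) {
        did <- sprintf("D%s%02d", gsub("E3L", "", sym), seq_len(plan$n_drug[i]))
        cid <- rep(NA_character_, length(did))
        if (plan$share[i]) cid[1] <- chem_ids[1]  # cross-source duplicate
        drugs[[length(drugs) + 1L]] <- tibble::tibble(
          drug_id = did, chembl_id = cid, smiles = NA_character_,
          target_symbol = sym,
          source = sample(c("DRUGBANK", "DGIDB"), length(did), replace = TRUE))
      }
      if (plan$n_cova[i] > 0) {
        cova[[length(cova) + 1L]] <- tibble::tibble(
          symbol = sym,
          cell_line = sample(c("HEK293T", "PC3", "MDA-MB-231"),
                             plan$n_cova[i], replace = TRUE),
          cysteine_site = sprintf("C%d", sample(20:600, plan$n_cova[i])))
      }
    }
    write_tsv_file(
      bind_or_schema(chembl, c("ligand_id", "chembl_id", "smiles",
                               "target_symbol", "pchembl")),
      file.path(dir, "chembl.tsv"))
    write_tsv_file(
      bind_or_schema(drugs, c("drug_id", "chembl_id", "smiles",
                              "target_symbol", "source")),
      file.path(dir, "drugs.tsv"))
    write_tsv_file(
      bind_or_schema(cova, c("symbol", "cell_line", "cysteine_site")),
      file.path(dir, "covalent.tsv"))
  })
}

write_catalog_tables <- function(plan, dir, seed) {
  with_seed(seed, {
    e3_texts <- c("RING E3 ligase", "E3 ubiquitin-protein ligase",
                  "HECT-type E3 activity")
    non_e3_texts <- c("ubiquitin conjugating enzyme",
                      "UBE3A-like HECT domain protein",  # "E3" not a token
                      "substrate adaptor of a CRL complex")
    ge <- plan[!is.na(plan$score_ge), c("symbol", "score_ge")]
    ge_tbl <- tibble::tibble(symbol = ge$symbol,
                             lit_validated = ge$score_ge == 2)
    # a within-source duplicate with the lower score; collapse keeps the max
    if (nrow(ge_tbl) > 0 && any(ge_tbl$lit_validated)) {
      dup_sym <- ge_tbl$symbol[which(ge_tbl$lit_validated)[1]]
      ge_tbl <- dplyr::bind_rows(
        ge_tbl, tibble::tibble(symbol = dup_sym, lit_validated = FALSE))
    }
    uh <- plan[!is.na(plan$score_ubihub), c("symbol", "score_ubihub")]
    uh_tbl <- tibble::tibble(
      symbol = uh$symbol,
      function_text = ifelse(uh$score_ubihub == 2,
                             sample(e3_texts, nrow(uh), replace = TRUE),
                             sample(non_e3_texts, nrow(uh), replace = TRUE)))
    ub <- plan[!is.na(plan$score_ubibrowser), c("symbol", "score_ubibrowser")]
    ub_tbl <- tibble::tibble(
      symbol = ub$symbol,
      esi_count = ifelse(ub$score_ubibrowser == 2,
                         sample(6:30, nrow(ub), replace = TRUE),
                         sample(0:5, nrow(ub), replace = TRUE)))

    # alias plumbing: a few symbols appear under a raw alias in the GE list
    alias <- tibble::tibble(alias = character(), symbol = character())
    if (nrow(ge_tbl) >= 3) {
      raw <- ge_tbl$symbol[1:3]
      alias <- tibble::tibble(alias = paste0(raw, "_ALT"), symbol = raw)
      ge_tbl$symbol[1:3] <- alias$alias
    }
    write_tsv_file(ge_tbl, file.path(dir, "ge.tsv"))
    write_tsv_file(uh_tbl, file.path(dir, "ubihub.tsv"))
    write_tsv_file(ub_tbl, file.path(dir, "ubibrowser.tsv"))
    write_tsv_file(alias, file.path(dir, "alias.tsv"))

    yaml::write_yaml(
      list(co_opted_symbols = plan$symbol[plan$co_opted],
           clinical_symbols = plan$symbol[plan$clinical]),
      file.path(dir, "co_opted.yaml"))
  })
}

write_hpa_table <- function(plan, tumor_types, n_samples, dir, seed) {
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(plan))) {
      high <- plan$hpa_high_types[[i]]
      for (ts in tumor_types) {
        n_mh <- if (ts %in% high) round(stats::runif(1, 0.45, 0.85) * n_samples)
                else sample(0:1, 1)
        calls <- c(sample(c("medium", "high"), n_mh, replace = TRUE),
                   sample(c("not_detected", "low"), n_samples - n_mh,
                          replace = TRUE))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          symbol = plan$symbol[i], cancer_type = ts,
          sample_id = sprintf("%s_P%02d", ts, seq_len(n_samples)),
          staining_call = calls)
      }
    }
    write_tsv_file(dplyr::bind_rows(rows), file.path(dir, "hpa.tsv"))
  })
}

write_annotation_tables <- function(plan, dir, seed) {
  with_seed(seed, {
    n_lines <- 20L
    lines <- sprintf("CL%02d", seq_len(n_lines))
    lineages <- rep(c("lung", "breast"), each = n_lines / 2)
    write_tsv_file(tibble::tibble(line = lines, lineage = lineages),
                   file.path(dir, "cell_lines.tsv"))
    ess_mat <- function(means) {
      m <- t(vapply(means, function(mu) {
        v <- stats::runif(n_lines, mu - 0.1, mu + 0.1)
        v - mean(v) + mu     # exact mean, values stay inside [0, 1]
      }, numeric(n_lines)))
      dimnames(m) <- list(plan$symbol, lines)
      m
    }
    for (screen in c("crispr", "rnai")) {
      m <- ess_mat(plan[[paste0("mean_", screen)]])
      write_tsv_file(
        dplyr::bind_cols(tibble::tibble(symbol = rownames(m)),
                         tibble::as_tibble(m)),
        file.path(dir, paste0("essentiality_", screen, ".tsv")))
    }

    loc <- list()
    srcs <- c("GO", "COMPARTMENTS", "UNIPROT")
    for (i in seq_len(nrow(plan))) {
      sym <- plan$symbol[i]
      add <- function(term) {
        src <- sample(srcs, 1)
        tibble::tibble(symbol = sym, source = src, term = term,
                       score = if (src == "COMPARTMENTS")
                         round(stats::runif(1, 3.2, 5), 2) else NA_real_)
      }
      if (plan$in_cytoplasm[i]) {
        loc[[length(loc) + 1L]] <- add(sample(c("cytoplasm", "cytosol"), 1))
      }
      if (plan$in_nucleus[i]) loc[[length(loc) + 1L]] <- add("nucleus")
      if (stats::runif(1) < 0.3) loc[[length(loc) + 1L]] <- add("mitochondrion")
      # low-confidence decoy that must be excluded (score <= 3)
      if (!plan$in_cytoplasm[i] && stats::runif(1) < 0.3) {
        loc[[length(loc) + 1L]] <- tibble::tibble(
          symbol = sym, source = "COMPARTMENTS", term = "cytoplasm",
          score = round(stats::runif(1, 0.5, 2.8), 2))
      }
    }
    write_tsv_file(dplyr::bind_rows(loc), file.path(dir, "locations.tsv"))

    pdb <- list()
    for (i in seq_len(nrow(plan))) {
      if (plan$n_pdb[i] > 0) {
        ids <- sprintf("P%s%02d", gsub("E3L", "", plan$symbol[i]),
                       seq_len(plan$n_pdb[i]))
        if (stats::runif(1) < 0.2) ids <- c(ids, ids[1])  # duplicate id row
        pdb[[length(pdb) + 1L]] <- tibble::tibble(symbol = plan$symbol[i],
                                                  structure_id = ids)
      }
    }
    write_tsv_file(bind_or_schema(pdb, c("symbol", "structure_id")),
                   file.path(dir, "pdb_index.tsv"))
    afdb_syms <- plan$symbol[plan$afdb_available]
    write_tsv_file(tibble::tibble(symbol = afdb_syms),
                   file.path(dir, "afdb.tsv"))

    iface <- list()
    for (i in seq_len(nrow(plan))) {
      ni <- plan$n_interfaces[i]
      if (ni == 0) next
      combos <- expand.grid(partner = plan$partners[[i]][seq_len(min(5, length(plan$partners[[i]])))],
                            source = c("PDB", "INTERACTOME3D", "ECLAIR_HIGH"),
                            stringsAsFactors = FALSE)
      if (nrow(combos) < ni) next
      pickr <- combos[sample.int(nrow(combos), ni), , drop = FALSE]
      start <- sample(10:400, ni, replace = TRUE)
      tb <- tibble::tibble(symbol = plan$symbol[i], partner = pickr$partner,
                           source = pickr$source,
                           residues = sprintf("%d-%d", start, start + sample(3:20, ni, replace = TRUE)))
      if (stats::runif(1) < 0.2) tb <- dplyr::bind_rows(tb, tb[1, ])  # dup row
      iface[[length(iface) + 1L]] <- tb
    }
    write_tsv_file(
      bind_or_schema(iface, c("symbol", "partner", "source", "residues")),
      file.path(dir, "interfaces.tsv"))
  })
}

write_tractability <- function(plan, targets, dir, seed) {
  with_seed(seed, {
    protactable <- sort(sample(targets, min(300, length(targets))))
    mapd <- sort(sample(targets, min(250, length(targets))))
    write_tsv_file(tibble::tibble(symbol = protactable),
                   file.path(dir, "protactable.tsv"))
    write_tsv_file(tibble::tibble(symbol = mapd), file.path(dir, "mapd.tsv"))
    list(protactable = protactable, mapd = mapd)
  })
}

# Interface counts can be clipped when a ligase has too few partners; read
# the emitted truth back from the planted attributes where possible.
truth_interfaces <- function(plan) {
  vapply(seq_len(nrow(plan)), function(i) {
    ni <- plan$n_interfaces[i]
    n_part <- min(5, length(plan$partners[[i]]))
    if (ni == 0 || n_part * 3 < ni) 0L else as.integer(ni)
  }, integer(1))
}

#' Generate a complete synthetic input bundle with a truth manifest
#'
#' Writes every table the pipeline readers expect into `out_dir`, plus
#' `truth_manifest.json` (planted expected values of every derived quantity)
#' and `checksums.txt` (MD5 per emitted file). The same seed yields a
#' byte-identical bundle.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created; must be empty or absent).
#' @return Invisibly, the truth manifest (list).
#' @export
generate_bundle <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  plan <- with_seed(table_seed(config$seed, "plan"), plan_ligases(config))
  tumor_types <- attr(plan, "tumor_types")
  tissues <- attr(plan, "tissues")
  targets <- attr(plan, "targets")

  write_catalog_tables(plan, out_dir, table_seed(config$seed, "catalog"))
  write_ligand_tables(plan, out_dir, table_seed(config$seed, "ligands"))
  write_bulk_dataset(plan, tumor_types, plan$tcga_high_types,
                     config$samples_per_tissue, "tcga", out_dir,
                     table_seed(config$seed, "tcga"))
  write_bulk_dataset(plan, tissues, plan$gtex_high_tissues,
                     config$samples_per_tissue, "gtex", out_dir,
                     table_seed(config$seed, "gtex"))
  write_hpa_table(plan, tumor_types, config$hpa_samples_per_type, out_dir,
                  table_seed(config$seed, "hpa"))
  write_sc_dataset(plan, tissues, config$cells_per_tissue, out_dir,
                   table_seed(config$seed, "tabula"))
  tumor_sc <- write_tumor_sc_dataset(plan, out_dir,
                                     table_seed(config$seed, "tumor_sc"))
  write_ppi_tables(plan, out_dir, table_seed(config$seed, "ppi"))
  tract <- write_tractability(plan, targets, out_dir,
                              table_seed(config$seed, "tract"))
  write_annotation_tables(plan, out_dir, table_seed(config$seed, "annot"))

  # planted truth, computed from the plan (not by running the pipeline)
  nn <- config$n_normal_tissues
  gtex_low_majority <- (nn - plan$n_gtex_high) / nn >= 0.7
  tabula_low_majority <- (nn - plan$n_tabula_high) / nn >= 0.7
  tumor_selective <- plan$n_tcga_high >= 1 & plan$n_hpa_high >= 1 &
    gtex_low_majority & tabula_low_majority

  adj <- stats::setNames(plan$partners, plan$symbol)
  co_syms <- plan$symbol[plan$co_opted]
  co_space <- sort(unique(unlist(adj[co_syms])))
  tract_union <- sort(union(tract$protactable, tract$mapd))
  count_e3 <- function(e3_syms) {
    long <- tibble::tibble(
      e3 = rep(names(adj), lengths(adj)), target = unlist(adj))
    long <- long[long$e3 %in% e3_syms, ]
    cnt <- table(factor(long$target, levels = tract_union))
    stats::median(as.integer(cnt))
  }

  marker_genes <- plan$symbol[1:3]
  tumor_sc_truth <- lapply(marker_genes, function(g) {
    list(gene = g,
         groups = lapply(colnames(tumor_sc$expressing), function(grp) {
           list(group = grp,
                n_cells = unname(tumor_sc$sizes[[grp]]),
                n_expressing = unname(tumor_sc$expressing[g, grp]))
         }))
  })

  per_ligase <- tibble::tibble(
    symbol = plan$symbol,
    score_ge = plan$score_ge, score_ubihub = plan$score_ubihub,
    score_ubibrowser = plan$score_ubibrowser,
    confidence = plan$confidence, n_sources = plan$n_sources,
    co_opted = plan$co_opted, clinical = plan$clinical,
    tier = plan$tier, has_drug = plan$has_drug, has_chem = plan$has_chem,
    has_cova = plan$has_cova,
    n_categories = as.integer(plan$has_drug) + as.integer(plan$has_chem) +
      as.integer(plan$has_cova),
    n_unique_ligands = plan$n_unique_ligands,
    n_tcga_high = plan$n_tcga_high, n_hpa_high = plan$n_hpa_high,
    n_gtex_high = plan$n_gtex_high, n_tabula_high = plan$n_tabula_high,
    tumor_high_any_tcga = plan$n_tcga_high >= 1,
    tumor_high_any_hpa = plan$n_hpa_high >= 1,
    normal_low_majority_gtex = gtex_low_majority,
    normal_low_majority_tabula = tabula_low_majority,
    tumor_selective = tumor_selective,
    n_ppi = plan$ppi_degree,
    essential_crispr = plan$mean_crispr > 0.5,
    essential_rnai = plan$mean_rnai > 0.5,
    in_cytoplasm = plan$in_cytoplasm, in_nucleus = plan$in_nucleus,
    n_pdb = plan$n_pdb, afdb_available = plan$afdb_available,
    n_interfaces = truth_interfaces(plan)
  )

  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    per_ligase = per_ligase,
    case1_passers = sort(plan$symbol[plan$is_passer]),
    co_opted_symbols = sort(co_syms),
    co_opted_target_space_n = length(co_space),
    tractable_overlap_n = length(intersect(tract$protactable, tract$mapd)),
    tractable_union_n = length(tract_union),
    tractable_median_co_opted = count_e3(co_syms),
    tractable_median_all = count_e3(plan$symbol),
    tumor_sc_markers = tumor_sc_truth
  )
  jsonlite::write_json(manifest, file.path(out_dir, "truth_manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")

  files <- sort(setdiff(list.files(out_dir), "checksums.txt"))
  sums <- tools::md5sum(file.path(out_dir, files))
  writeLines(paste(unname(sums), files), file.path(out_dir, "checksums.txt"))

  invisible(manifest)
}

#' Read a bundle's truth manifest
#'
#' @param bundle_dir Bundle directory.
#' @return The manifest list, with `per_ligase` as a tibble.
#' @export
read_truth_manifest <- function(bundle_dir) {
  m <- jsonlite::read_json(file.path(bundle_dir, "truth_manifest.json"),
                           simplifyVector = TRUE)
  m$per_ligase <- tibble::as_tibble(m$per_ligase)
  m
}

#' Minimal fixtures sitting exactly on every printed decision boundary
#'
#' Returns small in-memory tables that place one observation exactly on, and
#' one just past, each rule threshold: pChEMBL 5.0 / 4.99 (inclusive at 5),
#' bulk median 4.0 / 4.01 (strict above 4), staining fraction exactly 20\%
#' (inclusive by default), STRING 700 / 701 (strict above 700), predicted
#' ESI confidence 0.70 / 0.71 (strict above 0.7), essentiality mean 0.50 /
#' 0.51 (strict above 0.5), COMPARTMENTS score 3 / 3.01 (strict above 3),
#' single-cell fraction 12.75\% exactly and non-zero mean 2.325 exactly
#' (both strict), ESI count 5 / 6 (strict above 5).
#'
#' @return Named list of fixture tables/vectors with an `expected` entry
#'   documenting the call each boundary observation must receive.
#' @export
make_boundary_fixtures <- function() {
  sc_frac_cells <- c(rep(3, 51), rep(0, 349))        # 51/400 = 12.75% exactly
  sc_mean_cells <- c(rep(2.325, 60), rep(0, 340))    # 15% non-zero, mean 2.325
  list(
    chembl = tibble::tibble(
      ligand_id = c("L1", "L2"), chembl_id = c("CHEMBL1", "CHEMBL2"),
      smiles = NA_character_, target_symbol = "E3X",
      pchembl = c(5.0, 4.99)),
    bulk_levels = c(on = 4.0, above = 4.01),
    hpa_calls_20pct = c(rep("medium", 2), rep("low", 8)),
    string = tibble::tibble(protein1 = "E3X", protein2 = c("T1", "T2"),
                            combined_score = c(700, 701), species = "9606"),
    ubibrowser_pred = tibble::tibble(
      ligase = "E3X", substrate = c("S1", "S2"), evidence = "predicted",
      confidence = c(0.70, 0.71), organism = "9606"),
    essentiality = list(on = rep(0.5, 4), above = c(0.5, 0.5, 0.5, 0.54)),
    compartments = tibble::tibble(
      symbol = "E3X", source = "COMPARTMENTS", term = "cytoplasm",
      score = c(3, 3.01)),
    sc_fraction_on = sc_frac_cells,
    sc_mean_on = sc_mean_cells,
    esi_counts = c(on = 5L, above = 6L),
    expected = tibble::tibble(
      rule = c("pchembl>=5", "median>4", "hpa>=20%", "string>700",
               "esi_conf>0.7", "essential>0.5", "compartments>3",
               "sc_frac>12.75", "sc_mean>2.325", "esi_count>5"),
      boundary_call = c("retained", "Low", "High", "dropped", "dropped",
                        "not essential", "excluded", "Low", "Low", "score 1"))
  )
}
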