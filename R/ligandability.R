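#' Filter bioactivity records to active compounds
#'
#' Keeps small-molecule activity records whose pChEMBL (negative log10 of a
#' molar IC50/XC50/EC50/AC50/Ki/Kd/potency) is at least 5, i.e. 10 uM or
#' better. The boundary is inclusive: pChEMBL = 5.0 is active. Records
#' missing a pChEMBL value are dropped with a warning.
#'
#' @param activities Tibble of ChEMBL-like records with columns
#'   `target_symbol`, `pchembl` and ligand identifier columns.
#' @param min_pchembl Activity threshold (default 5, inclusive).
#' @return The retained rows, input order preserved.
#' @export
filter_active_chembl <- function(activities, min_pchembl = 5) {
  assert_cols(activities, "pchembl", "ChEMBL activity table")
  n_missing <- sum(is.na(activities$pchembl))
  if (n_missing > 0) {
    warning(n_missing, " activity record(s) without a pChEMBL value dropped",
            call. = FALSE)
  }
  activities[!is.na(activities$pchembl) &
               activities$pchembl >= min_pchembl, , drop = FALSE]
}

#' Canonical deduplication key for a ligand record
#'
#' Chemicals reported by several databases are counted once: a record keyed
#' by its ChEMBL id where available, else by its (lexically normalized)
#' SMILES, else by a source-qualified native id such as `"DGIDB:252166607"`.
#' SMILES normalization is lexical (whitespace stripped, case-insensitive
#' compare); pass `canonicalizer` to plug a chemistry-aware canonical form.
#'
#' @param rec Tibble of ligand records with columns `ligand_id`, `chembl_id`,
#'   `smiles`, `source` (any may be NA except `ligand_id`/`source`).
#' @param canonicalizer Optional function applied to SMILES strings before
#'   lexical normalization.
#' @return Character vector of keys, one per row.
#' @export
canonical_ligand_key <- function(rec, canonicalizer = NULL) {
  assert_cols(rec, c("ligand_id", "source"), "ligand table")
  chembl <- col_or(rec, "chembl_id", rep(NA_character_, nrow(rec)))
  smiles <- col_or(rec, "smiles", rep(NA_character_, nrow(rec)))
  if (!is.null(canonicalizer)) {
    ok <- !is.na(smiles)
    smiles[ok] <- vapply(smiles[ok], canonicalizer, character(1))
  }
  smiles_key <- toupper(gsub("\\s+", "", smiles))
  fallback <- paste(toupper(rec$source), rec$ligand_id, sep = ":")
  dplyr::case_when(
    !is.na(chembl) & nzchar(chembl) ~ chembl,
    !is.na(smiles_key) & nzchar(smiles_key) ~ smiles_key,
    TRUE ~ fallback
  )
}

#' Ligandability tier from category flags
#'
#' Four-tier label with strict precedence: any drug evidence makes the ligase
#' `E3drug`; else any bioactive small molecule makes it `E3chem`; else any
#' covalent-electrophile hit makes it `E3cova`; with no ligand evidence at
#' all it is `E3dark`.
#'
#' @param has_drug,has_chem,has_cova Logical vectors (recycled).
#' @return Character vector of tiers.
#' @export
classify_tier <- function(has_drug, has_chem, has_cova) {
  dplyr::case_when(
    has_drug ~ "E3drug",
    has_chem ~ "E3chem",
    has_cova ~ "E3cova",
    TRUE ~ "E3dark"
  )
}

#' Summarize ligand evidence per catalog ligase
#'
#' Aggregates three ligand evidence categories — drugs (DrugBank/DGIdb-like
#' tables), active ChEMBL-like small molecules (pre-filter with
#' [filter_active_chembl()] applied here), and covalent cysteine-profiling
#' hits — into one row per catalog ligase with the number of evidence
#' categories, the deduplicated unique-ligand count, and the tier label.
#' A covalent hit in any profiled cell line counts. Activity rows targeting
#' symbols outside the catalog are ignored (their count is messaged).
#'
#' @param catalog Catalog tibble from [assemble_catalog()] (or any tibble
#'   with a `symbol` column).
#' @param chembl ChEMBL-like tibble (`ligand_id`, `chembl_id`, `smiles`,
#'   `target_symbol`, `pchembl`); may be empty.
#' @param drugs Drug tibble (`drug_id`, `target_symbol`, `source`); may be
#'   empty.
#' @param covalent Covalent-hit tibble (`symbol`, `cell_line`,
#'   `cysteine_site`); may be empty.
#' @param min_pchembl Passed to [filter_active_chembl()].
#' @return Tibble with columns `symbol`, `tier`, `n_categories`,
#'   `n_unique_ligands`, `has_drug`, `has_chem`, `has_cova`.
#' @export
summarize_ligandability <- function(catalog, chembl = NULL, drugs = NULL,
                                    covalent = NULL, min_pchembl = 5) {
  assert_cols(catalog, "symbol", "catalog")
  symbols <- catalog$symbol

  empty_lig <- tibble::tibble(symbol = character(), key = character(),
                              category = character())
  pieces <- list(empty_lig)

  if (!is.null(chembl) && nrow(chembl) > 0) {
    active <- filter_active_chembl(chembl, min_pchembl)
    if (nrow(active) > 0) {
      if (!"source" %in% names(active)) active$source <- "CHEMBL"
      pieces <- c(pieces, list(tibble::tibble(
        symbol = active$target_symbol,
        key = canonical_ligand_key(active),
        category = "chem"
      )))
    }
  }
  if (!is.null(drugs) && nrow(drugs) > 0) {
    assert_cols(drugs, c("drug_id", "target_symbol", "source"), "drug table")
    drec <- tibble::tibble(ligand_id = drugs$drug_id,
                           chembl_id = col_or(drugs, "chembl_id",
                                              rep(NA_character_, nrow(drugs))),
                           smiles = col_or(drugs, "smiles",
                                           rep(NA_character_, nrow(drugs))),
                           source = drugs$source)
    pieces <- c(pieces, list(tibble::tibble(
      symbol = drugs$target_symbol,
      key = canonical_ligand_key(drec),
      category = "drug"
    )))
  }
  if (!is.null(covalent) && nrow(covalent) > 0) {
    assert_cols(covalent, c("symbol", "cell_line", "cysteine_site"),
                "covalent table")
    pieces <- c(pieces, list(tibble::tibble(
      symbol = covalent$symbol,
      key = paste0("COVALENT:", covalent$symbol, ":", covalent$cysteine_site),
      category = "cova"
    )))
  }

  lig <- dplyr::bind_rows(pieces)
  n_outside <- sum(!lig$symbol %in% symbols)
  if (n_outside > 0) {
    message(n_outside, " ligand record(s) target symbols outside the catalog; ignored")
    lig <- lig[lig$symbol %in% symbols, , drop = FALSE]
  }

  per <- lig |>
    dplyr::group_by(.data$symbol) |>
    dplyr::summarise(
      has_drug = any(.data$category == "drug"),
      has_chem = any(.data$category == "chem"),
      has_cova = any(.data$category == "cova"),
      n_unique_ligands = dplyr::n_distinct(.data$key),
      .groups = "drop"
    )

  tibble::tibble(symbol = symbols) |>
    dplyr::left_join(per, by = "symbol") |>
    dplyr::mutate(
      has_drug = dplyr::coalesce(.data$has_drug, FALSE),
      has_chem = dplyr::coalesce(.data$has_chem, FALSE),
      has_cova = dplyr::coalesce(.data$has_cova, FALSE),
      n_unique_ligands = dplyr::coalesce(.data$n_unique_ligands, 0L),
      n_categories = as.integer(.data$has_drug) + as.integer(.data$has_chem) +
        as.integer(.data$has_cova),
      tier = classify_tier(.data$has_drug, .data$has_chem, .data$has_cova)
    ) |>
    dplyr::select("symbol", "tier", "n_categories", "n_unique_ligands",
                  "has_drug", "has_chem", "has_cova")
}
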