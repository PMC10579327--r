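#' Harmonize gene symbols against an alias map
#'
#' Maps source-native gene symbols to canonical (HUGO-style) symbols. Symbols
#' absent from the alias map are returned unchanged: most symbols in a curated
#' list are already canonical, so absence is the normal case, not an error.
#'
#' @param raw Character vector of raw symbols; empty strings are an error.
#' @param alias_map Named character vector (`names` = raw alias, values =
#'   canonical symbol), or a two-column data frame `(alias, symbol)`.
#' @return Character vector of harmonized symbols.
#' @examples
#' harmonize_symbol("C10ORF90", c(C10ORF90 = "C10orf90"))
#' harmonize_symbol("VHL", character())
#' @export
harmonize_symbol <- function(raw, alias_map = character()) {
  if (is.data.frame(alias_map)) {
    assert_cols(alias_map, c("alias", "symbol"), "alias map")
    alias_map <- stats::setNames(alias_map$symbol, alias_map$alias)
  }
  if (any(is.na(raw)) || any(!nzchar(raw))) {
    stop("gene symbols must be non-empty", call. = FALSE)
  }
  hit <- match(raw, names(alias_map))
  out <- raw
  out[!is.na(hit)] <- unname(alias_map[hit[!is.na(hit)]])
  out
}

#' Create a single-source evidence record for an E3 ligase
#'
#' One record per (symbol, source). Each of the three catalog sources carries
#' a different kind of evidence: the literature-parsed list flags
#' literature-validated entries, the domain-signature list carries a free-text
#' function annotation, and the E3-substrate-interaction list counts curated
#' ESIs.
#'
#' @param symbol Harmonized gene symbol.
#' @param source One of `"GE"`, `"UBIHUB"`, `"UBIBROWSER"`.
#' @param lit_validated Logical; `GE` only.
#' @param function_text Character; `UBIHUB` only.
#' @param esi_count Non-negative integer; `UBIBROWSER` only.
#' @return A `source_record` list.
#' @export
source_record <- function(symbol, source,
                          lit_validated = NULL,
                          function_text = NULL,
                          esi_count = NULL) {
  source <- match.arg(source, c("GE", "UBIHUB", "UBIBROWSER"))
  if (source == "GE" && is.null(lit_validated)) {
    stop("GE records require `lit_validated`", call. = FALSE)
  }
  if (source == "UBIHUB" && is.null(function_text)) {
    stop("UBIHUB records require `function_text`", call. = FALSE)
  }
  if (source == "UBIBROWSER") {
    if (is.null(esi_count) || esi_count < 0) {
      stop("UBIBROWSER records require a non-negative `esi_count`", call. = FALSE)
    }
  }
  structure(
    list(symbol = symbol, source = source,
         lit_validated = lit_validated,
         function_text = function_text,
         esi_count = esi_count),
    class = "source_record"
  )
}

#' Score a single source record
#'
#' Per-source sub-score in \{1, 2\}:
#' * `GE`: 2 if the entry is literature-validated, else 1 (predicted).
#' * `UBIHUB`: 2 if the function annotation contains the keyword "E3"
#'   (case-insensitive, on word boundaries, so "UBE3A" does not match), else 1.
#' * `UBIBROWSER`: 2 if the ligase has over 5 curated E3-substrate
#'   interactions (strict: 5 scores 1), else 1.
#'
#' @param record A [source_record()].
#' @return Integer 1 or 2.
#' @export
score_source <- function(record) {
  stopifnot(inherits(record, "source_record"))
  switch(record$source,
    GE = if (isTRUE(record$lit_validated)) 2L else 1L,
    UBIHUB = if (grepl("\\bE3\\b", record$function_text,
                       ignore.case = TRUE, perl = TRUE)) 2L else 1L,
    UBIBROWSER = if (record$esi_count > 5) 2L else 1L,
    stop("unknown source tag: ", record$source, call. = FALSE)
  )
}

#' Cumulative confidence score for one ligase
#'
#' The confidence score (1-6; 6 is best) is the sum of per-source sub-scores
#' over the sources in which the ligase appears. A source that does not list
#' the ligase contributes nothing; a ligase listed nowhere is not an E3 ligase
#' and must not enter the catalog.
#'
#' @param records List of [source_record()]s for one symbol, at most one per
#'   source.
#' @return Integer in 1..6.
#' @export
confidence_score <- function(records) {
  if (length(records) == 0) {
    stop("a ligase with no source records cannot enter the catalog", call. = FALSE)
  }
  syms <- vapply(records, function(r) r$symbol, character(1))
  srcs <- vapply(records, function(r) r$source, character(1))
  if (length(unique(syms)) != 1) {
    stop("all records must carry the same symbol", call. = FALSE)
  }
  if (anyDuplicated(srcs)) {
    stop("at most one record per source", call. = FALSE)
  }
  sum(vapply(records, score_source, integer(1)))
}

#' Co-opted / clinical ligase configuration
#'
#' Which ligases have already been recruited ("co-opted") by at least one
#' published PROTAC, and which of those have advanced to clinical trials. The
#' default list carries the ten co-opted ligases named in prose in the
#' degrader literature; the full co-opted set is resource-dependent, so the
#' default is user-overridable configuration, not an authoritative registry.
#'
#' @param co_opted_symbols Character vector of co-opted ligase symbols.
#' @param clinical_symbols Subset of `co_opted_symbols` in clinical trials.
#' @return A `co_opted_config` list.
#' @export
co_opted_config <- function(
    co_opted_symbols = c("VHL", "CRBN", "MDM2", "KEAP1", "DCAF16",
                         "DCAF11", "XIAP", "BIRC2", "AHR", "RNF4"),
    clinical_symbols = c("VHL", "CRBN")) {
  if (!all(clinical_symbols %in% co_opted_symbols)) {
    stop("clinical symbols must be a subset of co-opted symbols", call. = FALSE)
  }
  structure(list(co_opted_symbols = unique(co_opted_symbols),
                 clinical_symbols = unique(clinical_symbols)),
            class = "co_opted_config")
}

# IAP family members collapsed to their two PROTAC-relevant representatives.
iap_family <- function() {
  c("BIRC3", "BIRC5", "BIRC6", "BIRC7", "BIRC8", "NAIP")
}

score_ge_table <- function(df) {
  assert_cols(df, c("symbol", "lit_validated"), "GE source table")
  ifelse(as.logical(df$lit_validated), 2L, 1L)
}

score_ubihub_table <- function(df) {
  assert_cols(df, c("symbol", "function_text"), "UbiHub source table")
  ifelse(grepl("\\bE3\\b", df$function_text, ignore.case = TRUE, perl = TRUE),
         2L, 1L)
}

score_ubibrowser_table <- function(df) {
  assert_cols(df, c("symbol", "esi_count"), "UbiBrowser source table")
  ifelse(df$esi_count > 5, 2L, 1L)
}

# One row per symbol with the max sub-score (duplicates within a source keep
# the higher-scoring record, conservative toward evidence).
collapse_source <- function(symbols, scores, source) {
  if (length(symbols) == 0) {
    return(tibble::tibble(symbol = character(), score = integer()))
  }
  dup <- anyDuplicated(symbols)
  if (dup) {
    message(sprintf("duplicate record(s) within source %s collapsed, keeping max sub-score", source))
  }
  tibble::tibble(symbol = symbols, score = scores) |>
    dplyr::group_by(.data$symbol) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop")
}

#' Assemble the unified E3-ligase catalog
#'
#' Builds one catalog entry per unique harmonized symbol across the union of
#' the three source lists, with per-source sub-scores, the cumulative
#' confidence score, and co-opted / clinical flags. IAP-family members other
#' than BIRC2 and XIAP are dropped, since those two represent IAPs in
#' IAP-based degraders. Ordering is lexicographic by symbol (deterministic).
#'
#' @param ge Tibble with columns `symbol`, `lit_validated`.
#' @param ubihub Tibble with columns `symbol`, `function_text`.
#' @param ubibrowser Tibble with columns `symbol`, `esi_count`.
#' @param co_opted A [co_opted_config()].
#' @param alias_map Optional alias map passed to [harmonize_symbol()].
#' @return Tibble with columns `symbol`, `score_ge`, `score_ubihub`,
#'   `score_ubibrowser` (NA where the source lacks the ligase), `confidence`,
#'   `n_sources`, `co_opted`, `clinical`.
#' @export
assemble_catalog <- function(ge, ubihub, ubibrowser,
                             co_opted = co_opted_config(),
                             alias_map = character()) {
  stopifnot(inherits(co_opted, "co_opted_config"))
  co_opted_symbols <- co_opted$co_opted_symbols
  clinical_symbols <- co_opted$clinical_symbols

  ge$symbol <- harmonize_symbol(ge$symbol, alias_map)
  ubihub$symbol <- harmonize_symbol(ubihub$symbol, alias_map)
  ubibrowser$symbol <- harmonize_symbol(ubibrowser$symbol, alias_map)

  s_ge <- collapse_source(ge$symbol, score_ge_table(ge), "GE")
  s_uh <- collapse_source(ubihub$symbol, score_ubihub_table(ubihub), "UBIHUB")
  s_ub <- collapse_source(ubibrowser$symbol, score_ubibrowser_table(ubibrowser),
                          "UBIBROWSER")

  cat_tbl <- dplyr::full_join(
    dplyr::rename(s_ge, score_ge = "score"),
    dplyr::rename(s_uh, score_ubihub = "score"),
    by = "symbol"
  ) |>
    dplyr::full_join(dplyr::rename(s_ub, score_ubibrowser = "score"),
                     by = "symbol") |>
    dplyr::filter(!(.data$symbol %in% iap_family())) |>
    dplyr::mutate(
      confidence = rowSums(cbind(.data$score_ge, .data$score_ubihub,
                                 .data$score_ubibrowser), na.rm = TRUE),
      n_sources = rowSums(!is.na(cbind(.data$score_ge, .data$score_ubihub,
                                       .data$score_ubibrowser))),
      co_opted = .data$symbol %in% .env$co_opted_symbols,
      clinical = .data$symbol %in% .env$clinical_symbols
    ) |>
    dplyr::arrange(.data$symbol)

  orphan <- setdiff(co_opted$co_opted_symbols, cat_tbl$symbol)
  if (length(orphan) > 0) {
    warning("co-opted symbol(s) absent from every source list (not added): ",
            paste(orphan, collapse = ", "), call. = FALSE)
  }
  cat_tbl
}

#' Read the three catalog source tables from TSV files
#'
#' @param ge_path,ubihub_path,ubibrowser_path Paths to headered TSVs with a
#'   `symbol` column plus `lit_validated` / `function_text` / `esi_count`
#'   respectively.
#' @return Named list of tibbles `ge`, `ubihub`, `ubibrowser`.
#' @export
read_catalog_sources <- function(ge_path, ubihub_path, ubibrowser_path) {
  list(
    ge = read_tsv_quiet(ge_path),
    ubihub = read_tsv_quiet(ubihub_path),
    ubibrowser = read_tsv_quiet(ubibrowser_path)
  )
}

#' Read a co-opted configuration from YAML or JSON
#'
#' Expects top-level keys `co_opted_symbols` and `clinical_symbols`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [co_opted_config()].
#' @export
read_co_opted_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  co_opted_config(co_opted_symbols = unlist(cfg$co_opted_symbols),
                  clinical_symbols = unlist(cfg$clinical_symbols))
}
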