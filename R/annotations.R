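#' Essentiality call from dependency probabilities
#'
#' A gene is called essential when the mean dependency probability across
#' cell lines is strictly greater than 0.5 (a mean of exactly 0.5 is not
#' essential). With `grouping = "by_lineage"` the mean is computed within
#' each cell-line lineage and a per-lineage call is returned; the overall
#' mean equals the lineage-size-weighted mean of lineage means.
#'
#' @param probs Named numeric vector of dependency probabilities in `[0, 1]`,
#'   one per cell line.
#' @param lineage_of Optional named character vector mapping cell line ->
#'   lineage (required for `by_lineage`).
#' @param grouping `"overall"` or `"by_lineage"`.
#' @param threshold Essentiality cutoff (default 0.5, strict).
#' @return Logical (overall) or a named logical vector per lineage.
#' @export
essentiality_call <- function(probs, lineage_of = NULL,
                              grouping = c("overall", "by_lineage"),
                              threshold = 0.5) {
  grouping <- match.arg(grouping)
  if (length(probs) == 0) stop("no cell lines", call. = FALSE)
  if (any(probs < 0 | probs > 1, na.rm = TRUE)) {
    stop("dependency probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (grouping == "overall") {
    return(mean(probs, na.rm = TRUE) > threshold)
  }
  if (is.null(lineage_of)) {
    stop("`lineage_of` is required for by-lineage grouping", call. = FALSE)
  }
  lin <- lineage_of[names(probs)]
  means <- tapply(probs, lin, mean, na.rm = TRUE)
  stats::setNames(as.vector(means) > threshold, names(means))
}

#' Essentiality calls for a probability matrix
#'
#' @param prob_mat Numeric matrix, genes x cell lines, dependency
#'   probabilities.
#' @param lineage_of Optional named character vector (cell line -> lineage).
#' @param threshold Cutoff (default 0.5, strict).
#' @return Tibble `symbol`, `mean_prob`, `essential`; with lineages, an
#'   additional long tibble in attribute `by_lineage`.
#' @export
essentiality_table <- function(prob_mat, lineage_of = NULL, threshold = 0.5) {
  if (any(prob_mat < 0 | prob_mat > 1, na.rm = TRUE)) {
    stop("dependency probabilities must lie in [0, 1]", call. = FALSE)
  }
  m <- rowMeans(prob_mat, na.rm = TRUE)
  out <- tibble::tibble(symbol = rownames(prob_mat),
                        mean_prob = unname(m),
                        essential = unname(m) > threshold)
  if (!is.null(lineage_of)) {
    lin <- lineage_of[colnames(prob_mat)]
    by_lin <- lapply(sort(unique(lin)), function(l) {
      mm <- rowMeans(prob_mat[, lin == l, drop = FALSE], na.rm = TRUE)
      tibble::tibble(symbol = rownames(prob_mat), lineage = l,
                     mean_prob = unname(mm), essential = unname(mm) > threshold)
    })
    attr(out, "by_lineage") <- dplyr::bind_rows(by_lin)
  }
  out
}

#' Summarize subcellular-location annotations for one ligase
#'
#' Integrates high-confidence location annotations from multiple sources
#' (GO / COMPARTMENTS / UniProt-like). COMPARTMENTS annotations qualify only
#' with score strictly greater than 3; GO/UniProt rows are assumed
#' pre-filtered to high-confidence evidence (config vocabulary upstream).
#' A ligase annotated to a location by any source is considered distributed
#' there. Favorable locations for degrader recruitment are cytoplasm
#' (terms containing "cytoplasm" and/or "cytosol") and nucleus (terms
#' containing "nucleus"); matching is case-insensitive substring.
#'
#' @param annotations Tibble with columns `source` (`GO`, `COMPARTMENTS`,
#'   `UNIPROT`), `term`, and `score` (COMPARTMENTS only; others NA).
#' @param compartments_min_score Strict lower bound for COMPARTMENTS
#'   (default 3).
#' @return List: `locations` (unique retained terms), `in_cytoplasm`,
#'   `in_nucleus`, `favorable`, `exclusivity` (one of "cytoplasm-only",
#'   "nucleus-only", "both", "neither").
#' @export
locate <- function(annotations, compartments_min_score = 3) {
  if (nrow(annotations) == 0) {
    return(list(locations = character(), in_cytoplasm = FALSE,
                in_nucleus = FALSE, favorable = FALSE, exclusivity = "neither"))
  }
  assert_cols(annotations, c("source", "term"), "location table")
  score <- col_or(annotations, "score", rep(NA_real_, nrow(annotations)))
  keep <- annotations$source != "COMPARTMENTS" |
    (!is.na(score) & score > compartments_min_score)
  terms <- unique(annotations$term[keep])
  tl <- tolower(terms)
  in_cyt <- any(grepl("cytoplasm", tl, fixed = TRUE) |
                  grepl("cytosol", tl, fixed = TRUE))
  in_nuc <- any(grepl("nucleus", tl, fixed = TRUE))
  exclusivity <- if (in_cyt && in_nuc) "both"
    else if (in_cyt) "cytoplasm-only"
    else if (in_nuc) "nucleus-only"
    else "neither"
  list(locations = sort(terms), in_cytoplasm = in_cyt, in_nucleus = in_nuc,
       favorable = in_cyt || in_nuc, exclusivity = exclusivity)
}

#' Location summary table for many ligases
#'
#' @param annotations Tibble with columns `symbol`, `source`, `term`, `score`.
#' @param symbols Symbols to report (unannotated symbols get "neither").
#' @inheritParams locate
#' @return Tibble `symbol`, `in_cytoplasm`, `in_nucleus`, `favorable_location`,
#'   `location_exclusivity`.
#' @export
location_table <- function(annotations, symbols, compartments_min_score = 3) {
  per <- lapply(symbols, function(s) {
    loc <- locate(annotations[annotations$symbol == s, , drop = FALSE],
                  compartments_min_score)
    tibble::tibble(symbol = s, in_cytoplasm = loc$in_cytoplasm,
                   in_nucleus = loc$in_nucleus,
                   favorable_location = loc$favorable,
                   location_exclusivity = loc$exclusivity)
  })
  dplyr::bind_rows(per)
}

#' Structure availability for one ligase
#'
#' Counts distinct experimentally determined structures; ligases with none
#' fall back to the predicted-structure archive, recorded as an availability
#' flag only (no coordinates are read).
#'
#' @param symbol Gene symbol.
#' @param pdb_index Tibble `symbol`, `structure_id` (experimental).
#' @param afdb_index Character vector of symbols with predicted structures.
#' @return List `symbol`, `n_pdb`, `afdb_available` (TRUE only when
#'   `n_pdb == 0` and the symbol is in the predicted archive).
#' @export
structure_summary <- function(symbol, pdb_index, afdb_index) {
  n_pdb <- length(unique(pdb_index$structure_id[pdb_index$symbol == symbol]))
  list(symbol = symbol, n_pdb = n_pdb,
       afdb_available = n_pdb == 0 && symbol %in% afdb_index)
}

#' Structure availability table
#'
#' @param symbols Symbols to report.
#' @inheritParams structure_summary
#' @return Tibble `symbol`, `n_pdb`, `afdb_available`.
#' @export
structure_table <- function(symbols, pdb_index, afdb_index) {
  counts <- pdb_index |>
    dplyr::group_by(.data$symbol) |>
    dplyr::summarise(n_pdb = dplyr::n_distinct(.data$structure_id),
                     .groups = "drop")
  tibble::tibble(symbol = symbols) |>
    dplyr::left_join(counts, by = "symbol") |>
    dplyr::mutate(n_pdb = dplyr::coalesce(.data$n_pdb, 0L),
                  afdb_available = .data$n_pdb == 0 & .data$symbol %in% afdb_index)
}

# Parse "start-end" 1-based inclusive residue ranges ("12-20,33-35" or "7").
parse_residue_ranges <- function(spec) {
  parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
  do.call(rbind, lapply(parts, function(p) {
    se <- as.integer(strsplit(trimws(p), "-", fixed = TRUE)[[1]])
    if (any(is.na(se)) || any(se < 1)) {
      stop("invalid residue range: ", p, call. = FALSE)
    }
    if (length(se) == 1) se <- c(se, se)
    c(start = se[1], end = se[2])
  }))
}

#' Interface summary for one ligase
#'
#' Counts the ligase's interaction interfaces as distinct (partner, source)
#' pairs — the default, since interface provenance (co-crystal, homology
#' model, high-confidence prediction) is reported separately — or distinct
#' partners with `collapse_partners = TRUE`. Also returns a residue-level
#' membership query.
#'
#' @param records Tibble with columns `symbol`, `partner`, `source`
#'   (`PDB`, `INTERACTOME3D`, `ECLAIR_HIGH`), `residues` ("start-end" 1-based
#'   inclusive, comma-separated for multiple ranges).
#' @param symbol Ligase symbol.
#' @param collapse_partners Count distinct partners instead of
#'   (partner, source) pairs.
#' @return List: `n_interfaces`, `interfaces` (deduplicated tibble), and
#'   `residue_in_interface(position)` returning TRUE when the residue lies
#'   in any interface range of this ligase.
#' @export
interface_summary <- function(records, symbol, collapse_partners = FALSE) {
  rec <- records[records$symbol == symbol, , drop = FALSE]
  if (nrow(rec) > 0) {
    assert_cols(rec, c("symbol", "partner", "source", "residues"),
                "interface table")
  }
  uniq <- if (collapse_partners) {
    dplyr::distinct(rec, .data$partner)
  } else {
    dplyr::distinct(rec, .data$partner, .data$source)
  }
  ranges <- if (nrow(rec) > 0) {
    do.call(rbind, lapply(rec$residues, parse_residue_ranges))
  } else {
    matrix(integer(), ncol = 2, dimnames = list(NULL, c("start", "end")))
  }
  list(
    n_interfaces = nrow(uniq),
    interfaces = uniq,
    residue_in_interface = function(position) {
      any(ranges[, "start"] <= position & position <= ranges[, "end"])
    }
  )
}

#' Interface counts for many ligases
#'
#' @param records Interface tibble (see [interface_summary()]).
#' @param symbols Symbols to report.
#' @param collapse_partners Count distinct partners instead of
#'   (partner, source) pairs.
#' @return Tibble `symbol`, `n_interfaces`.
#' @export
interface_table <- function(records, symbols, collapse_partners = FALSE) {
  uniq <- if (collapse_partners) {
    dplyr::distinct(records, .data$symbol, .data$partner)
  } else {
    dplyr::distinct(records, .data$symbol, .data$partner, .data$source)
  }
  counts <- uniq |>
    dplyr::group_by(.data$symbol) |>
    dplyr::summarise(n_interfaces = dplyr::n(), .groups = "drop")
  tibble::tibble(symbol = symbols) |>
    dplyr::left_join(counts, by = "symbol") |>
    dplyr::mutate(n_interfaces = dplyr::coalesce(.data$n_interfaces, 0L))
}
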