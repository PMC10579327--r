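#' Default physical-evidence detection-method vocabulary
#'
#' Interactions detected by yeast two-hybrid, affinity purification-mass
#' spectrometry, protein 3D structures, or low-throughput experiments are
#' flagged as physical associations. Matching is case-insensitive substring
#' on these tokens; the vocabulary is configuration, since sources name
#' methods in PSI-MI-style free text.
#'
#' @return Character vector of method tokens.
#' @export
physical_method_vocabulary <- function() {
  c("two hybrid", "two-hybrid", "y2h",
    "affinity purification", "ap-ms", "affinity chromatography",
    "x-ray", "3d structure", "crystal",
    "low throughput", "low-throughput")
}

is_physical_method <- function(method, vocab = physical_method_vocabulary()) {
  if (length(method) == 0) return(logical(0))
  method <- tolower(ifelse(is.na(method), "", method))
  Reduce(`|`, lapply(vocab, function(v) grepl(v, method, fixed = TRUE)))
}

human_organism_labels <- function() {
  c("9606", "homo sapiens", "human")
}

is_human <- function(x) {
  tolower(trimws(as.character(x))) %in% human_organism_labels()
}

#' Load and filter protein-interaction edges from one source dialect
#'
#' Applies the per-source retention rules before any merging:
#' * all dialects: non-human rows dropped;
#' * `STRING`: combined score must be strictly greater than 700 (0-1000 scale);
#' * `UBIBROWSER_PRED`: predicted E3-substrate interactions must have
#'   confidence strictly greater than 0.7;
#' * `UBIBROWSER_LIT`, `BIOGRID`, `INTACT`, `REACTOME`, `HURI`:
#'   literature-curated / assayed rows kept unconditionally.
#'
#' The physical-association flag is set when the row's detection method
#' matches the configured vocabulary ([physical_method_vocabulary()]); HuRI
#' rows default to the two-hybrid method of that atlas when no method column
#' is present.
#'
#' Expected columns by dialect: `UBIBROWSER`-like — `ligase`, `substrate`,
#' `evidence` ("literature"/"predicted"), `confidence`, `organism`;
#' `STRING`-like — `protein1`, `protein2`, `combined_score`, `species`;
#' all others — `symbol_a`, `symbol_b`, an organism column (`organism_a`/
#' `organism_b`, `taxid_a`/`taxid_b`, or `species`) and optionally `method`.
#'
#' @param table Tibble in the source's dialect.
#' @param source_tag One of `"UBIBROWSER"` (split internally into
#'   `UBIBROWSER_LIT`/`UBIBROWSER_PRED`), `"BIOGRID"`, `"INTACT"`,
#'   `"REACTOME"`, `"STRING"`, `"HURI"`.
#' @param physical_methods Method vocabulary for the physical flag.
#' @param alias_map Optional alias map applied to both symbols.
#' @return Tibble `a`, `b`, `source`, `score`, `physical` (one row per
#'   retained input row; not yet deduplicated).
#' @export
load_source_edges <- function(table, source_tag,
                              physical_methods = physical_method_vocabulary(),
                              alias_map = character()) {
  source_tag <- match.arg(source_tag, c("UBIBROWSER", "BIOGRID", "INTACT",
                                        "REACTOME", "STRING", "HURI"))
  if (nrow(table) == 0) {
    return(tibble::tibble(a = character(), b = character(), source = character(),
                          score = numeric(), physical = logical()))
  }

  if (source_tag == "UBIBROWSER") {
    assert_cols(table, c("ligase", "substrate", "evidence"), "UbiBrowser table")
    conf <- col_or(table, "confidence", rep(NA_real_, nrow(table)))
    org <- col_or(table, "organism", rep("9606", nrow(table)))
    keep_h <- is_human(org)
    pred <- tolower(table$evidence) == "predicted"
    keep <- keep_h & (!pred | (!is.na(conf) & conf > 0.7))
    out <- tibble::tibble(
      a = table$ligase[keep], b = table$substrate[keep],
      source = ifelse(pred[keep], "UBIBROWSER_PRED", "UBIBROWSER_LIT"),
      score = conf[keep],
      physical = is_physical_method(
        col_or(table, "method", rep(NA_character_, nrow(table)))[keep],
        physical_methods)
    )
  } else if (source_tag == "STRING") {
    assert_cols(table, c("protein1", "protein2", "combined_score"), "STRING table")
    org <- col_or(table, "species", rep("9606", nrow(table)))
    keep <- is_human(org) & !is.na(table$combined_score) &
      table$combined_score > 700
    out <- tibble::tibble(
      a = table$protein1[keep], b = table$protein2[keep],
      source = "STRING", score = table$combined_score[keep],
      physical = FALSE
    )
  } else {
    assert_cols(table, c("symbol_a", "symbol_b"), paste(source_tag, "table"))
    org_a <- col_or(table, "organism_a",
                    col_or(table, "taxid_a",
                           col_or(table, "species", rep("9606", nrow(table)))))
    org_b <- col_or(table, "organism_b", col_or(table, "taxid_b", org_a))
    keep <- is_human(org_a) & is_human(org_b)
    method <- col_or(table, "method", rep(NA_character_, nrow(table)))
    if (source_tag == "HURI") {
      method[is.na(method)] <- "two hybrid"
    }
    out <- tibble::tibble(
      a = table$symbol_a[keep], b = table$symbol_b[keep],
      source = source_tag, score = NA_real_,
      physical = is_physical_method(method[keep], physical_methods)
    )
  }

  bad <- is.na(out$a) | is.na(out$b) | !nzchar(out$a) | !nzchar(out$b)
  if (any(bad)) {
    warning(sprintf("%s: %d malformed row(s) skipped (rows %s)", source_tag,
                    sum(bad), paste(utils::head(which(bad), 5), collapse = ",")),
            call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  out$a <- harmonize_symbol(out$a, alias_map)
  out$b <- harmonize_symbol(out$b, alias_map)
  out
}

#' Merge raw edges from all sources into a deduplicated edge set
#'
#' Interactions are unordered: A-B and B-A collapse into one edge keyed by
#' the lexicographically sorted pair. Provenance is the union of reporting
#' sources, the physical flag is the OR across sources, and self-loops are
#' removed (set `keep_self_loops = TRUE` to retain them). Idempotent and
#' input-order invariant.
#'
#' @param raw_edges Tibble from (bound) [load_source_edges()] calls.
#' @param keep_self_loops Retain A-A edges (default FALSE).
#' @return Tibble `a`, `b` (a <= b), `sources` (comma-joined, sorted),
#'   `n_sources`, `physical`.
#' @export
merge_edges <- function(raw_edges, keep_self_loops = FALSE) {
  if (nrow(raw_edges) == 0) {
    return(tibble::tibble(a = character(), b = character(), sources = character(),
                          n_sources = integer(), physical = logical()))
  }
  lo <- pmin(raw_edges$a, raw_edges$b)
  hi <- pmax(raw_edges$a, raw_edges$b)
  df <- tibble::tibble(a = lo, b = hi, source = raw_edges$source,
                       physical = raw_edges$physical)
  if (!keep_self_loops) df <- df[df$a != df$b, , drop = FALSE]
  df |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(
      sources = paste(sort(unique(.data$source)), collapse = ","),
      n_sources = dplyr::n_distinct(.data$source),
      physical = any(.data$physical),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$a, .data$b)
}

#' Interaction partners of a set of E3 ligases
#'
#' All proteins with at least one merged edge to a member of `e3_set` — the
#' target space reachable through known interactions. Members of the E3 set
#' themselves are excluded by default (an E3 interacting with another E3 is
#' not a new degradation target).
#'
#' @param edges Merged edge tibble from [merge_edges()].
#' @param e3_set Character vector of ligase symbols.
#' @param exclude_e3 Drop partners that are themselves in `e3_set`.
#' @return Sorted character vector of target symbols.
#' @export
target_space <- function(edges, e3_set, exclude_e3 = TRUE) {
  if (length(e3_set) == 0 || nrow(edges) == 0) return(character())
  partners <- c(edges$b[edges$a %in% e3_set], edges$a[edges$b %in% e3_set])
  if (exclude_e3) partners <- setdiff(partners, e3_set)
  sort(unique(partners))
}

#' Percent increase between two counts
#'
#' `100 * (after - before) / before`, rounded half-up to one decimal —
#' the reporting convention for target-space expansion statistics (e.g.
#' 10,930 to 19,248 is a 76.1\% increase).
#'
#' @param before,after Counts; `before` must be positive.
#' @return Percentage at one decimal.
#' @export
percent_increase <- function(before, after) {
  if (any(before <= 0)) stop("`before` must be positive", call. = FALSE)
  round_half_up(100 * (after - before) / before, 1)
}

#' Number of interacting E3 ligases per target
#'
#' For each target, the number of distinct members of `e3_set` with a merged
#' edge to it, plus the median over targets. When an explicit target
#' universe is supplied (e.g. a degrader-tractability list), targets with no
#' interacting E3 count as 0 in the median denominator; without a universe
#' only observed partners enter.
#'
#' @param edges Merged edge tibble.
#' @param e3_set Character vector of ligase symbols.
#' @param targets Optional explicit target universe.
#' @return List with `counts` (tibble `target`, `n_e3`) and `median`.
#' @export
e3_per_target <- function(edges, e3_set, targets = NULL) {
  long <- dplyr::bind_rows(
    tibble::tibble(e3 = edges$a, target = edges$b),
    tibble::tibble(e3 = edges$b, target = edges$a)
  ) |>
    dplyr::filter(.data$e3 %in% e3_set, !.data$target %in% e3_set)
  counts <- long |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(n_e3 = dplyr::n_distinct(.data$e3), .groups = "drop")
  if (!is.null(targets)) {
    if (length(targets) == 0) {
      return(list(counts = tibble::tibble(target = character(), n_e3 = integer()),
                  median = NA_real_))
    }
    counts <- tibble::tibble(target = sort(unique(targets))) |>
      dplyr::left_join(counts, by = "target") |>
      dplyr::mutate(n_e3 = dplyr::coalesce(.data$n_e3, 0L))
  }
  list(counts = counts,
       median = if (nrow(counts) > 0) stats::median(counts$n_e3) else NA_real_)
}

#' Degrader-tractability target sets
#'
#' Combines two tractability assessments into their union and overlap.
#'
#' @param protactable_genome,mapd Character vectors of target symbols from
#'   the two assessments.
#' @return List with `protactable_genome`, `mapd`, `union`, `overlap`.
#' @export
tractability_sets <- function(protactable_genome, mapd) {
  list(
    protactable_genome = unique(protactable_genome),
    mapd = unique(mapd),
    union = sort(union(protactable_genome, mapd)),
    overlap = sort(intersect(protactable_genome, mapd))
  )
}

#' Per-ligase PPI degree
#'
#' Number of distinct partners of each symbol in the merged edge set.
#'
#' @param edges Merged edge tibble.
#' @param symbols Symbols to report (0 when absent from the edges).
#' @return Tibble `symbol`, `n_ppi`.
#' @export
ppi_degree <- function(edges, symbols) {
  long <- dplyr::bind_rows(
    tibble::tibble(symbol = edges$a, partner = edges$b),
    tibble::tibble(symbol = edges$b, partner = edges$a)
  )
  deg <- long |>
    dplyr::group_by(.data$symbol) |>
    dplyr::summarise(n_ppi = dplyr::n_distinct(.data$partner), .groups = "drop")
  tibble::tibble(symbol = symbols) |>
    dplyr::left_join(deg, by = "symbol") |>
    dplyr::mutate(n_ppi = dplyr::coalesce(.data$n_ppi, 0L))
}
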