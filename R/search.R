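#' Construct a candidate-search query
#'
#' The filter state of a prioritization search. Every switch is off by
#' default (off means the corresponding dimension is ignored), and each
#' printed threshold keeps its printed strictness: `min_confidence` and
#' `min_ppi` are strict lower bounds, `*_high_max_frac` are strict upper
#' bounds, `*_high_min` are inclusive minimum counts.
#'
#' @param min_confidence Keep ligases with confidence strictly greater than
#'   this (NULL = off).
#' @param require_ligand Require at least one ligand evidence category.
#' @param ligand_categories Accepted categories when `require_ligand` is on,
#'   subset of `c("drug", "chem", "cova")`.
#' @param tcga_high_min,hpa_high_min Minimum number of tumor types called
#'   High in the bulk tumor / protein-staining dataset (inclusive; NULL = off).
#' @param tcga_high_min_frac Minimum fraction of tumor types High (strict;
#'   NULL = off).
#' @param gtex_high_max_frac,tabula_high_max_frac Maximum fraction of normal
#'   tissues High (strict; NULL = off).
#' @param min_ppi Keep ligases with strictly more than this many distinct
#'   PPI partners (NULL = off).
#' @param require_structure Require at least one experimental structure or a
#'   predicted-structure fallback.
#' @param require_essential Require an essential call; `essential_screen`
#'   selects `"crispr"`, `"rnai"`, or `"either"`.
#' @param essential_screen See `require_essential`.
#' @param location_filter NULL or one of `"favorable"`, `"cytoplasm"`,
#'   `"nucleus"`, `"cytoplasm-only"`, `"nucleus-only"`.
#' @param require_interface Require at least one known PPI interface.
#' @param strict Use the printed strict comparisons (default); `FALSE`
#'   switches `min_confidence`/`min_ppi`/fraction bounds to inclusive, for
#'   sensitivity analysis.
#' @return A `candidate_query` list.
#' @export
candidate_query <- function(min_confidence = NULL,
                            require_ligand = FALSE,
                            ligand_categories = c("drug", "chem", "cova"),
                            tcga_high_min = NULL,
                            tcga_high_min_frac = NULL,
                            hpa_high_min = NULL,
                            gtex_high_max_frac = NULL,
                            tabula_high_max_frac = NULL,
                            min_ppi = NULL,
                            require_structure = FALSE,
                            require_essential = FALSE,
                            essential_screen = c("either", "crispr", "rnai"),
                            location_filter = NULL,
                            require_interface = FALSE,
                            strict = TRUE) {
  essential_screen <- match.arg(essential_screen)
  for (f in c(tcga_high_min_frac, gtex_high_max_frac, tabula_high_max_frac)) {
    if (!is.null(f) && (f < 0 || f > 1)) {
      stop("fractions must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(min_confidence = min_confidence, require_ligand = require_ligand,
         ligand_categories = match.arg(ligand_categories,
                                       c("drug", "chem", "cova"),
                                       several.ok = TRUE),
         tcga_high_min = tcga_high_min,
         tcga_high_min_frac = tcga_high_min_frac,
         hpa_high_min = hpa_high_min,
         gtex_high_max_frac = gtex_high_max_frac,
         tabula_high_max_frac = tabula_high_max_frac,
         min_ppi = min_ppi, require_structure = require_structure,
         require_essential = require_essential,
         essential_screen = essential_screen,
         location_filter = location_filter,
         require_interface = require_interface, strict = strict),
    class = "candidate_query"
  )
}

#' The worked-example search preset
#'
#' Moderately confident, ligandable, tumor-expressed, normal-spared, well
#' connected: confidence score > 3 (strict); any available ligand; High in
#' at least 1 bulk tumor type; High in less than 30\% of bulk normal tissues
#' (strict); more than 100 distinct PPI partners (strict). The tumor
#' condition uses the bulk tumor transcriptome only, exactly as worded.
#'
#' @return A [candidate_query()].
#' @export
case1_query <- function() {
  candidate_query(min_confidence = 3, require_ligand = TRUE,
                  tcga_high_min = 1, gtex_high_max_frac = 0.3, min_ppi = 100)
}

# Apply one comparison honoring query strictness.
cmp_gt <- function(x, bound, strict) if (strict) x > bound else x >= bound
cmp_lt <- function(x, bound, strict) if (strict) x < bound else x <= bound

#' General multi-switch candidate search
#'
#' Returns the ligases passing the conjunction of every enabled filter of
#' the query, ordered deterministically: confidence descending, then unique
#' ligand count descending, then symbol. A contradictory query (e.g.
#' `min_confidence = 7`) returns an empty result, not an error.
#'
#' @param atlas An `e3_atlas` from [build_atlas()].
#' @param query A [candidate_query()].
#' @return The summary rows of the passing ligases, ordered.
#' @export
general_search <- function(atlas, query = candidate_query()) {
  stopifnot(inherits(atlas, "e3_atlas"), inherits(query, "candidate_query"))
  s <- atlas$summary
  keep <- rep(TRUE, nrow(s))
  st <- query$strict

  if (!is.null(query$min_confidence)) {
    keep <- keep & cmp_gt(s$confidence, query$min_confidence, st)
  }
  if (query$require_ligand) {
    cat_ok <- rep(FALSE, nrow(s))
    if ("drug" %in% query$ligand_categories) cat_ok <- cat_ok | s$has_drug
    if ("chem" %in% query$ligand_categories) cat_ok <- cat_ok | s$has_chem
    if ("cova" %in% query$ligand_categories) cat_ok <- cat_ok | s$has_cova
    keep <- keep & cat_ok
  }
  if (!is.null(query$tcga_high_min)) {
    keep <- keep & s$n_tcga_high >= query$tcga_high_min
  }
  if (!is.null(query$tcga_high_min_frac)) {
    keep <- keep & cmp_gt(s$n_tcga_high / pmax(s$n_tcga_tissues, 1),
                          query$tcga_high_min_frac, st)
  }
  if (!is.null(query$hpa_high_min)) {
    keep <- keep & s$n_hpa_high >= query$hpa_high_min
  }
  if (!is.null(query$gtex_high_max_frac)) {
    keep <- keep & cmp_lt(s$n_gtex_high / pmax(s$n_gtex_tissues, 1),
                          query$gtex_high_max_frac, st)
  }
  if (!is.null(query$tabula_high_max_frac)) {
    keep <- keep & cmp_lt(s$n_tabula_high / pmax(s$n_tabula_tissues, 1),
                          query$tabula_high_max_frac, st)
  }
  if (!is.null(query$min_ppi)) {
    keep <- keep & cmp_gt(s$n_ppi, query$min_ppi, st)
  }
  if (query$require_structure) {
    keep <- keep & (s$n_pdb > 0 | s$afdb_available)
  }
  if (query$require_essential) {
    ess <- switch(query$essential_screen,
                  crispr = s$essential_crispr,
                  rnai = s$essential_rnai,
                  either = s$essential_crispr | s$essential_rnai)
    keep <- keep & ess
  }
  if (!is.null(query$location_filter)) {
    loc_ok <- switch(query$location_filter,
                     favorable = s$favorable_location,
                     cytoplasm = s$in_cytoplasm,
                     nucleus = s$in_nucleus,
                     `cytoplasm-only` = s$location_exclusivity == "cytoplasm-only",
                     `nucleus-only` = s$location_exclusivity == "nucleus-only",
                     stop("unknown location filter: ", query$location_filter,
                          call. = FALSE))
    keep <- keep & loc_ok
  }
  if (query$require_interface) {
    keep <- keep & s$n_interfaces > 0
  }

  s[keep, , drop = FALSE] |>
    dplyr::arrange(dplyr::desc(.data$confidence),
                   dplyr::desc(.data$n_unique_ligands), .data$symbol)
}

#' Search for E3 ligases interacting with a specific target
#'
#' Restricts [general_search()] to ligases having a merged edge to `target`;
#' with a `cancer_type`, additionally requires a High call in that tumor
#' type (in the bulk tumor and/or protein-staining dataset, per `datasets`).
#' A specificity tiebreak — ascending PPI degree, so the most target-
#' dedicated ligase leads among otherwise equal candidates — is appended to
#' the ordering.
#'
#' @param atlas An `e3_atlas`.
#' @param target Target symbol.
#' @param cancer_type Optional tumor-type label.
#' @param query A [candidate_query()].
#' @param datasets Which tumor datasets the cancer-type condition may be
#'   satisfied in (`"TCGA"`, `"HPA"`; either suffices when both given).
#' @return Summary rows of the passing ligases, specificity-ordered.
#' @export
search_by_target <- function(atlas, target, cancer_type = NULL,
                             query = candidate_query(),
                             datasets = c("TCGA", "HPA")) {
  datasets <- match.arg(datasets, several.ok = TRUE)
  interactors <- target_space(atlas$edges, target, exclude_e3 = FALSE)
  base <- general_search(atlas, query)
  res <- base[base$symbol %in% interactors, , drop = FALSE]
  if (!is.null(cancer_type) && nrow(res) > 0) {
    ok <- rep(FALSE, nrow(res))
    if ("TCGA" %in% datasets) {
      hi <- atlas$calls$tcga$symbol[atlas$calls$tcga$tissue == cancer_type &
                                      atlas$calls$tcga$call == "High"]
      ok <- ok | res$symbol %in% hi
    }
    if ("HPA" %in% datasets) {
      hi <- atlas$calls$hpa$symbol[atlas$calls$hpa$tissue == cancer_type &
                                     atlas$calls$hpa$call == "High"]
      ok <- ok | res$symbol %in% hi
    }
    res <- res[ok, , drop = FALSE]
  }
  res |>
    dplyr::arrange(dplyr::desc(.data$confidence),
                   dplyr::desc(.data$n_unique_ligands),
                   .data$n_ppi, .data$symbol)
}

#' Consolidated profile of one ligase
#'
#' Joins every characterization dimension for one catalog symbol into a
#' single record: catalog scores, ligandability, per-dataset expression
#' calls and flags, PPI degree and partners, essentiality, location,
#' structures, interfaces.
#'
#' @param atlas An `e3_atlas`.
#' @param symbol Catalog symbol; unknown symbols are an error.
#' @return A list (class `ligase_profile`).
#' @export
ligase_profile <- function(atlas, symbol) {
  stopifnot(inherits(atlas, "e3_atlas"))
  if (!symbol %in% atlas$catalog$symbol) {
    stop("symbol not in catalog: ", symbol, call. = FALSE)
  }
  row <- atlas$summary[atlas$summary$symbol == symbol, , drop = FALSE]
  calls <- lapply(atlas$calls, function(df) {
    df[df$symbol == symbol, setdiff(names(df), "symbol"), drop = FALSE]
  })
  partners <- target_space(atlas$edges, symbol, exclude_e3 = FALSE)
  structure(
    list(symbol = symbol, summary = row, calls = calls, partners = partners,
         n_ppi = row$n_ppi),
    class = "ligase_profile"
  )
}

#' @export
print.ligase_profile <- function(x, ...) {
  s <- x$summary
  cat("<ligase_profile>", x$symbol, "\n")
  cat("  confidence:", s$confidence, " tier:", s$tier,
      " ligands:", s$n_unique_ligands, "\n")
  cat("  tumor-selective:", s$tumor_selective, " PPIs:", s$n_ppi, "\n")
  invisible(x)
}

#' Hypergeometric enrichment of a gene set against term sets
#'
#' For each term, tests over-representation of `gene_set` in the term's
#' members with the upper-tail hypergeometric probability
#' P(X >= k) where k is the observed overlap, K the term size, n the gene
#' set size and N the universe size; p-values are adjusted across all
#' tested terms with the Benjamini-Hochberg procedure, and terms with
#' adjusted p below 0.05 are flagged significant.
#'
#' @param gene_set Character vector (must be a subset of `universe`).
#' @param term_sets Named list of character vectors (clipped to `universe`).
#' @param universe Character vector of all eligible genes.
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @return Tibble `term`, `k`, `n`, `K`, `N`, `p`, `p_adj`, `significant`,
#'   sorted by `p`.
#' @export
enrich_partners <- function(gene_set, term_sets, universe, alpha = 0.05) {
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  if (length(gene_set) == 0 || length(term_sets) == 0) {
    return(tibble::tibble(term = character(), k = integer(), n = integer(),
                          K = integer(), N = integer(), p = numeric(),
                          p_adj = numeric(), significant = logical()))
  }
  if (!all(gene_set %in% universe)) {
    stop("gene_set must be a subset of the universe", call. = FALSE)
  }
  N <- length(universe)
  n <- length(gene_set)
  rows <- lapply(names(term_sets), function(tm) {
    members <- intersect(unique(term_sets[[tm]]), universe)
    K <- length(members)
    k <- length(intersect(gene_set, members))
    # P(X >= k); k = 0 gives p = 1 by convention
    p <- if (k == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(term = tm, k = k, n = n, K = K, N = N, p = p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  dplyr::arrange(out, .data$p, .data$term)
}

#' Enrichment of one ligase's interaction partners
#'
#' Convenience wrapper: the gene set is the ligase's merged-edge partners,
#' the default universe is every protein appearing in the merged edge set.
#'
#' @param atlas An `e3_atlas`.
#' @param symbol Ligase symbol.
#' @param term_sets Named list of term member vectors.
#' @param universe Optional universe override.
#' @inheritParams enrich_partners
#' @return See [enrich_partners()].
#' @export
enrich_ligase_partners <- function(atlas, symbol, term_sets, universe = NULL,
                                   alpha = 0.05) {
  partners <- target_space(atlas$edges, symbol, exclude_e3 = FALSE)
  if (is.null(universe)) {
    universe <- sort(unique(c(atlas$edges$a, atlas$edges$b)))
  }
  enrich_partners(intersect(partners, universe), term_sets, universe, alpha)
}
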