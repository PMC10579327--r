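#' Per-tissue bulk expression level
#'
#' The bulk expression level of a gene in a tissue (or cancer type) is the
#' median of log2(TPM + 1) over that tissue's samples. Inputs are assumed
#' pre-normalized to log2(TPM + 1), as in uniformly recomputed compendia.
#'
#' @param mat Numeric matrix, genes x samples, rownames = gene symbols,
#'   colnames = sample ids, values log2(TPM + 1).
#' @param sample_meta Tibble with columns `sample`, `tissue` labelling every
#'   column of `mat`.
#' @param symbol Gene symbol (row of `mat`).
#' @param tissue Tissue / cancer-type label.
#' @return Median log2(TPM + 1); error if the tissue has no samples.
#' @export
bulk_tissue_level <- function(mat, sample_meta, symbol, tissue) {
  assert_cols(sample_meta, c("sample", "tissue"), "sample metadata")
  samples <- sample_meta$sample[sample_meta$tissue == tissue]
  samples <- intersect(samples, colnames(mat))
  if (length(samples) == 0) {
    stop("no samples labelled with tissue: ", tissue, call. = FALSE)
  }
  stats::median(mat[symbol, samples])
}

#' All per-tissue bulk levels for a matrix
#'
#' @inheritParams bulk_tissue_level
#' @return Tibble `symbol`, `tissue`, `level` (median log2(TPM + 1)),
#'   `call` ("High"/"Low" via [classify_bulk()]).
#' @export
bulk_tissue_calls <- function(mat, sample_meta) {
  assert_cols(sample_meta, c("sample", "tissue"), "sample metadata")
  if (any(mat < 0)) stop("log2(TPM + 1) values must be non-negative", call. = FALSE)
  tissues <- sort(unique(sample_meta$tissue))
  res <- lapply(tissues, function(ts) {
    idx <- sample_meta$sample[sample_meta$tissue == ts]
    idx <- intersect(idx, colnames(mat))
    med <- apply(mat[, idx, drop = FALSE], 1, stats::median)
    tibble::tibble(symbol = rownames(mat), tissue = ts, level = unname(med))
  })
  dplyr::bind_rows(res) |>
    dplyr::mutate(call = classify_bulk(.data$level))
}

#' High/Low call from a bulk expression level
#'
#' A tissue is "High" when the median log2(TPM + 1) is strictly higher
#' than 4 (4.0 exactly is Low); "Low" otherwise. Low is thus the exact
#' complement, level <= 4.
#'
#' @param level Numeric vector of median log2(TPM + 1) values.
#' @param threshold High-expression cutoff (default 4, strict).
#' @return Character vector "High"/"Low".
#' @export
classify_bulk <- function(level, threshold = 4) {
  ifelse(level > threshold, "High", "Low")
}

#' High/Low call from protein-staining sample calls
#'
#' An immunohistochemistry profile for one (gene, cancer type) is "High"
#' when the fraction of samples staining medium-or-high reaches the
#' threshold, by default 20\% inclusive (set `strict = TRUE` for a strictly
#' greater-than rule).
#'
#' @param calls Character vector of per-sample staining calls from
#'   \{`not_detected`, `low`, `medium`, `high`\}.
#' @param threshold_frac Fraction of medium/high samples required (default 0.20).
#' @param strict If `TRUE`, require strictly more than `threshold_frac`.
#' @param high_levels Staining levels counted as "median-high" expression.
#' @return `"High"` or `"Low"`.
#' @export
classify_hpa <- function(calls, threshold_frac = 0.20, strict = FALSE,
                         high_levels = c("medium", "high")) {
  vocab <- c("not_detected", "low", "medium", "high")
  if (length(calls) == 0) stop("no staining calls", call. = FALSE)
  if (!all(calls %in% vocab)) {
    stop("staining calls outside the 4-level vocabulary: ",
         paste(setdiff(calls, vocab), collapse = ", "), call. = FALSE)
  }
  frac <- mean(calls %in% high_levels)
  hit <- if (strict) frac > threshold_frac else frac >= threshold_frac
  if (hit) "High" else "Low"
}

#' Per-(symbol, cancer type) staining calls for a whole table
#'
#' @param staining Tibble with columns `symbol`, `cancer_type`, `sample_id`,
#'   `staining_call`.
#' @inheritParams classify_hpa
#' @return Tibble `symbol`, `tissue`, `frac_high`, `call`.
#' @export
hpa_tissue_calls <- function(staining, threshold_frac = 0.20, strict = FALSE,
                             high_levels = c("medium", "high")) {
  assert_cols(staining, c("symbol", "cancer_type", "sample_id", "staining_call"),
              "protein staining table")
  staining |>
    dplyr::group_by(.data$symbol, tissue = .data$cancer_type) |>
    dplyr::summarise(
      frac_high = mean(.data$staining_call %in% high_levels),
      .groups = "drop"
    ) |>
    dplyr::mutate(call = ifelse(
      if (strict) .data$frac_high > threshold_frac
      else .data$frac_high >= threshold_frac,
      "High", "Low"))
}

#' Derive single-cell High-expression thresholds from a reference pattern
#'
#' There is no established single-cell overexpression cutoff for degrader
#' safety, so thresholds are anchored to a reference expression pattern known
#' to be safe — VHL in platelets, expressed in 17\% of cells with a mean of
#' 3.1 over non-zero cells — scaled down (default 75\%) to be more stringent:
#' 0.75 x (17, 3.1) = (12.75, 2.325).
#'
#' @param ref_frac_pct Reference percentage of non-zero expressing cells.
#' @param ref_mean Reference mean expression over non-zero cells.
#' @param scale Scaling fraction applied to both components.
#' @return List with `frac_pct_threshold`, `mean_threshold`, `reference`,
#'   `scale` (class `sc_thresholds`).
#' @export
derive_sc_thresholds <- function(ref_frac_pct = 17, ref_mean = 3.1,
                                 scale = 0.75) {
  if (ref_frac_pct <= 0 || ref_mean <= 0 || scale <= 0) {
    stop("reference pattern and scale must be positive", call. = FALSE)
  }
  structure(
    list(frac_pct_threshold = scale * ref_frac_pct,
         mean_threshold = scale * ref_mean,
         reference = c(ref_frac_pct = ref_frac_pct, ref_mean = ref_mean),
         scale = scale),
    class = "sc_thresholds"
  )
}

#' High/Low call for one gene in one tissue at single-cell resolution
#'
#' A tissue is "High" for a gene when both conditions hold strictly: the
#' percentage of cells with non-zero expression exceeds the fraction
#' threshold (default 12.75\%), and the mean expression computed over the
#' non-zero cells only exceeds the mean threshold (default 2.325).
#'
#' @param cells Numeric vector: the gene's (normalized, log-scale) expression
#'   over one tissue's cells.
#' @param thr An `sc_thresholds` object from [derive_sc_thresholds()].
#' @return `"High"` or `"Low"`.
#' @export
classify_sc_tissue <- function(cells, thr = derive_sc_thresholds()) {
  stopifnot(inherits(thr, "sc_thresholds"))
  if (length(cells) == 0) stop("no cells for this tissue", call. = FALSE)
  nz <- cells[cells != 0]
  frac_pct <- 100 * length(nz) / length(cells)
  mean_nz <- if (length(nz) > 0) mean(nz) else 0
  if (frac_pct > thr$frac_pct_threshold && mean_nz > thr$mean_threshold) {
    "High"
  } else {
    "Low"
  }
}

#' Per-tissue single-cell calls for a whole expression matrix
#'
#' @param counts Sparse or dense matrix, genes x cells, normalized log-scale
#'   expression; rownames = gene symbols, colnames = cell ids.
#' @param cell_meta Tibble with columns `cell_id`, `tissue` (and optionally
#'   `cell_type`, `malignant`); every cell must carry a cell type when the
#'   column is present.
#' @param thr An `sc_thresholds` object.
#' @return Tibble `symbol`, `tissue`, `frac_pct`, `mean_nonzero`, `call`.
#' @export
sc_tissue_calls <- function(counts, cell_meta, thr = derive_sc_thresholds()) {
  assert_cols(cell_meta, c("cell_id", "tissue"), "cell metadata")
  if ("cell_type" %in% names(cell_meta) && anyNA(cell_meta$cell_type)) {
    stop("cells with missing cell_type are rejected at load", call. = FALSE)
  }
  tissues <- sort(unique(cell_meta$tissue))
  res <- lapply(tissues, function(ts) {
    cells <- intersect(cell_meta$cell_id[cell_meta$tissue == ts],
                       colnames(counts))
    sub <- counts[, cells, drop = FALSE]
    nnz <- Matrix::rowSums(sub != 0)
    tot <- Matrix::rowSums(sub)
    mean_nz <- ifelse(nnz > 0, tot / nnz, 0)
    tibble::tibble(
      symbol = rownames(counts), tissue = ts,
      frac_pct = unname(100 * nnz / length(cells)),
      mean_nonzero = unname(mean_nz)
    )
  })
  dplyr::bind_rows(res) |>
    dplyr::mutate(call = ifelse(
      .data$frac_pct > thr$frac_pct_threshold &
        .data$mean_nonzero > thr$mean_threshold,
      "High", "Low"))
}

#' Is a gene lowly expressed in the majority of tissues?
#'
#' TRUE when at least `majority_frac` (default 70\%, inclusive) of the
#' profiled tissues carry a "Low" call. The denominator is the number of
#' tissues present in the loaded dataset.
#'
#' @param calls Character vector (or tissue-named vector) of "High"/"Low"
#'   calls, one per tissue.
#' @param majority_frac Required fraction of Low tissues (default 0.70).
#' @return Logical.
#' @export
low_in_majority <- function(calls, majority_frac = 0.70) {
  if (length(calls) == 0) {
    warning("empty tissue profile; treating as not low-majority", call. = FALSE)
    return(FALSE)
  }
  mean(calls == "Low") >= majority_frac
}

#' Tumor-selectivity flag for one ligase
#'
#' A ligase is tumor-selective when it is highly expressed in at least one
#' tumor type in both the bulk tumor transcriptome (TCGA-like) and the
#' protein-staining pathology atlas (HPA-like), AND lowly expressed in the
#' majority of normal tissues in both the bulk normal transcriptome
#' (GTEx-like) and the normal single-cell atlas (Tabula-like).
#'
#' @param tcga_calls,hpa_calls,gtex_calls,tabula_calls Character vectors of
#'   per-tissue "High"/"Low" calls for the four dataset classes.
#' @param majority_frac Passed to [low_in_majority()].
#' @return Logical.
#' @export
tumor_selectivity <- function(tcga_calls, hpa_calls, gtex_calls, tabula_calls,
                              majority_frac = 0.70) {
  if (length(tcga_calls) == 0 || length(hpa_calls) == 0 ||
      length(gtex_calls) == 0 || length(tabula_calls) == 0) {
    warning("missing dataset profile; tumor selectivity is FALSE", call. = FALSE)
    return(FALSE)
  }
  any(tcga_calls == "High") && any(hpa_calls == "High") &&
    low_in_majority(gtex_calls, majority_frac) &&
    low_in_majority(tabula_calls, majority_frac)
}

#' Cell-group composition of a gene's expressing cells in a tumor dataset
#'
#' For a tumor single-cell dataset whose cells are grouped (malignant /
#' immune / other), reports per group: the number of cells, the number
#' expressing the gene (non-zero), the within-group expressing percentage,
#' and the group's share among all expressing cells. Percentages are rounded
#' half-up to one decimal for reporting; shares sum to 100 (+/- 0.1 from
#' rounding).
#'
#' @param expr Numeric vector: the gene's expression over the dataset's cells.
#' @param group Character vector of cell-group labels, same length as `expr`.
#' @return Tibble `group`, `n_cells`, `n_expressing`, `pct_within_group`,
#'   `pct_of_expressing`, plus attribute `flagged` = TRUE when no cell
#'   expresses the gene (shares undefined, set NA).
#' @export
sc_tumor_composition <- function(expr, group) {
  stopifnot(length(expr) == length(group))
  tab <- tibble::tibble(group = group, expressed = expr != 0) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     n_expressing = sum(.data$expressed),
                     .groups = "drop")
  total_expr <- sum(tab$n_expressing)
  flagged <- total_expr == 0
  tab <- tab |>
    dplyr::mutate(
      pct_within_group = round_half_up(100 * .data$n_expressing / .data$n_cells, 1),
      pct_of_expressing = if (flagged) NA_real_
                          else round_half_up(100 * .data$n_expressing / total_expr, 1)
    )
  attr(tab, "flagged") <- flagged
  tab
}

#' Integrated expression profiles across the four dataset classes
#'
#' Joins the per-tissue calls of the four datasets into one row per symbol
#' with tissue-call counts and the derived selectivity flags.
#'
#' @param symbols Character vector of catalog symbols.
#' @param tcga,hpa,gtex,tabula Call tibbles (`symbol`, `tissue`, `call`) from
#'   [bulk_tissue_calls()], [hpa_tissue_calls()], [sc_tissue_calls()].
#' @param majority_frac Passed to [low_in_majority()].
#' @return Tibble with per-dataset High counts and tissue totals, the four
#'   selectivity flags and `tumor_selective`.
#' @export
expression_profiles <- function(symbols, tcga, hpa, gtex, tabula,
                                majority_frac = 0.70) {
  count_calls <- function(df, prefix) {
    df |>
      dplyr::group_by(.data$symbol) |>
      dplyr::summarise(n_high = sum(.data$call == "High"),
                       n_tissues = dplyr::n(), .groups = "drop") |>
      stats::setNames(c("symbol", paste0("n_", prefix, "_high"),
                        paste0("n_", prefix, "_tissues")))
  }
  out <- tibble::tibble(symbol = symbols) |>
    dplyr::left_join(count_calls(tcga, "tcga"), by = "symbol") |>
    dplyr::left_join(count_calls(hpa, "hpa"), by = "symbol") |>
    dplyr::left_join(count_calls(gtex, "gtex"), by = "symbol") |>
    dplyr::left_join(count_calls(tabula, "tabula"), by = "symbol")
  out |>
    dplyr::mutate(
      dplyr::across(dplyr::starts_with("n_"), ~ dplyr::coalesce(.x, 0L)),
      tumor_high_any_tcga = .data$n_tcga_high >= 1,
      tumor_high_any_hpa = .data$n_hpa_high >= 1,
      normal_low_majority_gtex = .data$n_gtex_tissues > 0 &
        (.data$n_gtex_tissues - .data$n_gtex_high) / pmax(.data$n_gtex_tissues, 1) >= majority_frac,
      normal_low_majority_tabula = .data$n_tabula_tissues > 0 &
        (.data$n_tabula_tissues - .data$n_tabula_high) / pmax(.data$n_tabula_tissues, 1) >= majority_frac,
      tumor_selective = .data$tumor_high_any_tcga & .data$tumor_high_any_hpa &
        .data$normal_low_majority_gtex & .data$normal_low_majority_tabula
    )
}
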