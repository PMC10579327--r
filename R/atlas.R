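#' Build the integrated E3-ligase atlas from a bundle directory
#'
#' Reads every input table of a data bundle (real-data exports or a
#' synthetic bundle from [generate_bundle()]), runs all characterization
#' stages, and returns an `e3_atlas` object holding the component tables and
#' a one-row-per-ligase summary used by the search engine.
#'
#' Expected files (headered TSVs unless noted): `ge.tsv`, `ubihub.tsv`,
#' `ubibrowser.tsv`, `alias.tsv`, `co_opted.yaml`, `chembl.tsv`, `drugs.tsv`,
#' `covalent.tsv`, `tcga_expr.tsv` + `tcga_samples.tsv`, `gtex_expr.tsv` +
#' `gtex_samples.tsv`, `hpa.tsv`, `tabula_counts.mtx` + `tabula_genes.tsv` +
#' `tabula_cells.tsv`, optional `tumor_sc_counts.mtx` + `tumor_sc_genes.tsv`
#' + `tumor_sc_cells.tsv`, `ppi_<source>.tsv` for the six PPI dialects,
#' `protactable.tsv`, `mapd.tsv`, `essentiality_crispr.tsv`,
#' `essentiality_rnai.tsv`, `cell_lines.tsv`, `locations.tsv`,
#' `pdb_index.tsv`, `afdb.tsv`, `interfaces.tsv`. Missing optional files are
#' skipped with empty defaults.
#'
#' @param bundle_dir Directory containing the bundle.
#' @param sc_thresholds Single-cell High thresholds
#'   (default [derive_sc_thresholds()], i.e. 12.75\% / 2.325).
#' @param majority_frac Low-majority fraction (default 0.70).
#' @param hpa_strict Use the strictly-greater-than 20\% staining rule.
#' @return An `e3_atlas` object (list with `catalog`, `ligandability`,
#'   `calls`, `expression`, `edges`, `degree`, `tractability`,
#'   `essentiality`, `locations`, `structures`, `interfaces`, `summary`).
#' @export
build_atlas <- function(bundle_dir,
                        sc_thresholds = derive_sc_thresholds(),
                        majority_frac = 0.70,
                        hpa_strict = FALSE) {
  p <- function(f) file.path(bundle_dir, f)
  need <- function(f) {
    if (!file.exists(p(f))) stop("bundle is missing ", f, call. = FALSE)
    p(f)
  }

  alias_map <- if (file.exists(p("alias.tsv"))) {
    am <- read_tsv_quiet(p("alias.tsv"))
    stats::setNames(am$symbol, am$alias)
  } else {
    character()
  }
  co_opted <- if (file.exists(p("co_opted.yaml"))) {
    read_co_opted_config(p("co_opted.yaml"))
  } else {
    co_opted_config()
  }

  src <- read_catalog_sources(need("ge.tsv"), need("ubihub.tsv"),
                              need("ubibrowser.tsv"))
  catalog <- assemble_catalog(src$ge, src$ubihub, src$ubibrowser,
                              co_opted = co_opted, alias_map = alias_map)

  read_opt <- function(f, cols) {
    if (file.exists(p(f))) read_tsv_quiet(p(f))
    else stats::setNames(tibble::tibble(!!!rep(list(character()), length(cols))), cols)
  }
  ligandability <- summarize_ligandability(
    catalog,
    chembl = read_opt("chembl.tsv",
                      c("ligand_id", "chembl_id", "smiles", "target_symbol", "pchembl")),
    drugs = read_opt("drugs.tsv", c("drug_id", "target_symbol", "source")),
    covalent = read_opt("covalent.tsv", c("symbol", "cell_line", "cysteine_site"))
  )

  read_matrix <- function(f) {
    df <- read_tsv_quiet(need(f))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  tcga_calls <- bulk_tissue_calls(read_matrix("tcga_expr.tsv"),
                                  read_tsv_quiet(need("tcga_samples.tsv")))
  gtex_calls <- bulk_tissue_calls(read_matrix("gtex_expr.tsv"),
                                  read_tsv_quiet(need("gtex_samples.tsv")))
  hpa_calls <- hpa_tissue_calls(read_tsv_quiet(need("hpa.tsv")),
                                strict = hpa_strict)

  tab <- read_sc_dataset(p("tabula_counts.mtx"), p("tabula_genes.tsv"),
                         p("tabula_cells.tsv"))
  tabula_calls <- sc_tissue_calls(tab$counts, tab$cell_meta, sc_thresholds)

  tumor_sc <- if (file.exists(p("tumor_sc_counts.mtx"))) {
    read_sc_dataset(p("tumor_sc_counts.mtx"), p("tumor_sc_genes.tsv"),
                    p("tumor_sc_cells.tsv"))
  } else {
    NULL
  }

  expression <- expression_profiles(catalog$symbol, tcga_calls, hpa_calls,
                                    gtex_calls, tabula_calls, majority_frac)

  ppi_files <- c(UBIBROWSER = "ppi_ubibrowser.tsv", BIOGRID = "ppi_biogrid.tsv",
                 INTACT = "ppi_intact.tsv", REACTOME = "ppi_reactome.tsv",
                 STRING = "ppi_string.tsv", HURI = "ppi_huri.tsv")
  raw <- dplyr::bind_rows(lapply(names(ppi_files), function(tag) {
    f <- p(ppi_files[[tag]])
    if (!file.exists(f)) return(NULL)
    load_source_edges(read_tsv_quiet(f), tag, alias_map = alias_map)
  }))
  edges <- merge_edges(raw)
  degree <- ppi_degree(edges, catalog$symbol)

  tract <- tractability_sets(
    if (file.exists(p("protactable.tsv"))) read_tsv_quiet(p("protactable.tsv"))$symbol else character(),
    if (file.exists(p("mapd.tsv"))) read_tsv_quiet(p("mapd.tsv"))$symbol else character()
  )

  lineage_of <- if (file.exists(p("cell_lines.tsv"))) {
    cl <- read_tsv_quiet(p("cell_lines.tsv"))
    stats::setNames(cl$lineage, cl$line)
  } else {
    NULL
  }
  ess <- list(
    crispr = if (file.exists(p("essentiality_crispr.tsv"))) {
      essentiality_table(read_matrix("essentiality_crispr.tsv"), lineage_of)
    } else NULL,
    rnai = if (file.exists(p("essentiality_rnai.tsv"))) {
      essentiality_table(read_matrix("essentiality_rnai.tsv"), lineage_of)
    } else NULL
  )

  loc_tbl <- if (file.exists(p("locations.tsv"))) {
    location_table(read_tsv_quiet(p("locations.tsv")), catalog$symbol)
  } else {
    location_table(tibble::tibble(symbol = character(), source = character(),
                                  term = character(), score = numeric()),
                   catalog$symbol)
  }

  struct_tbl <- structure_table(
    catalog$symbol,
    if (file.exists(p("pdb_index.tsv"))) read_tsv_quiet(p("pdb_index.tsv"))
    else tibble::tibble(symbol = character(), structure_id = character()),
    if (file.exists(p("afdb.tsv"))) read_tsv_quiet(p("afdb.tsv"))$symbol
    else character()
  )

  iface_records <- if (file.exists(p("interfaces.tsv"))) {
    read_tsv_quiet(p("interfaces.tsv"))
  } else {
    tibble::tibble(symbol = character(), partner = character(),
                   source = character(), residues = character())
  }
  iface_tbl <- interface_table(iface_records, catalog$symbol)

  pick_ess <- function(which) {
    if (is.null(ess[[which]])) {
      return(tibble::tibble(symbol = catalog$symbol, essential = FALSE) |>
               stats::setNames(c("symbol", paste0("essential_", which))))
    }
    ess[[which]][, c("symbol", "essential")] |>
      stats::setNames(c("symbol", paste0("essential_", which)))
  }

  summary <- catalog |>
    dplyr::left_join(ligandability, by = "symbol") |>
    dplyr::left_join(expression, by = "symbol") |>
    dplyr::left_join(degree, by = "symbol") |>
    dplyr::left_join(pick_ess("crispr"), by = "symbol") |>
    dplyr::left_join(pick_ess("rnai"), by = "symbol") |>
    dplyr::left_join(loc_tbl, by = "symbol") |>
    dplyr::left_join(struct_tbl, by = "symbol") |>
    dplyr::left_join(iface_tbl, by = "symbol") |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("essential_"),
                                ~ dplyr::coalesce(.x, FALSE)))

  structure(
    list(catalog = catalog, ligandability = ligandability,
         calls = list(tcga = tcga_calls, hpa = hpa_calls,
                      gtex = gtex_calls, tabula = tabula_calls),
         tumor_sc = tumor_sc,
         expression = expression, edges = edges, degree = degree,
         tractability = tract, essentiality = ess, locations = loc_tbl,
         structures = struct_tbl, interfaces = iface_records,
         summary = summary, sc_thresholds = sc_thresholds,
         majority_frac = majority_frac),
    class = "e3_atlas"
  )
}

#' Read a single-cell dataset from MTX + side tables
#'
#' @param mtx_path MatrixMarket file, genes x cells.
#' @param genes_path One-column headered TSV of gene symbols (row order).
#' @param cells_path Cell-metadata TSV with `cell_id`, `tissue` and
#'   optionally `cell_type`, `malignant` (column order of the matrix).
#' @return List `counts` (dgCMatrix with dimnames), `cell_meta`.
#' @export
read_sc_dataset <- function(mtx_path, genes_path, cells_path) {
  counts <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  genes <- read_tsv_quiet(genes_path)
  cells <- read_tsv_quiet(cells_path)
  assert_cols(cells, c("cell_id", "tissue"), "cell metadata")
  if ("cell_type" %in% names(cells) && anyNA(cells$cell_type)) {
    stop("cells with missing cell_type are rejected at load", call. = FALSE)
  }
  stopifnot(nrow(counts) == nrow(genes), ncol(counts) == nrow(cells))
  dimnames(counts) <- list(genes[[1]], cells$cell_id)
  list(counts = counts, cell_meta = cells)
}

#' @export
print.e3_atlas <- function(x, ...) {
  cat("<e3_atlas>\n")
  cat("  ligases:      ", nrow(x$catalog), "\n")
  cat("  merged edges: ", nrow(x$edges), "\n")
  cat("  tumor types:  ", length(unique(x$calls$tcga$tissue)), "(bulk tumor)\n")
  cat("  normal tissues:", length(unique(x$calls$gtex$tissue)), "(bulk normal)\n")
  cat("  tumor-selective ligases:", sum(x$summary$tumor_selective), "\n")
  invisible(x)
}

#' Write the atlas's derived tables to TSV
#'
#' Emits `catalog.tsv`, `ligandability.tsv`, `summary.tsv`, `edges.tsv` and
#' the four per-tissue call tables.
#'
#' @param atlas An `e3_atlas`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_atlas_tables <- function(atlas, dir) {
  stopifnot(inherits(atlas, "e3_atlas"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_file(atlas$catalog, file.path(dir, "catalog.tsv"))
  write_tsv_file(atlas$ligandability, file.path(dir, "ligandability.tsv"))
  write_tsv_file(atlas$summary, file.path(dir, "summary.tsv"))
  write_tsv_file(atlas$edges, file.path(dir, "edges.tsv"))
  for (nm in names(atlas$calls)) {
    write_tsv_file(atlas$calls[[nm]], file.path(dir, paste0("calls_", nm, ".tsv")))
  }
  invisible(dir)
}
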