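#' Read a per-cell spatial/QC table
#'
#' Reads a comma-delimited cell table with one row per segmented cell. The
#' required columns are `cell_id`, `section_id`, `x`, `y`, `volume` and
#' `n_zplanes`; optional columns (`region`, `subclass`, `cluster`,
#' `subclass_confidence`, `cluster_confidence`, `doublet_score`,
#' `z_section_order`, `ccfx`, `ccfy`, `ccfz`) are added as missing when
#' absent. Coordinates are micrometres in each section's own imaging plane;
#' volumes are cubic micrometres.
#'
#' @param path Path to a CSV file with a header row.
#' @return A tibble with one row per cell.
#' @export
read_cell_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(df, c("cell_id", "section_id", "x", "y", "volume", "n_zplanes"),
                 "cell table")
  df$cell_id <- as.character(df$cell_id)
  dup <- unique(df$cell_id[duplicated(df$cell_id)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate cell_id value(s): %s",
                  paste(head(dup, 5), collapse = ", ")))
  }
  for (col in c("x", "y", "volume")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      abort(sprintf("non-numeric value in column '%s' at data row %s", col,
                    paste(head(bad, 5), collapse = ", ")))
    }
  }
  validate_cell_table(df)
}

# Fill optional columns and check invariants shared by readers and simulators.
validate_cell_table <- function(df) {
  opt_chr <- c("region", "subclass", "cluster")
  opt_num <- c("subclass_confidence", "cluster_confidence", "doublet_score",
               "ccfx", "ccfy", "ccfz")
  for (col in opt_chr) if (!col %in% names(df)) df[[col]] <- NA_character_
  for (col in opt_num) if (!col %in% names(df)) df[[col]] <- NA_real_
  if (!"z_section_order" %in% names(df)) {
    df$z_section_order <- match(df$section_id, sort(unique(df$section_id)))
  }
  if (any(df$volume <= 0, na.rm = TRUE)) abort("cell volumes must be positive")
  for (col in c("subclass_confidence", "cluster_confidence", "doublet_score")) {
    v <- df[[col]]
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      abort(sprintf("column '%s' must lie in [0, 1]", col))
    }
  }
  cl <- df$cluster[!is.na(df$cluster) & !is.na(df$subclass)]
  sc <- df$subclass[!is.na(df$cluster) & !is.na(df$subclass)]
  if (length(cl) > 0) {
    nmap <- tapply(sc, cl, function(s) length(unique(s)))
    if (any(nmap > 1)) {
      abort(sprintf("cluster label(s) map to more than one subclass: %s",
                    paste(head(names(nmap)[nmap > 1], 5), collapse = ", ")))
    }
  }
  as_tibble(df)
}

#' Write a cell table to CSV
#'
#' Missing values are written as empty fields so the file round-trips through
#' [read_cell_table()] without loss.
#'
#' @param cells A cell table tibble.
#' @param path Output file path.
#' @export
write_cell_table <- function(cells, path) {
  readr::write_csv(cells, path, na = "")
  invisible(path)
}

#' Read a cell-by-gene expression matrix
#'
#' Supports MatrixMarket triplet format (with `genes.txt` / `cells.txt`
#' sidecar files holding one identifier per line, in matrix order) and dense
#' delimited text (cells in rows, genes in columns, first column = cell id).
#'
#' @param path Path to the matrix file (`.mtx` or delimited text).
#' @param format One of `"mtx-triplet"` or `"dense-delimited"`. Guessed from
#'   the file extension when omitted. HDF5 single-cell containers are not
#'   supported by this build and raise an informative error.
#' @param genes_path,cells_path Sidecar paths for the triplet format; default
#'   to `genes.txt` and `cells.txt` next to `path`.
#' @return An [expr_set()] with the `"raw"` layer populated. Cells are rows.
#' @export
read_expression <- function(path, format = NULL,
                            genes_path = file.path(dirname(path), "genes.txt"),
                            cells_path = file.path(dirname(path), "cells.txt")) {
  ext <- tolower(tools::file_ext(path))
  format <- format %||% switch(ext,
    mtx = "mtx-triplet",
    h5 = "hdf5-container", h5ad = "hdf5-container",
    "dense-delimited")
  if (format == "hdf5-container") {
    abort("HDF5 single-cell containers are not supported; export the matrix as MatrixMarket triplet (.mtx + genes.txt/cells.txt) or dense CSV")
  }
  if (format == "mtx-triplet") {
    m <- Matrix::readMM(path)
    genes <- readLines(genes_path)
    cells <- readLines(cells_path)
    if (nrow(m) != length(cells) || ncol(m) != length(genes)) {
      abort(sprintf(
        "dimension mismatch: matrix is %d x %d but sidecars list %d cells and %d genes",
        nrow(m), ncol(m), length(cells), length(genes)))
    }
    expr_set(m, cells = cells, genes = genes)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    cells <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    expr_set(m, cells = cells, genes = colnames(m))
  }
}

#' Write an expression layer as MatrixMarket triplet plus sidecars
#'
#' @param x An [expr_set()].
#' @param dir Output directory (created if needed). Writes `matrix.mtx`,
#'   `genes.txt` and `cells.txt`.
#' @param layer Layer to write (default `"raw"`).
#' @export
write_expression <- function(x, dir, layer = "raw") {
  stopifnot(inherits(x, "expr_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- x$layers[[layer]]
  if (!inherits(m, "Matrix")) m <- Matrix::Matrix(m, sparse = TRUE)
  Matrix::writeMM(as(m, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(x$genes, file.path(dir, "genes.txt"))
  writeLines(x$cells, file.path(dir, "cells.txt"))
  invisible(dir)
}

#' Read a ligand-receptor interaction database
#'
#' Expects the CellChat-style column layout: `pair_name`, `ligand`,
#' `receptor`, `pathway` and optionally `category`. Multi-component ligands
#' or receptor complexes are encoded with gene names joined by underscores
#' (e.g. `Fzd1_Lrp5`) and are split into component lists.
#'
#' @param path Path to a delimited text file.
#' @return A tibble with list-columns `ligand_components` and
#'   `receptor_components`.
#' @export
read_lr_database <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(df, c("pair_name", "ligand", "receptor"), "LR database")
  lr_database(df$pair_name, df$ligand, df$receptor,
              pathway = if ("pathway" %in% names(df)) df$pathway else NA_character_,
              category = if ("category" %in% names(df)) df$category else NA_character_)
}

#' @rdname read_lr_database
#' @param pair_name,ligand,receptor,pathway,category Vectors defining the
#'   entries; `ligand` / `receptor` use underscore-joined component genes.
#' @export
lr_database <- function(pair_name, ligand, receptor,
                        pathway = NA_character_, category = NA_character_) {
  dup <- unique(pair_name[duplicated(pair_name)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate pair_name value(s): %s",
                  paste(head(dup, 5), collapse = ", ")))
  }
  empty <- pair_name[!nzchar(trimws(ifelse(is.na(ligand), "", ligand))) |
                     !nzchar(trimws(ifelse(is.na(receptor), "", receptor)))]
  if (length(empty) > 0) {
    abort(sprintf("empty ligand or receptor field for pair(s): %s",
                  paste(head(empty, 5), collapse = ", ")))
  }
  tibble(
    pair_name = as.character(pair_name),
    ligand_components = strsplit(as.character(ligand), "_", fixed = TRUE),
    receptor_components = strsplit(as.character(receptor), "_", fixed = TRUE),
    pathway = rep_len(as.character(pathway), length(pair_name)),
    category = rep_len(as.character(category), length(pair_name))
  )
}

#' Write result tables to a directory
#'
#' One CSV per named table, with a stable column order and empty-field
#' missing values so that [read_results()] round-trips values exactly.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(as_tibble(tables[[nm]]), p, na = "")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_results
#' @export
read_results <- function(out_dir) {
  files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  out <- lapply(files, readr::read_csv, show_col_types = FALSE, progress = FALSE)
  names(out) <- sub("\\.csv$", "", basename(files))
  out
}

#' Analysis configuration
#'
#' Collects every tunable of the pipeline with its standard default, and
#' serialises losslessly to a flat YAML file.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    # preprocessing
    volume_bounds_3z = c(50, 1500), volume_bounds_5z = c(80, 2500),
    volume_bounds_6z = c(100, 3000),
    mean_total_target = 250, total_quantile = 0.01, doublet_threshold = 0.25,
    # integration
    norm_total = 1000, n_partitions = 50, n_dims = 100, knn_graph = 15,
    k_anchor_mnn = 5, k_anchor_transfer = 100, k_impute = 30,
    max_fit_cells = 100000,
    subclass_conf_threshold = 0.8, cluster_conf_threshold = 0.5,
    # annotation
    nt_count_threshold = 2, complexity_k = 50,
    # spatial modules
    composition_k = 50, bandwidth_nn = 5,
    bandwidth_multiplier_l1 = 2, bandwidth_multiplier_l2 = 1,
    leiden_resolution_l1 = 1, leiden_resolution_l2 = 2,
    # gradients
    purity_k = 50, purity_n_pcs = 50,
    # interactions
    r_proximal_strict = 15, r_proximal_relaxed = 30, r_randomization = 100,
    n_rounds = 1000, alpha = 0.05, min_observed_pairs = 50,
    enrichment_threshold_default = 2, enrichment_threshold_complex = 6,
    enrichment_threshold_astrocyte = 1, nonneuronal_min_cells = 50,
    # signaling
    lr_fold_threshold = 2, lr_padj_threshold = 0.01, lr_exp_fraction = 0.4,
    gene_fold_threshold = 2, gene_padj_threshold = 0.01,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  radii <- c(cfg$r_proximal_strict, cfg$r_proximal_relaxed, cfg$r_randomization,
             cfg$mean_total_target, cfg$norm_total)
  if (any(radii <= 0)) abort("radii and normalisation targets must be positive")
  structure(cfg, class = "analysis_config")
}

#' @rdname analysis_config
#' @param config An `analysis_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname analysis_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(analysis_config, vals)
}
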