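#' Canonical neurotransmitter marker genes
#'
#' Transporter (and for histamine, synthesis) genes used to call
#' neurotransmitter identity from raw counts.
#' @export
nt_markers <- list(
  glut = c("Slc17a7", "Slc17a6", "Slc17a8"),
  gaba = "Slc32a1",
  sero = "Slc6a4",
  dopa = "Slc6a3",
  choli = "Slc18a3",
  glycine = "Slc6a5",
  nora = "Slc6a2",
  hist = "Hdc"
)

#' Assign neurotransmitter identities from marker counts
#'
#' A neuron is called glutamatergic when any of *Slc17a7*, *Slc17a6* or
#' *Slc17a8* has raw count at or above the threshold; each other identity
#' uses its single marker. Identities are independent flags, so dual
#' (e.g. glutamatergic and GABAergic) cells are permitted. The default
#' threshold of 2 counts per cell reflects typical MERFISH sensitivity.
#'
#' @param expr An [expr_set()] with raw counts containing all marker genes.
#' @param threshold Minimum raw count (default 2; inclusive).
#' @param markers Named list of marker genes per identity (default
#'   [nt_markers]).
#' @return Tibble with `cell_id`, one logical column per identity, and the
#'   per-identity maximum marker count used.
#' @export
assign_neurotransmitters <- function(expr, threshold = 2,
                                     markers = nt_markers) {
  need <- unique(unlist(markers))
  missing <- setdiff(need, expr$genes)
  if (length(missing) > 0) {
    abort(sprintf("marker gene(s) missing from the panel: %s",
                  paste(missing, collapse = ", ")))
  }
  m <- expr_layer(expr, "raw")
  out <- tibble(cell_id = expr$cells)
  for (nt in names(markers)) {
    cnt <- m[, markers[[nt]], drop = FALSE]
    maxc <- apply(cnt, 1, max)
    out[[nt]] <- maxc >= threshold
    out[[paste0(nt, "_count")]] <- maxc
  }
  out
}

#' Regional enrichment scores of subclasses
#'
#' The enrichment score of subclass `s` in region `r` is the fold change of
#' its average cell density in `r` over its whole-brain average density:
#' `score(s, r) = (n(s, r) / N(r)) / (n(s) / N)` with `n` subclass counts
#' and `N` total counts. Cell counts proxy the region volume; a per-region
#' size table can override the denominator when true region volumes are
#' known. By construction the density-weighted mean score over regions is 1.
#'
#' @param cells Cell table with non-missing `region` and `subclass`.
#' @param region_sizes Optional named numeric vector of region sizes
#'   replacing the total-cell-count denominator `N(r)` (same units across
#'   regions).
#' @return Tibble with `subclass`, `region`, `enrichment`.
#' @export
enrichment_score <- function(cells, region_sizes = NULL) {
  assert_columns(cells, c("region", "subclass"), "cell table")
  cells <- cells[!is.na(cells$region) & !is.na(cells$subclass) &
                   cells$region != "", , drop = FALSE]
  if (nrow(cells) == 0) abort("no cells with region and subclass labels")
  regions <- sort(unique(cells$region))
  n_r <- table(factor(cells$region, levels = regions))
  if (any(n_r == 0)) abort("empty region")
  size_r <- if (is.null(region_sizes)) as.numeric(n_r) else {
    miss <- setdiff(regions, names(region_sizes))
    if (length(miss)) abort(sprintf("region_sizes missing: %s",
                                    paste(miss, collapse = ", ")))
    as.numeric(region_sizes[regions])
  }
  total_size <- sum(size_r)
  counts <- table(factor(cells$subclass), factor(cells$region, levels = regions))
  n_s <- rowSums(counts)
  dens_in <- sweep(counts, 2, size_r, "/")
  dens_all <- n_s / total_size
  score <- sweep(dens_in, 1, dens_all, "/")
  out <- as_tibble(as.data.frame(as.table(score), stringsAsFactors = FALSE))
  names(out) <- c("subclass", "region", "enrichment")
  out
}

#' Local cell-type complexity
#'
#' For each cell, the number of distinct subclass labels among its `k`
#' nearest spatial neighbours within the same section (2D). Applied to
#' neurons with `k = 50`, this quantifies how locally diverse the neuronal
#' neighbourhood is.
#'
#' @param cells Cell table with `x`, `y`, `section_id` and a label column.
#' @param k Number of spatial neighbours (default 50). Sections with fewer
#'   than `k + 1` cells are computed over the available neighbours with a
#'   warning.
#' @param label_col Column holding the type labels (default `"subclass"`).
#' @return Tibble with `cell_id` and integer `complexity`.
#' @export
local_complexity <- function(cells, k = 50, label_col = "subclass") {
  assert_columns(cells, c("cell_id", "x", "y", "section_id", label_col),
                 "cell table")
  out <- integer(nrow(cells))
  for (sec in unique(cells$section_id)) {
    idx <- which(cells$section_id == sec)
    n <- length(idx)
    k_eff <- min(k, n - 1L)
    if (k_eff < k) {
      warn(sprintf("section '%s' has only %d cells; complexity uses %d neighbours",
                   sec, n, k_eff))
    }
    if (k_eff < 1) { out[idx] <- 0L; next }
    nn <- knn_within(cbind(cells$x[idx], cells$y[idx]), k_eff)$index
    labs <- cells[[label_col]][idx]
    out[idx] <- vapply(seq_len(n), function(i)
      length(unique(labs[nn[i, ]])), integer(1))
  }
  tibble(cell_id = cells$cell_id, complexity = out)
}

#' Heatmap of regional enrichment scores
#'
#' @param scores Tibble from [enrichment_score()].
#' @param cap Upper display cap on the colour scale (default 10).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(scores, cap = 10) {
  scores$enrichment_capped <- pmin(scores$enrichment, cap)
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$region, y = .data$subclass,
                                       fill = .data$enrichment_capped)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "enrichment") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
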