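#' Volume-based cell filtering
#'
#' Removes putative segmentation artefacts by imaged volume, with bounds
#' depending on the number of imaged z-planes: cells are kept when their
#' volume lies in \[50, 1500\] um^3 (3 z-planes), \[80, 2500\] (5 z-planes)
#' or \[100, 3000\] (6 z-planes). Boundary values are retained ("less than"
#' / "more than" are strict).
#'
#' @param cells Cell table with `volume` and `n_zplanes`.
#' @param bounds Named list of `c(lo, hi)` per z-plane count; defaults to the
#'   bounds above.
#' @return List with `cells` (filtered) and `qc` (per-step accounting tibble).
#' @export
volume_filter <- function(cells,
                          bounds = list(`3` = c(50, 1500), `5` = c(80, 2500),
                                        `6` = c(100, 3000))) {
  assert_columns(cells, c("volume", "n_zplanes"), "cell table")
  bad_z <- setdiff(unique(cells$n_zplanes), as.numeric(names(bounds)))
  if (length(bad_z) > 0) {
    abort(sprintf("unsupported n_zplanes value(s): %s",
                  paste(bad_z, collapse = ", ")))
  }
  lo <- vapply(as.character(cells$n_zplanes), function(z) bounds[[z]][1], 0)
  hi <- vapply(as.character(cells$n_zplanes), function(z) bounds[[z]][2], 0)
  keep <- cells$volume >= lo & cells$volume <= hi
  list(cells = cells[keep, , drop = FALSE],
       qc = qc_row("volume_filter", nrow(cells), sum(!keep)))
}

qc_row <- function(step, n_in, n_removed) {
  tibble(step = step, n_in = n_in, n_removed = n_removed,
         n_out = n_in - n_removed, fraction_removed = n_removed / n_in)
}

#' Normalise counts by imaged cell volume
#'
#' Adds a `"volnorm"` layer with `raw / volume` per cell, removing count
#' differences due to the soma volume captured in the image.
#'
#' @param expr An [expr_set()] whose cells match `cells$cell_id`.
#' @param cells Cell table providing `volume` (um^3, positive).
#' @return The [expr_set()] with a `"volnorm"` layer added.
#' @export
volume_normalize <- function(expr, cells) {
  vol <- setNames(cells$volume, cells$cell_id)[expr$cells]
  if (anyNA(vol)) abort("cells missing from the cell table")
  if (any(vol <= 0)) abort("zero or negative cell volume")
  set_expr_layer(expr, "volnorm", expr_layer(expr, "raw") / vol)
}

#' Rescale each group to a common mean total signal
#'
#' Within each group (typically one experiment or section), all values are
#' multiplied by `target / mean(per-cell totals)` so the group's mean total
#' equals `target` exactly. Idempotent.
#'
#' @param expr An [expr_set()].
#' @param group Per-cell group labels (length = number of cells); a single
#'   value treats all cells as one experiment.
#' @param target Target mean total per cell (default 250).
#' @param layer Layer to rescale in place (default `"volnorm"` when present,
#'   else `"raw"`).
#' @return The [expr_set()] with the layer rescaled, plus an attribute
#'   `scaling_factors` on the returned object's layer list is not kept;
#'   factors are returned via `attr(, "scaling_factors")`.
#' @export
rescale_mean_total <- function(expr, group = "all", target = 250,
                               layer = if (has_expr_layer(expr, "volnorm"))
                                 "volnorm" else "raw") {
  m <- expr_layer(expr, layer)
  group <- rep_len(as.character(group), nrow(m))
  totals <- rowSums(m)
  factors <- numeric(0)
  for (g in unique(group)) {
    sel <- group == g
    mu <- mean(totals[sel])
    if (mu == 0) abort(sprintf("group '%s' has all-zero totals", g))
    f <- target / mu
    m[sel, ] <- m[sel, ] * f
    factors[g] <- f
  }
  out <- set_expr_layer(expr, layer, m)
  attr(out, "scaling_factors") <- factors
  out
}

#' Filter cells by extreme total signal
#'
#' Removes cells whose total signal falls strictly below the `q` quantile or
#' strictly above the `1 - q` quantile of their group (linear-interpolation
#' quantiles, R type 7). `q = 0` is the identity.
#'
#' @param expr An [expr_set()].
#' @param cells Cell table aligned with `expr`.
#' @param q Tail fraction (default 0.01); must be < 0.5.
#' @param group Per-cell group labels (default: one group).
#' @param layer Layer whose totals are used.
#' @return List with `expr`, `cells` (both filtered) and `qc`.
#' @export
total_count_quantile_filter <- function(expr, cells, q = 0.01, group = "all",
                                        layer = if (has_expr_layer(expr, "volnorm"))
                                          "volnorm" else "raw") {
  if (q >= 0.5) abort("q must be below 0.5")
  if (length(expr$cells) < 3) abort("need at least 3 cells")
  totals <- rowSums(expr_layer(expr, layer))
  group <- rep_len(as.character(group), length(totals))
  keep <- rep(TRUE, length(totals))
  if (q > 0) {
    for (g in unique(group)) {
      sel <- group == g
      lo <- quantile(totals[sel], q, type = 7, names = FALSE)
      hi <- quantile(totals[sel], 1 - q, type = 7, names = FALSE)
      keep[sel] <- totals[sel] >= lo & totals[sel] <= hi
    }
  }
  ids <- expr$cells[keep]
  list(expr = expr[keep, ],
       cells = cells[cells$cell_id %in% ids, , drop = FALSE],
       qc = qc_row("total_count_quantile_filter", length(totals), sum(!keep)))
}

#' Remove doublets by score threshold
#'
#' Cells with `doublet_score` strictly greater than `threshold` are removed;
#' equality is retained. Scores come from an external doublet caller; when
#' absent the table passes through with a warning.
#'
#' @param cells Cell table.
#' @param threshold Removal threshold (default 0.25).
#' @return List with `cells` and `qc`.
#' @export
doublet_filter <- function(cells, threshold = 0.25) {
  if (!"doublet_score" %in% names(cells) || all(is.na(cells$doublet_score))) {
    warn("no doublet scores present; doublet filter is a pass-through")
    return(list(cells = cells, qc = qc_row("doublet_filter", nrow(cells), 0)))
  }
  keep <- is.na(cells$doublet_score) | cells$doublet_score <= threshold
  list(cells = cells[keep, , drop = FALSE],
       qc = qc_row("doublet_filter", nrow(cells), sum(!keep)))
}

#' Five-step preprocessing pipeline
#'
#' Applies, in order: (1) volume-based cell filtering, (2) volume
#' normalisation, (3) per-group rescaling of mean totals to `target`,
#' (4) removal of cells in the extreme total-signal quantiles, and
#' (5) doublet removal.
#'
#' @param expr An [expr_set()] (`"raw"` layer).
#' @param cells Cell table aligned with `expr`.
#' @param group Per-cell experiment/section labels used by steps 3-4
#'   (default: the section id).
#' @param target Mean total target (default 250).
#' @param q Quantile tail fraction (default 0.01).
#' @param doublet_threshold Doublet score threshold (default 0.25).
#' @return List with `expr`, `cells` and the combined `qc` report.
#' @export
preprocess_merfish <- function(expr, cells, group = cells$section_id,
                               target = 250, q = 0.01,
                               doublet_threshold = 0.25) {
  stopifnot(all(expr$cells == cells$cell_id))
  group <- as.character(group)
  s1 <- volume_filter(cells)
  keep <- expr$cells %in% s1$cells$cell_id
  expr <- expr[keep, ]
  group <- group[keep]
  cells <- s1$cells
  expr <- volume_normalize(expr, cells)
  expr <- rescale_mean_total(expr, group = group, target = target)
  s4 <- total_count_quantile_filter(expr, cells, q = q, group = group)
  expr <- s4$expr
  cells <- s4$cells
  s5 <- doublet_filter(cells, threshold = doublet_threshold)
  cells <- s5$cells
  expr <- expr[expr$cells %in% cells$cell_id, ]
  list(expr = expr, cells = cells,
       qc = dplyr::bind_rows(s1$qc, s4$qc, s5$qc))
}
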