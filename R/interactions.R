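#' Split complex brain regions along the rostral-caudal axis
#'
#' The hypothalamus and midbrain are each divided into anterior and
#' posterior halves at the midpoint of their cells' `ccfx` range (the mean
#' of the minimum and maximum `ccfx`); cells at or below the midpoint are
#' anterior. The hindbrain is split into pons and medulla using a provided
#' sub-annotation column (anatomical annotations, not a midpoint rule).
#' Other regions are unchanged.
#'
#' @param cells Cell table with `region` and, for the affected regions,
#'   `ccfx`.
#' @param midpoint_regions Regions split by the midpoint rule (default
#'   hypothalamus and midbrain).
#' @param hindbrain_region Region name split via `hindbrain_col` (default
#'   `"hindbrain"`).
#' @param hindbrain_col Column with `"pons"` / `"medulla"` sub-annotations.
#' @return The cell table with `region` refined.
#' @export
split_regions <- function(cells,
                          midpoint_regions = c("hypothalamus", "midbrain"),
                          hindbrain_region = "hindbrain",
                          hindbrain_col = "hindbrain_division") {
  for (reg in midpoint_regions) {
    sel <- which(cells$region == reg)
    if (length(sel) == 0) next
    if (anyNA(cells$ccfx[sel])) {
      abort(sprintf("missing ccfx for cells in region '%s'", reg))
    }
    mid <- (min(cells$ccfx[sel]) + max(cells$ccfx[sel])) / 2
    cells$region[sel] <- ifelse(cells$ccfx[sel] <= mid,
                                paste("anterior", reg),
                                paste("posterior", reg))
  }
  sel <- which(cells$region == hindbrain_region)
  if (length(sel) > 0) {
    if (!hindbrain_col %in% names(cells) || anyNA(cells[[hindbrain_col]][sel])) {
      abort(sprintf("hindbrain split requires a complete '%s' column",
                    hindbrain_col))
    }
    cells$region[sel] <- cells[[hindbrain_col]][sel]
  }
  cells
}

#' Select the subclasses analysed per region
#'
#' Neuronal subclasses enter a region's interaction analysis when their
#' enrichment score passes the region's threshold — 6 for the six
#' high-complexity regions (anterior/posterior hypothalamus,
#' anterior/posterior midbrain, pons, medulla), 2 elsewhere. Astrocyte
#' subclasses use threshold 1 everywhere; remaining non-neuronal subclasses
#' enter when they have more than `min_cells` cells in the region. Cells
#' should already be filtered to subclass transfer confidence >= 0.8.
#'
#' @param cells Cell table with `region` and `subclass`.
#' @param enrichment Tibble from [enrichment_score()] computed on the same
#'   regions.
#' @param subclass_class Tibble with `subclass` and `class`
#'   (`"neuronal"`, `"astrocyte"` or `"other"`).
#' @param threshold_default,threshold_complex,threshold_astrocyte Enrichment
#'   thresholds (defaults 2, 6, 1).
#' @param complex_regions Regions using `threshold_complex`.
#' @param min_cells Cell-count threshold for other non-neuronal subclasses
#'   (default 50, strict).
#' @return Named list: per region, the character vector of subclasses to
#'   test.
#' @export
select_region_subclasses <- function(cells, enrichment, subclass_class,
                                     threshold_default = 2,
                                     threshold_complex = 6,
                                     threshold_astrocyte = 1,
                                     complex_regions = c(
                                       "anterior hypothalamus",
                                       "posterior hypothalamus",
                                       "anterior midbrain",
                                       "posterior midbrain",
                                       "pons", "medulla"),
                                     min_cells = 50) {
  regions <- sort(unique(cells$region[!is.na(cells$region)]))
  missing <- setdiff(regions, unique(enrichment$region))
  if (length(missing) > 0) {
    abort(sprintf("region(s) absent from enrichment table: %s",
                  paste(missing, collapse = ", ")))
  }
  cls <- setNames(subclass_class$class, subclass_class$subclass)
  counts <- dplyr::count(cells, .data$region, .data$subclass)
  out <- list()
  for (reg in regions) {
    thr <- if (reg %in% complex_regions) threshold_complex else threshold_default
    er <- enrichment[enrichment$region == reg, ]
    sc <- sort(unique(cells$subclass[cells$region == reg &
                                       !is.na(cells$subclass)]))
    keep <- vapply(sc, function(s) {
      e <- er$enrichment[er$subclass == s]
      e <- if (length(e)) e[1] else 0
      n <- counts$n[counts$region == reg & counts$subclass == s]
      n <- if (length(n)) n[1] else 0L
      switch(cls[[s]] %||% "other",
             neuronal = e >= thr,
             astrocyte = e >= threshold_astrocyte,
             other = n > min_cells)
    }, logical(1))
    out[[reg]] <- sc[keep]
  }
  out
}

#' Count proximal cross-type cell pairs
#'
#' Counts unordered pairs (one cell from each type; for equal types each
#' unordered pair once) whose within-section centroid distance is at most
#' `r_proximal` micrometres. Distances never span sections.
#'
#' @param cells Cell table with `x`, `y`, `section_id`, `subclass`.
#' @param type_a,type_b Subclass labels.
#' @param r_proximal Distance threshold in micrometres (inclusive).
#' @return Integer pair count.
#' @export
count_proximal_pairs <- function(cells, type_a, type_b, r_proximal) {
  sub <- cells[cells$subclass %in% c(type_a, type_b), , drop = FALSE]
  if (nrow(sub) == 0) return(0L)
  co <- section_offset_coords(sub)
  types <- sort(unique(c(type_a, type_b)))
  tcode <- match(sub$subclass, types) - 1L
  m <- cross_type_pair_counts(co$x, co$y, tcode, length(types), r_proximal)
  ia <- match(type_a, types); ib <- match(type_b, types)
  as.integer(m[min(ia, ib), max(ia, ib)])
}

# One local-randomization round: displace every cell independently and
# uniformly within a disk of radius r_rand, then recount all type pairs.
# Displacements are reflected at the section bounding box (lo/hi vectors per
# cell): without reflection, density leaks out of the tissue near its edges
# and the null undercounts pairs there; reflection keeps each move local and
# maps a homogeneous pattern onto a homogeneous pattern.
displaced_counts <- function(x, y, tcode, ntypes, r, r_rand,
                             xlo, xhi, ylo, yhi) {
  n <- length(x)
  rad <- r_rand * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  xs <- reflect_into(x + rad * cos(th), xlo, xhi)
  ys <- reflect_into(y + rad * sin(th), ylo, yhi)
  cross_type_pair_counts(xs, ys, tcode, ntypes, r)
}

reflect_into <- function(v, lo, hi) {
  v <- ifelse(v < lo, 2 * lo - v, v)
  v <- ifelse(v > hi, 2 * hi - v, v)
  pmin(pmax(v, lo), hi)  # guard for spans smaller than the displacement
}

#' Proximity-based cell-cell interaction test
#'
#' For every subclass pair (within every region, when `region_col` is set),
#' compares the observed count of proximal cell pairs (centroid distance
#' <= `r_proximal`) with a local-randomization null: in each round, every
#' cell is displaced independently and uniformly within a disk of radius
#' `r_randomization`, and pairs are recounted. The null counts are fitted
#' to a normal distribution; the one-sided upper-tail p-value, fold change
#' (observed over null mean) and z-score are reported. P-values are
#' Benjamini-Hochberg adjusted across all pairs of the run, and a pair is
#' called significant when the adjusted p-value is below `alpha` and at
#' least `min_observed` proximal pairs were observed. Because the null
#' preserves local density exactly, significance reflects pairing, not
#' abundance. Depletion (fold change < 1) is reported but never called
#' significant. In the relaxed regime (`r_proximal = 30`), calls
#' additionally require ligand-receptor support via [add_lr_support()].
#'
#' @param cells Cell table (already filtered to confident subclass labels).
#' @param r_proximal Proximity radius, micrometres (15 strict / 30 relaxed).
#' @param r_randomization Displacement radius of the null (default 100).
#' @param n_rounds Randomization rounds (default 1,000).
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @param min_observed Minimum observed proximal pairs (default 50).
#' @param region_col Optional region column; when `NULL` all cells form one
#'   stratum.
#' @param subclass_sets Optional named list (per region) of subclasses to
#'   test, e.g. from [select_region_subclasses()]; default: all present.
#' @param seed Integer seed making the null reproducible.
#' @return Object of class `interaction_test` whose `results` tibble has
#'   one row per (region, subclass1, subclass2).
#' @export
test_interactions <- function(cells, r_proximal = 15, r_randomization = 100,
                              n_rounds = 1000, alpha = 0.05,
                              min_observed = 50, region_col = NULL,
                              subclass_sets = NULL, seed = 1L) {
  if (r_proximal >= r_randomization) {
    abort("r_proximal must be smaller than r_randomization")
  }
  if (n_rounds < 2) abort("n_rounds must be at least 2")
  cells <- cells[!is.na(cells$subclass), , drop = FALSE]
  region <- if (is.null(region_col)) rep("all", nrow(cells)) else
    as.character(cells[[region_col]])
  check_seed(seed)
  rows <- list()
  for (reg in sort(unique(region))) {
    sub <- cells[region == reg, , drop = FALSE]
    types <- if (!is.null(subclass_sets)) subclass_sets[[reg]] else
      sort(unique(sub$subclass))
    types <- sort(types)
    sub <- sub[sub$subclass %in% types, , drop = FALSE]
    if (length(types) < 1 || nrow(sub) < 2) next
    co <- section_offset_coords(sub, gap = NULL)
    tcode <- match(sub$subclass, types) - 1L
    ntypes <- length(types)
    obs <- cross_type_pair_counts(co$x, co$y, tcode, ntypes, r_proximal)
    # per-section bounding boxes (on the offset coordinates)
    xlo <- stats::ave(co$x, sub$section_id, FUN = min)
    xhi <- stats::ave(co$x, sub$section_id, FUN = max)
    ylo <- stats::ave(co$y, sub$section_id, FUN = min)
    yhi <- stats::ave(co$y, sub$section_id, FUN = max)
    null_sum <- matrix(0, ntypes, ntypes)
    null_sq <- matrix(0, ntypes, ntypes)
    for (rd in seq_len(n_rounds)) {
      cnt <- displaced_counts(co$x, co$y, tcode, ntypes, r_proximal,
                              r_randomization, xlo, xhi, ylo, yhi)
      null_sum <- null_sum + cnt
      null_sq <- null_sq + cnt^2
    }
    mu <- null_sum / n_rounds
    sdv <- sqrt(pmax(null_sq / n_rounds - mu^2, 0) * n_rounds / (n_rounds - 1))
    ut <- which(upper.tri(mu, diag = TRUE), arr.ind = TRUE)
    rows[[reg]] <- tibble(
      region = reg,
      subclass1 = types[ut[, 1]], subclass2 = types[ut[, 2]],
      proximal_count = as.integer(obs[ut]),
      permutation_mean = mu[ut], permutation_std = sdv[ut]
    )
  }
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0) abort("no testable subclass pairs")
  res$z_score <- ifelse(res$permutation_std > 0,
                        (res$proximal_count - res$permutation_mean) /
                          res$permutation_std, NA_real_)
  res$fold_change <- ifelse(res$permutation_mean > 0,
                            res$proximal_count / res$permutation_mean,
                            NA_real_)
  res$pval <- ifelse(
    res$permutation_std > 0,
    pnorm(res$proximal_count, res$permutation_mean, res$permutation_std,
          lower.tail = FALSE),
    ifelse(res$proximal_count > res$permutation_mean, 1 / (n_rounds + 1), 1))
  res$pval_adjusted <- bh_adjust(res$pval)
  res$significant <- res$pval_adjusted < alpha &
    res$proximal_count >= min_observed
  structure(
    list(results = res,
         params = list(r_proximal = r_proximal,
                       r_randomization = r_randomization,
                       n_rounds = n_rounds, alpha = alpha,
                       min_observed = min_observed, seed = seed)),
    class = "interaction_test"
  )
}

#' Require ligand-receptor support for relaxed-radius interaction calls
#'
#' Adds a `supported_by_lr` flag — TRUE when at least one ligand-receptor
#' pair is significantly upregulated in the proximal cell pairs of the
#' subclass pair (either orientation, same region) — and a
#' `significant_relaxed` column combining it with the proximity call.
#'
#' @param x An `interaction_test`.
#' @param lr_results Tibble of LR screen results (rows of
#'   [test_lr_upregulation()] outputs, needing `region`, `subclass_ligand`,
#'   `subclass_receptor`, `significant`).
#' @return The updated `interaction_test`.
#' @export
add_lr_support <- function(x, lr_results) {
  stopifnot(inherits(x, "interaction_test"))
  sig <- lr_results[lr_results$significant, , drop = FALSE]
  key <- function(r, a, b) paste(r, pmin(a, b), pmax(a, b))
  supported <- key(sig$region, sig$subclass_ligand, sig$subclass_receptor)
  x$results$supported_by_lr <-
    key(x$results$region, x$results$subclass1, x$results$subclass2) %in%
    supported
  x$results$significant_relaxed <- x$results$significant &
    x$results$supported_by_lr
  x
}

#' @export
print.interaction_test <- function(x, ...) {
  cat(sprintf(
    "<interaction_test> %d subclass pairs (R_proximal = %g µm, %d rounds): %d significant\n",
    nrow(x$results), x$params$r_proximal, x$params$n_rounds,
    sum(x$results$significant)))
  invisible(x)
}

#' @method tidy interaction_test
#' @export
tidy.interaction_test <- function(x, ...) x$results

#' @method glance interaction_test
#' @export
glance.interaction_test <- function(x, ...) {
  tibble(n_pairs = nrow(x$results),
         n_significant = sum(x$results$significant),
         r_proximal = x$params$r_proximal,
         n_rounds = x$params$n_rounds,
         min_fold = min(x$results$fold_change, na.rm = TRUE),
         max_fold = max(x$results$fold_change, na.rm = TRUE))
}

#' @method autoplot interaction_test
#' @export
autoplot.interaction_test <- function(object, ...) {
  df <- object$results
  df$pair <- paste(df$subclass1, df$subclass2, sep = " : ")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold_change,
                                   y = -log10(pmax(.data$pval_adjusted,
                                                   1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(object$params$alpha),
                        linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "fold change over null mean",
                  y = expression(-log[10] ~ "adjusted p"),
                  colour = "significant") +
    ggplot2::theme_minimal()
}
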