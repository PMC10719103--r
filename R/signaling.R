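#' Ligand-receptor expression score of a cell pair
#'
#' `S = log(1 + prod(ligand components) * prod(receptor components))`,
#' natural log, with ligand components taken from the sender cell and
#' receptor components from the receiver. A zero in any component
#' annihilates the score, so multi-subunit receptors require every subunit.
#' Expression values must be non-negative (imputed expression in practice).
#'
#' @param ligand_expr Non-negative expression of the ligand component(s) in
#'   the sender cell.
#' @param receptor_expr Non-negative expression of the receptor
#'   component(s) in the receiver cell.
#' @return The scalar score.
#' @export
lr_score <- function(ligand_expr, receptor_expr) {
  if (any(ligand_expr < 0) || any(receptor_expr < 0)) {
    abort("expression values must be non-negative")
  }
  log1p(prod(ligand_expr) * prod(receptor_expr))
}

# Vectorised scores over many (sender, receiver) index pairs.
lr_scores_for_pairs <- function(expr_mat, i_sender, j_receiver, lig, rec) {
  lp <- if (length(lig) == 1) expr_mat[i_sender, lig] else
    apply(expr_mat[i_sender, lig, drop = FALSE], 1, prod)
  rp <- if (length(rec) == 1) expr_mat[j_receiver, rec] else
    apply(expr_mat[j_receiver, rec, drop = FALSE], 1, prod)
  unname(log1p(lp * rp))
}

#' One-sided Welch's t-test (upper tail)
#'
#' Unequal-variance two-sample t statistic with Welch-Satterthwaite degrees
#' of freedom, testing whether the mean of `x` exceeds the mean of `y`.
#' When both samples have zero variance the convention is p = 0.5 for equal
#' means, 0 or 1 otherwise according to the direction.
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
welch_t_one_sided <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) abort("each sample needs at least 2 values")
  vx <- var(x); vy <- var(y)
  mx <- mean(x); my <- mean(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    p <- if (mx == my) 0.5 else if (mx > my) 0 else 1
    return(list(statistic = if (mx == my) 0 else sign(mx - my) * Inf,
                df = NA_real_, p_value = p))
  }
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(statistic = t, df = df, p_value = pt(t, df, lower.tail = FALSE))
}

# Proximal (<= r) and sampled non-proximal (> r) cross-type cell pairs.
# Returns 1-based index pairs into ia/ib positions. Sections are handled by
# coordinate offsetting upstream.
sample_pair_sets <- function(xa, ya, xb, yb, r, same_type = FALSE) {
  prox <- pairs_within_radius(xa, ya, xb, yb, r)
  if (same_type) {
    keep <- prox[, 1] < prox[, 2]
    prox <- prox[keep, , drop = FALSE]
  }
  na <- length(xa); nb <- length(yb)
  n_prox <- nrow(prox)
  total <- if (same_type) na * (nb - 1) / 2 else na * nb
  n_nonprox <- total - n_prox
  replace_flag <- n_nonprox < n_prox
  prox_key <- prox[, 1] + (prox[, 2] - 1) * na
  chosen <- integer(0)
  seen <- new.env(hash = TRUE)
  for (k in prox_key) assign(as.character(k), TRUE, envir = seen)
  target <- n_prox
  guard <- 0
  while (length(chosen) < target && guard < 200) {
    guard <- guard + 1
    cand_i <- sample.int(na, target * 2, replace = TRUE)
    cand_j <- sample.int(nb, target * 2, replace = TRUE)
    if (same_type) {
      ok <- cand_i < cand_j
      cand_i <- cand_i[ok]; cand_j <- cand_j[ok]
    }
    key <- cand_i + (cand_j - 1) * na
    fresh <- !vapply(as.character(key), function(k)
      exists(k, envir = seen, inherits = FALSE), logical(1))
    key <- key[fresh]
    if (!replace_flag) {
      for (k in key) assign(as.character(k), TRUE, envir = seen)
      key <- unique(key)
    }
    chosen <- c(chosen, key)
  }
  chosen <- chosen[seq_len(min(target, length(chosen)))]
  ctrl <- cbind((chosen - 1) %% na + 1, (chosen - 1) %/% na + 1)
  list(proximal = prox, control = ctrl, sampled_with_replacement = replace_flag)
}

#' Ligand-receptor upregulation screen for one interacting subclass pair
#'
#' For each database LR pair and each orientation (A as sender / B as
#' receiver, and the reverse), compares the distribution of LR expression
#' scores over all proximal cross-type cell pairs (centroid distance
#' <= `r_proximal`, within section) with an equal-size random sample of
#' non-proximal pairs (distance > `r_proximal`), using a one-sided Welch
#' t-test. P-values are Benjamini-Hochberg adjusted over all LR pairs and
#' orientations of the call; a pair is significant when the proximal mean
#' is at least `fold_threshold`-fold the non-proximal mean, the adjusted p
#' is below `padj_threshold`, and the score is positive in at least
#' `min_exp_fraction` of the proximal pairs.
#'
#' @param cells Cell table.
#' @param expr_values Cells x genes matrix of (imputed) expression, rows
#'   named by cell id.
#' @param type_a,type_b Subclass labels of the interacting pair.
#' @param lr_db LR database tibble ([lr_database()]).
#' @param r_proximal Proximity radius, micrometres (default 30).
#' @param fold_threshold,padj_threshold,min_exp_fraction The three calling
#'   criteria (defaults 2, 0.01, 0.4).
#' @param region Optional region tag recorded in the output.
#' @param seed Integer seed for the non-proximal sample.
#' @return Object of class `lr_test` with a `results` tibble (one row per
#'   LR pair x orientation).
#' @export
test_lr_upregulation <- function(cells, expr_values, type_a, type_b, lr_db,
                                 r_proximal = 30, fold_threshold = 2,
                                 padj_threshold = 0.01,
                                 min_exp_fraction = 0.4,
                                 region = "all", seed = 1L) {
  co <- section_offset_coords(cells)
  ia <- which(cells$subclass == type_a)
  ib <- which(cells$subclass == type_b)
  if (length(ia) == 0 || length(ib) == 0) {
    abort("both subclasses must be present")
  }
  check_seed(seed)
  same <- identical(type_a, type_b)
  ps <- sample_pair_sets(co$x[ia], co$y[ia], co$x[ib], co$y[ib], r_proximal,
                         same_type = same)
  if (nrow(ps$proximal) < 2) abort("fewer than 2 proximal cell pairs")
  if (ps$sampled_with_replacement) {
    warn("fewer non-proximal than proximal pairs; control sampled with replacement")
  }
  ids <- rownames(expr_values)
  a_rows <- match(cells$cell_id[ia], ids)
  b_rows <- match(cells$cell_id[ib], ids)
  orientations <- list(
    list(sender = type_a, receiver = type_b,
         si = a_rows[ps$proximal[, 1]], ri = b_rows[ps$proximal[, 2]],
         ci = a_rows[ps$control[, 1]], cj = b_rows[ps$control[, 2]]),
    list(sender = type_b, receiver = type_a,
         si = b_rows[ps$proximal[, 2]], ri = a_rows[ps$proximal[, 1]],
         ci = b_rows[ps$control[, 2]], cj = a_rows[ps$control[, 1]])
  )
  if (same) orientations <- orientations[1]
  rows <- list()
  for (orient in orientations) {
    for (e in seq_len(nrow(lr_db))) {
      lig <- lr_db$ligand_components[[e]]
      rec <- lr_db$receptor_components[[e]]
      if (!all(c(lig, rec) %in% colnames(expr_values))) next
      s_prox <- lr_scores_for_pairs(expr_values, orient$si, orient$ri, lig, rec)
      s_ctrl <- lr_scores_for_pairs(expr_values, orient$ci, orient$cj, lig, rec)
      wt <- welch_t_one_sided(s_prox, s_ctrl)
      mp <- mean(s_prox); mc <- mean(s_ctrl)
      rows[[length(rows) + 1]] <- tibble(
        subclass_ligand = orient$sender, subclass_receptor = orient$receiver,
        lr_pair = lr_db$pair_name[e], pathway = lr_db$pathway[e],
        n_proximal_pairs = length(s_prox),
        mean_proximal_lr_exp = mp, mean_nonproximal_lr_exp = mc,
        exp_fraction = mean(s_prox > 0),
        fold_change = if (mc > 0) mp / mc else if (mp > 0) Inf else 1,
        pval = wt$p_value, region = region)
    }
  }
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0) abort("no LR pairs with all components in the expression matrix")
  res$pval_adjusted <- bh_adjust(res$pval)
  res$significant <- res$fold_change >= fold_threshold &
    res$pval_adjusted < padj_threshold &
    res$exp_fraction >= min_exp_fraction
  structure(list(results = res,
                 params = list(type_a = type_a, type_b = type_b,
                               r_proximal = r_proximal,
                               fold_threshold = fold_threshold,
                               padj_threshold = padj_threshold,
                               min_exp_fraction = min_exp_fraction,
                               control_with_replacement =
                                 ps$sampled_with_replacement)),
            class = "lr_test")
}

#' Gene upregulation screen in proximal cells
#'
#' Splits the type-A cells into those within `r_proximal` of any type-B
#' cell and the rest, then tests each highly variable gene for higher mean
#' expression in the proximal group (one-sided Welch t-test,
#' Benjamini-Hochberg adjusted). Significant genes have fold change >=
#' `fold_threshold` and adjusted p < `padj_threshold`.
#'
#' @param cells Cell table.
#' @param expr_values Cells x genes (imputed) expression matrix, rows named
#'   by cell id.
#' @param type_a Subclass whose expression is tested.
#' @param type_b Interacting subclass defining proximity.
#' @param hvg Character vector of highly variable genes to test (see
#'   [select_hvg()]); only these are tested.
#' @param r_proximal Proximity radius, micrometres (default 30).
#' @param fold_threshold,padj_threshold Calling criteria (defaults 2, 0.01).
#' @param region Optional region tag.
#' @return Tibble with one row per tested gene.
#' @export
test_gene_upregulation <- function(cells, expr_values, type_a, type_b, hvg,
                                   r_proximal = 30, fold_threshold = 2,
                                   padj_threshold = 0.01, region = "all") {
  co <- section_offset_coords(cells)
  ia <- which(cells$subclass == type_a)
  ib <- which(cells$subclass == type_b)
  if (length(ia) == 0 || length(ib) == 0) abort("both subclasses must be present")
  pr <- pairs_within_radius(co$x[ia], co$y[ia], co$x[ib], co$y[ib], r_proximal)
  if (identical(type_a, type_b)) {
    pr <- pr[pr[, 1] != pr[, 2], , drop = FALSE]
  }
  prox <- rep(FALSE, length(ia))
  prox[unique(pr[, 1])] <- TRUE
  ids <- rownames(expr_values)
  rows_a <- match(cells$cell_id[ia], ids)
  g1 <- rows_a[prox]; g2 <- rows_a[!prox]
  hvg <- intersect(hvg, colnames(expr_values))
  out <- list()
  for (g in hvg) {
    if (length(g1) < 2 || length(g2) < 2) {
      out[[g]] <- tibble(gene = g, proximal_mean = NA_real_,
                         control_mean = NA_real_, fold_change = NA_real_,
                         pval = NA_real_, skipped = "a group has < 2 cells")
      next
    }
    x1 <- expr_values[g1, g]; x2 <- expr_values[g2, g]
    wt <- welch_t_one_sided(x1, x2)
    m1 <- mean(x1); m2 <- mean(x2)
    out[[g]] <- tibble(gene = g, proximal_mean = m1, control_mean = m2,
                       fold_change = if (m2 > 0) m1 / m2 else
                         if (m1 > 0) Inf else 1,
                       pval = wt$p_value, skipped = NA_character_)
  }
  res <- dplyr::bind_rows(out)
  res$subclass_gene_exp <- type_a
  res$subclass_interacting <- type_b
  res$region <- region
  tested <- !is.na(res$pval)
  res$pval_adjusted <- NA_real_
  res$pval_adjusted[tested] <- bh_adjust(res$pval[tested])
  res$significant <- !is.na(res$pval_adjusted) &
    res$fold_change >= fold_threshold & res$pval_adjusted < padj_threshold
  res
}

#' Pathway-level summary of an LR screen
#'
#' Per pathway, reports the LR pair with the highest upregulation fold
#' change among its significant pairs.
#'
#' @param lr An `lr_test` or its results tibble.
#' @param top_n Number of pathways returned (default 10).
#' @return Tibble with `pathway`, `lr_pair`, `fold_change`.
#' @export
pathway_summary <- function(lr, top_n = 10) {
  res <- if (inherits(lr, "lr_test")) lr$results else lr
  res <- res[res$significant & !is.na(res$pathway), , drop = FALSE]
  res |>
    dplyr::group_by(.data$pathway) |>
    dplyr::slice_max(.data$fold_change, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$fold_change)) |>
    head(top_n) |>
    dplyr::select("pathway", "lr_pair", "fold_change")
}

#' @export
print.lr_test <- function(x, ...) {
  cat(sprintf("<lr_test> %s : %s, %d LR tests, %d significant\n",
              x$params$type_a, x$params$type_b, nrow(x$results),
              sum(x$results$significant)))
  invisible(x)
}

#' @method tidy lr_test
#' @export
tidy.lr_test <- function(x, ...) x$results

#' @method glance lr_test
#' @export
glance.lr_test <- function(x, ...) {
  tibble(n_tests = nrow(x$results),
         n_significant = sum(x$results$significant),
         n_proximal_pairs = x$results$n_proximal_pairs[1],
         control_with_replacement = x$params$control_with_replacement)
}
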