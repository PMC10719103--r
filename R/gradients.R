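#' Neighbourhood purity and cluster discreteness
#'
#' For each cell, the fraction of its `k` nearest neighbours in gene
#' expression space (a PCA of the log-normalised layer) sharing its cluster
#' label. Cluster discreteness is the mean purity of the cluster's members;
#' subclass discreteness is the median discreteness over its clusters. Low
#' discreteness indicates clusters that blend continuously — the situation
#' in which spatial gradients are examined.
#'
#' @param expr An [expr_set()] (`"lognorm"` computed on the fly when
#'   absent).
#' @param clusters Character cluster label per cell.
#' @param subclass Optional subclass label per cell for the subclass-level
#'   aggregation.
#' @param k Expression-space neighbourhood size (default 50).
#' @param n_pcs PCA dimensionality of the expression space (default 50).
#' @return List with `purity` (tibble `cell_id`, `cluster`, `purity`),
#'   `cluster_discreteness` and, when `subclass` is given,
#'   `subclass_discreteness` tibbles.
#' @export
neighborhood_purity <- function(expr, clusters, subclass = NULL, k = 50,
                                n_pcs = 50) {
  n <- length(expr$cells)
  if (n < k + 1) abort(sprintf("need at least %d cells for k = %d", k + 1, k))
  if (!has_expr_layer(expr, "lognorm")) {
    expr <- preprocess_for_integration(expr)
  }
  emb <- pca_embed(expr_layer(expr, "lognorm"), n_pcs)
  nn <- knn_within(emb, k)$index
  same <- matrix(clusters[nn], nrow = n) == clusters
  purity <- rowMeans(same)
  pt <- tibble(cell_id = expr$cells, cluster = clusters, purity = purity)
  cd <- pt |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(discreteness = mean(.data$purity), n_cells = dplyr::n())
  cd$low_n <- cd$n_cells < 2
  out <- list(purity = pt, cluster_discreteness = cd)
  if (!is.null(subclass)) {
    map <- dplyr::distinct(tibble(cluster = clusters, subclass = subclass))
    out$subclass_discreteness <- dplyr::inner_join(cd, map, by = "cluster") |>
      dplyr::group_by(.data$subclass) |>
      dplyr::summarise(discreteness = median(.data$discreteness),
                       n_clusters = dplyr::n())
  }
  out
}

#' One-dimensional expression axis (PC1 or diffusion pseudotime)
#'
#' `"pc1"` returns first-principal-component scores of the log-normalised
#' data. `"pseudotime"` returns the first diffusion-map component of a
#' Gaussian-kernel k-nearest-neighbour transition operator built on the PCA
#' embedding. Both are centred. Sign conventions make the output
#' reproducible: PC1 is oriented so the gene with the largest absolute
#' loading has a positive loading, and pseudotime is oriented to correlate
#' positively with PC1.
#'
#' @param expr An [expr_set()].
#' @param method `"pc1"` or `"pseudotime"`.
#' @param n_pcs PCA dimensionality feeding the diffusion map (default 50).
#' @param k_diff Neighbourhood size of the diffusion kernel (default 15).
#' @return Named numeric vector of per-cell axis values.
#' @export
expression_axis <- function(expr, method = c("pc1", "pseudotime"),
                            n_pcs = 50, k_diff = 15) {
  method <- match.arg(method)
  if (length(expr$cells) < 2 || length(expr$genes) < 2) {
    abort("need at least 2 cells and 2 genes")
  }
  if (!has_expr_layer(expr, "lognorm")) {
    expr <- preprocess_for_integration(expr)
  }
  m <- expr_layer(expr, "lognorm")
  if (all(apply(m, 2, sd) == 0)) abort("zero-variance expression data")
  pr <- prcomp(m, center = TRUE, scale. = FALSE,
               rank. = min(n_pcs, ncol(m), nrow(m) - 1L))
  pc1 <- pr$x[, 1]
  top <- which.max(abs(pr$rotation[, 1]))
  if (pr$rotation[top, 1] < 0) pc1 <- -pc1
  if (method == "pc1") {
    return(setNames(pc1 - mean(pc1), expr$cells))
  }
  emb <- pr$x
  n <- nrow(emb)
  k_eff <- min(k_diff, n - 1L)
  nn <- knn_within(emb, k_eff)
  sigma <- pmax(nn$dist[, k_eff], 1e-12)
  # symmetric Gaussian affinity on the union kNN graph
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    w <- exp(-(nn$dist[i, ] / sigma[i])^2)
    A[i, nn$index[i, ]] <- pmax(A[i, nn$index[i, ]], w)
  }
  A <- pmax(A, t(A))
  dinv <- 1 / sqrt(rowSums(A))
  M <- A * (dinv %o% dinv)   # symmetric normalised operator
  ev <- eigen(M, symmetric = TRUE)
  psi <- ev$vectors[, 2] * dinv  # first nontrivial diffusion component
  if (cor(psi, pc1) < 0) psi <- -psi
  setNames(psi - mean(psi), expr$cells)
}

#' Correlation of an expression axis with a spatial coordinate
#'
#' Standard Pearson correlation of per-cell axis values (PC1 or pseudotime)
#' with any per-cell spatial scalar — a cell-table coordinate column,
#' cortical depth, or a position along an anatomical axis.
#'
#' @param axis Numeric per-cell axis values.
#' @param coordinate Numeric per-cell spatial coordinate, same length.
#' @return Tibble with `r`, `p_value`, `n`. Zero variance in either input
#'   yields missing `r`.
#' @export
gradient_correlation <- function(axis, coordinate) {
  ok <- is.finite(axis) & is.finite(coordinate)
  axis <- axis[ok]; coordinate <- coordinate[ok]
  if (length(axis) < 3) abort("need at least 3 paired values")
  if (sd(axis) == 0 || sd(coordinate) == 0) {
    return(tibble(r = NA_real_, p_value = NA_real_, n = length(axis)))
  }
  ct <- stats::cor.test(axis, coordinate, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(axis))
}
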