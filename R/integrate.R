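#' Normalise an expression set for integration
#'
#' Adds `"lognorm"` (per-cell totals normalised to `norm_total`, then
#' `log1p`) and `"scaled"` (per-gene z-scores of `"lognorm"`; constant genes
#' map to zero) layers.
#'
#' @param expr An [expr_set()] with a `"raw"` layer.
#' @param norm_total Per-cell total after normalisation (default 1,000).
#' @return The [expr_set()] with both layers added.
#' @export
preprocess_for_integration <- function(expr, norm_total = 1000) {
  m <- expr_layer(expr, "raw")
  tot <- rowSums(m)
  if (any(tot == 0)) {
    abort(sprintf("all-zero cell(s): %s",
                  paste(head(expr$cells[tot == 0], 5), collapse = ", ")))
  }
  ln <- log1p(m * (norm_total / tot))
  expr <- set_expr_layer(expr, "lognorm", ln)
  mu <- colMeans(ln)
  sdv <- apply(ln, 2, sd)
  sdv[is.na(sdv)] <- 0  # single-cell input
  sc <- sweep(ln, 2, mu, "-")
  sc <- sweep(sc, 2, ifelse(sdv == 0, 1, sdv), "/")
  sc[, sdv == 0] <- 0
  set_expr_layer(expr, "scaled", sc)
}

#' Select highly variable genes by normalised log dispersion
#'
#' Computes per-gene dispersion (variance over mean of the de-logged
#' `"lognorm"` layer), log-transforms it, z-scores it within mean-expression
#' bins (the standard single-cell dispersion method), and keeps genes whose
#' normalised log dispersion exceeds zero. Constant genes are always
#' excluded.
#'
#' @param expr An [expr_set()] with a `"lognorm"` layer (computed on the fly
#'   from `"raw"` when absent).
#' @param n_bins Number of mean-expression bins (default 20).
#' @return Character vector of retained gene names (a subset of
#'   `expr$genes`).
#' @export
select_hvg <- function(expr, n_bins = 20) {
  if (length(expr$genes) < 2) abort("need at least 2 genes")
  if (!has_expr_layer(expr, "lognorm")) {
    expr <- preprocess_for_integration(expr)
  }
  m <- expm1(expr_layer(expr, "lognorm"))
  mu <- colMeans(m)
  v <- apply(m, 2, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  logdisp <- suppressWarnings(log(disp))
  ok <- is.finite(logdisp)
  bins <- cut(rank(mu, ties.method = "first"),
              breaks = min(n_bins, length(mu)), labels = FALSE)
  z <- rep(-Inf, length(mu))
  for (b in unique(bins)) {
    sel <- bins == b & ok
    if (!any(sel)) next
    mb <- mean(logdisp[sel])
    sb <- sd(logdisp[sel])
    z[sel] <- if (is.na(sb) || sb == 0) logdisp[sel] - mb else
      (logdisp[sel] - mb) / sb
  }
  expr$genes[z > 0]
}

# PCA scores of a (already centred/scaled) matrix, capped at the data rank.
pca_embed <- function(x, n_dims) {
  p <- min(n_dims, ncol(x), nrow(x) - 1L)
  pr <- prcomp(x, center = TRUE, scale. = FALSE, rank. = p)
  pr$x
}

#' Co-embed two datasets by canonical correlation analysis
#'
#' Computes the singular value decomposition of the cross-product of the two
#' column-scaled matrices (the diagonal-covariance CCA used throughout
#' single-cell integration), optionally fitting on a random downsample of
#' each dataset and projecting all cells by the fitted gene-space linear
#' maps. Per-cell embeddings are L2-normalised.
#'
#' @param ref_scaled,query_scaled Cells x genes scaled matrices over the same
#'   gene columns.
#' @param n_dims Embedding dimensionality (default 100; capped at the data
#'   rank).
#' @param max_fit_cells Maximum cells per dataset used to fit the canonical
#'   directions (default 100,000); larger datasets are randomly downsampled
#'   and then projected.
#' @param seed Seed for the downsampling draw.
#' @return List with `ref` and `query` embedding matrices (cells x dims),
#'   the singular values `d`, and the gene-space maps.
#' @export
cca_coembed <- function(ref_scaled, query_scaled, n_dims = 100,
                        max_fit_cells = 100000, seed = NULL) {
  if (ncol(ref_scaled) != ncol(query_scaled)) {
    abort("ref and query must share the same gene columns")
  }
  check_seed(seed)
  fit_r <- if (nrow(ref_scaled) > max_fit_cells)
    ref_scaled[sample.int(nrow(ref_scaled), max_fit_cells), , drop = FALSE]
  else ref_scaled
  fit_q <- if (nrow(query_scaled) > max_fit_cells)
    query_scaled[sample.int(nrow(query_scaled), max_fit_cells), , drop = FALSE]
  else query_scaled
  max_d <- min(nrow(fit_r), nrow(fit_q), ncol(ref_scaled))
  if (n_dims > max_d) {
    abort(sprintf("n_dims (%d) exceeds the maximum embedding rank (%d)",
                  n_dims, max_d))
  }
  K <- fit_r %*% t(fit_q)
  sv <- svd(K, nu = n_dims, nv = n_dims)
  d <- sv$d[seq_len(n_dims)]
  d_safe <- ifelse(d > 1e-12, d, 1)
  map_ref <- t(fit_q) %*% sv$v %*% diag(1 / d_safe, n_dims)
  map_query <- t(fit_r) %*% sv$u %*% diag(1 / d_safe, n_dims)
  list(ref = l2_normalize_rows(ref_scaled %*% map_ref),
       query = l2_normalize_rows(query_scaled %*% map_query),
       d = d, map_ref = map_ref, map_query = map_query)
}

#' Find mutual-nearest-neighbour integration anchors
#'
#' A reference/query cell pair is an anchor when each cell is among the
#' other's `k` nearest cross-dataset neighbours (Euclidean, in the
#' co-embedding).
#'
#' @param embedding A co-embedding from [cca_coembed()] (list with `ref` and
#'   `query` matrices).
#' @param k Neighbourhood size (default 5).
#' @return Tibble with integer columns `ref` and `query` (row indices into
#'   the embedding matrices).
#' @export
find_anchors <- function(embedding, k = 5) {
  nr <- nrow(embedding$ref)
  nq <- nrow(embedding$query)
  if (k >= nr || k >= nq) abort("k must be smaller than both dataset sizes")
  # k nearest query cells of each ref cell, and vice versa
  r2q <- knn_between(embedding$query, embedding$ref, k)$index  # nr x k
  q2r <- knn_between(embedding$ref, embedding$query, k)$index  # nq x k
  ref_idx <- rep(seq_len(nr), each = k)
  qry_idx <- as.vector(t(r2q))
  # mutual: ref must appear among the query cell's k nearest refs
  mutual <- vapply(seq_along(ref_idx), function(i)
    any(q2r[qry_idx[i], ] == ref_idx[i]), logical(1))
  tibble(ref = ref_idx[mutual], query = qry_idx[mutual])
}

#' Transfer labels across datasets through anchors
#'
#' Each query cell takes the plurality label among its `k_anchor` nearest
#' anchor-participating reference cells in the co-embedding; the plurality
#' fraction is the transfer confidence. Ties break to the lexicographically
#' smallest label.
#'
#' @param anchors Anchor tibble from [find_anchors()].
#' @param ref_labels Character labels per reference cell (full reference).
#' @param embedding Co-embedding from [cca_coembed()].
#' @param k_anchor Number of nearest anchor cells consulted (default 100;
#'   capped at the number of distinct anchor reference cells).
#' @return Tibble with `label` and `confidence` per query cell.
#' @export
transfer_labels <- function(anchors, ref_labels, embedding, k_anchor = 100) {
  if (nrow(anchors) == 0) abort("no anchors available for label transfer")
  anchor_ref <- sort(unique(anchors$ref))
  k_eff <- min(k_anchor, length(anchor_ref))
  nn <- knn_between(embedding$ref[anchor_ref, , drop = FALSE],
                    embedding$query, k_eff)$index
  labs <- ref_labels[anchor_ref]
  lev <- sort(unique(labs))
  code <- match(labs, lev)
  n_query <- nrow(embedding$query)
  label <- character(n_query)
  confidence <- numeric(n_query)
  for (i in seq_len(n_query)) {
    counts <- tabulate(code[nn[i, ]], nbins = length(lev))
    best <- which(counts == max(counts))[1]  # levels sorted: lexicographic tie
    label[i] <- lev[best]
    confidence[i] <- counts[best] / k_eff
  }
  tibble(label = label, confidence = confidence)
}

#' Partition a reference taxonomy into balanced integration groups
#'
#' Builds the subclass connectivity graph (nodes = subclasses, edge weight =
#' number of nearest-neighbour-graph edges connecting cells of the two
#' subclasses, from a 15-NN graph in 100-dimensional PCA space) and cuts it
#' into `K` groups that balance cell counts while keeping the cut weight
#' small, by recursive spectral bisection with single-pass move refinement.
#'
#' @param ref_expr Reference [expr_set()] (`"scaled"` layer computed on the
#'   fly when absent).
#' @param subclasses Character subclass label per reference cell.
#' @param K Number of partitions (default 50; must not exceed the number of
#'   subclasses).
#' @param n_dims PCA dimensionality (default 100).
#' @param k_nn Nearest-neighbour graph size (default 15).
#' @return List with `partition` (named integer vector, subclass to
#'   partition id 1..K) and `graph` (the symmetric subclass weight matrix).
#' @export
partition_reference <- function(ref_expr, subclasses, K = 50, n_dims = 100,
                                k_nn = 15) {
  usub <- sort(unique(subclasses))
  if (K > length(usub)) {
    abort(sprintf("K (%d) exceeds the number of subclasses (%d)",
                  K, length(usub)))
  }
  if (!has_expr_layer(ref_expr, "scaled")) {
    ref_expr <- preprocess_for_integration(ref_expr)
  }
  emb <- pca_embed(expr_layer(ref_expr, "scaled"), n_dims)
  nn <- knn_within(emb, min(k_nn, nrow(emb) - 1L))$index
  code <- match(subclasses, usub)
  S <- length(usub)
  W <- matrix(0, S, S, dimnames = list(usub, usub))
  for (j in seq_len(ncol(nn))) {
    a <- code
    b <- code[nn[, j]]
    cross <- a != b
    if (any(cross)) {
      idx <- cbind(pmin(a[cross], b[cross]), pmax(a[cross], b[cross]))
      for (r in seq_len(nrow(idx))) W[idx[r, 1], idx[r, 2]] <-
          W[idx[r, 1], idx[r, 2]] + 1
    }
  }
  W <- W + t(W)
  sizes <- as.numeric(table(factor(subclasses, levels = usub)))
  groups <- balanced_kway_cut(W, sizes, K)
  part <- integer(S)
  for (g in seq_along(groups)) part[groups[[g]]] <- g
  list(partition = setNames(part, usub), graph = W)
}

# Recursive balanced k-way cut of a weighted graph. W: symmetric weights,
# sizes: node balance weights, K: parts. Returns list of index vectors.
balanced_kway_cut <- function(W, sizes, K) {
  rec <- function(nodes, K) {
    if (K == 1) return(list(nodes))
    if (length(nodes) == K) return(as.list(nodes))
    K1 <- K %/% 2
    K2 <- K - K1
    sides <- bisect_nodes(W, sizes, nodes, K1, K2)
    c(rec(sides[[1]], K1), rec(sides[[2]], K2))
  }
  rec(seq_len(nrow(W)), K)
}

bisect_nodes <- function(W, sizes, nodes, K1, K2) {
  n <- length(nodes)
  sub <- W[nodes, nodes, drop = FALSE]
  target1 <- sum(sizes[nodes]) * K1 / (K1 + K2)
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                           weighted = TRUE)
  comp <- igraph::components(g)$membership
  if (max(comp) > 1 && max(comp) >= 2) {
    side1 <- greedy_component_split(nodes, comp, sizes, target1, K1, K2)
  } else {
    deg <- rowSums(sub)
    L <- diag(deg) - sub
    ev <- eigen(L, symmetric = TRUE)
    fied <- ev$vectors[, n - 1]
    ord <- order(fied, nodes)
    csize <- cumsum(sizes[nodes[ord]])
    allowed <- seq(K1, n - K2)
    cutw <- vapply(allowed, function(m) {
      a <- ord[seq_len(m)]
      sum(sub[a, setdiff(seq_len(n), a), drop = FALSE])
    }, 0)
    balance_ok <- abs(csize[allowed] - target1) <= 0.2 * target1
    cand <- if (any(balance_ok)) allowed[balance_ok] else allowed
    candw <- cutw[match(cand, allowed)]
    best <- cand[order(candw, abs(csize[cand] - target1))][1]
    side1 <- nodes[ord[seq_len(best)]]
  }
  side2 <- setdiff(nodes, side1)
  refined <- refine_bisection(sub, sizes, nodes, side1, side2, target1, K1, K2)
  refined
}

greedy_component_split <- function(nodes, comp, sizes, target1, K1, K2) {
  comp_sizes <- tapply(sizes[nodes], comp, sum)
  ord <- order(-comp_sizes)
  side1 <- integer(0)
  s1 <- 0
  for (ci in as.integer(names(comp_sizes)[ord])) {
    members <- nodes[comp == ci]
    if (s1 < target1) {
      side1 <- c(side1, members)
      s1 <- s1 + sum(sizes[members])
    }
  }
  # respect minimum node counts on both sides
  side2 <- setdiff(nodes, side1)
  while (length(side1) < K1) {
    mv <- side2[which.min(sizes[side2])]
    side1 <- c(side1, mv)
    side2 <- setdiff(side2, mv)
  }
  while (length(side2) < K2) {
    mv <- side1[which.min(sizes[side1])]
    side2 <- c(side2, mv)
    side1 <- setdiff(side1, mv)
  }
  side1
}

refine_bisection <- function(sub, sizes, nodes, side1, side2, target1, K1, K2) {
  pos <- match(nodes, nodes)
  in1 <- nodes %in% side1
  s1 <- sum(sizes[side1])
  total <- sum(sizes[nodes])
  for (i in seq_along(nodes)) {
    ni <- nodes[i]
    to1 <- !in1[i]
    # cut change when node i switches sides
    w_same <- sum(sub[i, in1 == in1[i]])
    w_other <- sum(sub[i, in1 != in1[i]])
    gain <- w_same - w_other
    if (gain >= 0) next
    new_s1 <- s1 + if (to1) sizes[ni] else -sizes[ni]
    n1 <- sum(in1) + if (to1) 1L else -1L
    if (abs(new_s1 - target1) > 0.2 * target1) next
    if (n1 < K1 || (length(nodes) - n1) < K2) next
    in1[i] <- to1
    s1 <- new_s1
  }
  list(nodes[in1], nodes[!in1])
}

#' Impute expression through anchors
#'
#' Each query cell's imputed profile is the weighted average of the
#' expression of its `k_impute` nearest anchor-participating reference cells
#' in the co-embedding, with Gaussian kernel weights
#' `exp(-(d / sigma)^2)` where `sigma` is the distance to the
#' `k_impute`-th anchor.
#'
#' @param anchors Anchor tibble from [find_anchors()].
#' @param embedding Co-embedding from [cca_coembed()].
#' @param ref_values Reference cells x genes matrix (typically a `"lognorm"`
#'   layer over the full reference gene set), rows aligned with the
#'   embedding's reference rows.
#' @param k_impute Number of anchors averaged (default 30).
#' @return Query cells x genes imputed matrix.
#' @export
impute_expression <- function(anchors, embedding, ref_values, k_impute = 30) {
  if (nrow(anchors) == 0) abort("no anchors available for imputation")
  anchor_ref <- sort(unique(anchors$ref))
  k_eff <- min(k_impute, length(anchor_ref))
  nn <- knn_between(embedding$ref[anchor_ref, , drop = FALSE],
                    embedding$query, k_eff)
  n_query <- nrow(embedding$query)
  out <- matrix(NA_real_, n_query, ncol(ref_values),
                dimnames = list(rownames(embedding$query), colnames(ref_values)))
  for (i in seq_len(n_query)) {
    d <- nn$dist[i, ]
    sigma <- d[k_eff]
    w <- if (sigma > 0) exp(-(d / sigma)^2) else rep(1, k_eff)
    rows <- anchor_ref[nn$index[i, ]]
    out[i, ] <- colSums(ref_values[rows, , drop = FALSE] * w) / sum(w)
  }
  out
}

#' Two-round anchor-based label transfer with imputation
#'
#' Round 1 transfers balanced integration-partition labels from the
#' reference to the query through mutual-nearest-neighbour anchors in a CCA
#' co-embedding of the shared genes. Round 2 repeats the procedure within
#' each partition using that partition's highly variable genes to transfer
#' subclass and cluster labels. Because a cell-type label is only correct
#' when both rounds are, subclass and cluster confidences are adjusted by
#' multiplying with the partition confidence; cells pass at adjusted
#' subclass confidence >= 0.8 and cluster confidence >= 0.5.
#'
#' @param ref_expr Reference [expr_set()] (full gene set; the shared genes
#'   are used for embedding, all genes for imputation).
#' @param ref_labels Tibble with `cell_id`, `subclass`, `cluster` aligned
#'   with `ref_expr` cells.
#' @param query_expr Query [expr_set()] (panel genes).
#' @param n_partitions Number of integration partitions `K` (default 2 for
#'   desk-scale taxonomies; 50 suits atlas-scale ones). `1` skips round 1.
#' @param n_dims Co-embedding dimensionality (default 100, capped by rank).
#' @param k_mnn Mutual-nearest-neighbour size for anchors (default 5).
#' @param k_transfer Anchor neighbourhood for label transfer (default 100).
#' @param k_impute Anchor neighbourhood for imputation (default 30).
#' @param max_fit_cells CCA fit downsample cap (default 100,000).
#' @param subclass_threshold,cluster_threshold Adjusted-confidence pass
#'   thresholds (defaults 0.8 and 0.5, inclusive).
#' @param impute Compute the transcriptome-wide imputed layer (default TRUE).
#' @param seed Integer seed (downsampling).
#' @return An object of class `label_transfer`: list with `result` (per-query
#'   tibble), `imputed` (query x reference-genes matrix or NULL),
#'   `partitioning`, and the call parameters.
#' @export
two_round_transfer <- function(ref_expr, ref_labels, query_expr,
                               n_partitions = 2, n_dims = 100, k_mnn = 5,
                               k_transfer = 100, k_impute = 30,
                               max_fit_cells = 100000,
                               subclass_threshold = 0.8,
                               cluster_threshold = 0.5,
                               impute = TRUE, seed = 1L) {
  stopifnot(inherits(ref_expr, "expr_set"), inherits(query_expr, "expr_set"))
  stopifnot(all(ref_labels$cell_id == ref_expr$cells))
  shared <- intersect(ref_expr$genes, query_expr$genes)
  if (length(shared) == 0) abort("no shared genes between reference and query")
  ref_full <- preprocess_for_integration(ref_expr)
  ref_sh <- preprocess_for_integration(ref_expr[, shared])
  query_sh <- preprocess_for_integration(query_expr[, shared])
  nd <- function(...) min(...)

  # round 1: partition labels
  if (n_partitions > 1) {
    pt <- partition_reference(ref_sh, ref_labels$subclass, K = n_partitions,
                              n_dims = n_dims)
    ref_part <- unname(pt$partition[ref_labels$subclass])
    d1 <- nd(n_dims, length(shared), nrow(ref_sh$layers$raw) - 1,
             nrow(query_sh$layers$raw) - 1)
    emb1 <- cca_coembed(expr_layer(ref_sh, "scaled"),
                        expr_layer(query_sh, "scaled"),
                        n_dims = d1, max_fit_cells = max_fit_cells, seed = seed)
    an1 <- find_anchors(emb1, k = k_mnn)
    tr1 <- transfer_labels(an1, as.character(ref_part), emb1,
                           k_anchor = k_transfer)
    query_part <- as.integer(tr1$label)
    part_conf <- tr1$confidence
  } else {
    pt <- list(partition = setNames(
      rep(1L, length(unique(ref_labels$subclass))),
      sort(unique(ref_labels$subclass))), graph = NULL)
    ref_part <- rep(1L, nrow(ref_labels))
    query_part <- rep(1L, length(query_sh$cells))
    part_conf <- rep(1, length(query_sh$cells))
  }

  n_query <- length(query_sh$cells)
  res <- tibble(cell_id = query_sh$cells,
                partition = query_part, partition_confidence = part_conf,
                subclass = NA_character_, subclass_confidence = NA_real_,
                cluster = NA_character_, cluster_confidence = NA_real_)
  imputed <- if (impute)
    matrix(NA_real_, n_query, length(ref_full$genes),
           dimnames = list(query_sh$cells, ref_full$genes)) else NULL
  ref_lognorm_full <- expr_layer(ref_full, "lognorm")

  # round 2: subclass + cluster within each partition
  for (p in sort(unique(ref_part))) {
    qi <- which(query_part == p)
    ri <- which(ref_part == p)
    if (length(qi) == 0) {
      warn(sprintf("partition %d has no query cells; skipped", p))
      next
    }
    ref_p <- ref_sh[ri, ]
    query_p <- query_sh[qi, ]
    hvg <- tryCatch(select_hvg(ref_p), error = function(e) character(0))
    if (length(hvg) < 5) hvg <- shared
    ref_ps <- scale_columns(expr_layer(ref_p, "lognorm")[, hvg, drop = FALSE])
    query_ps <- scale_columns(expr_layer(query_p, "lognorm")[, hvg, drop = FALSE])
    d2 <- nd(n_dims, length(hvg), length(ri) - 1, length(qi) - 1)
    if (d2 < 1) next
    emb2 <- cca_coembed(ref_ps, query_ps, n_dims = d2,
                        max_fit_cells = max_fit_cells, seed = seed)
    an2 <- tryCatch(find_anchors(emb2, k = min(k_mnn, length(ri) - 1,
                                               length(qi) - 1)),
                    error = function(e) tibble(ref = integer(0),
                                               query = integer(0)))
    if (nrow(an2) == 0) {
      warn(sprintf("partition %d produced no anchors; labels left missing", p))
      next
    }
    trs <- transfer_labels(an2, ref_labels$subclass[ri], emb2,
                           k_anchor = k_transfer)
    trc <- transfer_labels(an2, ref_labels$cluster[ri], emb2,
                           k_anchor = k_transfer)
    res$subclass[qi] <- trs$label
    res$subclass_confidence[qi] <- trs$confidence
    res$cluster[qi] <- trc$label
    res$cluster_confidence[qi] <- trc$confidence
    if (impute) {
      imputed[qi, ] <- impute_expression(
        an2, emb2, ref_lognorm_full[ri, , drop = FALSE], k_impute = k_impute)
    }
  }

  res$subclass_confidence_adjusted <-
    res$subclass_confidence * res$partition_confidence
  res$cluster_confidence_adjusted <-
    res$cluster_confidence * res$partition_confidence
  res$pass_subclass <- !is.na(res$subclass_confidence_adjusted) &
    res$subclass_confidence_adjusted >= subclass_threshold
  res$pass_cluster <- !is.na(res$cluster_confidence_adjusted) &
    res$cluster_confidence_adjusted >= cluster_threshold

  structure(
    list(result = res, imputed = imputed, partitioning = pt,
         params = list(n_partitions = n_partitions, n_dims = n_dims,
                       k_mnn = k_mnn, k_transfer = k_transfer,
                       k_impute = k_impute,
                       subclass_threshold = subclass_threshold,
                       cluster_threshold = cluster_threshold)),
    class = "label_transfer"
  )
}

scale_columns <- function(m) {
  mu <- colMeans(m)
  sdv <- apply(m, 2, sd)
  sdv[is.na(sdv)] <- 0
  out <- sweep(m, 2, mu, "-")
  out <- sweep(out, 2, ifelse(sdv == 0, 1, sdv), "/")
  out[, sdv == 0] <- 0
  out
}

#' @export
print.label_transfer <- function(x, ...) {
  cat(sprintf(
    "<label_transfer> %d query cells, %d partitions; subclass pass %.1f%%, cluster pass %.1f%%\n",
    nrow(x$result), x$params$n_partitions,
    100 * mean(x$result$pass_subclass), 100 * mean(x$result$pass_cluster)))
  invisible(x)
}

#' @method tidy label_transfer
#' @export
tidy.label_transfer <- function(x, ...) x$result

#' @method glance label_transfer
#' @export
glance.label_transfer <- function(x, ...) {
  tibble(n_cells = nrow(x$result),
         n_partitions = x$params$n_partitions,
         subclass_pass_rate = mean(x$result$pass_subclass),
         cluster_pass_rate = mean(x$result$pass_cluster),
         mean_subclass_confidence = mean(x$result$subclass_confidence,
                                         na.rm = TRUE),
         mean_cluster_confidence = mean(x$result$cluster_confidence,
                                        na.rm = TRUE))
}

#' @method autoplot label_transfer
#' @export
autoplot.label_transfer <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$result[, c("cell_id", "subclass_confidence_adjusted",
                      "cluster_confidence_adjusted")],
    -"cell_id", names_to = "level", values_to = "confidence")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$confidence)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = NA) +
    ggplot2::facet_wrap(~level) +
    ggplot2::labs(x = "adjusted transfer confidence", y = "cells") +
    ggplot2::theme_minimal()
}
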