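#' Weighted local cell-type-composition vectors
#'
#' For each cell `i`, finds its `k` spatially nearest neighbours within the
#' section and accumulates, per cell type `t`, the sum of Gaussian weights
#' `Weight_ij = exp(-(D_ij / D_i0)^2)` over neighbours `j` of type `t`. The
#' per-cell bandwidth `D_i0` adapts to local density: it is
#' `bandwidth_multiplier` times the distance from `i` to its 5th nearest
#' neighbour (multiplier 2 at the coarse level, 1 at the fine level).
#' Randomly dispersed types (e.g. vascular and immune cells) can be excluded
#' before the search.
#'
#' @param cells Cell table with `x`, `y`, `section_id` and the type column.
#' @param type_col Column holding type labels (default `"subclass"`).
#' @param k Number of spatial neighbours (default 50).
#' @param bandwidth_multiplier Multiplier on the 5th-neighbour distance
#'   (default 2).
#' @param bandwidth_nn Neighbour rank defining the bandwidth (default 5).
#' @param exclude Character vector of type labels dropped before the search.
#' @return A cells x types numeric matrix (rownames = `cell_id`) with an
#'   attribute `"types"`; rows cover the non-excluded cells only.
#' @export
local_composition <- function(cells, type_col = "subclass", k = 50,
                              bandwidth_multiplier = 2, bandwidth_nn = 5,
                              exclude = character()) {
  assert_columns(cells, c("cell_id", "x", "y", "section_id", type_col),
                 "cell table")
  cells <- cells[!cells[[type_col]] %in% exclude & !is.na(cells[[type_col]]), ,
                 drop = FALSE]
  types <- sort(unique(cells[[type_col]]))
  comp <- matrix(0, nrow(cells), length(types),
                 dimnames = list(cells$cell_id, types))
  for (sec in unique(cells$section_id)) {
    idx <- which(cells$section_id == sec)
    n <- length(idx)
    if (n <= max(k, bandwidth_nn)) {
      abort(sprintf("section '%s' has %d cells after exclusion; need more than %d",
                    sec, n, max(k, bandwidth_nn)))
    }
    nn <- knn_within(cbind(cells$x[idx], cells$y[idx]), k)
    d0 <- bandwidth_multiplier * nn$dist[, bandwidth_nn]
    if (any(d0 == 0)) {
      abort(sprintf("zero bandwidth (coincident points) at cell %s",
                    cells$cell_id[idx[which(d0 == 0)[1]]]))
    }
    w <- exp(-(nn$dist / d0)^2)
    tcode <- match(cells[[type_col]][idx], types)
    for (i in seq_len(n)) {
      contrib <- tapply(w[i, ], tcode[nn$index[i, ]], sum)
      comp[idx[i], as.integer(names(contrib))] <-
        comp[idx[i], as.integer(names(contrib))] + contrib
    }
  }
  attr(comp, "types") <- types
  comp
}

#' Cluster composition vectors into spatial modules
#'
#' L2-normalises the composition rows, builds a k-nearest-neighbour graph in
#' composition space (cells from all sections pooled — composition space has
#' no spatial coordinates), and runs Leiden community detection.
#'
#' Community detection on kNN graphs of essentially homogeneous
#' neighbourhoods tends to over-fragment them; such fragments are
#' classically curated by hand. As a programmatic surrogate, modules whose mean
#' normalised composition vectors are nearly collinear are merged
#' afterwards (see [merge_similar_modules()]); set `min_cosine = 1` to
#' disable.
#'
#' @param comp Composition matrix from [local_composition()].
#' @param resolution Leiden resolution parameter (default 1).
#' @param k_graph Graph neighbourhood size (default 15).
#' @param min_cosine Cosine-similarity threshold above which modules are
#'   merged (default 0.85).
#' @param seed Integer seed for the Leiden run.
#' @return Character module labels named by cell id.
#' @export
cluster_compositions <- function(comp, resolution = 1, k_graph = 15,
                                 min_cosine = 0.85, seed = 1L) {
  if (nrow(comp) < 2) abort("need at least 2 cells to cluster")
  zero <- rowSums(comp^2) == 0
  if (any(zero)) {
    abort(sprintf("all-zero composition row(s), e.g. %s",
                  rownames(comp)[which(zero)[1]]))
  }
  nc <- l2_normalize_rows(comp)
  k_eff <- min(k_graph, nrow(nc) - 1L)
  nn <- knn_within(nc, k_eff)$index
  edges <- cbind(rep(seq_len(nrow(nc)), k_eff), as.vector(nn))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  check_seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5)
  labels <- setNames(as.character(igraph::membership(cl)), rownames(comp))
  if (min_cosine < 1) {
    labels <- merge_similar_modules(nc, labels, min_cosine = min_cosine)
  }
  labels
}

#' Merge modules with near-identical composition profiles
#'
#' Iteratively merges the pair of modules whose mean (L2-normalised)
#' composition vectors have the highest cosine similarity, while that
#' similarity exceeds `min_cosine`. Fragments that community detection
#' carves out of one homogeneous neighbourhood type have almost collinear
#' mean compositions, whereas genuinely distinct niches do not.
#'
#' @param comp Composition matrix (rows named by cell id).
#' @param labels Module labels named by cell id.
#' @param min_cosine Similarity threshold (default 0.85).
#' @return Relabelled module vector (labels renumbered 1..K by size).
#' @export
merge_similar_modules <- function(comp, labels, min_cosine = 0.85) {
  comp <- l2_normalize_rows(comp[names(labels), , drop = FALSE])
  repeat {
    mods <- sort(unique(labels))
    if (length(mods) < 2) break
    centro <- t(vapply(mods, function(m)
      colMeans(comp[labels == m, , drop = FALSE]), numeric(ncol(comp))))
    centro <- l2_normalize_rows(centro)
    sim <- tcrossprod(centro)
    diag(sim) <- -Inf
    best <- which(sim == max(sim), arr.ind = TRUE)[1, ]
    if (sim[best[1], best[2]] < min_cosine) break
    keep <- mods[min(best)]
    labels[labels == mods[max(best)]] <- keep
  }
  relabel <- rank(-table(labels), ties.method = "first")
  setNames(as.character(relabel[labels]), names(labels))
}

#' Two-level spatial module detection
#'
#' Level 1 clusters all (non-excluded) cells on subclass composition vectors
#' with bandwidth multiplier 2. Level 2 re-clusters the neurons of each
#' level-1 module separately on the concatenation of their subclass- and
#' cluster-level composition vectors with bandwidth multiplier 1, giving
#' nested ids `"L1.L2"`. Non-neurons receive level-1 ids only.
#'
#' @param cells Cell table with `subclass` and `cluster` labels.
#' @param neuronal_subclasses Character vector of subclasses considered
#'   neuronal (used to restrict level 2).
#' @param exclude Types excluded entirely (vascular/immune; default none).
#' @param k Spatial neighbourhood size (default 50).
#' @param resolution_l1,resolution_l2 Leiden resolutions (defaults 1 and 2).
#' @param min_cells Minimum module size before small-module merging (default
#'   0 = no merging).
#' @param seed Integer seed.
#' @return An object of class `spatial_modules`: list with `assignment`
#'   (tibble `cell_id`, `module_l1`, `module_l2`) and parameters.
#' @export
two_level_modules <- function(cells, neuronal_subclasses,
                              exclude = character(), k = 50,
                              resolution_l1 = 1, resolution_l2 = 2,
                              min_cells = 0, seed = 1L) {
  comp1 <- local_composition(cells, type_col = "subclass", k = k,
                             bandwidth_multiplier = 2, exclude = exclude)
  l1 <- cluster_compositions(comp1, resolution = resolution_l1, seed = seed)
  included <- cells[cells$cell_id %in% names(l1), , drop = FALSE]
  if (min_cells > 0) {
    l1 <- merge_small_modules(included, l1, min_cells = min_cells)
  }
  assignment <- tibble(cell_id = names(l1), module_l1 = unname(l1),
                       module_l2 = NA_character_)
  neurons <- included[included$subclass %in% neuronal_subclasses, ,
                      drop = FALSE]
  for (m in sort(unique(l1))) {
    ids <- names(l1)[l1 == m]
    sub <- neurons[neurons$cell_id %in% ids, , drop = FALSE]
    if (nrow(sub) < k + 5) {
      warn(sprintf("level-1 module %s has %d neurons; level 2 skipped",
                   m, nrow(sub)))
      next
    }
    comp_sc <- try_composition(sub, "subclass", k)
    comp_cl <- try_composition(sub, "cluster", k)
    if (is.null(comp_sc) || is.null(comp_cl)) {
      warn(sprintf("level-1 module %s: composition failed; level 2 skipped", m))
      next
    }
    comp2 <- cbind(comp_sc, comp_cl)
    l2 <- cluster_compositions(comp2, resolution = resolution_l2, seed = seed)
    if (min_cells > 0) {
      l2 <- merge_small_modules(sub, l2, min_cells = min_cells)
    }
    rows <- match(names(l2), assignment$cell_id)
    assignment$module_l2[rows] <- paste0(m, ".", unname(l2))
  }
  structure(list(assignment = assignment, cells = included,
                 params = list(k = k, resolution_l1 = resolution_l1,
                               resolution_l2 = resolution_l2,
                               exclude = exclude, min_cells = min_cells)),
            class = "spatial_modules")
}

try_composition <- function(cells, type_col, k) {
  tryCatch(local_composition(cells, type_col = type_col, k = k,
                             bandwidth_multiplier = 1),
           error = function(e) NULL)
}

#' Merge small modules into their most adjacent neighbour
#'
#' Modules below `min_cells` members are absorbed into the module holding
#' the majority of their members' spatial neighbours — a programmatic
#' surrogate for merging clusters without clear spatial boundaries.
#' Iterates smallest-first until a fixed point.
#'
#' @param cells Cell table covering the labelled cells.
#' @param labels Character module labels named by cell id.
#' @param min_cells Minimum module size (modules below it are merged).
#' @param k_adj Spatial neighbours consulted per cell (default 10).
#' @return Updated labels vector.
#' @export
merge_small_modules <- function(cells, labels, min_cells, k_adj = 10) {
  cells <- cells[match(names(labels), cells$cell_id), , drop = FALSE]
  co <- section_offset_coords(cells)
  k_eff <- min(k_adj, nrow(cells) - 1L)
  if (k_eff < 1) return(labels)
  nn <- knn_within(cbind(co$x, co$y), k_eff)$index
  repeat {
    sizes <- table(labels)
    small <- names(sizes)[sizes < min_cells]
    if (length(small) == 0 || length(sizes) == 1) break
    victim <- small[order(sizes[small], small)][1]
    members <- which(labels == victim)
    neigh_labels <- labels[as.vector(nn[members, , drop = FALSE])]
    neigh_labels <- neigh_labels[neigh_labels != victim]
    if (length(neigh_labels) == 0) {
      # spatially isolated: absorb into the largest module
      target <- names(sizes)[order(-sizes, names(sizes))][1]
      if (target == victim) break
    } else {
      tab <- sort(table(neigh_labels), decreasing = TRUE)
      target <- names(tab)[1]
    }
    labels[members] <- target
  }
  labels
}

#' Per-module type-composition summary
#'
#' Fractions of cells in each spatial module belonging to each type.
#'
#' @param modules A `spatial_modules` object.
#' @param level `"l1"` or `"l2"`.
#' @param type_col Cell-type column (default `"subclass"`).
#' @return Tibble with `module`, `type`, `n`, `fraction`.
#' @export
module_composition_summary <- function(modules, level = c("l1", "l2"),
                                       type_col = "subclass") {
  level <- match.arg(level)
  col <- paste0("module_", level)
  df <- dplyr::inner_join(modules$assignment,
                          modules$cells[, c("cell_id", type_col)],
                          by = "cell_id")
  df <- df[!is.na(df[[col]]), ]
  df |>
    dplyr::count(module = .data[[col]], type = .data[[type_col]], name = "n") |>
    dplyr::group_by(.data$module) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' @export
print.spatial_modules <- function(x, ...) {
  n1 <- length(unique(x$assignment$module_l1))
  n2 <- length(unique(stats::na.omit(x$assignment$module_l2)))
  cat(sprintf("<spatial_modules> %d cells: %d level-1 modules, %d level-2 modules\n",
              nrow(x$assignment), n1, n2))
  invisible(x)
}

#' @method tidy spatial_modules
#' @export
tidy.spatial_modules <- function(x, ...) x$assignment

#' @method glance spatial_modules
#' @export
glance.spatial_modules <- function(x, ...) {
  tibble(n_cells = nrow(x$assignment),
         n_modules_l1 = length(unique(x$assignment$module_l1)),
         n_modules_l2 = length(unique(stats::na.omit(x$assignment$module_l2))))
}

#' @method autoplot spatial_modules
#' @export
autoplot.spatial_modules <- function(object, level = "l1", ...) {
  col <- paste0("module_", level)
  df <- dplyr::inner_join(object$assignment,
                          object$cells[, c("cell_id", "x", "y", "section_id")],
                          by = "cell_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data[[col]])) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::facet_wrap(~section_id) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "module", x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}
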