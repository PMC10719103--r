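#' Simulation configuration
#'
#' Defines the synthetic study conditions used throughout the test-bench:
#' per-section 2D Poisson point patterns of cell types inside rectangular
#' spatial domains, negative-binomial counts from cluster-specific means
#' (volume-scaled, optionally with log-linear spatial gradients), optional
#' pairwise spatial attraction between designated type pairs, a larger-panel
#' single-cell reference drawn from the same cluster means, and
#' proximity-conditional ligand-receptor upregulation.
#'
#' Defaults emulate a small two-section experiment: 8 subclasses of 2
#' clusters each at 2,500 cells per mm^2 over 1 mm^2 sections (about 5,000
#' cells), 120 panel genes inside a 180-gene reference, negative-binomial
#' dispersion 2, 5 z-planes with log-normal volumes centred at 500 um^3, and
#' a 4 percent doublet fraction (typical of whole-brain MERFISH QC).
#'
#' @param n_sections Number of tissue sections.
#' @param section_extent `c(width, height)` of each section in micrometres.
#' @param domains List of domains, each
#'   `list(xmin=, xmax=, ymin=, ymax=, composition = c(subclass = weight))`
#'   with weights summing to 1. Default: one full-section domain with equal
#'   weights over all subclasses.
#' @param cluster_means Clusters x genes matrix of mean counts (rownames =
#'   cluster names, colnames = panel genes).
#' @param cluster_subclass Named character vector mapping each cluster to its
#'   subclass.
#' @param reference_means Clusters x reference-genes matrix; the panel genes
#'   must be a subset of its columns. Defaults to `cluster_means` plus extra
#'   cluster-varying genes.
#' @param base_intensity Cells per mm^2.
#' @param dispersion Negative-binomial size parameter; `Inf` switches to
#'   Poisson counts.
#' @param attraction_rules List of
#'   `list(type_a=, type_b=, radius=, strength=)`; a fraction `strength`
#'   (capped at 1) of type-B cells is relocated within `radius` of a random
#'   type-A cell in the same section.
#' @param gradient_rules List of
#'   `list(subclass=, axis=c(ax, ay), genes=, slope=)`; the mean of each
#'   listed gene gains a factor `exp(slope * t)` where `t` is the cell's
#'   section-centred coordinate along the unit axis, in micrometres.
#' @param lr_rules List of
#'   `list(type_a=, type_b=, pair_name=, fold=, radius=)` applied by
#'   [apply_lr_upregulation()].
#' @param doublet_fraction Fraction of cells flagged as doublets (score drawn
#'   above the 0.25 calling threshold; the rest below).
#' @param n_zplanes Number of imaged z-planes per cell (3, 5 or 6).
#' @param volume_meanlog,volume_sdlog Log-normal volume parameters (um^3).
#' @param seed Integer seed; all draws are deterministic given it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_sections = 2,
                       section_extent = c(1000, 1000),
                       domains = NULL,
                       cluster_means = NULL,
                       cluster_subclass = NULL,
                       reference_means = NULL,
                       base_intensity = 2500,
                       dispersion = 2,
                       attraction_rules = list(),
                       gradient_rules = list(),
                       lr_rules = list(),
                       doublet_fraction = 0.04,
                       n_zplanes = 5,
                       volume_meanlog = log(500),
                       volume_sdlog = 0.3,
                       seed = 1L) {
  if (is.null(cluster_means)) {
    d <- default_cluster_means(seed = seed)
    cluster_means <- d$means
    cluster_subclass <- d$subclass
    if (is.null(reference_means)) reference_means <- d$reference_means
  }
  if (is.null(cluster_subclass)) {
    abort("`cluster_subclass` is required when `cluster_means` is supplied")
  }
  if (is.null(reference_means)) {
    reference_means <- cluster_means
  }
  stopifnot(all(rownames(cluster_means) %in% names(cluster_subclass)))
  if (!all(colnames(cluster_means) %in% colnames(reference_means))) {
    abort("panel genes must be a subset of the reference gene set")
  }
  subclasses <- sort(unique(unname(cluster_subclass)))
  if (is.null(domains)) {
    domains <- list(list(xmin = 0, xmax = section_extent[1],
                         ymin = 0, ymax = section_extent[2],
                         composition = setNames(rep(1 / length(subclasses),
                                                    length(subclasses)),
                                                subclasses)))
  }
  for (d in domains) {
    if ((d$xmax - d$xmin) <= 0 || (d$ymax - d$ymin) <= 0) {
      abort("zero-area domain in configuration")
    }
    if (abs(sum(d$composition) - 1) > 1e-8) {
      abort("domain composition weights must sum to 1")
    }
  }
  for (r in attraction_rules) {
    if (r$strength < 0) abort("attraction strength must be >= 0")
    if (r$radius <= 0) abort("attraction radius must be positive")
  }
  for (r in lr_rules) if (r$fold < 1) abort("LR upregulation fold must be >= 1")
  if (!n_zplanes %in% c(3, 5, 6)) abort("n_zplanes must be 3, 5 or 6")
  structure(
    list(n_sections = n_sections, section_extent = section_extent,
         domains = domains, cluster_means = cluster_means,
         cluster_subclass = cluster_subclass,
         reference_means = reference_means,
         base_intensity = base_intensity, dispersion = dispersion,
         attraction_rules = attraction_rules, gradient_rules = gradient_rules,
         lr_rules = lr_rules, doublet_fraction = doublet_fraction,
         n_zplanes = n_zplanes, volume_meanlog = volume_meanlog,
         volume_sdlog = volume_sdlog, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Default cluster mean-expression structure
#'
#' Block-marker means: each subclass owns a block of strongly expressed
#' marker genes, each cluster a smaller block on top, over a low background —
#' the minimal structure under which type calling, label transfer and panel
#' selection are all well-posed. The reference adds extra (non-panel) genes
#' with log-normal cluster-varying means for imputation tests.
#'
#' @param n_subclasses,clusters_per_subclass Taxonomy size.
#' @param genes_per_subclass,genes_per_cluster Marker block sizes.
#' @param n_extra_panel Non-marker panel genes with uniform background mean.
#' @param n_reference_extra Reference-only genes.
#' @param base,subclass_level,cluster_level Mean counts for background,
#'   subclass markers and cluster markers.
#' @param seed Seed for the random reference-only means.
#' @return List with `means`, `subclass` (cluster to subclass map) and
#'   `reference_means`.
#' @export
default_cluster_means <- function(n_subclasses = 8, clusters_per_subclass = 2,
                                  genes_per_subclass = 8, genes_per_cluster = 4,
                                  n_extra_panel = 24, n_reference_extra = 60,
                                  base = 0.2, subclass_level = 15,
                                  cluster_level = 8, seed = 1L) {
  subclasses <- sprintf("SC%02d", seq_len(n_subclasses))
  clusters <- as.vector(t(outer(subclasses, seq_len(clusters_per_subclass),
                                function(s, k) paste0(s, "_", k))))
  cluster_subclass <- setNames(rep(subclasses, each = clusters_per_subclass),
                               clusters)
  n_marker <- n_subclasses * genes_per_subclass +
    length(clusters) * genes_per_cluster
  genes <- sprintf("g%03d", seq_len(n_marker + n_extra_panel))
  means <- matrix(base, nrow = length(clusters), ncol = length(genes),
                  dimnames = list(clusters, genes))
  gi <- 0
  for (s in seq_along(subclasses)) {
    cols <- gi + seq_len(genes_per_subclass)
    means[cluster_subclass == subclasses[s], cols] <- subclass_level
    gi <- gi + genes_per_subclass
  }
  for (cl in seq_along(clusters)) {
    cols <- gi + seq_len(genes_per_cluster)
    means[cl, cols] <- means[cl, cols] + cluster_level
    gi <- gi + genes_per_cluster
  }
  check_seed(seed)
  extra <- matrix(exp(rnorm(length(clusters) * n_reference_extra, 0, 1)),
                  nrow = length(clusters),
                  dimnames = list(clusters,
                                  sprintf("ref%03d", seq_len(n_reference_extra))))
  list(means = means, subclass = cluster_subclass,
       reference_means = cbind(means, extra))
}

#' Simulate segmented cells with known ground truth
#'
#' Per section, each subclass forms a homogeneous Poisson point pattern
#' within each spatial domain at intensity `base_intensity * weight`;
#' clusters are drawn uniformly within the subclass; volumes are log-normal;
#' a configured fraction of cells is flagged as doublets. Attraction rules,
#' if any, are applied afterwards via [apply_attraction()] by
#' [simulate_dataset()], not here.
#'
#' @param config A [sim_config()].
#' @return A list with `cells` (cell table tibble) and `truth` (tibble with
#'   per-cell true domain, subclass, cluster and doublet flag).
#' @export
simulate_cells <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  check_seed(config$seed)
  subclass_clusters <- split(names(config$cluster_subclass),
                             unname(config$cluster_subclass))
  rows <- list()
  for (sec in seq_len(config$n_sections)) {
    for (di in seq_along(config$domains)) {
      d <- config$domains[[di]]
      area_mm2 <- (d$xmax - d$xmin) * (d$ymax - d$ymin) / 1e6
      for (s in names(d$composition)) {
        w <- d$composition[[s]]
        if (w <= 0) next
        n <- rpois(1, config$base_intensity * w * area_mm2)
        if (n == 0) next
        rows[[length(rows) + 1]] <- tibble(
          section_id = sprintf("sec%02d", sec),
          x = runif(n, d$xmin, d$xmax),
          y = runif(n, d$ymin, d$ymax),
          domain = paste0("D", di),
          subclass = s,
          cluster = sample(subclass_clusters[[s]], n, replace = TRUE)
        )
      }
    }
  }
  cells <- dplyr::bind_rows(rows)
  n <- nrow(cells)
  cells$cell_id <- sprintf("cell%06d", seq_len(n))
  cells$volume <- exp(rnorm(n, config$volume_meanlog, config$volume_sdlog))
  cells$n_zplanes <- config$n_zplanes
  is_doublet <- runif(n) < config$doublet_fraction
  cells$doublet_score <- ifelse(is_doublet, runif(n, 0.3, 1), runif(n, 0, 0.2))
  cells$subclass_confidence <- 1
  cells$cluster_confidence <- 1
  truth <- tibble(cell_id = cells$cell_id, domain = cells$domain,
                  subclass = cells$subclass, cluster = cells$cluster,
                  is_doublet = is_doublet)
  cells$domain <- NULL
  list(cells = validate_cell_table(cells), truth = truth)
}

#' Relocate cells to create pairwise spatial attraction
#'
#' A fraction `strength` (capped at 1) of type-B cells is moved to a uniform
#' position within `radius` of a randomly chosen type-A cell in the same
#' section. Relocation rather than thinning keeps per-type cell counts
#' fixed, so downstream proximity tests are driven purely by pairing, not
#' abundance.
#'
#' @param cells Cell table.
#' @param rule `list(type_a=, type_b=, radius=, strength=)` (subclass names).
#' @param seed Optional integer seed.
#' @return The modified cell table.
#' @export
apply_attraction <- function(cells, rule, seed = NULL) {
  if (rule$radius <= 0) abort("attraction radius must be positive")
  strength <- min(rule$strength, 1)
  if (strength == 0) return(cells)
  check_seed(seed)
  for (sec in unique(cells$section_id)) {
    in_sec <- cells$section_id == sec
    ia <- which(in_sec & cells$subclass == rule$type_a)
    ib <- which(in_sec & cells$subclass == rule$type_b)
    if (length(ia) == 0 || length(ib) == 0) next
    n_move <- rbinom(1, length(ib), strength)
    if (n_move == 0) next
    move <- sample(ib, n_move)
    # distinct hosts where possible, so attraction induces A-B pairing
    # without clumping the moved B cells around shared A cells
    host <- if (n_move <= length(ia)) sample(ia, n_move) else
      sample(ia, n_move, replace = TRUE)
    # uniform in the disk of `radius` around the host cell
    r <- rule$radius * sqrt(runif(n_move))
    th <- runif(n_move, 0, 2 * pi)
    cells$x[move] <- cells$x[host] + r * cos(th)
    cells$y[move] <- cells$y[host] + r * sin(th)
  }
  cells
}

#' Simulate panel counts for simulated cells
#'
#' Counts are negative-binomial with mean equal to the cell's cluster mean
#' scaled by its volume (relative to the configured median volume) and the
#' configured dispersion (`Inf` = Poisson). Gradient rules multiply the mean
#' of listed genes by `exp(slope * t)`, `t` being the section-centred
#' coordinate along the rule axis.
#'
#' @param cells Cell table with `cluster` labels covered by the config means.
#' @param config A [sim_config()].
#' @param seed Optional seed (defaults to `config$seed + 1`).
#' @return An [expr_set()] with the `"raw"` layer.
#' @export
simulate_expression <- function(cells, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  mu_tab <- config$cluster_means
  if (any(mu_tab < 0)) abort("negative cluster mean expression")
  miss <- setdiff(unique(cells$cluster), rownames(mu_tab))
  if (length(miss) > 0) {
    abort(sprintf("no mean vector for cluster(s): %s",
                  paste(head(miss, 5), collapse = ", ")))
  }
  check_seed(seed)
  ref_vol <- exp(config$volume_meanlog)
  mu <- mu_tab[cells$cluster, , drop = FALSE] * (cells$volume / ref_vol)
  for (g in config$gradient_rules) {
    sel <- cells$subclass == g$subclass
    if (!any(sel)) next
    ax <- g$axis / sqrt(sum(g$axis^2))
    t_raw <- cells$x * ax[1] + cells$y * ax[2]
    t_cen <- t_raw - stats::ave(t_raw, cells$section_id)
    gene_cols <- match(g$genes, colnames(mu))
    if (anyNA(gene_cols)) abort("gradient rule names unknown gene(s)")
    mu[sel, gene_cols] <- mu[sel, gene_cols] * exp(g$slope * t_cen[sel])
  }
  counts <- draw_counts(mu, config$dispersion)
  rownames(counts) <- cells$cell_id
  expr_set(counts)
}

draw_counts <- function(mu, dispersion) {
  n <- length(mu)
  v <- if (is.infinite(dispersion)) rpois(n, as.vector(mu)) else
    rnbinom(n, size = dispersion, mu = as.vector(mu))
  matrix(v, nrow = nrow(mu), dimnames = dimnames(mu))
}

#' Upregulate ligand-receptor genes in proximal cells
#'
#' For type-A cells within `radius` of any type-B cell (same section), raw
#' counts of the rule's ligand-component genes are multiplied by `fold`;
#' receptor components likewise in the B cells proximal to any A cell. All
#' other cells are untouched; `fold = 1` is an exact identity.
#'
#' @param expr An [expr_set()] aligned with `cells`.
#' @param cells Cell table.
#' @param rule `list(type_a=, type_b=, pair_name=, fold=, radius=)`.
#' @param lr_db LR database tibble (see [lr_database()]) resolving
#'   `pair_name` to component genes.
#' @return The modified [expr_set()].
#' @export
apply_lr_upregulation <- function(expr, cells, rule, lr_db) {
  if (rule$fold == 1) return(expr)
  entry <- lr_db[lr_db$pair_name == rule$pair_name, ]
  if (nrow(entry) != 1) abort(sprintf("unknown LR pair '%s'", rule$pair_name))
  lig <- entry$ligand_components[[1]]
  rec <- entry$receptor_components[[1]]
  unknown <- setdiff(c(lig, rec), expr$genes)
  if (length(unknown) > 0) {
    abort(sprintf("unknown gene(s) in LR rule: %s", paste(unknown, collapse = ", ")))
  }
  co <- section_offset_coords(cells)
  ia <- which(cells$subclass == rule$type_a)
  ib <- which(cells$subclass == rule$type_b)
  if (length(ia) == 0 || length(ib) == 0) return(expr)
  pr <- pairs_within_radius(co$x[ia], co$y[ia], co$x[ib], co$y[ib], rule$radius)
  if (nrow(pr) == 0) return(expr)
  a_prox <- ia[unique(pr[, 1])]
  b_prox <- ib[unique(pr[, 2])]
  m <- expr_layer(expr, "raw")
  m[a_prox, lig] <- m[a_prox, lig] * rule$fold
  m[b_prox, rec] <- m[b_prox, rec] * rule$fold
  set_expr_layer(expr, "raw", m)
}

#' Simulate a labelled single-cell reference
#'
#' Draws reference cells from the same cluster means over the (larger)
#' reference gene set — panel genes are a subset — with no spatial
#' coordinates, emulating a dissociated scRNA-seq reference.
#'
#' @param config A [sim_config()].
#' @param n_per_cluster Cells per cluster.
#' @param seed Optional seed (defaults to `config$seed + 2`).
#' @return List with `expr` ([expr_set()]) and `labels` (tibble `cell_id`,
#'   `subclass`, `cluster`).
#' @export
simulate_reference <- function(config, n_per_cluster = 250,
                               seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  check_seed(seed)
  clusters <- rownames(config$reference_means)
  lab <- rep(clusters, each = n_per_cluster)
  mu <- config$reference_means[lab, , drop = FALSE]
  counts <- draw_counts(mu, config$dispersion)
  ids <- sprintf("ref%06d", seq_along(lab))
  rownames(counts) <- ids
  list(expr = expr_set(counts),
       labels = tibble(cell_id = ids,
                       subclass = unname(config$cluster_subclass[lab]),
                       cluster = lab))
}

#' Simulate a complete dataset
#'
#' Runs [simulate_cells()], applies all attraction rules, draws panel counts,
#' applies LR upregulation rules, and draws the reference. Ground truth lists
#' the truly attracted type pairs and truly upregulated LR pairs.
#'
#' @param config A [sim_config()].
#' @param lr_db Optional LR database; required when `lr_rules` are set.
#' @param n_reference_per_cluster Reference cells per cluster.
#' @return List with `cells`, `expr`, `reference`, `truth`, `config`.
#' @export
simulate_dataset <- function(config = sim_config(), lr_db = NULL,
                             n_reference_per_cluster = 250) {
  sim <- simulate_cells(config)
  cells <- sim$cells
  for (i in seq_along(config$attraction_rules)) {
    cells <- apply_attraction(cells, config$attraction_rules[[i]],
                              seed = config$seed + 100L + i)
  }
  expr <- simulate_expression(cells, config)
  for (i in seq_along(config$lr_rules)) {
    if (is.null(lr_db)) abort("lr_db required when lr_rules are configured")
    expr <- apply_lr_upregulation(expr, cells, config$lr_rules[[i]], lr_db)
  }
  reference <- simulate_reference(config, n_per_cluster = n_reference_per_cluster)
  truth <- sim$truth
  attr(truth, "attracted_pairs") <- lapply(config$attraction_rules, function(r)
    c(type_a = r$type_a, type_b = r$type_b))
  attr(truth, "lr_pairs") <- lapply(config$lr_rules, function(r)
    c(type_a = r$type_a, type_b = r$type_b, pair_name = r$pair_name))
  list(cells = cells, expr = expr, reference = reference, truth = truth,
       config = config)
}

#' Write simulation ground truth
#'
#' Per-cell truth as CSV plus a JSON manifest of attracted type pairs and
#' upregulated LR pairs.
#'
#' @param truth Truth tibble from [simulate_dataset()].
#' @param dir Output directory.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(truth, file.path(dir, "ground_truth.csv"), na = "")
  manifest <- list(
    attracted_pairs = lapply(attr(truth, "attracted_pairs") %||% list(), as.list),
    lr_pairs = lapply(attr(truth, "lr_pairs") %||% list(), as.list))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
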