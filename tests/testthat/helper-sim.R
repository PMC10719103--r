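# Shared fixture builders. All fixtures are generated in code at test time.

rect_domain <- function(xmin, xmax, ymin, ymax, composition) {
  list(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
       composition = composition)
}

# Flat cluster-mean matrix: every cluster the same mean for every gene.
flat_means <- function(clusters, genes, value = 2) {
  matrix(value, length(clusters), length(genes),
         dimnames = list(clusters, genes))
}

# Four subclasses x two clusters with uninformative expression; used for
# spatial tests where only positions and labels matter.
spatial_test_config <- function(domains = NULL, seed = 7,
                                base_intensity = 3000,
                                n_sections = 1, section_extent = c(1000, 1000),
                                ...) {
  subs <- sprintf("S%d", 1:4)
  cls <- as.vector(outer(subs, 1:2, function(s, k) paste0(s, "_", k)))
  sim_config(n_sections = n_sections, section_extent = section_extent,
             domains = domains,
             cluster_means = flat_means(cls, sprintf("g%02d", 1:40), 0.2),
             cluster_subclass = setNames(sub("_.*", "", cls), cls),
             base_intensity = base_intensity, seed = seed, ...)
}

# Small cell table laid out by hand for geometry tests.
manual_cells <- function(x, y, subclass, section_id = "sec01",
                         cluster = subclass) {
  tibble::tibble(cell_id = sprintf("c%03d", seq_along(x)),
                 section_id = section_id, x = x, y = y,
                 volume = 500, n_zplanes = 5,
                 subclass = subclass, cluster = cluster)
}

# Minimal expr_set from a dense matrix with generated ids.
quick_expr <- function(m, cells = sprintf("c%03d", seq_len(nrow(m))),
                       genes = sprintf("g%03d", seq_len(ncol(m)))) {
  dimnames(m) <- NULL
  expr_set(m, cells = cells, genes = genes)
}

# Independent step-up BH oracle (kept deliberately naive).
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Adjusted Rand index between two labelings (contingency-table formula).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# Benchmark taxonomy for integration tests: 5 subclasses x 3 clusters over a
# 200-gene panel (8 subclass + 8 cluster markers per type, 40 background
# genes) inside a 260-gene reference.
integration_benchmark <- function(seed_means = 2, seed_sim = 3,
                                  n_ref_per_cluster = 134) {
  d <- default_cluster_means(n_subclasses = 5, clusters_per_subclass = 3,
                             genes_per_subclass = 8, genes_per_cluster = 8,
                             n_extra_panel = 40, n_reference_extra = 60,
                             seed = seed_means)
  cfg <- sim_config(cluster_means = d$means, cluster_subclass = d$subclass,
                    reference_means = d$reference_means,
                    base_intensity = 1000, seed = seed_sim)
  simulate_dataset(cfg, n_reference_per_cluster = n_ref_per_cluster)
}

# Benchmark for the LR screen: sparse tissue (so that proximity to the
# partner type is the exception), 16 moderately expressed signalling genes
# paired into an 8-entry database (one two-component receptor complex).
lr_benchmark_config <- function(seed = 9, fold = 4, rule_radius = 30,
                                with_rule = TRUE) {
  d <- default_cluster_means(seed = 2)
  sig <- tail(colnames(d$means), 16)
  d$means[, sig] <- 2
  d$reference_means[, sig] <- 2
  db <- lr_database(
    pair_name = paste0("P", 1:8),
    ligand = sig[seq(1, 16, 2)],
    receptor = c(sig[seq(2, 16, 2)][1:7], paste0(sig[16], "_", sig[2])),
    pathway = rep(c("WNT", "BMP"), 4))
  rules <- if (with_rule)
    list(list(type_a = "SC01", type_b = "SC02", pair_name = "P3",
              fold = fold, radius = rule_radius)) else list()
  cfg <- sim_config(section_extent = c(2000, 2000), base_intensity = 480,
                    cluster_means = d$means, cluster_subclass = d$subclass,
                    reference_means = d$reference_means, seed = seed,
                    lr_rules = rules)
  list(config = cfg, db = db, signalling_genes = sig)
}
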