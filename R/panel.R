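#' Screen differentially expressed marker candidates
#'
#' For every ordered pair of clusters (foreground, background), retains
#' genes satisfying all of: fold change >= 2 between the cluster means,
#' two-sided Wilcoxon rank-sum p < 0.01, expressed in at least 50% of
#' foreground cells, and expressing-fraction enrichment over the background
#' above 3.3-fold (a background fraction of zero counts as infinite
#' enrichment). Within each pair and direction only the `top_n` genes with
#' the smallest p-values are kept.
#'
#' @param ref_expr Reference [expr_set()] (raw counts; a gene counts as
#'   expressed in a cell when its value is positive).
#' @param clusters Character cluster label per reference cell (each cluster
#'   needs at least 2 cells).
#' @param fold_threshold,p_threshold,min_fraction,fraction_ratio Screening
#'   criteria (defaults 2, 0.01, 0.5, 3.3).
#' @param top_n Genes kept per pair and direction, ranked by p (default 50).
#' @return Tibble of candidates with `gene`, `foreground`, `background`,
#'   `fold_change`, `p_value`, `fraction_fg`, `fraction_bg`,
#'   `fraction_ratio`.
#' @export
screen_deg_candidates <- function(ref_expr, clusters, fold_threshold = 2,
                                  p_threshold = 0.01, min_fraction = 0.5,
                                  fraction_ratio = 3.3, top_n = 50) {
  m <- expr_layer(ref_expr, "raw")
  ucl <- sort(unique(clusters))
  if (length(ucl) < 2) abort("need at least 2 clusters")
  sizes <- table(factor(clusters, levels = ucl))
  if (any(sizes < 2)) {
    abort(sprintf("cluster(s) with fewer than 2 cells: %s",
                  paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  means <- rowsum(m, clusters) / as.vector(sizes[ucl])
  fracs <- rowsum((m > 0) * 1, clusters) / as.vector(sizes[ucl])
  rows <- list()
  for (fg in ucl) for (bg in ucl) {
    if (fg == bg) next
    fold <- means[fg, ] / pmax(means[bg, ], .Machine$double.eps)
    frac_fg <- fracs[fg, ]
    frac_bg <- fracs[bg, ]
    ratio <- ifelse(frac_bg == 0, Inf, frac_fg / frac_bg)
    pass1 <- fold >= fold_threshold & frac_fg >= min_fraction &
      ratio > fraction_ratio
    if (!any(pass1)) next
    genes <- ref_expr$genes[pass1]
    xf <- m[clusters == fg, genes, drop = FALSE]
    xb <- m[clusters == bg, genes, drop = FALSE]
    pv <- vapply(seq_along(genes), function(j)
      suppressWarnings(wilcox.test(xf[, j], xb[, j])$p.value), 0)
    keep <- pv < p_threshold
    if (!any(keep)) next
    df <- tibble(gene = genes[keep], foreground = fg, background = bg,
                 fold_change = unname(fold[pass1][keep]),
                 p_value = pv[keep],
                 fraction_fg = unname(frac_fg[pass1][keep]),
                 fraction_bg = unname(frac_bg[pass1][keep]),
                 fraction_ratio = unname(ratio[pass1][keep]))
    df <- df[order(df$p_value, df$gene), , drop = FALSE]
    rows[[paste(fg, bg)]] <- head(df, top_n)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    tibble(gene = character(), foreground = character(),
           background = character(), fold_change = numeric(),
           p_value = numeric(), fraction_fg = numeric(),
           fraction_bg = numeric(), fraction_ratio = numeric())
  } else out
}

#' Filter candidates on imaging feasibility
#'
#' Removes genes that can accommodate fewer than 40 hybridisation probes
#' (too short) or are expressed at more than 3,000 mean counts in their
#' highest-expressing cluster (too abundant for combinatorial imaging).
#' Boundary values (exactly 40 probes, exactly 3,000 counts) are retained.
#'
#' @param candidates Candidate tibble from [screen_deg_candidates()].
#' @param gene_meta Tibble with `gene`, `probe_capacity`,
#'   `max_cluster_mean` covering every candidate gene.
#' @param min_probes,max_mean Thresholds (defaults 40 and 3,000).
#' @return List with `candidates` (filtered) and `excluded` (tibble of
#'   `gene`, `reason`).
#' @export
filter_panel_constraints <- function(candidates, gene_meta, min_probes = 40,
                                     max_mean = 3000) {
  missing <- setdiff(unique(candidates$gene), gene_meta$gene)
  if (length(missing) > 0) {
    abort(sprintf("gene_meta missing candidate gene(s): %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  meta <- gene_meta[match(unique(candidates$gene), gene_meta$gene), ]
  short <- meta$gene[meta$probe_capacity < min_probes]
  abundant <- meta$gene[meta$max_cluster_mean > max_mean]
  excluded <- dplyr::bind_rows(
    tibble(gene = short, reason = sprintf("fewer than %d probes", min_probes)),
    tibble(gene = setdiff(abundant, short),
           reason = sprintf("mean counts above %d in top cluster", max_mean)))
  list(candidates = candidates[!candidates$gene %in% c(short, abundant), ,
                               drop = FALSE],
       excluded = excluded)
}

#' Greedy completion of an imaging gene panel
#'
#' Starting from a seed gene set (curated markers), iteratively adds the
#' candidate gene covering the most (cluster pair, direction) slots that
#' still have fewer than `target_per_pair` selected discriminative genes.
#' Ties break to the gene with the smallest aggregate p-value over the
#' deficient slots it covers, then lexicographically. The search stops when
#' every pair has at least `target_per_pair` genes per direction or no gene
#' improves coverage; residual deficits are reported.
#'
#' @param candidates Candidate tibble (a gene covers slot
#'   `(foreground, background)` when it has a candidate row for it).
#' @param seed_genes Character vector of pre-selected genes (may be empty).
#' @param target_per_pair Required genes per ordered cluster pair
#'   (default 3).
#' @return Object of class `panel_report`: list with `selected` (all panel
#'   genes), `added` (greedy additions in order), `coverage` (per-slot
#'   counts) and `uncovered` (slots that cannot reach the target).
#' @export
greedy_complete_panel <- function(candidates, seed_genes = character(),
                                  target_per_pair = 3) {
  if (nrow(candidates) == 0) abort("empty candidate table")
  candidates$slot <- paste(candidates$foreground, candidates$background,
                           sep = " -> ")
  slots <- sort(unique(candidates$slot))
  cover <- split(candidates[, c("gene", "p_value")], candidates$slot)
  gene_slots <- split(candidates[, c("slot", "p_value")], candidates$gene)
  count <- setNames(integer(length(slots)), slots)
  for (s in slots) {
    count[s] <- sum(unique(cover[[s]]$gene) %in% seed_genes)
  }
  max_possible <- vapply(slots, function(s)
    length(unique(cover[[s]]$gene)), integer(1))
  selected <- unique(seed_genes)
  added <- character(0)
  pool <- setdiff(names(gene_slots), selected)
  repeat {
    deficient <- names(count)[count < pmin(target_per_pair, max_possible)]
    if (length(deficient) == 0 || length(pool) == 0) break
    gains <- vapply(pool, function(g) {
      sum(gene_slots[[g]]$slot %in% deficient)
    }, integer(1))
    if (max(gains) == 0) break
    best_gain <- pool[gains == max(gains)]
    aggp <- vapply(best_gain, function(g) {
      rows <- gene_slots[[g]]
      sum(rows$p_value[rows$slot %in% deficient])
    }, 0)
    pick <- best_gain[order(aggp, best_gain)][1]
    selected <- c(selected, pick)
    added <- c(added, pick)
    pool <- setdiff(pool, pick)
    hit <- gene_slots[[pick]]$slot
    count[hit] <- count[hit] + 1L
  }
  uncovered <- tibble(slot = names(count),
                      covered = as.integer(count),
                      achievable = pmin(target_per_pair, max_possible),
                      target = target_per_pair)
  uncovered <- uncovered[uncovered$covered < uncovered$target, , drop = FALSE]
  structure(list(selected = selected, added = added,
                 coverage = tibble(slot = names(count),
                                   covered = as.integer(count)),
                 uncovered = uncovered,
                 target_per_pair = target_per_pair),
            class = "panel_report")
}

#' @export
print.panel_report <- function(x, ...) {
  cat(sprintf("<panel_report> %d genes selected (%d greedy additions); %d slot(s) below target %d\n",
              length(x$selected), length(x$added), nrow(x$uncovered),
              x$target_per_pair))
  invisible(x)
}

#' @method tidy panel_report
#' @export
tidy.panel_report <- function(x, ...) x$coverage

#' @method glance panel_report
#' @export
glance.panel_report <- function(x, ...) {
  tibble(n_selected = length(x$selected), n_added = length(x$added),
         n_uncovered_slots = nrow(x$uncovered),
         target_per_pair = x$target_per_pair)
}
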