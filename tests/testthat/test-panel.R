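test_that("the DEG screen enforces all four criteria and the top-50 rule", {
  set.seed(33)
  n <- 60
  # gene 1: strong marker of k1; gene 2: good fold but weak fraction ratio;
  # gene 3: uninformative
  g1 <- c(rpois(n, 10), rpois(n, 0.1))
  g2 <- c(rpois(n, 5) + 1, c(rpois(n / 2, 2) + 1, rpois(n / 2, 1)))
  g3 <- rpois(2 * n, 4)
  ex <- quick_expr(cbind(g1, g2, g3), genes = c("m1", "m2", "m3"))
  cl <- rep(c("k1", "k2"), each = n)
  cand <- screen_deg_candidates(ex, cl)
  up1 <- cand[cand$foreground == "k1", ]
  expect_true("m1" %in% up1$gene)
  expect_false("m3" %in% cand$gene)
  # all retained rows satisfy the stated thresholds
  expect_true(all(cand$fold_change >= 2))
  expect_true(all(cand$p_value < 0.01))
  expect_true(all(cand$fraction_fg >= 0.5))
  expect_true(all(cand$fraction_ratio > 3.3))
  expect_error(screen_deg_candidates(ex, c("k1", rep("k2", 2 * n - 1))),
               "fewer than 2")
})

test_that("a fraction ratio at or below 3.3 excludes the gene", {
  # construct exact fractions: fg 0.6, bg 0.2 -> ratio 3.0 (excluded);
  # fg 0.6, bg 0.1 -> ratio 6.0 (kept if other criteria hold)
  n <- 100
  gA <- c(rep(5, 60), rep(0, 40), rep(5, 20), rep(0, 80))   # ratio 3.0
  gB <- c(rep(5, 60), rep(0, 40), rep(5, 10), rep(0, 90))   # ratio 6.0
  ex <- quick_expr(cbind(gA, gB), genes = c("gA", "gB"))
  cl <- rep(c("k1", "k2"), each = n)
  cand <- screen_deg_candidates(ex, cl)
  k1 <- cand[cand$foreground == "k1", ]
  expect_false("gA" %in% k1$gene)
  expect_true("gB" %in% k1$gene)
})

test_that("only the 50 smallest p-values survive per pair and direction", {
  set.seed(34)
  n <- 40
  m <- sapply(1:60, function(g) c(rpois(n, 12), rpois(n, 0.15)))
  ex <- quick_expr(m)
  cl <- rep(c("k1", "k2"), each = n)
  cand <- screen_deg_candidates(ex, cl)
  up <- cand[cand$foreground == "k1", ]
  expect_equal(nrow(up), 50)
  all_p <- sapply(1:60, function(g)
    suppressWarnings(wilcox.test(m[cl == "k1", g], m[cl == "k2", g])$p.value))
  expect_equal(sort(up$p_value), sort(all_p)[1:50], tolerance = 1e-12)
})

test_that("panel constraints exclude short and over-abundant genes, boundary kept", {
  cand <- tibble::tibble(gene = c("a", "b", "c", "d"),
                         foreground = "k1", background = "k2",
                         fold_change = 3, p_value = 1e-4,
                         fraction_fg = 0.8, fraction_bg = 0.1,
                         fraction_ratio = 8)
  meta <- tibble::tibble(gene = c("a", "b", "c", "d"),
                         probe_capacity = c(39, 40, 64, 64),
                         max_cluster_mean = c(100, 3000, 3001, 50))
  out <- filter_panel_constraints(cand, meta)
  expect_setequal(out$candidates$gene, c("b", "d"))
  expect_setequal(out$excluded$gene, c("a", "c"))
  expect_error(filter_panel_constraints(cand, meta[-1, ]), "missing")
})

test_that("greedy completion matches best-first search and never wastes picks", {
  # 3 clusters; gene G covers every deficient slot, others cover one each
  slots <- tidyr::expand_grid(foreground = c("k1", "k2", "k3"),
                              background = c("k1", "k2", "k3"))
  slots <- slots[slots$foreground != slots$background, ]
  all_cov <- tibble::tibble(gene = "G", foreground = slots$foreground,
                            background = slots$background,
                            p_value = 1e-5)
  single <- tibble::tibble(gene = paste0("s", seq_len(nrow(slots))),
                           foreground = slots$foreground,
                           background = slots$background, p_value = 1e-6)
  cand <- dplyr::bind_rows(all_cov, single)
  cand$fold_change <- 3; cand$fraction_fg <- 1
  cand$fraction_bg <- 0.1; cand$fraction_ratio <- 10
  rep1 <- greedy_complete_panel(cand, target_per_pair = 1)
  expect_equal(rep1$added[1], "G")    # brute-force best first pick
  expect_equal(nrow(rep1$uncovered), 0)

  # target met by seeds alone: zero additions
  rep2 <- greedy_complete_panel(all_cov, seed_genes = "G", target_per_pair = 1)
  expect_length(rep2$added, 0)

  # uncoverable slots are reported and the search still terminates
  partial <- all_cov[1:3, ]
  rep3 <- greedy_complete_panel(partial, target_per_pair = 2)
  expect_gt(nrow(rep3$uncovered), 0)
  expect_error(greedy_complete_panel(all_cov[0, ]), "empty")
})

test_that("greedy coverage recomputes exactly and picks are maximal stepwise", {
  set.seed(35)
  genes <- paste0("g", 1:30)
  pairs <- tidyr::expand_grid(foreground = paste0("k", 1:5),
                              background = paste0("k", 1:5))
  pairs <- pairs[pairs$foreground != pairs$background, ]
  rows <- list()
  for (g in genes) {
    hit <- pairs[sample(nrow(pairs), sample(2:6, 1)), ]
    rows[[g]] <- tibble::tibble(gene = g, foreground = hit$foreground,
                                background = hit$background,
                                p_value = runif(nrow(hit), 1e-8, 1e-3))
  }
  cand <- dplyr::bind_rows(rows)
  rep <- greedy_complete_panel(cand, target_per_pair = 3)
  # recompute coverage from scratch
  cand$slot <- paste(cand$foreground, cand$background, sep = " -> ")
  for (i in seq_len(nrow(rep$coverage))) {
    s <- rep$coverage$slot[i]
    expect_equal(rep$coverage$covered[i],
                 length(unique(cand$gene[cand$slot == s &
                                           cand$gene %in% rep$selected])))
  }
  # replay the greedy run: each pick must match the exhaustive best gain
  count <- setNames(rep(0L, length(unique(cand$slot))), sort(unique(cand$slot)))
  max_possible <- vapply(names(count), function(s)
    length(unique(cand$gene[cand$slot == s])), integer(1))
  pool <- unique(cand$gene)
  for (pick in rep$added) {
    deficient <- names(count)[count < pmin(3L, max_possible)]
    gains <- vapply(pool, function(g)
      length(unique(cand$slot[cand$gene == g & cand$slot %in% deficient])),
      integer(1))
    expect_equal(gains[[pick]], max(gains))
    expect_gt(gains[[pick]], 0)
    hit <- unique(cand$slot[cand$gene == pick])
    count[hit] <- count[hit] + 1L
    pool <- setdiff(pool, pick)
  }
})
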