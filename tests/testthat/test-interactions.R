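test_that("proximal pair counting matches the worked geometry", {
  cells <- manual_cells(c(0, 10, 0), c(0, 0, 12),
                        subclass = c("A", "A", "B"))
  expect_equal(count_proximal_pairs(cells, "A", "B", 15), 1)   # 12 and 15.62
  expect_equal(count_proximal_pairs(cells, "A", "B", 16), 2)
  # boundary: distance exactly R counts as proximal
  two <- manual_cells(c(0, 15), c(0, 0), subclass = c("A", "B"))
  expect_equal(count_proximal_pairs(two, "A", "B", 15), 1)
  # pairs never span sections
  split <- manual_cells(c(0, 1), c(0, 0), subclass = c("A", "B"),
                        section_id = c("s1", "s2"))
  expect_equal(count_proximal_pairs(split, "A", "B", 15), 0)
})

test_that("pair counts agree with a brute-force double loop", {
  sim <- simulate_cells(spatial_test_config(seed = 23, base_intensity = 800))
  cells <- sim$cells
  for (pair in list(c("S1", "S2"), c("S3", "S3"))) {
    fast <- count_proximal_pairs(cells, pair[1], pair[2], 20)
    slow <- 0
    a <- cells[cells$subclass == pair[1], ]
    b <- cells[cells$subclass == pair[2], ]
    for (i in seq_len(nrow(a))) {
      d <- sqrt((b$x - a$x[i])^2 + (b$y - a$y[i])^2)
      d[b$section_id != a$section_id[i]] <- Inf
      slow <- slow + sum(d <= 20)
    }
    if (pair[1] == pair[2]) slow <- (slow - nrow(a)) / 2
    expect_equal(fast, slow)
  }
})

test_that("region splitting follows the ccfx midpoint with anterior ties", {
  cells <- manual_cells(1:5, 1:5, subclass = "A")
  cells$region <- "hypothalamus"
  cells$ccfx <- c(2, 3.9, 4, 5, 6)
  out <- split_regions(cells)
  expect_equal(out$region,
               c("anterior hypothalamus", "anterior hypothalamus",
                 "anterior hypothalamus", "posterior hypothalamus",
                 "posterior hypothalamus"))
  other <- manual_cells(1:2, 1:2, subclass = "A")
  other$region <- "isocortex"
  expect_equal(split_regions(other)$region, c("isocortex", "isocortex"))
  miss <- cells
  miss$ccfx[2] <- NA
  expect_error(split_regions(miss), "ccfx")
  hb <- manual_cells(1:2, 1:2, subclass = "A")
  hb$region <- "hindbrain"
  expect_error(split_regions(hb), "hindbrain_division")
  hb$hindbrain_division <- c("pons", "medulla")
  expect_equal(split_regions(hb)$region, c("pons", "medulla"))
})

test_that("per-region subclass selection applies the tiered thresholds", {
  cells <- dplyr::bind_rows(
    manual_cells(1:60, 1:60, subclass = "NeuA", section_id = "s"),
    manual_cells(61:120, 61:120, subclass = "Astro", section_id = "s"),
    manual_cells(121:172, 121:172, subclass = "Microglia", section_id = "s"))
  cells$cell_id <- sprintf("u%03d", seq_len(nrow(cells)))
  cells$region <- rep(c("pons", "isocortex"), length.out = nrow(cells))
  enr <- tidyr::expand_grid(subclass = c("NeuA", "Astro", "Microglia"),
                            region = c("pons", "isocortex"))
  enr$enrichment <- c(5.9, 5.9, 1.2, 0.5, 1, 1)
  classes <- tibble::tibble(subclass = c("NeuA", "Astro", "Microglia"),
                            class = c("neuronal", "astrocyte", "other"))
  sel <- select_region_subclasses(cells, enr, classes)
  expect_false("NeuA" %in% sel$pons)          # 5.9 < 6 in a complex region
  expect_true("NeuA" %in% sel$isocortex)      # 5.9 >= 2 elsewhere
  expect_true("Astro" %in% sel$pons)          # astrocyte threshold 1
  expect_false("Astro" %in% sel$isocortex)    # 0.5 < 1
  # microglia: 26 cells per region, below the 50-cell rule
  expect_false("Microglia" %in% sel$pons)
  enr2 <- enr[enr$region == "pons", ]
  expect_error(select_region_subclasses(cells, enr2, classes), "absent")
})

test_that("the interaction null is reproducible and preserves type counts", {
  sim <- simulate_cells(spatial_test_config(seed = 24, base_intensity = 1000))
  it1 <- test_interactions(sim$cells, r_proximal = 15, n_rounds = 50, seed = 7)
  it2 <- test_interactions(sim$cells, r_proximal = 15, n_rounds = 50, seed = 7)
  expect_identical(it1$results, it2$results)
  # the randomization only moves cells: totals over all pairs stay bounded by
  # the cell count, and every pair row is present
  expect_equal(nrow(it1$results), 4 * 5 / 2)
  expect_error(test_interactions(sim$cells, r_proximal = 200), "smaller")
})

test_that("z, p and fold change follow the normal-fit definitions", {
  sim <- simulate_cells(spatial_test_config(seed = 25, base_intensity = 800))
  it <- test_interactions(sim$cells, r_proximal = 15, n_rounds = 100, seed = 3)
  r <- it$results
  ok <- r$permutation_std > 0
  expect_equal(r$z_score[ok],
               (r$proximal_count[ok] - r$permutation_mean[ok]) /
                 r$permutation_std[ok])
  expect_equal(r$pval[ok],
               pnorm(r$z_score[ok], lower.tail = FALSE))
  expect_equal(r$fold_change[ok],
               r$proximal_count[ok] / r$permutation_mean[ok])
  # worked example: observed 60, null mean 40, sd 5 -> z = 4
  expect_equal(pnorm(4, lower.tail = FALSE), 3.167124e-05, tolerance = 1e-6)
})

test_that("BH adjustment matches the independent step-up oracle", {
  expect_equal(merfishkit:::bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  set.seed(26)
  for (i in 1:5) {
    p <- runif(50)^2
    expect_equal(merfishkit:::bh_adjust(p), bh_oracle(p))
  }
})

test_that("the minimum-observed-pairs rule vetoes tiny counts", {
  sim <- simulate_cells(spatial_test_config(seed = 27, base_intensity = 1000,
    attraction_rules = NULL))
  cells <- apply_attraction(
    sim$cells, list(type_a = "S1", type_b = "S2", radius = 10, strength = 1),
    seed = 2)
  it <- test_interactions(cells, r_proximal = 15, n_rounds = 100,
                          min_observed = 1e6, seed = 3)
  expect_false(any(it$results$significant))
  it2 <- test_interactions(cells, r_proximal = 15, n_rounds = 100, seed = 3)
  r12 <- it2$results[it2$results$subclass1 == "S1" &
                       it2$results$subclass2 == "S2", ]
  expect_true(r12$significant)
  expect_gt(r12$fold_change, 1.5)
})

test_that("LR support gating produces the relaxed-regime calls", {
  sim <- simulate_cells(spatial_test_config(seed = 28, base_intensity = 1000))
  cells <- apply_attraction(
    sim$cells, list(type_a = "S1", type_b = "S2", radius = 10, strength = 1),
    seed = 2)
  it <- test_interactions(cells, r_proximal = 30, n_rounds = 100, seed = 3)
  lr_res <- tibble::tibble(region = "all", subclass_ligand = "S1",
                           subclass_receptor = "S2", significant = TRUE)
  it <- add_lr_support(it, lr_res)
  r <- it$results
  expect_true(all(r$significant_relaxed <= r$significant))
  expect_true(all(r$supported_by_lr ==
                    (r$subclass1 == "S1" & r$subclass2 == "S2")))
  expect_s3_class(autoplot(it), "ggplot")
  expect_equal(glance(it)$n_pairs, nrow(r))
})
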