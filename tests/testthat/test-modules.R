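test_that("neighbour weights follow exp(-(D/D0)^2) with adaptive bandwidth", {
  # ring of 6 neighbours at distance 10 around a centre cell, one more at 20
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  cells <- manual_cells(c(0, 10 * cos(th), 20), c(0, 10 * sin(th), 0),
                        subclass = c("ctr", rep("A", 6), "B"))
  comp <- local_composition(cells, k = 7, bandwidth_nn = 5,
                            bandwidth_multiplier = 1)
  # centre cell: 5th neighbour at distance 10 -> D0 = 10
  # six A neighbours at D = 10 (weight e^-1), one B at 20 (weight e^-4)
  expect_equal(comp["c001", "A"], 6 * exp(-1), tolerance = 1e-12)
  expect_equal(comp["c001", "B"], exp(-4), tolerance = 1e-12)

  # bandwidth multiplier 2 doubles D0
  comp2 <- local_composition(cells, k = 7, bandwidth_nn = 5,
                             bandwidth_multiplier = 2)
  expect_equal(comp2["c001", "A"], 6 * exp(-0.25), tolerance = 1e-12)
})

test_that("composition vectors match a brute-force oracle to machine precision", {
  sim <- simulate_cells(spatial_test_config(seed = 16, base_intensity = 500))
  cells <- head(sim$cells, 400)
  k <- 30
  comp <- local_composition(cells, k = k, bandwidth_multiplier = 2)
  types <- attr(comp, "types")
  # brute force double loop
  for (i in sample(nrow(cells), 8)) {
    d <- sqrt((cells$x - cells$x[i])^2 + (cells$y - cells$y[i])^2)
    d[i] <- Inf
    d[cells$section_id != cells$section_id[i]] <- Inf
    ord <- order(d)[seq_len(k)]
    d0 <- 2 * sort(d)[5]
    w <- exp(-(d[ord] / d0)^2)
    expected <- vapply(types, function(t)
      sum(w[cells$subclass[ord] == t]), 0)
    expect_equal(unname(comp[cells$cell_id[i], ]), unname(expected),
                 tolerance = 1e-12)
  }
})

test_that("compositions are invariant to global coordinate scaling", {
  sim <- simulate_cells(spatial_test_config(seed = 17, base_intensity = 400))
  cells <- sim$cells
  comp <- local_composition(cells, k = 20)
  cells2 <- cells
  cells2$x <- cells$x * 2
  cells2$y <- cells$y * 2
  expect_equal(local_composition(cells2, k = 20), comp, tolerance = 1e-12)

  # all-one-type neighbourhood: a single nonzero entry
  mono <- simulate_cells(spatial_test_config(
    domains = list(rect_domain(0, 1000, 0, 1000, c(S1 = 1))), seed = 18))
  compm <- local_composition(mono$cells, k = 20)
  expect_equal(colnames(compm), "S1")
  expect_true(all(compm > 0))
})

test_that("coincident points give a zero-bandwidth error naming the cell", {
  cells <- manual_cells(c(rep(0, 8), 1:50), c(rep(0, 8), 1:50),
                        subclass = "A")
  expect_error(local_composition(cells, k = 10), "c00")
})

test_that("clustering recovers planted domains and honours L2 invariance", {
  cfg <- spatial_test_config(domains = list(
    rect_domain(0, 500, 0, 1000, c(S1 = 0.6, S2 = 0.4)),
    rect_domain(500, 1000, 0, 1000, c(S3 = 0.6, S4 = 0.4))), seed = 7)
  sim <- simulate_cells(cfg)
  comp <- local_composition(sim$cells, k = 50)
  lab <- cluster_compositions(comp, resolution = 1, seed = 1)
  truth <- sim$truth$domain[match(names(lab), sim$truth$cell_id)]
  expect_equal(length(unique(lab)), 2)
  expect_gt(ari(lab, truth), 0.9)

  # scaling a row leaves its normalised vector unchanged
  comp2 <- comp
  comp2[1, ] <- comp2[1, ] * 7
  lab2 <- cluster_compositions(comp2, resolution = 1, seed = 1)
  expect_equal(lab2, lab)

  zero <- comp
  zero[2, ] <- 0
  expect_error(cluster_compositions(zero), "all-zero")
})

test_that("small modules merge into their spatial surroundings to a fixed point", {
  sim <- simulate_cells(spatial_test_config(seed = 19, base_intensity = 500))
  cells <- sim$cells
  set.seed(20)
  labels <- setNames(sample(c(rep("big1", 200), rep("big2", 200),
                              sample(c("t1", "t2", "t3"),
                                     nrow(cells) - 400, TRUE))),
                     cells$cell_id)
  merged <- merge_small_modules(cells, labels, min_cells = 50)
  expect_true(all(table(merged) >= 50))
  # idempotent at the fixed point
  expect_equal(merge_small_modules(cells, merged, min_cells = 50), merged)
  # all-large labelings pass through unchanged
  big <- setNames(rep(c("x", "y"), length.out = nrow(cells)), cells$cell_id)
  expect_equal(sort(unique(merge_small_modules(cells, big, min_cells = 10))),
               sort(unique(unname(big))))
})

test_that("two-level modules nest and leave non-neurons without level 2", {
  subs <- sprintf("S%d", 1:4)
  cfg <- spatial_test_config(n_sections = 1, section_extent = c(2000, 1000),
    domains = list(
      rect_domain(0, 500, 0, 1000, c(S1 = .5, S2 = .5)),
      rect_domain(500, 1000, 0, 1000, c(S1 = .5, S2 = .5)),
      rect_domain(1000, 1500, 0, 1000, c(S3 = .5, S4 = .5)),
      rect_domain(1500, 2000, 0, 1000, c(S3 = .5, S4 = .5))), seed = 11)
  sim <- simulate_cells(cfg)
  cells <- sim$cells
  fine1 <- sim$truth$domain %in% c("D1", "D3")
  cells$cluster <- paste0(cells$subclass, ifelse(fine1, "_1", "_2"))
  # S4 treated as non-neuronal
  mods <- suppressWarnings(two_level_modules(
    cells, neuronal_subclasses = c("S1", "S2", "S3"), seed = 1))
  a <- tidy(mods)
  joined <- dplyr::inner_join(a, cells[, c("cell_id", "subclass")], "cell_id")
  expect_true(all(is.na(joined$module_l2[joined$subclass == "S4"])))
  expect_true(all(!is.na(joined$module_l1)))
  l2 <- joined$module_l2[!is.na(joined$module_l2)]
  expect_true(all(grepl("^[0-9]+\\.[0-9]+$", l2)))
  expect_s3_class(autoplot(mods), "ggplot")
  cs <- module_composition_summary(mods)
  sums <- tapply(cs$fraction, cs$module, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)))
})
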