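test_that("cell simulation is deterministic and Poisson at the set intensity", {
  cfg <- spatial_test_config(domains = NULL, seed = 3)
  a <- simulate_cells(cfg)
  b <- simulate_cells(cfg)
  expect_identical(a$cells, b$cells)
  expect_identical(a$truth, b$truth)

  # one domain, one subclass: counts across seeds behave like Poisson(1000)
  one <- sim_config(n_sections = 1, section_extent = c(1000, 1000),
                    cluster_means = flat_means(c("A_1"), c("g1", "g2")),
                    cluster_subclass = c(A_1 = "A"),
                    base_intensity = 1000, doublet_fraction = 0)
  counts <- vapply(1:20, function(s) {
    one$seed <- s
    nrow(simulate_cells(one)$cells)
  }, 0)
  expect_gt(mean(counts), 1000 - 3 * sqrt(1000 / 20))
  expect_lt(mean(counts), 1000 + 3 * sqrt(1000 / 20))
})

test_that("disjoint domain compositions never mix and zero area errors", {
  cfg <- spatial_test_config(domains = list(
    rect_domain(0, 500, 0, 1000, c(S1 = 1)),
    rect_domain(500, 1000, 0, 1000, c(S2 = 1))))
  sim <- simulate_cells(cfg)
  expect_true(all(sim$cells$subclass[sim$cells$x < 500] == "S1"))
  expect_true(all(sim$cells$subclass[sim$cells$x > 500] == "S2"))
  expect_error(
    spatial_test_config(domains = list(rect_domain(0, 0, 0, 1, c(S1 = 1)))),
    "zero-area")
  expect_error(
    spatial_test_config(domains = list(rect_domain(0, 1, 0, 1, c(S1 = 0.5)))),
    "sum to 1")
})

test_that("doublet flags match the configured fraction with scores split at 0.25", {
  sim <- simulate_cells(sim_config(doublet_fraction = 0.1, seed = 8))
  n <- nrow(sim$cells)
  flagged <- sim$truth$is_doublet
  expect_gt(sum(flagged), 0.1 * n - 3 * sqrt(0.1 * 0.9 * n))
  expect_lt(sum(flagged), 0.1 * n + 3 * sqrt(0.1 * 0.9 * n))
  expect_true(all(sim$cells$doublet_score[flagged] > 0.25))
  expect_true(all(sim$cells$doublet_score[!flagged] < 0.25))
})

test_that("attraction relocates the configured fraction and preserves counts", {
  cfg <- spatial_test_config(seed = 5)
  sim <- simulate_cells(cfg)
  rule0 <- list(type_a = "S1", type_b = "S2", radius = 10, strength = 0)
  expect_identical(apply_attraction(sim$cells, rule0, seed = 1), sim$cells)

  rule1 <- list(type_a = "S1", type_b = "S2", radius = 10, strength = 1)
  moved <- apply_attraction(sim$cells, rule1, seed = 1)
  expect_equal(table(moved$subclass), table(sim$cells$subclass))
  # every S2 cell now sits within 10 um of an S1 cell in its section
  for (sec in unique(moved$section_id)) {
    a <- moved[moved$section_id == sec & moved$subclass == "S1", ]
    b <- moved[moved$section_id == sec & moved$subclass == "S2", ]
    d <- sqrt(outer(b$x, a$x, "-")^2 + outer(b$y, a$y, "-")^2)
    expect_true(all(apply(d, 1, min) <= 10 + 1e-9))
  }

  # strength 0.5 relocates a Binomial(nB, 0.5) subset
  rule5 <- list(type_a = "S1", type_b = "S2", radius = 10, strength = 0.5)
  fr <- vapply(1:10, function(s) {
    m <- apply_attraction(sim$cells, rule5, seed = s)
    mean(m$x != sim$cells$x | m$y != sim$cells$y)
  }, 0)
  nb <- sum(sim$cells$subclass == "S2")
  expect_gt(mean(fr) * nrow(sim$cells) / nb, 0.45)
  expect_lt(mean(fr) * nrow(sim$cells) / nb, 0.55)
  expect_error(apply_attraction(sim$cells, list(type_a = "S1", type_b = "S2",
                                                radius = 0, strength = 1)),
               "radius")
})

test_that("negative-binomial expression has the configured means", {
  cls <- c("A_1")
  cfg <- sim_config(n_sections = 1, section_extent = c(2000, 2000),
                    cluster_means = flat_means(cls, c("g1", "g2"), 5),
                    cluster_subclass = c(A_1 = "A"),
                    base_intensity = 2500, dispersion = Inf,
                    volume_sdlog = 0, seed = 10)
  sim <- simulate_cells(cfg)
  ex <- simulate_expression(sim$cells, cfg)
  m <- expr_layer(ex, "raw")
  n <- nrow(m)
  se <- sqrt(5 / n)
  expect_lt(abs(mean(m[, "g1"]) - 5), 3 * se)

  # gradient slope 0: expression uncorrelated with position
  expect_lt(abs(cor(m[, "g1"], sim$cells$x)), 0.05)
})

test_that("clusters with orthogonal means separate by nearest-mean classification", {
  means <- rbind(A_1 = c(rep(20, 10), rep(0, 10)),
                 A_2 = c(rep(0, 10), rep(20, 10)))
  colnames(means) <- sprintf("g%02d", 1:20)
  cfg <- sim_config(n_sections = 1, cluster_means = means,
                    cluster_subclass = c(A_1 = "A", A_2 = "A"),
                    base_intensity = 2000, seed = 11)
  sim <- simulate_cells(cfg)
  ex <- simulate_expression(sim$cells, cfg)
  m <- expr_layer(ex, "raw")
  pred <- ifelse(m[, 1:10, drop = FALSE] |> rowSums() >
                   m[, 11:20, drop = FALSE] |> rowSums(), "A_1", "A_2")
  expect_gt(mean(pred == sim$truth$cluster), 0.99)
})

test_that("LR upregulation rules are exact identities when inert", {
  bench <- lr_benchmark_config(seed = 12, with_rule = FALSE)
  sim <- simulate_cells(bench$config)
  ex <- simulate_expression(sim$cells, bench$config)
  rule_f1 <- list(type_a = "SC01", type_b = "SC02", pair_name = "P1",
                  fold = 1, radius = 30)
  expect_identical(apply_lr_upregulation(ex, sim$cells, rule_f1, bench$db), ex)

  # disjoint (cross-section) types never proximal: move all SC02 far away
  cells2 <- sim$cells
  cells2$x[cells2$subclass == "SC02"] <- cells2$x[cells2$subclass == "SC02"] + 1e7
  rule4 <- list(type_a = "SC01", type_b = "SC02", pair_name = "P1",
                fold = 4, radius = 30)
  expect_equal(expr_layer(apply_lr_upregulation(ex, cells2, rule4, bench$db), "raw"),
               expr_layer(ex, "raw"))

  bad <- list(type_a = "SC01", type_b = "SC02", pair_name = "nope",
              fold = 4, radius = 30)
  expect_error(apply_lr_upregulation(ex, sim$cells, bad, bench$db), "unknown")
})

test_that("proximal LR upregulation multiplies exactly by the fold", {
  bench <- lr_benchmark_config(seed = 13, with_rule = FALSE)
  sim <- simulate_cells(bench$config)
  ex <- simulate_expression(sim$cells, bench$config)
  # place every SC01 cell on top of an SC02 cell: all proximal
  cells <- sim$cells
  ia <- which(cells$subclass == "SC01")
  ib <- which(cells$subclass == "SC02")
  host <- rep_len(ib, length(ia))
  cells$x[ia] <- cells$x[host]; cells$y[ia] <- cells$y[host]
  cells$section_id[ia] <- cells$section_id[host]
  rule <- list(type_a = "SC01", type_b = "SC02", pair_name = "P1",
               fold = 4, radius = 30)
  up <- apply_lr_upregulation(ex, cells, rule, bench$db)
  lig <- bench$db$ligand_components[[1]]
  expect_equal(mean(expr_layer(up, "raw")[ia, lig]),
               4 * mean(expr_layer(ex, "raw")[ia, lig]))
})

test_that("the reference covers the panel and reproduces cluster means", {
  cfg <- sim_config(seed = 14)
  ref <- simulate_reference(cfg, n_per_cluster = 500)
  expect_true(all(colnames(cfg$cluster_means) %in% ref$expr$genes))
  expect_identical(simulate_reference(cfg, n_per_cluster = 50)$expr,
                   simulate_reference(cfg, n_per_cluster = 50)$expr)
  m <- expr_layer(ref$expr, "raw")
  emp <- rowsum(m, ref$labels$cluster) /
    as.vector(table(ref$labels$cluster))
  for (cl in rownames(cfg$reference_means)) {
    expect_gt(cor(emp[cl, ], cfg$reference_means[cl, ]), 0.99)
  }
})

test_that("ground truth files are written as CSV plus JSON manifest", {
  cfg <- spatial_test_config(seed = 15,
    attraction_rules = list(list(type_a = "S1", type_b = "S2",
                                 radius = 10, strength = 0.5)))
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_ground_truth(sim$truth, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$attracted_pairs[[1]]$type_a, "S1")
})
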