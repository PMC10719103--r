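test_that("integration normalisation reproduces the worked arithmetic", {
  ex <- quick_expr(matrix(c(2, 8), nrow = 1))
  out <- preprocess_for_integration(ex)
  expect_equal(expr_layer(out, "lognorm")[1, ],
               c(g001 = log(201), g002 = log(801)))

  set.seed(2)
  m <- matrix(rpois(600, 5), 30, 20) + 1  # no all-zero cells
  m[, 1] <- 7                    # constant gene ...
  m[, 20] <- m[, 20] + max(rowSums(m)) - rowSums(m)  # ... at equal totals,
  # so it stays constant after per-cell total normalisation
  sc <- expr_layer(preprocess_for_integration(quick_expr(m)), "scaled")
  expect_equal(unname(colMeans(sc)), rep(0, 20), tolerance = 1e-12)
  sds <- apply(sc, 2, sd)
  expect_equal(unname(sds[-1]), rep(1, 19), tolerance = 1e-12)
  expect_true(all(sc[, 1] == 0))

  allzero <- matrix(c(1, 0, 2, 0), 2, 2)
  expect_error(preprocess_for_integration(quick_expr(allzero)), "all-zero")
})

test_that("highly variable gene selection keeps structure, drops constants", {
  set.seed(3)
  n <- 200
  m <- matrix(rpois(n * 30, 5), n, 30)
  m[, 1] <- 4                                  # constant
  m[, 2] <- c(rpois(n / 2, 40), rpois(n / 2, 1))  # bimodal, high variance
  ex <- quick_expr(m)
  hvg <- select_hvg(ex)
  expect_false(ex$genes[1] %in% hvg)
  expect_true(ex$genes[2] %in% hvg)
  expect_true(all(hvg %in% ex$genes))
})

test_that("CCA co-embedding maps copies onto themselves", {
  set.seed(4)
  ref <- matrix(rnorm(120 * 25), 120, 25)
  emb <- cca_coembed(scale(ref), scale(ref), n_dims = 10)
  nn <- knn_brute(emb$ref, emb$query, 1L, integer(0))$index[, 1]
  expect_gt(mean(nn == seq_len(120)), 0.99)

  # permutation equivariance of the query projection (per-dimension signs
  # of the refit singular vectors are arbitrary)
  perm <- sample(120)
  emb2 <- cca_coembed(scale(ref), scale(ref)[perm, ], n_dims = 10)
  expect_equal(abs(emb2$query), abs(emb$query[perm, ]), tolerance = 1e-8)

  expect_error(cca_coembed(scale(ref), scale(ref), n_dims = 26), "n_dims")
})

test_that("CCA on identical two-gene datasets gives a perfect first pair", {
  set.seed(5)
  x <- cbind(rnorm(300), rnorm(300))
  x[, 2] <- x[, 1] * 0.5 + x[, 2]
  emb <- cca_coembed(scale(x), scale(x), n_dims = 1)
  pr <- (scale(x) %*% emb$map_ref)[, 1]
  pq <- (scale(x) %*% emb$map_query)[, 1]
  expect_equal(abs(cor(pr, pq)), 1, tolerance = 1e-8)  # canonical corr = 1
  expect_gt(emb$d[1], 0)
})

test_that("anchors are mutual nearest neighbours and symmetric", {
  set.seed(6)
  pts <- matrix(rnorm(10 * 3), 10, 3)
  emb <- list(ref = pts, query = pts)
  an <- find_anchors(emb, k = 1)
  expect_equal(nrow(an), 10)
  expect_equal(an$ref, an$query)

  # symmetric under swapping the datasets
  pts2 <- matrix(rnorm(12 * 3), 12, 3)
  e12 <- find_anchors(list(ref = pts, query = pts2), k = 3)
  e21 <- find_anchors(list(ref = pts2, query = pts), k = 3)
  expect_setequal(paste(e12$ref, e12$query), paste(e21$query, e21$ref))

  # an outlier far from everything participates in no anchor
  far <- rbind(pts2, c(100, 100, 100))
  ef <- find_anchors(list(ref = pts, query = far), k = 2)
  expect_false(13 %in% ef$query)
  expect_error(find_anchors(list(ref = pts, query = pts), k = 10), "smaller")
})

test_that("label transfer takes the plurality with its fraction as confidence", {
  set.seed(7)
  ref <- matrix(rnorm(100 * 2, sd = 0.01), 100, 2)
  query <- matrix(0, 1, 2)
  emb <- list(ref = ref, query = query)
  anchors <- tibble::tibble(ref = 1:100, query = rep(1, 100))
  labels <- c(rep("X", 80), rep("Y", 20))
  tr <- transfer_labels(anchors, labels, emb, k_anchor = 100)
  expect_equal(tr$label, "X")
  expect_equal(tr$confidence, 0.8)

  tr2 <- transfer_labels(anchors, rep("Z", 100), emb, k_anchor = 100)
  expect_equal(tr2$confidence, 1)

  # 50/50 tie breaks to the lexicographically smaller label
  tr3 <- transfer_labels(anchors, c(rep("b", 50), rep("a", 50)), emb,
                         k_anchor = 100)
  expect_equal(tr3$label, "a")
  expect_equal(tr3$confidence, 0.5)
})

test_that("reference partitioning balances cells and respects structure", {
  set.seed(8)
  # two well-separated expression blobs (distinct gene programs, not just
  # magnitude: per-cell normalisation removes scale differences), two
  # subclasses each
  blob <- function(program, n) {
    base <- matrix(rnorm(n * 20, 2, 0.5), n, 20)
    base[, program] <- base[, program] + 12
    base
  }
  m <- rbind(blob(1:10, 100), blob(1:10, 100),
             blob(11:20, 100), blob(11:20, 100))
  subs <- rep(c("a1", "a2", "b1", "b2"), each = 100)
  ex <- quick_expr(pmax(round(m + 5), 0), cells = sprintf("r%03d", 1:400))
  pt <- partition_reference(ex, subs, K = 2, n_dims = 20)
  expect_equal(pt$partition[["a1"]], pt$partition[["a2"]])
  expect_equal(pt$partition[["b1"]], pt$partition[["b2"]])
  expect_false(pt$partition[["a1"]] == pt$partition[["b1"]])

  # K = number of subclasses: singleton partitions
  pt4 <- partition_reference(ex, subs, K = 4, n_dims = 20)
  expect_equal(sort(unname(pt4$partition)), 1:4)
  expect_error(partition_reference(ex, subs, K = 5), "exceeds")
})

test_that("a disconnected subclass graph splits into its components at zero cut", {
  W <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  W[1, 2] <- W[2, 1] <- 5
  W[3, 4] <- W[4, 3] <- 7
  groups <- merfishkit:::balanced_kway_cut(W, sizes = c(10, 10, 10, 10), K = 2)
  parts <- lapply(groups, sort)
  expect_setequal(vapply(parts, paste, "", collapse = ","), c("1,2", "3,4"))
})

test_that("imputation is an anchor-convex distance-weighted average", {
  # two anchors at known distances; verify the weighted mean directly
  emb <- list(ref = matrix(c(0, 0, 3, 0), 2, 2, byrow = TRUE),
              query = matrix(c(1, 0), 1, 2))
  anchors <- tibble::tibble(ref = 1:2, query = c(1, 1))
  refv <- matrix(c(4, 8), 2, 1, dimnames = list(NULL, "g"))
  out <- impute_expression(anchors, emb, refv, k_impute = 2)
  d <- c(1, 2); sigma <- 2
  w <- exp(-(d / sigma)^2)
  expect_equal(unname(out[1, "g"]), sum(w * c(4, 8)) / sum(w))
  expect_gte(out[1, "g"], 4); expect_lte(out[1, "g"], 8)

  # identical anchor profiles: imputation returns them regardless of weights
  refsame <- matrix(7, 2, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(unname(impute_expression(anchors, emb, refsame, k_impute = 2)[1, ]),
               rep(7, 3))
})

test_that("adjusted confidence is exactly the product and thresholds are inclusive", {
  sim <- integration_benchmark()
  lt <- suppressWarnings(two_round_transfer(
    sim$reference$expr, sim$reference$labels, sim$expr,
    n_partitions = 2, n_dims = 30, seed = 1))
  res <- tidy(lt)
  expect_equal(res$subclass_confidence_adjusted,
               res$subclass_confidence * res$partition_confidence)
  expect_true(all(res$subclass_confidence_adjusted <=
                    pmin(res$partition_confidence, res$subclass_confidence) + 1e-12))
  at <- res$subclass_confidence_adjusted >= 0.8
  expect_equal(res$pass_subclass, at)
  g <- glance(lt)
  expect_equal(g$n_cells, nrow(res))
  p <- autoplot(lt)
  expect_s3_class(p, "ggplot")
})
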