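test_that("parameter arithmetic follows the 3/4-power, weighting and ceiling rules", {
  expect_identical(default_mtry(1727), 267L)
  expect_identical(default_mtry(744), 142L)
  expect_identical(default_mtry(411), 91L)
  expect_identical(default_mtry(2471), 350L)
  expect_identical(default_mtry(1), 1L)
  expect_error(default_mtry(0), "p")

  w <- default_class_weights(c(organic = 92, conventional = 178))
  expect_equal(w[["organic"]], 178 / 92)
  expect_equal(w[["conventional"]], 1)
  expect_equal(unname(default_class_weights(c(a = 30, b = 30))), c(1, 1))
  expect_equal(unname(default_class_weights(c(a = 10, b = 40))), c(4, 1))
  expect_error(default_class_weights(c(a = 0, b = 5)), "class_counts")

  expect_identical(surrogate_count(1727, 0.05), 87L)
  expect_identical(surrogate_count(744, 0.20), 149L)
  expect_identical(surrogate_count(100, 0.10), 10L)
  expect_error(surrogate_count(100, 1.5), "fraction")
})

test_that("a perfectly separable variable is the root split of every tree", {
  x1 <- c(rep(0, 5), rep(10, 5))
  set.seed(20)
  vals <- cbind(x1, matrix(rnorm(30), 10, 3))
  tab <- toy_table(5, 5, 4, values = vals)
  f <- fit_forest(tab, forest_params(ntree = 50, mtry = 4, s = 3, seed = 2))
  roots <- vapply(f$trees, function(tr) tr$split_var[1], integer(1))
  expect_true(all(roots == 1L))
  expect_equal(oob_confusion(f, tab)$accuracy, 100)
})

test_that("forest fits are reproducible and seed-sensitive", {
  tab <- toy_table(8, 8, 10, seed = 21)
  p <- forest_params(ntree = 30, s = 3, seed = 7)
  f1 <- fit_forest(tab, p)
  f2 <- fit_forest(tab, p)
  f3 <- fit_forest(tab, forest_params(ntree = 30, s = 3, seed = 8))
  expect_identical(f1$trees, f2$trees)
  expect_identical(f1$oob, f2$oob)
  expect_false(identical(f1$trees, f3$trees))
  expect_identical(predict(f1, tab), predict(f2, tab))
})

test_that("the chosen Gini split matches exhaustive search on small nodes", {
  set.seed(22)
  for (rep in 1:5) {
    vals <- matrix(rnorm(12 * 5), 12, 5)
    tab <- toy_table(6, 6, 5, values = vals)
    f <- fit_forest(tab, forest_params(ntree = 8, mtry = 5, s = 4,
                                       case_weights = rep(1, 12),
                                       seed = rep))
    y <- as.integer(tab$classes) - 1L
    for (t in seq_along(f$trees)) {
      tr <- f$trees[[t]]
      if (tr$split_var[1] == 0L) next
      counts <- f$inbag[t, ]
      oracle <- oracle_best_split(tab$values, y, counts)
      # the implementation's split achieves the oracle's best decrease
      idx <- rep(seq_along(counts), counts)
      yn <- y[idx]
      got <- oracle_best_split(
        tab$values[, tr$split_var[1], drop = FALSE], y, counts)
      expect_equal(got$dec, oracle$dec, tolerance = 1e-12)
      # unique optimum: variable and threshold must agree exactly
      expect_identical(tr$split_var[1], oracle$var)
      expect_equal(tr$threshold[1], oracle$thr, tolerance = 1e-12)
    }
  }
})

test_that("stored surrogates equal the exhaustive node-level search", {
  set.seed(23)
  vals <- matrix(rnorm(12 * 5), 12, 5)
  vals[, 4] <- vals[, 2] + rnorm(12, 0, 0.1)   # a good mimic of v2 exists
  tab <- toy_table(6, 6, 5, values = vals)
  f <- fit_forest(tab, forest_params(ntree = 6, mtry = 5, s = 4,
                                     case_weights = rep(1, 12), seed = 3))
  for (t in seq_along(f$trees)) {
    tr <- f$trees[[t]]
    if (tr$split_var[1] == 0L) next
    counts <- f$inbag[t, ]
    idx <- rep(seq_along(counts), counts)
    node_vals <- tab$values[idx, , drop = FALSE]
    oracle <- find_surrogates(node_vals, tr$split_var[1], tr$threshold[1],
                              s = 4)
    expect_identical(tr$surr_var[[1]], oracle$variable)
    expect_equal(tr$surr_adj[[1]], oracle$adjusted_agreement,
                 tolerance = 1e-12)
    expect_identical(tr$surr_dir[[1]], oracle$direction)
  }
})

test_that("find_surrogates scores a perfect mimic 1 and ranks a hand-built node", {
  # 8-sample node: v2 copies v1 (perfect mimic), v3 partial, v4 useless
  node <- cbind(v1 = c(1, 2, 3, 4, 10, 11, 12, 13),
                v2 = c(5, 6, 7, 8, 20, 21, 22, 23),
                v3 = c(1, 2, 10, 3, 11, 12, 4, 13),
                v4 = c(1, 2, 1, 2, 1, 2, 1, 2))
  out <- find_surrogates(node, 1, 7, s = 3)
  expect_equal(out$variable[1], 2)
  expect_equal(out$adjusted_agreement[1], 1)
  # hand enumeration for v3: the best threshold (3.5) routes 7/8 samples
  # with the primary; baseline m = 1/2, so adjusted agreement
  # = (0.875 - 0.5) / 0.5 = 0.75
  expect_equal(out$adjusted_agreement[out$variable == 3], 0.75)
  expect_false(4 %in% out$variable)
  # degenerate primary split stores nothing
  allsame <- cbind(v1 = rep(1, 4), v2 = 1:4)
  expect_equal(nrow(find_surrogates(allsame, 1, 2, s = 2)), 0)
})

test_that("adjusted agreements are in (0, 1] and sorted descending", {
  tab <- toy_table(10, 10, 12, seed = 24)
  f <- fit_forest(tab, forest_params(ntree = 40, s = 6, seed = 4))
  for (tr in f$trees) {
    for (k in seq_along(tr$surr_adj)) {
      adj <- tr$surr_adj[[k]]
      if (!length(adj)) next
      expect_true(all(adj > 0 & adj <= 1 + 1e-12))
      expect_true(all(diff(adj) <= 1e-12))
      expect_lte(length(adj), 6)
      expect_false(tr$split_var[k] %in% tr$surr_var[[k]])
    }
  }
})

test_that("the OOB fraction concentrates near 1 - (1 - 1/n)^n", {
  tab <- toy_table(15, 15, 5, seed = 25)
  f <- fit_forest(tab, forest_params(ntree = 1000, s = 0,
                                     case_weights = rep(1, 30), seed = 5))
  oob_frac <- mean(rowMeans(f$oob))
  expect_gt(oob_frac, 0.33)
  expect_lt(oob_frac, 0.41)
  # every tree partitions the samples into in-bag and OOB
  expect_true(all((f$inbag > 0) == !f$oob))
  expect_true(all(rowSums(f$inbag) == 30))
})

test_that("label-independent data shows no optimistic OOB bias", {
  set.seed(26)
  accs <- vapply(1:10, function(s) {
    vals <- matrix(rnorm(40 * 15), 40, 15)
    tab <- toy_table(20, 20, 15, values = vals)
    f <- fit_forest(tab, forest_params(ntree = 150, s = 0, seed = s))
    oob_confusion(f, tab)$accuracy / 100
  }, numeric(1))
  # the OOB estimate must never look better than chance on pure noise;
  # at this n it is in fact slightly pessimistic (each sample's OOB trees
  # under-represent its own class in the bootstrap), so only the
  # optimistic direction is bounded
  expect_lt(mean(accs), 0.5 + 1.96 * sqrt(0.25 / (10 * 40)) + 0.05)
})

test_that("confusion summaries are row-normalized with the printed layout", {
  d <- default_dataset()
  lc <- preprocess_lcms(d$lcms)
  f <- fit_forest(lc, forest_params(ntree = 200, seed = 6))
  cs <- oob_confusion(f, lc)
  expect_equal(unname(rowSums(cs$table)), c(100, 100), tolerance = 0.01)
  expect_true(cs$accuracy >= 0 && cs$accuracy <= 100)
  expect_equal(unname(cs$sensitivity), unname(diag(cs$table)))
  txt <- capture.output(print(cs))
  expect_true(any(grepl("Specificity", txt)))
  expect_error(oob_confusion(f, d$photometry), "variable set")
})

test_that("prediction is the majority vote over trees", {
  x1 <- c(rep(0, 6), rep(10, 6))
  tab <- toy_table(6, 6, 2, values = cbind(x1, rnorm(12)))
  f <- fit_forest(tab, forest_params(ntree = 25, mtry = 2, s = 1, seed = 9))
  newx <- cbind(c(-1, 20), c(0, 0))
  colnames(newx) <- f$variable_ids
  pred <- predict(f, newx)
  expect_identical(as.character(pred), c("organic", "conventional"))
})
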