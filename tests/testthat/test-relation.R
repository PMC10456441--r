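test_that("duplicated variables relate with mean adjusted agreement ~ 1", {
  set.seed(40)
  vals <- matrix(rnorm(30 * 30), 30, 30)
  vals[, 1] <- c(rep(0, 15), rep(5, 15)) + rnorm(30, 0, 0.3)
  vals[, 2] <- vals[, 1]                      # exact copy column
  tab <- toy_table(15, 15, 30, values = vals)
  f <- fit_forest(tab, forest_params(ntree = 100, s = 3, seed = 1))
  rel <- mean_adjusted_agreement(f)
  expect_gt(rel$S["v01", "v02"], 0.9)
  # independent noise pairs stay near zero
  expect_lt(rel$S["v05", "v06"], 0.1)
  expect_lt(rel$S["v10", "v20"], 0.1)
})

test_that("the relation matrix equals hand-computed averages on a built forest", {
  # tree 1: v1 primary at root (surr: v2 adj .8, v3 adj .4);
  #         v2 primary at depth 1 (surr: v1 adj .5)
  t1 <- toy_tree(depth = c(0, 1, 1, 2, 2),
                 split_var = c(1, 2, 0, 0, 0),
                 left = c(2, 4, 0, 0, 0), right = c(3, 5, 0, 0, 0),
                 label = c(1, 1, 2, 1, 2),
                 surr_var = list(c(2L, 3L), 1L, integer(0), integer(0),
                                 integer(0)),
                 surr_adj = list(c(0.8, 0.4), 0.5, numeric(0), numeric(0),
                                 numeric(0)))
  # tree 2: v1 primary at root with no stored surrogate for v2
  t2 <- toy_tree(depth = c(0, 1, 1), split_var = c(1, 0, 0),
                 left = c(2, 0, 0), right = c(3, 0, 0), label = c(1, 1, 2),
                 surr_var = list(3L, integer(0), integer(0)),
                 surr_adj = list(0.6, numeric(0), numeric(0)))
  f <- toy_forest(list(t1, t2), p = 3)
  rel <- mean_adjusted_agreement(f)
  # R[v1, v2]: v1 splits twice; adj(v2) = .8 then 0 -> .4
  expect_equal(rel$R["v01", "v02"], 0.4)
  # R[v1, v3]: (.4 + .6)/2 = .5
  expect_equal(rel$R["v01", "v03"], 0.5)
  # R[v2, v1]: v2 splits once, adj .5
  expect_equal(rel$R["v02", "v01"], 0.5)
  # v3 never primary: zero row
  expect_equal(unname(rel$R["v03", ]), c(0, 0, 0))
  expect_equal(rel$n_never_primary, 1)
  # symmetrization and diagonal
  expect_equal(rel$S["v01", "v02"], (0.4 + 0.5) / 2)
  expect_identical(rel$S, t(rel$S))
  expect_equal(unname(diag(rel$S)), rep(1, 3))
  expect_true(all(rel$S >= 0 & rel$S <= 1))
  expect_error(mean_adjusted_agreement(f, character(0)), "empty")
  expect_error(mean_adjusted_agreement(f, "bogus"), "unknown")
})

test_that("low-level fusion concatenates blocks and keeps tags", {
  tab <- toy_table(4, 4, 6, seed = 41)
  tab2 <- tab
  tab2$variables$id <- paste0("b_", tab2$variables$id)
  tab2$variables$block <- "nir"
  colnames(tab2$values) <- tab2$variables$id
  fused <- low_level_fuse(list(tab, tab2))
  expect_equal(ncol(fused$values), 12)
  expect_equal(unname(fused$values[, 7:12]), unname(tab$values))
  expect_equal(as.vector(table(fused$variables$block)[c("lcms", "nir")]),
               c(6, 6))
  # the headline fused dimensioning: 1727 + 744 -> 2471 -> mtry 350
  expect_identical(default_mtry(1727 + 744), 350L)
  # mismatched samples are reported
  tab3 <- tab2
  tab3$sample_ids[1] <- "other"
  rownames(tab3$values)[1] <- "other"
  expect_error(low_level_fuse(list(tab, tab3)), "sample ids")
  expect_error(low_level_fuse(list(tab, tab)), "disjoint")
})

test_that("fused tables round-trip through CSV", {
  tab <- toy_table(3, 3, 4, seed = 42)
  tab2 <- tab
  tab2$variables$id <- paste0("n_", tab2$variables$id)
  tab2$variables$block <- "nir"
  colnames(tab2$values) <- tab2$variables$id
  fused <- low_level_fuse(list(tab, tab2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(fused, path)
  r <- read_feature_table(path)
  expect_equal(r$values, fused$values, tolerance = 1e-14)
  expect_identical(r$variables$block, fused$variables$block)
})

test_that("Ward clustering recovers block-diagonal structure exactly", {
  ids <- sprintf("v%02d", 1:9)
  S <- matrix(0.05, 9, 9, dimnames = list(ids, ids))
  for (b in list(1:3, 4:6, 7:9)) S[b, b] <- 0.9
  diag(S) <- 1
  rel <- structure(list(S = S, R = S,
                        variables = data.frame(id = ids,
                                               block = rep(c("lcms", "nir",
                                                             "lcms"),
                                                           each = 3)),
                        n_never_primary = 0), class = "relation_matrix")
  rep3 <- cluster_relation_matrix(rel, k = 3)
  expect_equal(length(unique(rep3$assignments[1:3])), 1)
  expect_equal(length(unique(rep3$assignments[4:6])), 1)
  expect_equal(length(unique(rep3$assignments[7:9])), 1)
  expect_equal(length(unique(rep3$assignments)), 3)
  expect_error(cluster_relation_matrix(rel, k = 10), "k")

  cm <- cross_modal_report(rep3)
  expect_identical(sort(cm$type), sort(c("single-block", "single-block",
                                         "single-block")))
  # permutation equivariance
  perm <- c(4, 1, 7, 2, 9, 5, 3, 8, 6)
  rel_p <- rel
  rel_p$S <- S[perm, perm]
  rel_p$R <- rel_p$S
  rel_p$variables <- rel$variables[perm, ]
  rep_p <- cluster_relation_matrix(rel_p, k = 3)
  same_cluster <- function(asg, i, j) asg[i] == asg[j]
  for (i in 1:8) for (j in (i + 1):9) {
    expect_equal(
      same_cluster(rep3$assignments, ids[perm][i], ids[perm][j]),
      same_cluster(rep_p$assignments, ids[perm][i], ids[perm][j]))
  }
})

test_that("mixed-block clusters are flagged in the cross-modal report", {
  ids <- c("l1", "l2", "n1", "n2")
  S <- matrix(0.05, 4, 4, dimnames = list(ids, ids))
  S[1:2, 1:2] <- 0.9          # pure LC-MS cluster
  S[3:4, 3:4] <- 0.9          # will merge with nothing
  S[2, 3] <- S[3, 2] <- 0.05
  diag(S) <- 1
  rel <- structure(list(S = S, R = S,
                        variables = data.frame(id = ids,
                                               block = c("lcms", "lcms",
                                                         "lcms", "nir")),
                        n_never_primary = 0), class = "relation_matrix")
  cm <- cross_modal_report(cluster_relation_matrix(rel, k = 2))
  expect_identical(cm$type[cm$cluster == 1], "single-block")
  expect_identical(cm$type[cm$cluster == 2], "mixed-block")
  expect_identical(cm$members[[2]]$id, c("n1", "n2"))
})
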