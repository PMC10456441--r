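# Shared fixtures and independent oracles for the test suite.
# Everything here is built in code at test time; no stored data.

# small two-class feature table with reproducible random values
toy_table <- function(n_org = 4, n_conv = 4, p = 6, seed = 42,
                      values = NULL) {
  set.seed(seed)
  n <- n_org + n_conv
  if (is.null(values)) values <- matrix(rlnorm(n * p), n, p)
  colnames(values) <- sprintf("v%02d", seq_len(p))
  feature_table(values,
                rep(c("organic", "conventional"), c(n_org, n_conv)))
}

# hand-buildable forest skeleton compatible with smd / relation code
toy_tree <- function(depth, split_var, left, right, label,
                     surr_var = NULL, surr_adj = NULL, max_depth = NULL) {
  nn <- length(depth)
  if (is.null(surr_var)) surr_var <- rep(list(integer(0)), nn)
  if (is.null(surr_adj)) surr_adj <- rep(list(numeric(0)), nn)
  if (is.null(max_depth)) max_depth <- max(depth)
  list(depth = as.integer(depth), split_var = as.integer(split_var),
       threshold = ifelse(split_var == 0L, NA_real_, 0.5),
       left = as.integer(left), right = as.integer(right),
       label = as.integer(label), size = rep(1L, nn),
       surr_var = surr_var, surr_adj = surr_adj,
       surr_dir = rep(list(integer(0)), nn), max_depth = max_depth)
}

toy_forest <- function(trees, p, blocks = rep("lcms", p)) {
  ids <- sprintf("v%02d", seq_len(p))
  structure(list(trees = trees, oob = NULL, inbag = NULL,
                 params = forest_params(ntree = length(trees), mtry = 1,
                                        s = 5, seed = 1),
                 variable_ids = ids,
                 variables = data.frame(id = ids, block = blocks),
                 class_levels = c("organic", "conventional"),
                 n = 2L, p = as.integer(p)),
            class = "surrogate_forest")
}

# exhaustive-search oracle for the best Gini split over all variables
# and all midpoint thresholds of a node's in-bag multiset
oracle_best_split <- function(X, y, counts) {
  idx <- rep(seq_along(counts), counts)
  Xn <- X[idx, , drop = FALSE]
  yn <- y[idx]
  m <- length(yn)
  gini <- function(lab) {
    if (!length(lab)) return(0)
    pr <- tabulate(lab + 1L, 2L) / length(lab)
    1 - sum(pr^2)
  }
  parent <- gini(yn)
  best <- list(dec = 0, var = NA_integer_, thr = NA_real_)
  for (v in seq_len(ncol(Xn))) {
    ux <- sort(unique(Xn[, v]))
    if (length(ux) < 2) next
    for (thr in (ux[-1] + ux[-length(ux)]) / 2) {
      l <- Xn[, v] <= thr
      dec <- parent - mean(l) * gini(yn[l]) - mean(!l) * gini(yn[!l])
      if (dec > best$dec) best <- list(dec = dec, var = v, thr = thr)
    }
  }
  best
}

# brute-force group-presence filter: explicit double loop
oracle_presence_keep <- function(values, classes, min_fraction) {
  keep <- logical(ncol(values))
  for (v in seq_len(ncol(values))) {
    for (g in levels(classes)) {
      rows <- which(classes == g)
      hits <- 0
      for (i in rows) if (values[i, v] > 0) hits <- hits + 1
      if (hits / length(rows) >= min_fraction) keep[v] <- TRUE
    }
  }
  keep
}

# quick strong-signal dataset reused by several files (cached per session)
default_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_dataset(sim_config(seed = 101))
    cache
  }
})
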