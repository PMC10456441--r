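#' Per-tree surrogate minimal depths for all variables
#'
#' For each tree, a variable's surrogate minimal depth is the depth
#' (root = 0) of the shallowest node where it is either the primary
#' splitter or one of the stored surrogate variables.  A variable that
#' appears nowhere in a tree contributes that tree's maximal terminal
#' depth as a bounded penalty.
#'
#' @param forest a fitted `surrogate_forest` (or a hand-built forest
#'   list with the same structure).
#' @param relative divide each tree's depths by that tree's maximal
#'   terminal depth, mapping them to `[0, 1]` (absent variables get
#'   exactly 1).  This scale is comparable across forests whose tree
#'   shapes differ — e.g. shallow trees on strongly separable data
#'   versus deep trees on permuted labels — and is what the selection
#'   threshold is calibrated on.
#' @return numeric matrix, trees in rows, variables in columns.
#' @export
smd_depth_matrix <- function(forest, relative = FALSE) {
  p <- forest$p
  ntree <- length(forest$trees)
  D <- matrix(NA_real_, ntree, p)
  for (t in seq_len(ntree)) {
    tr <- forest$trees[[t]]
    d <- rep(as.numeric(tr$max_depth), p)
    internal <- which(tr$split_var != 0L)
    for (nd in internal) {
      dep <- tr$depth[nd]
      v <- tr$split_var[nd]
      if (dep < d[v]) d[v] <- dep
      sv <- tr$surr_var[[nd]]
      if (length(sv)) {
        upd <- sv[d[sv] > dep]
        if (length(upd)) d[upd] <- dep
      }
    }
    if (relative) d <- d / max(tr$max_depth, 1L)
    D[t, ] <- d
  }
  colnames(D) <- forest$variable_ids
  D
}

#' Surrogate minimal depth (SMD) of one variable
#'
#' @param forest a fitted `surrogate_forest`.
#' @param variable variable id (or column index).
#' @return list with `depths` (per-tree) and `mean`.
#' @export
surrogate_minimal_depth <- function(forest, variable) {
  if (is.character(variable)) {
    idx <- match(variable, forest$variable_ids)
    if (is.na(idx)) stop("unknown variable id: ", variable, call. = FALSE)
  } else {
    idx <- as.integer(variable)
    if (idx < 1 || idx > forest$p)
      stop("variable index out of range", call. = FALSE)
  }
  D <- smd_depth_matrix(forest)
  list(depths = D[, idx], mean = mean(D[, idx]))
}

#' Permutation-null selection threshold for SMD
#'
#' Estimates the null distribution of relative SMD scores by refitting
#' the forest `n_perm` times on the same table with the class labels
#' randomly permuted.  Every variable in such a refit is label-
#' independent by construction while all between-variable structure
#' (spectral collinearity, the row-wise common factor introduced by
#' vector normalization) is preserved, so the refits sample exactly the
#' no-signal behaviour of the real variables.  The threshold is the
#' stated lower quantile of the pooled null scores on the relative
#' depth scale (see [smd_depth_matrix()]), which is comparable across
#' fits whose tree shapes differ.  Variables in the real fit scoring
#' below it sit shallower than essentially any label-independent
#' variable does by chance.
#'
#' @param table the [feature_table()] used for the real fit.
#' @param params the [forest_params()] used for the real fit; the null
#'   refits use identical parameters with derived seeds.
#' @param n_perm number of permuted-label refits pooled (default 3).
#' @param quantile lower quantile of the pooled null score distribution
#'   (default 0.01).
#' @return numeric threshold on the relative depth scale, with
#'   attributes `null_smd` (per-variable null scores, one column per
#'   permutation) and `n_perm`.
#' @export
smd_threshold <- function(table, params, n_perm = 3, quantile = 0.01) {
  stopifnot(inherits(table, "feature_table"))
  if (n_perm < 1) stop_field("n_perm", "must be >= 1")
  cls <- as.character(table$classes)
  null_smd <- vapply(seq_len(n_perm), function(r) {
    perm <- with_seed(child_seed(params$seed, 900L + r), sample(cls))
    ptab <- feature_table(table$values, perm,
                          variables = table$variables,
                          sample_ids = table$sample_ids)
    pparams <- params
    pparams$seed <- child_seed(params$seed, 950L + r)
    colMeans(smd_depth_matrix(fit_forest(ptab, pparams), relative = TRUE))
  }, numeric(ncol(table$values)))
  thr <- as.numeric(stats::quantile(null_smd, probs = quantile,
                                    names = FALSE))
  attr(thr, "null_smd") <- null_smd
  attr(thr, "n_perm") <- n_perm
  thr
}

#' Select variables by surrogate minimal depth
#'
#' @param smd either a fitted `surrogate_forest` (both the absolute
#'   mean SMD and the relative score used for selection are computed
#'   from it) or a named numeric vector of per-variable scores compared
#'   to the threshold directly.
#' @param threshold selection threshold from [smd_threshold()] (on the
#'   relative depth scale when `smd` is a forest); variables scoring
#'   strictly below it are selected.
#' @param variables optional variable metadata (data frame with `id`
#'   and `block`) used to tag the result when `smd` is a plain vector.
#' @return an `smd_result`: a data frame sorted ascending by the
#'   selection score (ties keep variable order) with columns `id`,
#'   `block`, `mean_depth` (absolute mean SMD, root = 0),
#'   `relative_depth` (per-tree depth over maximal terminal depth) and
#'   `selected`, plus attributes `threshold` and `selected_ids`.
#' @export
select_variables <- function(smd, threshold, variables = NULL) {
  if (inherits(smd, "surrogate_forest")) {
    means <- colMeans(smd_depth_matrix(smd))
    score <- colMeans(smd_depth_matrix(smd, relative = TRUE))
    blocks <- smd$variables$block
  } else {
    means <- smd
    score <- smd
    blocks <- rep(NA_character_, length(means))
    if (!is.null(variables))
      blocks <- variables$block[match(names(means), variables$id)]
  }
  ord <- order(score)  # stable: ties keep variable id order
  res <- data.frame(id = names(means)[ord], block = blocks[ord],
                    mean_depth = as.numeric(means)[ord],
                    relative_depth = as.numeric(score)[ord],
                    selected = as.numeric(score)[ord] <
                      as.numeric(threshold),
                    stringsAsFactors = FALSE)
  structure(res, threshold = as.numeric(threshold),
            selected_ids = res$id[res$selected],
            class = c("smd_result", "data.frame"))
}

#' @export
print.smd_result <- function(x, ...) {
  cat(sprintf("<smd_result> %d / %d variables selected (threshold %.4g)\n",
              sum(x$selected), nrow(x), attr(x, "threshold")))
  print.data.frame(utils::head(x, 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}
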