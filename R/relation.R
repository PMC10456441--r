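#' Mean adjusted agreement between variables
#'
#' For an ordered pair (i, j), the relation value is the average over
#' all nodes of all trees where i is the primary splitter of the stored
#' adjusted agreement of j at that node (0 when j is not among the
#' node's stored surrogates).  Variables that never act as primary
#' splitter get a zero row.  The asymmetric matrix R is symmetrized as
#' S = (R + t(R)) / 2 and the diagonal of S is fixed at 1.  High values
#' mean two variables influence the classification model in a mutually
#' replaceable way.
#'
#' @param forest a fitted `surrogate_forest` with stored surrogates.
#' @param variables variable ids to relate (typically the SMD-selected
#'   set); defaults to all forest variables.
#' @return a `relation_matrix` with elements `S` (symmetrized, unit
#'   diagonal), `R` (raw asymmetric), `variables` (metadata incl.
#'   blocks) and `n_never_primary`.
#' @export
mean_adjusted_agreement <- function(forest, variables = NULL) {
  stopifnot(inherits(forest, "surrogate_forest"))
  if (is.null(variables)) variables <- forest$variable_ids
  if (length(variables) == 0) stop("empty variable set", call. = FALSE)
  idx <- match(variables, forest$variable_ids)
  if (anyNA(idx))
    stop("unknown variable id(s): ",
         paste(variables[is.na(idx)], collapse = ", "), call. = FALSE)
  k <- length(idx)
  pos <- integer(forest$p)           # forest index -> selected position
  pos[idx] <- seq_len(k)
  acc <- matrix(0, k, k)
  nodes_as_primary <- numeric(k)
  for (tr in forest$trees) {
    internal <- which(tr$split_var != 0L)
    for (nd in internal) {
      i <- pos[tr$split_var[nd]]
      if (i == 0L) next
      nodes_as_primary[i] <- nodes_as_primary[i] + 1
      sv <- tr$surr_var[[nd]]
      if (length(sv)) {
        sel <- pos[sv]
        keep <- sel != 0L
        if (any(keep))
          acc[i, sel[keep]] <- acc[i, sel[keep]] + tr$surr_adj[[nd]][keep]
      }
    }
  }
  R <- acc / pmax(nodes_as_primary, 1)
  R[nodes_as_primary == 0, ] <- 0
  dimnames(R) <- list(variables, variables)
  S <- (R + t(R)) / 2
  diag(S) <- 1
  vmeta <- forest$variables[idx, , drop = FALSE]
  structure(list(S = S, R = R, variables = vmeta,
                 n_never_primary = sum(nodes_as_primary == 0)),
            class = "relation_matrix")
}

#' @export
print.relation_matrix <- function(x, ...) {
  cat(sprintf("<relation_matrix> %d variables; mean off-diagonal %.3f\n",
              nrow(x$S), mean(x$S[upper.tri(x$S)])))
  if (x$n_never_primary > 0)
    cat(sprintf("(%d variable(s) never split primarily: zero rows in R)\n",
                x$n_never_primary))
  invisible(x)
}

#' Low-level data fusion of feature blocks
#'
#' Column-wise concatenation of preprocessed feature tables from
#' different instruments into one table for a joint model, with block
#' tags preserved.  No rescaling beyond each block's own preprocessing
#' is applied unless `autoscale_after = TRUE`.  Fusing the 1727-variable
#' LC-MS table with the 744-variable NIR table gives 2471 variables and
#' a default mtry of 350.
#'
#' @param tables list of [feature_table()]s with identical samples (ids,
#'   order and classes) and disjoint variable ids.
#' @param autoscale_after re-autoscale the merged table (default FALSE).
#' @return the fused [feature_table()].
#' @export
low_level_fuse <- function(tables, autoscale_after = FALSE) {
  stopifnot(is.list(tables), length(tables) >= 2)
  ref <- tables[[1L]]
  for (t in tables[-1L]) {
    if (!identical(t$sample_ids, ref$sample_ids)) {
      bad <- union(setdiff(t$sample_ids, ref$sample_ids),
                   setdiff(ref$sample_ids, t$sample_ids))
      stop("sample ids do not match across blocks",
           if (length(bad)) paste0(": ", paste(utils::head(bad, 5L),
                                               collapse = ", ")) else
             " (same ids, different order)", call. = FALSE)
    }
    if (!identical(as.character(t$classes), as.character(ref$classes)))
      stop("class labels disagree across blocks", call. = FALSE)
  }
  ids <- unlist(lapply(tables, function(t) t$variables$id))
  if (anyDuplicated(ids))
    stop("variable ids must be disjoint across blocks", call. = FALSE)
  values <- do.call(cbind, lapply(tables, function(t) t$values))
  cols <- Reduce(function(a, b) union(a, b),
                 lapply(tables, function(t) names(t$variables)))
  vars <- do.call(rbind, lapply(tables, function(t) {
    v <- t$variables
    for (mis in setdiff(cols, names(v))) v[[mis]] <- NA
    v[, cols, drop = FALSE]
  }))
  out <- feature_table(values, ref$classes, variables = vars,
                       sample_ids = ref$sample_ids)
  if (autoscale_after) out <- autoscale(out)
  out
}

#' Ward clustering of the relation matrix
#'
#' Rows of the symmetrized relation matrix are clustered with Euclidean
#' distances and the Ward algorithm, and the tree is cut into `k`
#' clusters.  With the default k = 3 the typical outcome on fused data
#' is one single-block LC-MS cluster, one single-block NIR cluster and —
#' when two instruments see the same underlying compounds — one
#' mixed-block cluster.
#'
#' @param relation a `relation_matrix`.
#' @param k number of clusters (default 3).
#' @return a `cluster_report`: cluster `assignments` (named integer
#'   vector), per-cluster block `composition`, logical `mixed` flags,
#'   the `hclust` object and the variable metadata.
#' @export
cluster_relation_matrix <- function(relation, k = 3) {
  stopifnot(inherits(relation, "relation_matrix"))
  S <- relation$S
  if (k > nrow(S)) stop_field("k", "more clusters than variables")
  hc <- stats::hclust(stats::dist(S, method = "euclidean"),
                      method = "ward.D2")
  assignments <- stats::cutree(hc, k = k)
  blocks <- relation$variables$block
  composition <- table(cluster = assignments, block = blocks)
  mixed <- apply(composition > 0, 1L, sum) > 1
  structure(list(assignments = assignments, composition = composition,
                 mixed = mixed, hclust = hc, variables = relation$variables,
                 k = k),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> %d clusters over %d variables\n", x$k,
              length(x$assignments)))
  print(x$composition)
  invisible(x)
}

#' Cross-modal cluster summary
#'
#' Labels each cluster of a [cluster_relation_matrix()] result as
#' single-block or mixed-block and lists its member variables with
#' their axis metadata (wavenumbers, m/z), so clusters joining LC-MS
#' and NIR variables — evidence that both instruments report the same
#' underlying compounds — are immediately visible.
#'
#' @param report a `cluster_report`.
#' @return data frame with one row per cluster: `cluster`, `size`,
#'   per-block counts, `type` (`"single-block"` / `"mixed-block"`) and
#'   a `members` list-column of per-cluster variable metadata.
#' @export
cross_modal_report <- function(report) {
  stopifnot(inherits(report, "cluster_report"))
  comp <- as.data.frame.matrix(report$composition)
  out <- data.frame(cluster = as.integer(rownames(comp)),
                    size = rowSums(comp), comp,
                    type = ifelse(report$mixed, "mixed-block",
                                  "single-block"),
                    stringsAsFactors = FALSE)
  out$members <- lapply(out$cluster, function(cl) {
    report$variables[report$assignments == cl, , drop = FALSE]
  })
  rownames(out) <- NULL
  out
}

#' Write a relation matrix (CSV) and dendrogram (Newick)
#'
#' The symmetrized matrix is written as a square CSV whose header names
#' are the block-prefixed variable ids; the cluster dendrogram can be
#' exported in Newick format for external tree viewers (requires the
#' `ape` package).
#'
#' @param relation a `relation_matrix`.
#' @param path CSV path.
#' @export
write_relation_matrix <- function(relation, path) {
  stopifnot(inherits(relation, "relation_matrix"))
  S <- relation$S
  ids <- paste(relation$variables$block, relation$variables$id, sep = ":")
  dimnames(S) <- list(ids, ids)
  utils::write.csv(as.data.frame(S), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_relation_matrix
#' @param report a `cluster_report`.
#' @export
write_dendrogram_newick <- function(report, path) {
  stopifnot(inherits(report, "cluster_report"))
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the `ape` package is required for Newick export", call. = FALSE)
  phy <- ape::as.phylo(report$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
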