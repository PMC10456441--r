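#' Default mtry: the 3/4 power rule
#'
#' Number of candidate variables drawn at each node, computed as the
#' floor of the 3/4 power of the total variable count (minimum 1).  For
#' p = 1727, 744, 411 and 2471 this gives 267, 142, 91 and 350.
#'
#' @param p number of variables (>= 1).
#' @return integer mtry.
#' @export
default_mtry <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || p < 1)
    stop_field("p", "must be a single count >= 1")
  max(1L, as.integer(floor(p^0.75)))
}

#' Default class weights: inverse class-size balancing
#'
#' Each class is weighted by the size of the largest class divided by
#' its own size, so the largest class gets weight 1 and smaller classes
#' are upweighted.  Used as bootstrap sampling weights to compensate
#' class imbalance.
#'
#' @param class_counts named vector or table of per-class sample counts.
#' @return named numeric vector of per-class weights.
#' @export
default_class_weights <- function(class_counts) {
  cc <- c(class_counts)
  if (any(cc <= 0)) stop_field("class_counts", "all counts must be > 0")
  w <- max(cc) / cc
  names(w) <- names(class_counts)
  w
}

#' Number of surrogate variables stored per node
#'
#' `ceiling(fraction * p)`: 5% of 1727 LC-MS variables gives 87, 20% of
#' 744 NIR variables gives 149.  A larger fraction suits blocks with
#' higher collinearity (spectra).
#'
#' @param p number of variables.
#' @param fraction fraction of variables, in (0, 1].
#' @return integer surrogate count.
#' @export
surrogate_count <- function(p, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop_field("fraction", "must be in (0, 1]")
  if (!is.numeric(p) || length(p) != 1L || p < 1)
    stop_field("p", "must be a single count >= 1")
  as.integer(ceiling(fraction * p))
}

#' Forest hyper-parameters
#'
#' @param ntree number of trees (the full-scale analysis uses 10,000;
#'   desk-scale runs use fewer).
#' @param mtry candidate variables per node; `NULL` means
#'   [default_mtry()] of the table width at fit time.
#' @param min_node_size minimal node size to attempt a split (1 grows
#'   trees to purity).
#' @param s surrogate splits stored per node; `NULL` means
#'   [surrogate_count()] with `s_fraction`.
#' @param s_fraction fraction used when `s` is `NULL` (default 0.05).
#' @param case_weights per-sample sampling weights; `NULL` means
#'   per-class weights from [default_class_weights()].
#' @param seed integer seed for the forest's own RNG stream.
#' @return a `forest_params` list.
#' @export
forest_params <- function(ntree = 10000, mtry = NULL, min_node_size = 1,
                          s = NULL, s_fraction = 0.05, case_weights = NULL,
                          seed = 1) {
  stopifnot(ntree >= 1, min_node_size >= 1)
  structure(list(ntree = as.integer(ntree), mtry = mtry,
                 min_node_size = as.integer(min_node_size), s = s,
                 s_fraction = s_fraction, case_weights = case_weights,
                 seed = as.integer(seed)),
            class = "forest_params")
}

#' Fit a surrogate random forest
#'
#' Grows `ntree` unpruned CART-style classification trees.  Each tree is
#' built on a bootstrap sample of size n drawn with replacement with
#' selection probabilities proportional to the case weights; samples
#' never drawn form the tree's out-of-bag (OOB) set (about 37% of the
#' samples under equal weights).  At each node, `mtry` candidate
#' variables are drawn without replacement and the split maximizing the
#' Gini impurity decrease over midpoint thresholds is chosen; ties
#' resolve to the lower variable index, then the lower threshold.  At
#' every internal node the `s` best surrogate splits — splits on other
#' variables that best mimic the primary routing, scored by adjusted
#' agreement — are stored for surrogate minimal depth and relation
#' analysis.
#'
#' @param table a [feature_table()].
#' @param params a [forest_params()] object.
#' @return an object of class `surrogate_forest`.
#' @export
fit_forest <- function(table, params = forest_params()) {
  stopifnot(inherits(table, "feature_table"))
  X <- table$values
  n <- nrow(X)
  p <- ncol(X)
  cls <- table$classes
  counts <- table(cls)
  if (any(counts < 2))
    stop("need at least 2 samples per class", call. = FALSE)
  mtry <- if (is.null(params$mtry)) default_mtry(p) else as.integer(params$mtry)
  if (mtry < 1 || mtry > p)
    stop_field("mtry", sprintf("must be in [1, %d]", p))
  s <- if (is.null(params$s)) surrogate_count(p, params$s_fraction) else
    as.integer(params$s)
  w <- params$case_weights
  if (is.null(w)) {
    cw <- default_class_weights(counts)
    w <- as.numeric(cw[as.character(cls)])
  }
  if (length(w) != n || any(w <= 0))
    stop_field("case_weights", "need one positive weight per sample")
  y <- as.integer(cls) - 1L  # 0 = organic, 1 = conventional
  fit <- rf_fit_cpp(X, y, w, params$ntree, mtry, params$min_node_size,
                    s, params$seed)
  params$mtry <- mtry
  params$s <- s
  params$case_weights <- w
  structure(list(trees = fit$trees, oob = fit$oob, inbag = fit$inbag,
                 params = params, variable_ids = colnames(X),
                 variables = table$variables,
                 class_levels = levels(cls), n = n, p = p),
            class = "surrogate_forest")
}

#' @export
print.surrogate_forest <- function(x, ...) {
  cat(sprintf(
    "<surrogate_forest> %d trees, %d samples x %d variables (mtry %d, s %d)\n",
    length(x$trees), x$n, x$p, x$params$mtry, x$params$s))
  invisible(x)
}

votes_matrix <- function(forest, values) {
  if (!identical(colnames(values), forest$variable_ids))
    stop("variable set of the new data does not match the forest",
         call. = FALSE)
  rf_predict_cpp(forest$trees, values)
}

majority_label <- function(votes_1, votes_2, levels) {
  # per-sample majority with deterministic ties to the first class level
  factor(ifelse(votes_2 > votes_1, levels[2L], levels[1L]), levels = levels)
}

#' Surrogate splits for a single node
#'
#' Given the in-bag data of a node (rows may repeat to reflect
#' bootstrap multiplicity) and its accepted primary split, finds for
#' every other candidate variable the split that best mimics the
#' primary routing.  The agreement A of a mimicking split is the
#' fraction of node samples routed the same way as the primary split
#' (direction reversal allowed); the adjusted agreement rescales it
#' against the majority-direction baseline m = max(p_L, p_R):
#' (A - m) / (1 - m), which is 1 for a perfect mimic and <= 0 for a
#' split no better than always guessing the larger side.  Only
#' surrogates with positive adjusted agreement are kept, sorted
#' descending, ties broken by the lower variable index.
#'
#' @param values numeric matrix of the node's in-bag samples.
#' @param primary column index (or name) of the primary split variable.
#' @param threshold primary split threshold (`x <= threshold` goes
#'   left).
#' @param s maximal number of surrogates to return.
#' @param candidates column indices to search (default: all but the
#'   primary).
#' @return data frame with columns `variable` (column index),
#'   `adjusted_agreement` and `direction` (+1 when `x <= thr` routes
#'   with the primary left branch, -1 when reversed); zero rows when
#'   the primary split is degenerate (m = 1).
#' @export
find_surrogates <- function(values, primary, threshold, s,
                            candidates = NULL) {
  values <- as.matrix(values)
  if (is.character(primary)) primary <- match(primary, colnames(values))
  route_left <- values[, primary] <= threshold
  m <- nrow(values)
  TL <- sum(route_left)
  mfrac <- max(TL, m - TL) / m
  empty <- data.frame(variable = integer(0),
                      adjusted_agreement = numeric(0),
                      direction = integer(0))
  if (mfrac == 1) return(empty)
  if (is.null(candidates)) candidates <- setdiff(seq_len(ncol(values)),
                                                 primary)
  rows <- lapply(candidates, function(j) {
    x <- values[, j]
    ux <- sort(unique(x))
    if (length(ux) < 2) return(NULL)
    thr <- (ux[-1] + ux[-length(ux)]) / 2
    best_cnt <- -1L          # integer agreement counts: exact comparisons
    bestDir <- 1L
    for (tt in thr) {
      left <- x <= tt
      same <- sum(left == route_left)
      rev <- m - same
      if (same >= rev) {
        if (same > best_cnt) { best_cnt <- same; bestDir <- 1L }
      } else if (rev > best_cnt) {
        best_cnt <- rev; bestDir <- -1L
      }
    }
    if (best_cnt <= max(TL, m - TL)) return(NULL)
    adj <- (best_cnt / m - mfrac) / (1 - mfrac)
    data.frame(variable = j, adjusted_agreement = adj, direction = bestDir)
  })
  out <- do.call(rbind, c(list(empty), rows))
  out <- out[order(-out$adjusted_agreement, out$variable), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, s)
}

#' Predict class labels with a fitted forest
#'
#' Majority vote over all trees; ties resolve to the first class level.
#'
#' @param object a fitted `surrogate_forest`.
#' @param newdata a [feature_table()] (or numeric matrix) with the same
#'   variables as the training table.
#' @param ... unused.
#' @return factor of predicted class labels.
#' @export
predict.surrogate_forest <- function(object, newdata, ...) {
  values <- if (inherits(newdata, "feature_table")) newdata$values else
    as.matrix(newdata)
  votes <- votes_matrix(object, values)
  v2 <- colSums(votes == 2L)
  v1 <- nrow(votes) - v2
  out <- majority_label(v1, v2, object$class_levels)
  names(out) <- rownames(values)
  out
}

#' Out-of-bag confusion summary
#'
#' Each sample is predicted by majority vote over only the trees in
#' which it was out-of-bag, giving an unbiased error estimate without a
#' separate test set.  The summary is row-normalized per true class (in
#' percent): the diagonal percentages are the per-class sensitivities,
#' the per-predicted-class precision is reported in the "Specificity"
#' row of the printed layout, and the overall accuracy is the percentage
#' of correctly classified samples.  Samples that are OOB in no tree
#' (possible at very small ntree) are excluded and counted.
#'
#' @param forest a fitted `surrogate_forest`.
#' @param table the training [feature_table()].
#' @return an object of class `confusion_summary` with elements
#'   `table` (2x2 row percentages), `sensitivity`, `precision`,
#'   `accuracy` (percent), `counts`, `n_excluded` and `oob_predictions`.
#' @export
oob_confusion <- function(forest, table) {
  stopifnot(inherits(forest, "surrogate_forest"),
            inherits(table, "feature_table"))
  votes <- votes_matrix(forest, table$values)
  oob <- forest$oob
  v2 <- colSums(votes * oob == 2L) # votes for class level 2, OOB trees only
  ntr <- colSums(oob)
  v1 <- ntr - v2
  usable <- ntr > 0
  n_excluded <- sum(!usable)
  if (n_excluded > 0)
    warning(n_excluded, " sample(s) out-of-bag in no tree were excluded ",
            "from the OOB confusion", call. = FALSE)
  lv <- forest$class_levels
  pred <- majority_label(v1, v2, lv)
  truth <- table$classes
  cm <- base::table(truth = truth[usable], predicted = pred[usable])
  pct <- sweep(cm, 1L, rowSums(cm), "/") * 100
  sens <- diag(pct)
  prec <- 100 * diag(cm) / colSums(cm)
  acc <- 100 * sum(diag(cm)) / sum(cm)
  structure(list(table = unclass(pct), counts = unclass(cm),
                 sensitivity = sens, precision = prec, accuracy = acc,
                 n_excluded = n_excluded,
                 oob_predictions = stats::setNames(pred, table$sample_ids)),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  lv <- rownames(x$table)
  m <- rbind(cbind(x$table, Sensitivity = x$sensitivity),
             `Specificity (%)` = c(x$precision, x$accuracy))
  colnames(m) <- c(paste0("Predicted ", lv, " (%)"), "Sensitivity (%)")
  rownames(m)[seq_along(lv)] <- paste0("True ", lv, " (%)")
  print(round(m, 1))
  if (x$n_excluded > 0)
    cat(sprintf("(%d sample(s) excluded: out-of-bag in no tree)\n",
                x$n_excluded))
  invisible(x)
}
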