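#' Group-presence filter for LC-MS bucket tables
#'
#' A bucket (feature) is kept if it is detectable in at least
#' `min_fraction` of the samples of at least one class group.  With the
#' default of 0.5 this is the rule "detectable in at least 50% of all
#' samples from one sample group".  Detectability defaults to a value
#' strictly greater than zero, since bucket tables encode absence as 0;
#' set `detect = "nonmissing"` to count non-NA entries instead.
#'
#' @param table a [feature_table()] with both classes present.
#' @param min_fraction required presence fraction in (0, 1].
#' @param detect `"positive"` (value > 0, default) or `"nonmissing"`.
#' @return the filtered [feature_table()], variable order preserved.
#' @export
group_presence_filter <- function(table, min_fraction = 0.5,
                                  detect = c("positive", "nonmissing")) {
  stopifnot(inherits(table, "feature_table"))
  detect <- match.arg(detect)
  if (min_fraction <= 0 || min_fraction > 1)
    stop_field("min_fraction", "must be in (0, 1]")
  cls <- table$classes
  if (any(tabulate(cls, 2L) == 0))
    stop("both classes must contain at least one sample", call. = FALSE)
  present <- if (detect == "positive") table$values > 0 else
    !is.na(table$values)
  keep <- rep(FALSE, ncol(table$values))
  for (g in levels(cls)) {
    frac <- colMeans(present[cls == g, , drop = FALSE])
    keep <- keep | frac >= min_fraction
  }
  subset_variables(table, which(keep))
}

subset_variables <- function(table, idx) {
  out <- feature_table(table$values[, idx, drop = FALSE], table$classes,
                       variables = table$variables[idx, , drop = FALSE],
                       sample_ids = table$sample_ids)
  for (a in c("scaling", "preprocess_state"))
    if (!is.null(attr(table, a))) attr(out, a) <- attr(table, a)
  out
}

#' Vector normalization (unit row norm)
#'
#' Divides every sample row by its Euclidean norm so each sample
#' spectrum/profile has norm 1, removing global intensity differences
#' between runs.
#'
#' @param table a [feature_table()] with no all-zero sample.
#' @return the normalized [feature_table()].
#' @export
vector_normalize <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  nrm <- sqrt(rowSums(table$values^2))
  zero <- nrm == 0
  if (any(zero))
    stop("zero-norm sample row(s): ",
         paste(table$sample_ids[zero], collapse = ", "), call. = FALSE)
  out <- table
  out$values <- table$values / nrm
  out
}

#' Autoscaling (column standardization)
#'
#' Centers every variable to mean 0 and scales to sample standard
#' deviation 1 (denominator n - 1).  The column means and standard
#' deviations are stored in the `"scaling"` attribute so the same
#' transform can be applied to new data.
#'
#' @param table a [feature_table()]; every column needs nonzero variance.
#' @return the autoscaled [feature_table()].
#' @export
autoscale <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  mu <- colMeans(table$values)
  sdev <- apply(table$values, 2L, stats::sd)
  bad <- sdev == 0
  if (any(bad))
    stop("constant variable(s) cannot be autoscaled: ",
         paste(utils::head(table$variables$id[bad], 5L), collapse = ", "),
         call. = FALSE)
  out <- table
  out$values <- scale(table$values, center = mu, scale = sdev)
  attr(out$values, "scaled:center") <- NULL
  attr(out$values, "scaled:scale") <- NULL
  attr(out, "scaling") <- list(center = as.numeric(mu),
                               scale = as.numeric(sdev))
  out
}

#' LC-MS bucket-table preprocessing
#'
#' Group-presence filter, then vector normalization, then autoscaling —
#' the standard processing of an exported bucket table before
#' classification.
#'
#' @param table raw bucket [feature_table()] (non-negative intensities,
#'   absence encoded as 0).
#' @param min_fraction presence fraction for [group_presence_filter()].
#' @return preprocessed [feature_table()] with block tag `"lcms"`.
#' @export
preprocess_lcms <- function(table, min_fraction = 0.5) {
  out <- group_presence_filter(table, min_fraction)
  out <- vector_normalize(out)
  out <- autoscale(out)
  out$variables$block <- "lcms"
  colnames(out$values) <- out$variables$id
  out
}

#' Photometric spectrum preprocessing
#'
#' Vector normalization followed by autoscaling, i.e. the same chain as
#' for LC-MS but without the presence filter, which is meaningless for
#' dense absorbance spectra.
#'
#' @param table raw photometry [feature_table()] (380-790 nm at 1 nm
#'   resolution gives 411 variables).
#' @return preprocessed [feature_table()] with block tag `"photometry"`.
#' @export
preprocess_photometry <- function(table) {
  out <- vector_normalize(table)
  out <- autoscale(out)
  out$variables$block <- "photometry"
  out
}
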