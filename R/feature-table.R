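#' Feature tables: the common container for all data blocks
#'
#' A `feature_table` holds a samples x variables numeric matrix together
#' with per-sample class labels (organic / conventional) and per-variable
#' metadata: a variable id, the block it belongs to (`"lcms"`, `"nir"` or
#' `"photometry"`) and its physical axis (m/z and retention time for
#' LC-MS buckets, wavenumber in cm^-1 for NIR bins, wavelength in nm for
#' photometry).  Every preprocessing, classification and relation stage
#' consumes and produces this container.
#'
#' @param values numeric matrix, samples in rows, variables in columns.
#'   Column names are used as variable ids when `variables` is missing.
#' @param classes factor or character vector of per-sample class labels
#'   with exactly the levels `"organic"` and `"conventional"`.
#' @param variables optional data frame of variable metadata with at
#'   least columns `id` and `block`; axis columns (`mz`, `rt`,
#'   `wavenumber_cm1`, `wavelength_nm`) are carried along untouched.
#' @param block default block tag applied when `variables` is missing.
#' @param sample_ids optional character vector of sample ids; defaults
#'   to the rownames of `values`.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, classes, variables = NULL,
                          block = "lcms", sample_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  p <- ncol(values)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- sprintf("sample_%03d", seq_len(n))
  }
  if (length(sample_ids) != n)
    stop_field("sample_ids", "length must equal the number of rows")
  classes <- as_class_factor(classes)
  if (length(classes) != n)
    stop_field("classes", "length must equal the number of rows")
  if (anyNA(values) || any(!is.finite(values)))
    stop_field("values", "all values must be finite")
  if (is.null(variables)) {
    ids <- colnames(values)
    if (is.null(ids)) ids <- sprintf("%s_%04d", block, seq_len(p))
    variables <- data.frame(id = ids, block = rep(block, p),
                            stringsAsFactors = FALSE)
  }
  variables <- as.data.frame(variables)
  if (!all(c("id", "block") %in% names(variables)))
    stop_field("variables", "must contain columns `id` and `block`")
  if (nrow(variables) != p)
    stop_field("variables", "one row per variable is required")
  if (anyDuplicated(variables$id))
    stop_field("variables", "variable ids must be unique")
  rownames(values) <- sample_ids
  colnames(values) <- variables$id
  structure(list(values = values, classes = classes,
                 variables = variables, sample_ids = sample_ids),
            class = "feature_table")
}

as_class_factor <- function(x) {
  lv <- c("organic", "conventional")
  if (is.factor(x)) x <- as.character(x)
  if (!all(x %in% lv))
    stop_field("classes", "labels must be 'organic' or 'conventional'")
  factor(x, levels = lv)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d variables\n",
              nrow(x$values), ncol(x$values)))
  cat("  blocks:", paste(sprintf("%s (%d)", names(table(x$variables$block)),
                                 table(x$variables$block)), collapse = ", "),
      "\n")
  cat("  classes:", paste(sprintf("%s (%d)", levels(x$classes),
                                  table(x$classes)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Write / read a feature table as CSV with a JSON metadata sidecar
#'
#' The CSV layout is `sample_id, class, <variable ids...>` with one row
#' per sample.  Variable metadata (block tags, axis values) and any
#' stored preprocessing parameters go to `<path>.meta.json`, so a table
#' round-trips losslessly.
#'
#' @param x a [feature_table()].
#' @param path CSV file path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a [feature_table()].
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  df <- data.frame(sample_id = x$sample_ids,
                   class = as.character(x$classes),
                   x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(variables = x$variables)
  for (a in c("scaling", "preprocess_state"))
    if (!is.null(attr(x, a))) meta[[a]] <- attr(x, a)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "class") %in% names(df)))
    stop("malformed feature table CSV: columns `sample_id` and `class` ",
         "are required in ", path, call. = FALSE)
  vals <- as.matrix(df[, setdiff(names(df), c("sample_id", "class")),
                       drop = FALSE])
  meta_path <- paste0(path, ".meta.json")
  variables <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    variables <- as.data.frame(meta$variables)
  }
  ft <- feature_table(vals, df$class, variables = variables,
                      sample_ids = df$sample_id)
  if (file.exists(meta_path) && !is.null(meta$scaling))
    attr(ft, "scaling") <- meta$scaling
  ft
}
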