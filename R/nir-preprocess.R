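#' Replicate NIR spectra container
#'
#' FT-NIR measurements are acquired as several technical replicates per
#' sample on one shared wavenumber grid.  The container stores all
#' replicates of all samples as one matrix (rows are replicates, columns
#' grid points) so the preprocessing chain can be applied vectorised.
#'
#' @param values numeric matrix, one row per replicate spectrum.
#' @param grid wavenumber grid in cm^-1, strictly monotone, one value
#'   per column of `values`.
#' @param sample_ids character vector, one entry per replicate row,
#'   naming the sample each replicate belongs to.
#' @param classes per-sample class labels, named by unique sample id or
#'   ordered as `unique(sample_ids)`.
#' @return an object of class `replicate_spectra`.
#' @export
replicate_spectra <- function(values, grid, sample_ids, classes) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(grid) != ncol(values))
    stop_field("grid", "length must equal the number of spectral points")
  dg <- diff(grid)
  if (length(dg) && !(all(dg > 0) || all(dg < 0)))
    stop_field("grid", "wavenumber grid must be strictly monotone")
  if (length(sample_ids) != nrow(values))
    stop_field("sample_ids", "one id per replicate row is required")
  if (any(!is.finite(values)))
    stop_field("values", "absorbances must be finite")
  uid <- unique(sample_ids)
  classes <- as_class_factor(classes)
  if (!is.null(names(classes))) classes <- classes[uid]
  if (length(classes) != length(uid))
    stop_field("classes", "one label per unique sample id is required")
  names(classes) <- uid
  structure(list(values = values, grid = as.numeric(grid),
                 sample_ids = as.character(sample_ids), classes = classes),
            class = "replicate_spectra")
}

#' @export
print.replicate_spectra <- function(x, ...) {
  cat(sprintf(
    "<replicate_spectra> %d samples, %d replicate spectra, %d points (%.0f-%.0f cm-1)\n",
    length(unique(x$sample_ids)), nrow(x$values), length(x$grid),
    max(x$grid), min(x$grid)))
  invisible(x)
}

#' Multiplicative scatter correction
#'
#' Each spectrum `x` is regressed on a reference spectrum,
#' `x = a + b * reference + e`, and returned as `(x - a) / b`.  This
#' removes the additive and multiplicative scatter caused by varying
#' particle size.  The reference defaults to the mean of the input
#' spectra and should be stored and reused when correcting new data.
#'
#' @param spectra numeric matrix (rows = spectra) or a single vector.
#' @param reference reference spectrum; defaults to `colMeans(spectra)`.
#' @return matrix (or vector) of corrected spectra with attribute
#'   `"reference"` carrying the reference used.
#' @export
msc <- function(spectra, reference = NULL) {
  vec_in <- is.null(dim(spectra))
  spectra <- rbind(spectra)
  if (is.null(reference)) reference <- colMeans(spectra)
  if (length(reference) != ncol(spectra))
    stop_field("reference", "length must match the spectra")
  if (stats::sd(reference) == 0)
    stop_field("reference", "reference spectrum is constant")
  rc <- reference - mean(reference)
  denom <- sum(rc * rc)
  b <- as.numeric(spectra %*% rc) / denom          # slope of x ~ reference
  a <- rowMeans(spectra) - b * mean(reference)
  bad <- abs(b) < 1e-12
  if (any(bad))
    stop("degenerate spectrum in MSC (slope ~ 0) at replicate row(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  out <- (spectra - a) / b
  dimnames(out) <- dimnames(spectra)
  attr(out, "reference") <- as.numeric(reference)
  if (vec_in) {
    out <- structure(out[1L, ], reference = as.numeric(reference))
  }
  out
}

#' First derivative of a spectrum on an even grid
#'
#' Central differences in the interior, one-sided differences at the two
#' ends, so the output keeps the input length.  Offsets and other purely
#' additive baseline effects are removed by this step.
#'
#' @param spectrum numeric vector or matrix (rows = spectra).
#' @param grid axis values (evenly spaced, ascending or descending).
#' @return derivative with the same shape as the input.
#' @export
first_derivative <- function(spectrum, grid) {
  vec_in <- is.null(dim(spectrum))
  spectrum <- rbind(spectrum)
  np <- ncol(spectrum)
  if (np < 3) stop("need at least 3 points for a derivative", call. = FALSE)
  if (length(grid) != np)
    stop_field("grid", "length must match the spectrum")
  dg <- diff(grid)
  if (max(abs(dg - dg[1])) > 1e-6 * abs(dg[1]))
    stop_field("grid", "grid must be evenly spaced")
  h <- dg[1]
  out <- spectrum
  i <- 2:(np - 1)
  out[, i] <- (spectrum[, i + 1, drop = FALSE] -
               spectrum[, i - 1, drop = FALSE]) / (2 * h)
  out[, 1] <- (spectrum[, 2] - spectrum[, 1]) / h
  out[, np] <- (spectrum[, np] - spectrum[, np - 1]) / h
  if (vec_in) out[1L, ] else out
}

# SG convolution weights for the smoothing (0th derivative) case:
# value at the window centre of the least-squares polynomial fit
sg_weights <- function(window, polyorder) {
  if (window %% 2 != 1) stop_field("window", "must be odd")
  if (polyorder >= window)
    stop_field("polyorder", "must be smaller than the window")
  half <- (window - 1) / 2
  A <- outer(-half:half, 0:polyorder, `^`)
  # first row of (A'A)^-1 A' gives the fitted value at offset 0
  solve(crossprod(A), t(A))[1L, ]
}

#' Savitzky-Golay smoothing
#'
#' Replaces each point by the centre value of a least-squares polynomial
#' of degree `polyorder` fitted over the surrounding window, improving
#' the signal-to-noise ratio while preserving low-degree structure.  The
#' first and last half-windows are filled from least-squares polynomial
#' fits over the first and last full window, so polynomials of degree
#' <= `polyorder` pass through unchanged over the whole length.
#'
#' @param spectrum numeric vector or matrix (rows = spectra).
#' @param window odd window length (default 11).
#' @param polyorder polynomial degree (default 2), `< window`.
#' @return smoothed spectrum, same shape as the input.
#' @export
savitzky_golay_smooth <- function(spectrum, window = 11, polyorder = 2) {
  vec_in <- is.null(dim(spectrum))
  spectrum <- rbind(spectrum)
  np <- ncol(spectrum)
  if (window >= np)
    stop("window must be shorter than the spectrum", call. = FALSE)
  wts <- sg_weights(window, polyorder)
  half <- (window - 1) / 2
  out <- matrix(0, nrow(spectrum), np, dimnames = dimnames(spectrum))
  # interior: convolution with the centred weights
  mid <- (half + 1):(np - half)
  for (k in seq_len(window))
    out[, mid] <- out[, mid] +
      wts[k] * spectrum[, mid + k - half - 1, drop = FALSE]
  # edges: fitted values of the polynomial over the first / last window
  A <- outer(0:(window - 1), 0:polyorder, `^`)
  Fe <- A %*% solve(crossprod(A), t(A))
  out[, 1:half] <- spectrum[, 1:window, drop = FALSE] %*%
    t(Fe[1:half, , drop = FALSE])
  out[, (np - half + 1):np] <- spectrum[, (np - window + 1):np,
                                        drop = FALSE] %*%
    t(Fe[(half + 2):window, , drop = FALSE])
  if (vec_in) out[1L, ] else out
}

#' Bin adjacent spectral variables
#'
#' Consecutive non-overlapping groups of `bin_width` points are averaged;
#' a shorter trailing group is averaged over its available points.  The
#' binned axis value is the mean axis value of each group.  Binning five
#' adjacent wavenumbers turns a 3720-point spectrum into 744 variables.
#'
#' @param spectrum numeric vector or matrix (rows = spectra).
#' @param bin_width points per bin (>= 1).
#' @param grid optional axis; when given, the binned axis is returned in
#'   attribute `"grid"`.
#' @return binned spectrum of length `ceiling(p / bin_width)`.
#' @export
bin_spectrum <- function(spectrum, bin_width = 5, grid = NULL) {
  vec_in <- is.null(dim(spectrum))
  spectrum <- rbind(spectrum)
  np <- ncol(spectrum)
  if (np == 0) stop("empty spectrum", call. = FALSE)
  if (bin_width < 1) stop_field("bin_width", "must be >= 1")
  bin_width <- as.integer(bin_width)
  nb <- ceiling(np / bin_width)
  grp <- rep(seq_len(nb), each = bin_width, length.out = np)
  cnts <- tabulate(grp, nb)
  out <- t(rowsum(t(spectrum), grp)) # group order is 1..nb
  out <- sweep(out, 2L, cnts, "/")
  dimnames(out) <- list(rownames(spectrum), NULL)
  if (!is.null(grid))
    attr(out, "grid") <- as.numeric(rowsum(as.numeric(grid), grp) / cnts)
  if (vec_in) {
    g <- attr(out, "grid")
    out <- out[1L, ]
    attr(out, "grid") <- g
  }
  out
}

#' Pointwise median across technical replicates
#'
#' @param replicates numeric matrix, one row per processed replicate.
#' @return a single spectrum (numeric vector).
#' @export
replicate_median <- function(replicates) {
  replicates <- rbind(replicates)
  if (nrow(replicates) == 0) stop("no replicates", call. = FALSE)
  apply(replicates, 2L, stats::median)
}

#' FT-NIR preprocessing chain
#'
#' Applies, in this order: multiplicative scatter correction, first
#' derivative, Savitzky-Golay smoothing and binning to every replicate
#' spectrum, then takes the pointwise median over the technical
#' replicates of each sample.  With the default bin width of five a
#' 3720-point spectrum yields a 744-variable table.
#'
#' @param spectra a [replicate_spectra()] object.
#' @param sg_window,sg_polyorder Savitzky-Golay window and degree.
#' @param bin_width points per bin.
#' @param msc_reference reference spectrum for MSC; defaults to the mean
#'   over all replicates of all samples and is stored in the result's
#'   `"preprocess_state"` attribute for reuse on new data.
#' @return a [feature_table()] with block tag `"nir"`, variables named
#'   `nir_<wavenumber>` and binned wavenumbers in `wavenumber_cm1`.
#' @export
preprocess_nir <- function(spectra, sg_window = 11, sg_polyorder = 2,
                           bin_width = 5, msc_reference = NULL) {
  stopifnot(inherits(spectra, "replicate_spectra"))
  corr <- msc(spectra$values, msc_reference)
  reference <- attr(corr, "reference")
  der <- first_derivative(corr, spectra$grid)
  smo <- savitzky_golay_smooth(der, sg_window, sg_polyorder)
  binned <- bin_spectrum(smo, bin_width, grid = spectra$grid)
  bgrid <- attr(binned, "grid")
  uid <- unique(spectra$sample_ids)
  med <- t(vapply(uid, function(s) {
    replicate_median(binned[spectra$sample_ids == s, , drop = FALSE])
  }, numeric(ncol(binned))))
  vars <- data.frame(id = sprintf("nir_%.1f", bgrid),
                     block = "nir", wavenumber_cm1 = bgrid,
                     stringsAsFactors = FALSE)
  ft <- feature_table(med, spectra$classes[uid], variables = vars,
                      sample_ids = uid)
  attr(ft, "preprocess_state") <- list(
    msc_reference = reference, sg_window = sg_window,
    sg_polyorder = sg_polyorder, bin_width = bin_width)
  ft
}

#' Write / read replicate spectra as CSV
#'
#' Layout: first column `wavenumber_cm-1` (descending grid), then one
#' column per replicate named `<sample_id>__rep<k>`.  Class labels go to
#' a `<path>.meta.json` sidecar.
#'
#' @param x a [replicate_spectra()].
#' @param path CSV file path.
#' @export
write_replicate_spectra <- function(x, path) {
  stopifnot(inherits(x, "replicate_spectra"))
  rep_idx <- stats::ave(seq_along(x$sample_ids), x$sample_ids,
                        FUN = seq_along)
  cols <- sprintf("%s__rep%d", x$sample_ids, rep_idx)
  df <- data.frame(`wavenumber_cm-1` = x$grid, t(x$values),
                   check.names = FALSE)
  names(df) <- c("wavenumber_cm-1", cols)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(classes = as.list(stats::setNames(
    as.character(x$classes), names(x$classes)))),
    paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_replicate_spectra
#' @export
read_replicate_spectra <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "wavenumber_cm-1")
    stop("malformed spectra CSV: first column must be `wavenumber_cm-1` in ",
         path, call. = FALSE)
  grid <- df[[1]]
  vals <- t(as.matrix(df[, -1, drop = FALSE]))
  ids <- sub("__rep[0-9]+$", "", rownames(vals))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  classes <- factor(unlist(meta$classes), levels = c("organic", "conventional"))
  names(classes) <- names(meta$classes)
  replicate_spectra(vals, grid, ids, classes)
}
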