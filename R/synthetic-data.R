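#' Configuration of the synthetic multimodal generator
#'
#' Defines a two-class (organic / conventional) multimodal dataset with
#' known ground truth that reproduces the statistical structure the
#' analysis pipeline assumes:
#'
#' * zero-inflated LC-MS markers present only in the conventional class
#'   (a feed-additive carotenoid such as canthaxanthin behaves this
#'   way),
#' * LC-MS markers whose class means differ by `effect_size` standard
#'   deviations (polyunsaturated triacylglycerols elevated in organic
#'   eggs),
#' * one shared latent lipid factor with a class-shifted mean that loads
#'   simultaneously on a block of LC-MS variables and, as a Gaussian
#'   absorption band near 5800 cm^-1, on the NIR spectrum — the
#'   cross-modal structure a fused relation analysis should recover,
#' * an independent protein factor driving a 5900-6100 cm^-1 NIR band,
#' * additive and multiplicative scatter on the NIR technical
#'   replicates, and two carotenoid absorption bands (480 nm stronger in
#'   conventional, 450 nm stronger in organic samples) in photometry.
#'
#' @param n_organic,n_conventional per-class sample counts (defaults
#'   20 / 40, keeping the roughly 1:2 imbalance of a typical organic
#'   authentication study at a size where the full pipeline runs in
#'   minutes).
#' @param p_lcms number of LC-MS bucket variables.
#' @param p_nir_raw raw NIR grid length (default 3720 points spanning
#'   11,550-3950 cm^-1, stored descending).
#' @param n_nir_replicates technical replicates per sample (default 5).
#' @param p_photometry photometry grid length (default 411: 380-790 nm
#'   at 1 nm).
#' @param k_exclusive number of conventional-only zero-inflated markers.
#' @param k_shift number of organic-elevated mean-shift markers.
#' @param latent_block_lcms indices of LC-MS variables loaded by the
#'   shared latent factor; default: the 10 variables following the
#'   markers.  Must be disjoint from the marker indices
#'   `1:(k_exclusive + k_shift)`.
#' @param latent_band_nir wavenumber interval (cm^-1) of the shared
#'   lipid band (default c(5750, 5850)).
#' @param protein_band_nir wavenumber interval of the independent
#'   protein band (default c(5900, 6100)).
#' @param effect_size standardized mean difference of the shift markers.
#' @param latent_shift class shift (organic minus conventional) of the
#'   latent factor mean, in factor standard deviations.
#' @param exclusive_presence probability that an exclusive marker is
#'   detected in a conventional sample (default 0.95; occasional zeros
#'   occur even in the carrying class).
#' @param scatter_sd_add,scatter_sd_mult additive / multiplicative
#'   replicate scatter magnitudes (a ~ Normal(0, add), b ~ LogNormal(0,
#'   mult)).
#' @param noise_sd residual per-point noise.
#' @param seed integer; fully determines the dataset.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_organic = 20, n_conventional = 40, p_lcms = 300,
                       p_nir_raw = 3720, n_nir_replicates = 5,
                       p_photometry = 411, k_exclusive = 5, k_shift = 10,
                       latent_block_lcms = NULL,
                       latent_band_nir = c(5750, 5850),
                       protein_band_nir = c(5900, 6100),
                       effect_size = 1.5, latent_shift = 1.5,
                       exclusive_presence = 0.95,
                       scatter_sd_add = 0.05, scatter_sd_mult = 0.1,
                       noise_sd = 0.02, seed = 1) {
  for (f in c("n_organic", "n_conventional", "p_lcms", "p_nir_raw",
              "n_nir_replicates", "p_photometry")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || v < 1)
      stop_field(f, "must be a positive count")
  }
  if (k_exclusive < 0) stop_field("k_exclusive", "must be >= 0")
  if (k_shift < 0) stop_field("k_shift", "must be >= 0")
  n_marker <- k_exclusive + k_shift
  if (is.null(latent_block_lcms)) {
    latent_block_lcms <- if (n_marker + 10 <= p_lcms)
      seq(n_marker + 1, n_marker + 10) else integer(0)
  }
  latent_block_lcms <- as.integer(latent_block_lcms)
  if (n_marker + length(latent_block_lcms) > p_lcms)
    stop_field("latent_block_lcms",
               "markers plus latent block exceed p_lcms")
  if (any(latent_block_lcms < 1 | latent_block_lcms > p_lcms))
    stop_field("latent_block_lcms", "indices out of range")
  if (any(latent_block_lcms <= n_marker))
    stop_field("latent_block_lcms",
               "overlaps the marker indices 1:(k_exclusive + k_shift)")
  for (f in c("latent_band_nir", "protein_band_nir")) {
    v <- get(f)
    if (length(v) != 2L || v[1] >= v[2])
      stop_field(f, "must be an increasing interval c(lo, hi)")
  }
  if (exclusive_presence <= 0 || exclusive_presence > 1)
    stop_field("exclusive_presence", "must be in (0, 1]")
  structure(list(n_organic = as.integer(n_organic),
                 n_conventional = as.integer(n_conventional),
                 p_lcms = as.integer(p_lcms),
                 p_nir_raw = as.integer(p_nir_raw),
                 n_nir_replicates = as.integer(n_nir_replicates),
                 p_photometry = as.integer(p_photometry),
                 k_exclusive = as.integer(k_exclusive),
                 k_shift = as.integer(k_shift),
                 latent_block_lcms = latent_block_lcms,
                 latent_band_nir = as.numeric(latent_band_nir),
                 protein_band_nir = as.numeric(protein_band_nir),
                 effect_size = effect_size, latent_shift = latent_shift,
                 exclusive_presence = exclusive_presence,
                 scatter_sd_add = scatter_sd_add,
                 scatter_sd_mult = scatter_sd_mult, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# sd of a LogNormal(0, 1): the natural intensity scale of the background
LNORM_SD <- sqrt((exp(1) - 1) * exp(1))

gauss_band <- function(x, center, width) exp(-((x - center) / width)^2)

#' Generate a synthetic multimodal dataset with ground truth
#'
#' @param config a [sim_config()].
#' @return a list of class `synthetic_dataset` with elements `lcms`
#'   (raw bucket [feature_table()]), `nir` ([replicate_spectra()]),
#'   `photometry` (raw [feature_table()]), `truth` (ground-truth id
#'   lists and band intervals) and `config`.
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  n <- cf$n_organic + cf$n_conventional
  classes <- factor(rep(c("organic", "conventional"),
                        c(cf$n_organic, cf$n_conventional)),
                    levels = c("organic", "conventional"))
  organic <- classes == "organic"
  sample_ids <- sprintf("egg_%03d", seq_len(n))

  with_seed(cf$seed, {
    ## shared latent lipid factor: standard normal, class-shifted mean
    f_latent <- stats::rnorm(n, mean = ifelse(organic, cf$latent_shift, 0))
    ## independent protein factor, no class information
    f_protein <- stats::rnorm(n)

    ## ---- LC-MS bucket table -------------------------------------------
    p <- cf$p_lcms
    X <- matrix(stats::rlnorm(n * p, 0, 1), n, p)
    ke <- cf$k_exclusive
    ks <- cf$k_shift
    if (ke > 0) {
      for (j in seq_len(ke)) {
        X[organic, j] <- 0
        conv <- which(!organic)
        present <- stats::rbinom(length(conv), 1, cf$exclusive_presence) == 1
        X[conv, j] <- ifelse(present, stats::rlnorm(length(conv), 1, 0.5), 0)
      }
    }
    if (ks > 0) {
      shift_idx <- ke + seq_len(ks)
      X[organic, shift_idx] <- X[organic, shift_idx] +
        cf$effect_size * LNORM_SD
    }
    if (length(cf$latent_block_lcms)) {
      lb <- cf$latent_block_lcms
      # log-additive loading keeps intensities strictly positive
      X[, lb] <- exp(log(pmax(X[, lb], 1e-8)) + f_latent)
    }
    lcms_ids <- sprintf("lcms_%04d", seq_len(p))
    lcms_vars <- data.frame(id = lcms_ids, block = "lcms",
                            mz = round(stats::runif(p, 100, 1700), 4),
                            rt = round(stats::runif(p, 0.5, 30), 2),
                            stringsAsFactors = FALSE)
    lcms <- feature_table(X, classes, variables = lcms_vars,
                          sample_ids = sample_ids)

    ## ---- FT-NIR replicate spectra -------------------------------------
    grid <- seq(11550, 3950, length.out = cf$p_nir_raw)
    base <- 0.55 + 0.30 * gauss_band(grid, 8300, 1600) +
      0.25 * gauss_band(grid, 5200, 700) +
      0.15 * gauss_band(grid, 4400, 350)
    lat_c <- mean(cf$latent_band_nir)
    lat_w <- diff(cf$latent_band_nir) / 3
    pro_c <- mean(cf$protein_band_nir)
    pro_w <- diff(cf$protein_band_nir) / 3
    truth_spectra <- t(vapply(seq_len(n), function(i) {
      base + 0.08 * f_latent[i] * gauss_band(grid, lat_c, lat_w) +
        0.08 * f_protein[i] * gauss_band(grid, pro_c, pro_w)
    }, numeric(length(grid))))
    nrep <- cf$n_nir_replicates
    rep_sample <- rep(seq_len(n), each = nrep)
    a <- stats::rnorm(n * nrep, 0, cf$scatter_sd_add)
    b <- stats::rlnorm(n * nrep, 0, cf$scatter_sd_mult)
    reps <- a + b * truth_spectra[rep_sample, , drop = FALSE] +
      matrix(stats::rnorm(n * nrep * length(grid), 0, cf$noise_sd),
             n * nrep, length(grid))
    nir <- replicate_spectra(reps, grid, sample_ids[rep_sample],
                             stats::setNames(classes, sample_ids))

    ## ---- photometry ---------------------------------------------------
    wl <- seq(380, by = 1, length.out = cf$p_photometry)
    a480 <- stats::rnorm(n, ifelse(organic, 0.7, 1.2), 0.15)
    a450 <- stats::rnorm(n, ifelse(organic, 1.2, 0.7), 0.15)
    phot <- t(vapply(seq_len(n), function(i) {
      a480[i] * gauss_band(wl, 480, 30) + a450[i] * gauss_band(wl, 450, 25)
    }, numeric(length(wl)))) +
      matrix(stats::rnorm(n * length(wl), 0, 0.01), n, length(wl))
    phot_vars <- data.frame(id = sprintf("phot_%d", wl),
                            block = "photometry", wavelength_nm = wl,
                            stringsAsFactors = FALSE)
    photometry <- feature_table(phot, classes, variables = phot_vars,
                                sample_ids = sample_ids)

    ## ---- ground truth -------------------------------------------------
    bin5 <- bin_spectrum(grid, 5, grid = grid)
    bgrid <- attr(bin5, "grid")
    in_band <- function(interval)
      sprintf("nir_%.1f", bgrid[bgrid >= interval[1] & bgrid <= interval[2]])
    truth <- list(
      marker_ids_exclusive = lcms_ids[seq_len(ke)],
      marker_ids_shift = lcms_ids[ke + seq_len(ks)],
      latent_linked_lcms = lcms_ids[cf$latent_block_lcms],
      latent_linked_nir = in_band(cf$latent_band_nir),
      protein_nir = in_band(cf$protein_band_nir),
      latent_band_nir = cf$latent_band_nir,
      protein_band_nir = cf$protein_band_nir)

    structure(list(lcms = lcms, nir = nir, photometry = photometry,
                   truth = truth, config = cf),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset>\n")
  print(x$lcms)
  print(x$nir)
  print(x$photometry)
  invisible(x)
}

#' Write / read a synthetic dataset as plain files
#'
#' Writes one CSV per block (`lcms.csv`, `nir_spectra.csv`,
#' `photometry.csv`, each with a JSON metadata sidecar) plus
#' `truth.json` and `config.json` into a directory; `read_dataset()`
#' restores a dataset that round-trips losslessly through these files.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir target directory (created if missing).
#' @return `write_dataset` returns `dir` invisibly; `read_dataset`
#'   returns a `synthetic_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2L) != 0)
    stop("directory not writable: ", dir, call. = FALSE)
  write_feature_table(dataset$lcms, file.path(dir, "lcms.csv"))
  write_replicate_spectra(dataset$nir, file.path(dir, "nir_spectra.csv"))
  write_feature_table(dataset$photometry, file.path(dir, "photometry.csv"))
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, digits = NA)
  cfg <- unclass(dataset$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  config <- do.call(sim_config, cfg[setdiff(names(cfg), character(0))])
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  structure(list(
    lcms = read_feature_table(file.path(dir, "lcms.csv")),
    nir = read_replicate_spectra(file.path(dir, "nir_spectra.csv")),
    photometry = read_feature_table(file.path(dir, "photometry.csv")),
    truth = truth, config = config),
    class = "synthetic_dataset")
}
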