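#' Preprocessing configuration
#'
#' The standardized pipeline applied to every spectrum before modelling:
#' linear baseline subtraction anchored in the flat 3900-4000 cm^-1 region,
#' per-spectrum min-max normalization to \[0, 1\] over the full range, and
#' mean-binning to a fixed number of variables. Spectra whose point count is
#' not `bin_width * target_length` are first linearly resampled onto a
#' uniform grid of that many points spanning 4000 to 1000 cm^-1, which makes
#' the model input layer well-defined regardless of the instrument's native
#' sampling.
#'
#' @param baseline_window `c(low, high)` cm^-1 window for the baseline fit.
#' @param bin_width Points averaged per bin.
#' @param target_length Number of output variables.
#' @param range `c(high, low)` cm^-1 span the spectra are restricted to.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(baseline_window = c(3900, 4000),
                              bin_width = 8,
                              target_length = 375,
                              range = c(4000, 1000)) {
  stopifnot(bin_width >= 1, target_length >= 1,
            baseline_window[1] < baseline_window[2])
  structure(list(baseline_window = baseline_window,
                 bin_width = as.integer(bin_width),
                 target_length = as.integer(target_length),
                 range = range),
            class = "preprocess_config")
}

#' Linear baseline correction
#'
#' Fits an ordinary least-squares line to the absorbance values whose
#' wavenumbers fall inside `window` (a spectrally flat region) and subtracts
#' that line from the whole spectrum. The mean residual inside the window is
#' zero up to floating-point error, and the operation is idempotent.
#'
#' @param absorbance Numeric absorbance vector.
#' @param wavenumber Wavenumber grid (cm^-1), same length.
#' @param window `c(low, high)` cm^-1 anchor window.
#' @return Baseline-corrected absorbance vector.
#' @export
baseline_correct <- function(absorbance, wavenumber,
                             window = c(3900, 4000)) {
  stopifnot(length(absorbance) == length(wavenumber))
  idx <- wavenumber >= window[1] & wavenumber <= window[2]
  if (sum(idx) < 2) {
    stop_labelled("baseline_window",
                  sprintf("need >= 2 grid points in [%g, %g]; found %d",
                          window[1], window[2], sum(idx)))
  }
  fit <- stats::lm.fit(cbind(1, wavenumber[idx]), absorbance[idx])
  absorbance - (fit$coefficients[1] + fit$coefficients[2] * wavenumber)
}

#' Min-max normalization to \[0, 1\]
#'
#' Spectra whose full range is below `tol` (absorbance units) are treated as
#' constant — for example a pure baseline whose correction leaves only
#' floating-point residue — and rejected rather than normalized into noise.
#'
#' @param x Numeric vector with `max(x) > min(x)`.
#' @param tol Minimal admissible range, in absorbance units.
#' @return `(x - min) / (max - min)`.
#' @export
minmax_normalize <- function(x, tol = 1e-8) {
  r <- range(x)
  if (!is.finite(r[1]) || !is.finite(r[2])) {
    stop_labelled("nonfinite", "spectrum contains non-finite values")
  }
  if (r[2] - r[1] <= tol) {
    stop_labelled("degenerate_spectrum",
                  "constant spectrum: min-max normalization undefined")
  }
  (x - r[1]) / (r[2] - r[1])
}

#' Mean-bin a spectrum to a fixed length
#'
#' Restricts the spectrum to the configured wavenumber range, resamples it
#' by linear interpolation onto a uniform grid of
#' `bin_width * target_length` points (high-to-low) when the point count
#' differs from that product, then averages consecutive non-overlapping
#' groups of `bin_width` points. Bin centers are the mean wavenumber of each
#' group. Mean-binning is average-preserving and keeps values inside the
#' input's range.
#'
#' @param absorbance Numeric absorbance vector.
#' @param wavenumber Wavenumber grid (cm^-1), strictly monotone.
#' @param config A [preprocess_config()].
#' @return List with `values` (length `target_length`) and `bin_centers`.
#' @export
bin_spectrum <- function(absorbance, wavenumber,
                         config = preprocess_config()) {
  stopifnot(length(absorbance) == length(wavenumber))
  hi <- max(config$range); lo <- min(config$range)
  keep <- wavenumber >= lo & wavenumber <= hi
  wn <- wavenumber[keep]; a <- absorbance[keep]
  if (length(wn) < config$target_length) {
    stop_labelled("too_few_points",
                  sprintf("%d grid points < target_length %d",
                          length(wn), config$target_length))
  }
  # work high-to-low (instrument convention)
  ord <- order(wn, decreasing = TRUE)
  wn <- wn[ord]; a <- a[ord]
  m <- config$bin_width * config$target_length
  if (length(wn) != m) {
    grid <- seq(hi, lo, length.out = m)
    a <- stats::approx(wn, a, xout = grid, rule = 2)$y
    wn <- grid
  }
  grp <- matrix(a, nrow = config$bin_width)
  ctr <- matrix(wn, nrow = config$bin_width)
  list(values = colMeans(grp), bin_centers = colMeans(ctr))
}

#' Apply the full preprocessing pipeline to a spectrum set
#'
#' Steps, in order: baseline correction, min-max normalization, binning.
#'
#' @param set A [spectrum_set()].
#' @param config A [preprocess_config()].
#' @return Object of class `processed_spectra`: list with `x` (n_samples x
#'   target_length matrix, rows named by sample id), `bin_centers`,
#'   `metadata`, and `provenance` (applied steps with parameters).
#' @export
preprocess_set <- function(set, config = preprocess_config()) {
  n <- ncol(set$absorbance)
  out <- matrix(NA_real_, nrow = n, ncol = config$target_length)
  rownames(out) <- colnames(set$absorbance)
  centers <- NULL
  for (j in seq_len(n)) {
    a <- baseline_correct(set$absorbance[, j], set$wavenumber,
                          config$baseline_window)
    a <- minmax_normalize(a)
    b <- bin_spectrum(a, set$wavenumber, config)
    out[j, ] <- b$values
    centers <- b$bin_centers
  }
  colnames(out) <- sprintf("wn_%.1f", centers)
  structure(
    list(x = out,
         bin_centers = centers,
         metadata = set$metadata,
         provenance = list(
           steps = c("baseline_correct", "minmax_normalize", "bin_spectrum"),
           baseline_window = config$baseline_window,
           bin_width = config$bin_width,
           target_length = config$target_length,
           range = config$range)),
    class = "processed_spectra"
  )
}

#' @export
print.processed_spectra <- function(x, ...) {
  cat(sprintf("processed_spectra: %d samples x %d variables (%.1f to %.1f cm^-1)\n",
              nrow(x$x), ncol(x$x), x$bin_centers[1],
              x$bin_centers[length(x$bin_centers)]))
  cat("steps:", paste(x$provenance$steps, collapse = " -> "), "\n")
  invisible(x)
}

#' Write a processed matrix as CSV with a bin-center header
#' @param processed A `processed_spectra`.
#' @param file Output CSV path (rows = samples, first column sample_id).
#' @return Invisibly, `file`.
#' @export
write_processed <- function(processed, file) {
  df <- data.frame(sample_id = rownames(processed$x), processed$x,
                   check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
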