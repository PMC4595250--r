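#' Preprocessing configuration
#'
#' Parameters of the four-stage spectral conditioning chain: quality control,
#' iterative polynomial autofluorescence baseline removal, Savitzky-Golay
#' smoothing, and normalization over the fingerprint region.
#'
#' @param saturation_ceiling_quantile Fraction of the cohort-wide maximum
#'   intensity above which a run of points counts as oversaturated.
#' @param saturation_run_length Minimum run length (grid points) at or above
#'   the ceiling for rejection.
#' @param baseline_degree Degree of the background polynomial (default 4).
#' @param baseline_max_iter,baseline_tol Stopping rule of the iterative
#'   modified polyfit: stop when the fit changes by less than `baseline_tol`
#'   relative to the spectrum maximum, or after `baseline_max_iter`
#'   iterations.
#' @param sg_window Savitzky-Golay window (odd number of points,
#'   `> sg_polyorder`).
#' @param sg_polyorder Savitzky-Golay polynomial order.
#' @param normalization `"area"` (trapezoidal integral = 1, default),
#'   `"vector"` (Euclidean norm = 1) or `"minmax"` (min 0, max 1), computed
#'   over `normalization_region`.
#' @param normalization_region Two wavenumbers (cm^-1) bounding the region
#'   used by normalization.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(saturation_ceiling_quantile = 0.999,
                              saturation_run_length = 25,
                              baseline_degree = 4,
                              baseline_max_iter = 100,
                              baseline_tol = 1e-6,
                              sg_window = 11,
                              sg_polyorder = 3,
                              normalization = c("area", "vector", "minmax"),
                              normalization_region = c(200, 1800)) {
  normalization <- match.arg(normalization)
  if (sg_window %% 2 == 0)
    stop("config error: sg_window must be odd")
  if (sg_window <= sg_polyorder)
    stop("config error: sg_window must exceed sg_polyorder")
  stopifnot(baseline_degree >= 1, baseline_max_iter >= 1, baseline_tol > 0,
            saturation_ceiling_quantile > 0, saturation_ceiling_quantile <= 1,
            saturation_run_length >= 1,
            length(normalization_region) == 2,
            normalization_region[1] < normalization_region[2])
  structure(as.list(environment()), class = "preprocess_config")
}

#' Quality-control filter for raw cohorts
#'
#' Rejects a spectrum iff it contains a non-finite intensity, or a run of at
#' least `saturation_run_length` consecutive points at or above the
#' saturation ceiling (cohort-wide maximum intensity times
#' `saturation_ceiling_quantile`). Kept and rejected spectra partition the
#' input.
#'
#' @param cohort A raw [sers_cohort()].
#' @param config A [preprocess_config()].
#' @return A list with `kept` (a `sers_cohort` whose state gains
#'   `qc_passed`) and `rejected` (data frame `spectrum_id`, `reason` with
#'   reasons `"nonfinite"` or `"oversaturated"`).
#' @export
qc_filter <- function(cohort, config = preprocess_config()) {
  stopifnot(inherits(cohort, "sers_cohort"))
  if (n_spectra(cohort) == 0) stop("empty cohort")
  ceiling_val <- max(cohort$intensity[is.finite(cohort$intensity)]) *
    config$saturation_ceiling_quantile
  reason <- vapply(seq_len(n_spectra(cohort)), function(i) {
    y <- cohort$intensity[i, ]
    if (any(!is.finite(y))) return("nonfinite")
    r <- rle(y >= ceiling_val)
    if (any(r$lengths[r$values] >= config$saturation_run_length))
      return("oversaturated")
    NA_character_
  }, character(1))
  bad <- !is.na(reason)
  if (all(bad)) stop("qc_filter rejected every spectrum")
  kept <- subset_cohort(cohort, spectra = which(!bad))
  kept$state <- c(kept$state, "qc_passed")
  list(kept = kept,
       rejected = data.frame(spectrum_id = cohort$meta$spectrum_id[bad],
                             reason = reason[bad],
                             stringsAsFactors = FALSE))
}

# Iterative modified polyfit (Lieber-style peak clipping): fit a polynomial,
# replace points above the fit by the fit, refit; converges to a curve under
# the peaks. Returns list(corrected, baseline).
fit_baseline <- function(x, y, degree, max_iter, tol) {
  if (length(y) < degree + 1)
    stop("too few points (", length(y), ") for degree ", degree, " baseline")
  u <- 2 * (x - min(x)) / diff(range(x)) - 1  # scaled for conditioning
  basis <- cbind(1, stats::poly(u, degree))
  qr_b <- qr(basis)
  scale <- max(abs(y))
  if (scale == 0) scale <- 1
  w <- y
  fit_prev <- NULL
  for (k in seq_len(max_iter)) {
    fit <- drop(basis %*% qr.coef(qr_b, w))
    if (!is.null(fit_prev) &&
        max(abs(fit - fit_prev)) / scale < tol) break
    fit_prev <- fit
    w <- pmin(w, fit)
  }
  list(corrected = pmax(y - fit, 0), baseline = fit)
}

#' Remove the autofluorescence baseline from a spectrum
#'
#' Iterative modified polynomial fitting: a degree-`baseline_degree`
#' polynomial is fit to the intensities, points above the fit are replaced
#' by the fit, and the fit is repeated until it changes by less than
#' `baseline_tol` (relative to the spectrum maximum) or `baseline_max_iter`
#' iterations. The corrected spectrum is the input minus the final fit,
#' floored at zero. A plain single polyfit would be biased upward by the
#' peaks; the clipping iteration removes that bias.
#'
#' @param spectrum A [sers_spectrum()] not yet baseline-corrected.
#' @param config A [preprocess_config()].
#' @return A list with `corrected` and `baseline`, both `sers_spectrum`.
#' @export
remove_baseline <- function(spectrum, config = preprocess_config()) {
  stopifnot(inherits(spectrum, "sers_spectrum"))
  if ("baseline_corrected" %in% spectrum$state)
    stop("spectrum is already baseline corrected")
  fb <- fit_baseline(spectrum$wavenumber, spectrum$intensity,
                     config$baseline_degree, config$baseline_max_iter,
                     config$baseline_tol)
  corrected <- spectrum
  corrected$intensity <- fb$corrected
  corrected$state <- c(spectrum$state, "baseline_corrected")
  baseline <- spectrum
  baseline$intensity <- fb$baseline
  baseline$meta$spectrum_id <- paste0(spectrum$meta$spectrum_id, "-baseline")
  list(corrected = corrected, baseline = baseline)
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing with window `sg_window` and
#' order `sg_polyorder`. Length is preserved and edges are handled by the
#' boundary polynomial fits, so any polynomial of degree at most
#' `sg_polyorder` passes through unchanged.
#'
#' @param spectrum A [sers_spectrum()].
#' @param config A [preprocess_config()].
#' @return The smoothed `sers_spectrum` (state gains `smoothed`).
#' @export
smooth_spectrum <- function(spectrum, config = preprocess_config()) {
  stopifnot(inherits(spectrum, "sers_spectrum"))
  if (config$sg_window > length(spectrum$intensity))
    stop("sg_window exceeds spectrum length")
  out <- spectrum
  out$intensity <- sg_smooth_vec(spectrum$intensity, config)
  out$state <- c(spectrum$state, "smoothed")
  out
}

sg_smooth_vec <- function(y, config) {
  as.numeric(signal::sgolayfilt(y, p = config$sg_polyorder,
                                n = config$sg_window))
}

#' Normalize a spectrum over the fingerprint region
#'
#' Area mode (default) scales so the trapezoidal integral over
#' `normalization_region` equals 1; vector mode scales the region's
#' Euclidean norm to 1; minmax affinely maps the region's minimum to 0 and
#' maximum to 1.
#'
#' @param spectrum A baseline-corrected [sers_spectrum()].
#' @param config A [preprocess_config()].
#' @return The normalized `sers_spectrum` (state gains `normalized`).
#' @export
normalize_spectrum <- function(spectrum, config = preprocess_config()) {
  stopifnot(inherits(spectrum, "sers_spectrum"))
  out <- spectrum
  out$intensity <- normalize_vec(spectrum$wavenumber, spectrum$intensity,
                                 config)
  out$state <- c(spectrum$state, "normalized")
  out
}

normalize_vec <- function(x, y, config) {
  r <- config$normalization_region
  idx <- x >= r[1] & x <= r[2]
  if (!any(idx)) stop("normalization region outside the grid")
  yr <- y[idx]
  if (all(yr == 0)) stop("degenerate input: spectrum is zero over the region")
  switch(config$normalization,
         area = y / pracma::trapz(x[idx], yr),
         vector = y / sqrt(sum(yr^2)),
         minmax = {
           if (max(yr) == min(yr))
             stop("degenerate input: constant over the region")
           (y - min(yr)) / (max(yr) - min(yr))
         })
}

#' Run the full preprocessing chain on a cohort
#'
#' Applies, in order: quality control ([qc_filter()]), baseline removal,
#' Savitzky-Golay smoothing, and normalization, to every kept spectrum. The
#' chain is deterministic and refuses to run twice (state guard). The QC
#' rejection log is attached as attribute `"rejected"`.
#'
#' @param cohort A raw [sers_cohort()].
#' @param config A [preprocess_config()].
#' @return The processed `sers_cohort` with state
#'   `raw > qc_passed > baseline_corrected > smoothed > normalized`.
#' @export
preprocess_cohort <- function(cohort, config = preprocess_config()) {
  stopifnot(inherits(cohort, "sers_cohort"))
  done <- intersect(cohort$state,
                    c("qc_passed", "baseline_corrected", "smoothed",
                      "normalized"))
  if (length(done))
    stop("cohort already preprocessed (state: ",
         paste(cohort$state, collapse = " > "), ")")
  qc <- qc_filter(cohort, config)
  out <- qc$kept
  x <- out$wavenumber
  out$intensity <- t(apply(out$intensity, 1, function(y) {
    y <- fit_baseline(x, y, config$baseline_degree,
                      config$baseline_max_iter, config$baseline_tol)$corrected
    y <- sg_smooth_vec(y, config)
    normalize_vec(x, y, config)
  }))
  rownames(out$intensity) <- out$meta$spectrum_id
  out$state <- c("raw", "qc_passed", "baseline_corrected", "smoothed",
                 "normalized")
  attr(out, "rejected") <- qc$rejected
  out
}
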