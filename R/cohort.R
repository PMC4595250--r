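#' Wavenumber grid constructor
#'
#' Builds the regular Raman-shift axis shared by all spectra in a cohort.
#' The default covers the serum SERS fingerprint region, 200--1800 cm^-1 at
#' 2 cm^-1 resolution (801 points).
#'
#' @param start First Raman shift (cm^-1).
#' @param stop Last Raman shift (cm^-1).
#' @param step Grid spacing (cm^-1), must be positive.
#' @return Numeric vector of strictly increasing wavenumbers.
#' @examples
#' length(sers_grid()) # 801
#' @export
sers_grid <- function(start = 200, stop = 1800, step = 2) {
  if (step <= 0) stop("grid step must be positive")
  if (stop <= start) stop("grid stop must exceed start")
  seq(start, stop, by = step)
}

valid_groups <- c("PA", "WT", "MEC", "Normal")

#' Single SERS spectrum
#'
#' A spectrum is a wavenumber axis, an intensity vector of the same length,
#' identifying metadata, and a record of the preprocessing stages already
#' applied (ordered subset of `raw`, `qc_passed`, `baseline_corrected`,
#' `smoothed`, `normalized`).
#'
#' @param wavenumber Strictly increasing numeric axis (cm^-1).
#' @param intensity Numeric intensities, same length as `wavenumber`, finite.
#' @param spectrum_id,patient_id,group Identifying metadata. `group` must be
#'   one of `PA`, `WT`, `MEC`, `Normal` (or `NA` when unknown).
#' @param state Character vector of preprocessing states already applied.
#' @return An object of class `sers_spectrum`.
#' @export
sers_spectrum <- function(wavenumber, intensity, spectrum_id = NA_character_,
                          patient_id = NA_character_, group = NA_character_,
                          state = "raw") {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity))
    stop("wavenumber and intensity must have equal length")
  if (any(!is.finite(wavenumber)) || any(diff(wavenumber) <= 0))
    stop("wavenumber axis must be finite and strictly increasing")
  if (!is.na(group) && !group %in% valid_groups)
    stop("unknown group label: ", group)
  structure(
    list(wavenumber = wavenumber, intensity = intensity,
         meta = list(spectrum_id = as.character(spectrum_id),
                     patient_id = as.character(patient_id),
                     group = as.character(group)),
         state = state),
    class = "sers_spectrum")
}

#' @export
print.sers_spectrum <- function(x, ...) {
  cat(sprintf("<sers_spectrum> %s  [%s]\n",
              x$meta$spectrum_id,
              paste(x$state, collapse = " > ")))
  cat(sprintf("  %d points, %.0f-%.0f cm^-1; patient %s, group %s\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
              x$meta$patient_id, x$meta$group))
  invisible(x)
}

#' SERS spectra cohort
#'
#' The central container consumed by every stage: a shared wavenumber axis,
#' an `n_spectra x n_points` intensity matrix, and per-spectrum metadata
#' (spectrum id, patient id, group). A patient belongs to exactly one group.
#'
#' @param wavenumber Shared strictly increasing axis (cm^-1).
#' @param intensity Numeric matrix, one row per spectrum, `length(wavenumber)`
#'   columns.
#' @param meta Data frame with columns `spectrum_id`, `patient_id`, `group`
#'   (one row per spectrum). Extra columns are kept.
#' @param state Character vector of preprocessing states applied to all
#'   spectra in the cohort.
#' @return An object of class `sers_cohort`.
#' @export
sers_cohort <- function(wavenumber, intensity, meta, state = "raw") {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.matrix(intensity)
  if (ncol(intensity) != length(wavenumber))
    stop("intensity must have one column per wavenumber")
  if (nrow(intensity) != nrow(meta))
    stop("meta must have one row per spectrum")
  need <- c("spectrum_id", "patient_id", "group")
  if (!all(need %in% names(meta)))
    stop("meta must contain columns: ", paste(need, collapse = ", "))
  if (any(diff(wavenumber) <= 0))
    stop("wavenumber axis must be strictly increasing")
  bad <- setdiff(unique(meta$group), valid_groups)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  # one group per patient
  pg <- unique(meta[, c("patient_id", "group")])
  if (anyDuplicated(pg$patient_id))
    stop("patient mapped to more than one group: ",
         paste(pg$patient_id[duplicated(pg$patient_id)], collapse = ", "))
  if (anyDuplicated(meta$spectrum_id))
    stop("duplicate spectrum_id in cohort")
  rownames(intensity) <- meta$spectrum_id
  structure(list(wavenumber = wavenumber, intensity = intensity,
                 meta = as.data.frame(meta), state = state),
            class = "sers_cohort")
}

#' Number of spectra in a cohort
#' @param cohort A `sers_cohort`.
#' @return Integer count of spectra.
#' @export
n_spectra <- function(cohort) nrow(cohort$intensity)

#' @export
print.sers_cohort <- function(x, ...) {
  tab <- table(x$meta$group)
  pat <- tapply(x$meta$patient_id, x$meta$group,
                function(p) length(unique(p)))
  cat(sprintf("<sers_cohort> %d spectra / %d patients, %d points (%.0f-%.0f cm^-1)\n",
              n_spectra(x), length(unique(x$meta$patient_id)),
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  cat("  state:", paste(x$state, collapse = " > "), "\n")
  for (g in names(tab))
    cat(sprintf("  %-7s %3d spectra / %2d patients\n", g, tab[[g]], pat[[g]]))
  invisible(x)
}

#' @export
summary.sers_cohort <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Extract the spectra of one or more groups or patients
#'
#' @param cohort A `sers_cohort`.
#' @param groups Optional group labels to keep.
#' @param patients Optional patient ids to keep.
#' @param spectra Optional logical/integer row index of spectra to keep.
#' @return A `sers_cohort` restricted to the selection.
#' @export
subset_cohort <- function(cohort, groups = NULL, patients = NULL,
                          spectra = NULL) {
  keep <- rep(TRUE, n_spectra(cohort))
  if (!is.null(groups)) keep <- keep & cohort$meta$group %in% groups
  if (!is.null(patients)) keep <- keep & cohort$meta$patient_id %in% patients
  if (!is.null(spectra)) {
    sel <- rep(FALSE, n_spectra(cohort))
    sel[spectra] <- TRUE
    keep <- keep & sel
  }
  if (!any(keep)) stop("selection leaves no spectra")
  out <- cohort
  out$intensity <- cohort$intensity[keep, , drop = FALSE]
  out$meta <- cohort$meta[keep, , drop = FALSE]
  rownames(out$meta) <- NULL
  out
}

#' Extract one spectrum from a cohort
#' @param cohort A `sers_cohort`.
#' @param i Row index or spectrum id.
#' @return A `sers_spectrum`.
#' @export
get_spectrum <- function(cohort, i) {
  if (is.character(i)) i <- match(i, cohort$meta$spectrum_id)
  if (is.na(i) || i < 1 || i > n_spectra(cohort)) stop("no such spectrum")
  sers_spectrum(cohort$wavenumber, cohort$intensity[i, ],
                spectrum_id = cohort$meta$spectrum_id[i],
                patient_id = cohort$meta$patient_id[i],
                group = cohort$meta$group[i],
                state = cohort$state)
}
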