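#' Read one two-column spectrum file
#'
#' Reads a plain-text spectrum: column 1 = Raman shift (cm^-1), column 2 =
#' intensity (counts). Comma or tab delimiters are auto-detected and a
#' one-line header (`wavenumber,intensity`) is optional. The axis is sorted
#' ascending (intensities permuted consistently); duplicate wavenumbers are
#' an error.
#'
#' @param path File path.
#' @param dialect `"auto"` (default), `"csv"` or `"tsv"`.
#' @param spectrum_id Identifier; defaults to the file name without extension.
#' @param patient_id,group Optional metadata (normally supplied by the
#'   manifest, see [read_cohort()]).
#' @return A [sers_spectrum()].
#' @export
read_spectrum <- function(path, dialect = c("auto", "csv", "tsv"),
                          spectrum_id = NULL, patient_id = NA_character_,
                          group = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 8) stop("spectrum file too short (< 8 rows): ", path)
  sep <- switch(dialect, csv = ",", tsv = "\t",
                auto = if (grepl("\t", lines[[1]])) "\t" else ",")
  first <- strsplit(lines[[1]], sep, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  body <- if (has_header) lines[-1] else lines
  parts <- strsplit(body, sep, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2))
    stop(sprintf("parse error in %s: expected 2 columns, line %d has %d",
                 path, which(nf != 2)[1] + has_header, nf[nf != 2][1]))
  m <- suppressWarnings(
    matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE))
  if (anyNA(m)) {
    bad <- which(apply(m, 1, anyNA))[1]
    stop(sprintf("parse error in %s: non-numeric value on line %d",
                 path, bad + has_header))
  }
  o <- order(m[, 1])
  wn <- m[o, 1]
  if (any(diff(wn) == 0))
    stop("format error in ", path, ": duplicate wavenumbers")
  if (is.null(spectrum_id))
    spectrum_id <- sub("\\.[^.]*$", "", basename(path))
  sers_spectrum(wn, m[o, 2], spectrum_id = spectrum_id,
                patient_id = patient_id, group = group)
}

#' Read a cohort from a manifest
#'
#' The manifest is a CSV with exactly the columns `file`, `spectrum_id`,
#' `patient_id`, `group`; `file` paths are resolved relative to the manifest's
#' directory. Group labels are validated against `PA`, `WT`, `MEC`, `Normal`
#' and each patient must map to a single group. Spectra whose axes differ
#' from the first spectrum's are harmonized onto it by linear interpolation;
#' a spectrum that does not fully cover the target range is rejected rather
#' than extrapolated.
#'
#' @param manifest_path Path to the manifest CSV.
#' @return A [sers_cohort()].
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("no such manifest: ", manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("file", "spectrum_id", "patient_id", "group")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (nrow(man) == 0) stop("empty manifest: cohort has no spectra")
  bad <- setdiff(unique(man$group), valid_groups)
  if (length(bad))
    stop("unknown group label(s) in manifest: ", paste(bad, collapse = ", "))
  pg <- unique(man[, c("patient_id", "group")])
  if (anyDuplicated(pg$patient_id))
    stop("patient mapped to more than one group: ",
         paste(unique(pg$patient_id[duplicated(pg$patient_id)]),
               collapse = ", "))
  dir <- dirname(manifest_path)
  specs <- lapply(seq_len(nrow(man)), function(i) {
    read_spectrum(file.path(dir, man$file[i]),
                  spectrum_id = man$spectrum_id[i],
                  patient_id = man$patient_id[i], group = man$group[i])
  })
  target <- specs[[1]]$wavenumber
  inten <- t(vapply(specs, function(s) {
    if (length(s$wavenumber) == length(target) &&
        all(s$wavenumber == target)) return(s$intensity)
    if (min(s$wavenumber) > min(target) || max(s$wavenumber) < max(target))
      stop("range error: spectrum ", s$meta$spectrum_id,
           " does not cover the target axis ",
           sprintf("%g-%g cm^-1", min(target), max(target)))
    stats::approx(s$wavenumber, s$intensity, xout = target)$y
  }, numeric(length(target))))
  sers_cohort(target, inten,
              data.frame(spectrum_id = man$spectrum_id,
                         patient_id = man$patient_id,
                         group = man$group,
                         stringsAsFactors = FALSE))
}

#' Write a cohort to a directory
#'
#' Writes one two-column CSV per spectrum (full double precision) plus a
#' `manifest.csv` with columns `file`, `spectrum_id`, `patient_id`, `group`.
#' Round-trips through [read_cohort()] bit-exactly.
#'
#' @param cohort A non-empty [sers_cohort()].
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sers_cohort"))
  if (n_spectra(cohort) == 0) stop("cohort is empty")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, mode = 2) != 0) stop("directory not writable: ", dir)
  files <- paste0(gsub("[^A-Za-z0-9._-]", "_", cohort$meta$spectrum_id),
                  ".csv")
  if (anyDuplicated(files)) stop("spectrum ids collide after sanitization")
  wn <- formatC(cohort$wavenumber, format = "g", digits = 17)
  for (i in seq_len(n_spectra(cohort))) {
    y <- formatC(cohort$intensity[i, ], format = "g", digits = 17)
    writeLines(c("wavenumber,intensity", paste(wn, y, sep = ",")),
               file.path(dir, files[i]))
  }
  man <- data.frame(file = files,
                    spectrum_id = cohort$meta$spectrum_id,
                    patient_id = cohort$meta$patient_id,
                    group = cohort$meta$group,
                    stringsAsFactors = FALSE)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
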