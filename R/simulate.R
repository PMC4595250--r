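#' Synthetic cohort configuration
#'
#' Parameters of the serum SERS cohort simulator. Defaults emulate the study
#' conditions the analysis was designed for: a 20/21/19/31-patient cohort
#' (PA/WT/MEC/Normal), 4--6 spectra per patient adjusted to group totals of
#' 101/105/95/153 (454 spectra overall), a 200--1800 cm^-1 axis at 2 cm^-1,
#' pseudo-Voigt bands of 12 cm^-1 FWHM at the catalogue positions, a random
#' degree-4 polynomial autofluorescence background, and group-specific band
#' intensity changes given by the catalogue effect lists.
#'
#' The patient random effect is a vector of per-band log-normal amplitude
#' multipliers shared by all spectra of a patient (SD `patient_sd` on the
#' log scale); each spectrum additionally gets smaller independent per-band
#' jitter (`spectrum_sd`). Modelling the patient effect per band rather than
#' as one overall scale factor is what makes leave-one-patient-out genuinely
#' harder than leave-one-spectrum-out: an overall factor would be removed by
#' spectrum normalization.
#'
#' @param patients_per_group Named counts for `PA`, `WT`, `MEC`, `Normal`.
#' @param spectra_per_patient Inclusive integer range (length 2) of spectra
#'   acquired per patient.
#' @param spectra_totals Named per-group spectrum totals the per-patient
#'   draws are adjusted to hit, or `NULL` for unconstrained draws.
#' @param grid Wavenumber axis, see [sers_grid()].
#' @param baseline_degree Polynomial degree of the autofluorescence
#'   background (default 4; set 5 to probe model mismatch in the
#'   preprocessing).
#' @param baseline_amplitude Overall background scale (a.u.); 0 disables it.
#' @param peak_shape `"pseudo-voigt"`, `"lorentzian"` or `"gaussian"`.
#' @param peak_fwhm Band full width at half maximum (cm^-1).
#' @param base_amplitudes Baseline band amplitudes (a.u.), either one value
#'   recycled over catalogue sites or a vector of length `n_sites`
#'   (16 catalogue entries + 1 unassigned site under the default catalogue).
#' @param effect_size Multiplicative change applied to a group's increased
#'   bands (decreased bands are divided by it; symmetric on the log scale).
#' @param patient_sd Log-scale SD of the per-patient per-band multiplier.
#' @param spectrum_sd Log-scale SD of the per-spectrum per-band jitter.
#' @param noise_sd SD of additive Gaussian instrument noise (a.u.).
#' @param common_band_centres,common_band_amplitudes,common_band_fwhm
#'   Positions (cm^-1), amplitudes (a.u.) and width (cm^-1) of the common
#'   serum band envelope: broad bands shared by all groups that carry no
#'   diagnostic signal. Serum SERS spectra are dense, and this shared
#'   spectral mass keeps the normalization area stable, so a group's
#'   multiplicative band changes survive normalization as the same-signed
#'   differences they are generated as (without it, a group with many
#'   increased bands is simply rescaled). Set
#'   `common_band_amplitudes = 0` to disable.
#' @param saturation_fraction Probability a spectrum is oversaturated
#'   (applied by [inject_saturation()]; 0 = clean cohort).
#' @param seed Integer seed; fixed seed gives a bit-identical cohort.
#' @param catalogue A [peak_catalogue()].
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(patients_per_group = c(PA = 20, WT = 21,
                                                    MEC = 19, Normal = 31),
                             spectra_per_patient = c(4, 6),
                             spectra_totals = c(PA = 101, WT = 105,
                                                MEC = 95, Normal = 153),
                             grid = sers_grid(),
                             baseline_degree = 4,
                             baseline_amplitude = 5,
                             peak_shape = c("pseudo-voigt", "lorentzian",
                                            "gaussian"),
                             peak_fwhm = 12,
                             base_amplitudes = NULL,
                             effect_size = 1.5,
                             patient_sd = 0.3,
                             spectrum_sd = 0.05,
                             noise_sd = 0.05,
                             common_band_centres = c(240, 330, 390, 480,
                               620, 680, 800, 860, 900, 980, 1020, 1180,
                               1220, 1300, 1410, 1480, 1580, 1660, 1740,
                               1780),
                             common_band_amplitudes = c(1.0, 1.4, 0.9,
                               1.2, 1.1, 1.5, 1.3, 1.0, 1.2, 1.6, 1.1,
                               1.4, 1.0, 1.3, 1.2, 0.9, 1.1, 1.3, 1.0,
                               0.8),
                             common_band_fwhm = 35,
                             saturation_fraction = 0,
                             seed = 20151005,
                             catalogue = peak_catalogue()) {
  peak_shape <- match.arg(peak_shape)
  stopifnot(all(patients_per_group > 0),
            length(spectra_per_patient) == 2,
            spectra_per_patient[1] >= 1, spectra_per_patient[2] <= 20,
            spectra_per_patient[1] <= spectra_per_patient[2],
            effect_size > 0, peak_fwhm > 0,
            saturation_fraction >= 0, saturation_fraction < 1,
            patient_sd >= 0, spectrum_sd >= 0, noise_sd >= 0,
            baseline_degree >= 1, baseline_amplitude >= 0)
  if (!all(valid_groups %in% names(patients_per_group)))
    stop("patients_per_group must name PA, WT, MEC and Normal")
  if (!is.null(spectra_totals)) {
    lo <- patients_per_group * spectra_per_patient[1]
    hi <- patients_per_group * spectra_per_patient[2]
    tot <- spectra_totals[names(patients_per_group)]
    if (any(is.na(tot)) || any(tot < lo) || any(tot > hi))
      stop("spectra_totals unreachable with the given per-patient range")
  }
  sites <- catalogue_sites(catalogue, grid)
  if (is.null(base_amplitudes)) {
    # plausible relative serum SERS band strengths; hypoxanthine dominant
    amp <- c("294" = 0.6, "450" = 0.4, "546" = 0.5, "726" = 1.5,
             "746" = 0.8, "934" = 0.7, "1084" = 0.6, "1094" = 0.6,
             "1128" = 0.5, "1140" = 0.4, "1262" = 0.5, "1328" = 0.9,
             "1370" = 0.8, "1444" = 1.0, "1546" = 0.6, "1608" = 0.7,
             "1698" = 0.5)
    base_amplitudes <- unname(amp[as.character(sites$centre)])
    base_amplitudes[is.na(base_amplitudes)] <- 0.5
  } else if (length(base_amplitudes) == 1) {
    base_amplitudes <- rep(base_amplitudes, nrow(sites))
  } else if (length(base_amplitudes) != nrow(sites)) {
    stop("base_amplitudes must have length 1 or n_sites = ", nrow(sites))
  }
  if (length(common_band_amplitudes) == 1)
    common_band_amplitudes <- rep(common_band_amplitudes,
                                  length(common_band_centres))
  stopifnot(length(common_band_amplitudes) == length(common_band_centres),
            all(common_band_amplitudes >= 0), common_band_fwhm > 0)
  structure(list(patients_per_group = patients_per_group,
                 spectra_per_patient = spectra_per_patient,
                 spectra_totals = spectra_totals,
                 grid = grid, baseline_degree = baseline_degree,
                 baseline_amplitude = baseline_amplitude,
                 peak_shape = peak_shape, peak_fwhm = peak_fwhm,
                 base_amplitudes = base_amplitudes,
                 effect_size = effect_size, patient_sd = patient_sd,
                 spectrum_sd = spectrum_sd, noise_sd = noise_sd,
                 common_band_centres = common_band_centres,
                 common_band_amplitudes = common_band_amplitudes,
                 common_band_fwhm = common_band_fwhm,
                 saturation_fraction = saturation_fraction,
                 seed = as.integer(seed), catalogue = catalogue,
                 sites = sites),
            class = "synthetic_config")
}

# band profile, unit height, centred at x0
peak_profile <- function(x, x0, fwhm, shape) {
  u <- (x - x0) / fwhm
  lor <- 1 / (1 + 4 * u^2)
  gau <- exp(-4 * log(2) * u^2)
  switch(shape,
         "lorentzian" = lor,
         "gaussian" = gau,
         "pseudo-voigt" = 0.5 * lor + 0.5 * gau)
}

# random smooth positive polynomial background on the grid
random_baseline <- function(grid, degree, amplitude) {
  if (amplitude == 0) return(numeric(length(grid)))
  u <- 2 * (grid - min(grid)) / diff(range(grid)) - 1
  coef <- stats::runif(degree, -0.3, 0.3)
  b <- 1 + drop(outer(u, seq_len(degree), `^`) %*% coef)
  pmax(amplitude * b, 0)
}

#' Simulate all spectra of one patient
#'
#' Each spectrum is a random polynomial autofluorescence background plus
#' pseudo-Voigt (or Lorentzian/Gaussian) bands at the catalogue sites, with
#' band amplitude = base amplitude x group effect x patient multiplier x
#' per-spectrum jitter, plus i.i.d. Gaussian noise; intensities are clipped
#' at zero. Uses the current RNG state; seed upstream (or use
#' [generate_cohort()], which seeds from its config).
#'
#' @param group Group label (`PA`, `WT`, `MEC` or `Normal`).
#' @param config A [synthetic_config()].
#' @param n_spectra Number of spectra; default drawn uniformly from
#'   `config$spectra_per_patient`.
#' @return A list of [sers_spectrum()] (metadata unset; [generate_cohort()]
#'   fills ids).
#' @export
generate_patient <- function(group, config, n_spectra = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!group %in% valid_groups) stop("config error: unknown group ", group)
  rng <- config$spectra_per_patient
  if (is.null(n_spectra))
    n_spectra <- sample(seq(rng[1], rng[2]), 1)
  sites <- config$sites
  x <- config$grid
  # all band sites: diagnostic catalogue sites + the common serum envelope
  centres <- c(sites$centre, config$common_band_centres)
  fwhms <- c(rep(config$peak_fwhm, nrow(sites)),
             rep(config$common_band_fwhm,
                 length(config$common_band_centres)))
  bases <- c(config$base_amplitudes, config$common_band_amplitudes)
  eff <- c(site_effects(config$catalogue, sites, group, config$effect_size),
           rep(1, length(config$common_band_centres)))
  patient_mult <- exp(stats::rnorm(length(centres), 0, config$patient_sd))
  profiles <- vapply(seq_along(centres), function(i)
    peak_profile(x, centres[i], fwhms[i], config$peak_shape),
    numeric(length(x)))
  lapply(seq_len(n_spectra), function(s) {
    jitter <- exp(stats::rnorm(length(centres), 0, config$spectrum_sd))
    amps <- bases * eff * patient_mult * jitter
    y <- random_baseline(x, config$baseline_degree,
                         config$baseline_amplitude) +
      drop(profiles %*% amps) +
      stats::rnorm(length(x), 0, config$noise_sd)
    sers_spectrum(x, pmax(y, 0), group = group)
  })
}

# per-patient spectra counts drawn uniformly in the range then nudged
# (within the range) to hit the published group total
draw_counts <- function(n_patients, rng, total = NULL) {
  counts <- sample(seq(rng[1], rng[2]), n_patients, replace = TRUE)
  if (is.null(total)) return(counts)
  while (sum(counts) != total) {
    if (sum(counts) < total) {
      i <- sample(which(counts < rng[2]), 1)
      counts[i] <- counts[i] + 1
    } else {
      i <- sample(which(counts > rng[1]), 1)
      counts[i] <- counts[i] - 1
    }
  }
  counts
}

#' Generate a synthetic SERS cohort
#'
#' Deterministic for a fixed `config$seed`: seeds the RNG locally and
#' restores the caller's RNG state on exit. Under the default configuration
#' the cohort has 91 patients (20 PA, 21 WT, 19 MEC, 31 Normal) and
#' 101/105/95/153 spectra (454 total).
#'
#' @param config A [synthetic_config()].
#' @return A raw [sers_cohort()].
#' @examples
#' co <- generate_cohort(synthetic_config(
#'   patients_per_group = c(PA = 2, WT = 2, MEC = 2, Normal = 3),
#'   spectra_totals = NULL, seed = 1))
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  groups <- names(config$patients_per_group)
  specs <- list(); meta <- list()
  for (g in groups) {
    np <- config$patients_per_group[[g]]
    counts <- draw_counts(np, config$spectra_per_patient,
                          config$spectra_totals[[g]])
    for (p in seq_len(np)) {
      pid <- sprintf("%s-%02d", g, p)
      sp <- generate_patient(g, config, n_spectra = counts[p])
      for (s in seq_along(sp)) {
        specs[[length(specs) + 1]] <- sp[[s]]$intensity
        meta[[length(meta) + 1]] <-
          data.frame(spectrum_id = sprintf("%s-s%d", pid, s),
                     patient_id = pid, group = g,
                     stringsAsFactors = FALSE)
      }
    }
  }
  sers_cohort(config$grid, do.call(rbind, specs), do.call(rbind, meta))
}

#' Inject oversaturated spectra into a cohort
#'
#' Marks a Bernoulli(`fraction`) subset of spectra as oversaturated by
#' clamping a contiguous region to the cohort-wide maximum intensity, and
#' flags them in `meta$saturated` so quality-control behaviour can be
#' checked against ground truth.
#'
#' @param cohort A raw [sers_cohort()].
#' @param fraction Probability in `[0, 1)` that a spectrum is clamped.
#' @param region_length Length of the clamped run, in grid points.
#' @param seed Optional seed for the selection (RNG state restored on exit).
#' @return The cohort with `meta$saturated` set and selected rows clamped.
#' @export
inject_saturation <- function(cohort, fraction, region_length = 60,
                              seed = NULL) {
  stopifnot(inherits(cohort, "sers_cohort"),
            fraction >= 0, fraction < 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- n_spectra(cohort)
  cohort$meta$saturated <- FALSE
  if (fraction == 0) return(cohort)
  ceiling_val <- max(cohort$intensity)
  hit <- which(stats::runif(n) < fraction)
  np <- length(cohort$wavenumber)
  for (i in hit) {
    start <- sample(seq_len(np - region_length + 1), 1)
    cohort$intensity[i, start:(start + region_length - 1)] <- ceiling_val
  }
  cohort$meta$saturated[hit] <- TRUE
  cohort
}
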