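#' Group mean spectrum with dispersion band
#'
#' Pointwise arithmetic mean and sample standard deviation (n-1 denominator)
#' over the spectra of one group.
#'
#' @param cohort A preprocessed [sers_cohort()].
#' @param group Group label with at least 2 spectra in the cohort.
#' @return An object of class `sers_mean_spectrum`: list with `wavenumber`,
#'   `mean`, `sd`, `group`, `n`.
#' @export
group_mean <- function(cohort, group) {
  stopifnot(inherits(cohort, "sers_cohort"))
  if (!group %in% valid_groups) stop("unknown group: ", group)
  idx <- cohort$meta$group == group
  if (sum(idx) < 2) stop("group ", group, " has fewer than 2 spectra")
  m <- cohort$intensity[idx, , drop = FALSE]
  structure(list(wavenumber = cohort$wavenumber,
                 mean = colMeans(m),
                 sd = apply(m, 2, stats::sd),
                 group = group, n = sum(idx),
                 n_patients = length(unique(cohort$meta$patient_id[idx]))),
            class = "sers_mean_spectrum")
}

#' @export
print.sers_mean_spectrum <- function(x, ...) {
  cat(sprintf("<sers_mean_spectrum> %s, n = %d spectra, %d points\n",
              x$group, x$n, length(x$wavenumber)))
  invisible(x)
}

#' Plot a mean spectrum with its standard-deviation band
#'
#' @param x A `sers_mean_spectrum`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sers_mean_spectrum <- function(x, ...) {
  graphics::plot(x$wavenumber, x$mean, type = "n",
                 xlab = expression(paste("Raman shift (", cm^-1, ")")),
                 ylab = "Intensity (a.u.)", main = x$group, ...)
  graphics::polygon(c(x$wavenumber, rev(x$wavenumber)),
                    c(x$mean + x$sd, rev(x$mean - x$sd)),
                    col = "grey85", border = NA)
  graphics::lines(x$wavenumber, x$mean)
  invisible(x)
}

#' Difference of two group mean spectra
#'
#' Pointwise `a$mean - b$mean`; both means must share one grid. The result's
#' metadata records the comparison direction.
#'
#' @param a,b [group_mean()] results on the same grid.
#' @return A [sers_spectrum()] (possibly negative intensities) whose
#'   `spectrum_id` is `"<A> minus <B>"` and state is `"difference"`.
#' @export
difference_spectrum <- function(a, b) {
  stopifnot(inherits(a, "sers_mean_spectrum"),
            inherits(b, "sers_mean_spectrum"))
  if (length(a$wavenumber) != length(b$wavenumber) ||
      any(a$wavenumber != b$wavenumber))
    stop("grid mismatch between mean spectra")
  # conservative pointwise standard error of the difference: spectra of one
  # patient are correlated, so the patient count, not the spectrum count, is
  # the effective sample size
  se <- sqrt(a$sd^2 / (a$n_patients %||% a$n) +
             b$sd^2 / (b$n_patients %||% b$n))
  structure(
    list(wavenumber = a$wavenumber, intensity = a$mean - b$mean,
         se = se,
         meta = list(spectrum_id = paste(a$group, "minus", b$group),
                     patient_id = NA_character_, group = NA_character_),
         state = "difference"),
    class = "sers_spectrum")
}

# prominence of each local maximum of y (standard topographic definition)
local_max_prominence <- function(y) {
  n <- length(y)
  peaks <- which(diff(sign(diff(y))) < 0) + 1
  peaks <- peaks[y[peaks] > y[peaks - 1] & y[peaks] > y[peaks + 1]]
  prom <- vapply(peaks, function(p) {
    h <- y[p]
    # walk left until terrain rises above h (or the edge), track the minimum
    left <- if (p == 1) h else {
      i <- p - 1; m <- y[i]
      while (i > 1 && y[i] <= h) { i <- i - 1; m <- min(m, y[i]) }
      if (y[i] > h) m else min(m, y[i])
    }
    right <- if (p == n) h else {
      i <- p + 1; m <- y[i]
      while (i < n && y[i] <= h) { i <- i + 1; m <- min(m, y[i]) }
      if (y[i] > h) m else min(m, y[i])
    }
    h - max(left, right)
  }, numeric(1))
  list(index = peaks, prominence = prom)
}

#' Detect signed peaks in a difference spectrum
#'
#' Local maxima of the difference (sign `increase`) and of its negation
#' (sign `decrease`) with topographic prominence at least `min_prominence`,
#' thinned so that kept peaks of the same sign are at least `min_separation`
#' cm^-1 apart (larger prominence wins). By default (`min_prominence =
#' NULL`) a local maximum is kept when its apex height is at least six
#' times the pointwise standard error of the difference at that position
#' (the between-patient sampling noise of the two group means, carried by
#' [difference_spectrum()]); for a bare spectrum without a standard error
#' the default falls back to a global prominence threshold of twice the
#' median absolute deviation of the second differences. Sampling noise in
#' a group mean produces smooth band-shaped bumps that roughness-based
#' thresholds cannot see, and topographic prominence in flat inter-band
#' regions references distant saddles, so the default significance test is
#' on the apex height against its local standard error. An explicit
#' `min_prominence` is applied as a global absolute prominence threshold
#' instead.
#'
#' @param diff A difference [sers_spectrum()] (see [difference_spectrum()]).
#' @param min_prominence Minimum prominence (a.u.); `NULL` for the default.
#' @param min_separation Minimum distance between same-signed hits (cm^-1).
#' @return Data frame with columns `position` (cm^-1), `sign`
#'   (`"increase"`/`"decrease"`), `magnitude` (prominence, a.u.) and
#'   `assignment` (`NA` until [assign_peaks()]), sorted by position.
#' @export
detect_signed_peaks <- function(diff, min_prominence = NULL,
                                min_separation = 10) {
  stopifnot(inherits(diff, "sers_spectrum"))
  y <- diff$intensity
  x <- diff$wavenumber
  use_se <- is.null(min_prominence) && !is.null(diff$se) &&
    any(diff$se > 0)
  threshold <- if (!is.null(min_prominence)) {
    rep(min_prominence, length(y))
  } else if (use_se) {
    6 * diff$se  # apex-height significance threshold
  } else {
    rep(2 * stats::mad(base::diff(y, differences = 2)), length(y))
  }
  one_sign <- function(v, label) {
    lm <- local_max_prominence(v)
    keep <- if (use_se) {
      v[lm$index] >= threshold[lm$index] & lm$prominence > 0
    } else {
      lm$prominence >= threshold[lm$index] & lm$prominence > 0
    }
    idx <- lm$index[keep]; prom <- lm$prominence[keep]
    if (!length(idx)) return(NULL)
    # greedy separation: strongest first
    o <- order(prom, decreasing = TRUE)
    chosen <- integer(0)
    for (i in o) {
      if (!length(chosen) ||
          all(abs(x[idx[i]] - x[idx[chosen]]) >= min_separation))
        chosen <- c(chosen, i)
    }
    data.frame(position = x[idx[chosen]], sign = label,
               magnitude = prom[chosen], stringsAsFactors = FALSE)
  }
  hits <- rbind(one_sign(y, "increase"), one_sign(-y, "decrease"))
  if (is.null(hits))
    hits <- data.frame(position = numeric(0), sign = character(0),
                       magnitude = numeric(0), stringsAsFactors = FALSE)
  hits <- hits[order(hits$position), , drop = FALSE]
  rownames(hits) <- NULL
  hits$assignment <- rep(NA_character_, nrow(hits))
  hits
}

#' Assign detected peaks to catalogue entries
#'
#' Each hit is assigned to the unique catalogue entry whose shift range,
#' widened by `tolerance`, contains its position; the nearest entry wins if
#' widened ranges overlap; otherwise `"unassigned"`. Assignment is total and
#' deterministic.
#'
#' @param hits Data frame from [detect_signed_peaks()].
#' @param catalogue A [peak_catalogue()].
#' @param tolerance Range widening in cm^-1 (default 3).
#' @return The hits with the `assignment` column filled.
#' @export
assign_peaks <- function(hits, catalogue = peak_catalogue(), tolerance = 3) {
  hits$assignment <- catalogue_assignment(catalogue, hits$position,
                                          tolerance)
  hits
}

#' Difference-spectrum peak table for a pair of groups
#'
#' Convenience wrapper: mean spectra, subtraction (`a - b`), signed peak
#' detection and catalogue assignment in one call.
#'
#' @param cohort A preprocessed [sers_cohort()].
#' @param a,b Group labels; the difference is `mean(a) - mean(b)`.
#' @param catalogue A [peak_catalogue()].
#' @param min_prominence,min_separation See [detect_signed_peaks()].
#' @param tolerance See [assign_peaks()].
#' @return The assigned hit table, with the difference spectrum attached as
#'   attribute `"difference"`.
#' @export
peak_table <- function(cohort, a, b, catalogue = peak_catalogue(),
                       min_prominence = NULL, min_separation = 10,
                       tolerance = 3) {
  d <- difference_spectrum(group_mean(cohort, a), group_mean(cohort, b))
  hits <- assign_peaks(detect_signed_peaks(d, min_prominence,
                                           min_separation),
                       catalogue, tolerance)
  attr(hits, "difference") <- d
  hits
}
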