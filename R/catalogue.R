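#' Serum SERS peak catalogue with group effect directions
#'
#' The reference catalogue of serum SERS bands used throughout the package:
#' 16 Raman-shift ranges with their biochemical assignments (Au-S and S-S
#' bands, hypoxanthine, thymine, protein/lipid C-C and C-H modes, amide I/II,
#' phenylalanine/tyrosine), plus the direction of change of each tumour
#' group's bands relative to normal serum (increased / decreased lists in
#' cm^-1). One reported band (450 cm^-1, Warthin's tumour) has no catalogue
#' assignment and is carried as an unassigned site.
#'
#' @return An object of class `peak_catalogue`: a list with
#'   \describe{
#'     \item{entries}{data frame `shift_lo`, `shift_hi`, `assignment` (16 rows,
#'       non-overlapping, within 200--1800 cm^-1).}
#'     \item{effects}{named list (`PA`, `WT`, `MEC`) of lists with numeric
#'       `increased` and `decreased` band positions (cm^-1).}
#'   }
#' @examples
#' cat <- peak_catalogue()
#' nrow(cat$entries) # 16
#' @export
peak_catalogue <- function() {
  entries <- data.frame(
    shift_lo = c(292, 543, 723, 744, 933, 1084, 1094, 1127, 1140, 1261,
                 1326, 1368, 1441, 1541, 1607, 1698),
    shift_hi = c(296, 548, 727, 747, 933, 1084, 1094, 1127, 1140, 1264,
                 1329, 1373, 1445, 1551, 1607, 1699),
    assignment = c(
      "Au-S band",
      "S-S disulfide stretching in Proteins",
      "Hypoxanthine",
      "Thymine in DNA",
      "C-C stretching mode, C-C alpha helix in proteins",
      "C-C stretching mode in phospholipids",
      "C-N stretching mode in D-Mannos",
      "C-C stretching in lipids, C-N stretching in D-Mannos",
      "Carotenoids",
      "CH bending in lipids",
      "CH vibration in DNA/RNA, CH2 twisting in lipids",
      "Guanine in DNA, Tryptophan in proteins",
      "CH2, CH3 bending in proteins and lipids",
      "C-N stretching, Amide II",
      "C=C band in Phenylalanine or Tyrosine",
      "Amide I"),
    stringsAsFactors = FALSE)
  effects <- list(
    PA = list(increased = c(548, 724, 747, 933, 1094, 1328, 1371, 1445, 1698),
              decreased = c(295, 1551, 1607)),
    WT = list(increased = c(296, 450, 543, 727, 744, 1084, 1140, 1264, 1326,
                            1373, 1444, 1699),
              decreased = c(1548)),
    MEC = list(increased = c(548, 723, 934, 1127, 1329, 1368, 1441),
               decreased = c(292, 1261, 1541, 1607)))
  cat <- structure(list(entries = entries, effects = effects),
                   class = "peak_catalogue")
  validate_catalogue(cat)
  cat
}

validate_catalogue <- function(cat) {
  e <- cat$entries
  if (any(e$shift_lo > e$shift_hi)) stop("catalogue entry with lo > hi")
  o <- order(e$shift_lo)
  if (any(e$shift_lo[o][-1] <= e$shift_hi[o][-nrow(e)]))
    stop("catalogue entries overlap")
  pos <- unlist(lapply(cat$effects, unlist), use.names = FALSE)
  if (any(pos < 200 | pos > 1800))
    stop("effect-list position outside 200-1800 cm^-1")
  invisible(cat)
}

#' @export
print.peak_catalogue <- function(x, ...) {
  cat(sprintf("<peak_catalogue> %d entries, effect lists for %s\n",
              nrow(x$entries), paste(names(x$effects), collapse = ", ")))
  invisible(x)
}

#' Look up the catalogue assignment covering a position
#'
#' @param catalogue A [peak_catalogue()].
#' @param position Raman shift (cm^-1), vectorized.
#' @param tolerance Widening (cm^-1) applied to each entry's range; on
#'   overlap after widening the nearest entry (by range midpoint) wins.
#' @return Character vector of assignments, `"unassigned"` where no entry
#'   covers the position.
#' @export
catalogue_assignment <- function(catalogue, position, tolerance = 3) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  e <- catalogue$entries
  mid <- (e$shift_lo + e$shift_hi) / 2
  vapply(position, function(p) {
    hit <- which(p >= e$shift_lo - tolerance & p <= e$shift_hi + tolerance)
    if (!length(hit)) return("unassigned")
    if (length(hit) > 1) hit <- hit[which.min(abs(mid[hit] - p))]
    e$assignment[hit]
  }, character(1))
}

# Peak sites the simulator places: one canonical centre per catalogue entry
# (range midpoint snapped to the grid) plus any effect-list position not
# covered by an entry within `tolerance` (the unassigned 450 cm^-1 WT band).
catalogue_sites <- function(catalogue, grid = sers_grid(), tolerance = 3) {
  e <- catalogue$entries
  step <- grid[2] - grid[1]
  snap <- function(p) grid[1] + step * round_half_away((p - grid[1]) / step, 0)
  centre <- snap((e$shift_lo + e$shift_hi) / 2)
  assignment <- e$assignment
  entry <- seq_len(nrow(e))
  extra <- setdiff(
    unlist(lapply(catalogue$effects, unlist), use.names = FALSE),
    NULL)
  extra <- unique(extra[catalogue_assignment(catalogue, extra,
                                             tolerance) == "unassigned"])
  if (length(extra)) {
    centre <- c(centre, snap(extra))
    assignment <- c(assignment, rep("unassigned", length(extra)))
    entry <- c(entry, rep(NA_integer_, length(extra)))
  }
  o <- order(centre)
  data.frame(centre = centre[o], assignment = assignment[o],
             entry = entry[o], stringsAsFactors = FALSE)
}

# Per-site multiplicative effect for a group: effect_size where any of the
# group's increased positions falls within tolerance of the site's entry
# range (or the site itself for unassigned sites), 1/effect_size for
# decreased positions, 1 otherwise.
site_effects <- function(catalogue, sites, group, effect_size,
                         tolerance = 3) {
  mult <- rep(1, nrow(sites))
  if (group == "Normal") return(mult)
  eff <- catalogue$effects[[group]]
  if (is.null(eff)) stop("config error: unknown group ", group)
  e <- catalogue$entries
  covers <- function(site_row, p) {
    if (!is.na(sites$entry[site_row])) {
      k <- sites$entry[site_row]
      p >= e$shift_lo[k] - tolerance & p <= e$shift_hi[k] + tolerance
    } else {
      abs(sites$centre[site_row] - p) <= tolerance
    }
  }
  for (i in seq_len(nrow(sites))) {
    if (any(covers(i, eff$increased))) mult[i] <- effect_size
    else if (any(covers(i, eff$decreased))) mult[i] <- 1 / effect_size
  }
  mult
}

# round half away from zero, the display convention used throughout
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  trunc(abs(x) * p + 0.5) * sign(x) / p
}
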