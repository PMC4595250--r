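# shared fixtures: small synthetic configurations and toy data built in code

# balanced scaled-down cohort config; override any field via ...
small_config <- function(..., np = 5) {
  defaults <- list(
    patients_per_group = c(PA = np, WT = np, MEC = np, Normal = np),
    spectra_per_patient = c(3, 4),
    spectra_totals = NULL,
    seed = 42)
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_config, args)
}

# reduced hyperparameter grid: keeps SVM tests fast while spanning the
# useful C/gamma range for column-standardized spectra
small_model <- function(...) {
  model_config(C_grid = 2^c(0, 4, 8), gamma_grid = 2^c(-12, -10, -8, -6),
               ...)
}

# two well-separated Gaussian blobs in d dimensions, as a sers_task-like list
make_blobs <- function(n_per_class = 20, d = 5, sep = 6, sd = 1,
                       seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per_class * d, 0, sd), n_per_class),
             matrix(stats::rnorm(n_per_class * d, sep, sd), n_per_class))
  list(x = x,
       y = factor(rep(c("neg", "pos"), each = n_per_class),
                  levels = c("neg", "pos")),
       patient_id = paste0("p", seq_len(2 * n_per_class)),
       positive = "pos", negative = "neg")
}

# write a two-column spectrum file; returns the path
write_spec_file <- function(path, wavenumber, intensity, sep = ",",
                            header = TRUE) {
  lines <- paste(wavenumber, intensity, sep = sep)
  if (header) lines <- c(paste("wavenumber", "intensity", sep = sep), lines)
  writeLines(lines, path)
  path
}

# build a small cohort on disk (dir with spectra + manifest); returns manifest
write_toy_cohort <- function(dir, n_per_group = 2,
                             groups = c("PA", "Normal"),
                             grid = seq(200, 1800, by = 2)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  set.seed(99)
  for (g in groups) {
    for (p in seq_len(n_per_group)) {
      pid <- sprintf("%s-%02d", g, p)
      for (s in 1:2) {
        sid <- sprintf("%s-s%d", pid, s)
        f <- paste0(sid, ".csv")
        write_spec_file(file.path(dir, f), grid,
                        abs(stats::rnorm(length(grid), 10, 1)))
        rows[[length(rows) + 1]] <- data.frame(
          file = f, spectrum_id = sid, patient_id = pid, group = g,
          stringsAsFactors = FALSE)
      }
    }
  }
  man <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE, quote = FALSE)
  path
}

# check that every expected band position has a same-signed hit nearby;
# band centres are snapped to the grid and shared across groups, so listed
# positions can sit up to ~5 cm^-1 from the generated site
has_hits_near <- function(hits, positions, sign, tol = 6) {
  vapply(positions, function(p)
    any(hits$sign == sign & abs(hits$position - p) <= tol), logical(1))
}
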