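test_that("build_task assembles the two-group feature matrix", {
  pp <- preprocess_cohort(generate_cohort(small_config(np = 3)))
  task <- build_task(pp, "Normal", "MEC")
  expect_equal(nrow(task$x),
               sum(pp$meta$group %in% c("Normal", "MEC")))
  expect_equal(ncol(task$x), length(pp$wavenumber))
  expect_setequal(levels(task$y), c("Normal", "MEC"))
  expect_length(task$patient_id, nrow(task$x))
  expect_error(build_task(pp, "PA", "PA"), "config error")
  co <- subset_cohort(pp, groups = c("PA", "WT"))
  expect_error(build_task(co, "PA", "Normal"), "missing")
})

test_that("jackknife grid search finds a separating model on toy blobs", {
  task <- make_blobs(n_per_class = 12, d = 5, sep = 8)
  cfg <- model_config(C_grid = 2^c(0, 4), gamma_grid = 2^c(-6, -2),
                      scale_features = FALSE)
  opt <- jackknife_optimize(task, cfg)
  expect_equal(opt$inner_accuracy, 1)
  expect_true(opt$C %in% cfg$C_grid)
  expect_true(opt$gamma %in% cfg$gamma_grid)
  expect_equal(nrow(opt$grid), 4)
})

test_that("jackknife accuracy is near chance on shuffled labels", {
  task <- make_blobs(n_per_class = 30, d = 5, sep = 8, seed = 2)
  set.seed(21)
  task$y <- sample(task$y)  # label permutation destroys the signal
  cfg <- model_config(C_grid = 2^c(0, 4), gamma_grid = 2^c(-6, -2),
                      scale_features = FALSE)
  opt <- jackknife_optimize(task, cfg)
  # best-of-grid LOO accuracy on pure noise: near 0.5, never separable
  expect_lt(opt$inner_accuracy, 0.75)
})

test_that("degenerate grids and degenerate classes are handled", {
  task <- make_blobs(n_per_class = 10, d = 4, sep = 8)
  cfg1 <- model_config(C_grid = 2, gamma_grid = 0.1,
                       scale_features = FALSE)
  opt <- jackknife_optimize(task, cfg1)
  expect_equal(opt$C, 2)
  expect_equal(opt$gamma, 0.1)
  # single-class data refuses
  task$y <- factor(rep("pos", 20), levels = c("neg", "pos"))
  expect_error(jackknife_optimize(task, cfg1), "2 rows per class")
})

test_that("ties break toward the smallest C then the smallest gamma", {
  task <- make_blobs(n_per_class = 10, d = 4, sep = 10)
  # widely separable: most grid points reach accuracy 1; tie-break applies
  cfg <- model_config(C_grid = 2^c(4, 0), gamma_grid = c(0.2, 0.05),
                      scale_features = FALSE)
  opt <- jackknife_optimize(task, cfg)
  best <- opt$grid[opt$grid$accuracy == opt$inner_accuracy, ]
  expect_equal(opt$C, min(best$C))
  expect_equal(opt$gamma, min(best$gamma[best$C == opt$C]))
})

test_that("LOSO pools exactly one prediction per spectrum", {
  pp <- preprocess_cohort(generate_cohort(small_config(np = 3)))
  task <- build_task(pp, "Normal", "MEC")
  cv <- cross_validate(task, "LOSO", small_model(), optimize = "once")
  n <- nrow(task$x)
  expect_equal(nrow(cv$predictions), n)
  expect_setequal(cv$predictions$row, seq_len(n))
  counts <- cv$counts
  expect_equal(counts$tp + counts$fn, sum(task$y == "Normal"))
  expect_equal(counts$tn + counts$fp, sum(task$y == "MEC"))
})

test_that("LOPO folds hold out whole patients with no identity leakage", {
  pp <- preprocess_cohort(generate_cohort(small_config(np = 3)))
  task <- build_task(pp, "Normal", "MEC")
  cv <- cross_validate(task, "LOPO", small_model(), optimize = "once")
  expect_equal(length(cv$folds), length(unique(task$patient_id)))
  for (k in seq_along(cv$folds)) {
    test_idx <- cv$folds[[k]]
    train_idx <- setdiff(seq_len(nrow(task$x)), test_idx)
    expect_length(intersect(task$patient_id[train_idx],
                            task$patient_id[test_idx]), 0)
    # a fold contains all spectra of exactly one patient
    expect_length(unique(task$patient_id[test_idx]), 1)
    pid <- unique(task$patient_id[test_idx])
    expect_setequal(test_idx, which(task$patient_id == pid))
  }
  # totals still pooled without loss
  expect_equal(cv$counts$tp + cv$counts$fn, sum(task$y == "Normal"))
  expect_equal(cv$counts$tn + cv$counts$fp, sum(task$y == "MEC"))
})

test_that("a LOPO fold owning an entire class is skipped with a warning", {
  grid <- seq(200, 300, by = 2)
  set.seed(8)
  n <- 12
  meta <- data.frame(
    spectrum_id = paste0("s", 1:n),
    patient_id = c(rep("pa1", 4), rep("n1", 4), rep("n2", 4)),
    group = c(rep("PA", 4), rep("Normal", 8)))
  co <- sers_cohort(grid, matrix(stats::rnorm(n * length(grid), 10), n),
                    meta, state = c("raw", "normalized"))
  task <- build_task(co, "PA", "Normal")
  cfg <- model_config(C_grid = 1, gamma_grid = 0.01)
  expect_warning(cv <- cross_validate(task, "LOPO", cfg, optimize = "once"),
                 "single class")
  expect_equal(cv$skipped_folds, "pa1")
  # the remaining folds only cover the negatives
  expect_equal(cv$counts$tp + cv$counts$fn, 0)
  expect_equal(cv$counts$tn + cv$counts$fp, 8)
})

test_that("nested per-fold optimization works on a small task", {
  task <- make_blobs(n_per_class = 8, d = 4, sep = 8)
  cfg <- model_config(C_grid = 2^c(0, 4), gamma_grid = 0.1,
                      scale_features = FALSE)
  cv <- cross_validate(task, "LOSO", cfg, optimize = "nested")
  expect_equal(nrow(cv$predictions), 16)
  m <- compute_metrics(cv$counts)
  expect_equal(m$ACC, 1)  # trivially separable even without the held-out row
  expect_length(cv$params, 16)
})

test_that("metrics match their closed-form definitions", {
  # worked example: SE 97.4 % of 153, SP 73.7 % of 95
  m <- compute_metrics(confusion_counts(tp = 149, fn = 4, tn = 70, fp = 25))
  expect_equal(round(100 * m$ACC, 1), 88.3)
  expect_equal(round(m$MCC, 3), 0.755)
  expect_equal(m$SE, 149 / 153)
  expect_equal(m$SP, 70 / 95)

  perfect <- compute_metrics(confusion_counts(10, 0, 12, 0))
  expect_equal(perfect$SP, 1)
  expect_equal(perfect$SE, 1)
  expect_equal(perfect$ACC, 1)
  expect_equal(perfect$MCC, 1)

  worst <- compute_metrics(confusion_counts(0, 7, 0, 9))
  expect_equal(worst$MCC, -1)

  # zero marginal -> MCC 0 convention
  degenerate <- compute_metrics(confusion_counts(0, 0, 5, 5))
  expect_equal(degenerate$MCC, 0)
  expect_error(compute_metrics(confusion_counts(0, 0, 0, 0)), "all-zero")
})

test_that("metric symmetries hold across random confusion tables", {
  set.seed(13)
  for (i in 1:25) {
    cts <- as.list(stats::rpois(4, 20) + 1)
    names(cts) <- c("tp", "fn", "tn", "fp")
    m <- compute_metrics(do.call(confusion_counts, cts))
    # MCC invariant under tp<->tn, fp<->fn swap
    sw <- compute_metrics(confusion_counts(cts$tn, cts$fp, cts$tp, cts$fn))
    expect_equal(sw$MCC, m$MCC)
    # label swap: ACC invariant, SE and SP exchange
    expect_equal(sw$ACC, m$ACC)
    expect_equal(sw$SE, m$SP)
    expect_equal(sw$SP, m$SE)
    expect_gte(m$MCC, -1)
    expect_lte(m$MCC, 1)
  }
})

test_that("counts_from_rates reconstructs published counts", {
  c1 <- counts_from_rates(0.935, 0.772, 153, 101)
  expect_equal(c1$tp, 143)
  expect_equal(c1$tn, 78)
  c2 <- counts_from_rates(0.514, 0.791, 105, 153)
  expect_equal(c2$tp, 54)
  expect_equal(c2$tn, 121)
  c3 <- counts_from_rates(1, 1, 10, 10)
  expect_equal(c(c3$tp, c3$fn, c3$tn, c3$fp), c(10, 0, 10, 0))
  # rounding is half away from zero
  c4 <- counts_from_rates(0.5, 0.5, 5, 5)
  expect_equal(c4$tp, 3)
})
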