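#' Two-step SVM diagnostic evaluation
#'
#' The full diagnostic: step 1 discriminates normal serum from each tumour
#' group (Normal vs PA, Normal vs WT, Normal vs MEC; normal as the positive
#' class), step 2 discriminates the tumour types pairwise (PA vs WT,
#' PA vs MEC, WT vs MEC; the first-named group positive). Each of the six
#' binary tasks is evaluated under the requested cross-validation schemes
#' (leave-one-spectrum-out and/or leave-one-patient-out) and summarized by
#' specificity, sensitivity, accuracy and Matthews correlation coefficient.
#'
#' @param cohort A preprocessed [sers_cohort()]. Missing groups yield a
#'   partial report with a warning.
#' @param config A [model_config()].
#' @param schemes Character subset of `c("LOSO", "LOPO")`.
#' @param optimize `"nested"` (per-fold jackknife re-optimization, no
#'   selection leakage) or `"once"` (jackknife once per task; cheaper).
#' @return An object of class `two_step_svm`: list with `results` (one row
#'   per task x scheme: step, positive, negative, scheme, tp/fn/tn/fp,
#'   SP/SE/ACC/MCC, C, gamma, n, skipped folds) and `cv` (the underlying
#'   [cross_validate()] objects). Has `print`, `summary` and
#'   `as.data.frame` methods; see [metric_tables()] for publication-style
#'   rendering.
#' @export
two_step_svm <- function(cohort, config = model_config(),
                         schemes = c("LOSO", "LOPO"),
                         optimize = c("nested", "once")) {
  stopifnot(inherits(cohort, "sers_cohort"))
  optimize <- match.arg(optimize)
  schemes <- match.arg(schemes, several.ok = TRUE)
  pairs <- list(list(step = 1, positive = "Normal", negative = "PA"),
                list(step = 1, positive = "Normal", negative = "WT"),
                list(step = 1, positive = "Normal", negative = "MEC"),
                list(step = 2, positive = "PA", negative = "WT"),
                list(step = 2, positive = "PA", negative = "MEC"),
                list(step = 2, positive = "WT", negative = "MEC"))
  present <- unique(cohort$meta$group)
  rows <- list(); cvs <- list()
  for (p in pairs) {
    if (!all(c(p$positive, p$negative) %in% present)) {
      warning("group missing; skipping task ", p$positive, " vs ",
              p$negative)
      next
    }
    task <- build_task(cohort, p$positive, p$negative)
    for (sc in schemes) {
      cv <- cross_validate(task, sc, config, optimize)
      m <- compute_metrics(cv$counts)
      par <- if (optimize == "once") cv$params else {
        cs <- vapply(cv$params, function(q) q$C, numeric(1))
        gs <- vapply(cv$params, function(q) q$gamma, numeric(1))
        list(C = stats::median(cs), gamma = stats::median(gs))
      }
      rows[[length(rows) + 1]] <- data.frame(
        step = p$step, positive = p$positive, negative = p$negative,
        scheme = sc, tp = cv$counts$tp, fn = cv$counts$fn,
        tn = cv$counts$tn, fp = cv$counts$fp,
        SP = m$SP, SE = m$SE, ACC = m$ACC, MCC = m$MCC,
        C = par$C, gamma = par$gamma, n = m$n,
        n_skipped_folds = length(cv$skipped_folds),
        stringsAsFactors = FALSE)
      cvs[[paste(p$positive, p$negative, sc, sep = ".")]] <- cv
    }
  }
  if (!length(rows)) stop("no task could be evaluated")
  structure(list(results = do.call(rbind, rows), cv = cvs,
                 optimize = optimize, config = config),
            class = "two_step_svm")
}

#' @export
as.data.frame.two_step_svm <- function(x, ...) x$results

#' @export
print.two_step_svm <- function(x, ...) {
  cat("Two-step SERS SVM diagnostic (", x$optimize,
      " hyperparameter selection)\n\n", sep = "")
  for (tab in metric_tables(x)) {
    cat(attr(tab, "title"), "\n")
    attr(tab, "title") <- NULL
    print(tab, quote = FALSE, right = TRUE)
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.two_step_svm <- function(object, ...) {
  print(object)
  invisible(object$results)
}

#' Publication-style metric tables
#'
#' Renders one table per (step, scheme): rows SP, SE, ACC, MCC; one column
#' per task; percentages to one decimal and MCC to three decimals (round
#' half away from zero).
#'
#' @param report A [two_step_svm()] object, or its `results` data frame.
#' @return Named list of character matrices, each with a `"title"`
#'   attribute.
#' @export
metric_tables <- function(report) {
  res <- if (inherits(report, "two_step_svm")) report$results else report
  out <- list()
  for (st in sort(unique(res$step))) {
    for (sc in unique(res$scheme)) {
      sub <- res[res$step == st & res$scheme == sc, , drop = FALSE]
      if (!nrow(sub)) next
      cols <- paste(sub$positive, "vs", sub$negative)
      m <- rbind(SP = vapply(sub$SP, format_pct, character(1)),
                 SE = vapply(sub$SE, format_pct, character(1)),
                 ACC = vapply(sub$ACC, format_pct, character(1)),
                 MCC = sprintf("%.3f", round_half_away(sub$MCC, 3)))
      colnames(m) <- cols
      attr(m, "title") <- sprintf(
        "Step %d, %s cross-validation", st,
        if (sc == "LOSO") "leave-one-spectrum-out" else
          "leave-one-patient-out")
      out[[paste0("step", st, ".", sc)]] <- m
    }
  }
  out
}

#' Run the full pipeline and write a report directory
#'
#' Simulate (or ingest) a cohort, preprocess it, compute the three
#' tumour-vs-normal difference-spectrum peak tables, evaluate the two-step
#' SVM diagnostic, and write everything under `out_dir`: the cohort
#' manifest and spectra, the QC rejection log, `peaks_<pair>.csv`,
#' `metrics.csv`, rendered text tables and a run log recording the seed and
#' session. Deterministic: the same configuration writes identical metric
#' and peak tables.
#'
#' @param out_dir Output directory (created).
#' @param cohort Optional raw [sers_cohort()]; by default one is simulated
#'   from `synth`.
#' @param synth A [synthetic_config()] (ignored when `cohort` is given).
#' @param pre A [preprocess_config()].
#' @param model A [model_config()].
#' @param schemes,optimize Passed to [two_step_svm()].
#' @param write_spectra Also write the raw spectra and manifest (may be
#'   many files).
#' @return Invisibly, a list with the processed cohort, peak tables and the
#'   [two_step_svm()] report.
#' @export
run_full_pipeline <- function(out_dir, cohort = NULL,
                              synth = synthetic_config(),
                              pre = preprocess_config(),
                              model = model_config(),
                              schemes = c("LOSO", "LOPO"),
                              optimize = "nested",
                              write_spectra = TRUE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log <- file.path(out_dir, "run_log.txt")
  note <- function(...) cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ",
                            sprintf(...), "\n", sep = "", file = log,
                            append = TRUE)
  cat("", file = log)
  if (is.null(cohort)) {
    note("simulate: seed %d, %d patients",
         synth$seed, sum(synth$patients_per_group))
    cohort <- generate_cohort(synth)
  } else note("ingest: %d spectra supplied", n_spectra(cohort))
  if (write_spectra) write_cohort(cohort, file.path(out_dir, "cohort"))
  processed <- preprocess_cohort(cohort, pre)
  rej <- attr(processed, "rejected")
  utils::write.csv(rej, file.path(out_dir, "rejections.csv"),
                   row.names = FALSE)
  note("preprocess: %d kept, %d rejected", n_spectra(processed), nrow(rej))
  peaks <- list()
  for (g in intersect(c("PA", "WT", "MEC"), processed$meta$group)) {
    tab <- peak_table(processed, g, "Normal")
    peaks[[g]] <- tab
    utils::write.csv(tab, file.path(out_dir,
                                    sprintf("peaks_%s_vs_Normal.csv", g)),
                     row.names = FALSE)
    note("peaks: %s vs Normal, %d hits", g, nrow(tab))
  }
  report <- two_step_svm(processed, model, schemes, optimize)
  utils::write.csv(report$results, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  tables_txt <- character(0)
  for (tab in metric_tables(report)) {
    title <- attr(tab, "title")
    attr(tab, "title") <- NULL
    tables_txt <- c(tables_txt, title,
                    utils::capture.output(print(tab, quote = FALSE,
                                                right = TRUE)), "")
  }
  writeLines(tables_txt, file.path(out_dir, "tables.txt"))
  note("classify: %d task x scheme rows", nrow(report$results))
  note("R %s, sersdx %s", getRversion(),
       as.character(utils::packageVersion("sersdx")))
  invisible(list(cohort = processed, peaks = peaks, report = report,
                 out_dir = out_dir))
}
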