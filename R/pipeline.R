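#' Demographic and clinical cohort summary
#'
#' Builds the standard demographics table: per diagnostic group (plus a
#' Total column-equivalent row), sample count, age mean and SD, sex counts
#' with percentages, and counts/percentages of the five psychotropic
#' treatment classes. Percentages are printed to one decimal, rounding
#' half away from zero; the overall row is recomputed from the per-sample
#' rows so every count equals the sum of the group counts.
#'
#' @param cohort Cohort tibble (`sample`, `diagnosis`, `sex`, `age`,
#'   treatment flags).
#' @return Tibble with one row per group and a leading `Total` row.
#' @export
cohort_summary <- function(cohort) {
  if (nrow(cohort) == 0) abort("empty cohort")
  y <- as_diagnosis(cohort$diagnosis)
  groups <- levels(droplevels(y))
  empty <- setdiff(levels(y), groups)
  if (length(empty) > 0) {
    warn(paste0("empty group(s) omitted: ", paste(empty, collapse = ", ")))
  }
  one <- function(label, idx) {
    n <- sum(idx)
    row <- tibble(
      group = label, n = n,
      age_mean = round_half_up(mean(cohort$age[idx]), 1),
      age_sd = round_half_up(sd(cohort$age[idx]), 1),
      male_n = sum(cohort$sex[idx] == "M"),
      female_n = sum(cohort$sex[idx] == "F")
    )
    row$male_pct <- round_half_up(100 * row$male_n / n, 1)
    row$female_pct <- round_half_up(100 * row$female_n / n, 1)
    for (tc in intersect(TREATMENT_CLASSES, names(cohort))) {
      row[[paste0(tc, "_n")]] <- sum(cohort[[tc]][idx])
      row[[paste0(tc, "_pct")]] <-
        round_half_up(100 * sum(cohort[[tc]][idx]) / n, 1)
    }
    row
  }
  bind_rows(
    one("Total", rep(TRUE, nrow(cohort))),
    purrr::map_dfr(groups, function(g) one(g, y == g))
  )
}

#' Overall summary cells from per-group summary cells
#'
#' Recovers the Total column of a demographics table when only group-level
#' summaries are available: counts add, the overall age mean is the
#' size-weighted average of the group means, and percentages are
#' recomputed from the summed counts (one decimal, half away from zero).
#'
#' @param groups Tibble with one row per group: `n`, optionally
#'   `age_mean`, and any number of `*_n` count columns.
#' @return One-row tibble with the overall `n`, `age_mean` (if supplied)
#'   and, per `*_n` column, the summed count and recomputed `*_pct`.
#' @export
overall_from_groups <- function(groups) {
  n <- sum(groups$n)
  out <- tibble(group = "Total", n = n)
  if ("age_mean" %in% names(groups)) {
    out$age_mean <- round_half_up(sum(groups$n * groups$age_mean) / n, 1)
  }
  for (col in grep("_n$", names(groups), value = TRUE)) {
    total <- sum(groups[[col]])
    out[[col]] <- total
    out[[sub("_n$", "_pct", col)]] <- round_half_up(100 * total / n, 1)
  }
  out
}

#' Default pipeline configuration
#'
#' @param spec A [cohort_spec()]; defaults to the study-sized synthetic
#'   cohort.
#' @param qc A [qc_config()].
#' @param fs An [fs_config()].
#' @param rf An [rf_config()].
#' @param n_synthetic Monte-Carlo synthetic points (default 500).
#' @param tei_reference Reference group(s) of the TEI fitting split.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = cohort_spec_study(),
                            qc = qc_config(),
                            fs = fs_config(),
                            rf = rf_config(),
                            n_synthetic = 500,
                            tei_reference = "CTRL",
                            seed = 1L) {
  structure(list(spec = spec, qc = qc, fs = fs, rf = rf,
                 n_synthetic = n_synthetic, tei_reference = tei_reference,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized sections: `cohort` (arguments of [cohort_spec_study()] /
#' [cohort_spec()] scalar fields, including `class_sizes` as a map and
#' `seed`), `qc`, `selection`, `rf` (scalar fields of the respective
#' config constructors), plus top-level `n_synthetic`, `tei_reference`
#' and `seed`.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  spec_args <- raw$cohort %||% list()
  if (!is.null(spec_args$class_sizes)) {
    spec_args$class_sizes <- unlist(spec_args$class_sizes)
  }
  spec <- do.call(cohort_spec_study, spec_args)
  pipeline_config(
    spec = spec,
    qc = do.call(qc_config, raw$qc %||% list()),
    fs = do.call(fs_config, raw$selection %||% list()),
    rf = do.call(rf_config, raw$rf %||% list()),
    n_synthetic = raw$n_synthetic %||% 500,
    tei_reference = raw$tei_reference %||% "CTRL",
    seed = raw$seed %||% 1L
  )
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic-cohort simulation (or ingestion of
#' supplied data), cohort summary, global-editing normalization, the
#' feature-selection cascade, per-gene TEI with pairwise group tests, the
#' six mROC signatures, the covariate-adjusted random forest, and
#' Monte-Carlo augmentation with fidelity validation and prediction-error
#' estimation. Every stage's table is written as TSV under `outdir`
#' together with a machine-readable JSON manifest and a plain-text log;
#' identical config and seed give byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @param data Optional list with `biomarkers` and `cohort` tibbles to
#'   analyze instead of simulating.
#' @param quiet Suppress progress messages.
#' @return A list of class `pipeline_result` with each stage's objects.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         data = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, paste0("[", format(length(log_lines) + 1),
                                      "] ", msg))
    if (!quiet) message(msg)
  }
  seed <- config$seed
  stage_seed <- function(k) seed + k  # small offsets keep seeds < 2^31

  completed <- list()
  run_stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e) {
      abort(paste0(
        "pipeline aborted at stage '", name, "': ", conditionMessage(e),
        if (length(completed) > 0) {
          paste0(" (completed: ", paste(names(completed), collapse = ", "), ")")
        } else ""
      ))
    })
  }

  # -- simulate / ingest ------------------------------------------------
  sim <- run_stage("simulate", {
    if (is.null(data)) {
      spec <- config$spec
      spec$seed <- stage_seed(1L)
      generate_cohort(spec)
    } else {
      list(biomarkers = as_tibble(data$biomarkers),
           cohort = mutate(as_tibble(data$cohort),
                           diagnosis = as_diagnosis(.data$diagnosis)))
    }
  })
  labels <- droplevels(sim$cohort$diagnosis)

  summary_tbl <- run_stage("summary", cohort_summary(sim$cohort))
  normalized <- run_stage("normalize",
                          normalize_by_global_editing(sim$biomarkers))
  selection <- run_stage("select",
    select_features(sim$biomarkers, labels, config$fs,
                    seed = stage_seed(2L)))
  tei <- run_stage("tei", {
    res <- compute_tei(sim$biomarkers, labels, selection$selected,
                       reference = config$tei_reference)
    res$tests <- tei_group_tests(res, fdr_cutoff = config$fs$fdr_cutoff,
                                 config = config$fs)
    res
  })
  signatures <- run_stage("signature",
    run_all_comparisons(normalized, labels, features = selection$selected))
  rf_cfg <- config$rf
  rf_cfg$seed <- stage_seed(3L)
  rf <- run_stage("rf",
    rf_integrate(sim$biomarkers, sim$cohort, features = selection$selected,
                 config = rf_cfg))
  augment <- run_stage("augment", {
    gen <- fit_mc_generator(
      sim$biomarkers[, c("sample", selection$selected)], sim$cohort)
    synth <- sample_synthetic(gen, n = config$n_synthetic,
                              seed = stage_seed(4L))
    sim_sel <- list(
      biomarkers = sim$biomarkers[, c("sample", selection$selected)],
      cohort = sim$cohort
    )
    fidelity <- validate_synthetic(sim_sel, synth)
    err <- estimate_prediction_error(rf, synth)
    list(generator = gen, synthetic = synth, fidelity = fidelity,
         prediction_error = err)
  })

  result <- structure(list(
    cohort = sim, summary = summary_tbl, normalized = normalized,
    selection = selection, tei = tei, signatures = signatures, rf = rf,
    augment = augment, config = config
  ), class = "pipeline_result")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, name) {
      readr::write_tsv(x, file.path(outdir, name))
      say("wrote ", name)
    }
    w(sim$cohort, "cohort.tsv")
    w(sim$biomarkers, "biomarkers.tsv")
    if (!is.null(sim$spec)) {
      write_site_panel_bed(sim$spec$site_panel,
                           file.path(outdir, "site_panel.bed"))
    }
    w(summary_tbl, "cohort_summary.tsv")
    w(normalized, "biomarkers_normalized.tsv")
    w(selection$report, "feature_selection.tsv")
    w(tei$tei, "tei.tsv")
    w(tei$tests, "tei_group_tests.tsv")
    w(glance(signatures), "signature_performance.tsv")
    w(tidy(signatures), "signature_coefficients.tsv")
    for (nm in names(signatures$coordinates)) {
      if (!is.null(signatures$coordinates[[nm]])) {
        w(signatures$coordinates[[nm]],
          paste0("signature_coordinates_", nm, ".tsv"))
      }
    }
    w(as_tibble(rf$votes) |>
        mutate(sample = sim$cohort$sample[rf$split$test], .before = 1),
      "rf_votes.tsv")
    w(rf$importance, "rf_importance.tsv")
    w(rf$per_class, "rf_per_class.tsv")
    w(augment$synthetic$biomarkers, "mc_synthetic_biomarkers.tsv")
    w(augment$synthetic$cohort, "mc_synthetic_cohort.tsv")
    w(augment$fidelity, "mc_fidelity.tsv")
    w(augment$prediction_error, "mc_prediction_error.tsv")
    manifest <- list(
      package = "editsig",
      version = as.character(utils::packageVersion("editsig")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = seed,
      stages = c("simulate", "summary", "normalize", "select", "tei",
                 "signature", "rf", "augment"),
      n_samples = nrow(sim$cohort),
      n_biomarkers = ncol(sim$biomarkers) - 1L,
      n_selected = length(selection$selected),
      rf_accuracy = rf$accuracy
    )
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    writeLines(log_lines, file.path(outdir, "run.log"))
  }
  say(sprintf("pipeline finished in %.1f s",
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  samples:", nrow(x$cohort$cohort), "\n")
  cat("  selected biomarkers:", length(x$selection$selected), "\n")
  cat("  RF test accuracy:", sprintf("%.3f", x$rf$accuracy), "\n")
  invisible(x)
}
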