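#' Run the full simulate -> fit -> score -> associate pipeline
#'
#' Orchestrates the whole analysis end to end and writes every stage artifact
#' under `outdir`: the simulated (or provided) cohort CSV, the fitted
#' reference chart and its centile grid, the scored cohort, the association
#' tables (univariable and multivariable ORs), the ROC/cross-validation
#' comparison, the cutoff sweep, the ICM-by-MVS trend strata, the baseline
#' table, a markdown run report, and a machine-readable provenance block
#' (`provenance.json`: config echo, seed, package version). Deterministic
#' given the same seed and inputs.
#'
#' @param outdir output directory (created if absent).
#' @param seed integer seed controlling simulation and cross-validation.
#' @param cohort optional existing cohort data.frame or CSV path; when `NULL`
#'   a synthetic cohort is generated.
#' @param n_embryos cohort size when simulating.
#' @param rho latent correlation when simulating.
#' @param k,repeats cross-validation folds and repeats.
#' @param cutoff MVS classification cutoff.
#' @param centiles percentiles for the exported grid.
#' @param quiet suppress per-stage log lines.
#' @return (Invisibly) a list with the cohort, chart, scored cohort and all
#'   result objects, plus the paths written.
#' @export
run_pipeline <- function(outdir, seed = 1L, cohort = NULL, n_embryos = 340L,
                         rho = 0.5, k = 5L, repeats = 100L, cutoff = 0.3,
                         centiles = DEFAULT_CENTILES, quiet = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log_stage <- function(stage, ...) {
    if (!quiet) {
      message(sprintf("[mvsref] %-14s %s (%.1fs)", stage, paste0(...),
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
  }
  paths <- list()
  p <- function(f) file.path(outdir, f)

  if (is.null(cohort)) {
    config <- simulation_config(n_embryos = n_embryos, rho = rho, seed = seed)
    cohort <- generate_cohort(config)
    log_stage("simulate", "n = ", nrow(cohort), ", seed = ", seed)
  } else if (is.character(cohort)) {
    cohort <- read_cohort(cohort)
    log_stage("load", "n = ", nrow(cohort))
  }
  paths$cohort <- write_cohort(cohort, p("cohort.csv"))

  chart <- fit_reference_chart(cohort, centiles = centiles)
  paths$chart <- write_chart(chart, p("reference_chart.txt"))
  paths$grid <- write_centile_grid(export_centile_grid(chart, digits = NULL),
                                   p("centile_grid.csv"))
  log_stage("fit-reference", "logLik = ", round(chart$fit_meta$logLik, 1))

  scored <- score_cohort(cohort, chart, cutoff = cutoff)
  paths$scored <- write_cohort(scored, p("scored.csv"))
  log_stage("score", "median MVS = ", round(stats::median(scored$mvs), 3))

  uni <- lapply(MODEL_TERMS, function(t) fit_univariable(scored, t))
  uni_tab <- do.call(rbind, lapply(seq_along(uni), function(i) {
    cbind(model_term = MODEL_TERMS[i], uni[[i]]$terms)
  }))
  multi <- fit_multivariable(scored)
  utils::write.csv(uni_tab, p("univariable_or.csv"), row.names = FALSE)
  utils::write.csv(multi$terms, p("multivariable_or.csv"), row.names = FALSE)

  roc <- roc_compare(scored)
  cv <- cross_validate_auc(scored, k = k, repeats = repeats, seed = seed)
  cut_sel <- select_cutoff(scored, reference_cutoff = cutoff)
  trend <- trend_test(scored)
  groups <- compare_mvs_by_outcome(scored)
  base_tab <- baseline_table(cohort)
  utils::write.csv(trend$strata, p("trend_strata.csv"), row.names = FALSE)
  utils::write.csv(cut_sel$sweep, p("cutoff_sweep.csv"), row.names = FALSE)
  utils::write.csv(base_tab, p("baseline_table.csv"), row.names = FALSE)
  log_stage("associate", sprintf("AUC %.3f vs %.3f", roc$auc_base,
                                 roc$auc_augmented))

  provenance <- list(
    package = "mvsref",
    version = as.character(utils::packageVersion("mvsref")),
    seed = seed,
    n_embryos = nrow(cohort),
    rho = if (exists("config", inherits = FALSE)) rho else NA,
    k = k, repeats = repeats, cutoff = cutoff, centiles = centiles,
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S")
  )
  jsonlite::write_json(provenance, p("provenance.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  report <- c(
    "# mvsref run report", "",
    sprintf("- cohort: %d embryos (seed %d)", nrow(cohort), seed),
    sprintf("- live birth rate: %.1f%%",
            100 * mean(cohort$outcome == "live_birth")),
    sprintf("- reference fit: logLik %.1f, converged: %s",
            chart$fit_meta$logLik, chart$fit_meta$converged),
    sprintf("- MVS: median %.3f, SD %.3f",
            stats::median(scored$mvs), stats::sd(scored$mvs)),
    sprintf("- multivariable MVS OR (per SD): %.2f (%.2f-%.2f)",
            multi$terms$odds_ratio[multi$terms$term == "mvs"],
            multi$terms$ci_low[multi$terms$term == "mvs"],
            multi$terms$ci_high[multi$terms$term == "mvs"]),
    sprintf("- apparent AUC: %.3f (base) vs %.3f (+MVS), DeLong p = %.4g",
            roc$auc_base, roc$auc_augmented, roc$p_value),
    sprintf("- CV AUC (%d-fold x %d): %.3f +/- %.3f vs %.3f +/- %.3f, p = %.4g",
            k, repeats, cv$mean_base, cv$sd_base, cv$mean_augmented,
            cv$sd_augmented, cv$p_value),
    sprintf("- NPV-maximizing cutoff: %.3f (NPV %.3f)", cut_sel$cutoff,
            cut_sel$npv),
    sprintf("- ICM x MVS trend: chi-squared %.2f, p = %.4g",
            trend$statistic, trend$p_value)
  )
  writeLines(report, p("report.md"))
  paths$report <- p("report.md")
  log_stage("report", "written to ", outdir)

  invisible(list(cohort = cohort, chart = chart, scored = scored,
                 univariable = uni, multivariable = multi, roc = roc,
                 cv = cv, cutoff = cut_sel, trend = trend, groups = groups,
                 baseline = base_tab, paths = paths))
}

#' Percentile calculator against a reference grid or chart
#'
#' The programmatic equivalent of an online reference-range calculator: given
#' a chart (or a grid CSV path), returns the percentile and Z-score for single
#' (milestone, hours) queries, or scores a whole cohort CSV.
#'
#' @param chart a `reference_chart`, or path to a centile-grid CSV or chart
#'   file.
#' @param milestone,hours a single query (both scalar), or `NULL` to score
#'   `cohort` instead.
#' @param cohort optional cohort data.frame or CSV path.
#' @param cutoff MVS cutoff for categories.
#' @return For a single query: one-row data.frame with `milestone`, `hours`,
#'   `z`, `percentile`. For a cohort: the scored cohort.
#' @export
calculator <- function(chart, milestone = NULL, hours = NULL, cohort = NULL,
                       cutoff = 0.3) {
  if (is.character(chart)) {
    first <- readLines(chart, n = 1L)
    chart <- if (grepl("^# mvsref reference chart", first)) {
      read_chart(chart)
    } else {
      chart_from_params(derive_gaussian_params(load_reference_grid(chart)))
    }
  }
  stopifnot(inherits(chart, "reference_chart"))
  if (!is.null(milestone)) {
    stopifnot(length(milestone) == length(hours))
    z <- z_score(hours, milestone, chart)
    return(data.frame(milestone = milestone, hours = hours,
                      z = unname(z),
                      percentile = unname(100 * stats::pnorm(z))))
  }
  if (is.null(cohort)) stop("supply either a (milestone, hours) query or a cohort",
                            call. = FALSE)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  score_cohort(cohort, chart, cutoff = cutoff)
}
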