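# End-to-end pipeline: knowledge bases -> workflow -> analysis -> reports.

#' Pipeline configuration
#'
#' @param cohort a [cohort_config()] describing the synthetic cohort, or a
#'   path to a long-format cohort CSV (see [read_cohort_csv()]).
#' @param task task requirement class name.
#' @param k neighbour count for KNN imputation.
#' @param cf_subset parameter subset for the CF dynamics (`NULL` = all 21).
#' @param m_sweep subset sizes for the CF subset-search profile (`NULL`
#'   disables the sweep).
#' @param threshold_grid link-importance threshold grid for the KMT scan.
#' @param restarts partition-search restarts.
#' @param alpha significance level for the comparison suite.
#' @param seed master seed for every stochastic step.
#' @param out_dir output directory for the report bundle (`NULL` = return
#'   results only).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), task = "ConsistencyAnalysis",
                            k = 5L, cf_subset = NULL, m_sweep = NULL,
                            threshold_grid = seq(0, 0.6, by = 0.0125),
                            restarts = 20L, alpha = 0.05, seed = 1L,
                            out_dir = NULL) {
  if (is.character(cohort) && !file.exists(cohort))
    stop("cohort CSV not found: ", cohort)
  structure(list(cohort = cohort, task = task, k = k, cf_subset = cf_subset,
                 m_sweep = m_sweep, threshold_grid = threshold_grid,
                 restarts = restarts, alpha = alpha, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full consistency-analysis pipeline
#'
#' Executes the ontology-driven workflow end to end: merge the packaged
#' knowledge bases, extract the task sub-ontology, profile the data, build
#' the workflow, then execute its stages — KNN imputation when the workflow
#' selects it, CF dynamics with the optimal-subset profile, the KMT
#' functional dynamics with critical periods, and the Mann-Whitney
#' comparison suite.  With `out_dir` set, the bundle (workflow JSON, CSV
#' tables, run log) is written to disk; every numeric table is reproducible
#' from the seed.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `abs_pipeline`: list with `workflow`,
#'   `profile`, `cohort` (imputed), `cf`, `comparisons`, `kmt`,
#'   `subset_profile`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  say("pipeline start (abstate %s, seed %d)",
      as.character(utils::packageVersion("abstate")), config$seed)
  kb <- stage("knowledge base", {
    m <- load_merged_kb()
    say("merged KB: %d entities, %d axioms", kb_n_entities(m), kb_n_axioms(m))
    m
  })
  sub <- stage("sub-ontology extraction", {
    s <- kb_extract(kb, config$task)
    say("extracted sub-ontology for %s: %d entities, %d axioms",
        config$task, kb_n_entities(s), kb_n_axioms(s))
    s
  })
  cohort <- stage("data", {
    if (is.character(config$cohort)) read_cohort_csv(config$cohort)
    else generate_cohort(config$cohort)
  })
  say("cohort: %d patients, %.1f%% missing", length(cohort$group),
      100 * mean(is.na(cohort$values)))
  profile <- stage("data understanding", profile_data(cohort, kb = kb))
  say("profile: %s", paste(profile$characteristics, collapse = ", "))
  workflow <- stage("workflow construction",
                    build_workflow(sub, config$task, profile))
  say("workflow selections: %s", paste(workflow$selections, collapse = ", "))

  if (anyNA(cohort$values) && "KNN_Imputation_ED" %in% workflow$selections) {
    cohort <- stage("imputation", impute_cohort(cohort, k = config$k))
    say("imputation: KNN_Imputation_ED, k = %d", config$k)
  } else if (anyNA(cohort$values) && "Mean_Imputation" %in% workflow$selections) {
    cohort <- stage("imputation", impute_cohort(cohort, method = "mean"))
    say("imputation: Mean_Imputation")
  } else say("imputation stage skipped (no missing values)")

  cf <- subset_profile <- comparisons <- kmt <- NULL
  if ("CF" %in% workflow$selections) {
    cf <- stage("CF dynamics", cf_dynamics(cohort, subset = config$cf_subset))
    say("CF dynamics over %d parameters (reference '%s')",
        length(cf$subset), cf$reference)
    if (!is.null(config$m_sweep)) {
      subset_profile <- stage("CF subset search", {
        g1 <- which(cohort$group == sort(unique(cohort$group))[1])
        ref <- cohort$values[g1, , 1]
        S <- estimate_correlation(ref)
        X <- cohort$values[g1, , dim(cohort$values)[3]]
        Z <- sweep(sweep(X, 2, colMeans(ref), "-"), 2, apply(ref, 2, stats::sd), "/")
        cf_subset_profile(Z, S, m_values = config$m_sweep)
      })
      say("CF subset profile for m = %s", paste(config$m_sweep, collapse = ", "))
    }
    comparisons <- stage("comparisons", comparison_suite(cf, alpha = config$alpha))
    say("%d Mann-Whitney comparisons, %d significant at alpha = %g",
        nrow(comparisons), sum(comparisons$significant), config$alpha)
  }
  if ("Kupershtokh_Mirkin_Trofimov" %in% workflow$selections) {
    kmt <- stage("KMT functional dynamics",
                 functional_dynamics(cohort, grid = config$threshold_grid,
                                     restarts = config$restarts, seed = config$seed))
    say("KMT dynamics: critical period of group 1 in F: %d -> %d",
        kmt$critical$from[kmt$critical$group == "1" & kmt$critical$measure == "F"],
        kmt$critical$to[kmt$critical$group == "1" & kmt$critical$measure == "F"])
  }
  say("pipeline done")

  out <- structure(list(workflow = workflow, profile = profile, cohort = cohort,
                        cf = cf, subset_profile = subset_profile,
                        comparisons = comparisons, kmt = kmt, log = log),
                   class = "abs_pipeline")
  if (!is.null(config$out_dir)) write_pipeline_bundle(out, config$out_dir)
  out
}

#' Write the report bundle of a pipeline run
#'
#' @param result an `abs_pipeline` result.
#' @param out_dir directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  workflow_to_json(result$workflow, file.path(out_dir, "workflow.json"))
  if (!is.null(result$cf)) {
    utils::write.csv(result$cf$summary, file.path(out_dir, "cf_dynamics.csv"),
                     row.names = FALSE)
    utils::write.csv(result$comparisons, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
  }
  if (!is.null(result$subset_profile))
    utils::write.csv(result$subset_profile, file.path(out_dir, "cf_subsets.csv"),
                     row.names = FALSE)
  if (!is.null(result$kmt)) {
    utils::write.csv(result$kmt$table, file.path(out_dir, "functional_indicators.csv"),
                     row.names = FALSE)
    utils::write.csv(result$kmt$critical, file.path(out_dir, "critical_periods.csv"),
                     row.names = FALSE)
  }
  writeLines(result$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.abs_pipeline <- function(x, ...) {
  cat("<abs_pipeline>\n")
  print(x$workflow)
  if (!is.null(x$cf)) print(x$cf)
  if (!is.null(x$kmt)) print(x$kmt)
  invisible(x)
}
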