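# Data profiling and workflow construction.

test_that("the default synthetic cohort profiles as continuous MNAR data", {
  co <- generate_cohort(cohort_config(seed = 3))
  pr <- profile_data(co, kb = load_merged_kb())
  expect_true(all(c("Continuous", "DataWithMissingValue", "Missing_not_Random")
                  %in% pr$characteristics))
  expect_false("LongTSDataset" %in% pr$characteristics)
  expect_equal(pr$metadata$n_samples, 391)
  expect_equal(pr$metadata$n_labels, 3)
})

test_that("complete data profile has no missing-value characteristic", {
  co <- generate_cohort(small_config(missing_rate = 0))
  pr <- profile_data(co)
  expect_true("DataWithoutMissingValue" %in% pr$characteristics)
  expect_false(any(c("DataWithMissingValue", "Missing_not_Random",
                     "Missing_Random") %in% pr$characteristics))
})

test_that("a completely random mask is not flagged MNAR", {
  cfg <- cohort_config(n_patients = c(131L, 130L, 130L), mnar_coef = 0, seed = 13)
  co <- generate_cohort(cfg)
  pr <- profile_data(co)
  expect_true("Missing_Random" %in% pr$characteristics)
})

test_that("the long-series characteristic follows the KB threshold exactly", {
  kb <- load_merged_kb()
  mk <- function(tn) {
    cohort_config(n_patients = c(4L, 4L, 4L), parameters = paste0("v", 1:4),
                  block_sizes = 4L, n_timepoints = tn,
                  time_profile = rep(0, tn), missing_rate = 0, seed = 1)
  }
  co700 <- generate_cohort(mk(700L))
  co701 <- generate_cohort(mk(701L))
  expect_false("LongTSDataset" %in% profile_data(co700, kb)$characteristics)
  expect_true("LongTSDataset" %in% profile_data(co701, kb)$characteristics)
})

test_that("the consistency-analysis workflow selects the documented algorithms", {
  kb <- load_merged_kb()
  wf <- build_workflow(kb, "ConsistencyAnalysis",
                       c("Continuous", "DataWithMissingValue", "Missing_not_Random"))
  expect_setequal(wf$selections,
                  c("KNN_Imputation_ED", "CF", "Kupershtokh_Mirkin_Trofimov"))
  stages <- vapply(wf$stages, `[[`, character(1), "stage")
  expect_equal(stages, c("TaskUnderstanding", "DataUnderstanding", "DataPreparation",
                         "DataProcessing", "Evaluation"))
  prep <- wf$stages[[3]]$processes
  expect_equal(prep[[1]]$process, "MissingValueProcessing")
  expect_equal(prep[[1]]$algorithms, "KNN_Imputation_ED")
  expect_setequal(prep[[1]]$parameters$KNN_Imputation_ED,
                  c("NeighborCountParameter", "DistanceMeasureParameter"))
  proc <- wf$stages[[4]]$processes
  expect_equal(proc[[1]]$process, "ConsistencyModelling")
  expect_equal(proc[[1]]$algorithms, c("CF", "Kupershtokh_Mirkin_Trofimov"))
})

test_that("complete data yields a workflow without the imputation process", {
  kb <- load_merged_kb()
  wf <- build_workflow(kb, "ConsistencyAnalysis",
                       c("Continuous", "DataWithoutMissingValue"))
  procs <- unlist(lapply(wf$stages, function(st)
    vapply(st$processes, `[[`, character(1), "process")))
  expect_false("MissingValueProcessing" %in% procs)
  expect_true("MissingValueProcessing" %in% wf$skipped)
  expect_setequal(wf$selections, c("CF", "Kupershtokh_Mirkin_Trofimov"))
})

test_that("the post-imputation profile converges (no second imputation pass)", {
  kb <- load_merged_kb()
  wf <- build_workflow(kb, "ConsistencyAnalysis",
                       c("Continuous", "DataWithMissingValue", "Missing_not_Random"))
  wf2 <- build_workflow(kb, "ConsistencyAnalysis", wf$profile_final)
  procs2 <- unlist(lapply(wf2$stages, function(st)
    vapply(st$processes, `[[`, character(1), "process")))
  expect_false("MissingValueProcessing" %in% procs2)
})

test_that("every selected algorithm is in the KB answer set of its process", {
  kb <- load_merged_kb()
  cl <- kb_classify(kb)
  wf <- build_workflow(kb, "ConsistencyAnalysis",
                       c("Continuous", "DataWithMissingValue", "Missing_not_Random"))
  for (st in wf$stages) for (pr in st$processes) for (alg in pr$algorithms)
    expect_true(alg %in% kb_query(
      kb, paste("Algorithm and employedBy some", pr$process), cl))
})

test_that("the extracted sub-ontology yields the same workflow as the merged KB", {
  kb <- load_merged_kb()
  sub <- kb_extract(kb, "ConsistencyAnalysis")
  prof <- c("Continuous", "DataWithMissingValue", "Missing_not_Random")
  wa <- build_workflow(kb, "ConsistencyAnalysis", prof)
  wb <- build_workflow(sub, "ConsistencyAnalysis", prof)
  expect_equal(wb$selections, wa$selections)
  expect_equal(lapply(wb$stages, `[[`, "stage"), lapply(wa$stages, `[[`, "stage"))
})

test_that("a required process without a suitable algorithm is an explicit error", {
  kb <- load_merged_kb()
  keep <- !(kb$axioms$s %in% c("KNN_Imputation_ED", "Mean_Imputation"))
  crippled <- knowledge_base(kb$axioms[keep, ], namespace = "x")
  expect_error(
    build_workflow(crippled, "ConsistencyAnalysis",
                   c("Continuous", "DataWithMissingValue", "Missing_not_Random")),
    "no candidate algorithm.*MissingValueProcessing")
  expect_error(build_workflow(kb, "NoSuchTask", "Continuous"), "unresolvable task")
  expect_error(build_workflow(kb, "ConsistencyAnalysis", "NoSuchCharacteristic"),
               "not in KB")
})

test_that("process ordering is a linear extension of the precedence graph", {
  kb <- load_merged_kb()
  expect_equal(order_processes(c("Modelling", "MissingValueProcessing"), kb),
               c("MissingValueProcessing", "Modelling"))
  expect_equal(order_processes("Modelling", kb), "Modelling")
  # random hasPostprocess DAGs: result must respect every edge
  set.seed(37)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    nodes <- paste0("N", seq_len(n))
    edges <- NULL
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (runif(1) < 0.3) edges <- rbind(edges, c(nodes[i], "hasPostprocess", nodes[j]))
    ax <- axiom_table(subclass = cbind(nodes, "Process"),
                      restriction = edges)
    kb2 <- knowledge_base(ax)
    ord <- order_processes(nodes, kb2)
    pos <- match(nodes, ord)
    if (!is.null(edges))
      for (k in seq_len(nrow(edges)))
        expect_lt(pos[match(edges[k, 1], nodes)], pos[match(edges[k, 3], nodes)])
  }
  # a precedence cycle is reported
  cyc <- knowledge_base(axiom_table(
    subclass = rbind(c("A", "Process"), c("B", "Process")),
    restriction = rbind(c("A", "hasPostprocess", "B"),
                        c("B", "hasPostprocess", "A"))))
  expect_error(order_processes(c("A", "B"), cyc), "cycle")
})
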