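# Packaged knowledge-base content: the data-mining core KB, the medical
# domain KB, the ABS parameter dictionary and the competency-question suite.

.extdata <- function(file) {
  p <- system.file("extdata", file, package = "abstate")
  if (p == "") p <- file.path("inst", "extdata", file)  # pre-install fallback
  p
}

#' Load the packaged data-mining core knowledge base
#'
#' The core KB describes the CRISP-DM stages (chained by `hasPostprocess`),
#' their sub-processes with input/output restrictions, the algorithm taxonomy
#' with suitability characteristics and parameters, and the INPUT
#' sub-ontology of data characteristics and task requirements.  It contains
#' everything needed to answer the nine competency questions and to assemble
#' the consistency-analysis workflow: in particular `KNN_Imputation_ED`
#' (employing `KNN_Algorithm` with measure `Euclidean_Distance`) and the two
#' descriptive algorithms `CF` and `Kupershtokh_Mirkin_Trofimov` linked to
#' `ConsistencyAnalysis`.
#'
#' @return a `knowledge_base`.
#' @export
load_dm_core <- function() read_kb(.extdata("dm_core.kb"), namespace = "dm_core")

#' Load the packaged medical domain knowledge base
#'
#' Declares `MedicalDataAnalysisTask` (with subclass `ConsistencyAnalysis`),
#' `MedicalData`, the data characteristics observed on ABS cohorts
#' (`Continuous`, `Missing_not_Random`) and the medical rendering of the
#' five-stage analysis workflow.
#'
#' @return a `knowledge_base`.
#' @export
load_medical_domain <- function()
  read_kb(.extdata("medical_domain.kb"), namespace = "medical_domain")

#' Load the merged medical data-mining knowledge base
#'
#' [kb_merge()] of [load_dm_core()] and [load_medical_domain()] into one
#' namespace; the KB the consistency-analysis workflow is built against.
#'
#' @return a `knowledge_base`.
#' @export
load_merged_kb <- function()
  kb_merge(load_dm_core(), load_medical_domain(), namespace = "medical_dm")

#' The acid-base state parameter dictionary
#'
#' The 21 blood-gas and electrolyte parameters measured on each patient at
#' each time point, with their descriptions, in dictionary order.
#'
#' @return a `data.frame` with columns `name` and `description` (21 rows).
#' @export
abs_parameter_table <- function() {
  utils::read.csv(.extdata("abs_parameters.csv"), stringsAsFactors = FALSE,
                  check.names = FALSE)
}

#' Names of the ABS parameters
#' @return character vector of length 21.
#' @export
abs_parameter_names <- function() abs_parameter_table()$name

#' The competency-question suite
#'
#' Nine benchmark questions the packaged KB must answer correctly: eight
#' conjunctive DL queries and one numeric definition lookup (the minimum
#' length defining a long time-series dataset).  Names printed with spaces in
#' the source material are rendered with underscores so they are legal query
#' tokens.
#'
#' @return a list of cases with fields `id`, `question`, `type`
#'   (`"query"` or `"definition"`), `query` (or `subject`/`prop`), and
#'   `expected`.
#' @export
competency_questions <- function() {
  list(
    list(id = "CQ1",
         question = "Which characteristics make an algorithm suitable for data with class imbalance?",
         type = "query",
         query = "Characteristics and suitableFor some DataWithClassImbalance",
         expected = "ToleranceToClassImbalance"),
    list(id = "CQ2",
         question = "Which output models are available for binary classification?",
         type = "query",
         query = "OutputModel and availableFor some BinaryClassification",
         expected = "BinaryClassificationModel"),
    list(id = "CQ3",
         question = "Which characteristics does BayesianAlgorithm have?",
         type = "query",
         query = "Characteristics and characteristicOf some BayesianAlgorithm",
         expected = c("ToleranceToClassImbalance", "HandlingOfClassificationCosts",
                      "BiasVarianceProfile")),
    list(id = "CQ4",
         question = "What outputs does the process data_mining_goals_identification have?",
         type = "query",
         query = "Output and outputOf some data_mining_goals_identification",
         expected = c("data_mining_goals_description",
                      "data_mining_success_criteria_description")),
    list(id = "CQ5",
         question = "Which algorithms does the process DimensionReduction employ?",
         type = "query",
         query = "Algorithm and employedBy some DimensionReduction",
         expected = "PCA"),
    list(id = "CQ6",
         question = "How is the data characteristic LongTSDataset defined?",
         type = "definition",
         subject = "LongTSDataset", prop = "hasMinLength",
         expected = "700"),
    list(id = "CQ7",
         question = "What are the post processes of BusinessUnderstanding?",
         type = "query",
         query = "Process and postprocessOf some BusinessUnderstanding",
         expected = "DataUnderstanding"),
    list(id = "CQ8",
         question = "What sub-processes does the stage BusinessUnderstanding have?",
         type = "query",
         query = "Process and subprocessOf some BusinessUnderstanding",
         expected = c("application_objectives_identification",
                      "application_resources_assessment",
                      "data_mining_goals_identification")),
    list(id = "CQ9",
         question = "What parameters does SVC-Algorithm need?",
         type = "query",
         query = "Parameter and parameterOf some SVC-Algorithm",
         expected = c("CapacityParameter", "KernelTypeParameter"))
  )
}

#' Run the competency-question suite against a knowledge base
#'
#' Each question is answered with [kb_query()] (or, for the definition
#' lookup, [kb_data_values()]); a question passes when the answer set equals
#' the expected set exactly.
#'
#' @param kb a knowledge base (classified internally).
#' @return a `data.frame` with one row per question: `id`, `question`,
#'   `expected`, `answer`, `pass`.
#' @export
run_competency_suite <- function(kb) {
  closure <- kb_classify(kb)
  cqs <- competency_questions()
  rows <- lapply(cqs, function(cq) {
    ans <- tryCatch({
      if (cq$type == "query") kb_query(kb, cq$query, closure = closure)
      else as.character(kb_data_values(kb, cq$subject, cq$prop))
    }, error = function(e) character())
    data.frame(
      id = cq$id, question = cq$question,
      expected = paste(sort(cq$expected, method = "radix"), collapse = ", "),
      answer = paste(ans, collapse = ", "),
      pass = setequal(ans, cq$expected) && !anyDuplicated(ans),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
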