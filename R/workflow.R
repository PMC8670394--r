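# Workflow construction: from a task requirement and a data profile to an
# ordered CRISP-DM style workflow with knowledge-base-selected algorithms.
#
# The builder follows the stepwise query procedure: (1) query the stages of
# the task, (2) query the available processes of each stage, (3) keep the
# processes whose input characteristics the current data satisfy, (4) query
# the suitable algorithm for each kept process — then runs the
# query-execute-estimate cycle: each selected preprocessing step is applied
# virtually, the profile is updated from the process's output restrictions,
# and readiness for the next stage is re-checked.

#' Profile a cohort against a knowledge base
#'
#' Estimates the data characteristics the workflow queries are phrased in:
#' `Continuous` (all parameters numeric-continuous), `DataWithMissingValue` /
#' `DataWithoutMissingValue`, the missingness mechanism (`Missing_not_Random`
#' when a logistic screen associates an entry's missingness with the
#' magnitude of the same parameter at adjacent time points at p < `alpha`,
#' `Missing_Random` otherwise), and `LongTSDataset` when the series length
#' exceeds the threshold stored in the KB (`hasMinLength` on
#' `LongTSDataset`).
#'
#' @param cohort a `cohort`.
#' @param kb knowledge base supplying the long-series threshold; optional.
#' @param alpha significance level of the MNAR screen.
#' @return an object of class `data_profile`: list with `characteristics`
#'   (character vector), `metadata` (`n_samples`, `n_labels`,
#'   `n_timepoints`, `missing_fraction` per parameter) and `mnar_p` (screen
#'   p-value, `NA` when complete).
#' @export
profile_data <- function(cohort, kb = NULL, alpha = 0.05) {
  stopifnot(inherits(cohort, "cohort"))
  vals <- cohort$values
  if (length(vals) == 0) stop("empty dataset")
  chars <- character()
  if (is.numeric(vals)) chars <- c(chars, "Continuous")
  mnar_p <- NA_real_
  if (anyNA(vals)) {
    chars <- c(chars, "DataWithMissingValue")
    mnar_p <- .mnar_screen(cohort)
    chars <- c(chars, if (is.finite(mnar_p) && mnar_p < alpha) "Missing_not_Random"
                      else "Missing_Random")
  } else chars <- c(chars, "DataWithoutMissingValue")
  Tn <- dim(vals)[3]
  min_len <- Inf
  if (!is.null(kb)) {
    v <- suppressWarnings(as.numeric(kb_data_values(kb, "LongTSDataset", "hasMinLength")))
    if (length(v) && is.finite(v[1])) min_len <- v[1]
  }
  if (Tn > min_len) chars <- c(chars, "LongTSDataset")
  structure(list(
    characteristics = chars,
    metadata = list(n_samples = nrow(vals), n_labels = length(unique(cohort$group)),
                    n_timepoints = Tn,
                    missing_fraction = apply(is.na(vals), 2, mean)),
    mnar_p = mnar_p), class = "data_profile")
}

# logistic screen: missingness indicator vs |standardized value| of the same
# parameter at an adjacent observed time point
.mnar_screen <- function(cohort) {
  vals <- cohort$values
  d <- dim(vals); Tn <- d[3]
  # standardize per group x parameter x time on observed values
  z <- vals
  for (g in unique(cohort$group)) {
    rows <- cohort$group == g
    for (t in seq_len(Tn)) {
      x <- vals[rows, , t]
      mu <- colMeans(x, na.rm = TRUE)
      sdv <- apply(x, 2, stats::sd, na.rm = TRUE)
      sdv[!is.finite(sdv) | sdv == 0] <- 1
      z[rows, , t] <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
    }
  }
  miss <- c(); absz <- c()
  for (t in seq_len(Tn)) {
    adj <- if (t > 1) z[, , t - 1] else z[, , t + 1]
    if (t > 1 && t < Tn) {            # prefer the earlier neighbour, fall back
      fb <- z[, , t + 1]
      adj[is.na(adj)] <- fb[is.na(adj)]
    }
    ok <- !is.na(adj)
    miss <- c(miss, is.na(vals[, , t])[ok])
    absz <- c(absz, abs(adj[ok]))
  }
  if (length(unique(miss)) < 2) return(NA_real_)
  fit <- stats::glm(miss ~ absz, family = stats::binomial())
  stats::coef(summary(fit))["absz", "Pr(>|z|)"]
}

#' @export
print.data_profile <- function(x, ...) {
  cat("<data_profile>", paste(x$characteristics, collapse = ", "), "\n")
  cat(sprintf("  %d samples, %d labels, %d time points, %.1f%% missing overall\n",
              x$metadata$n_samples, x$metadata$n_labels, x$metadata$n_timepoints,
              100 * mean(x$metadata$missing_fraction)))
  invisible(x)
}

# is filler f satisfied by some available characteristic (x <= f)?
.satisfied <- function(f, avail, anc) {
  any(vapply(avail, function(x) !is.null(anc[[x]]) && f %in% anc[[x]], logical(1)))
}

#' Order processes by their precedence constraints
#'
#' Precedence edges come from `hasPostprocess` restrictions (p precedes q
#' when q is subsumed by a `hasPostprocess` filler of p) and from
#' input/output matching (an output characteristic of p that some input
#' restriction of q requires puts p first).  Returns a total order extending
#' this partial order, deterministic via lexicographic tie-break; a cycle is
#' an error naming the entities involved.
#'
#' @param processes character vector of process class names.
#' @param kb knowledge base.
#' @param closure optional precomputed [kb_classify()] closure.
#' @return the processes in execution order.
#' @export
order_processes <- function(processes, kb, closure = NULL) {
  if (length(processes) <= 1) return(processes)
  if (is.null(closure)) closure <- kb_classify(kb)
  anc <- closure$class_anc
  n <- length(processes)
  prec <- matrix(FALSE, n, n, dimnames = list(processes, processes))
  io <- lapply(processes, function(p) list(
    post = kb_fillers(kb, p, "hasPostprocess", closure),
    outp = kb_fillers(kb, p, "hasOutput", closure),
    inp = kb_fillers(kb, p, "hasInput", closure)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    q <- processes[j]
    after <- any(vapply(io[[i]]$post, function(f) f %in% anc[[q]], logical(1)))
    feeds <- any(vapply(io[[i]]$outp, function(fo)
      any(vapply(io[[j]]$inp, function(fi) fi %in% anc[[fo]], logical(1))), logical(1)))
    if (after || feeds) prec[i, j] <- TRUE
  }
  out <- character(); left <- processes
  while (length(left)) {
    ready <- left[vapply(left, function(q)
      !any(prec[setdiff(left, q), q]), logical(1))]
    if (!length(ready))
      stop("cycle in process precedence: ", paste(sort(left), collapse = ", "))
    nxt <- sort(ready, method = "radix")[1]
    out <- c(out, nxt); left <- setdiff(left, nxt)
  }
  out
}

#' Build the data-mining workflow for a task
#'
#' Runs the four-step query procedure and the query-execute-estimate cycle
#' against the knowledge base, returning the ordered stages, their kept
#' processes, and the algorithm (with its declared parameters) the KB
#' selects for each process.  All co-optimal suitable algorithms are
#' reported, in lexicographic order.
#'
#' A process is *required* when all of its `hasInput` characteristics are
#' satisfied by the current profile (a process with no input restriction is
#' an always-on organizational step).  A required data-transforming process
#' for which no suitable algorithm exists is an error naming the process.
#' After a process with a selected algorithm, the profile is updated: its
#' input characteristics are consumed, its data-characteristic outputs are
#' added, and characteristics that merely characterize a consumed one (via
#' `characterizes` restrictions) lapse with it.
#'
#' @param kb knowledge base (merged or task-extracted).
#' @param task task requirement class name, e.g. `"ConsistencyAnalysis"`.
#' @param profile a [profile_data()] result, or a character vector of
#'   characteristic names.
#' @return an object of class `dm_workflow`: list with `task`,
#'   `dm_objective`, `stages` (each with `stage` and `processes`, each
#'   process with `process`, `algorithms`, `parameters`), `selections`
#'   (all selected algorithms), `profile_initial`, `profile_final`.
#' @export
build_workflow <- function(kb, task, profile) {
  if (!kb_has_entity(kb, task)) stop("unresolvable task: ", task)
  chars <- if (inherits(profile, "data_profile")) profile$characteristics else profile
  for (ch in chars) if (!kb_has_entity(kb, ch))
    stop("profile characteristic not in KB: ", ch)
  closure <- kb_classify(kb)
  anc <- closure$class_anc

  stages <- unique(unlist(lapply(anc[[task]], function(A)
    tryCatch(kb_query(kb, paste("Stage and stageOf some", A), closure = closure),
             error = function(e) character()))))
  if (!length(stages)) stop("no stages defined for task ", task)
  stages <- order_processes(stages, kb, closure)

  cur <- chars
  stage_list <- list(); selections <- character(); skipped <- character()
  for (st in stages) {
    procs <- kb_query(kb, paste("Process and subprocessOf some", st), closure = closure)
    procs <- setdiff(procs, stages)
    procs <- order_processes(procs, kb, closure)
    plist <- list()
    for (pr in procs) {
      inputs <- kb_fillers(kb, pr, "hasInput", closure)
      required <- !length(inputs) ||
        all(vapply(inputs, .satisfied, logical(1), avail = cur, anc = anc))
      if (!required) { skipped <- c(skipped, pr); next }
      candidates <- kb_query(kb, paste("Algorithm and employedBy some", pr),
                             closure = closure)
      avail <- unique(c(cur, task))
      suitable <- Filter(function(alg) {
        req <- kb_fillers(kb, alg, "suitableFor", closure)
        all(vapply(req, .satisfied, logical(1), avail = avail, anc = anc))
      }, candidates)
      suitable <- sort(unlist(suitable), method = "radix")
      if (length(inputs) && !length(suitable))
        stop("no candidate algorithm for process ", pr)
      params <- lapply(stats::setNames(suitable, suitable), function(alg)
        kb_query(kb, paste("Parameter and parameterOf some", alg), closure = closure))
      plist[[length(plist) + 1L]] <- list(process = pr, algorithms = suitable,
                                          parameters = params)
      selections <- c(selections, suitable)
      if (length(suitable)) {   # virtual execution: update the profile
        outs <- kb_fillers(kb, pr, "hasOutput", closure)
        outs <- outs[vapply(outs, function(o)
          is.null(anc[["DataCharacteristic"]]) || "DataCharacteristic" %in% anc[[o]],
          logical(1))]
        consumed <- cur[vapply(cur, function(x)
          any(vapply(inputs, function(f) f %in% anc[[x]], logical(1))), logical(1))]
        lapsed <- cur[vapply(cur, function(x) {
          dep <- kb_fillers(kb, x, "characterizes", closure)
          length(dep) && any(dep %in% consumed)
        }, logical(1))]
        cur <- unique(c(setdiff(cur, c(consumed, lapsed)), outs))
      }
    }
    stage_list[[length(stage_list) + 1L]] <- list(stage = st, processes = plist)
  }
  objective <- as.character(kb_data_values(kb, task, "hasDMObjective"))
  structure(list(task = task, dm_objective = objective, stages = stage_list,
                 selections = unique(selections), skipped = skipped,
                 profile_initial = chars, profile_final = cur),
            class = "dm_workflow")
}

#' @export
print.dm_workflow <- function(x, ...) {
  cat(sprintf("<dm_workflow> task: %s\n", x$task))
  if (length(x$dm_objective))
    cat("  DM objective:", paste(x$dm_objective, collapse = ", "), "\n")
  for (st in x$stages) {
    cat("  ", st$stage, "\n", sep = "")
    for (pr in st$processes) {
      alg <- if (length(pr$algorithms)) paste(pr$algorithms, collapse = ", ") else "-"
      cat(sprintf("    %s -> %s\n", pr$process, alg))
    }
  }
  invisible(x)
}

#' Serialize a workflow to JSON
#'
#' @param workflow a `dm_workflow`.
#' @param path output file; when `NULL` the JSON string is returned.
#' @return `path` (invisibly) or the JSON string.
#' @export
workflow_to_json <- function(workflow, path = NULL) {
  obj <- list(task = workflow$task,
              dm_objective = workflow$dm_objective,
              stages = lapply(workflow$stages, function(st) list(
                stage = st$stage,
                processes = lapply(st$processes, function(pr) list(
                  process = pr$process, algorithms = pr$algorithms,
                  parameters = pr$parameters)))),
              selections = workflow$selections,
              profile_initial = workflow$profile_initial,
              profile_final = workflow$profile_final)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
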