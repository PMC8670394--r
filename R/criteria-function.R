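# The criteria function (CF): a Mahalanobis-type quadratic form
# C(A_m) = X_m' S_m^{-1} X_m of a patient's standardized parameter vector
# X_m against the correlation matrix S_m of a reference patient group, with
# branch-and-bound search for the optimal feature subset and group/time CF
# dynamics.  CF measures how far a patient departs from the reference
# correlation structure of the parameter system: values near m (the subset
# size) are typical of the reference state, larger values mean loss of
# consistency.

#' Estimate a correlation structure
#'
#' Pearson correlation of the columns of a complete data matrix.  If the
#' condition number exceeds `cond_max`, a ridge `S + lambda I` is applied
#' (escalating tenfold until well-conditioned) so the inverse in the
#' quadratic form is stable.
#'
#' @param x complete numeric matrix (rows = patients, columns = parameters).
#' @param lambda initial ridge (default `1e-6`).
#' @param cond_max condition-number threshold triggering regularization.
#' @return an object of class `cf_correlation`: list with the (possibly
#'   regularized) matrix `S`, its Cholesky factor `chol`, and the `lambda`
#'   actually applied.
#' @export
estimate_correlation <- function(x, lambda = 1e-6, cond_max = 1e10) {
  stopifnot(is.matrix(x), !anyNA(x))
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(x)[sds == 0]
    if (is.null(nm)) nm <- which(sds == 0)
    stop("constant column(s): ", paste(nm, collapse = ", "))
  }
  S <- stats::cor(x)
  lam <- 0
  while (kappa(S, exact = FALSE) > cond_max || inherits(try(chol(S), silent = TRUE), "try-error")) {
    lam <- if (lam == 0) lambda else lam * 10
    S <- stats::cor(x) + lam * diag(ncol(x))
    if (lam > 1) stop("correlation matrix cannot be regularized")
  }
  structure(list(S = S, chol = chol(S), lambda = lam), class = "cf_correlation")
}

#' @export
print.cf_correlation <- function(x, ...) {
  cat(sprintf("<cf_correlation> %d x %d, ridge lambda = %g\n",
              nrow(x$S), ncol(x$S), x$lambda))
  invisible(x)
}

#' Compute the criteria function
#'
#' The quadratic form `x' S^{-1} x`; non-negative by positive definiteness
#' of the correlation matrix.
#'
#' @param x standardized patient vector.
#' @param S a `cf_correlation`, or a plain positive-definite matrix.
#' @return the CF value (scalar).
#' @export
compute_cf <- function(x, S) {
  R <- if (inherits(S, "cf_correlation")) S$chol else chol(S)
  if (length(x) != ncol(R)) stop("dimension mismatch: x has length ", length(x),
                                 ", S is ", ncol(R), " x ", ncol(R))
  y <- backsolve(R, x, transpose = TRUE)
  sum(y^2)
}

# mean CF over rows for a column subset: tr(S_A^{-1} M_A) with M = X'X / n
.mean_cf <- function(M, S, idx) {
  Si <- solve(S[idx, idx, drop = FALSE])
  sum(Si * M[idx, idx, drop = FALSE])
}

#' Branch-and-bound search for the optimal CF feature subset
#'
#' Finds the size-`m` parameter subset maximizing the mean CF over patients.
#' Because the quadratic form is monotone under subset nesting (the CF of a
#' superset is at least the CF of any of its subsets, for every patient), the
#' mean CF of a partial selection plus all remaining candidates bounds every
#' completion from above; branches whose bound cannot beat the incumbent are
#' pruned, so the search is exact.
#'
#' @param x matrix of standardized patient vectors (rows = patients).
#' @param S reference correlation of the columns of `x` (a
#'   [estimate_correlation()] result or plain matrix).
#' @param m subset size, `1 <= m <= ncol(x)`.
#' @return a list with `subset` (column names or indices), `objective`
#'   (achieved mean CF), `m` and `n_nodes` (search-tree nodes visited).
#' @export
best_subset_cf <- function(x, S, m) {
  stopifnot(is.matrix(x))
  S <- if (inherits(S, "cf_correlation")) S$S else S
  p <- ncol(x)
  if (m < 1 || m > p) stop("infeasible subset size m = ", m)
  M <- crossprod(x) / nrow(x)
  # candidates in decreasing single-feature objective: better incumbents sooner
  ord <- order(diag(M), decreasing = TRUE)
  best_val <- -Inf; best_set <- integer(); nodes <- 0L
  rec <- function(cur, rest) {
    nodes <<- nodes + 1L
    if (length(cur) == m) {
      v <- .mean_cf(M, S, cur)
      if (v > best_val) { best_val <<- v; best_set <<- cur }
      return()
    }
    if (length(cur) + length(rest) < m) return()
    if (.mean_cf(M, S, c(cur, rest)) <= best_val + 1e-12) return()
    rec(c(cur, rest[1L]), rest[-1L])
    rec(cur, rest[-1L])
  }
  rec(integer(), ord)
  best_set <- sort(best_set)
  nm <- if (!is.null(colnames(x))) colnames(x)[best_set] else best_set
  list(subset = nm, index = best_set, objective = best_val, m = m, n_nodes = nodes)
}

#' Mean-CF profile over subset sizes
#'
#' Runs [best_subset_cf()] for each requested size, reporting the full
#' size-versus-objective profile (the optimal mean CF is non-decreasing in
#' the subset size).
#'
#' @param x,S as in [best_subset_cf()].
#' @param m_values subset sizes to evaluate.
#' @return `data.frame` with columns `m`, `objective`, `subset`.
#' @export
cf_subset_profile <- function(x, S, m_values = seq_len(ncol(x))) {
  rows <- lapply(m_values, function(m) {
    r <- best_subset_cf(x, S, m)
    data.frame(m = m, objective = r$objective,
               subset = paste(r$subset, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' CF dynamics of a cohort
#'
#' Computes per-patient CF values per group and time point, plus the pooled
#' "overall" series, and summarizes them as mean/SD per group x time point.
#'
#' With the default `reference = "baseline"`, each group's first time point
#' provides the standardization (mean/SD per parameter) and the correlation
#' matrix, so CF at later points measures the departure of a patient's
#' parameter system from the group's baseline consistency structure.  With
#' `reference = "cell"`, every group x time-point cell is self-referenced;
#' CF then measures only within-cell outlyingness and is centred near `m`
#' everywhere.
#'
#' @param cohort an imputed (complete) `cohort`.
#' @param subset parameter names to use (default: all).
#' @param reference `"baseline"` or `"cell"`.
#' @param baseline_timepoint which time point anchors the baseline reference.
#' @return an object of class `cf_result`: list with `cf` (long
#'   `data.frame`: `group`, `patient_id`, `timepoint`, `cf`), `summary`
#'   (`group`, `timepoint`, `mean_cf`, `sd_cf`, `n`), `subset`, `reference`.
#' @export
cf_dynamics <- function(cohort, subset = NULL,
                        reference = c("baseline", "cell"),
                        baseline_timepoint = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  reference <- match.arg(reference)
  vals <- cohort$values
  if (anyNA(vals)) stop("cohort contains missing values; impute first")
  if (is.null(subset)) subset <- colnames(vals)
  if (!all(subset %in% colnames(vals)))
    stop("unknown parameter(s): ", paste(setdiff(subset, colnames(vals)), collapse = ", "))
  Tn <- dim(vals)[3]
  groups <- sort(unique(cohort$group))
  sets <- c(stats::setNames(lapply(groups, function(g) which(cohort$group == g)),
                            as.character(groups)),
            list(overall = seq_len(nrow(vals))))
  rows <- list()
  for (gname in names(sets)) {
    idx <- sets[[gname]]
    if (reference == "baseline") {
      ref <- vals[idx, subset, baseline_timepoint, drop = FALSE][, , 1]
      mu <- colMeans(ref); sdv <- apply(ref, 2, stats::sd)
      if (any(sdv == 0)) stop("constant column(s) in baseline of group ", gname)
      S <- estimate_correlation(ref)
    }
    for (t in seq_len(Tn)) {
      X <- vals[idx, subset, t, drop = FALSE][, , 1]
      if (reference == "cell") {
        mu <- colMeans(X); sdv <- apply(X, 2, stats::sd)
        if (any(sdv == 0)) stop("constant column(s) in group ", gname, ", time ", t)
        S <- estimate_correlation(X)
      }
      Z <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
      y <- backsolve(S$chol, t(Z), transpose = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        group = gname, patient_id = rownames(vals)[idx], timepoint = t,
        cf = colSums(y^2), stringsAsFactors = FALSE)
    }
  }
  cf <- do.call(rbind, rows)
  rownames(cf) <- NULL
  agg <- do.call(rbind, lapply(split(cf, list(cf$group, cf$timepoint), drop = TRUE),
    function(d) data.frame(group = d$group[1], timepoint = d$timepoint[1],
                           mean_cf = mean(d$cf), sd_cf = stats::sd(d$cf),
                           n = nrow(d), stringsAsFactors = FALSE)))
  agg <- agg[order(agg$group, agg$timepoint), ]
  rownames(agg) <- NULL
  structure(list(cf = cf, summary = agg, subset = subset, reference = reference),
            class = "cf_result")
}

#' @export
print.cf_result <- function(x, ...) {
  cat(sprintf("<cf_result> %d parameters, reference '%s'\n mean CF by group x time point:\n",
              length(x$subset), x$reference))
  wide <- stats::reshape(x$summary[, c("group", "timepoint", "mean_cf")],
                         idvar = "group", timevar = "timepoint", direction = "wide")
  names(wide) <- sub("mean_cf\\.", "t", names(wide))
  print(wide, row.names = FALSE, digits = 4)
  invisible(x)
}
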