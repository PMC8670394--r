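# K-nearest-neighbour imputation with Euclidean distance, the algorithm the
# knowledge base selects for continuous data with values missing not at
# random.

#' Impute missing entries by k nearest neighbours
#'
#' For each missing entry, the k donor rows closest in Euclidean distance —
#' computed over the jointly observed coordinates and rescaled by
#' `sqrt(p / n_shared)` to stay comparable across overlap sizes — supply the
#' replacement as the (optionally distance-weighted) mean of their observed
#' values in that column.  Columns are standardized before distance
#' computation so parameters on wildly different scales contribute equally;
#' imputed values are returned on the original scale.  Observed entries are
#' never changed, and ties in distance are broken by row index, so the result
#' is deterministic.
#'
#' @param x numeric matrix with `NA` for missing entries.
#' @param k number of donor neighbours (default 5).
#' @param weighted if `TRUE`, donors are weighted by inverse distance.
#' @param standardize standardize columns (observed mean/SD) before distance
#'   computation.
#' @return the completed matrix.
#' @export
knn_impute <- function(x, k = 5L, weighted = FALSE, standardize = TRUE) {
  stopifnot(is.matrix(x), is.numeric(x), k >= 1)
  n <- nrow(x); p <- ncol(x)
  obs <- !is.na(x)
  if (any(rowSums(obs) == 0))
    stop("row(s) with no observed value: ", paste(which(rowSums(obs) == 0), collapse = ", "))
  short <- which(colSums(obs) < k)
  if (length(short)) {
    nm <- if (!is.null(colnames(x))) colnames(x)[short] else short
    stop("column(s) with fewer than k = ", k, " observed donor values: ",
         paste(nm, collapse = ", "))
  }
  if (!any(!obs)) return(x)

  z <- x
  if (standardize) {
    mu <- colMeans(x, na.rm = TRUE)
    sdv <- apply(x, 2, stats::sd, na.rm = TRUE)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    z <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  }

  out <- x
  need <- which(rowSums(!obs) > 0)
  for (i in need) {
    shared <- sweep(obs, 2, obs[i, ], "&")         # coords observed in both
    nsh <- rowSums(shared)
    diff2 <- sweep(z, 2, z[i, ], "-")^2
    diff2[!shared] <- 0
    d2 <- rowSums(diff2) * p / pmax(nsh, 1L)
    d2[nsh == 0] <- Inf
    d2[i] <- Inf
    for (j in which(!obs[i, ])) {
      donors <- which(obs[, j] & seq_len(n) != i)
      ord <- donors[order(d2[donors], donors)]     # ties broken by row index
      nn <- ord[seq_len(k)]
      if (anyNA(nn) || any(!is.finite(d2[nn])))
        stop("fewer than k = ", k, " comparable donors for row ", i,
             ", column ", if (!is.null(colnames(x))) colnames(x)[j] else j)
      if (weighted) {
        w <- 1 / (sqrt(d2[nn]) + 1e-8)
        out[i, j] <- sum(w * x[nn, j]) / sum(w)
      } else out[i, j] <- mean(x[nn, j])
    }
  }
  out
}

#' Column-mean imputation
#'
#' Baseline imputation replacing each missing entry by its column mean of
#' the observed values; used as the comparison standard for the KNN method.
#'
#' @param x numeric matrix with `NA`s.
#' @return the completed matrix.
#' @export
mean_impute <- function(x) {
  mu <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  x[idx] <- mu[idx[, 2]]
  x
}

#' Impute a cohort
#'
#' Applies [knn_impute()] (or the [mean_impute()] baseline) independently
#' within each time point (patient x parameter matrix); cross-time donors
#' are excluded so post-operative dynamics never leak into the imputation
#' of another time point.
#'
#' @param cohort a `cohort`.
#' @param k,weighted,standardize passed to [knn_impute()].
#' @param method `"knn"` (default) or `"mean"`.
#' @return the cohort with `values` completed; the original missingness mask
#'   is kept in the `mask` field.
#' @export
impute_cohort <- function(cohort, k = 5L, weighted = FALSE, standardize = TRUE,
                          method = c("knn", "mean")) {
  stopifnot(inherits(cohort, "cohort"))
  method <- match.arg(method)
  vals <- cohort$values
  mask <- is.na(vals)
  for (t in seq_len(dim(vals)[3]))
    vals[, , t] <- if (method == "knn")
      knn_impute(vals[, , t], k = k, weighted = weighted,
                 standardize = standardize)
    else mean_impute(vals[, , t])
  cohort$values <- vals
  cohort$mask <- mask
  cohort
}
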