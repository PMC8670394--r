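# The Kupershtokh-Mirkin-Trofimov (KMT) electrolyte-balance functional.
#
# Parameters R = (R_1, ..., R_m) are partitioned into disjoint classes
# ("functional subsystems") locally maximizing
#
#     F(a, R) = sum_s sum_{i<j in R_s} (a_ij - a)
#
# where a_ij is the link indicator (correlation) between parameters i and j
# and a is the link-importance threshold: links with a_ij > a are
# significant.  Three indicators are tracked: the functional value F, the
# threshold a, and the number of classes S.

#' Link matrix of a parameter set
#'
#' Pairwise Pearson correlations of the columns of a complete data matrix;
#' by default absolute values, treating a link as an importance magnitude
#' regardless of sign (negative physiological couplings are still
#' couplings).  The diagonal is never used by the functional.
#'
#' @param x complete numeric matrix (rows = patients).
#' @param method `"absolute"` (default) or `"signed"`.
#' @return symmetric link matrix with unit diagonal.
#' @export
link_matrix <- function(x, method = c("absolute", "signed")) {
  method <- match.arg(method)
  stopifnot(is.matrix(x), !anyNA(x), nrow(x) >= 3)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(x)[sds == 0]
    if (is.null(nm)) nm <- which(sds == 0)
    stop("constant column(s): ", paste(nm, collapse = ", "))
  }
  A <- stats::cor(x)
  if (method == "absolute") A <- abs(A)
  A
}

.check_partition <- function(membership, n) {
  stopifnot(length(membership) == n, !anyNA(membership))
  tab <- tabulate(membership)
  if (any(tab[unique(membership)] == 0)) stop("empty class in partition")
  invisible(TRUE)
}

#' Value of the KMT functional
#'
#' `F(a, R) = sum_s sum_{i<j in R_s} (a_ij - a)`, summing each unordered
#' within-class pair once; singleton classes contribute nothing, so the
#' all-singleton partition is the zero baseline.
#'
#' @param a_matrix symmetric link matrix.
#' @param membership integer class label per parameter (or a list of
#'   index/name vectors forming a partition).
#' @param a link-importance threshold.
#' @return the functional value.
#' @export
functional_value <- function(a_matrix, membership, a) {
  n <- ncol(a_matrix)
  if (is.list(membership)) {
    mem <- integer(n)
    idx <- lapply(membership, function(cl)
      if (is.character(cl)) match(cl, colnames(a_matrix)) else cl)
    flat <- unlist(idx)
    if (anyNA(flat) || length(flat) != n || anyDuplicated(flat))
      stop("invalid partition: classes must disjointly cover all parameters")
    for (s in seq_along(idx)) mem[idx[[s]]] <- s
    membership <- mem
  }
  .check_partition(membership, n)
  total <- 0
  for (s in unique(membership)) {
    ids <- which(membership == s)
    if (length(ids) > 1) {
      sub <- a_matrix[ids, ids, drop = FALSE]
      k <- length(ids)
      total <- total + sum(sub[upper.tri(sub)]) - a * choose(k, 2)
    }
  }
  total
}

# gain of moving element x from its class to class `to` (0 = new singleton)
.move_gain <- function(A, a, membership, x, to) {
  from <- membership[x]
  own <- which(membership == from); own <- own[own != x]
  lose <- if (length(own)) sum(A[x, own] - a) else 0
  gain <- if (to > 0) { tgt <- which(membership == to); sum(A[x, tgt] - a) } else 0
  gain - lose
}

.relocate <- function(A, a, membership) {
  n <- ncol(A)
  repeat {
    improved <- FALSE
    for (x in seq_len(n)) {
      classes <- setdiff(unique(membership), membership[x])
      cand <- c(classes, 0L)  # 0 = split off as a new singleton
      gains <- vapply(cand, function(to) .move_gain(A, a, membership, x, to), numeric(1))
      b <- which.max(gains)
      if (gains[b] > 1e-12) {
        to <- cand[b]
        membership[x] <- if (to == 0L) max(membership) + 1L else to
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  membership
}

.renumber <- function(membership) {
  as.integer(factor(membership, levels = unique(membership)))
}

# greedy agglomeration from singletons: merge the pair of classes with the
# largest positive merge gain until no merge helps
.agglomerate <- function(A, a) {
  n <- ncol(A)
  membership <- seq_len(n)
  repeat {
    cls <- unique(membership)
    if (length(cls) == 1) break
    best <- 0; bi <- bj <- 0L
    for (ii in seq_along(cls)[-length(cls)]) for (jj in (ii + 1):length(cls)) {
      ids_i <- which(membership == cls[ii]); ids_j <- which(membership == cls[jj])
      g <- sum(A[ids_i, ids_j] - a)
      if (g > best + 1e-12) { best <- g; bi <- cls[ii]; bj <- cls[jj] }
    }
    if (bi == 0L) break
    membership[membership == bj] <- bi
  }
  membership
}

#' Is a partition 1-move locally optimal?
#'
#' Certificate check: no relocation of a single parameter (to another class
#' or to a fresh singleton) increases the functional.
#'
#' @param a_matrix link matrix.
#' @param membership integer membership vector.
#' @param a threshold.
#' @return logical.
#' @export
is_local_optimum <- function(a_matrix, membership, a) {
  n <- ncol(a_matrix)
  for (x in seq_len(n)) {
    cand <- c(setdiff(unique(membership), membership[x]), 0L)
    gains <- vapply(cand, function(to) .move_gain(a_matrix, a, membership, x, to),
                    numeric(1))
    if (any(gains > 1e-12)) return(FALSE)
  }
  TRUE
}

#' Optimize the KMT partition at a fixed threshold
#'
#' Greedy agglomeration from singletons followed by single-element
#' relocation to a 1-move local maximum, repeated over `restarts` seeded
#' random initial partitions; the best local maximum found is returned and
#' is certified 1-move optimal.
#'
#' @param a_matrix symmetric link matrix.
#' @param a link-importance threshold.
#' @param restarts number of seeded starts (the first is the deterministic
#'   greedy agglomeration).
#' @param seed integer seed for the random restarts.
#' @return an object of class `kmt_partition`: list with `membership`,
#'   `classes` (list of parameter names/indices), `F`, `a`, `n_classes`.
#' @export
optimize_partition <- function(a_matrix, a, restarts = 20L, seed = 1L) {
  n <- ncol(a_matrix)
  stopifnot(isTRUE(all.equal(a_matrix, t(a_matrix))), n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  best_mem <- NULL; best_F <- -Inf
  for (r in seq_len(restarts)) {
    mem <- if (r == 1L) .agglomerate(a_matrix, a)
           else sample.int(sample.int(n, 1L), n, replace = TRUE)
    mem <- .relocate(a_matrix, a, .renumber(mem))
    f <- functional_value(a_matrix, .renumber(mem), a)
    if (f > best_F + 1e-12) { best_F <- f; best_mem <- .renumber(mem) }
  }
  nm <- colnames(a_matrix)
  classes <- split(if (is.null(nm)) seq_len(n) else nm, best_mem)
  names(classes) <- paste0("class", seq_along(classes))
  structure(list(membership = best_mem, classes = classes, F = best_F, a = a,
                 n_classes = length(classes)), class = "kmt_partition")
}

#' @export
print.kmt_partition <- function(x, ...) {
  cat(sprintf("<kmt_partition> F = %.4f at a = %.3f, %d classes\n",
              x$F, x$a, x$n_classes))
  for (s in seq_along(x$classes))
    cat("  ", names(x$classes)[s], ": ", paste(x$classes[[s]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Scan the link-importance threshold
#'
#' Optimizes the partition at every grid point and reports the three KMT
#' indicators (functional value, threshold, class count) along the grid.
#'
#' The selected threshold `a_selected` is the grid point achieving the
#' largest functional among those whose optimal partition is non-trivial
#' (more than one class) — in practice the level at which the parameter
#' system first decomposes, which tracks the strength of the cross-subsystem
#' links.  The full scan is always returned so no information is hidden.
#'
#' @param a_matrix symmetric link matrix.
#' @param grid threshold grid; defaults to 21 points spanning 0 to the
#'   largest off-diagonal link.
#' @param restarts,seed passed to [optimize_partition()].
#' @param select scoring rule for the reported threshold: `"max_F_nontrivial"`
#'   (default) or `"max_F"` (unconstrained).
#' @return an object of class `kmt_scan`: list with `table` (`data.frame`
#'   of `a`, `F`, `n_classes`), `partitions` (per grid point), `a_selected`
#'   and `selected` (the partition at `a_selected`).
#' @export
scan_threshold <- function(a_matrix, grid = NULL, restarts = 20L, seed = 1L,
                           select = c("max_F_nontrivial", "max_F")) {
  select <- match.arg(select)
  off <- a_matrix[upper.tri(a_matrix)]
  if (is.null(grid)) grid <- seq(0, max(off), length.out = 21L)
  if (!length(grid)) stop("empty threshold grid")
  parts <- lapply(seq_along(grid), function(i)
    optimize_partition(a_matrix, grid[i], restarts = restarts, seed = seed + i))
  tab <- data.frame(a = grid,
                    F = vapply(parts, `[[`, numeric(1), "F"),
                    n_classes = vapply(parts, `[[`, integer(1), "n_classes"))
  ok <- if (select == "max_F_nontrivial") tab$n_classes > 1 else rep(TRUE, nrow(tab))
  if (!any(ok)) ok <- rep(TRUE, nrow(tab))
  sel <- which(ok)[which.max(tab$F[ok])]
  structure(list(table = tab, partitions = parts,
                 a_selected = grid[sel], selected = parts[[sel]]),
            class = "kmt_scan")
}

#' @export
print.kmt_scan <- function(x, ...) {
  cat(sprintf("<kmt_scan> %d grid points; selected a = %.3f (F = %.4f, %d classes)\n",
              nrow(x$table), x$a_selected, x$selected$F, x$selected$n_classes))
  invisible(x)
}

#' KMT indicator dynamics and critical periods of a cohort
#'
#' Computes the three KMT indicators per group and time point (plus the
#' pooled "overall" series) from the per-cell link matrices, and identifies
#' each group's critical period: the consecutive time-point interval with
#' the largest absolute change in the functional value (and, separately, in
#' the selected threshold).
#'
#' The selected threshold per cell comes from the decomposition boundary
#' (see [scan_threshold()]) and tracks the strength of cross-subsystem
#' links.  The functional value and class count are evaluated at a *fixed
#' reference threshold* (`f_reference`, default 0.3 — midway between
#' typical cross-subsystem and within-subsystem link levels), the same for
#' every cell, so that changes in `F` over time reflect changes in link
#' strength rather than movement of the selection point; the functional
#' right at the decomposition boundary is dominated by the coarsest
#' partition and jumps by the within-pair count times one grid step
#' whenever the boundary moves by one point.  The per-cell scans are
#' returned in full.
#'
#' @param cohort an imputed (complete) `cohort`.
#' @param grid threshold grid for [scan_threshold()] (default: steps of
#'   0.025 on `[0, 0.9]`, shared across cells so thresholds are
#'   comparable).
#' @param restarts,seed passed to the optimizer.
#' @param method link method, see [link_matrix()].
#' @param f_reference fixed threshold at which the functional value and
#'   class count are reported; the nearest grid point is used.
#' @return an object of class `kmt_dynamics`: list with `table` (`group`,
#'   `timepoint`, `F`, `a_selected`, `n_classes`), `critical` (`group`,
#'   `measure`, `from`, `to`, `delta`) and `scans` (per cell).
#' @export
functional_dynamics <- function(cohort, grid = seq(0, 0.6, by = 0.0125),
                                restarts = 20L, seed = 1L,
                                method = c("absolute", "signed"),
                                f_reference = 0.3) {
  stopifnot(inherits(cohort, "cohort"))
  method <- match.arg(method)
  vals <- cohort$values
  if (anyNA(vals)) stop("cohort contains missing values; impute first")
  Tn <- dim(vals)[3]
  groups <- sort(unique(cohort$group))
  sets <- c(stats::setNames(lapply(groups, function(g) which(cohort$group == g)),
                            as.character(groups)),
            list(overall = seq_len(nrow(vals))))
  rows <- list(); scans <- list()
  for (gname in names(sets)) {
    idx <- sets[[gname]]
    for (t in seq_len(Tn)) {
      A <- link_matrix(vals[idx, , t, drop = FALSE][, , 1], method = method)
      sc <- scan_threshold(A, grid = grid, restarts = restarts,
                           seed = seed + 1000L * t)
      scans[[paste(gname, t, sep = ".")]] <- sc
      ref <- which.min(abs(grid - f_reference))
      rows[[length(rows) + 1L]] <- data.frame(
        group = gname, timepoint = t, F = sc$table$F[ref],
        a_selected = sc$a_selected, n_classes = sc$table$n_classes[ref],
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  crit <- list()
  for (gname in names(sets)) {
    d <- tab[tab$group == gname, ]
    d <- d[order(d$timepoint), ]
    for (measure in c("F", "a_selected")) {
      ch <- abs(diff(d[[measure]]))
      k <- which.max(ch)
      crit[[length(crit) + 1L]] <- data.frame(
        group = gname, measure = measure, from = d$timepoint[k],
        to = d$timepoint[k + 1L], delta = ch[k], stringsAsFactors = FALSE)
    }
  }
  structure(list(table = tab, critical = do.call(rbind, crit), scans = scans),
            class = "kmt_dynamics")
}

#' @export
print.kmt_dynamics <- function(x, ...) {
  cat("<kmt_dynamics> KMT indicators by group x time point:\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat("critical periods (largest consecutive change):\n")
  print(x$critical, row.names = FALSE, digits = 4)
  invisible(x)
}
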