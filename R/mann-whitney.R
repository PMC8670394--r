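# Mann-Whitney comparisons of CF values between patient groups and between
# the baseline time point and each later point.

#' Mann-Whitney rank test
#'
#' The U statistic is the number of pairs `(x_i, y_j)` with `x_i > y_j`
#' plus half the tied pairs.  For small samples (`n1 + n2 <= 20`) the
#' p-value is computed by full enumeration of all `choose(n1+n2, n1)`
#' labelings (exact even under ties); otherwise by the normal approximation
#' with the tie-corrected variance.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"` (default), `"greater"` (x tends larger)
#'   or `"less"`.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the enumeration; default
#'   enumerates iff `n1 + n2 <= 20`.
#' @return an object of class `mw_test`: list with `U` (for `x`), `U_y`,
#'   `p_value`, `n1`, `n2`, `method`, `alternative`.
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "greater", "less"),
                         exact = NULL) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("empty sample")
  if (is.null(exact)) exact <- (n1 + n2) <= 20
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # = #{x>y} + ties/2 under midranks
  mu <- n1 * n2 / 2
  eps <- 1e-9
  if (exact) {
    combos <- utils::combn(n1 + n2, n1)
    Uperm <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- switch(alternative,
      two.sided = mean(abs(Uperm - mu) >= abs(U - mu) - eps),
      greater = mean(Uperm >= U - eps),
      less = mean(Uperm <= U + eps))
    method <- "exact enumeration"
  } else {
    N <- n1 + n2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (U - mu) / sqrt(sigma2)
    p <- switch(alternative,
      two.sided = min(1, 2 * stats::pnorm(-abs(z))),
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z))
    method <- "normal approximation with tie correction"
  }
  structure(list(U = U, U_y = n1 * n2 - U, p_value = p, n1 = n1, n2 = n2,
                 method = method, alternative = alternative),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney (%s, %s): U = %.1f (n1 = %d, n2 = %d), p = %.4g\n",
              x$method, x$alternative, x$U, x$n1, x$n2, x$p_value))
  invisible(x)
}

#' Mann-Whitney comparison suite over a CF table
#'
#' The comparisons behind the study-style conclusions: (i) each pair of
#' patient groups, compared on per-patient CF averaged over time points;
#' (ii) within each group and overall, the baseline time point against each
#' later point, compared on per-patient CF at those points.  Uncorrected
#' p-values at level `alpha` by default (Holm correction available).
#'
#' @param cf a [cf_dynamics()] result.
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default) or `"holm"`.
#' @return an object of class `cf_comparisons`: `data.frame` with columns
#'   `comparison`, `group`, `n1`, `n2`, `U`, `p_value`, `significant`.
#' @export
comparison_suite <- function(cf, alpha = 0.05, adjust = c("none", "holm")) {
  stopifnot(inherits(cf, "cf_result"))
  adjust <- match.arg(adjust)
  d <- cf$cf
  groups <- setdiff(sort(unique(d$group)), "overall")
  rows <- list()
  add <- function(comparison, group, mw) {
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = comparison, group = group, n1 = mw$n1, n2 = mw$n2,
      U = mw$U, p_value = mw$p_value, stringsAsFactors = FALSE)
  }
  # (i) group vs group on per-patient mean CF across time points
  mean_by_patient <- function(g) {
    dd <- d[d$group == g, ]
    tapply(dd$cf, dd$patient_id, mean)
  }
  if (length(groups) > 1)
    for (i in seq_along(groups)[-length(groups)]) for (j in (i + 1):length(groups))
      add(sprintf("group %s vs group %s", groups[i], groups[j]), "-",
          mann_whitney(mean_by_patient(groups[i]), mean_by_patient(groups[j])))
  # (ii) baseline point vs each later point, per group and overall
  t0 <- min(d$timepoint)
  for (g in c(groups, "overall")) {
    dd <- d[d$group == g, ]
    base <- dd$cf[dd$timepoint == t0]
    for (t in setdiff(sort(unique(dd$timepoint)), t0))
      add(sprintf("point %d vs point %d", t0, t), g,
          mann_whitney(base, dd$cf[dd$timepoint == t]))
  }
  out <- do.call(rbind, rows)
  out$p_value <- if (adjust == "holm") stats::p.adjust(out$p_value, "holm") else out$p_value
  out$significant <- out$p_value < alpha
  rownames(out) <- NULL
  structure(out, class = c("cf_comparisons", "data.frame"),
            alpha = alpha, adjust = adjust)
}

#' @export
print.cf_comparisons <- function(x, ...) {
  cat(sprintf("CF comparisons (Mann-Whitney, alpha = %g, adjust = %s):\n",
              attr(x, "alpha"), attr(x, "adjust")))
  for (i in seq_len(nrow(x))) {
    lab <- if (x$group[i] == "-") x$comparison[i]
           else sprintf("%s, %s", if (x$group[i] == "overall") "overall"
                        else paste("group", x$group[i]), x$comparison[i])
    cat(sprintf("  %-32s U = %8.1f  p = %-10.3g %s\n", lab, x$U[i], x$p_value[i],
                if (x$significant[i]) "significant" else ""))
  }
  invisible(x)
}
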