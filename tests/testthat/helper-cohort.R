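# Small cohort configurations and numeric oracles shared across tests.

# a small, fast cohort: 3 groups x 15 patients, 6 parameters in 2 blocks;
# the MNAR coefficient is doubled so the screen keeps its power at this size
small_config <- function(seed = 1, missing_rate = 0.1, ...) {
  cohort_config(n_patients = c(15L, 15L, 15L), parameters = paste0("v", 1:6),
                block_sizes = c(3L, 3L), missing_rate = missing_rate,
                mnar_coef = 2, seed = seed, ...)
}

# draw n rows from N(mu, C) given a correlation matrix
rmvn <- function(n, C, mu = 0) {
  p <- ncol(C)
  matrix(stats::rnorm(n * p), n, p) %*% chol(C) + mu
}

block_cor <- function(membership, r_in, r_out) {
  C <- ifelse(outer(membership, membership, "=="), r_in, r_out)
  diag(C) <- 1
  C
}

# exhaustive KNN imputation oracle: explicit double loops, no shared code
knn_oracle <- function(x, k) {
  n <- nrow(x); p <- ncol(x)
  mu <- colMeans(x, na.rm = TRUE)
  sdv <- apply(x, 2, stats::sd, na.rm = TRUE)
  z <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  out <- x
  for (i in seq_len(n)) for (j in seq_len(p)) {
    if (!is.na(x[i, j])) next
    d <- rep(Inf, n)
    for (r in seq_len(n)) {
      if (r == i || is.na(x[r, j])) next
      sh <- which(!is.na(z[i, ]) & !is.na(z[r, ]))
      if (!length(sh)) next
      d[r] <- sum((z[i, sh] - z[r, sh])^2) * p / length(sh)
    }
    nn <- order(d, seq_len(n))[seq_len(k)]
    out[i, j] <- mean(x[nn, j])
  }
  out
}

# enumerate all set partitions of 1..n via restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(code, mx) {
    k <- length(code) + 1L
    if (k > n) { out[[length(out) + 1L]] <<- code; return() }
    for (c in seq_len(mx + 1L)) rec(c(code, c), max(mx, c))
  }
  rec(integer(), 0L)
  out
}

# direct double-loop evaluation of the partition functional
functional_oracle <- function(A, membership, a) {
  n <- ncol(A)
  total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (membership[i] == membership[j]) total <- total + A[i, j] - a
  total
}

# exhaustive maximum of the functional over every partition of the matrix
exhaustive_partition_max <- function(A, a) {
  parts <- all_partitions(ncol(A))
  best <- -Inf
  for (m in parts) {
    f <- functional_oracle(A, m, a)
    if (f > best) best <- f
  }
  best
}

# Mann-Whitney oracle: U by explicit pair counting, exact p by enumeration
mw_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  U <- 0
  for (xi in x) for (yj in y) U <- U + (xi > yj) + 0.5 * (xi == yj)
  pooled <- c(x, y)
  combos <- utils::combn(n1 + n2, n1)
  mu <- n1 * n2 / 2
  Us <- apply(combos, 2, function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    u <- 0
    for (xi in xs) for (yj in ys) u <- u + (xi > yj) + 0.5 * (xi == yj)
    u
  })
  list(U = U, p = mean(abs(Us - mu) >= abs(U - mu) - 1e-9))
}
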