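# Criteria function: correlation estimation, the quadratic form, the
# branch-and-bound subset search, and CF dynamics.

test_that("correlation estimation matches the textbook Pearson formula", {
  x <- cbind(a = c(1, 2, 4, 5, 9), b = c(2, 1, 5, 4, 8), c = c(9, 7, 5, 1, 2))
  S <- estimate_correlation(x)$S
  pearson <- function(u, v)
    sum((u - mean(u)) * (v - mean(v))) /
      sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  expect_equal(S["a", "b"], pearson(x[, "a"], x[, "b"]), tolerance = 1e-12)
  expect_equal(S["a", "c"], pearson(x[, "a"], x[, "c"]), tolerance = 1e-12)
  expect_equal(diag(S), c(a = 1, b = 1, c = 1))
})

test_that("perfectly correlated columns are regularized before inversion", {
  x <- cbind(a = 1:20 + 0, b = 2 * (1:20) + 5)
  S <- estimate_correlation(x)
  expect_equal(S$S[1, 2], 1, tolerance = 1e-6)
  expect_gt(S$lambda, 0)
  expect_true(all(is.finite(compute_cf(c(1, 1), S))))
  expect_error(estimate_correlation(cbind(a = rep(1, 10), b = rnorm(10))),
               "constant column.*a")
})

test_that("independent large-sample columns give a near-identity correlation", {
  set.seed(8)
  x <- matrix(rnorm(10000 * 5), ncol = 5)
  S <- estimate_correlation(x)$S
  expect_lt(max(abs(S[upper.tri(S)])), 0.05)
})

test_that("the quadratic form reduces to known closed forms", {
  expect_equal(compute_cf(c(1, 2), diag(2)), 5)
  expect_equal(compute_cf(3, matrix(1)), 9)
  # 3x3 equicorrelated with r = 0.5 and x = (1,1,1): row sums of S are 2,
  # so S^{-1} x = x/2 and the form is 3/2; cross-check by linear solve
  S <- matrix(0.5, 3, 3); diag(S) <- 1
  x <- c(1, 1, 1)
  expect_equal(compute_cf(x, S), 1.5)
  expect_equal(compute_cf(x, S), sum(x * solve(S, x)), tolerance = 1e-12)
  expect_error(compute_cf(c(1, 2, 3), diag(2)), "dimension mismatch")
})

test_that("with identity correlation the CF is the squared Euclidean norm", {
  set.seed(4)
  for (rep in 1:5) {
    x <- rnorm(6)
    expect_equal(compute_cf(x, diag(6)), sum(x^2), tolerance = 1e-12)
  }
})

test_that("CF is monotone under subset nesting", {
  set.seed(12)
  C <- block_cor(rep(1:2, each = 4), 0.6, 0.2)
  S <- estimate_correlation(rmvn(200, C))
  for (rep in 1:20) {
    x <- rnorm(8)
    a <- sort(sample(8, sample(1:7, 1)))
    rest <- setdiff(1:8, a)
    extra <- rest[sample.int(length(rest), 1)]
    b <- sort(c(a, extra))
    expect_lte(compute_cf(x[a], S$S[a, a, drop = FALSE]),
               compute_cf(x[b], S$S[b, b, drop = FALSE]) + 1e-10)
  }
})

test_that("branch-and-bound equals exhaustive enumeration", {
  set.seed(17)
  for (rep in 1:8) {
    n <- sample(8:12, 1); m <- sample(2:6, 1)
    C <- block_cor(sample(1:3, n, replace = TRUE), 0.6, 0.1)
    S <- estimate_correlation(rmvn(300, C))$S
    X <- rmvn(40, C, mu = rnorm(1))
    bb <- best_subset_cf(X, S, m)
    M <- crossprod(X) / nrow(X)
    combos <- utils::combn(n, m)
    vals <- apply(combos, 2, function(idx)
      sum(solve(S[idx, idx]) * M[idx, idx]))
    expect_equal(bb$objective, max(vals), tolerance = 1e-9)
    expect_equal(bb$index, sort(combos[, which.max(vals)]))
  }
})

test_that("the optimal mean CF profile is non-decreasing in subset size", {
  set.seed(19)
  C <- block_cor(rep(1:2, each = 5), 0.6, 0.1)
  S <- estimate_correlation(rmvn(300, C))$S
  X <- rmvn(30, C, mu = 0.5)
  prof <- cf_subset_profile(X, S, m_values = c(1, 3, 5, 7, 10))
  expect_true(all(diff(prof$objective) > -1e-9))
  expect_equal(best_subset_cf(X, S, 10)$index, 1:10)   # m = n keeps everything
  expect_error(best_subset_cf(X, S, 11), "infeasible")
})

test_that("the expected CF of in-distribution vectors is close to the dimension", {
  set.seed(23)
  C <- block_cor(rep(1:2, each = 3), 0.5, 0.1)
  S <- estimate_correlation(rmvn(10000, C))
  X <- rmvn(10000, C)
  y <- backsolve(S$chol, t(X), transpose = TRUE)
  expect_equal(mean(colSums(y^2)), 6, tolerance = 0.05 * 6)
})

test_that("CF dynamics are permutation-invariant and duplicate patients agree", {
  co <- generate_cohort(small_config(missing_rate = 0, seed = 21))
  cf <- cf_dynamics(co)
  perm <- sample(nrow(co$values))
  co2 <- co
  co2$values <- co$values[perm, , ]
  co2$truth <- co$truth[perm, , ]
  co2$group <- co$group[perm]
  cf2 <- cf_dynamics(co2)
  expect_equal(cf2$summary, cf$summary, tolerance = 1e-9)
  # duplicated patients receive identical CF values
  co3 <- co
  co3$values[2, , ] <- co3$values[1, , ]
  cf3 <- cf_dynamics(co3)
  d <- cf3$cf[cf3$cf$group != "overall", ]
  p1 <- d$cf[d$patient_id == rownames(co3$values)[1]]
  p2 <- d$cf[d$patient_id == rownames(co3$values)[2]]
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("baseline-referenced CF separates groups 1 and 2 on the default cohort", {
  co <- impute_cohort(generate_cohort(cohort_config(seed = 11)))
  cf <- cf_dynamics(co)
  cmp <- comparison_suite(cf)
  p <- cmp$p_value[cmp$comparison == "group 1 vs group 2"]
  expect_lt(p, 0.05)
  # group 2 departs further from baseline than group 1 at the final point
  s <- cf$summary
  expect_gt(s$mean_cf[s$group == "2" & s$timepoint == 6],
            s$mean_cf[s$group == "1" & s$timepoint == 6])
})

test_that("cell-referenced CF is centred near the parameter count everywhere", {
  co <- generate_cohort(cohort_config(n_patients = c(200L, 200L, 200L),
                                      missing_rate = 0, seed = 31))
  cf <- cf_dynamics(co, reference = "cell")
  expect_true(all(abs(cf$summary$mean_cf - 21) < 2))
})
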