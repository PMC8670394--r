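# Synthetic ABS-like cohorts.
#
# Emulates the statistical structure the downstream analyses assume: three
# patient groups measured on 21 continuous parameters at six time points,
# with a planted block-correlation structure among parameters, group- and
# time-dependent mean shifts and correlation perturbations, within-patient
# persistence across time points, and a missing-not-at-random mask whose
# missingness probability grows with the magnitude of the (unobserved)
# standardized value.

#' Configuration of a synthetic ABS-like cohort
#'
#' Defaults encode the study conditions the package emulates: 391 patients in
#' three near-equal groups, six time points, the 21 ABS parameters in four
#' planted correlation blocks (within-block correlation 0.7, cross-block
#' 0.1), and roughly 10% missing values generated not-at-random.  The
#' group/time schedule perturbs means and correlations so that groups 1 and 2
#' change most between time points 5 and 6, group 2 twice as strongly as
#' group 1, and group 3 stays near-constant.
#'
#' @param n_patients integer vector of per-group patient counts.
#' @param n_timepoints number of measurement points per patient.
#' @param parameters parameter names; defaults to [abs_parameter_names()].
#' @param block_sizes sizes of the planted parameter blocks (must sum to the
#'   number of parameters).
#' @param rho_in,rho_out baseline within-block and cross-block correlation;
#'   requires `rho_out < rho_in <= 1`.
#' @param group_amplitude per-group amplitude of the mean-shift schedule.
#' @param time_profile per-time-point perturbation profile (0 at baseline,
#'   largest at the final point).
#' @param shift_scale mean shift, in within-group standard deviations, per
#'   unit of `group_amplitude * time_profile`.
#' @param within_drop per-group total drop of the within-block correlation
#'   at full perturbation (`time_profile = 1`).
#' @param cross_rise per-group total rise of the cross-block correlation at
#'   full perturbation; must keep `rho_out + rise < rho_in - drop` so the
#'   block structure never inverts.
#' @param missing_rate target marginal missingness probability; 0 disables
#'   the mask.
#' @param mnar_coef log-odds increase of missingness per standard deviation
#'   of absolute standardized value (0 = missing completely at random).
#' @param ar_phi latent first-order autoregressive coefficient tying a
#'   patient's consecutive time points together (unit marginal variance is
#'   preserved).
#' @param tails_df degrees of freedom for heavier-tailed (multivariate-t
#'   style) draws; `Inf` keeps the Gaussian default.
#' @param seed integer seed; every draw is reproducible from it.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = c(131L, 130L, 130L),
                          n_timepoints = 6L,
                          parameters = abs_parameter_names(),
                          block_sizes = c(6L, 5L, 5L, 5L),
                          rho_in = 0.7, rho_out = 0.1,
                          group_amplitude = c(0.2, 0.5, 0.04),
                          time_profile = c(0, 0.10, 0.15, 0.12, 0.18, 1.0),
                          shift_scale = 5,
                          within_drop = c(0.18, 0.36, 0.015),
                          cross_rise = c(0.03, 0.16, 0.005),
                          missing_rate = 0.10,
                          mnar_coef = 1.0,
                          ar_phi = 0.5,
                          tails_df = Inf,
                          seed = 1L) {
  stopifnot(length(n_patients) == length(group_amplitude),
            length(within_drop) == length(n_patients),
            length(cross_rise) == length(n_patients),
            all(n_patients >= 1), n_timepoints >= 1,
            sum(block_sizes) == length(parameters),
            rho_out < rho_in, rho_in <= 1,
            all(rho_out + cross_rise * max(time_profile) <
                rho_in - within_drop * max(time_profile)),
            missing_rate >= 0, missing_rate <= 1,
            abs(ar_phi) < 1,
            length(time_profile) == n_timepoints)
  structure(list(
    n_patients = as.integer(n_patients), n_timepoints = as.integer(n_timepoints),
    parameters = parameters, block_sizes = as.integer(block_sizes),
    rho_in = rho_in, rho_out = rho_out,
    group_amplitude = group_amplitude, time_profile = time_profile,
    shift_scale = shift_scale, within_drop = within_drop, cross_rise = cross_rise,
    missing_rate = missing_rate, mnar_coef = mnar_coef,
    ar_phi = ar_phi, tails_df = tails_df, seed = as.integer(seed)),
    class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<cohort_config> %d patients (%s) x %d parameters x %d time points\n",
    "  blocks %s, rho_in %.2f, rho_out %.2f, missing %.0f%% (MNAR coef %.1f), seed %d\n"),
    sum(x$n_patients), paste(x$n_patients, collapse = "/"),
    length(x$parameters), x$n_timepoints,
    paste(x$block_sizes, collapse = "+"), x$rho_in, x$rho_out,
    100 * x$missing_rate, x$mnar_coef, x$seed))
  invisible(x)
}

#' Planted ground truth of a cohort configuration
#'
#' Returns the planted parameter partition and the full group/time schedule
#' implied by a configuration.  Depends only on the configuration, never on
#' the random seed, so recovery tests can compare against it directly.
#'
#' @param config a [cohort_config()].
#' @return a list with `membership` (integer block id per parameter),
#'   `blocks` (list of parameter-name vectors), and `schedule` (matrices
#'   `mean_shift`, `rho_in`, `rho_out`, each groups x time points).
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  membership <- rep(seq_along(config$block_sizes), config$block_sizes)
  names(membership) <- config$parameters
  blocks <- split(config$parameters, membership)
  names(blocks) <- paste0("block", seq_along(blocks))
  G <- length(config$n_patients); Tn <- config$n_timepoints
  sched <- list(
    mean_shift = config$shift_scale * outer(config$group_amplitude, config$time_profile),
    rho_in = config$rho_in - outer(config$within_drop, config$time_profile),
    rho_out = config$rho_out + outer(config$cross_rise, config$time_profile))
  dimnames(sched$mean_shift) <- dimnames(sched$rho_in) <- dimnames(sched$rho_out) <-
    list(group = seq_len(G), timepoint = seq_len(Tn))
  list(membership = membership, blocks = blocks, schedule = sched)
}

# block correlation matrix with given within/cross correlations
.block_cor <- function(membership, r_in, r_out) {
  same <- outer(membership, membership, "==")
  C <- ifelse(same, r_in, r_out)
  diag(C) <- 1
  C
}

#' Generate a synthetic ABS-like cohort
#'
#' Per group and time point, patient vectors are drawn from a multivariate
#' normal with the planted block-correlation matrix and the scheduled mean
#' shift; consecutive time points of one patient are tied by a latent AR(1)
#' process with unit marginal variance.  The missing-not-at-random mask makes
#' an entry's missingness log-odds increase with its absolute standardized
#' value.
#'
#' @param config a [cohort_config()].
#' @return an object of class `cohort`: a list with `values`
#'   (patients x parameters x time points array, `NA` where masked),
#'   `truth` (the same array before masking), `group` (integer label per
#'   patient, 1-based), and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  pt <- planted_truth(config)
  p <- length(config$parameters); Tn <- config$n_timepoints
  G <- length(config$n_patients); N <- sum(config$n_patients)
  group <- rep(seq_len(G), config$n_patients)
  vals <- array(NA_real_, dim = c(N, p, Tn),
                dimnames = list(patient = paste0("P", seq_len(N)),
                                parameter = config$parameters,
                                timepoint = seq_len(Tn)))
  phi <- config$ar_phi
  for (g in seq_len(G)) {
    rows <- which(group == g); n_g <- length(rows)
    U <- NULL
    for (t in seq_len(Tn)) {
      C <- .block_cor(pt$membership, pt$schedule$rho_in[g, t], pt$schedule$rho_out[g, t])
      L <- tryCatch(chol(C), error = function(e)
        stop(sprintf("implied correlation matrix for group %d, time %d is not positive definite", g, t)))
      Z <- matrix(stats::rnorm(n_g * p), n_g, p)
      if (is.finite(config$tails_df)) {
        w <- sqrt(config$tails_df / stats::rchisq(n_g, df = config$tails_df))
        Z <- Z * w
      }
      W <- Z %*% L
      U <- if (is.null(U)) W else phi * U + sqrt(1 - phi^2) * W
      vals[rows, , t] <- U + pt$schedule$mean_shift[g, t]
    }
  }
  truth <- vals
  if (config$missing_rate > 0) {
    mu <- array(0, dim(vals))
    for (g in seq_len(G))
      mu[group == g, , ] <- rep(pt$schedule$mean_shift[g, ], each = sum(group == g) * p)
    z <- abs(vals - mu)  # unit marginal variance by construction
    lo <- stats::qlogis(config$missing_rate) +
      config$mnar_coef * (z - sqrt(2 / pi))  # centre at E|Z| so the rate holds
    miss <- array(stats::runif(length(vals)) < stats::plogis(lo), dim(vals))
    # keep every patient x time record partially observed (donor rows must exist)
    for (t in seq_len(Tn)) {
      allm <- rowSums(!miss[, , t]) == 0
      if (any(allm)) miss[allm, 1L, t] <- FALSE
    }
    vals[miss] <- NA_real_
  }
  structure(list(values = vals, truth = truth, group = group, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<cohort> %d patients x %d parameters x %d time points; groups %s; %.1f%% missing\n",
              d[1], d[2], d[3], paste(tabulate(x$group), collapse = "/"),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Convert a cohort to long format
#'
#' @param x a `cohort`.
#' @param ... unused.
#' @return `data.frame` with columns `patient_id`, `group`, `timepoint`,
#'   `parameter`, `value` (`NA` for masked entries).
#' @export
as.data.frame.cohort <- function(x, ...) {
  d <- dim(x$values)
  data.frame(
    patient_id = rep(rownames(x$values), times = d[2] * d[3]),
    group = rep(x$group, times = d[2] * d[3]),
    timepoint = rep(rep(seq_len(d[3]), each = d[1] * d[2])),
    parameter = rep(rep(colnames(x$values), each = d[1]), times = d[3]),
    value = as.vector(x$values),
    stringsAsFactors = FALSE)
}

#' Write / read a cohort as long-format CSV
#'
#' Columns `patient_id, group, timepoint, parameter, value`; an empty value
#' cell denotes a missing (masked) measurement.
#'
#' @param cohort a `cohort`.
#' @param path CSV file path.
#' @return `path` invisibly (writer); a `cohort` without ground truth
#'   (reader).
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = "")
  need <- c("patient_id", "group", "timepoint", "parameter", "value")
  if (!all(need %in% names(df)))
    stop("cohort CSV must have columns: ", paste(need, collapse = ", "))
  pats <- unique(df$patient_id)
  pars <- unique(df$parameter)
  tps <- sort(unique(df$timepoint))
  vals <- array(NA_real_, dim = c(length(pats), length(pars), length(tps)),
                dimnames = list(patient = pats, parameter = pars, timepoint = tps))
  idx <- cbind(match(df$patient_id, pats), match(df$parameter, pars),
               match(df$timepoint, tps))
  vals[idx] <- df$value
  group <- df$group[match(pats, df$patient_id)]
  structure(list(values = vals, truth = NULL, group = as.integer(group),
                 config = NULL), class = "cohort")
}
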