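cat3 <- c("positive", "negative", "unable")

#' 3x3 intention-to-diagnose contingency table
#'
#' A paired cross-classification of two categorical test results with the
#' explicit third category "unable to assess", so untestable patients stay in
#' the analysis rather than being silently discarded. Rows are test A,
#' columns test B, category order positive / negative / unable.
#'
#' @param counts 3x3 matrix of non-negative integer counts (rows = test A).
#' @param labels Character pair naming tests A and B.
#' @return A `contingency_3x3`.
#' @examples
#' tab <- contingency_3x3(rbind(c(15, 4, 1), c(6, 20, 1), c(2, 0, 0)),
#'                        labels = c("confrontation", "app"))
#' @export
contingency_3x3 <- function(counts, labels = c("A", "B")) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3, 3))) stop("counts must be 3x3", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) < 1) stop("grand total must be at least 1", call. = FALSE)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(cat3, cat3)
  structure(list(counts = counts, labels = labels), class = "contingency_3x3")
}

#' Cross-tabulate two result columns into a 3x3 table
#'
#' @param data Data frame (e.g. from [simulate_study_cohort()]).
#' @param a,b Column names for tests A (rows) and B (columns); values must be
#'   in `positive` / `negative` / `unable`.
#' @return A [contingency_3x3()].
#' @export
xtab_3x3 <- function(data, a, b) {
  fa <- factor(data[[a]], levels = cat3)
  fb <- factor(data[[b]], levels = cat3)
  if (anyNA(fa) || anyNA(fb)) {
    stop("results must be one of positive/negative/unable", call. = FALSE)
  }
  contingency_3x3(unclass(table(fa, fb)), labels = c(a, b))
}

#' @export
print.contingency_3x3 <- function(x, ...) {
  cat(sprintf("<contingency_3x3> rows: %s, cols: %s\n", x$labels[1], x$labels[2]))
  print(x$counts)
  invisible(x)
}

#' Complete-case reduction of a 3x3 table
#'
#' Drops the unable-to-assess row and column, leaving the 2x2 core of
#' patients with a usable result from both tests.
#'
#' @param table A [contingency_3x3()].
#' @return List with `core` (2x2 matrix) and `n_useable`.
#' @examples
#' tab <- contingency_3x3(rbind(c(15, 4, 1), c(6, 20, 1), c(2, 0, 0)))
#' complete_case_2x2(tab)$n_useable # 45
#' @export
complete_case_2x2 <- function(table) {
  stopifnot(inherits(table, "contingency_3x3"))
  core <- table$counts[1:2, 1:2]
  if (sum(core) == 0) {
    stop("degenerate table: no patient has a usable result on both tests",
         call. = FALSE)
  }
  list(core = core, n_useable = sum(core))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Obtained by inverting the binomial tail probabilities, computed through
#' the beta-quantile formulation: the lower limit is
#' `qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`) and the upper limit
#' `qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`).
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param level Confidence level.
#' @return Numeric `c(lo, hi)`.
#' @examples
#' exact_binomial_ci(15, 21) # c(0.478, 0.891) to 3 d.p.
#' @export
exact_binomial_ci <- function(x, n, level = 0.95) {
  if (length(x) != 1 || length(n) != 1 || n < 1 || x < 0 || x > n ||
      x != round(x) || n != round(n)) {
    stop("need integers 0 <= x <= n with n >= 1", call. = FALSE)
  }
  alpha <- 1 - level
  lo <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lo, hi)
}

proportion_estimate <- function(x, n, level) {
  if (n == 0) {
    return(list(numerator = x, denominator = n, estimate = NA_real_,
                ci_lo = NA_real_, ci_hi = NA_real_))
  }
  ci <- exact_binomial_ci(x, n, level)
  list(numerator = x, denominator = n, estimate = x / n,
       ci_lo = ci[1], ci_hi = ci[2])
}

#' Accuracy measures from a 2x2 core
#'
#' Sensitivity, specificity, PPV and NPV with exact binomial intervals. The
#' reference axis states which test is treated as the reference standard:
#' with `"columns"`, sensitivity is both-positive over the column-positive
#' total (and the axis choice swaps the roles symmetrically, so
#' `accuracy_measures(t(core), "rows")` is identical). A metric whose
#' denominator is zero is reported as undefined (`NA`), never as 0. The
#' returned object always carries its convention record, because a silently
#' transposed table yields plausible-looking but wrong values.
#'
#' @param core 2x2 matrix, rows and columns ordered positive then negative.
#' @param reference_axis `"columns"` or `"rows"`.
#' @param level Confidence level for the intervals.
#' @param n_useable Optional usable-data total to carry in the result.
#' @param policy Untestable-handling label to record (set by
#'   [itd_measures()]).
#' @return An `accuracy_estimates` object.
#' @examples
#' core <- rbind(c(15, 4), c(6, 20))
#' accuracy_measures(core, "columns")
#' @export
accuracy_measures <- function(core, reference_axis = c("columns", "rows"),
                              level = 0.95, n_useable = sum(core),
                              policy = "complete-case") {
  reference_axis <- match.arg(reference_axis)
  core <- as.matrix(core)
  stopifnot(all(dim(core) == c(2, 2)), all(core >= 0))
  a <- core[1, 1]; b <- core[1, 2]; c_ <- core[2, 1]; d <- core[2, 2]
  if (reference_axis == "columns") {
    sens <- proportion_estimate(a, a + c_, level)
    spec <- proportion_estimate(d, b + d, level)
    ppv <- proportion_estimate(a, a + b, level)
    npv <- proportion_estimate(d, c_ + d, level)
  } else {
    sens <- proportion_estimate(a, a + b, level)
    spec <- proportion_estimate(d, c_ + d, level)
    ppv <- proportion_estimate(a, a + c_, level)
    npv <- proportion_estimate(d, b + d, level)
  }
  structure(list(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
                 n_useable = n_useable,
                 convention = list(reference_axis = reference_axis,
                                   untestable_policy = policy,
                                   ci_method = "clopper-pearson",
                                   level = level)),
            class = "accuracy_estimates")
}

#' @export
print.accuracy_estimates <- function(x, ...) {
  fmt <- function(m) {
    if (is.na(m$estimate)) return("undefined (zero denominator)")
    sprintf("%.2f (%.2f-%.2f)  [%d/%d]", round2(m$estimate),
            round2(m$ci_lo), round2(m$ci_hi), m$numerator, m$denominator)
  }
  cat(sprintf("<accuracy_estimates> n useable = %d, reference = %s, policy = %s\n",
              x$n_useable, x$convention$reference_axis,
              x$convention$untestable_policy))
  cat("  sensitivity:", fmt(x$sensitivity), "\n")
  cat("  specificity:", fmt(x$specificity), "\n")
  cat("  PPV:        ", fmt(x$ppv), "\n")
  cat("  NPV:        ", fmt(x$npv), "\n")
  invisible(x)
}

# display rounding: half-up at 2 d.p. (computation stays full precision)
round2 <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Intention-to-diagnose accuracy measures from a 3x3 table
#'
#' Complete-case policy drops the unable row and column before computing the
#' measures. Untestable-as-incorrect keeps reference-testable patients and
#' scores an unable *index* result against them: a false negative when the
#' reference is positive and a false positive when it is negative; patients
#' with an unable reference result are excluded under either policy.
#'
#' @param table A [contingency_3x3()].
#' @param reference_axis `"columns"` or `"rows"` — which test is the
#'   reference standard.
#' @param policy `"complete-case"` or `"untestable-as-incorrect"`.
#' @param level Confidence level.
#' @return An `accuracy_estimates` object (with its convention record).
#' @export
itd_measures <- function(table, reference_axis = c("columns", "rows"),
                         policy = c("complete-case", "untestable-as-incorrect"),
                         level = 0.95) {
  stopifnot(inherits(table, "contingency_3x3"))
  reference_axis <- match.arg(reference_axis)
  policy <- match.arg(policy)
  cc <- complete_case_2x2(table)
  if (policy == "complete-case") {
    return(accuracy_measures(cc$core, reference_axis, level,
                             n_useable = cc$n_useable, policy = policy))
  }
  m <- table$counts
  if (reference_axis == "rows") {
    # reference = rows; index = columns; column "unable" folds into the
    # incorrect index call for each reference-testable row
    core <- rbind(c(m[1, 1], m[1, 2] + m[1, 3]),
                  c(m[2, 1] + m[2, 3], m[2, 2]))
    sens <- proportion_estimate(m[1, 1], sum(m[1, ]), level)
    spec <- proportion_estimate(m[2, 2], sum(m[2, ]), level)
    ppv <- proportion_estimate(m[1, 1], m[1, 1] + m[2, 1] + m[2, 3], level)
    npv <- proportion_estimate(m[2, 2], m[2, 2] + m[1, 2] + m[1, 3], level)
    n_use <- sum(m[1:2, ])
  } else {
    sens <- proportion_estimate(m[1, 1], sum(m[, 1]), level)
    spec <- proportion_estimate(m[2, 2], sum(m[, 2]), level)
    ppv <- proportion_estimate(m[1, 1], m[1, 1] + m[1, 2] + m[3, 2], level)
    npv <- proportion_estimate(m[2, 2], m[2, 2] + m[2, 1] + m[3, 1], level)
    n_use <- sum(m[, 1:2])
  }
  structure(list(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
                 n_useable = n_use,
                 convention = list(reference_axis = reference_axis,
                                   untestable_policy = policy,
                                   ci_method = "clopper-pearson",
                                   level = level)),
            class = "accuracy_estimates")
}

#' Sample size for a paired comparison of two sensitivities
#'
#' McNemar-style calculation for a paired design in which both tests are
#' applied to every diseased subject. With discordant-pair probability `psi`
#' (defaulting to the independence value `p0 (1 - p1) + p1 (1 - p0)`) and
#' difference `delta = |p1 - p0|`, the required number of paired subjects is
#'
#' `n = (z_{1-alpha/2} sqrt(psi) + z_{power} sqrt(psi - delta^2))^2 / delta^2`
#'
#' rounded up. `n` counts subjects contributing a paired result (for a
#' sensitivity comparison, subjects with the condition).
#'
#' @param p0,p1 The two sensitivities to distinguish.
#' @param alpha Two-sided type-I error.
#' @param power Target power (1 - beta).
#' @param psi Optional discordance probability override.
#' @return Integer sample size.
#' @examples
#' paired_sensitivity_sample_size(0.5, 0.7)
#' @export
paired_sensitivity_sample_size <- function(p0, p1, alpha = 0.05, power = 0.8,
                                           psi = NULL) {
  stopifnot(p0 > 0, p0 < 1, p1 > 0, p1 < 1)
  if (p0 == p1) stop("sample size undefined for p0 == p1", call. = FALSE)
  delta <- abs(p1 - p0)
  if (is.null(psi)) psi <- p0 * (1 - p1) + p1 * (1 - p0)
  stopifnot(psi >= delta, psi <= 1)
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  ceiling((za * sqrt(psi) + zb * sqrt(psi - delta^2))^2 / delta^2)
}

#' Read / write the 3x3 contingency CSV dialect
#'
#' A 3x3 table is stored with a header row and a leading label column, rows
#' and columns in the fixed order positive / negative / unable.
#'
#' @param path File path.
#' @param labels Test names (A = rows, B = columns) for [contingency_3x3()].
#' @return A [contingency_3x3()].
#' @export
read_contingency_csv <- function(path, labels = c("A", "B")) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  contingency_3x3(as.matrix(df), labels = labels)
}

#' @rdname read_contingency_csv
#' @param table A [contingency_3x3()] to write.
#' @export
write_contingency_csv <- function(table, path) {
  stopifnot(inherits(table, "contingency_3x3"))
  utils::write.csv(as.data.frame(table$counts), path, row.names = TRUE)
  invisible(path)
}

#' Format accuracy estimates as a one-row text table
#'
#' Mirrors the usual accuracy-table layout: usable n, then each metric as
#' `estimate (lo-hi)` rounded half-up to 2 d.p.
#'
#' @param est An `accuracy_estimates`.
#' @param comparison Optional "A versus B" label.
#' @return A single character string.
#' @export
format_accuracy_row <- function(est, comparison = NULL) {
  stopifnot(inherits(est, "accuracy_estimates"))
  f <- function(m) {
    if (is.na(m$estimate)) return("NA")
    sprintf("%.2f (%.2f-%.2f)", round2(m$estimate), round2(m$ci_lo),
            round2(m$ci_hi))
  }
  paste(c(comparison, est$n_useable, f(est$sensitivity), f(est$specificity),
          f(est$ppv), f(est$npv)), collapse = "\t")
}
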