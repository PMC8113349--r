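# Shared test-result container -------------------------------------------

new_test_result <- function(statistic, p_value, method, tails = "two",
                            n_resamples = NA_integer_, seed = NA_integer_,
                            extra = list()) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(
    c(list(statistic = unname(statistic), p_value = unname(p_value),
           method = method, tails = tails,
           n_resamples = n_resamples, seed = seed),
      extra),
    class = "dd_test")
}

#' @exportS3Method base::print
print.dd_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.6g, p = %.4g (%s-sided)\n",
              x$statistic, x$p_value, x$tails))
  if (!is.na(x$n_resamples))
    cat(sprintf("  resamples = %d\n", x$n_resamples))
  invisible(x)
}

#' Serialize a test result to JSON
#'
#' @param x A `dd_test` object.
#' @param ... Passed to [jsonlite::toJSON()].
#' @return A JSON string with method, statistic, p-value, number of
#'   resamples and seed.
#' @export
test_result_json <- function(x, ...) {
  stopifnot(inherits(x, "dd_test"))
  jsonlite::toJSON(
    list(method = x$method, statistic = x$statistic, p = x$p_value,
         tails = x$tails, n_resamples = x$n_resamples, seed = x$seed),
    auto_unbox = TRUE, digits = NA, ...)
}

# Bootstrap across units --------------------------------------------------

#' Bootstrap significance of a summary statistic across units
#'
#' Resamples experimental units (animals, sessions, ...) with replacement
#' and computes a two-sided p-value from the sign distribution of the
#' resampled statistic: the fraction of bootstrap statistics at or beyond
#' zero on either side, doubled and capped at 1.  This is the test used to
#' compare, e.g., response times between the shortest and longest delays
#' across mice.
#'
#' @param values Numeric vector, one value per unit (typically paired
#'   differences), or a list of per-unit values that `statistic` reduces.
#' @param statistic Function mapping a resampled set of units to a scalar.
#'   Default is the mean.
#' @param n Number of bootstrap resamples.
#' @param seed Optional integer seed for reproducibility.
#' @return A `dd_test` with the observed statistic and bootstrap p-value.
#'   Resamples on which the statistic is undefined (NA/NaN) are redrawn and
#'   counted in `$n_redrawn`.
#' @export
bootstrap_p <- function(values, statistic = mean, n = 5000, seed = NULL) {
  if (length(values) < 2L) stop("bootstrap_p() needs at least 2 units")
  if (!is.null(seed)) set.seed(seed)
  obs <- statistic(values)
  stats_boot <- numeric(n)
  n_redrawn <- 0L
  for (i in seq_len(n)) {
    repeat {
      s <- statistic(values[sample.int(length(values), replace = TRUE)])
      if (is.finite(s)) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 100L * n) stop("statistic undefined on nearly all resamples")
    }
    stats_boot[i] <- s
  }
  # add-one smoothing keeps p >= 1/(n+1)
  p_lo <- (sum(stats_boot <= 0) + 1) / (n + 1)
  p_hi <- (sum(stats_boot >= 0) + 1) / (n + 1)
  p <- min(1, 2 * min(p_lo, p_hi))
  new_test_result(obs, p, "bootstrap across units", "two", n,
                  if (is.null(seed)) NA_integer_ else seed,
                  extra = list(boot_stats = stats_boot, n_redrawn = n_redrawn))
}

# Two-sample permutation test ---------------------------------------------

#' Two-sample permutation test
#'
#' Shuffles group labels and reports the two-sided p-value for a group
#' statistic (mean difference by default), with add-one smoothing
#' ((k+1)/(n+1)) so p is never exactly zero.  When the number of distinct
#' label assignments is small the full enumeration is used instead and the
#' p-value is exact.
#'
#' @param a,b Numeric vectors for the two groups.
#' @param statistic Function of `(a, b)` returning a scalar; default mean
#'   difference `mean(a) - mean(b)`.
#' @param n Number of random shuffles.
#' @param seed Optional integer seed.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exhaustive enumeration;
#'   default `NULL` enumerates when there are at most 200 assignments.
#' @return A `dd_test`.
#' @export
permutation_p <- function(a, b, statistic = function(a, b) mean(a) - mean(b),
                          n = 5000, seed = NULL, exact = NULL) {
  if (length(a) < 1L || length(b) < 1L)
    stop("permutation_p() needs both groups non-empty")
  pooled <- c(a, b)
  na <- length(a)
  obs <- statistic(a, b)
  n_splits <- choose(length(pooled), na)
  if (is.null(exact)) exact <- n_splits <= 200
  if (exact) {
    idx <- utils::combn(length(pooled), na)
    stats_perm <- apply(idx, 2, function(i)
      statistic(pooled[i], pooled[-i]))
    p <- mean(abs(stats_perm) >= abs(obs) - 1e-12)
    n_used <- ncol(idx)
    method <- "exact permutation test (full enumeration)"
  } else {
    if (!is.null(seed)) set.seed(seed)
    stats_perm <- replicate(n, {
      i <- sample.int(length(pooled), na)
      statistic(pooled[i], pooled[-i])
    })
    p <- (sum(abs(stats_perm) >= abs(obs) - 1e-12) + 1) / (n + 1)
    n_used <- n
    method <- "permutation test (label shuffle)"
  }
  new_test_result(obs, p, method, "two", n_used,
                  if (is.null(seed)) NA_integer_ else seed,
                  extra = list(perm_stats = stats_perm))
}

# Pearson chi-squared on a 2x2 table --------------------------------------

#' Pearson chi-squared test for a 2x2 contingency table
#'
#' Continuity correction is off by default; the statistic then equals the
#' closed form n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)).
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return A `dd_test` with the chi-squared statistic (df = 1).
#' @export
chi_squared_2x2 <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all table margins must be positive")
  ct <- stats::chisq.test(tab, correct = correct)
  new_test_result(ct$statistic, ct$p.value,
                  paste0("Pearson chi-squared (2x2",
                         if (correct) ", continuity-corrected" else "", ")"),
                  "two", extra = list(df = unname(ct$parameter), table = tab))
}

# Repeated-measures two-way ANOVA -----------------------------------------

#' Repeated-measures two-way ANOVA on subject-level cell means
#'
#' Fully within-subject design: every subject contributes one value per
#' factor-A x factor-B cell (e.g., per-session error-rate increase for
#' easy/hard x short/long-delay trials).  Each effect is tested against
#' its own effect-by-subject interaction stratum.
#'
#' @param data Data frame with columns `subject`, `A`, `B`, `value`
#'   (alternative column names can be given via `cols`).
#' @param cols Named character vector mapping the roles
#'   `c(subject=, A=, B=, value=)` onto columns of `data`.
#' @return A list of `dd_test` objects for the two main effects and the
#'   interaction, plus the underlying `aov` summary.
#' @export
rm_anova2 <- function(data, cols = c(subject = "subject", A = "A",
                                     B = "B", value = "value")) {
  d <- data.frame(subject = factor(data[[cols[["subject"]]]]),
                  A = factor(data[[cols[["A"]]]]),
                  B = factor(data[[cols[["B"]]]]),
                  value = as.numeric(data[[cols[["value"]]]]))
  if (anyNA(d$value)) stop("missing cell values are not allowed")
  counts <- table(d$subject, d$A, d$B)
  if (any(counts != 1L))
    stop("design must be complete and balanced: one value per subject x A x B cell")
  fit <- stats::aov(value ~ A * B + Error(subject / (A * B)), data = d)
  sm <- summary(fit)
  pull <- function(stratum, term) {
    tabs <- sm[[stratum]][[1]]
    row <- trimws(rownames(tabs)) == term
    list(F = tabs[row, "F value"], p = tabs[row, "Pr(>F)"],
         df = tabs[row, "Df"])
  }
  eff <- list(A = pull("Error: subject:A", "A"),
              B = pull("Error: subject:B", "B"),
              `A:B` = pull("Error: subject:A:B", "A:B"))
  out <- lapply(names(eff), function(nm) {
    e <- eff[[nm]]
    new_test_result(e$F, e$p,
                    sprintf("repeated-measures two-way ANOVA, effect %s", nm),
                    "two", extra = list(df = e$df))
  })
  names(out) <- names(eff)
  out$aov_summary <- sm
  out
}
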