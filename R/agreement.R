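# Two-device agreement battery: Shapiro-Wilk gated paired location tests
# (paired t / Wilcoxon signed-rank) and the single-measure,
# absolute-agreement intraclass correlation ICC(A,1) from a two-way ANOVA,
# with its F test against 0 and McGraw-Wong 95% confidence interval.

#' Paired measurements of one parameter from two devices
#'
#' @param label Parameter name, e.g. `"left knee IC"`.
#' @param a,b Numeric vectors of the same parameter measured by device A
#'   and device B on the same jumps, in the same order.
#' @param jump_id Optional pairing keys (unique); defaults to sequence
#'   numbers.
#' @return Object of class `paired_measurements`.
#' @export
paired_measurements <- function(label, a, b, jump_id = NULL) {
  if (length(a) != length(b))
    abort_validation("device A and B vectors must have equal length")
  if (length(a) < 3)
    abort_parameter("at least 3 paired observations required")
  if (anyNA(a) || anyNA(b))
    abort_validation("paired measurements must not contain missing values")
  if (is.null(jump_id)) jump_id <- seq_along(a)
  if (anyDuplicated(jump_id)) abort_validation("jump_id keys must be unique")
  structure(list(label = label, a = as.numeric(a), b = as.numeric(b),
                 jump_id = jump_id),
            class = "paired_measurements")
}

#' @export
print.paired_measurements <- function(x, ...) {
  cat(sprintf("<paired_measurements> %s: n = %d\n", x$label, length(x$a)))
  invisible(x)
}

#' Normality-gated choice of paired location test
#'
#' Runs the Shapiro-Wilk test on each device's sample. The paired t-test
#' is selected only when both samples are consistent with normality
#' (p >= alpha for both); otherwise the Wilcoxon signed-rank test.
#'
#' @param pm A [paired_measurements()] object.
#' @param alpha Normality significance level (default 0.05).
#' @return `"paired_t"` or `"wilcoxon"`, with attributes `shapiro_a` and
#'   `shapiro_b` carrying the two `htest` results.
#' @export
shapiro_gate <- function(pm, alpha = 0.05) {
  stopifnot(inherits(pm, "paired_measurements"))
  n <- length(pm$a)
  if (n < 3 || n > 5000)
    abort_parameter("Shapiro-Wilk requires 3 <= n <= 5000 (got %d)", n)
  sa <- stats::shapiro.test(pm$a)
  sb <- stats::shapiro.test(pm$b)
  test <- if (sa$p.value >= alpha && sb$p.value >= alpha) "paired_t" else "wilcoxon"
  structure(test, shapiro_a = sa, shapiro_b = sb)
}

#' Paired location test between two devices
#'
#' Two-sided paired t-test or Wilcoxon signed-rank test on device A minus
#' device B. The Wilcoxon variant discards zero differences, mid-ranks
#' ties, and uses the exact null distribution up to n = 25 zero-free,
#' tie-free differences (normal approximation with continuity correction
#' otherwise).
#'
#' @param pm A [paired_measurements()] object.
#' @param test `"paired_t"` or `"wilcoxon"`; typically the output of
#'   [shapiro_gate()].
#' @param alpha Normality level forwarded to [shapiro_gate()] when `test`
#'   is missing.
#' @return Object of class `location_test_result`: a list with
#'   `parameter`, `test_name`, `statistic`, `p_value`, `mean_a`, `sd_a`,
#'   `mean_b`, `sd_b`, `difference` (mean A - mean B), `n`, and the
#'   Shapiro-Wilk `shapiro_w_a/p_a/w_b/p_b` fields.
#' @export
paired_location_test <- function(pm, test = NULL, alpha = 0.05) {
  stopifnot(inherits(pm, "paired_measurements"))
  if (is.null(test) || length(pm$a) <= 5000) {
    gate <- shapiro_gate(pm, alpha = alpha)
    sh <- list(w_a = unname(attr(gate, "shapiro_a")$statistic),
               p_a = attr(gate, "shapiro_a")$p.value,
               w_b = unname(attr(gate, "shapiro_b")$statistic),
               p_b = attr(gate, "shapiro_b")$p.value)
    if (is.null(test)) test <- as.character(gate)
  } else {
    sh <- list(w_a = NA_real_, p_a = NA_real_, w_b = NA_real_, p_b = NA_real_)
  }
  test <- match.arg(test, c("paired_t", "wilcoxon"))
  d <- pm$a - pm$b
  if (test == "paired_t") {
    if (stats::sd(d) <= 1e-10 * max(abs(mean(d)), 1)) {
      # constant differences: t.test refuses; the closed form is 0/0 -> 0
      # for identical samples and +/-Inf for a pure shift
      stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      p <- if (mean(d) == 0) 1 else 0
    } else {
      ht <- stats::t.test(pm$a, pm$b, paired = TRUE)
      stat <- unname(ht$statistic); p <- ht$p.value
    }
  } else {
    nz <- d[d != 0]
    if (length(nz) == 0)
      abort_degenerate("all paired differences are zero: Wilcoxon signed-rank undefined")
    exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
    ht <- suppressWarnings(
      stats::wilcox.test(nz, exact = exact, correct = TRUE))
    stat <- unname(ht$statistic); p <- ht$p.value
  }
  structure(list(
    parameter = pm$label, test_name = test, statistic = stat,
    p_value = p, mean_a = mean(pm$a), sd_a = stats::sd(pm$a),
    mean_b = mean(pm$b), sd_b = stats::sd(pm$b),
    difference = mean(pm$a) - mean(pm$b), n = length(pm$a),
    shapiro_w_a = sh$w_a, shapiro_p_a = sh$p_a,
    shapiro_w_b = sh$w_b, shapiro_p_b = sh$p_b
  ), class = "location_test_result")
}

#' @export
print.location_test_result <- function(x, ...) {
  cat(sprintf("%s: %s, A %.2f +/- %.2f, B %.2f +/- %.2f, diff %.2f, p = %.3g\n",
              x$parameter, x$test_name, x$mean_a, x$sd_a, x$mean_b, x$sd_b,
              x$difference, x$p_value))
  invisible(x)
}

# two-way ANOVA mean squares for an n x k ratings matrix
.anova_ms <- function(x) {
  n <- nrow(x); k <- ncol(x)
  gm <- mean(x)
  ssr <- k * sum((rowMeans(x) - gm)^2)
  ssc <- n * sum((colMeans(x) - gm)^2)
  sse <- sum((x - gm)^2) - ssr - ssc
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Absolute-agreement single-measure intraclass correlation ICC(A,1)
#'
#' The two-way model, absolute-agreement, single-measures ICC (identical
#' point estimate under the mixed and random column-effect models), as
#' implemented by SPSS. Rows are jumps, columns are devices. The F test
#' against a true ICC of 0 uses MSR/MSE with df1 = n - 1 and
#' df2 = (n - 1)(k - 1) and a one-sided p-value; the confidence interval
#' is the McGraw-Wong construction with a Satterthwaite denominator df.
#'
#' @param pm A [paired_measurements()] object (k = 2 devices), or an
#'   n-by-k numeric matrix of ratings.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return Object of class `icc_result`: list with `icc`, `ci_low`,
#'   `ci_high`, `f_value`, `df1`, `df2`, `p_value`, `reliability_class`,
#'   `msr`, `msc`, `mse`, `n`, `k`.
#' @export
icc_a1 <- function(pm, conf_level = 0.95) {
  x <- if (inherits(pm, "paired_measurements")) cbind(pm$a, pm$b) else as.matrix(pm)
  if (!is.numeric(x) || ncol(x) < 2) abort_parameter("need an n-by-k matrix with k >= 2")
  if (nrow(x) < 3) abort_parameter("at least 3 rows (jumps) required")
  ms <- .anova_ms(x)
  n <- ms$n; k <- ms$k
  if (ms$msr < 1e-300 && ms$mse < 1e-300)
    abort_degenerate("zero between-row variance: ICC undefined")
  icc <- (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))
  fv <- ms$msr / ms$mse
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  p <- stats::pf(fv, df1, df2, lower.tail = FALSE)
  # McGraw-Wong CI for ICC(A,1)
  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  if (is.finite(a) && is.finite(b) && (a * ms$msc + b * ms$mse) > 0) {
    v <- (a * ms$msc + b * ms$mse)^2 /
      ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (ms$msr - fl * ms$mse) /
      (fl * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
    hi <- n * (fu * ms$msr - ms$mse) /
      (k * ms$msc + (k * n - k - n) * ms$mse + n * fu * ms$msr)
  } else {
    lo <- NA_real_; hi <- NA_real_
  }
  structure(list(icc = icc, ci_low = lo, ci_high = hi,
                 f_value = fv, df1 = df1, df2 = df2, p_value = p,
                 reliability_class = classify_icc(icc),
                 msr = ms$msr, msc = ms$msc, mse = ms$mse, n = n, k = k),
            class = "icc_result")
}

# consistency-type single-measure ICC(C,1); kept unexported as a
# cross-check that absolute agreement penalizes systematic bias
icc_c1 <- function(pm) {
  x <- if (inherits(pm, "paired_measurements")) cbind(pm$a, pm$b) else as.matrix(pm)
  ms <- .anova_ms(x)
  (ms$msr - ms$mse) / (ms$msr + (ms$k - 1) * ms$mse)
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f [%.3f, %.3f], F(%d, %d) = %.3f, p = %.3g (%s)\n",
              x$icc, x$ci_low, x$ci_high, x$df1, x$df2, x$f_value,
              x$p_value, x$reliability_class))
  invisible(x)
}

#' Classify an ICC value into a reliability band
#'
#' Below 0.5: poor; 0.5 to below 0.75: moderate; 0.75 to below 0.9: good;
#' 0.9 and above: excellent. Band edges belong to the higher band.
#'
#' @param icc Finite ICC value(s).
#' @return Character vector: `"poor"`, `"moderate"`, `"good"` or
#'   `"excellent"`.
#' @export
classify_icc <- function(icc) {
  if (any(!is.finite(icc))) abort_parameter("icc must be finite")
  cut(icc, breaks = c(-Inf, 0.5, 0.75, 0.9, Inf), right = FALSE,
      labels = c("poor", "moderate", "good", "excellent")) |> as.character()
}

#' Agreement report over a set of parameters
#'
#' Builds the two standard report layouts for a collection of paired
#' parameters: per-parameter location tests (means, SDs, difference of
#' means, gated test, p-value) and per-parameter ICC(A,1) results
#' (estimate, 95% CI, F test, reliability class). Values are kept at full
#' precision; rounding happens only when the tables are serialized.
#'
#' @param pms List of [paired_measurements()] objects.
#' @param alpha Normality level for the test gate.
#' @return List of class `dvj_agreement_table` with data frames
#'   `location` (columns `parameter`, `mean_sd_A`, `mean_sd_B`,
#'   `difference`, `test`, `p_value`, plus unrounded numeric columns) and
#'   `icc` (columns `parameter`, `icc`, `ci_low`, `ci_high`, `F`, `df1`,
#'   `df2`, `p_value`, `class`).
#' @export
build_agreement_table <- function(pms, alpha = 0.05) {
  if (length(pms) < 1) abort_parameter("need at least one parameter")
  loc <- lapply(pms, function(pm) {
    r <- paired_location_test(pm, alpha = alpha)
    data.frame(parameter = r$parameter,
               mean_sd_A = sprintf("%.2f ± %.2f", r$mean_a, r$sd_a),
               mean_sd_B = sprintf("%.2f ± %.2f", r$mean_b, r$sd_b),
               difference = r$difference, test = r$test_name,
               p_value = r$p_value,
               mean_A = r$mean_a, sd_A = r$sd_a,
               mean_B = r$mean_b, sd_B = r$sd_b)
  })
  icc <- lapply(pms, function(pm) {
    r <- icc_a1(pm)
    data.frame(parameter = pm$label, icc = r$icc,
               ci_low = r$ci_low, ci_high = r$ci_high,
               F = r$f_value, df1 = r$df1, df2 = r$df2,
               p_value = r$p_value, class = r$reliability_class)
  })
  structure(list(location = do.call(rbind, loc), icc = do.call(rbind, icc)),
            class = "dvj_agreement_table")
}

#' @export
print.dvj_agreement_table <- function(x, ...) {
  cat("Location tests:\n")
  print(x$location[, c("parameter", "mean_sd_A", "mean_sd_B",
                       "difference", "test", "p_value")], row.names = FALSE)
  cat("\nICC(A,1):\n")
  print(x$icc, row.names = FALSE)
  invisible(x)
}

#' Write agreement tables to CSV
#'
#' Serializes the two report layouts with publication-style rounding
#' (2 decimals for angles/differences, 3 for ICCs and p-values).
#'
#' @param tab A [build_agreement_table()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
write_agreement_tables <- function(tab, dir) {
  stopifnot(inherits(tab, "dvj_agreement_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  loc <- tab$location[, c("parameter", "mean_sd_A", "mean_sd_B",
                          "difference", "test", "p_value")]
  loc$difference <- round(loc$difference, 2)
  loc$p_value <- signif(loc$p_value, 3)
  icc <- tab$icc
  for (cn in c("icc", "ci_low", "ci_high", "F")) icc[[cn]] <- round(icc[[cn]], 3)
  icc$p_value <- signif(icc$p_value, 3)
  p1 <- file.path(dir, "location_tests.csv")
  p2 <- file.path(dir, "icc_agreement.csv")
  utils::write.csv(loc, p1, row.names = FALSE)
  utils::write.csv(icc, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
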