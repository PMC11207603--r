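# Sample-size calculators for the three designs used in two-device
# agreement studies: paired t-test, Wilcoxon signed-rank (asymptotic
# relative efficiency method), and the ICC hypothesis test of
# Walter, Eliasziw and Donner.

# power of a two-sided one-sample/paired t-test at effective sample size
# ne (may be fractional) and effect size d, via the noncentral t
.paired_t_power <- function(ne, d, alpha, two_sided = TRUE) {
  df <- ne - 1
  ncp <- d * sqrt(ne)
  if (two_sided) {
    tc <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
  } else {
    tc <- stats::qt(1 - alpha, df)
    1 - stats::pt(tc, df, ncp)
  }
}

.check_power_args <- function(d, alpha, power) {
  if (!is.numeric(d) || d <= 0) abort_parameter("effect size d must be > 0")
  if (alpha <= 0 || alpha >= 1) abort_parameter("alpha must be in (0, 1)")
  if (power <= 0 || power >= 1) abort_parameter("target power must be in (0, 1)")
}

#' Sample size for a paired t-test
#'
#' Smallest n such that a two-sided paired t-test at level `alpha` with
#' noncentrality `d * sqrt(n)` and `n - 1` degrees of freedom reaches the
#' target power, where `d` is Cohen's d for paired differences
#' (mean difference / SD of differences).
#'
#' @param d Effect size (d = 0.5 is the conventional medium effect).
#' @param alpha Significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @param two_sided Two-sided test (default) or one-sided.
#' @return Integer sample size (number of pairs).
#' @export
n_paired_t <- function(d, alpha = 0.05, power = 0.80, two_sided = TRUE) {
  .check_power_args(d, alpha, power)
  for (n in 2:1e6) {
    if (.paired_t_power(n, d, alpha, two_sided) >= power) return(n)
  }
  abort_parameter("target power not reachable with n <= 1e6")
}

.are_table <- c(normal = 3 / pi, uniform = 1, laplace = 1.5, min_are = 0.864)

#' Sample size for the Wilcoxon signed-rank test (ARE method)
#'
#' Converts the paired-t sample-size condition via the asymptotic relative
#' efficiency (ARE) of the signed-rank test under a given parent
#' distribution of the differences: the t-test power condition is
#' evaluated at effective sample size `n * ARE`, and the smallest integer
#' `n` meeting the target power is returned. ARE values: normal 3/pi
#' (0.955), uniform 1, laplace 1.5, and the distribution-free lower bound
#' `min_are` 0.864.
#'
#' @inheritParams n_paired_t
#' @param parent Parent distribution of the paired differences:
#'   `"normal"` (default), `"uniform"`, `"laplace"` or `"min_are"`.
#' @return Integer sample size (number of pairs).
#' @export
n_wilcoxon <- function(d, alpha = 0.05, power = 0.80, parent = "normal",
                       two_sided = TRUE) {
  .check_power_args(d, alpha, power)
  if (!parent %in% names(.are_table))
    abort_parameter("unknown parent '%s' (use %s)", parent,
                    paste(names(.are_table), collapse = ", "))
  are <- .are_table[[parent]]
  for (n in 3:1e6) {
    if (.paired_t_power(n * are, d, alpha, two_sided) >= power) return(n)
  }
  abort_parameter("target power not reachable with n <= 1e6")
}

#' Sample size for detecting an ICC above a null value
#'
#' The Walter-Eliasziw-Donner approximation for testing H0: ICC = rho0
#' against H1: ICC = rho1 with k raters at one-sided level `alpha`:
#' \deqn{n = 1 + \frac{2k(z_{1-\alpha} + z_{1-\beta})^2}{(k-1)(\ln C_0)^2}}
#' with \eqn{C_0 = (1-\rho_1)(1+(k-1)\rho_0) / [(1-\rho_0)(1+(k-1)\rho_1)]},
#' rounded up.
#'
#' @param rho0 Null ICC (e.g. 0).
#' @param rho1 Alternative ICC to detect (must exceed `rho0`).
#' @param k Number of raters/devices (>= 2).
#' @param alpha One-sided significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @return Integer number of subjects.
#' @export
n_icc <- function(rho0, rho1, k = 2, alpha = 0.05, power = 0.80) {
  if (alpha <= 0 || alpha >= 1) abort_parameter("alpha must be in (0, 1)")
  if (power <= 0 || power >= 1) abort_parameter("target power must be in (0, 1)")
  if (k < 2) abort_parameter("k must be >= 2")
  if (!(rho0 > -1 && rho0 < rho1 && rho1 < 1))
    abort_parameter("need -1 < rho0 < rho1 < 1")
  c0 <- (1 - rho1) * (1 + (k - 1) * rho0) /
    ((1 - rho0) * (1 + (k - 1) * rho1))
  za <- stats::qnorm(1 - alpha); zb <- stats::qnorm(power)
  ceiling(1 + 2 * k * (za + zb)^2 / ((k - 1) * log(c0)^2))
}

#' Power/sample-size summary table
#'
#' Convenience wrapper computing the three designs at one setting.
#'
#' @inheritParams n_paired_t
#' @inheritParams n_icc
#' @param parent Parent distribution for the Wilcoxon row.
#' @return Data frame with columns `design` and `n`.
#' @export
power_table <- function(d = 0.5, alpha = 0.05, power = 0.80,
                        parent = "normal", rho0 = 0, rho1 = 0.3, k = 2) {
  data.frame(
    design = c("paired_t", "wilcoxon", "icc"),
    n = c(n_paired_t(d, alpha, power),
          n_wilcoxon(d, alpha, power, parent),
          n_icc(rho0, rho1, k, alpha, power))
  )
}
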