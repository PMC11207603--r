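test_that("paired measurement containers validate their invariants", {
  expect_dvj_error(paired_measurements("p", 1:4, 1:3), "dvj_validation_error")
  expect_dvj_error(paired_measurements("p", 1:2, 1:2), "dvj_parameter_error")
  expect_dvj_error(paired_measurements("p", c(1, NA, 3), 1:3), "dvj_validation_error")
  expect_dvj_error(paired_measurements("p", 1:3, 1:3, jump_id = c(1, 1, 2)),
                   "dvj_validation_error")
})

test_that("the normality gate routes normal pairs to t and skewed pairs to Wilcoxon", {
  set.seed(101)
  a <- rnorm(200, -2, 3); b <- a + rnorm(200, 0.5, 1)
  pm <- paired_measurements("normal", a, b)
  expect_identical(as.character(shapiro_gate(pm)), "paired_t")
  set.seed(102)
  skew <- rexp(200, 0.3) - 5
  pm2 <- paired_measurements("skewed", skew, rnorm(200))
  expect_identical(as.character(shapiro_gate(pm2)), "wilcoxon")
  # the gate requires normality of BOTH devices' samples
  pm3 <- paired_measurements("mixed", rnorm(200), rexp(200))
  expect_identical(as.character(shapiro_gate(pm3)), "wilcoxon")
})

test_that("identical samples give t = 0, p = 1; a constant shift is detected", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 2.8, 3.9, 1.7, 4.1, 3.3)
  pm <- paired_measurements("same", x, x)
  r <- paired_location_test(pm, test = "paired_t")
  expect_equal(r$statistic, 0); expect_equal(r$p_value, 1)
  expect_equal(r$difference, 0)

  set.seed(5)
  b <- rnorm(30, 10, 2)
  pm2 <- paired_measurements("shift", b + 1, b)
  r2 <- paired_location_test(pm2, test = "paired_t")
  expect_equal(r2$difference, 1, tolerance = 1e-12)
  expect_lt(r2$p_value, 1e-6)

  # with non-constant differences the p-value matches the reference
  a3 <- b + 1 + rnorm(30, 0, 0.3)
  pm3 <- paired_measurements("shift+noise", a3, b)
  r4 <- paired_location_test(pm3, test = "paired_t")
  expect_equal(r4$p_value, t.test(a3, b, paired = TRUE)$p.value)
  expect_equal(r4$statistic, unname(t.test(a3, b, paired = TRUE)$statistic))

  r3 <- paired_location_test(pm2, test = "wilcoxon")
  expect_lt(r3$p_value, 1e-4)
  expect_dvj_error(paired_location_test(pm, test = "wilcoxon"),
                   "dvj_degenerate_error")
})

test_that("difference of means is mean A minus mean B at full precision", {
  mk <- function(m) m + c(-1, 0, 1)           # exact mean m
  d <- function(ma, mb)
    paired_location_test(paired_measurements("p", mk(ma), mk(mb)),
                         test = "paired_t")$difference
  expect_equal(round(d(-1.59, -2.10), 2), 0.51)
  expect_equal(round(d(-2.00, -3.12), 2), 1.12)
  expect_equal(round(d(-4.22, -4.68), 2), 0.46)
})

test_that("identical columns give ICC = 1; a constant offset forces ICC < 1", {
  x <- cbind(1:5, 1:5)
  r <- icc_a1(x)
  expect_equal(r$icc, 1)
  y <- matrix(c(1, 2, 2, 3, 3, 4, 4, 5), 4, 2, byrow = TRUE)
  ry <- icc_a1(y)
  expect_equal(ry$icc, 10 / 13, tolerance = 1e-12)   # closed form
  expect_equal(ry$icc, icc_a1_oracle(y), tolerance = 1e-12)
  expect_lt(ry$icc, 1)
})

test_that("ICC(A,1) equals the brute-force ANOVA oracle on random matrices", {
  set.seed(77)
  for (i in 1:60) {
    n <- sample(5:50, 1)
    x <- matrix(rnorm(2 * n, 5, 2), n, 2)
    x[, 2] <- x[, 2] + rnorm(1, 0, 1)
    r <- icc_a1(x)
    expect_equal(r$icc, icc_a1_oracle(x), tolerance = 1e-12)
    # and the mean squares match a two-way aov decomposition
    if (i <= 5) {
      d <- data.frame(v = as.vector(x), row = factor(rep(1:n, 2)),
                      col = factor(rep(1:2, each = n)))
      ms <- summary(aov(v ~ row + col, d))[[1]][["Mean Sq"]]
      expect_equal(c(r$msr, r$msc, r$mse), ms, tolerance = 1e-10)
    }
    expect_equal(r$df1, n - 1); expect_equal(r$df2, n - 1)
    expect_true(r$ci_low <= r$icc && r$icc <= r$ci_high)
    expect_true(r$p_value >= 0 && r$p_value <= 1)
  }
})

test_that("estimate, F test and CI match an established reference on a fixed dataset", {
  # frozen from an independent ICC implementation (pingouin 0.6.1, ICC(A,1))
  set.seed(42)
  x <- matrix(rnorm(40, 10, 3), 20, 2)
  x[, 2] <- x[, 1] + rnorm(20, 0.5, 1.5)
  r <- icc_a1(x)
  expect_equal(r$icc, 0.926884, tolerance = 1e-5)
  expect_equal(r$f_value, 27.760703, tolerance = 1e-5)
  expect_equal(r$p_value, 4.999621e-10, tolerance = 1e-4)
  expect_equal(round(r$ci_low, 2), 0.83)
  expect_equal(round(r$ci_high, 2), 0.97)
})

test_that("bias to one device lowers absolute agreement; shared shifts do not", {
  set.seed(88)
  t0 <- rnorm(60, 0, 2)
  x <- cbind(t0 + rnorm(60, 0, 0.5), t0 + rnorm(60, 0, 0.5))
  base <- icc_a1(x)$icc
  biased <- x; biased[, 2] <- biased[, 2] + 2
  expect_lt(icc_a1(biased)$icc, base)
  shared <- x + 3.7
  expect_equal(icc_a1(shared)$icc, base, tolerance = 1e-12)
  perm <- sample(60)
  expect_equal(icc_a1(x[perm, ])$icc, base, tolerance = 1e-12)
})

test_that("degenerate ratings are rejected", {
  expect_dvj_error(icc_a1(matrix(1, 3, 2)), "dvj_degenerate_error")
  expect_dvj_error(icc_a1(matrix(1:4, 2, 2)), "dvj_parameter_error")
})

test_that("reliability bands follow the 0.5/0.75/0.9 thresholds", {
  expect_identical(classify_icc(c(0.135, 0.446, 0.608, 0.655)),
                   c("poor", "poor", "moderate", "moderate"))
  expect_identical(classify_icc(c(0.5, 0.75, 0.9, 1.0, 0.82)),
                   c("moderate", "good", "excellent", "excellent", "good"))
  # monotone step function
  grid <- seq(-0.2, 1, by = 0.01)
  lv <- match(classify_icc(grid), c("poor", "moderate", "good", "excellent"))
  expect_true(all(diff(lv) >= 0))
  expect_dvj_error(classify_icc(NaN), "dvj_parameter_error")
})

test_that("the agreement table has one row per parameter in both layouts", {
  set.seed(33)
  t0 <- rnorm(40, 0, 2)
  pms <- lapply(sprintf("param %d", 1:6), function(lb)
    paired_measurements(lb, t0 + rnorm(40, 0, 0.5), t0 + rnorm(40, 0, 0.8)))
  tab <- build_agreement_table(pms)
  expect_equal(nrow(tab$location), 6)
  expect_equal(nrow(tab$icc), 6)
  expect_identical(tab$icc$class, classify_icc(tab$icc$icc))

  ident <- lapply(1:3, function(i)
    paired_measurements(paste("p", i), t0 + i, t0 + i))
  tab2 <- build_agreement_table(ident)
  expect_equal(tab2$icc$icc, rep(1, 3))
  expect_equal(tab2$location$difference, rep(0, 3))

  dir <- withr::local_tempdir()
  files <- write_agreement_tables(tab, dir)
  expect_true(all(file.exists(files)))
  back <- read.csv(files[2])
  expect_equal(back$icc, round(tab$icc$icc, 3))
})
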