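# independent sums-of-squares oracle for ICC(A,1), written as explicit
# elementwise loops (no shared code with the implementation)
icc_a1_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  gm <- sum(x) / (n * k)
  ssr <- 0
  for (i in 1:n) ssr <- ssr + k * (sum(x[i, ]) / k - gm)^2
  ssc <- 0
  for (j in 1:k) ssc <- ssc + n * (sum(x[, j]) / n - gm)^2
  sst <- 0
  for (i in 1:n) for (j in 1:k) sst <- sst + (x[i, j] - gm)^2
  msr <- ssr / (n - 1); msc <- ssc / (k - 1)
  mse <- (sst - ssr - ssc) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
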