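# Independent statistical oracles, written from first principles so they
# share no code path with the package implementations.

# ICC(2,1) from explicit sums of squares (no aov()).
iccOracle <- function(x, y) {
  n <- length(x); k <- 2
  m <- cbind(x, y)
  grand <- mean(m)
  rowM <- rowMeans(m); colM <- colMeans(m)
  ssr <- k * sum((rowM - grand)^2)
  ssc <- n * sum((colM - grand)^2)
  sse <- sum((m - outer(rowM, rep(1, k)) -
                outer(rep(1, n), colM) + grand)^2)
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign
# assignments of the nonzero paired differences (valid when |differences|
# are untied).
signedRankExact <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  dist <- as.numeric(signs %*% r)
  mu <- n * (n + 1) / 4
  p <- if (v > mu) 2 * mean(dist >= v) else 2 * mean(dist <= v)
  min(1, p)
}
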