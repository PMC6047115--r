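# Independent oracles used to cross-check the package's statistics.

# One-way ANOVA by explicit sums of squares (textbook definition, no reuse of
# package code).
anova_oracle <- function(values, groups) {
  groups <- as.character(groups)
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- groups[keep]
  lev <- unique(groups)
  grand <- mean(values)
  ssb <- 0; ssw <- 0
  for (g in lev) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  df1 <- length(lev) - 1
  df2 <- length(values) - length(lev)
  Fv <- (ssb / df1) / (ssw / df2)
  list(F = Fv, p = pf(Fv, df1, df2, lower.tail = FALSE), df1 = df1, df2 = df2)
}

# Cook's distance from first principles via the hat matrix
# (H = Q Q' from a QR of the design): D_i = e_i^2 / (p s^2) * h_ii / (1 - h_ii)^2
cooks_oracle <- function(t, y, degree) {
  X <- outer(t, 0:degree, `^`)
  Q <- qr.Q(qr(X))
  h <- rowSums(Q^2)
  e <- y - Q %*% crossprod(Q, y)
  p <- degree + 1
  s2 <- sum(e^2) / (length(y) - p)
  as.vector(e^2 / (p * s2) * h / (1 - h)^2)
}

# Weighted mean / s.d. (ML, denominator = total weight)
weighted_moments <- function(x, w) {
  m <- sum(w * x) / sum(w)
  list(mean = m, sd = sqrt(sum(w * (x - m)^2) / sum(w)))
}

# Polynomial OLS solved directly by QR on the raw-power design matrix
polyfit_oracle <- function(t, y, degree) {
  X <- outer(t, 0:degree, `^`)
  as.vector(qr.coef(qr(X), y))
}
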