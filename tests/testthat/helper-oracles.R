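# independent brute-force oracles, written from the textbook definitions

oracle_oneway <- function(y, g) {
  g <- factor(g)
  grand <- mean(y)
  ssb <- 0; ssw <- 0
  for (lv in levels(g)) {
    yi <- y[g == lv]
    ssb <- ssb + length(yi) * (mean(yi) - grand)^2
    ssw <- ssw + sum((yi - mean(yi))^2)
  }
  df1 <- nlevels(g) - 1; df2 <- length(y) - nlevels(g)
  list(F = (ssb / df1) / (ssw / df2), df1 = df1, df2 = df2)
}

oracle_twoway_balanced <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  n <- length(y); grand <- mean(y)
  ma <- tapply(y, a, mean); mb <- tapply(y, b, mean)
  mab <- tapply(y, list(a, b), mean)
  ncell <- n / (nlevels(a) * nlevels(b))
  ssa <- ncell * nlevels(b) * sum((ma - grand)^2)
  ssb <- ncell * nlevels(a) * sum((mb - grand)^2)
  ssab <- 0; sse <- 0
  for (i in seq_len(nlevels(a))) for (j in seq_len(nlevels(b))) {
    ssab <- ssab + ncell * (mab[i, j] - ma[i] - mb[j] + grand)^2
    yij <- y[a == levels(a)[i] & b == levels(b)[j]]
    sse <- sse + sum((yij - mab[i, j])^2)
  }
  dfe <- n - nlevels(a) * nlevels(b)
  mse <- sse / dfe
  list(Fa = unname((ssa / (nlevels(a) - 1)) / mse),
       Fb = unname((ssb / (nlevels(b) - 1)) / mse),
       Fab = unname((ssab / ((nlevels(a) - 1) * (nlevels(b) - 1))) / mse),
       dfe = dfe)
}
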