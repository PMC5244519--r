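test_that("one-way ANOVA matches the sum-of-squares oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    k <- sample(2:4, 1)
    ns <- sample(3:8, k, replace = TRUE)
    g <- rep(letters[1:k], ns)
    y <- rnorm(length(g), mean = rep(runif(k, 0, 2), ns))
    got <- one_way_anova(y, g)
    want <- oracle_oneway(y, g)
    expect_equal(got$effects$F, want$F, tolerance = 1e-10)
    expect_equal(got$effects$df1, want$df1)
    expect_equal(got$effects$df2, want$df2)
    # permuting rows changes nothing
    perm <- sample(length(y))
    expect_equal(one_way_anova(y[perm], g[perm])$effects$F, got$effects$F,
                 tolerance = 1e-12)
  }
})

test_that("three groups of seven give df (2, 18)", {
  set.seed(1)
  res <- one_way_anova(rnorm(21), rep(c("WT", "Het", "KO"), each = 7))
  expect_equal(res$effects$df1, 2)
  expect_equal(res$effects$df2, 18)
})

test_that("identical groups give F = 0; two groups give F = t^2", {
  y0 <- rep(c(1, 3, 5, 2), 3)
  g0 <- rep(c("a", "b", "c"), each = 4)
  expect_equal(one_way_anova(y0, g0)$effects$F, 0)

  set.seed(5)
  y <- rnorm(16); g <- rep(c("a", "b"), each = 8)
  f <- one_way_anova(y, g)$effects$F
  t2 <- stats::t.test(y ~ g, var.equal = TRUE)$statistic^2
  expect_equal(f, unname(t2), tolerance = 1e-10)

  expect_error(one_way_anova(rep(1, 6), rep(c("a", "b"), 3)),
               "residual variance")
  expect_error(one_way_anova(1:3, c("a", "a", "b")), ">= 2 observations")
})

test_that("balanced two-way ANOVA matches the cell-means oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    a <- rep(rep(c("WT", "Het", "KO"), each = 7), 2)
    b <- rep(c("M", "F"), each = 21)
    y <- rnorm(42, mean = as.integer(factor(a)) * 0.3)
    got <- two_way_anova(y, a, b, a_name = "genotype", b_name = "sex")
    want <- oracle_twoway_balanced(y, a, b)
    e <- got$effects
    expect_equal(e$F[e$name == "genotype"], want$Fa, tolerance = 1e-10)
    expect_equal(e$F[e$name == "sex"], want$Fb, tolerance = 1e-10)
    expect_equal(e$F[e$name == "genotype:sex"], want$Fab,
                 tolerance = 1e-10)
    # 3 genotypes x 2 sexes x 7: df (2,36) and (1,36)
    expect_equal(e$df1, c(2, 1, 2))
    expect_true(all(e$df2 == 36))
    # df bookkeeping: effects + residual = N - 1
    expect_equal(sum(e$df1) + got$residual_df, 42 - 1)
  }
})

test_that("unbalanced developmental design has error df 32 and agrees
           with an independent Type III oracle", {
  # cells 7,5,6,6,7,7: 38 animals, 3 ages x 2 genotypes
  dev <- development_design(ko_dorsal_scale = 0.7)
  tab <- simulate_cohort_responses(dev, seed = 4)
  res <- two_way_anova(tab$norm_AMPM, tab$genotype, tab$age_group,
                       a_name = "genotype", b_name = "age")
  e <- res$effects
  expect_equal(e$df1[e$name == "age"], 2)
  expect_equal(e$df2[e$name == "age"], 32)
  expect_equal(e$df1[e$name == "genotype"], 1)
  expect_equal(e$df2[e$name == "genotype"], 32)

  # statsmodels Type III on the same data (independent implementation)
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(y = tab$norm_AMPM, g = tab$genotype,
                              a = tab$age_group), csv, row.names = FALSE)
  py <- paste(
    "import sys, pandas as pd, statsmodels.api as sm",
    "from statsmodels.formula.api import ols",
    "d = pd.read_csv(sys.argv[1])",
    "m = ols('y ~ C(g, Sum) * C(a, Sum)', data=d).fit()",
    "t = sm.stats.anova_lm(m, typ=3)",
    "print('G', t.loc['C(g, Sum)', 'F'])",
    "print('A', t.loc['C(a, Sum)', 'F'])",
    sep = "; ")
  out <- suppressWarnings(system2("python", c("-c", shQuote(py),
                                              shQuote(csv)),
                                  stdout = TRUE, stderr = TRUE))
  fg <- as.numeric(sub("^G ", "", grep("^G ", out, value = TRUE)))
  fa <- as.numeric(sub("^A ", "", grep("^A ", out, value = TRUE)))
  expect_equal(e$F[e$name == "genotype"], fg, tolerance = 1e-6)
  expect_equal(e$F[e$name == "age"], fa, tolerance = 1e-6)

  # Type II runs and reports the same layout
  res2 <- two_way_anova(tab$norm_AMPM, tab$genotype, tab$age_group,
                        ss_type = "II", a_name = "genotype", b_name = "age")
  expect_equal(res2$effects$name, res$effects$name)
  expect_error(two_way_anova(tab$norm_AMPM[tab$age_group != "P17"],
                             tab$genotype[tab$age_group != "P17"],
                             tab$age_group[tab$age_group != "P17"]),
               NA)  # dropping a level still works after droplevels
  expect_error(two_way_anova(c(1, 2, 3, 4),
                             c("a", "a", "b", "b"), c("x", "x", "x", "y")),
               "empty")
})

test_that("Bonferroni post hoc adjusts and caps", {
  set.seed(8)
  y <- rnorm(21) + rep(c(0, 0, 2), each = 7)
  g <- rep(c("WT", "Het", "KO"), each = 7)
  ph <- bonferroni_posthoc(y, g)
  expect_equal(nrow(ph), 3)
  expect_equal(ph$p_adj, pmin(1, 3 * ph$p_raw))
  expect_true(all(ph$p_adj >= ph$p_raw))
  expect_true(all(ph$df == 18))
  ph1 <- bonferroni_posthoc(y, g, comparisons = list(c("WT", "KO")))
  expect_equal(ph1$p_adj, ph1$p_raw)  # m = 1
  expect_error(bonferroni_posthoc(y, g, comparisons = list(c("WT", "XX"))),
               "unknown group")
})

test_that("identical groups give near-uniform raw post hoc p-values", {
  set.seed(3)
  ps <- replicate(200, {
    y <- rnorm(14)
    bonferroni_posthoc(y, rep(c("a", "b"), each = 7),
                       comparisons = list(c("a", "b")))$p_raw
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("rejection rate respects alpha = 0", {
  des <- adult_design(n_per_cell = 3)
  expect_equal(rejection_rate(des, reps = 100, alpha = 0, seed = 1,
                              sex = "M"), 0)
  expect_error(rejection_rate(des, reps = 10), "reps")
})
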