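# Factorial statistics: classical one-way and two-way ANOVA with
# Bonferroni-adjusted pairwise post hoc tests, plus simulation utilities
# for type-I error and power calibration. Sums of squares are computed
# in-package: the classical decomposition for balanced designs, and
# Type III (sum-to-zero contrasts, column-drop F tests against the full
# model) or Type II for unbalanced designs.

.anova_result <- function(effects, residual_df, ms_within, group_stats = NULL) {
  structure(list(effects = effects, residual_df = residual_df,
                 ms_within = ms_within, group_stats = group_stats,
                 posthoc = NULL),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  e <- x$effects
  for (i in seq_len(nrow(e))) {
    cat(sprintf("%-12s F(%d,%d) = %.4g, p = %.4g\n",
                e$name[i], e$df1[i], e$df2[i], e$F[i], e$p[i]))
  }
  if (!is.null(x$posthoc)) {
    cat("post hoc (Bonferroni):\n")
    ph <- x$posthoc
    for (i in seq_len(nrow(ph))) {
      cat(sprintf("  %-12s p = %.4g (adj %.4g)\n", ph$pair[i],
                  ph$p_raw[i], ph$p_adj[i]))
    }
  }
  invisible(x)
}

#' One-way ANOVA
#'
#' Classical between/within decomposition:
#' `F = MS_between / MS_within` with `df = (k - 1, N - k)`, p-value from
#' the F distribution.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor); `>= 2` groups with
#'   `>= 2` observations each.
#' @param effect_name Label for the tested effect.
#' @return An `anova_result`.
#' @export
one_way_anova <- function(values, groups, effect_name = "group") {
  g <- factor(groups)
  ok <- stats::complete.cases(values, g)
  values <- values[ok]; g <- droplevels(g[ok])
  k <- nlevels(g); n <- length(values)
  if (k < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs >= 2 observations")
  grand <- mean(values)
  means <- tapply(values, g, mean)
  ns <- tapply(values, g, length)
  ss_b <- sum(ns * (means - grand)^2)
  ss_w <- sum((values - means[g])^2)
  df_b <- k - 1L; df_w <- n - k
  ms_w <- ss_w / df_w
  if (ms_w <= 0) stop("zero residual variance: F is degenerate")
  f <- (ss_b / df_b) / ms_w
  eff <- data.frame(name = effect_name, F = f, df1 = df_b, df2 = df_w,
                    p = stats::pf(f, df_b, df_w, lower.tail = FALSE),
                    ss = ss_b, stringsAsFactors = FALSE)
  .anova_result(eff, df_w, ms_w,
                group_stats = data.frame(group = names(means),
                                         mean = as.numeric(means),
                                         n = as.numeric(ns)))
}

.rss <- function(y, x) {
  fit <- stats::lm.fit(x, y)
  sum(fit$residuals^2)
}

#' Two-way ANOVA
#'
#' Balanced designs use the classical cell-means decomposition. Unbalanced
#' designs use Type III sums of squares with sum-to-zero contrasts (each
#' effect's SS is the residual-sum-of-squares increase when its columns
#' are dropped from the full model), or Type II via `ss_type = "II"`.
#' The interaction is included by default.
#'
#' @param values Numeric response vector.
#' @param factor_a,factor_b Factors (coerced); every cell must be
#'   non-empty.
#' @param include_interaction Include the A:B term (default TRUE).
#' @param ss_type `"auto"` (classical when balanced, else Type III),
#'   `"III"`, or `"II"`.
#' @param a_name,b_name Effect labels in the output.
#' @return An `anova_result` with rows for A, B and (optionally) A:B.
#' @export
two_way_anova <- function(values, factor_a, factor_b,
                          include_interaction = TRUE,
                          ss_type = c("auto", "III", "II"),
                          a_name = "A", b_name = "B") {
  ss_type <- match.arg(ss_type)
  a <- factor(factor_a); b <- factor(factor_b)
  ok <- stats::complete.cases(values, a, b)
  values <- values[ok]; a <- droplevels(a[ok]); b <- droplevels(b[ok])
  if (nlevels(a) < 2 || nlevels(b) < 2) stop("need >= 2 levels per factor")
  cells <- table(a, b)
  if (any(cells == 0)) stop("empty design cell")
  n <- length(values)
  df_a <- nlevels(a) - 1L
  df_b <- nlevels(b) - 1L
  df_ab <- df_a * df_b
  df_res <- n - nlevels(a) * nlevels(b)
  if (!include_interaction) df_res <- n - 1L - df_a - df_b
  balanced <- length(unique(as.vector(cells))) == 1L

  if (balanced && ss_type %in% c("auto", "III")) {
    grand <- mean(values)
    m_a <- tapply(values, a, mean)
    m_b <- tapply(values, b, mean)
    m_ab <- tapply(values, list(a, b), mean)
    n_cell <- cells[1, 1]
    ss_a <- n_cell * nlevels(b) * sum((m_a - grand)^2)
    ss_b_ <- n_cell * nlevels(a) * sum((m_b - grand)^2)
    ss_ab <- n_cell * sum((m_ab - outer(m_a, rep(1, nlevels(b))) -
                             outer(rep(1, nlevels(a)), m_b) + grand)^2)
    ss_res <- sum((values - m_ab[cbind(a, b)])^2)
    if (!include_interaction) {
      ss_res <- ss_res + ss_ab
    }
  } else {
    # sum-to-zero model matrices, effects tested by column drops
    dat <- data.frame(y = values, A = a, B = b)
    form <- if (include_interaction) y ~ A * B else y ~ A + B
    mm <- stats::model.matrix(form, dat,
                              contrasts.arg = list(A = "contr.sum",
                                                   B = "contr.sum"))
    asn <- attr(mm, "assign")  # 0 = intercept, 1 = A, 2 = B, 3 = A:B
    rss_full <- .rss(values, mm)
    if (ss_type == "II") {
      mm_ab <- mm[, asn <= 2, drop = FALSE]
      rss_add <- .rss(values, mm_ab)
      ss_a <- .rss(values, mm[, asn %in% c(0L, 2L), drop = FALSE]) - rss_add
      ss_b_ <- .rss(values, mm[, asn %in% c(0L, 1L), drop = FALSE]) - rss_add
      ss_ab <- if (include_interaction) rss_add - rss_full else 0
    } else {
      ss_a <- .rss(values, mm[, asn != 1L, drop = FALSE]) - rss_full
      ss_b_ <- .rss(values, mm[, asn != 2L, drop = FALSE]) - rss_full
      ss_ab <- if (include_interaction) {
        .rss(values, mm[, asn != 3L, drop = FALSE]) - rss_full
      } else 0
    }
    ss_res <- rss_full
  }

  ms_res <- ss_res / df_res
  if (ms_res <= 0) stop("zero residual variance: F is degenerate")
  mk <- function(nm, ss, df1) {
    f <- (ss / df1) / ms_res
    data.frame(name = nm, F = f, df1 = df1, df2 = df_res,
               p = stats::pf(f, df1, df_res, lower.tail = FALSE), ss = ss,
               stringsAsFactors = FALSE)
  }
  eff <- rbind(mk(a_name, ss_a, df_a), mk(b_name, ss_b_, df_b))
  if (include_interaction) {
    eff <- rbind(eff, mk(paste0(a_name, ":", b_name), ss_ab, df_ab))
  }
  .anova_result(eff, df_res, ms_res)
}

#' Bonferroni-adjusted pairwise post hoc tests
#'
#' Pairwise t-tests between group means using the pooled residual variance
#' of the one-way ANOVA on the same data; adjusted
#' `p = min(1, m * p_raw)` where `m` is the number of comparisons.
#'
#' @param values Numeric response vector.
#' @param groups Group labels.
#' @param comparisons List of length-2 character vectors naming the pairs
#'   to compare, or `"all"` (default) for all pairwise comparisons.
#' @return Data frame with `pair`, `estimate`, `t`, `df`, `p_raw`,
#'   `p_adj`.
#' @export
bonferroni_posthoc <- function(values, groups, comparisons = "all") {
  g <- factor(groups)
  aov1 <- one_way_anova(values, g)
  gs <- aov1$group_stats
  if (identical(comparisons, "all")) {
    comparisons <- utils::combn(gs$group, 2, simplify = FALSE)
  }
  bad <- setdiff(unique(unlist(comparisons)), gs$group)
  if (length(bad)) stop("unknown group(s): ", paste(bad, collapse = ", "))
  m <- length(comparisons)
  rows <- lapply(comparisons, function(cmp) {
    i <- match(cmp[1], gs$group); j <- match(cmp[2], gs$group)
    est <- gs$mean[i] - gs$mean[j]
    se <- sqrt(aov1$ms_within * (1 / gs$n[i] + 1 / gs$n[j]))
    tt <- est / se
    p <- 2 * stats::pt(-abs(tt), aov1$residual_df)
    data.frame(pair = paste(cmp, collapse = " vs "), estimate = est,
               t = tt, df = aov1$residual_df, p_raw = p,
               p_adj = min(1, m * p), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulated rejection rate of an ANOVA effect
#'
#' Simulates `reps` cohorts from `design`, tests the named effect on one
#' area's normalized amplitude, and returns the fraction of simulations
#' with `p < alpha`. Used for type-I-error calibration (null designs) and
#' power analysis (programmed effects).
#'
#' @param design A [cohort_design()].
#' @param area Area column tested (e.g. `"AMPM"`).
#' @param effect `"genotype"` (one-way across genotypes) or `"age"` /
#'   `"genotype_by_age"` (two-way genotype x age effects).
#' @param reps Number of simulated cohorts (`>= 100`).
#' @param alpha Significance level.
#' @param seed Integer seed; per-rep seeds are drawn reproducibly from it.
#' @param sex Optional sex filter applied before testing.
#' @return Proportion of rejections.
#' @export
rejection_rate <- function(design, area = "AMPM", effect = "genotype",
                           reps = 1000, alpha = 0.05, seed = 1L,
                           sex = NULL) {
  stopifnot(reps >= 100)
  seeds <- .with_seed(seed, sample.int(.Machine$integer.max - 1L, reps))
  col <- paste0("norm_", area)
  hits <- 0L
  for (r in seq_len(reps)) {
    tab <- simulate_cohort_responses(design, seed = seeds[r])
    if (!is.null(sex)) tab <- tab[tab$sex == sex, ]
    p <- if (effect == "genotype" &&
             length(unique(tab$age_group)) == 1L) {
      one_way_anova(tab[[col]], tab$genotype)$effects$p[1]
    } else {
      res <- two_way_anova(tab[[col]], tab$genotype, tab$age_group,
                           a_name = "genotype", b_name = "age")
      nm <- switch(effect, genotype = "genotype", age = "age",
                   genotype_by_age = "genotype:age",
                   stop("unknown effect: ", effect))
      res$effects$p[res$effects$name == nm]
    }
    if (p < alpha) hits <- hits + 1L
  }
  hits / reps
}
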