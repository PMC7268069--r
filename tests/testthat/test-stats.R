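# group statistics: ANOVA (raw and from summaries), Tukey, Levene/Shapiro,
# ANCOVA with covariates, ROC (univariate and multivariate), chi-square

test_that("one-way ANOVA matches the textbook decomposition", {
  set.seed(3)
  g <- list(a = rnorm(12, 1), b = rnorm(9, 1.4), c = rnorm(15, 0.8))
  a <- one_way_anova(g)
  # independent textbook computation
  x <- unlist(g); n <- vapply(g, length, 0L)
  grand <- mean(x)
  ssb <- sum(n * (vapply(g, mean, 0) - grand)^2)
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0))
  f_ref <- (ssb / 2) / (ssw / (sum(n) - 3))
  expect_equal(a$F, f_ref, tolerance = 1e-9)
  expect_equal(a$df_between, 2)
  expect_equal(a$df_within, sum(n) - 3)
  expect_equal(a$p, pf(f_ref, 2, sum(n) - 3, lower.tail = FALSE),
               tolerance = 1e-9)

  # affine invariance and the zero-spread limit
  g2 <- lapply(g, function(v) 3.7 * v - 2)
  expect_equal(one_way_anova(g2)$F, a$F, tolerance = 1e-9)
  expect_equal(one_way_anova(list(a = c(1, 1), b = c(1, 1)))$F, 0)
  degenerate <- one_way_anova(list(a = c(1, 1), b = c(2, 2)))
  expect_true(is.infinite(degenerate$F))
})

test_that("summary ANOVA equals raw ANOVA on moment-matched data", {
  # construct raw groups with exactly the requested moments
  make_group <- function(n, m, s) {
    z <- scale(rnorm(n))  # mean 0, sd 1 exactly
    as.numeric(m + s * z)
  }
  set.seed(5)
  spec <- list(c(26, 1.95, 0.42), c(18, 1.62, 0.39), c(16, 1.56, 0.34))
  g <- lapply(spec, function(v) make_group(v[1], v[2], v[3]))
  raw <- one_way_anova(g)
  summ <- anova_from_summary(vapply(spec, `[`, 0, 2),
                             vapply(spec, `[`, 0, 3),
                             vapply(spec, `[`, 0, 1))
  expect_equal(summ$F, raw$F, tolerance = 1e-9)
  expect_equal(summ$p, raw$p, tolerance = 1e-9)
  expect_equal(anova_from_summary(c(1, 1), c(0.3, 0.3), c(10, 10))$F, 0)
})

test_that("Tukey post hoc: identical groups give p near 1 and a shifted
           group is flagged; p order follows mean differences", {
  set.seed(6)
  base <- rnorm(20)
  g <- list(a = base, b = base, c = base + 10 * sd(base))
  tk <- tukey_posthoc(g)
  expect_gt(tk$p_adj[tk$comparison == "b-a"], 0.99)
  expect_lt(tk$p_adj[tk$comparison == "c-a"], 0.001)

  g2 <- list(a = rnorm(25), b = rnorm(25) + 0.3, c = rnorm(25) + 1.5)
  tk2 <- tukey_posthoc(g2)
  means <- vapply(g2, mean, 0)
  dabs <- c(abs(means[2] - means[1]), abs(means[3] - means[1]),
            abs(means[3] - means[2]))
  expect_equal(order(c(tk2$p_adj[tk2$comparison == "b-a"],
                       tk2$p_adj[tk2$comparison == "c-a"],
                       tk2$p_adj[tk2$comparison == "c-b"])),
               order(-dabs))
})

test_that("Levene test: location invariant, calibrated under the null,
           powered against a 9x variance ratio", {
  set.seed(7)
  g <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  w1 <- variance_and_normality_checks(g)$levene_W
  g2 <- g; g2$b <- g2$b + 100
  expect_equal(variance_and_normality_checks(g2)$levene_W, w1,
               tolerance = 1e-9)

  null_p <- vapply(1:200, function(seed) {
    set.seed(seed)
    variance_and_normality_checks(
      list(a = rnorm(25), b = rnorm(25), c = rnorm(25)))$levene_p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(null_p, "punif"))$p.value, 0.01)

  hits <- vapply(1:60, function(seed) {
    set.seed(seed + 500)
    variance_and_normality_checks(
      list(a = rnorm(50), b = rnorm(50, 0, 3), c = rnorm(50)))$levene_p < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("Shapiro-Wilk is reported per group with degenerate flags", {
  set.seed(9)
  a <- rnorm(20); c_ <- runif(20)
  chk <- variance_and_normality_checks(list(a = a, b = rep(1, 20), c = c_))
  expect_true(chk$degenerate[["b"]])
  expect_false(chk$degenerate[["a"]])
  expect_equal(chk$shapiro_p[["a"]], shapiro.test(a)$p.value)
  expect_equal(chk$shapiro_p[["c"]], shapiro.test(c_)$p.value)
})

test_that("Kruskal-Wallis wrapper matches stats::kruskal.test", {
  set.seed(10)
  g <- list(a = rnorm(15), b = rnorm(12, 0.5), c = rexp(14))
  kw <- kruskal_anova(g)
  ref <- kruskal.test(unlist(g),
                      factor(rep(c("a", "b", "c"), c(15, 12, 14))))
  expect_equal(kw$H, unname(ref$statistic))
  expect_equal(kw$p, ref$p.value)
})

test_that("ANCOVA reports the factorial degrees of freedom and calibrated
           null behaviour of the group term", {
  cfg <- cohort_sim_config(seed = 2)
  tt <- simulate_cohort(cfg, generate_series = FALSE)$truth
  tt$measure <- tt$true_gsh_mm
  tt <- add_cingulate(tt)
  g <- fit_glm(tt)
  eff <- g$effects
  expect_equal(eff$df[eff$source == "group"], 2)
  expect_equal(eff$df[eff$source == "region"], 2)
  expect_equal(eff$df[eff$source == "group:region"], 4)
  expect_equal(eff$df[eff$source == "age"], 1)
  expect_true(all(c("AD - MCI", "AD - NC", "MCI - NC") %in%
                    g$group_contrasts$contrast))
  # injected depletion is detected with the right sign
  expect_lt(g$group_contrasts$estimate[g$group_contrasts$contrast ==
                                         "MCI - NC"], 0)
  expect_lt(eff$p[eff$source == "group"], 0.001)
})

test_that("Bonferroni contrasts equal the unadjusted p times the number of
           comparisons (capped at 1)", {
  set.seed(11)
  d <- data.frame(group = rep(c("NC", "MCI", "AD"), each = 20),
                  region = rep(c("ACC", "PCC"), 30),
                  age = rnorm(60, 70, 7),
                  sex = sample(c("M", "F"), 60, TRUE),
                  measure = rnorm(60, 2, 0.4))
  g <- fit_glm(d)
  em <- suppressMessages(emmeans::emmeans(g$model, "group"))
  raw <- summary(emmeans::contrast(em, "pairwise"), adjust = "none")
  expect_equal(g$group_contrasts$p_adj, pmin(1, 3 * raw$p.value),
               tolerance = 1e-9)
})

test_that("univariate ROC equals brute-force pair counting and the DeLong
           components formula on a toy set with ties", {
  sc <- c(1.2, 2.3, 2.3, 3.1, 0.8, 1.9, 2.7, 3.5)
  lb <- c(1, 1, 0, 0, 1, 1, 0, 0)
  r <- roc_univariate(sc, lb, positive = 1)

  pos <- sc[lb == 1]; neg <- sc[lb == 0]
  psi <- outer(pos, neg, function(a, b) (a < b) + 0.5 * (a == b))
  expect_identical(r$auc, mean(psi))
  v10 <- rowMeans(psi); v01 <- colMeans(psi)
  se_ref <- sqrt(var(v10) / length(pos) + var(v01) / length(neg))
  expect_equal(r$auc_se, se_ref, tolerance = 1e-12)
  expect_equal(r$auc_ci_95,
               pmin(pmax(r$auc + c(-1, 1) * qnorm(0.975) * se_ref, 0), 1))
})

test_that("univariate ROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  sc <- c(rnorm(30, 2.0, 0.4), rnorm(25, 1.6, 0.4))
  lb <- rep(c(0, 1), c(30, 25))
  r <- roc_univariate(sc, lb, positive = 1)
  pr <- pROC::roc(lb, sc, direction = ">", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  ci <- pROC::ci.auc(pr, method = "delong")
  expect_equal(r$auc_ci_95, as.numeric(ci[c(1, 3)]), tolerance = 1e-9)
  best <- pROC::coords(pr, "best", best.method = "youden",
                       transpose = FALSE)
  expect_equal(r$sensitivity, 100 * best$sensitivity, tolerance = 1e-9)
  expect_equal(r$specificity, 100 * best$specificity, tolerance = 1e-9)
})

test_that("ROC orientation puts AUC above one half with cutoffs in
           concentration units; edge cases behave", {
  set.seed(13)
  nc <- rnorm(25, 2.4, 0.4); ad <- rnorm(18, 1.7, 0.4)
  r <- roc_univariate(c(nc, ad), rep(c("NC", "AD"), c(25, 18)),
                      positive = "AD")
  expect_gte(r$auc, 0.5)
  expect_equal(r$direction, "lower")
  expect_gt(r$youden_cutoff, min(c(nc, ad)))
  expect_lt(r$youden_cutoff, max(c(nc, ad)))

  sep <- roc_univariate(c(1, 2, 3, 11, 12, 13), rep(c(1, 0), each = 3),
                        positive = 1)
  expect_equal(sep$auc, 1)
  expect_equal(sep$sensitivity, 100)
  expect_equal(sep$specificity, 100)

  set.seed(14)
  null_auc <- roc_univariate(rnorm(2000), rbinom(2000, 1, 0.5),
                             positive = 1)$auc
  expect_lt(abs(null_auc - 0.5), 0.05)
  expect_error(roc_univariate(1:5, rep(1, 5)), "two classes")
})

test_that("multivariate ROC reduces to univariate on one informative
           feature and recovers known logistic coefficients", {
  set.seed(15)
  x <- rnorm(300)
  y <- rbinom(300, 1, plogis(0.5 + 1.2 * x))
  mv <- roc_multivariate(data.frame(x = x), y, positive = 1)
  uni <- roc_univariate(x, y, positive = 1)
  expect_equal(mv$auc, uni$auc, tolerance = 1e-9)

  set.seed(16)
  n <- 2000
  x1 <- rnorm(n); x2 <- rnorm(n)
  beta <- c(-0.3, 0.8, -1.1)
  y2 <- rbinom(n, 1, plogis(beta[1] + beta[2] * x1 + beta[3] * x2))
  mv2 <- roc_multivariate(data.frame(x1 = x1, x2 = x2), y2, positive = 1)
  ref <- glm(y2 ~ x1 + x2, family = binomial())
  se <- sqrt(diag(vcov(ref)))
  expect_true(all(abs(mv2$coefficients - beta) < 3 * se))
  expect_false(mv2$separation)
})

test_that("complete separation is flagged, with AUC 1", {
  x <- c(rnorm(20, -5), rnorm(20, 5))
  y <- rep(c(0, 1), each = 20)
  expect_warning(mv <- roc_multivariate(data.frame(x = x), y, positive = 1),
                 "separation")
  expect_true(mv$separation)
  expect_equal(mv$auc, 1)
})

test_that("chi-square matches the 2x2 closed form and degenerates on
           proportional rows", {
  tb <- matrix(c(12, 8, 5, 15), 2, byrow = TRUE)
  r <- chi_square_contingency(tb)
  a <- 12; b <- 8; c_ <- 5; d <- 15; N <- sum(tb)
  ref <- (a * d - b * c_)^2 * N /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
  expect_equal(r$chi2, ref, tolerance = 1e-12)
  expect_equal(r$df, 1)

  prop <- matrix(c(10, 20, 5, 10), 2, byrow = TRUE)
  expect_equal(chi_square_contingency(prop)$chi2, 0, tolerance = 1e-12)
  expect_error(chi_square_contingency(matrix(c(0, 0, 1, 2), 2)),
               "marginal")
})
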