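#' One-way analysis of variance on raw group values
#'
#' Standard between/within decomposition via [stats::lm()]. Zero
#' within-group variance with unequal means yields an infinite F sentinel.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return List with `F`, `df_between`, `df_within`, `p`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(length(groups) >= 2, all(vapply(groups, length, 0L) >= 2))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names_or_index(groups), vapply(groups, length, 0L)))
  tab <- suppressWarnings(stats::anova(stats::lm(x ~ g)))
  ssb <- tab["g", "Sum Sq"]
  ssw <- tab["Residuals", "Sum Sq"]
  f <- if (ssw <= 1e-12 * (ssb + ssw)) {
    if (ssb > 0) Inf else 0
  } else tab["g", "F value"]
  list(F = f, df_between = tab["g", "Df"],
       df_within = tab["Residuals", "Df"],
       p = if (is.infinite(f)) 0 else if (f == 0 && ssb == 0 && ssw == 0)
         NA_real_ else tab["g", "Pr(>F)"])
}

names_or_index <- function(x) {
  nm <- names(x)
  if (is.null(nm) || any(nm == "")) nm <- as.character(seq_along(x))
  nm
}

#' One-way ANOVA from published group summaries
#'
#' Recomputes the F statistic from per-group mean, standard deviation and
#' sample size alone: `SSb = sum(n_i (mean_i - grand)^2)` and
#' `SSw = sum((n_i - 1) sd_i^2)`. Equals [one_way_anova()] on any raw data
#' with exactly those moments, which makes published mean +/- SD (N) tables
#' directly verifiable.
#'
#' @param means,sds,ns Per-group mean, SD and size (>= 2 groups).
#' @return List with `F`, `df_between`, `df_within`, `p`.
#' @export
anova_from_summary <- function(means, sds, ns) {
  stopifnot(length(means) >= 2, length(means) == length(sds),
            length(means) == length(ns), all(sds >= 0), all(ns >= 2))
  grand <- sum(ns * means) / sum(ns)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  dfb <- length(means) - 1
  dfw <- sum(ns) - length(means)
  f <- if (ssw == 0) { if (ssb > 0) Inf else 0 } else (ssb / dfb) / (ssw / dfw)
  list(F = f, df_between = dfb, df_within = dfw,
       p = if (is.infinite(f)) 0 else stats::pf(f, dfb, dfw,
                                                lower.tail = FALSE))
}

#' Tukey-Kramer pairwise post hoc comparisons
#'
#' Studentized-range-based pairwise tests after a one-way ANOVA, with the
#' unequal-n (Tukey-Kramer) adjustment, via [stats::TukeyHSD()].
#'
#' @param groups Named list of numeric vectors.
#' @return Data frame with `comparison`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_posthoc <- function(groups) {
  stopifnot(length(groups) >= 2, all(vapply(groups, length, 0L) >= 2))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names_or_index(groups), vapply(groups, length, 0L)))
  tk <- stats::TukeyHSD(stats::aov(x ~ g))$g
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL)
}

#' Homoscedasticity and normality checks
#'
#' Levene's test in its mean-centered form (one-way ANOVA on the absolute
#' deviations from the group means, computed directly) and a per-group
#' Shapiro-Wilk normality test via [stats::shapiro.test()]. Constant groups
#' are flagged as degenerate (their Shapiro p is `NA`).
#'
#' @param groups Named list of numeric vectors (n >= 3 per group for the
#'   normality test).
#' @return List with `levene_W`, `levene_p`, `shapiro_p` (named per group)
#'   and logical `degenerate` per group.
#' @export
variance_and_normality_checks <- function(groups) {
  stopifnot(length(groups) >= 2, all(vapply(groups, length, 0L) >= 3))
  z <- lapply(groups, function(v) abs(v - mean(v)))
  lev <- one_way_anova(z)
  shap <- vapply(groups, function(v) {
    if (stats::sd(v) == 0) NA_real_ else stats::shapiro.test(v)$p.value
  }, numeric(1))
  names(shap) <- names_or_index(groups)
  list(levene_W = lev$F, levene_p = lev$p, shapiro_p = shap,
       degenerate = is.na(shap))
}

#' Rank-based (Kruskal-Wallis) one-way test
#'
#' Thin wrapper over [stats::kruskal.test()] for variables that fail the
#' normality checks.
#'
#' @param groups Named list of numeric vectors.
#' @return List with `H`, `df`, `p`.
#' @export
kruskal_anova <- function(groups) {
  stopifnot(length(groups) >= 2)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names_or_index(groups), vapply(groups, length, 0L)))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Pearson chi-square test on a contingency table
#'
#' `sum((O - E)^2 / E)` with expected counts from the row/column marginals
#' and no continuity correction; `df = (r - 1)(c - 1)`.
#'
#' @param table Counts matrix (r x c, non-negative, no zero marginal).
#' @return List with `chi2`, `df`, `p`.
#' @export
chi_square_contingency <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in contingency table")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Add derived whole-cingulate records
#'
#' The combined cingulate measure for a subject is the sum of that
#' subject's ACC and PCC measures (areas and concentrations are additive
#' across the two voxels); subjects lacking either region are dropped.
#'
#' @param records Data frame with `subject_id`, `region` in
#'   \{"ACC", "PCC"\} and a `measure` column.
#' @param measure Name of the measure column.
#' @return `records` with `CINGULATE` rows appended.
#' @export
add_cingulate <- function(records, measure = "measure") {
  both <- intersect(records$subject_id[records$region == "ACC"],
                    records$subject_id[records$region == "PCC"])
  acc <- records[records$region == "ACC" & records$subject_id %in% both, ]
  pcc <- records[records$region == "PCC" & records$subject_id %in% both, ]
  pcc <- pcc[match(acc$subject_id, pcc$subject_id), ]
  cing <- acc
  cing$region <- "CINGULATE"
  cing[[measure]] <- acc[[measure]] + pcc[[measure]]
  rbind(records, cing)
}

#' Linear model of a measure on group, region and covariates
#'
#' Fits `measure ~ group + region + group:region + age + sex` by ordinary
#' least squares with sum-to-zero factor coding, reports per-term F tests
#' from partial (type-III) sums of squares, and (optionally) estimated
#' marginal means with Bonferroni-adjusted pairwise group and region
#' contrasts and 95% confidence intervals. This is the Gaussian-identity
#' analysis-of-covariance reading of a "generalized linear model with
#' covariates": mean squares and R-squared are defined only in that case.
#'
#' @param records Data frame with columns `group`, `region`, `age`, `sex`
#'   and the measure.
#' @param measure Name of the response column.
#' @param contrasts Also compute marginal-mean contrasts (slower)?
#' @return A `glm_effects` list: `effects` (Source, df, mean_square, F, p),
#'   `r_squared`, `model`, and (optionally) `group_contrasts`,
#'   `region_contrasts` data frames.
#' @export
fit_glm <- function(records, measure = "measure", contrasts = TRUE) {
  stopifnot(all(c("group", "region", "age", "sex", measure) %in%
                  names(records)))
  d <- records
  d$group <- factor(d$group)
  d$region <- factor(d$region)
  d$sex <- factor(d$sex)
  d$.y <- d[[measure]]
  mod <- stats::lm(.y ~ group * region + age + sex, data = d,
                   contrasts = list(group = "contr.sum",
                                    region = "contr.sum",
                                    sex = "contr.sum"))
  a3 <- car::Anova(mod, type = 3)
  rows <- setdiff(rownames(a3), "(Intercept)")
  eff <- data.frame(
    source = rows,
    df = a3[rows, "Df"],
    mean_square = a3[rows, "Sum Sq"] / a3[rows, "Df"],
    F = a3[rows, "F value"],
    p = a3[rows, "Pr(>F)"], row.names = NULL)
  ali <- is.na(eff$F) & eff$source != "Residuals"
  if (any(ali))
    warning("aliased term(s): ", paste(eff$source[ali], collapse = ", "))

  out <- list(effects = eff, r_squared = summary(mod)$r.squared, model = mod)
  if (contrasts) {
    emm_pairs <- function(spec) {
      em <- suppressMessages(emmeans::emmeans(mod, spec))
      pr <- summary(emmeans::contrast(em, method = "pairwise"),
                    adjust = "bonferroni", infer = TRUE)
      data.frame(contrast = as.character(pr$contrast),
                 estimate = pr$estimate, se = pr$SE,
                 lower = pr$lower.CL, upper = pr$upper.CL,
                 p_adj = pr$p.value, row.names = NULL)
    }
    out$group_contrasts <- emm_pairs("group")
    out$region_contrasts <- emm_pairs("region")
  }
  structure(out, class = "glm_effects")
}

#' @export
print.glm_effects <- function(x, ...) {
  cat("Type-III ANCOVA effects (R^2 =", round(x$r_squared, 3), ")\n")
  print(x$effects, digits = 4)
  invisible(x)
}

# ---- ROC -----------------------------------------------------------------

#' Univariate ROC analysis with DeLong interval and Youden cutoff
#'
#' The AUC is the Mann-Whitney probability that a random positive scores on
#' the disease side of a random negative (ties count one half); its 95%
#' confidence interval and p-value against AUC = 0.5 use DeLong's
#' structural-components variance. When the positive class has the lower
#' mean score (e.g. metabolite depletion marks disease), scores are negated
#' internally so AUC >= 0.5, while the Youden-optimal cutoff is reported in
#' the original measurement units. Youden ties are broken toward higher
#' specificity.
#'
#' @param scores Numeric marker values.
#' @param labels Binary class labels.
#' @param positive Level of `labels` treated as diseased (default: the
#'   level with the lower mean score).
#' @return A `roc_result`: `auc`, `auc_ci_95`, `auc_se`, `p`,
#'   `youden_cutoff` (original units), `youden_j`, `sensitivity`,
#'   `specificity`, `accuracy` (percent), `direction`, `n_negative`,
#'   `n_positive`.
#' @export
roc_univariate <- function(scores, labels, positive = NULL) {
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  lv <- unique(labels)
  if (length(lv) != 2) stop("labels must contain exactly two classes")
  if (is.null(positive)) {
    m <- vapply(lv, function(l) mean(scores[labels == l]), numeric(1))
    positive <- lv[which.min(m)]
  }
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  m <- length(pos); n <- length(neg)

  # lower scores indicate disease when the positive mean is lower
  direction <- if (mean(pos) <= mean(neg)) "lower" else "higher"
  sp <- if (direction == "lower") -pos else pos
  sn <- if (direction == "lower") -neg else neg

  psi <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(psi)
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  var_auc <- stats::var(v10) / m + stats::var(v01) / n
  se <- sqrt(var_auc)
  ci <- pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  p <- if (se == 0) 0 else
    2 * stats::pnorm(-abs(auc - 0.5) / se)

  # Youden cutoff over observed thresholds (oriented scores: predict
  # positive when oriented score >= threshold)
  thr <- sort(unique(c(sp, sn)))
  sens <- vapply(thr, function(t) mean(sp >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(sn < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(spec[best])]
  cutoff <- if (direction == "lower") -thr[best] else thr[best]
  acc <- 100 * (sens[best] * m + spec[best] * n) / (m + n)

  structure(list(auc = auc, auc_ci_95 = ci, auc_se = se, p = p,
                 youden_cutoff = cutoff, youden_j = j[best],
                 sensitivity = 100 * sens[best],
                 specificity = 100 * spec[best], accuracy = acc,
                 direction = direction, positive = positive,
                 n_negative = n, n_positive = m),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f [%.3f-%.3f], p = %.3g\n", x$auc,
              x$auc_ci_95[1], x$auc_ci_95[2], x$p))
  cat(sprintf("  Youden cutoff %.4g (J = %.3f): sens %.1f%%, spec %.1f%%, acc %.1f%%\n",
              x$youden_cutoff, x$youden_j, x$sensitivity, x$specificity,
              x$accuracy))
  invisible(x)
}

#' Multivariate ROC via binary logistic regression
#'
#' Fits a maximum-likelihood logistic regression of the class labels on the
#' supplied features (e.g. ACC and PCC concentrations with age and sex),
#' then scores the predicted probabilities with [roc_univariate()].
#' Complete separation is detected and flagged; the coefficients are still
#' returned with a warning rather than failing silently.
#'
#' @param features Data frame of predictors (complete cases only).
#' @param labels Binary class labels.
#' @param positive Diseased level (default: second level of
#'   `factor(labels)`).
#' @return A `roc_result` with extra fields `coefficients`, `separation`
#'   and `converged`.
#' @export
roc_multivariate <- function(features, labels, positive = NULL) {
  features <- as.data.frame(features)
  stopifnot(nrow(features) == length(labels))
  if (anyNA(features) || anyNA(labels)) stop("complete cases required")
  yf <- factor(labels)
  if (nlevels(yf) != 2) stop("labels must contain exactly two classes")
  if (is.null(positive)) positive <- levels(yf)[2]
  y <- as.integer(yf == positive)
  d <- cbind(.y = y, features)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = d, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 50)))
  pr <- stats::fitted(fit)
  separation <- max(pr) > 1 - 1e-6 && min(pr) < 1e-6
  if (separation)
    warning("complete separation detected; coefficients are unstable")
  roc <- roc_univariate(pr, y, positive = 1)
  roc$coefficients <- stats::coef(fit)
  roc$separation <- separation
  roc$converged <- fit$converged
  roc
}
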