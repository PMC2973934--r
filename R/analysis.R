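# Comparison-analysis stage: group contrasts, interaction tests, and the
# main-effects ANOVA with balanced adjusted means.

new_comparison_result <- function(groups, statistic, df, p_value, test) {
  tm_check(is.na(p_value) || (p_value > 0 && p_value <= 1),
           "p-value outside (0, 1]")
  structure(list(groups = groups, statistic = unname(statistic),
                 df = unname(df), p_value = unname(p_value), test = test),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4g\n", x$test,
              x$statistic, paste(signif(x$df, 6), collapse = ", "),
              x$p_value))
  if (is.data.frame(x$groups)) print(x$groups, row.names = FALSE)
  invisible(x)
}

group_summary <- function(values_a, values_b,
                          labels = c("group_a", "group_b")) {
  data.frame(label = labels,
             n = c(length(values_a), length(values_b)),
             mean = c(mean(values_a), mean(values_b)),
             sd = c(sd(values_a), sd(values_b)),
             stringsAsFactors = FALSE)
}

#' Compare two groups of continuous values
#'
#' Classical two-sample tests: pooled-variance Student t (the default,
#' matching common practice for comparing mean standardized differences),
#' Welch t, or the Mann-Whitney rank test. Two-sided p-values.
#'
#' @param values_a,values_b Numeric vectors (n >= 2 for t tests, n >= 1 for
#'   Mann-Whitney).
#' @param test `"student_t"`, `"welch_t"`, or `"mann_whitney"`.
#' @param labels Group labels for the summary block.
#' @return A `comparison_result` with group summaries, statistic, df, and p.
#' @export
two_group_compare <- function(values_a, values_b,
                              test = c("student_t", "welch_t",
                                       "mann_whitney"),
                              labels = c("group_a", "group_b")) {
  test <- match.arg(test)
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (test == "mann_whitney") {
    tm_check(length(values_a) >= 1 && length(values_b) >= 1,
             "each group needs at least 1 value")
    ht <- suppressWarnings(wilcox.test(values_a, values_b))
    return(new_comparison_result(group_summary(values_a, values_b, labels),
                                 ht$statistic, NA_real_, ht$p.value,
                                 "mann_whitney"))
  }
  tm_check(length(values_a) >= 2 && length(values_b) >= 2,
           "each group needs at least 2 values for a t test")
  pooled <- test == "student_t"
  v <- ((length(values_a) - 1) * stats::var(values_a) +
          (length(values_b) - 1) * stats::var(values_b)) /
    (length(values_a) + length(values_b) - 2)
  if (v == 0) {
    if (mean(values_a) != mean(values_b)) {
      tm_stop("zero pooled variance with unequal means", "tm_degenerate_input")
    }
    # both groups constant and equal: no evidence of a difference
    return(new_comparison_result(
      group_summary(values_a, values_b, labels), 0,
      length(values_a) + length(values_b) - 2, 1, test))
  }
  ht <- t.test(values_a, values_b, var.equal = pooled)
  new_comparison_result(group_summary(values_a, values_b, labels),
                        ht$statistic, ht$parameter, ht$p.value, test)
}

#' Compare categorical compositions
#'
#' Pearson chi-square (no continuity correction by default) on a contingency
#' table, switching to Fisher's exact test when any expected count falls
#' below `fisher_threshold` (the classical rule; set the threshold to 0 to
#' force chi-square, or pass `test` explicitly).
#'
#' @param tab Matrix of nonnegative integer counts (rows = groups).
#' @param test `"auto"` (expected-count rule), `"chi_square"`, or
#'   `"fisher_exact"`.
#' @param fisher_threshold Expected-count threshold for the automatic switch.
#' @param correct Apply Yates continuity correction to the chi-square test.
#' @return A `comparison_result`.
#' @export
categorical_compare <- function(tab, test = c("auto", "chi_square",
                                              "fisher_exact"),
                                fisher_threshold = 5, correct = FALSE) {
  test <- match.arg(test)
  tab <- as.matrix(tab)
  tm_check(all(tab >= 0) && all(tab == round(tab)),
           "counts must be nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    tm_stop("table has an empty row or column margin", "tm_degenerate_input")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (test == "auto") {
    test <- if (any(expected < fisher_threshold)) "fisher_exact"
    else "chi_square"
  }
  groups <- data.frame(label = paste0("row", seq_len(nrow(tab))),
                       n = rowSums(tab),
                       mean = tab[, 1] / rowSums(tab), sd = NA_real_,
                       stringsAsFactors = FALSE)
  if (test == "chi_square") {
    ht <- suppressWarnings(chisq.test(tab, correct = correct))
    new_comparison_result(groups, ht$statistic, ht$parameter, ht$p.value,
                          "chi_square")
  } else {
    ht <- fisher.test(tab)
    # fisher.test can return 1 + eps from summing the tail probabilities
    new_comparison_result(groups, NA_real_, NA_real_, min(ht$p.value, 1),
                          "fisher_exact")
  }
}

#' One-way analysis of variance
#'
#' Standard fixed-effects F test, \eqn{F = MS_{between}/MS_{within}} on
#' \eqn{(k-1, N-k)} degrees of freedom. For two groups, F equals the square
#' of the pooled t statistic.
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 2).
#' @param labels Optional group labels.
#' @return A `comparison_result` with `test = "anova_f"`.
#' @export
oneway_anova <- function(groups, labels = NULL) {
  tm_check(is.list(groups) && length(groups) >= 2, "need at least 2 groups")
  groups <- lapply(groups, function(g) g[!is.na(g)])
  tm_check(all(vapply(groups, length, integer(1)) >= 2),
           "each group needs at least 2 values")
  if (is.null(labels)) labels <- paste0("group", seq_along(groups))
  k <- length(groups)
  ns <- vapply(groups, length, integer(1))
  N <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw == 0) {
    if (ssb == 0) {
      gs <- data.frame(label = labels, n = ns, mean = means,
                       sd = vapply(groups, sd, numeric(1)))
      return(new_comparison_result(gs, 0, c(k - 1, N - k), 1, "anova_f"))
    }
    tm_stop("zero within-group variance with unequal means",
            "tm_degenerate_input")
  }
  Fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  gs <- data.frame(label = labels, n = ns, mean = means,
                   sd = vapply(groups, sd, numeric(1)),
                   stringsAsFactors = FALSE)
  new_comparison_result(gs, Fstat, c(k - 1, N - k), max(p, .Machine$double.xmin),
                        "anova_f")
}

#' Interaction between trial design and a covariate
#'
#' Two-way fixed-effects ANOVA of `values` on `factor_a * factor_b`; returns
#' the interaction term's F-test p-value. Used to decide whether a single
#' pooled covariate effect may be reported across superiority and
#' noninferiority trials.
#'
#' @param values Numeric response.
#' @param factor_a,factor_b Factors (coerced); every crossed cell must be
#'   nonempty, otherwise the interaction is inestimable (classed error
#'   `tm_empty_cell`, e.g. an elderly-by-noninferiority cell with no trials).
#' @return The interaction p-value (scalar).
#' @export
interaction_test <- function(values, factor_a, factor_b) {
  keep <- !is.na(values) & !is.na(factor_a) & !is.na(factor_b)
  d <- data.frame(y = values[keep],
                  a = factor(factor_a[keep]), b = factor(factor_b[keep]))
  if (nlevels(d$a) < 2 || nlevels(d$b) < 2) {
    tm_stop("a factor has a single level: interaction inestimable",
            "tm_empty_cell")
  }
  cells <- table(d$a, d$b)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    tm_stop(sprintf("empty cell %s x %s: interaction inestimable",
                    rownames(cells)[bad[1]], colnames(cells)[bad[2]]),
            "tm_empty_cell")
  }
  fit <- lm(y ~ a * b, data = d)
  an <- anova(fit)
  unname(an["a:b", "Pr(>F)"])
}

#' Main-effects ANOVA with balanced adjusted means
#'
#' Least-squares fit of the (absolute) standardized difference on categorical
#' predictors, main effects only. Adjusted means are balanced-population
#' marginal means: the model prediction for each level of a factor averaged
#' over an equal-weight grid of all other factors' levels, with standard
#' errors from the model covariance. Per-factor p-values are partial
#' (drop-one) F tests; for a main-effects model these coincide with Type
#' II/III sums of squares.
#'
#' @param records Registry data frame (or any data frame).
#' @param predictors Character vector of categorical column names.
#' @param response Response column (default `"std_diff"`; absolute values
#'   are analyzed so the sign convention cannot flip group means).
#' @param weighting `"balanced"` (equal weight per level combination,
#'   default) or `"observed"` (weights from the observed margins).
#' @return Object of class `adjusted_means`: `means` (data frame factor /
#'   level / n / mean / se), `p_values` (per factor), `r2_adjusted`.
#' @export
adjusted_means_anova <- function(records, predictors,
                                 response = "std_diff",
                                 weighting = c("balanced", "observed")) {
  weighting <- match.arg(weighting)
  tm_check(all(predictors %in% names(records)),
           paste("missing predictor column(s):",
                 paste(setdiff(predictors, names(records)), collapse = ", ")))
  d <- records[, c(response, predictors)]
  d <- d[complete.cases(d), , drop = FALSE]
  d[[response]] <- abs(d[[response]])
  for (p in predictors) d[[p]] <- factor(d[[p]])
  fit <- lm(reformulate(predictors, response), data = d)
  if (anyNA(coef(fit))) {
    tm_stop(paste("rank-deficient fit; aliased terms:",
                  paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
            "tm_rank_deficient")
  }
  tt <- delete.response(terms(fit))
  V <- vcov(fit)
  beta <- coef(fit)

  rows <- list()
  for (p in predictors) {
    others <- setdiff(predictors, p)
    for (lev in levels(d[[p]])) {
      if (weighting == "balanced") {
        grid <- expand.grid(c(setNames(list(lev), p),
                              lapply(d[others], levels)),
                            stringsAsFactors = FALSE)
        w <- rep(1 / nrow(grid), nrow(grid))
      } else {
        grid <- d[others]
        grid[[p]] <- lev
        w <- rep(1 / nrow(grid), nrow(grid))
      }
      for (q in predictors) grid[[q]] <- factor(grid[[q]],
                                                levels = levels(d[[q]]))
      X <- model.matrix(tt, grid)
      cvec <- colSums(X * w)
      rows[[length(rows) + 1L]] <- data.frame(
        factor = p, level = lev, n = sum(d[[p]] == lev),
        mean = sum(cvec * beta),
        se = sqrt(drop(t(cvec) %*% V %*% cvec)),
        stringsAsFactors = FALSE)
    }
  }
  dr <- drop1(fit, test = "F")
  pv <- setNames(dr[predictors, "Pr(>F)"], predictors)
  structure(list(means = do.call(rbind, rows), p_values = pv,
                 r2_adjusted = summary(fit)$adj.r.squared,
                 weighting = weighting, fit = fit),
            class = "adjusted_means")
}

#' @export
print.adjusted_means <- function(x, ...) {
  cat(sprintf("adjusted means (%s weighting), adjusted R^2 = %.3f\n",
              x$weighting, x$r2_adjusted))
  m <- x$means
  m$mean <- round(m$mean, 3); m$se <- round(m$se, 3)
  print(m, row.names = FALSE)
  cat("per-factor p-values:\n")
  print(signif(x$p_values, 3))
  invisible(x)
}

#' Summary tables for a registry with extracted standardized differences
#'
#' Produces the study-level comparison blocks: (1) per outcome scale and
#' combined, mean (SD) and count of the absolute standardized difference per
#' design, with the Student t p-value for the superiority-vs-noninferiority
#' contrast; (2) per covariate, stratum means (SD) per design with per-design
#' p-values (t test or one-way ANOVA), a pooled p-value for the covariate
#' from the main-effects two-way ANOVA adjusting for design, and the
#' design-by-covariate interaction p (NA when a crossed cell is empty);
#' (3) distribution summaries (quartiles and range) per design.
#'
#' @param records Registry data frame with `std_diff` filled (see
#'   [extract_registry()]).
#' @param covariates Covariate columns for the stratified block.
#' @return List with elements `by_scale`, `by_covariate`, `distribution`.
#' @export
summarize_registry <- function(records,
                               covariates = c("year_band", "context",
                                              "pharmacological", "age_group",
                                              "mortality", "statistician",
                                              "multicenter", "funding")) {
  tm_check("std_diff" %in% names(records), "run extract_registry first")
  d <- records[!is.na(records$std_diff), , drop = FALSE]
  d$std_diff <- abs(d$std_diff)
  sup <- d[d$design == "superiority", ]
  ni <- d[d$design == "noninferiority", ]

  scale_row <- function(scale_label, sel) {
    a <- sup$std_diff[sel(sup)]; b <- ni$std_diff[sel(ni)]
    p <- if (length(a) >= 2 && length(b) >= 2)
      two_group_compare(a, b, "student_t")$p_value else NA_real_
    data.frame(scale = scale_label,
               mean_superiority = mean(a), sd_superiority = sd(a),
               n_superiority = length(a),
               mean_noninferiority = mean(b), sd_noninferiority = sd(b),
               n_noninferiority = length(b), p_value = p,
               stringsAsFactors = FALSE)
  }
  by_scale <- rbind(
    scale_row("proportions", function(x) x$scale == "proportions"),
    scale_row("means", function(x) x$scale == "means"),
    scale_row("combined", function(x) rep(TRUE, nrow(x))))

  cov_rows <- list()
  for (cv in covariates) {
    lv <- sort(unique(as.character(d[[cv]])))
    per_design_p <- sapply(list(sup, ni), function(dd) {
      gl <- split(dd$std_diff, as.character(dd[[cv]]))
      gl <- gl[vapply(gl, length, integer(1)) >= 2]
      if (length(gl) < 2) return(NA_real_)
      if (length(gl) == 2) two_group_compare(gl[[1]], gl[[2]])$p_value
      else oneway_anova(gl)$p_value
    })
    pooled_p <- tryCatch(suppressWarnings({
      am <- adjusted_means_anova(d, c("design", cv))
      unname(am$p_values[[cv]])
    }), tm_error = function(e) NA_real_, error = function(e) NA_real_)
    inter_p <- tryCatch(
      suppressWarnings(interaction_test(d$std_diff, d$design, d[[cv]])),
      tm_empty_cell = function(e) NA_real_)
    for (l in lv) {
      a <- sup$std_diff[as.character(sup[[cv]]) == l]
      b <- ni$std_diff[as.character(ni[[cv]]) == l]
      cov_rows[[length(cov_rows) + 1L]] <- data.frame(
        covariate = cv, level = l,
        mean_superiority = if (length(a)) mean(a) else NA_real_,
        sd_superiority = if (length(a) > 1) sd(a) else NA_real_,
        n_superiority = length(a),
        mean_noninferiority = if (length(b)) mean(b) else NA_real_,
        sd_noninferiority = if (length(b) > 1) sd(b) else NA_real_,
        n_noninferiority = length(b),
        p_superiority = per_design_p[1], p_noninferiority = per_design_p[2],
        p_pooled = pooled_p, p_interaction = inter_p,
        stringsAsFactors = FALSE)
    }
  }
  by_covariate <- do.call(rbind, cov_rows)

  dist_row <- function(dd, label) {
    q <- quantile(dd$std_diff, c(0, 0.25, 0.5, 0.75, 1))
    data.frame(design = label, n = nrow(dd), min = q[1], q1 = q[2],
               median = q[3], q3 = q[4], max = q[5],
               stringsAsFactors = FALSE, row.names = NULL)
  }
  distribution <- rbind(dist_row(sup, "superiority"),
                        dist_row(ni, "noninferiority"))

  list(by_scale = by_scale, by_covariate = by_covariate,
       distribution = distribution)
}
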