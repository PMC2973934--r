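test_that("two-group comparisons reproduce hand-computed fixtures", {
  r <- two_group_compare(c(1, 2, 3), c(1, 2, 3), "student_t")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # pooled s^2 = 0.5, se = sqrt(0.5), t = -2/sqrt(0.5)
  r2 <- two_group_compare(c(0, 1), c(2, 3), "student_t")
  expect_equal(r2$statistic, -2.8284, tolerance = 1e-4)
  expect_equal(r2$df, 2)
  expect_equal(r2$p_value, 0.1056, tolerance = 1e-3)
  expect_identical(r2$groups$n, c(2L, 2L))

  expect_error(two_group_compare(c(1, 1), c(2, 2), "student_t"),
               class = "tm_degenerate_input")

  rw <- two_group_compare(c(1, 5, 9), c(2, 6, 10), "mann_whitney")
  expect_gt(rw$p_value, 0.5)
  rwl <- two_group_compare(c(1, 2, 3), c(11, 12, 13), "welch_t")
  expect_lt(rwl$p_value, 0.01)
})

test_that("categorical comparisons: chi-square, independence, Fisher", {
  # multicenter composition 67/100 vs 86/100
  r <- categorical_compare(rbind(c(67, 33), c(86, 14)))
  expect_identical(r$test, "chi_square")
  expect_equal(r$statistic, 10.04, tolerance = 1e-2)
  expect_equal(r$p_value, 0.00153, tolerance = 1e-2)

  # transposition invariance
  rt <- categorical_compare(cbind(c(67, 33), c(86, 14)))
  expect_equal(rt$statistic, r$statistic, tolerance = 1e-12)

  r0 <- categorical_compare(rbind(c(10, 10), c(10, 10)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # exact hypergeometric enumeration: 2 * (1/20)
  rf <- categorical_compare(rbind(c(3, 0), c(0, 3)))
  expect_identical(rf$test, "fisher_exact")
  expect_equal(rf$p_value, 0.1, tolerance = 1e-12)

  expect_error(categorical_compare(rbind(c(0, 0), c(5, 5))),
               class = "tm_degenerate_input")
})

test_that("Fisher agrees with direct enumeration on small balanced tables", {
  # independent oracle: enumerate the hypergeometric support directly
  fisher_enum <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    supp <- max(0, k - n):min(k, m)
    pr <- dhyper(supp, m, n, k)
    sum(pr[pr <= dhyper(tab[1, 1], m, n, k) * (1 + 1e-7)])
  }
  set.seed(21)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 3) + c(1, 0, 0, 1), 2)
    if (sum(tab) > 20 || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      next
    r <- categorical_compare(tab, test = "fisher_exact")
    expect_equal(r$p_value, fisher_enum(tab), tolerance = 1e-7)
  }
})

test_that("one-way ANOVA: fixture, identity cases, t^2 = F", {
  r <- oneway_anova(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(r$statistic, 16)
  expect_equal(r$df, c(2, 3))
  expect_equal(r$p_value, 0.0251, tolerance = 1e-3)

  ri <- oneway_anova(list(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(ri$statistic, 0)
  expect_equal(ri$p_value, 1)

  set.seed(31)
  a <- rnorm(12); b <- rnorm(15, 0.5)
  t2 <- two_group_compare(a, b, "student_t")
  f2 <- oneway_anova(list(a, b))
  expect_equal(f2$statistic, t2$statistic^2, tolerance = 1e-10)
  expect_equal(f2$p_value, t2$p_value, tolerance = 1e-10)

  expect_error(oneway_anova(list(c(1, 1), c(2, 2))),
               class = "tm_degenerate_input")
})

test_that("interaction test: additivity, empty cells, crossed effects", {
  # exactly additive cell means with symmetric within-cell spread
  a <- rep(c("sup", "ni"), each = 8)
  b <- rep(rep(c("x", "y"), each = 4), 2)
  mu <- ifelse(a == "sup", 1, 0) + ifelse(b == "x", 0.5, 0)
  y <- mu + rep(c(-1, 1), 8)
  expect_equal(interaction_test(y, a, b), 1, tolerance = 1e-10)

  # empty cell (no elderly noninferiority trials, say)
  a2 <- c("sup", "sup", "sup", "ni", "ni")
  b2 <- c("adult", "adult", "elderly", "adult", "adult")
  expect_error(interaction_test(rnorm(5), a2, b2), class = "tm_empty_cell")

  # strong crossed effect detected
  set.seed(41)
  a3 <- rep(c("sup", "ni"), each = 40)
  b3 <- rep(rep(c("x", "y"), each = 20), 2)
  y3 <- ifelse(a3 == "sup", 1, -1) * ifelse(b3 == "x", 1, -1) +
    rnorm(80, sd = 0.3)
  expect_lt(interaction_test(y3, a3, b3), 1e-3)
})

test_that("type I error of the implemented tests is near nominal", {
  set.seed(51)
  reps <- 1000
  n <- 12
  band <- 3 * sqrt(0.05 * 0.95 / reps)

  x <- matrix(rnorm(reps * n), n); y <- matrix(rnorm(reps * n), n)
  rej_t <- mean(sapply(seq_len(reps), function(i)
    two_group_compare(x[, i], y[, i], "student_t")$p_value < 0.05))
  expect_lt(abs(rej_t - 0.05), band)

  z <- matrix(rnorm(reps * n), n)
  rej_f <- mean(sapply(seq_len(reps), function(i)
    oneway_anova(list(x[, i], y[, i], z[, i]))$p_value < 0.05))
  expect_lt(abs(rej_f - 0.05), band)

  a <- rep(c("s", "n"), each = 10)
  b <- rep(rep(c("u", "v"), each = 5), 2)
  rej_i <- mean(sapply(seq_len(reps), function(i)
    interaction_test(rnorm(20), a, b) < 0.05))
  expect_lt(abs(rej_i - 0.05), band)
})

test_that("adjusted means: orthogonality, oracle agreement, rank checks", {
  # balanced design: adjusted means equal raw group means
  bal <- data.frame(
    std_diff = c(1, 2, 3, 4, 5, 6, 7, 8),
    f1 = rep(c("a", "b"), each = 4),
    f2 = rep(c("u", "v"), 4))
  am <- adjusted_means_anova(bal, c("f1", "f2"))
  raw <- tapply(bal$std_diff, bal$f1, mean)
  got <- am$means[am$means$factor == "f1", ]
  expect_equal(got$mean[match(c("a", "b"), got$level)], as.vector(raw),
               tolerance = 1e-10)

  # unbalanced fixture vs brute-force normal-equations oracle
  set.seed(61)
  unb <- data.frame(
    std_diff = abs(rnorm(8, 0.4, 0.2)),
    f1 = c("a", "a", "a", "a", "a", "b", "b", "b"),
    f2 = c("u", "u", "v", "v", "v", "u", "v", "v"))
  am2 <- adjusted_means_anova(unb, c("f1", "f2"))
  orc <- ls_adjusted_means_oracle(unb, c("f1", "f2"))
  for (i in seq_len(nrow(am2$means))) {
    key <- paste(am2$means$factor[i], am2$means$level[i], sep = ":")
    expect_equal(am2$means$mean[i], unname(orc[[key]]["mean"]),
                 tolerance = 1e-8)
    expect_equal(am2$means$se[i], unname(orc[[key]]["se"]),
                 tolerance = 1e-8)
  }
  expect_true(all(am2$means$se > 0))
  expect_equal(am2$r2_adjusted, summary(am2$fit)$adj.r.squared)

  # aliased predictors are reported, not silently dropped
  ali <- unb; ali$f3 <- ali$f1
  expect_error(adjusted_means_anova(ali, c("f1", "f3")),
               class = "tm_rank_deficient")
})

test_that("adjusted means support observed-margins weighting", {
  set.seed(62)
  d <- data.frame(std_diff = abs(rnorm(30, 0.4, 0.15)),
                  f1 = sample(c("a", "b"), 30, TRUE, prob = c(0.7, 0.3)),
                  f2 = sample(c("u", "v"), 30, TRUE))
  amb <- adjusted_means_anova(d, c("f1", "f2"))
  amo <- adjusted_means_anova(d, c("f1", "f2"), weighting = "observed")
  expect_false(isTRUE(all.equal(amb$means$mean, amo$means$mean)))
})

test_that("summarize_registry: degenerate and calibrated registries", {
  reg <- generate_registry(registry_config(n_superiority = 2,
                                           n_noninferiority = 2), seed = 71)
  reg$std_diff <- 0.4; reg$scale <- "proportions"
  reg$provenance <- "direct"
  s <- summarize_registry(reg)
  comb <- s$by_scale[s$by_scale$scale == "combined", ]
  expect_equal(comb$mean_superiority, 0.4)
  expect_equal(comb$sd_superiority, 0)

  # constant grouping column collapses to the global summary
  reg$year_band <- "2004-06"
  s2 <- summarize_registry(reg, covariates = "year_band")
  row <- s2$by_covariate
  expect_identical(nrow(row), 1L)
  expect_equal(row$n_superiority + row$n_noninferiority, nrow(reg))
  expect_equal(row$mean_superiority, comb$mean_superiority)
})
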