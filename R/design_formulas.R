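#' Specify a two-arm trial design
#'
#' Bundles the planning inputs consumed by the sample-size formulas: design
#' type, outcome type, type I error and sidedness, power, and the effect or
#' margin parameters.
#'
#' @param design `"superiority"` or `"noninferiority"`.
#' @param outcome `"binary"` or `"continuous"`.
#' @param alpha Type I error rate, in (0, 1). Used verbatim with the stated
#'   sidedness: a two-sided `alpha` contributes the \eqn{z_{1-\alpha/2}}
#'   multiplier, a one-sided `alpha` contributes \eqn{z_{1-\alpha}}. No
#'   silent halving is applied for noninferiority designs: sidedness is part
#'   of the design record, not a convention.
#' @param sides `"two"` or `"one"`.
#' @param power Target power \eqn{1-\beta}, in (0, 1).
#' @param p1,p2 Planning event proportions (binary outcomes). For binary
#'   noninferiority, `p2` defaults to `p1` (planning under true equality).
#' @param delta Planning difference in means (continuous superiority), in
#'   outcome units.
#' @param sd Planning standard deviation (continuous outcomes).
#' @param margin Noninferiority margin, strictly positive, in outcome units
#'   (continuous) or on the proportion scale (binary).
#' @param allocation Allocation ratio n2:n1; only 1 (equal allocation) is
#'   supported by the formulas here.
#' @return An object of class `design_spec`.
#' @seealso [n_per_group()], [empirical_power()]
#' @export
design_spec <- function(design = c("superiority", "noninferiority"),
                        outcome = c("binary", "continuous"),
                        alpha = 0.05, sides = c("two", "one"), power = 0.80,
                        p1 = NULL, p2 = NULL, delta = NULL, sd = NULL,
                        margin = NULL, allocation = 1) {
  design <- match.arg(design)
  outcome <- match.arg(outcome)
  sides <- match.arg(sides)
  chk_prob(alpha, "alpha")
  chk_prob(power, "power")
  tm_check(identical(allocation, 1) || isTRUE(all.equal(allocation, 1)),
           "only equal (1:1) allocation is supported")
  if (design == "noninferiority") {
    tm_check(is.numeric(margin) && margin > 0,
             "noninferiority designs need a margin > 0")
  }
  if (outcome == "binary") {
    if (design == "noninferiority" && is.null(p2) && !is.null(p1)) p2 <- p1
    if (!is.null(p1)) chk_prob(p1, "p1")
    if (!is.null(p2)) chk_prob(p2, "p2")
  } else {
    if (!is.null(sd)) tm_check(sd > 0, "planning sd must be > 0")
  }
  structure(list(design = design, outcome = outcome, alpha = alpha,
                 sides = sides, power = power, p1 = p1, p2 = p2,
                 delta = delta, sd = sd, margin = margin,
                 allocation = 1),
            class = "design_spec")
}

# z-multiplier sum (z_{1-alpha*} + z_{1-beta}); alpha* folds in sidedness
z_sum <- function(spec) {
  astar <- if (spec$sides == "two") spec$alpha / 2 else spec$alpha
  qnorm(1 - astar) + qnorm(spec$power)
}

#' Per-group sample size for a two-arm design
#'
#' Normal-approximation closed forms for the four design-by-outcome
#' combinations:
#' \itemize{
#'   \item continuous superiority: \eqn{n = (z_{1-\alpha^*}+z_{1-\beta})^2
#'     \, 2\sigma^2/\delta^2};
#'   \item continuous noninferiority: same form with the margin in place of
#'     \eqn{\delta} (planning under true equality) and the stated one-sided
#'     \eqn{\alpha^*};
#'   \item binary superiority: \eqn{n = (z_{1-\alpha^*}+z_{1-\beta})^2\,
#'     [p_1(1-p_1)+p_2(1-p_2)]/(p_2-p_1)^2} (unpooled variance; a
#'     pooled-variance variant is available via `formula_id`);
#'   \item binary noninferiority: same numerator over
#'     \eqn{(\mathrm{margin} - (p_2-p_1))^2}, with \eqn{p_2 = p_1} as the
#'     default planning assumption.
#' }
#' \eqn{\alpha^* = \alpha/2} for two-sided designs, \eqn{\alpha} one-sided.
#'
#' @param spec A [design_spec()].
#' @param rounding `"ceiling"` (default, conservative) or `"nearest"`.
#' @param formula_id `"unpooled"` (default) or `"pooled"` variance for binary
#'   designs; the pooled variant uses
#'   \eqn{(z_{1-\alpha^*}\sqrt{2\bar p \bar q} + z_{1-\beta}
#'   \sqrt{p_1q_1+p_2q_2})^2} in the numerator.
#' @return A `sample_size_result`: list with `n_per_group_raw` (real-valued
#'   solution), `n_per_group` (integer, after rounding, at least 2),
#'   `rounding`, `formula_id`.
#' @export
#' @examples
#' # half-a-standard-deviation difference, 90% power, two-sided 5% alpha
#' sp <- design_spec("superiority", "continuous", alpha = 0.05, sides = "two",
#'                   power = 0.90, delta = 0.5, sd = 1)
#' n_per_group(sp, rounding = "nearest")$n_per_group  # 84
n_per_group <- function(spec, rounding = c("ceiling", "nearest"),
                        formula_id = c("unpooled", "pooled")) {
  tm_check(inherits(spec, "design_spec"), "`spec` must be a design_spec")
  rounding <- match.arg(rounding)
  formula_id <- match.arg(formula_id)
  n_raw <- n_raw_formula(spec, formula_id)
  if (spec$outcome == "continuous") formula_id <- "normal"
  n <- if (rounding == "ceiling") ceiling(n_raw) else round(n_raw)
  n_int <- if (is.finite(n) && n <= .Machine$integer.max)
    max(2L, as.integer(n)) else NA_integer_
  structure(list(n_per_group_raw = n_raw, n_per_group = n_int,
                 rounding = rounding, formula_id = formula_id),
            class = "sample_size_result")
}

# real-valued formula core, shared with the inverse solvers
n_raw_formula <- function(spec, formula_id = "unpooled") {
  zs <- z_sum(spec)
  if (spec$outcome == "continuous") {
    tm_check(is.numeric(spec$sd) && spec$sd > 0,
             "continuous designs need a planning sd > 0")
    eff <- if (spec$design == "superiority") spec$delta else spec$margin
    tm_check(is.numeric(eff) && length(eff) == 1L,
             "continuous designs need delta (superiority) or margin (noninferiority)")
    if (abs(eff) < 1e-12) {
      tm_stop("zero effect: sample size is unbounded", "tm_infeasible_design")
    }
    zs^2 * 2 * spec$sd^2 / eff^2
  } else {
    tm_check(!is.null(spec$p1) && !is.null(spec$p2),
             "binary designs need planning proportions p1, p2")
    p1 <- spec$p1; p2 <- spec$p2
    v_unpooled <- p1 * (1 - p1) + p2 * (1 - p2)
    denom <- if (spec$design == "superiority") {
      if (abs(p2 - p1) < 1e-12) {
        tm_stop("binary superiority with p1 = p2 has zero effect",
                "tm_infeasible_design")
      }
      (p2 - p1)^2
    } else {
      if (abs(spec$margin - (p2 - p1)) < 1e-12) {
        tm_stop("margin equal to the assumed true difference: infeasible design",
                "tm_infeasible_design")
      }
      (spec$margin - (p2 - p1))^2
    }
    if (formula_id == "unpooled") {
      zs^2 * v_unpooled / denom
    } else {
      astar <- if (spec$sides == "two") spec$alpha / 2 else spec$alpha
      pbar <- (p1 + p2) / 2
      (qnorm(1 - astar) * sqrt(2 * pbar * (1 - pbar)) +
         qnorm(spec$power) * sqrt(v_unpooled))^2 / denom
    }
  }
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat(sprintf("n per group: %d (raw %.4f, %s rounding, %s formula)\n",
              x$n_per_group, x$n_per_group_raw, x$rounding, x$formula_id))
  invisible(x)
}

#' Continuity-corrected sample size for binary outcomes
#'
#' Inflates a normal-approximation per-group sample size to approximate the
#' behaviour of Fisher's exact test, via the classical correction
#' \eqn{n' = (n/4)\,(1 + \sqrt{1 + 4/(n\,|d|)})^2} where \eqn{d} is the
#' difference in proportions. Always at least the uncorrected size.
#'
#' @param n_raw Uncorrected (real-valued) per-group sample size, > 0.
#' @param effect Difference in proportions, nonzero.
#' @return Corrected per-group size (real-valued; round afterwards).
#' @export
continuity_corrected_n <- function(n_raw, effect) {
  tm_check(is.numeric(n_raw) && n_raw > 0, "n_raw must be > 0")
  if (!is.numeric(effect) || effect == 0) {
    tm_stop("zero difference in proportions: correction undefined",
            "tm_infeasible_design")
  }
  (n_raw / 4) * (1 + sqrt(1 + 4 / (n_raw * abs(effect))))^2
}

#' Monte-Carlo power oracle
#'
#' Simulates trials under the planning parameters of a [design_spec()] and
#' returns the fraction rejecting the null -- the empirical power at a given
#' per-group size. Used to validate the closed forms in [n_per_group()]:
#' continuous designs are analyzed with the two-sample pooled-variance t test
#' (simulated via sufficient statistics), binary designs with the unpooled
#' two-proportion z test; noninferiority designs use the margin-shifted
#' one-sided test under true equality.
#'
#' @param spec A [design_spec()].
#' @param n Per-group sample size to simulate.
#' @param reps Number of simulated trials (>= 1000).
#' @param seed Integer seed; results are reproducible given the seed.
#' @return Rejection fraction in \[0, 1\].
#' @export
empirical_power <- function(spec, n, reps = 20000, seed = 1) {
  tm_check(inherits(spec, "design_spec"), "`spec` must be a design_spec")
  tm_check(reps >= 1000, "use at least 1000 replicates")
  tm_check(n >= 2, "n must be >= 2")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  astar <- if (spec$sides == "two") spec$alpha / 2 else spec$alpha

  if (spec$outcome == "continuous") {
    sd <- spec$sd
    true_diff <- if (spec$design == "superiority") spec$delta else 0
    shift <- if (spec$design == "noninferiority") spec$margin else 0
    xb1 <- rnorm(reps, 0, sd / sqrt(n))
    xb2 <- rnorm(reps, true_diff, sd / sqrt(n))
    df <- 2 * n - 2
    s2 <- sd^2 * rchisq(reps, df) / df
    tstat <- (xb2 - xb1 + shift) / sqrt(s2 * 2 / n)
    crit <- qt(1 - astar, df)
    rej <- if (spec$design == "superiority" && spec$sides == "two")
      abs(tstat) > crit else tstat > crit
  } else {
    p1 <- spec$p1
    p2_true <- if (spec$design == "superiority") spec$p2 else spec$p2
    shift <- if (spec$design == "noninferiority") spec$margin else 0
    x1 <- rbinom(reps, n, p1)
    x2 <- rbinom(reps, n, p2_true)
    ph1 <- x1 / n; ph2 <- x2 / n
    se <- sqrt(ph1 * (1 - ph1) / n + ph2 * (1 - ph2) / n)
    num <- ph2 - ph1 + shift
    z <- ifelse(se > 0, num / se, ifelse(num == 0, 0, sign(num) * Inf))
    crit <- qnorm(1 - astar)
    rej <- if (spec$design == "superiority" && spec$sides == "two")
      abs(z) > crit else z > crit
  }
  mean(rej)
}
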