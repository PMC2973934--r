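# Synthetic trial-registry generator, calibrated to the design-parameter
# structure of a 100 + 100 superiority/noninferiority sample.

REGISTRY_SCHEMA_VERSION <- "tm-registry-1"

REGISTRY_COLUMNS <- c(
  "trial_id", "design", "outcome", "alpha", "sides", "power", "n_per_group",
  "p1", "p2", "diff", "delta_means", "sd", "d_true",
  "context", "mortality", "multicenter", "pharmacological", "age_group",
  "funding", "year_band", "statistician",
  "std_diff", "scale", "provenance", "consistency")

registry_col_classes <- function() {
  c(trial_id = "integer", design = "character", outcome = "character",
    alpha = "numeric", sides = "character", power = "numeric",
    n_per_group = "integer", p1 = "numeric", p2 = "numeric",
    diff = "numeric", delta_means = "numeric", sd = "numeric",
    d_true = "numeric", context = "character", mortality = "logical",
    multicenter = "logical", pharmacological = "logical",
    age_group = "character", funding = "character", year_band = "character",
    statistician = "logical", std_diff = "numeric", scale = "character",
    provenance = "character", consistency = "numeric")
}

default_covariate_freqs <- function() {
  list(
    superiority = list(
      context = c(cardiovascular = 0.14, infectious = 0.03,
                  oncology = 0.06, other = 0.77),
      mortality = 0.12, multicenter = 0.67, pharmacological = 0.54,
      age_group = c(children = 0.18, adults = 0.77, elderly = 0.05),
      funding = c(industry = 0.50, institution = 0.33,
                  none_or_unstated = 0.17),
      year_band = c(`2004-06` = 0.59, `2007-09` = 0.41),
      statistician = 0.46),
    noninferiority = list(
      context = c(cardiovascular = 0.19, infectious = 0.23,
                  oncology = 0.10, other = 0.48),
      mortality = 0.19, multicenter = 0.86, pharmacological = 0.73,
      age_group = c(children = 0.18, adults = 0.82, elderly = 0.00),
      funding = c(industry = 0.70, institution = 0.25,
                  none_or_unstated = 0.05),
      year_band = c(`2004-06` = 0.59, `2007-09` = 0.41),
      statistician = 0.54))
}

#' Configuration of the synthetic trial registry
#'
#' The defaults encode the stated world the generator emulates: 100
#' superiority plus 100 noninferiority two-arm trials; dichotomous primary
#' outcomes in 60% of superiority and 86% of noninferiority trials; true
#' standardized differences drawn per (design x outcome-scale) stratum from a
#' normal truncated to `d_bounds`, with stratum means/SDs 0.37 (0.20) and
#' 0.56 (0.30) for superiority proportions/means and 0.27 (0.12) and
#' 0.40 (0.11) for noninferiority; covariate marginals from the published
#' sample composition; a 19.5% masking rate creating the imputation workload.
#'
#' @param n_superiority,n_noninferiority Number of trials per design.
#' @param binary_fraction Named fractions of binary-outcome trials per design.
#' @param d_strata Per-design, per-scale `c(mean, sd)` of the true
#'   standardized-difference distribution.
#' @param d_family `"truncated-normal"` (default) or `"lognormal"` (matched
#'   by moments, then truncated to the same bounds).
#' @param d_bounds Truncation bounds for the standardized difference; the
#'   lower bound keeps the sample-size formulas finite, the upper reflects
#'   the largest planning differences seen in practice.
#' @param alpha,sides Named per-design type I error and sidedness
#'   conventions: superiority two-sided 0.05, noninferiority one-sided 0.025.
#' @param power_levels,power_probs Mixture over target powers; the default
#'   0.6/0.4 mix of 0.80 and 0.90 reproduces a median power of 0.80 with
#'   upper quartile 0.90.
#' @param p1_range Uniform range for the baseline event proportion of binary
#'   trials.
#' @param sd_lognormal `c(meanlog, sdlog)` of the outcome-unit SD draw for
#'   continuous trials (scale-free downstream: only delta/sd matters).
#' @param covariates Per-design covariate marginal frequencies.
#' @param masking_rate Fraction of records whose effect parameters are hidden
#'   by [mask_fields()].
#' @param rounding Rounding mode for the reported per-group sample size.
#' @return An object of class `registry_config`.
#' @export
registry_config <- function(n_superiority = 100, n_noninferiority = 100,
                            binary_fraction = c(superiority = 0.60,
                                                noninferiority = 0.86),
                            d_strata = list(
                              superiority = list(
                                proportions = c(mean = 0.37, sd = 0.20),
                                means = c(mean = 0.56, sd = 0.30)),
                              noninferiority = list(
                                proportions = c(mean = 0.27, sd = 0.12),
                                means = c(mean = 0.40, sd = 0.11))),
                            d_family = c("truncated-normal", "lognormal"),
                            d_bounds = c(0.01, 1.6),
                            alpha = c(superiority = 0.05,
                                      noninferiority = 0.025),
                            sides = c(superiority = "two",
                                      noninferiority = "one"),
                            power_levels = c(0.80, 0.90),
                            power_probs = c(0.6, 0.4),
                            p1_range = c(0.1, 0.7),
                            sd_lognormal = c(meanlog = log(10), sdlog = 0.5),
                            covariates = default_covariate_freqs(),
                            masking_rate = 0.195,
                            rounding = c("ceiling", "nearest")) {
  d_family <- match.arg(d_family)
  rounding <- match.arg(rounding)
  tm_check(n_superiority >= 0 && n_noninferiority >= 0, "negative trial counts")
  tm_check(all(binary_fraction >= 0 & binary_fraction <= 1),
           "binary fractions must be in [0, 1]")
  tm_check(masking_rate >= 0 && masking_rate < 1,
           "masking_rate must be in [0, 1)")
  tm_check(all(vapply(d_strata, function(s)
    all(vapply(s, function(x) x[["mean"]] > 0 && x[["sd"]] > 0, logical(1))),
    logical(1))), "stratum means and sds must be > 0")
  tm_check(abs(sum(power_probs) - 1) < 1e-12, "power_probs must sum to 1")
  structure(list(n_superiority = n_superiority,
                 n_noninferiority = n_noninferiority,
                 binary_fraction = binary_fraction, d_strata = d_strata,
                 d_family = d_family, d_bounds = d_bounds, alpha = alpha,
                 sides = sides, power_levels = power_levels,
                 power_probs = power_probs, p1_range = p1_range,
                 sd_lognormal = sd_lognormal, covariates = covariates,
                 masking_rate = masking_rate, rounding = rounding),
            class = "registry_config")
}

# draw from the configured standardized-difference distribution, truncated
draw_d <- function(n, mean, sd, family, bounds) {
  out <- numeric(0)
  for (tries in 1:200) {
    m <- max(2L * (n - length(out)), 16L)
    x <- if (family == "truncated-normal") {
      rnorm(m, mean, sd)
    } else {
      sdlog <- sqrt(log(1 + sd^2 / mean^2))
      rlnorm(m, log(mean) - sdlog^2 / 2, sdlog)
    }
    out <- c(out, x[x > bounds[1] & x < bounds[2]])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  tm_stop("standardized-difference draws keep falling outside bounds",
          "tm_config_error")
}

# p2 - p1 solving (p2-p1)/sqrt(Pbar(1-Pbar)) = d at equal allocation
prop_spread_for_d <- function(p1, d) {
  a <- 1 + d^2 / 4
  b <- -d^2 * (1 - 2 * p1) / 2
  cc <- -d^2 * p1 * (1 - p1)
  (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
}

#' Generate a synthetic trial registry
#'
#' Draws, per trial: design and outcome type (fixed stratum counts per the
#' configured composition), covariates from their marginal frequencies, a
#' true standardized difference from its (design x scale) stratum
#' distribution, then converts it to outcome parameters -- binary: baseline
#' `p1` uniform in `p1_range` and `p2` placed so the standardized difference
#' matches (superiority) or a margin on the proportion scale with planning
#' `p2 = p1` (noninferiority); continuous: an outcome-unit SD and
#' `delta_means = d * sd`. The reported per-group sample size is computed
#' through [n_per_group()], so every generated record is internally
#' consistent up to rounding. Output is byte-reproducible given `seed`.
#'
#' @param config A [registry_config()].
#' @param seed Integer seed.
#' @return Registry data frame (one row per trial; derived columns
#'   `std_diff`, `scale`, `provenance`, `consistency` left empty for
#'   [extract_registry()] to fill). The generator's ground truth is kept in
#'   `d_true`.
#' @export
generate_registry <- function(config = registry_config(), seed = 1) {
  tm_check(inherits(config, "registry_config"),
           "`config` must be a registry_config")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  rows <- list()
  id <- 0L
  for (design in c("superiority", "noninferiority")) {
    nd <- if (design == "superiority") config$n_superiority else
      config$n_noninferiority
    if (nd == 0) next
    n_bin <- round(config$binary_fraction[[design]] * nd)
    outcome <- sample(rep(c("binary", "continuous"), c(n_bin, nd - n_bin)))
    cv <- config$covariates[[design]]
    for (i in seq_len(nd)) {
      id <- id + 1L
      out_i <- outcome[i]
      scale_i <- if (out_i == "binary") "proportions" else "means"
      st <- config$d_strata[[design]][[scale_i]]
      d <- draw_d(1L, st[["mean"]], st[["sd"]], config$d_family,
                  config$d_bounds)
      power <- sample(config$power_levels, 1L, prob = config$power_probs)
      alpha <- config$alpha[[design]]
      sides <- config$sides[[design]]

      p1 <- p2 <- diff <- delta_means <- sdv <- NA_real_
      if (out_i == "binary") {
        ok <- FALSE
        for (try in 1:200) {
          p1c <- runif(1, config$p1_range[1], config$p1_range[2])
          if (design == "superiority") {
            s <- prop_spread_for_d(p1c, d)
            if (is.finite(s) && p1c + s < 0.995) {
              p1 <- p1c; p2 <- p1c + s; diff <- s; ok <- TRUE; break
            }
          } else {
            m <- d * sqrt(p1c * (1 - p1c))
            if (m > 0 && m < 1) {
              p1 <- p1c; p2 <- p1c; diff <- m; ok <- TRUE; break
            }
          }
        }
        if (!ok) {
          tm_stop(sprintf(
            "stratum %s/%s: standardized difference %.3f unattainable for baselines in [%.2f, %.2f]",
            design, scale_i, d, config$p1_range[1], config$p1_range[2]),
            "tm_config_error")
        }
        sp <- if (design == "superiority") {
          design_spec(design, "binary", alpha = alpha, sides = sides,
                      power = power, p1 = p1, p2 = p2)
        } else {
          design_spec(design, "binary", alpha = alpha, sides = sides,
                      power = power, p1 = p1, p2 = p2, margin = diff)
        }
      } else {
        sdv <- rlnorm(1, config$sd_lognormal[["meanlog"]],
                      config$sd_lognormal[["sdlog"]])
        delta_means <- d * sdv
        sp <- if (design == "superiority") {
          design_spec(design, "continuous", alpha = alpha, sides = sides,
                      power = power, delta = delta_means, sd = sdv)
        } else {
          design_spec(design, "continuous", alpha = alpha, sides = sides,
                      margin = delta_means, sd = sdv, power = power)
        }
      }
      n_rep <- n_per_group(sp, rounding = config$rounding)$n_per_group

      rows[[id]] <- data.frame(
        trial_id = id, design = design, outcome = out_i, alpha = alpha,
        sides = sides, power = power, n_per_group = n_rep,
        p1 = p1, p2 = p2, diff = diff, delta_means = delta_means, sd = sdv,
        d_true = d,
        context = sample(names(cv$context), 1L, prob = cv$context),
        mortality = runif(1) < cv$mortality,
        multicenter = runif(1) < cv$multicenter,
        pharmacological = runif(1) < cv$pharmacological,
        age_group = sample(names(cv$age_group), 1L, prob = cv$age_group),
        funding = sample(names(cv$funding), 1L, prob = cv$funding),
        year_band = sample(names(cv$year_band), 1L, prob = cv$year_band),
        statistician = runif(1) < cv$statistician,
        std_diff = NA_real_, scale = NA_character_,
        provenance = NA_character_, consistency = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  reg <- do.call(rbind, rows)
  rownames(reg) <- NULL
  reg
}

#' Hide effect parameters to create an imputation workload
#'
#' Selects a fixed-size uniform random subset of `round(masking_rate * n)`
#' records and hides the parameters a published report most often omits:
#' binary records lose both proportions but keep the difference (or margin);
#' continuous records lose the SD. Every masked record remains
#' reconstructible from its reported sample size.
#'
#' @param registry Registry data frame.
#' @param masking_rate Fraction of records to mask (default from the config
#'   that generated the registry is 0.195).
#' @param seed Integer seed for the subset draw.
#' @return The registry with masked fields set to `NA`.
#' @export
mask_fields <- function(registry, masking_rate = 0.195, seed = 1) {
  tm_check(is.data.frame(registry), "`registry` must be a data frame")
  tm_check(masking_rate >= 0 && masking_rate <= 1,
           "masking_rate must be in [0, 1]")
  k <- round(masking_rate * nrow(registry))
  if (k == 0) return(registry)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  idx <- sample(nrow(registry), k)
  for (i in idx) {
    if (registry$outcome[i] == "binary") {
      registry$p1[i] <- NA_real_
      registry$p2[i] <- NA_real_
    } else {
      registry$sd[i] <- NA_real_
    }
  }
  registry
}

#' Write / read the registry CSV
#'
#' Lossless round-trip with a fixed, versioned header. Missing values are
#' written as empty fields. Reading checks the header exactly and fails with
#' a schema error naming the offending column.
#'
#' @param registry Registry data frame.
#' @param path File path.
#' @return `read_registry` returns the registry data frame; `write_registry`
#'   returns `path` invisibly.
#' @export
write_registry <- function(registry, path) {
  tm_check(is.data.frame(registry), "`registry` must be a data frame")
  missing_cols <- setdiff(REGISTRY_COLUMNS, names(registry))
  tm_check(length(missing_cols) == 0,
           paste("registry lacks column(s):",
                 paste(missing_cols, collapse = ", ")), "tm_schema_error")
  write.csv(registry[, REGISTRY_COLUMNS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  tm_check(file.exists(path), sprintf("no such file: %s", path))
  header <- names(read.csv(path, nrows = 0, check.names = FALSE))
  extra <- setdiff(header, REGISTRY_COLUMNS)
  if (length(extra)) {
    tm_stop(paste("unknown registry column(s):", paste(extra, collapse = ", ")),
            "tm_schema_error")
  }
  missing_cols <- setdiff(REGISTRY_COLUMNS, header)
  if (length(missing_cols)) {
    tm_stop(paste("registry file lacks column(s):",
                  paste(missing_cols, collapse = ", ")), "tm_schema_error")
  }
  cls <- registry_col_classes()
  read.csv(path, colClasses = unname(cls[header]), na.strings = "",
           check.names = FALSE)
}
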