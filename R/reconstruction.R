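# Inverse power analysis: recover planning parameters that a published report
# omitted, by inverting the sample-size formulas at the reported n.

#' Recover planning proportions from a reported sample size
#'
#' Inverts the binary sample-size formula at the reported per-group size. The
#' supported situations mirror what trial reports actually omit:
#' \itemize{
#'   \item `p1` and `diff` both known: `p2 = p1 + diff` directly.
#'   \item `p1` known, difference unknown (superiority): root-find `p2` on the
#'     side of `p1` given by `direction`; without a stated direction the two
#'     sides genuinely differ, so an ambiguity error is raised rather than a
#'     silent choice.
#'   \item difference (or margin) known, baseline unknown: solve for `p1`
#'     under the constraint `p2 = p1 + diff` (superiority) or `p2 = p1`
#'     (noninferiority). Two admissible roots always exist, reflections
#'     `(p1, p2) -> (1 - p2, 1 - p1)` with identical variance term and pooled
#'     proportion -- the standardized difference is invariant -- so the root
#'     with pooled proportion at most 1/2 is returned deterministically.
#' }
#'
#' @param spec A [design_spec()] carrying design type, alpha, sidedness,
#'   power (its `p1`/`p2` fields are ignored; the margin is taken from
#'   `diff` or from the spec for noninferiority designs).
#' @param n_reported Reported per-group sample size (>= 2). Inversion is on
#'   the pre-rounding formula; an integer `n_reported` induces a small
#'   rounding-bounded perturbation, surfaced via
#'   [verify_reported_sample_size()].
#' @param p1 Baseline proportion, if known.
#' @param diff Reported difference in proportions (superiority) or margin
#'   (noninferiority), if known.
#' @param direction `"increase"` or `"decrease"`: stated direction of benefit,
#'   needed only when root-finding `p2` from a known `p1`.
#' @param tol Root tolerance in `p2`.
#' @return List with `p1`, `p2`, and `diff` (signed difference used).
#' @export
solve_p2 <- function(spec, n_reported, p1 = NULL, diff = NULL,
                     direction = NULL, tol = 1e-10) {
  tm_check(inherits(spec, "design_spec"), "`spec` must be a design_spec")
  tm_check(is.numeric(n_reported) && n_reported >= 2, "n_reported must be >= 2")
  K <- z_sum(spec)^2

  if (spec$design == "noninferiority") {
    margin <- if (!is.null(diff)) diff else spec$margin
    tm_check(is.numeric(margin) && margin > 0,
             "noninferiority inversion needs a margin > 0")
    if (!is.null(p1)) {
      return(list(p1 = p1, p2 = p1, diff = margin))
    }
    # n = K * 2 p1 q1 / margin^2  =>  p1 q1 = n margin^2 / (2K)
    pq <- n_reported * margin^2 / (2 * K)
    if (pq > 0.25) {
      # integer n induces an interval of admissible parameters; if n - 1 is
      # feasible the infeasibility is rounding-induced -> boundary p = 1/2
      if ((n_reported - 1) * margin^2 / (2 * K) <= 0.25) {
        pq <- 0.25
      } else {
        tm_stop(sprintf(
          "no root in (0,1): reported n = %.6g needs p(1-p) = %.4g > 0.25 at margin %.4g",
          n_reported, pq, margin), "tm_reconstruction_infeasible",
          pq_required = pq)
      }
    }
    p1 <- (1 - sqrt(1 - 4 * pq)) / 2
    return(list(p1 = p1, p2 = p1, diff = margin))
  }

  # superiority
  if (!is.null(p1) && !is.null(diff)) {
    p2 <- p1 + diff
    tm_check(p2 > 0 && p2 < 1, "p1 + diff falls outside (0, 1)",
             "tm_reconstruction_infeasible")
    return(list(p1 = p1, p2 = p2, diff = diff))
  }

  if (is.null(p1) && !is.null(diff)) {
    d <- abs(diff)
    tm_check(d > 0, "zero difference cannot be inverted",
             "tm_reconstruction_infeasible")
    # p1 q1 + p2 q2 with p2 = a + d equals -2a^2 + 2a(1-d) + d - d^2
    V <- n_reported * d^2 / K
    disc <- (1 - d)^2 - 2 * (V - d + d^2)
    if (disc < 0) {
      # rounding-induced infeasibility: accept the boundary (pooled mean 1/2)
      V_floor <- (n_reported - 1) * d^2 / K
      if ((1 - d)^2 - 2 * (V_floor - d + d^2) >= 0) {
        disc <- 0
      } else {
        tm_stop(sprintf(
          "no root in (0,1): variance term %.4g unattainable for diff %.4g (max %.4g)",
          V, d, ((1 - d)^2) / 2 + d - d^2), "tm_reconstruction_infeasible",
          variance_required = V)
      }
    }
    a <- ((1 - d) - sqrt(disc)) / 2          # pooled mean <= 1/2 root
    if (a <= 0 || a + d >= 1) {
      tm_stop("recovered baseline falls outside (0, 1)",
              "tm_reconstruction_infeasible", root = a)
    }
    if (diff >= 0) return(list(p1 = a, p2 = a + d, diff = diff))
    return(list(p1 = a + d, p2 = a, diff = diff))
  }

  if (!is.null(p1) && is.null(diff)) {
    if (is.null(direction)) {
      tm_stop("two admissible roots (above and below p1) and no stated direction of benefit",
              "tm_ambiguous_root")
    }
    direction <- match.arg(direction, c("increase", "decrease"))
    eps <- 1e-9
    f <- function(p2) {
      sp <- spec; sp$p1 <- p1; sp$p2 <- p2
      n_raw_formula(sp) - n_reported
    }
    br <- if (direction == "increase") c(p1 + eps, 1 - eps) else c(eps, p1 - eps)
    lo <- f(br[1]); hi <- f(br[2])
    if (!is.finite(lo) || !is.finite(hi) || sign(lo) == sign(hi)) {
      tm_stop(sprintf(
        "no root bracketed for p2 in (%.3g, %.3g): f = %.4g .. %.4g at n_reported = %.6g",
        br[1], br[2], lo, hi, n_reported), "tm_reconstruction_infeasible",
        bracket = br, f_bracket = c(lo, hi))
    }
    p2 <- uniroot(f, br, tol = tol)$root
    return(list(p1 = p1, p2 = p2, diff = p2 - p1))
  }

  tm_stop("need at least one of p1 or the reported difference",
          "tm_reconstruction_required")
}

#' Recover the planning standard deviation from a reported sample size
#'
#' Closed-form inverse of the continuous formula:
#' \eqn{\sigma = |\delta| \sqrt{n/2} / (z_{1-\alpha^*} + z_{1-\beta})}.
#' Feeding the result back through [n_per_group()] reproduces `n_reported`
#' exactly (pre-rounding).
#'
#' @inheritParams solve_p2
#' @param delta Reported difference in means (or margin), nonzero.
#' @return The recovered standard deviation.
#' @export
solve_sd <- function(spec, n_reported, delta) {
  tm_check(inherits(spec, "design_spec"), "`spec` must be a design_spec")
  tm_check(is.numeric(n_reported) && n_reported >= 2, "n_reported must be >= 2")
  if (!is.numeric(delta) || delta == 0) {
    tm_stop("zero difference in means cannot be inverted",
            "tm_reconstruction_infeasible")
  }
  abs(delta) * sqrt(n_reported / 2) / z_sum(spec)
}

# Build the design_spec implied by a complete registry record (internal).
record_spec <- function(rec) {
  if (rec$outcome == "binary") {
    if (rec$design == "superiority") {
      design_spec("superiority", "binary", alpha = rec$alpha,
                  sides = rec$sides, power = rec$power,
                  p1 = rec$p1, p2 = rec$p2)
    } else {
      design_spec("noninferiority", "binary", alpha = rec$alpha,
                  sides = rec$sides, power = rec$power,
                  p1 = rec$p1, p2 = rec$p2, margin = rec$diff)
    }
  } else {
    if (rec$design == "superiority") {
      design_spec("superiority", "continuous", alpha = rec$alpha,
                  sides = rec$sides, power = rec$power,
                  delta = rec$delta_means, sd = rec$sd)
    } else {
      design_spec("noninferiority", "continuous", alpha = rec$alpha,
                  sides = rec$sides, power = rec$power,
                  margin = rec$delta_means, sd = rec$sd)
    }
  }
}

has_val <- function(x) !is.null(x) && length(x) == 1L && !is.na(x)

#' Check a reported sample size against the recomputed one
#'
#' Recomputes the pre-rounding per-group sample size from a record's complete
#' planning parameters and returns the relative gap
#' \eqn{|n_{recomputed} - n_{reported}| / n_{reported}}. Self-generated
#' records show only the rounding gap (< 0.5/n for nearest rounding, < 1/n
#' for ceiling); larger gaps flag internally inconsistent reports. The default
#' irreconcilability threshold used by [validate_registry()] is 0.15.
#'
#' @param rec A registry record (named list or one-row data frame).
#' @return Nonnegative relative gap.
#' @export
verify_reported_sample_size <- function(rec) {
  rec <- as.list(rec)
  needed <- c("design", "outcome", "alpha", "sides", "power", "n_per_group")
  if (!all(vapply(rec[needed], has_val, logical(1)))) {
    tm_stop("record lacks planning parameters; reconstruct them first",
            "tm_reconstruction_required")
  }
  complete <- if (rec$outcome == "binary") {
    has_val(rec$p1) && has_val(rec$p2) &&
      (rec$design == "superiority" || has_val(rec$diff))
  } else {
    has_val(rec$delta_means) && has_val(rec$sd)
  }
  if (!complete) {
    tm_stop("record lacks effect parameters; reconstruct them first",
            "tm_reconstruction_required")
  }
  n_raw <- n_per_group(record_spec(rec))$n_per_group_raw
  abs(n_raw - rec$n_per_group) / rec$n_per_group
}

#' Extract (or reconstruct) a record's standardized difference
#'
#' The extraction decision tree applied to one registry record:
#' \enumerate{
#'   \item effect parameters complete (both proportions, or mean difference
#'     plus SD): compute the standardized difference directly
#'     (`provenance = "direct"`);
#'   \item binary with the difference/margin but missing proportions: recover
#'     them with [solve_p2()] from the reported sample size, then compute
#'     (`provenance = "imputed"`);
#'   \item continuous without an SD: recover it with [solve_sd()], then
#'     compute (`provenance = "imputed"`).
#' }
#' A record fitting no branch raises an unextractable-record error (class
#' `tm_unextractable`), which [extract_registry()] counts rather than
#' propagates. For noninferiority designs the quantity standardized is the
#' margin (the largest difference to be ruled out), evaluated at the planning
#' proportions / SD.
#'
#' @param rec A registry record (named list or one-row data frame).
#' @return List with `std_diff` (a `standardized_difference`), `recovered`
#'   (named list of reconstructed parameters, empty iff provenance is
#'   direct), and `consistency` (relative reported-vs-recomputed sample-size
#'   gap, `NA` when planning parameters are unavailable).
#' @export
extract_standardized_difference <- function(rec) {
  rec <- as.list(rec)
  tm_check(has_val(rec$design) && has_val(rec$outcome),
           "record needs design and outcome type")
  recovered <- list()

  if (rec$outcome == "binary") {
    if (!(has_val(rec$p1) && has_val(rec$p2))) {
      if (!has_val(rec$diff)) {
        tm_stop("binary record with neither proportions nor difference",
                "tm_unextractable")
      }
      needed <- c("alpha", "sides", "power", "n_per_group")
      if (has_val(rec$p1)) {
        # difference determines p2 given p1 (superiority); NI planning p2 = p1
        sol <- list(
          p1 = rec$p1,
          p2 = if (rec$design == "superiority") rec$p1 + rec$diff else rec$p1)
        recovered$p2 <- sol$p2
      } else {
        if (!all(vapply(rec[needed], has_val, logical(1)))) {
          tm_stop("binary record not reconstructible: missing design parameters",
                  "tm_unextractable")
        }
        sp <- design_spec(rec$design, "binary", alpha = rec$alpha,
                          sides = rec$sides, power = rec$power,
                          p1 = 0.5, p2 = 0.5,
                          margin = if (rec$design == "noninferiority") rec$diff)
        sol <- solve_p2(sp, rec$n_per_group, p1 = NULL, diff = rec$diff)
        recovered$p1 <- sol$p1
        recovered$p2 <- sol$p2
      }
      rec$p1 <- sol$p1; rec$p2 <- sol$p2
    }
    pbar <- weighted_mean_proportion(rec$p1, rec$p2)
    eff <- if (rec$design == "superiority") rec$p2 - rec$p1 else rec$diff
    sdiff <- new_standardized_difference(
      eff / sqrt(pbar * (1 - pbar)), "proportions",
      if (length(recovered)) "imputed" else "direct")
  } else {
    if (!has_val(rec$delta_means)) {
      tm_stop("continuous record without a difference in means",
              "tm_unextractable")
    }
    if (!has_val(rec$sd)) {
      needed <- c("alpha", "sides", "power", "n_per_group")
      if (!all(vapply(rec[needed], has_val, logical(1)))) {
        tm_stop("continuous record not reconstructible: missing design parameters",
                "tm_unextractable")
      }
      sp <- design_spec(rec$design, "continuous", alpha = rec$alpha,
                        sides = rec$sides, power = rec$power,
                        delta = rec$delta_means, sd = 1,
                        margin = if (rec$design == "noninferiority")
                          rec$delta_means)
      rec$sd <- solve_sd(sp, rec$n_per_group, rec$delta_means)
      recovered$sd <- rec$sd
    }
    sdiff <- standardized_difference_means(
      0, rec$delta_means, sd = rec$sd,
      provenance = if (length(recovered)) "imputed" else "direct")
  }

  consistency <- tryCatch(verify_reported_sample_size(rec),
                          tm_reconstruction_required = function(e) NA_real_)
  list(std_diff = sdiff, recovered = recovered, consistency = consistency)
}

#' Run extraction across a whole registry
#'
#' Applies [extract_standardized_difference()] to every row, filling the
#' derived columns `std_diff`, `scale`, `provenance`, `consistency`.
#' Unextractable records are kept with `provenance = "unextractable"` and
#' `std_diff = NA`; their count mirrors the reports a reviewer must exclude.
#'
#' @param registry Registry data frame (see [generate_registry()] for the
#'   schema).
#' @return The registry with derived columns filled; counts of direct,
#'   imputed, and unextractable records are attached as attribute
#'   `extraction_counts`.
#' @export
extract_registry <- function(registry) {
  tm_check(is.data.frame(registry), "`registry` must be a data frame")
  n <- nrow(registry)
  registry$std_diff <- NA_real_
  registry$scale <- NA_character_
  registry$provenance <- NA_character_
  registry$consistency <- NA_real_
  for (i in seq_len(n)) {
    res <- tryCatch(extract_standardized_difference(registry[i, ]),
                    tm_unextractable = function(e) NULL)
    if (is.null(res)) {
      registry$provenance[i] <- "unextractable"
      next
    }
    registry$std_diff[i] <- res$std_diff$value
    registry$scale[i] <- res$std_diff$scale
    registry$provenance[i] <- res$std_diff$provenance
    registry$consistency[i] <- res$consistency
  }
  counts <- c(direct = sum(registry$provenance == "direct", na.rm = TRUE),
              imputed = sum(registry$provenance == "imputed", na.rm = TRUE),
              unextractable = sum(registry$provenance == "unextractable",
                                  na.rm = TRUE))
  attr(registry, "extraction_counts") <- counts
  registry
}
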