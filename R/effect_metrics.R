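#' Weighted mean of two event proportions
#'
#' Pools the control- and experimental-arm event proportions into the overall
#' proportion \eqn{\bar P} used as the denominator basis of the standardized
#' difference in proportions. Weights are the arm sizes; when arm sizes are
#' unknown, 1:1 allocation is assumed and the simple midpoint is returned.
#'
#' @param p1,p2 Event proportions in the control and experimental arm, in
#'   \eqn{[0, 1]}.
#' @param n1,n2 Optional arm sizes (counts, at least 1). Both must be given or
#'   both omitted.
#' @return The pooled proportion, a numeric scalar within
#'   \eqn{[\min(p_1,p_2), \max(p_1,p_2)]}.
#' @details A pooled proportion of exactly 0 or 1 makes the standardized
#'   difference denominator \eqn{\sqrt{\bar P(1-\bar P)}} vanish, so it is
#'   signalled as a degenerate-input error rather than returned.
#' @seealso [standardized_difference_proportions()]
#' @export
#' @examples
#' weighted_mean_proportion(0.2, 0.3)            # 0.25
#' weighted_mean_proportion(0.2, 0.3, 100, 300)  # 0.275
weighted_mean_proportion <- function(p1, p2, n1 = NULL, n2 = NULL) {
  chk_prob(p1, "p1", open = FALSE)
  chk_prob(p2, "p2", open = FALSE)
  if (is.null(n1) != is.null(n2)) {
    tm_stop("supply both arm sizes or neither", "tm_invalid_input")
  }
  if (is.null(n1)) {
    pbar <- (p1 + p2) / 2
  } else {
    tm_check(n1 >= 1 && n2 >= 1, "arm sizes must be >= 1")
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  }
  if (pbar <= 0 || pbar >= 1) {
    tm_stop(sprintf("pooled proportion %.4g is degenerate: denominator sqrt(P(1-P)) vanishes",
                    pbar), "tm_degenerate_input")
  }
  pbar
}

new_standardized_difference <- function(value, scale, provenance = "direct") {
  tm_check(is.finite(value), "standardized difference must be finite",
           "tm_degenerate_input")
  structure(list(value = value,
                 scale = match.arg(scale, c("proportions", "means")),
                 provenance = match.arg(provenance, c("direct", "imputed"))),
            class = "standardized_difference")
}

#' @export
print.standardized_difference <- function(x, ...) {
  cat(sprintf("standardized difference (%s, %s): %.5f\n",
              x$scale, x$provenance, x$value))
  invisible(x)
}

#' Standardized difference in proportions
#'
#' \eqn{(P_2 - P_1)/\sqrt{\bar P(1-\bar P)}}, where \eqn{\bar P} is the
#' weighted mean of the two proportions (see [weighted_mean_proportion()]).
#' This is the binary-outcome analogue of the standardized mean difference,
#' putting planning differences from trials with dichotomous and continuous
#' primary outcomes on one unitless scale.
#'
#' @inheritParams weighted_mean_proportion
#' @param provenance `"direct"` when both proportions were observed,
#'   `"imputed"` when a missing parameter was reconstructed upstream.
#' @return A `standardized_difference` object (fields `value`, `scale`,
#'   `provenance`). The sign convention is experimental minus control.
#' @export
#' @examples
#' standardized_difference_proportions(0.2, 0.3)$value  # 0.23094
standardized_difference_proportions <- function(p1, p2, n1 = NULL, n2 = NULL,
                                                provenance = "direct") {
  pbar <- weighted_mean_proportion(p1, p2, n1, n2)
  new_standardized_difference((p2 - p1) / sqrt(pbar * (1 - pbar)),
                              "proportions", provenance)
}

#' Pooled standard deviation of two arms
#'
#' Student-t pooled estimator
#' \eqn{\sqrt{((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}}. When the two SDs
#' are equal the result equals them regardless of arm sizes.
#'
#' @param sd1,sd2 Per-arm standard deviations, strictly positive.
#' @param n1,n2 Arm sizes, at least 2.
#' @return Pooled SD (numeric scalar).
#' @export
pooled_sd <- function(sd1, sd2, n1, n2) {
  tm_check(is.numeric(sd1) && is.numeric(sd2) && sd1 > 0 && sd2 > 0,
           "per-arm standard deviations must be > 0")
  tm_check(n1 >= 2 && n2 >= 2, "arm sizes must be >= 2 to pool SDs")
  sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
}

#' Standardized difference in means
#'
#' \eqn{(m_2 - m_1)/SD} with `SD` the pooled standard deviation. If a pooled
#' `sd` is not supplied it is formed from per-arm SDs via [pooled_sd()]; if a
#' single per-arm SD is available it is used directly (the fallback used when
#' only the results-section SD is reported).
#'
#' @param m1,m2 Control and experimental arm means (outcome units).
#' @param sd Pooled standard deviation (optional if per-arm SDs given).
#' @param sd1,sd2 Per-arm SDs, used with `n1`, `n2` to pool when `sd` absent.
#' @param n1,n2 Arm sizes for pooling.
#' @inheritParams standardized_difference_proportions
#' @return A `standardized_difference` object with `scale = "means"`.
#' @export
#' @examples
#' standardized_difference_means(0, 5, sd = 10)$value  # 0.5
standardized_difference_means <- function(m1, m2, sd = NULL,
                                          sd1 = NULL, sd2 = NULL,
                                          n1 = NULL, n2 = NULL,
                                          provenance = "direct") {
  tm_check(is.numeric(m1) && is.numeric(m2), "arm means must be numeric")
  if (is.null(sd)) {
    if (!is.null(sd1) && !is.null(sd2) && !is.null(n1) && !is.null(n2)) {
      sd <- pooled_sd(sd1, sd2, n1, n2)
    } else if (!is.null(sd1) && is.null(sd2)) {
      sd <- sd1
    } else if (!is.null(sd2) && is.null(sd1)) {
      sd <- sd2
    } else {
      tm_stop("no usable standard deviation: reconstruct it from the reported sample size (see solve_sd)",
              "tm_reconstruction_required")
    }
  }
  tm_check(sd > 0, "standard deviation must be > 0", "tm_degenerate_input")
  new_standardized_difference((m2 - m1) / sd, "means", provenance)
}
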