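# Independent oracles used across test files.

# Brute-force least-squares fit via normal equations on a hand-built
# indicator matrix (treatment coding), plus balanced marginal means by
# direct enumeration. Independent of lm()/model.matrix() paths used by the
# implementation beyond base solve().
ls_adjusted_means_oracle <- function(df, predictors, response = "std_diff") {
  y <- abs(df[[response]])
  levs <- lapply(df[predictors], function(x) sort(unique(as.character(x))))
  X <- matrix(1, nrow = nrow(df), ncol = 1)
  colnames(X) <- "(Intercept)"
  for (p in predictors) {
    for (l in levs[[p]][-1]) {
      X <- cbind(X, as.numeric(as.character(df[[p]]) == l))
      colnames(X)[ncol(X)] <- paste0(p, l)
    }
  }
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  resid <- y - X %*% beta
  s2 <- sum(resid^2) / (nrow(X) - ncol(X))
  V <- s2 * solve(XtX)

  pred_row <- function(assign) {
    # indicator row for one full level assignment
    v <- c(1)
    for (p in predictors) {
      for (l in levs[[p]][-1]) v <- c(v, as.numeric(assign[[p]] == l))
    }
    v
  }
  out <- list()
  for (p in predictors) {
    others <- setdiff(predictors, p)
    for (l in levs[[p]]) {
      combos <- expand.grid(lapply(levs[others], identity),
                            stringsAsFactors = FALSE)
      if (nrow(combos) == 0) combos <- data.frame(row.names = 1)
      cvec <- 0
      for (j in seq_len(nrow(combos))) {
        assign <- c(setNames(list(l), p),
                    as.list(combos[j, , drop = FALSE]))
        names(assign) <- c(p, others)
        cvec <- cvec + pred_row(assign)
      }
      cvec <- cvec / max(nrow(combos), 1)
      out[[paste(p, l, sep = ":")]] <- c(
        mean = drop(cvec %*% beta),
        se = sqrt(drop(t(cvec) %*% V %*% cvec)))
    }
  }
  out
}

# minimal complete registry row for record-level tests
make_record <- function(design = "superiority", outcome = "binary",
                        alpha = 0.05, sides = "two", power = 0.80,
                        n_per_group = NA, p1 = NA, p2 = NA, diff = NA,
                        delta_means = NA, sd = NA) {
  list(trial_id = 1L, design = design, outcome = outcome, alpha = alpha,
       sides = sides, power = power, n_per_group = n_per_group,
       p1 = p1, p2 = p2, diff = diff, delta_means = delta_means, sd = sd)
}

# grid of design specs used by round-trip and monotonicity properties
spec_grid <- function() {
  specs <- list()
  for (alpha in c(0.05, 0.01)) for (sides in c("two", "one"))
    for (power in c(0.80, 0.90)) {
      for (p1 in c(0.15, 0.3, 0.45)) for (d in c(0.08, 0.15, 0.25)) {
        specs[[length(specs) + 1L]] <- design_spec(
          "superiority", "binary", alpha = alpha, sides = sides,
          power = power, p1 = p1, p2 = p1 + d)
        specs[[length(specs) + 1L]] <- design_spec(
          "noninferiority", "binary", alpha = alpha, sides = sides,
          power = power, p1 = p1, margin = d)
      }
      for (es in c(0.2, 0.35, 0.5, 0.9)) {
        specs[[length(specs) + 1L]] <- design_spec(
          "superiority", "continuous", alpha = alpha, sides = sides,
          power = power, delta = es * 12, sd = 12)
        specs[[length(specs) + 1L]] <- design_spec(
          "noninferiority", "continuous", alpha = alpha, sides = sides,
          power = power, margin = es * 12, sd = 12)
      }
    }
  specs
}
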