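test_that("solve_sd inverts the continuous formula in closed form", {
  sp <- design_spec("superiority", "continuous", alpha = 0.05, sides = "two",
                    power = 0.80, delta = 5, sd = 1)
  s <- solve_sd(sp, 64, delta = 5)
  expect_equal(s, 5 * sqrt(32) / (qnorm(0.975) + qnorm(0.80)),
               tolerance = 1e-12)
  expect_equal(round(s, 3), 10.096)
  # algebraic round trip, pre-rounding
  sp$sd <- s
  expect_equal(n_per_group(sp)$n_per_group_raw, 64, tolerance = 1e-9)
  # sqrt(n) scaling
  expect_equal(solve_sd(sp, 256, delta = 5), 2 * s, tolerance = 1e-12)
  expect_error(solve_sd(sp, 64, delta = 0),
               class = "tm_reconstruction_infeasible")
})

test_that("solve_p2 recovers the missing proportion", {
  sp <- design_spec("superiority", "binary", alpha = 0.05, sides = "two",
                    power = 0.80, p1 = 0.2, p2 = 0.3)
  n_raw <- n_per_group(sp)$n_per_group_raw
  # exact inversion at the pre-rounding n
  sol <- solve_p2(sp, n_raw, p1 = 0.2, direction = "increase")
  expect_equal(sol$p2, 0.3, tolerance = 1e-6)
  # inversion at the rounded (published) n lands within the rounding bound
  sol291 <- solve_p2(sp, 291, p1 = 0.2, direction = "increase")
  expect_equal(sol291$p2, 0.3, tolerance = 2e-3)
  # difference fully determines p2 given p1
  expect_equal(solve_p2(sp, 291, p1 = 0.2, diff = 0.1),
               list(p1 = 0.2, p2 = 0.3, diff = 0.1))
  # recovered effect shrinks monotonically as reported n grows
  ns <- c(1e3, 1e4, 1e5, 1e6)
  effs <- sapply(ns, function(n)
    solve_p2(sp, n, p1 = 0.2, direction = "increase")$p2 - 0.2)
  expect_true(all(diff(effs) < 0))
  expect_lt(effs[4], 5e-3)
})

test_that("solve_p2 handles baseline-unknown and noninferiority inversion", {
  sp <- design_spec("superiority", "binary", alpha = 0.05, sides = "two",
                    power = 0.80, p1 = 0.2, p2 = 0.3)
  n_raw <- n_per_group(sp)$n_per_group_raw
  sol <- solve_p2(sp, n_raw, diff = 0.1)
  # reflection-invariant root: same variance term, pooled mean <= 1/2
  expect_equal(sol$p2 - sol$p1, 0.1, tolerance = 1e-12)
  expect_lte((sol$p1 + sol$p2) / 2, 0.5)
  v <- sol$p1 * (1 - sol$p1) + sol$p2 * (1 - sol$p2)
  expect_equal(v, 0.37, tolerance = 1e-9)
  # the standardized difference is invariant to which root was returned
  expect_equal(abs(standardized_difference_proportions(sol$p1, sol$p2)$value),
               abs(standardized_difference_proportions(0.2, 0.3)$value),
               tolerance = 1e-9)

  spn <- design_spec("noninferiority", "binary", alpha = 0.025,
                     sides = "one", power = 0.80, p1 = 0.8, margin = 0.1)
  n_ni <- n_per_group(spn)$n_per_group_raw
  soln <- solve_p2(spn, n_ni, diff = 0.1)
  expect_equal(soln$p1, soln$p2, tolerance = 1e-12)
  expect_equal(soln$p1 * (1 - soln$p1), 0.8 * 0.2, tolerance = 1e-9)
})

test_that("solve_p2 signals ambiguity and infeasibility explicitly", {
  sp <- design_spec("superiority", "binary", alpha = 0.05, sides = "two",
                    power = 0.80, p1 = 0.5, p2 = 0.6)
  expect_error(solve_p2(sp, 300, p1 = 0.5), class = "tm_ambiguous_root")
  # n too small for any p2 in (0, 1)
  err <- tryCatch(solve_p2(sp, 3, p1 = 0.5, direction = "increase"),
                  tm_reconstruction_infeasible = function(e) e)
  expect_s3_class(err, "tm_reconstruction_infeasible")
  expect_false(is.null(err$bracket))
  # variance term unattainable for a large diff at tiny n
  expect_error(solve_p2(sp, 2000, diff = 0.9),
               class = "tm_reconstruction_infeasible")
})

test_that("round trip across a grid of designs recovers hidden parameters", {
  specs <- spec_grid()
  expect_gte(length(specs), 200)
  for (sp in specs) {
    n_raw <- n_per_group(sp)$n_per_group_raw
    if (sp$outcome == "continuous") {
      delta <- if (sp$design == "superiority") sp$delta else sp$margin
      expect_equal(solve_sd(sp, n_raw, delta), sp$sd,
                   tolerance = 1e-6 * sp$sd)
    } else {
      d <- if (sp$design == "superiority") sp$p2 - sp$p1 else sp$margin
      sol <- solve_p2(sp, n_raw, diff = d)
      v_true <- sp$p1 * (1 - sp$p1) + sp$p2 * (1 - sp$p2)
      v_rec <- sol$p1 * (1 - sol$p1) + sol$p2 * (1 - sol$p2)
      expect_equal(v_rec, v_true, tolerance = 1e-6 * v_true)
      if (sp$design == "superiority") {
        sol2 <- solve_p2(sp, n_raw, p1 = sp$p1, direction = "increase")
        expect_equal(sol2$p2, sp$p2, tolerance = 1e-6)
      }
    }
  }
})

test_that("verify_reported_sample_size measures the reported-vs-formula gap", {
  sp <- design_spec("superiority", "binary", alpha = 0.05, sides = "two",
                    power = 0.80, p1 = 0.2, p2 = 0.3)
  res <- n_per_group(sp, rounding = "nearest")
  rec <- make_record(n_per_group = res$n_per_group, p1 = 0.2, p2 = 0.3,
                     diff = 0.1)
  expect_lt(verify_reported_sample_size(rec), 0.5 / res$n_per_group)

  # inflating the reported n by 2x: |n_raw - 2 n_raw| / (2 n_raw) = 0.5
  rec2 <- rec; rec2$n_per_group <- 2 * res$n_per_group
  expect_equal(verify_reported_sample_size(rec2), 0.5, tolerance = 2e-3)

  # continuity-corrected published n vs uncorrected formula: the known gap
  n_cc <- round(continuity_corrected_n(res$n_per_group_raw, 0.1))
  rec3 <- rec; rec3$n_per_group <- n_cc
  expect_equal(verify_reported_sample_size(rec3),
               abs(res$n_per_group_raw - n_cc) / n_cc, tolerance = 1e-9)
  expect_equal(verify_reported_sample_size(rec3), 0.063, tolerance = 0.005)

  # monotone in the perturbation of n
  gaps <- sapply(c(1, 1.05, 1.1, 1.3), function(f) {
    r <- rec; r$n_per_group <- round(f * res$n_per_group)
    verify_reported_sample_size(r)
  })
  expect_true(all(diff(gaps) > 0))

  expect_error(verify_reported_sample_size(make_record(p1 = 0.2, p2 = 0.3)),
               class = "tm_reconstruction_required")
})

test_that("extraction decision tree: direct, imputed, unextractable", {
  # complete binary record -> direct
  r1 <- make_record(p1 = 0.2, p2 = 0.3, diff = 0.1, n_per_group = 291)
  e1 <- extract_standardized_difference(r1)
  expect_equal(round(e1$std_diff$value, 5), 0.23094)
  expect_identical(e1$std_diff$provenance, "direct")
  expect_length(e1$recovered, 0)
  expect_lt(e1$consistency, 0.01)

  # difference-only with known baseline -> same value, imputed
  r2 <- make_record(p1 = 0.2, diff = 0.1, n_per_group = 291)
  e2 <- extract_standardized_difference(r2)
  expect_equal(e2$std_diff$value, e1$std_diff$value, tolerance = 1e-12)
  expect_identical(e2$std_diff$provenance, "imputed")
  expect_named(e2$recovered, "p2")

  # difference-only, baseline reconstructed from n
  r3 <- make_record(diff = 0.1, n_per_group = 291)
  e3 <- extract_standardized_difference(r3)
  expect_identical(e3$std_diff$provenance, "imputed")
  expect_equal(abs(e3$std_diff$value), e1$std_diff$value, tolerance = 5e-3)

  # continuous without SD -> solve_sd branch
  r4 <- make_record(outcome = "continuous", delta_means = 5, n_per_group = 64)
  e4 <- extract_standardized_difference(r4)
  expect_equal(round(e4$std_diff$value, 4), 0.4953)
  expect_identical(e4$std_diff$provenance, "imputed")
  expect_named(e4$recovered, "sd")

  # provenance correctness: imputed iff something was recovered
  for (e in list(e1, e2, e3, e4)) {
    expect_identical(e$std_diff$provenance == "imputed",
                     length(e$recovered) > 0)
  }

  # nothing to work with
  expect_error(extract_standardized_difference(make_record()),
               class = "tm_unextractable")
  expect_error(
    extract_standardized_difference(make_record(outcome = "continuous")),
    class = "tm_unextractable")
})
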