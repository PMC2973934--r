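# End-to-end driver: simulate (or read) a registry -> extract/reconstruct ->
# analyze -> report.

#' Run the full pipeline
#'
#' Orchestrates the stages end to end: obtain a registry (generate a
#' synthetic one from `config`, or read an existing CSV), mask the configured
#' fraction of effect parameters (generated registries only), extract or
#' reconstruct every standardized difference, and write the report bundle:
#' the completed registry CSV (with `std_diff`, `provenance`, `consistency`),
#' the by-scale and by-covariate summary tables, the adjusted-means report,
#' and a run log with direct/imputed/unextractable counts. All randomness is
#' confined to generation and masking; a single `seed` fans out to fixed
#' per-stage substreams so stages can be rerun independently.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [registry_config()] used when `registry_path` is `NULL`.
#' @param registry_path Optional path to an existing registry CSV; when
#'   given, no generation or masking is performed.
#' @param seed Integer seed (< 2^30); generation uses `seed`, masking
#'   `seed + 2^17`.
#' @param predictors Factors for the adjusted-means model.
#' @return (Invisibly) list with `registry`, `summary`, `adjusted_means`,
#'   `counts`, and the written file paths.
#' @export
run_pipeline <- function(out_dir, config = registry_config(),
                         registry_path = NULL, seed = 1,
                         predictors = c("design", "mortality", "context")) {
  tm_check(is.numeric(seed) && abs(seed) < 2^30, "seed must be < 2^30")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  if (is.null(registry_path)) {
    say("simulate: %d superiority + %d noninferiority trials (seed %d)",
        config$n_superiority, config$n_noninferiority, as.integer(seed))
    reg <- generate_registry(config, seed = seed)
    reg <- mask_fields(reg, config$masking_rate, seed = seed + 2^17)
    say("masking: rate %.3f -> %d record(s) masked", config$masking_rate,
        sum(is.na(reg$p1) & reg$outcome == "binary") +
          sum(is.na(reg$sd) & reg$outcome == "continuous"))
  } else {
    say("read registry: %s", registry_path)
    reg <- read_registry(registry_path)
  }

  reg <- extract_registry(reg)
  counts <- attr(reg, "extraction_counts")
  say("extraction: %d direct, %d imputed, %d unextractable",
      counts[["direct"]], counts[["imputed"]], counts[["unextractable"]])

  summ <- summarize_registry(reg)
  adj <- tryCatch(adjusted_means_anova(reg, predictors),
                  tm_error = function(e) {
                    say("adjusted means skipped: %s", conditionMessage(e))
                    NULL
                  })

  paths <- list(
    registry = file.path(out_dir, "registry.csv"),
    by_scale = file.path(out_dir, "summary_by_scale.csv"),
    by_covariate = file.path(out_dir, "summary_by_covariate.csv"),
    distribution = file.path(out_dir, "distribution.csv"),
    adjusted_means = file.path(out_dir, "adjusted_means.csv"),
    log = file.path(out_dir, "run_log.txt"))
  write_registry(reg, paths$registry)
  write.csv(summ$by_scale, paths$by_scale, row.names = FALSE)
  write.csv(summ$by_covariate, paths$by_covariate, row.names = FALSE)
  write.csv(summ$distribution, paths$distribution, row.names = FALSE)
  if (!is.null(adj)) {
    am <- adj$means
    am$p_value <- adj$p_values[am$factor]
    am$r2_adjusted <- adj$r2_adjusted
    write.csv(am, paths$adjusted_means, row.names = FALSE)
  }
  writeLines(log_lines, paths$log)

  invisible(list(registry = reg, summary = summ, adjusted_means = adj,
                 counts = counts, paths = paths))
}

#' Validate a registry file
#'
#' Schema check, per-record invariant checks (probabilities in (0,1),
#' positive SDs, sample sizes >= 2, exactly one populated outcome-parameter
#' block), and a consistency screen recomputing the sample size where the
#' record is complete. Returns a diagnostics data frame (empty when clean)
#' with one row per finding: record id, field, severity, message.
#'
#' @param x Path to a registry CSV, or a registry data frame.
#' @param consistency_threshold Relative reported-vs-recomputed sample-size
#'   gap above which a record is flagged irreconcilable (default 0.15).
#' @return Data frame of diagnostics; attribute `clean` is `TRUE` iff no
#'   error-severity findings.
#' @export
validate_registry <- function(x, consistency_threshold = 0.15) {
  reg <- if (is.character(x)) read_registry(x) else x
  tm_check(is.data.frame(reg), "`x` must be a path or data frame")
  diag <- list()
  flag <- function(id, field, severity, msg) {
    diag[[length(diag) + 1L]] <<- data.frame(
      trial_id = id, field = field, severity = severity, message = msg,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(reg))) {
    r <- as.list(reg[i, ])
    id <- r$trial_id
    for (f in c("p1", "p2", "alpha", "power")) {
      if (has_val(r[[f]]) && (r[[f]] <= 0 || r[[f]] >= 1)) {
        flag(id, f, "error", sprintf("%s = %g outside (0, 1)", f, r[[f]]))
      }
    }
    if (has_val(r$sd) && r$sd <= 0) {
      flag(id, "sd", "error", sprintf("sd = %g not positive", r$sd))
    }
    if (has_val(r$n_per_group) && r$n_per_group < 2) {
      flag(id, "n_per_group", "error", "per-group sample size below 2")
    }
    if (!r$design %in% c("superiority", "noninferiority")) {
      flag(id, "design", "error", sprintf("unknown design '%s'", r$design))
    }
    if (!r$outcome %in% c("binary", "continuous")) {
      flag(id, "outcome", "error", sprintf("unknown outcome '%s'", r$outcome))
    }
    cons <- tryCatch(verify_reported_sample_size(r),
                     tm_error = function(e) NA_real_)
    if (!is.na(cons) && cons > consistency_threshold) {
      flag(id, "n_per_group", "warning",
           sprintf("reported n differs from recomputed by %.1f%%", 100 * cons))
    }
  }
  out <- if (length(diag)) do.call(rbind, diag) else
    data.frame(trial_id = integer(0), field = character(0),
               severity = character(0), message = character(0),
               stringsAsFactors = FALSE)
  attr(out, "clean") <- !any(out$severity == "error")
  out
}
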