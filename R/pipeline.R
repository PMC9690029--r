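#' Analysis configuration
#'
#' Collects every tunable of a one-direction analysis with the
#' conventional defaults: genome-wide significance `5e-8`, clumping at
#' squared correlation `0.001` within a 10,000 kb window, palindrome
#' frequency bound 0.42, 1,000 bootstrap and simulation replicates, and a
#' fixed default seed of 1 so runs are reproducible by default.
#'
#' @param p_threshold instrument significance threshold.
#' @param clump_r2,clump_kb LD-clumping thresholds.
#' @param palindrome_eaf_limit see [harmonize()].
#' @param methods estimator subset, see [mr_fit()].
#' @param n_boot,seed,conmix_psi,presso_nsim,presso_alpha see [mr_fit()].
#' @param alpha two-sided level for the power calculation.
#' @param hypothesized_or odds ratio for the power calculation; `NULL`
#'   skips power.
#' @return A list of class `mr_config`.
#' @export
mr_config <- function(p_threshold = 5e-8, clump_r2 = 0.001, clump_kb = 10000,
                      palindrome_eaf_limit = 0.42,
                      methods = c("ivw", "weighted_median", "egger",
                                  "presso", "conmix"),
                      n_boot = 1000, seed = 1, conmix_psi = "auto",
                      presso_nsim = 1000, presso_alpha = 0.05,
                      alpha = 0.05, hypothesized_or = NULL) {
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_kb = clump_kb,
                 palindrome_eaf_limit = palindrome_eaf_limit,
                 methods = methods, n_boot = n_boot, seed = seed,
                 conmix_psi = conmix_psi, presso_nsim = presso_nsim,
                 presso_alpha = presso_alpha, alpha = alpha,
                 hypothesized_or = hypothesized_or),
            class = "mr_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' @param path a `.yaml`/`.yml` or `.json` file whose keys match the
#'   arguments of [mr_config()].
#' @return A validated `mr_config`.
#' @export
read_mr_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(vals), names(formals(mr_config)))
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  do.call(mr_config, vals)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run one direction of a two-sample MR analysis
#'
#' Orchestrates the full pipeline for one exposure/outcome pair:
#' significance selection of exposure instruments, greedy LD clumping,
#' harmonization against the outcome table, the estimator suite of
#' [mr_fit()], heterogeneity and MR-PRESSO diagnostics, instrument-strength
#' F statistics, and (when a hypothesized odds ratio is configured)
#' analytic power. Errors abort with a message naming the failing stage;
#' fewer than two surviving instruments is an abort, not a silent
#' degenerate fit. Stage-by-stage progress is logged to standard error.
#'
#' @param exposure,outcome file paths of tab-separated summary tables, or
#'   `gwas_assoc` data frames.
#' @param config an [mr_config()].
#' @param ld LD matrix (or TSV path, see [read_ld_matrix()]); `NULL`
#'   prunes by physical distance alone.
#' @param exposure_name,outcome_name trait labels.
#' @param dialect column mapping for file inputs.
#' @param out_dir when given, `report.json`, `estimates.tsv` and
#'   `harmonized.tsv` are written there. Reports carry full provenance
#'   (inputs, thresholds, seeds, package version) and are byte-identical
#'   across reruns with the same inputs and seed.
#' @param quiet suppress progress logging.
#' @return An object of class `mr_report`: list with `direction`,
#'   `counts` (instruments at each selection stage), `fit` (the
#'   `mr_fit`), `set`, `strength`, `power`, `provenance`.
#' @export
mr_run_direction <- function(exposure, outcome, config = mr_config(),
                             ld = NULL,
                             exposure_name = "exposure",
                             outcome_name = "outcome",
                             dialect = gwas_dialect(), out_dir = NULL,
                             quiet = FALSE) {
  log_stage <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  exposure_path <- if (is.character(exposure)) exposure else "<in-memory>"
  outcome_path <- if (is.character(outcome)) outcome else "<in-memory>"

  ex <- .stage("read_exposure",
               if (is.character(exposure)) read_gwas_table(exposure, dialect)
               else exposure)
  ou <- .stage("read_outcome",
               if (is.character(outcome)) read_gwas_table(outcome, dialect)
               else outcome)
  if (is.character(ld)) ld <- .stage("read_ld", read_ld_matrix(ld))
  log_stage("[%s -> %s] read %d exposure / %d outcome associations",
            exposure_name, outcome_name, nrow(ex), nrow(ou))

  n_total <- nrow(ex)
  sig <- .stage("select_by_pvalue", select_by_pvalue(ex, config$p_threshold))
  n_sig <- nrow(sig)
  clumped <- .stage("ld_clump",
                    ld_clump(sig, ld = ld, r2_threshold = config$clump_r2,
                             window_kb = config$clump_kb))
  n_clumped <- nrow(clumped)
  log_stage("[%s -> %s] %d significant, %d after clumping",
            exposure_name, outcome_name, n_sig, n_clumped)

  n_exposure <- if (all(is.na(sig$n))) NULL else stats::median(sig$n, na.rm = TRUE)
  set <- .stage("harmonize", harmonize(
    clumped, ou, palindrome_eaf_limit = config$palindrome_eaf_limit,
    exposure_name = exposure_name, outcome_name = outcome_name,
    selection_record = list(p_threshold = config$p_threshold,
                            clump_r2 = config$clump_r2,
                            clump_kb = config$clump_kb,
                            n_input = n_total, n_significant = n_sig,
                            n_clumped = n_clumped,
                            n_exposure = n_exposure)))
  J <- nrow(set$instruments)
  if (J < 2) {
    stop(sprintf("stage harmonize: only %d instrument(s) survive; need >= 2", J),
         call. = FALSE)
  }
  log_stage("[%s -> %s] %d harmonized instrument(s)",
            exposure_name, outcome_name, J)

  fit <- .stage("estimate", mr_fit(
    set, methods = config$methods, n_boot = config$n_boot,
    seed = config$seed, conmix_psi = config$conmix_psi,
    presso_nsim = config$presso_nsim, presso_alpha = config$presso_alpha,
    n_exposure = n_exposure))

  n_outcome <- if (all(is.na(ou$n))) NULL else stats::median(ou$n, na.rm = TRUE)
  power <- NULL
  if (!is.null(config$hypothesized_or) && !is.null(n_outcome) &&
      !is.null(fit$strength) && !is.na(fit$strength$r2_total)) {
    # case fraction is not in the summary tables; power needs it supplied
    # via the hypothesized_or attribute list when known
    kf <- attr(config$hypothesized_or, "case_fraction")
    if (!is.null(kf)) {
      power <- list(
        power = mr_power_binary(n = n_outcome, k_ratio = kf,
                                odds_ratio = as.numeric(config$hypothesized_or),
                                r2 = fit$strength$r2_total,
                                alpha = config$alpha),
        n = n_outcome, case_fraction = kf,
        odds_ratio = as.numeric(config$hypothesized_or),
        r2 = fit$strength$r2_total, alpha = config$alpha)
    }
  }

  report <- structure(list(
    direction = sprintf("%s -> %s", exposure_name, outcome_name),
    counts = list(input = n_total, significant = n_sig, clumped = n_clumped,
                  harmonized = J, dropped_in_harmonization = nrow(set$dropped)),
    fit = fit, set = set, strength = fit$strength, power = power,
    provenance = list(
      exposure = exposure_path, outcome = outcome_path,
      exposure_name = exposure_name, outcome_name = outcome_name,
      config = unclass(config),
      package = "bimr",
      version = as.character(utils::packageVersion("bimr")))
  ), class = "mr_report")
  log_stage("[%s -> %s] done in %.1f s", exposure_name, outcome_name,
            proc.time()[["elapsed"]] - t0)

  if (!is.null(out_dir)) write_mr_report(report, out_dir)
  report
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("MR analysis %s\n", x$direction))
  cat(sprintf("  instruments: %d input, %d significant, %d clumped, %d harmonized\n",
              x$counts$input, x$counts$significant, x$counts$clumped,
              x$counts$harmonized))
  print(x$fit)
  if (!is.null(x$power))
    cat(sprintf("  power for OR %.2f at alpha %.2f: %.1f%%\n",
                x$power$odds_ratio, x$power$alpha, 100 * x$power$power))
  invisible(x)
}

# Flatten a report into plain lists for JSON serialization.
.report_as_list <- function(report) {
  fit <- report$fit
  est <- fit$estimates
  eg <- fit$details$egger
  pr <- fit$details$presso
  cm <- fit$details$conmix
  list(
    direction = report$direction,
    counts = report$counts,
    estimates = est,
    egger_intercept = if (!is.null(eg)) eg$intercept,
    heterogeneity = if (!is.null(fit$heterogeneity))
      unclass(fit$heterogeneity),
    presso = if (!is.null(pr)) list(
      global_rss = pr$global_rss, global_pvalue = pr$global_pvalue,
      outlier_variants = pr$outlier_variants,
      outlier_pvalues = pr$outlier_pvalues,
      distortion_pvalue = pr$distortion_pvalue,
      theta_raw = pr$theta_raw$theta, theta_corrected = pr$theta_corrected$theta,
      n_sim = pr$n_sim, seed = pr$seed, outlier_alpha = pr$outlier_alpha),
    conmix = if (!is.null(cm)) list(
      psi = cm$psi, ci_set = cm$ci_set, n_valid = sum(cm$valid),
      grid_range = cm$grid_range, grid_steps = cm$grid_steps),
    strength = if (!is.null(report$strength)) unclass(report$strength),
    power = report$power,
    leave_one_out = {
      inst <- report$set$instruments
      w <- 1 / inst$wald_se^2
      S0 <- sum(w); S1 <- sum(w * inst$wald_ratio)
      data.frame(variant_id = inst$variant_id,
                 theta = (S1 - w * inst$wald_ratio) / (S0 - w),
                 stringsAsFactors = FALSE)
    },
    skipped = fit$skipped,
    note = "no multiple-testing adjustment is applied across directions or outcomes",
    provenance = report$provenance
  )
}

#' Write a direction report to disk
#'
#' Emits `report.json` (full report with provenance), `estimates.tsv`
#' (one row per method) and `harmonized.tsv` (+ JSON sidecar) under
#' `out_dir`. Output is byte-stable for identical inputs and seeds.
#'
#' @param report an `mr_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_mr_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(.report_as_list(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  est <- report$fit$estimates
  out <- est
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.table(out, file.path(out_dir, "estimates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_instrument_set(report$set, file.path(out_dir, "harmonized.tsv"))
  invisible(out_dir)
}

#' Run a bidirectional two-sample MR analysis
#'
#' Runs [mr_run_direction()] in both directions with direction-specific
#' instrument selection, and combines the results. One direction may abort
#' (e.g. too few instruments) while the other completes; the failure
#' message is carried in the report. Identical input files for both traits
#' are flagged as complete sample overlap.
#'
#' @param a,b file paths (or `gwas_assoc` data frames) for the two traits.
#' @param config an [mr_config()] applied to both directions, or a list of
#'   two configs `list(forward =, reverse =)`.
#' @param ld_a,ld_b LD matrices (or paths) for each trait's instruments.
#' @param a_name,b_name trait labels.
#' @param dialect column mapping for file inputs.
#' @param out_dir when given, per-direction subdirectories `forward/` and
#'   `reverse/` plus a combined `summary.json` are written.
#' @param quiet suppress progress logging.
#' @return A list of class `mr_bidirectional` with `forward`, `reverse`
#'   (each an `mr_report` or an error message string), `overlap_flag` and
#'   a combined `table` of estimates.
#' @export
mr_run_bidirectional <- function(a, b, config = mr_config(),
                                 ld_a = NULL, ld_b = NULL,
                                 a_name = "trait_A", b_name = "trait_B",
                                 dialect = gwas_dialect(), out_dir = NULL,
                                 quiet = FALSE) {
  cfg_f <- if (inherits(config, "mr_config")) config else config$forward
  cfg_r <- if (inherits(config, "mr_config")) config else config$reverse
  overlap <- is.character(a) && is.character(b) &&
    normalizePath(a, mustWork = FALSE) == normalizePath(b, mustWork = FALSE)
  if (!overlap && is.data.frame(a) && is.data.frame(b)) overlap <- identical(a, b)
  if (overlap) warning("exposure and outcome inputs are identical: complete sample overlap")

  run_one <- function(x, y, cfg, ld, xn, yn, sub) {
    tryCatch(
      mr_run_direction(x, y, cfg, ld = ld, exposure_name = xn,
                       outcome_name = yn, dialect = dialect,
                       out_dir = if (is.null(out_dir)) NULL
                                 else file.path(out_dir, sub),
                       quiet = quiet),
      error = function(e) conditionMessage(e))
  }
  forward <- run_one(a, b, cfg_f, ld_a, a_name, b_name, "forward")
  reverse <- run_one(b, a, cfg_r, ld_b, b_name, a_name, "reverse")

  grab <- function(rep, dir_label) {
    if (!inherits(rep, "mr_report")) return(NULL)
    cbind(direction = rep$direction, rep$fit$estimates)
  }
  table <- do.call(rbind, c(list(grab(forward)), list(grab(reverse))))
  res <- structure(list(forward = forward, reverse = reverse,
                        overlap_flag = overlap, table = table),
                   class = "mr_bidirectional")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(list(
      overlap_flag = overlap,
      forward = if (inherits(forward, "mr_report")) "completed" else forward,
      reverse = if (inherits(reverse, "mr_report")) "completed" else reverse,
      table = table),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows",
      null = "null")
  }
  res
}

#' @export
print.mr_bidirectional <- function(x, ...) {
  for (d in c("forward", "reverse")) {
    rep <- x[[d]]
    if (inherits(rep, "mr_report")) print(rep)
    else cat(sprintf("%s direction failed: %s\n", d, rep))
    cat("\n")
  }
  if (x$overlap_flag) cat("warning: complete sample overlap between inputs\n")
  invisible(x)
}
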