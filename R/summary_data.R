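#' Default column dialect for GWAS summary-statistics tables
#'
#' Maps the canonical field names used throughout the package to the column
#' headers of a tab-separated summary-statistics file. Override individual
#' entries to read tables with different headers; there is deliberately no
#' auto-detection, so a misnamed column fails loudly instead of being
#' silently misread.
#'
#' @param ... named overrides, e.g. `beta = "b"`, `variant_id = "MarkerName"`.
#' @return Named character vector mapping canonical names (`variant_id`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`,
#'   `chrom`, `pos`) to file column names.
#' @export
#' @examples
#' gwas_dialect(beta = "b", se = "std_err")
gwas_dialect <- function(...) {
  d <- c(
    variant_id    = "variant_id",
    effect_allele = "effect_allele",
    other_allele  = "other_allele",
    eaf           = "eaf",
    beta          = "beta",
    se            = "se",
    pvalue        = "pvalue",
    n             = "n",
    chrom         = "chrom",
    pos           = "pos"
  )
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(d))
    if (length(bad)) stop("unknown dialect field(s): ", paste(bad, collapse = ", "))
    d[names(ov)] <- ov
  }
  d
}

# Fields that must be present and parse for a row to be retained.
.mandatory_fields <- c("variant_id", "effect_allele", "other_allele",
                       "beta", "se", "pvalue")
.optional_fields <- c("eaf", "n", "chrom", "pos")

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated table of per-variant association statistics
#' (one header row) and validates each row against the field invariants:
#' alleles must be single bases A/C/G/T and distinct, `se > 0`,
#' `pvalue` in (0, 1], and `eaf` (when present) strictly inside (0, 1).
#' Alleles are upper-cased. Rows violating an invariant are rejected and
#' reported row-by-row; missing mandatory columns are a configuration
#' error.
#'
#' @param path path to a tab-separated file with one header row.
#' @param dialect column-name mapping from [gwas_dialect()].
#' @return A `gwas_assoc` data frame with canonical columns `variant_id`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`,
#'   `chrom`, `pos` (optional fields are `NA` when absent from the file).
#'   Rejected rows are attached as attribute `"rejected"` (a data frame of
#'   row numbers, variant ids and reasons) and reported in a warning.
#' @export
read_gwas_table <- function(path, dialect = gwas_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (nrow(raw) == 0L) stop("empty summary-statistics file: ", path)
  missing_cols <- setdiff(dialect[.mandatory_fields], names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    variant_id    = raw[[dialect[["variant_id"]]]],
    effect_allele = toupper(raw[[dialect[["effect_allele"]]]]),
    other_allele  = toupper(raw[[dialect[["other_allele"]]]]),
    stringsAsFactors = FALSE
  )
  num_field <- function(f) {
    col <- dialect[[f]]
    if (col %in% names(raw)) suppressWarnings(as.numeric(raw[[col]])) else rep(NA_real_, nrow(raw))
  }
  out$eaf    <- num_field("eaf")
  out$beta   <- num_field("beta")
  out$se     <- num_field("se")
  out$pvalue <- num_field("pvalue")
  out$n      <- num_field("n")
  out$chrom  <- if (dialect[["chrom"]] %in% names(raw)) raw[[dialect[["chrom"]]]] else rep(NA_character_, nrow(raw))
  out$pos    <- num_field("pos")

  reasons <- character(nrow(out))
  flag <- function(bad, msg) {
    bad <- which(bad & !nzchar(reasons))
    reasons[bad] <<- msg
  }
  flag(is.na(out$beta), "unparseable or missing beta")
  flag(is.na(out$se), "unparseable or missing se")
  flag(is.na(out$pvalue), "unparseable or missing pvalue")
  flag(!out$effect_allele %in% c("A", "C", "G", "T"), "effect_allele not one of A/C/G/T")
  flag(!out$other_allele %in% c("A", "C", "G", "T"), "other_allele not one of A/C/G/T")
  flag(out$effect_allele == out$other_allele, "effect_allele equals other_allele")
  flag(!is.na(out$se) & out$se <= 0, "se not strictly positive")
  flag(!is.na(out$pvalue) & (out$pvalue <= 0 | out$pvalue > 1), "pvalue outside (0,1]")
  flag(!is.na(out$eaf) & (out$eaf <= 0 | out$eaf >= 1), "eaf outside (0,1)")

  bad <- nzchar(reasons)
  rejected <- data.frame(row = which(bad),
                         variant_id = out$variant_id[bad],
                         reason = reasons[bad],
                         stringsAsFactors = FALSE)
  if (nrow(rejected)) {
    warning(sprintf("%d row(s) rejected from %s: %s", nrow(rejected), path,
                    paste(sprintf("row %d (%s): %s", rejected$row,
                                  rejected$variant_id, rejected$reason),
                          collapse = "; ")))
  }
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, rejected = rejected, class = c("gwas_assoc", "data.frame"))
}

#' Write a GWAS summary-statistics table
#'
#' Inverse of [read_gwas_table()] for the canonical dialect; floats are
#' written with full precision so tables round-trip losslessly.
#'
#' @param assoc a `gwas_assoc` data frame (or any data frame with the
#'   canonical columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gwas_table <- function(assoc, path) {
  cols <- c(.mandatory_fields[1:3], "eaf", "beta", "se", "pvalue", "n", "chrom", "pos")
  df <- as.data.frame(assoc)[, intersect(cols, names(assoc)), drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  df[df == "NA"] <- "NA"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.is_palindromic <- function(a1, a2) .complement[a1] == a2

#' Harmonize exposure and outcome summary statistics into an instrument set
#'
#' Aligns the outcome association of every variant shared between the two
#' studies onto the exposure's effect allele, then computes per-variant Wald
#' ratios. Alignment rules for non-palindromic variants:
#' \itemize{
#'   \item identical allele pair: kept as-is;
#'   \item swapped alleles: outcome beta negated, outcome eaf complemented;
#'   \item complementary-strand pair (possibly swapped): strand flipped,
#'     then the same rules;
#'   \item irreconcilable pair: dropped.
#' }
#' Palindromic variants (A/T or C/G) carry no strand information in their
#' alleles: after nominal alignment they are retained (action
#' `palindromic_aligned`) only when both effect-allele frequencies are
#' available, both lie outside `[palindrome_eaf_limit, 1 - palindrome_eaf_limit]`,
#' and both fall on the same side of 0.5; otherwise they are dropped.
#' Variants with a zero exposure beta are dropped (the Wald ratio is
#' undefined).
#'
#' @param exposure,outcome `gwas_assoc` tables (see [read_gwas_table()]),
#'   keyed by `variant_id`. Only variants present in both are used.
#' @param palindrome_eaf_limit frequency bound below/above which a
#'   palindromic variant's strand is considered inferable (default 0.42).
#' @param exposure_name,outcome_name trait labels carried into reports.
#' @param selection_record optional named list of upstream filter settings
#'   and counts, carried through to the serialized set.
#' @return An object of class `mr_instrument_set`: a list with elements
#'   `exposure_name`, `outcome_name`, `instruments` (data frame with
#'   `variant_id`, `effect_allele`, `other_allele`, `beta_exposure`,
#'   `se_exposure`, `eaf_exposure`, `beta_outcome`, `se_outcome`,
#'   `eaf_outcome`, `wald_ratio`, `wald_se`, `action`), `dropped` (same
#'   shape plus a `reason`), and `selection_record`.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_limit = 0.42,
                      exposure_name = "exposure", outcome_name = "outcome",
                      selection_record = list()) {
  stopifnot(palindrome_eaf_limit > 0, palindrome_eaf_limit < 0.5)
  if (anyDuplicated(exposure$variant_id)) stop("duplicate variant_id in exposure table")
  if (anyDuplicated(outcome$variant_id)) stop("duplicate variant_id in outcome table")
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  ex <- exposure[match(shared, exposure$variant_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$variant_id), , drop = FALSE]

  n <- length(shared)
  action <- character(n)
  reason <- character(n)
  b_out <- ou$beta
  eaf_out <- ou$eaf
  ea <- ou$effect_allele
  oa <- ou$other_allele

  for (i in seq_len(n)) {
    pal <- .is_palindromic(ex$effect_allele[i], ex$other_allele[i])
    same <- ea[i] == ex$effect_allele[i] && oa[i] == ex$other_allele[i]
    swap <- ea[i] == ex$other_allele[i] && oa[i] == ex$effect_allele[i]
    if (!same && !swap && !pal) {
      # try the complementary strand
      cea <- .complement[[ea[i]]]; coa <- .complement[[oa[i]]]
      if (cea == ex$effect_allele[i] && coa == ex$other_allele[i]) {
        ea[i] <- cea; oa[i] <- coa
        action[i] <- "allele_flipped"; same <- TRUE
      } else if (cea == ex$other_allele[i] && coa == ex$effect_allele[i]) {
        ea[i] <- cea; oa[i] <- coa
        action[i] <- "allele_flipped"; swap <- TRUE
      }
    }
    if (!same && !swap) {
      action[i] <- "dropped"; reason[i] <- "alleles irreconcilable with exposure"
      next
    }
    if (swap) {
      b_out[i] <- -b_out[i]
      if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
      ea[i] <- ex$effect_allele[i]; oa[i] <- ex$other_allele[i]
      if (action[i] == "") action[i] <- "allele_flipped"
    }
    if (pal) {
      lo <- palindrome_eaf_limit; hi <- 1 - palindrome_eaf_limit
      fx <- ex$eaf[i]; fy <- eaf_out[i]
      informative <- !is.na(fx) && !is.na(fy) &&
        (fx < lo || fx > hi) && (fy < lo || fy > hi)
      if (informative && sign(fx - 0.5) == sign(fy - 0.5)) {
        action[i] <- "palindromic_aligned"
      } else {
        action[i] <- "dropped"
        reason[i] <- if (informative) "palindromic eafs on opposite sides of 0.5"
                     else "palindromic with uninformative or missing eaf"
        next
      }
    }
    if (ex$beta[i] == 0) {
      action[i] <- "dropped"; reason[i] <- "zero exposure beta, Wald ratio undefined"
      next
    }
    if (action[i] == "") action[i] <- "unchanged"
  }

  tab <- data.frame(
    variant_id    = shared,
    effect_allele = ex$effect_allele,
    other_allele  = ex$other_allele,
    beta_exposure = ex$beta,
    se_exposure   = ex$se,
    eaf_exposure  = ex$eaf,
    pvalue_exposure = ex$pvalue,
    beta_outcome  = b_out,
    se_outcome    = ou$se,
    eaf_outcome   = eaf_out,
    chrom         = ex$chrom,
    pos           = ex$pos,
    action        = action,
    stringsAsFactors = FALSE
  )
  keep <- action != "dropped"
  inst <- tab[keep, , drop = FALSE]
  inst$wald_ratio <- inst$beta_outcome / inst$beta_exposure
  inst$wald_se <- inst$se_outcome / abs(inst$beta_exposure)
  dropped <- tab[!keep, , drop = FALSE]
  dropped$reason <- reason[!keep]
  rownames(inst) <- rownames(dropped) <- NULL

  selection_record$palindrome_eaf_limit <- palindrome_eaf_limit
  selection_record$n_shared <- n
  selection_record$n_retained <- nrow(inst)
  selection_record$n_dropped <- nrow(dropped)

  structure(
    list(exposure_name = exposure_name, outcome_name = outcome_name,
         instruments = inst, dropped = dropped,
         selection_record = selection_record),
    class = "mr_instrument_set"
  )
}

#' @export
print.mr_instrument_set <- function(x, ...) {
  cat(sprintf("Harmonized instrument set: %s -> %s\n",
              x$exposure_name, x$outcome_name))
  cat(sprintf("  %d instrument(s) retained, %d dropped (of %d shared variants)\n",
              nrow(x$instruments), nrow(x$dropped),
              x$selection_record$n_shared %||% (nrow(x$instruments) + nrow(x$dropped))))
  if (nrow(x$instruments)) {
    acts <- table(x$instruments$action)
    cat("  actions:", paste(sprintf("%s=%d", names(acts), acts), collapse = ", "), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a harmonized instrument set
#'
#' Writes the retained instruments as a TSV (full float precision) with a
#' JSON sidecar (`<path>.json`) holding the selection record, trait names
#' and dropped-variant log.
#'
#' @param set an `mr_instrument_set`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_instrument_set <- function(set, path) {
  df <- set$instruments
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(
    exposure_name = set$exposure_name,
    outcome_name = set$outcome_name,
    selection_record = set$selection_record,
    dropped = set$dropped
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Read back a serialized instrument set
#'
#' @param path TSV path previously written by [write_instrument_set()];
#'   the JSON sidecar `<path>.json` must sit next to it.
#' @return An `mr_instrument_set`.
#' @export
read_instrument_set <- function(path) {
  inst <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "")
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dropped <- side$dropped
  if (is.null(dropped) || length(dropped) == 0L) {
    dropped <- inst[0, , drop = FALSE]
    dropped$reason <- character(0)
  }
  structure(
    list(exposure_name = side$exposure_name, outcome_name = side$outcome_name,
         instruments = inst, dropped = as.data.frame(dropped),
         selection_record = side$selection_record),
    class = "mr_instrument_set"
  )
}

# Internal: build an mr_instrument_set directly from aligned effect vectors.
# Used by the simulator, tests and estimator-level utilities where the
# allele bookkeeping has already been resolved.
instrument_set <- function(beta_exposure, se_exposure, beta_outcome, se_outcome,
                           variant_id = sprintf("snp_%03d", seq_along(beta_exposure)),
                           eaf_exposure = rep(NA_real_, length(beta_exposure)),
                           eaf_outcome = eaf_exposure,
                           exposure_name = "exposure", outcome_name = "outcome",
                           selection_record = list()) {
  J <- length(beta_exposure)
  se_exposure <- rep_len(se_exposure, J)
  beta_outcome <- rep_len(beta_outcome, J)
  se_outcome <- rep_len(se_outcome, J)
  eaf_exposure <- rep_len(eaf_exposure, J)
  eaf_outcome <- rep_len(eaf_outcome, J)
  stopifnot(all(se_exposure > 0), all(se_outcome > 0), all(beta_exposure != 0))
  inst <- data.frame(
    variant_id = variant_id,
    effect_allele = "A", other_allele = "G",
    beta_exposure = beta_exposure, se_exposure = se_exposure,
    eaf_exposure = eaf_exposure,
    pvalue_exposure = 2 * stats::pnorm(-abs(beta_exposure / se_exposure)),
    beta_outcome = beta_outcome, se_outcome = se_outcome,
    eaf_outcome = eaf_outcome,
    chrom = NA_character_, pos = NA_real_,
    action = "unchanged",
    wald_ratio = beta_outcome / beta_exposure,
    wald_se = se_outcome / abs(beta_exposure),
    stringsAsFactors = FALSE
  )
  dropped <- inst[0, , drop = FALSE]
  dropped$reason <- character(0)
  selection_record$n_shared <- nrow(inst)
  selection_record$n_retained <- nrow(inst)
  selection_record$n_dropped <- 0L
  structure(list(exposure_name = exposure_name, outcome_name = outcome_name,
                 instruments = inst, dropped = dropped,
                 selection_record = selection_record),
            class = "mr_instrument_set")
}
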