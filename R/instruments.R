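#' Filter associations at a significance threshold
#'
#' Keeps exactly the records with `pvalue <= threshold`, preserving input
#' order. The conventional genome-wide threshold for instrument discovery
#' is `5e-8`.
#'
#' @param assocs a `gwas_assoc` data frame.
#' @param threshold significance level in (0, 1].
#' @return The filtered `gwas_assoc`. An empty result triggers a warning
#'   (downstream estimation needs at least one instrument) but not an error.
#' @export
select_by_pvalue <- function(assocs, threshold = 5e-8) {
  stopifnot(threshold > 0, threshold <= 1)
  out <- assocs[!is.na(assocs$pvalue) & assocs$pvalue <= threshold, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no associations pass p <= ", format(threshold))
  out
}

#' Read a square LD matrix of squared correlations
#'
#' Reads a tab-separated square matrix with a header row of variant ids
#' (and the same ids implied row-wise, in order). Validates symmetry, a
#' unit diagonal and entries in \[0, 1\].
#'
#' @param path TSV path.
#' @return A numeric matrix with variant ids as dimnames.
#' @export
read_ld_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE, quote = ""))
  rownames(m) <- colnames(m)
  validate_ld_matrix(m)
  m
}

#' @rdname read_ld_matrix
#' @param r2 a square matrix of squared correlations with variant-id dimnames.
#' @export
validate_ld_matrix <- function(r2) {
  if (!is.matrix(r2) || nrow(r2) != ncol(r2)) stop("LD matrix must be square")
  if (is.null(colnames(r2))) stop("LD matrix must carry variant ids as dimnames")
  if (any(r2 < 0 | r2 > 1)) stop("LD r-squared entries must lie in [0, 1]")
  if (max(abs(r2 - t(r2))) > 1e-8) stop("LD matrix must be symmetric")
  if (max(abs(diag(r2) - 1)) > 1e-8) stop("LD matrix diagonal must be 1")
  invisible(r2)
}

#' Greedy LD clumping
#'
#' Greedy index-variant selection: sort by ascending p-value (ties broken
#' lexicographically by variant id for determinism); accept the best
#' remaining variant; discard every remaining variant with squared
#' correlation above `r2_threshold` to an accepted variant, or — when the
#' pair has no LD entry — lying within `window_kb` of it on the same
#' chromosome; repeat until exhausted. LD takes precedence over physical
#' distance when both are available.
#'
#' @param assocs a `gwas_assoc` data frame.
#' @param ld LD matrix (squared correlations, unit diagonal) covering the
#'   variants, or `NULL` to prune purely by distance.
#' @param r2_threshold squared-correlation threshold (default 0.001).
#' @param window_kb physical pruning window in kb (default 10000).
#' @return The accepted subset of `assocs`, in acceptance order.
#' @export
ld_clump <- function(assocs, ld = NULL, r2_threshold = 0.001, window_kb = 10000) {
  if (nrow(assocs) == 0L) return(assocs)
  if (!is.null(ld)) validate_ld_matrix(ld)
  ids <- assocs$variant_id
  in_ld <- if (is.null(ld)) rep(FALSE, nrow(assocs)) else ids %in% colnames(ld)
  has_coord <- !is.na(assocs$chrom) & !is.na(assocs$pos)
  if (any(!in_ld & !has_coord)) {
    stop("variant(s) missing from the LD matrix and lacking coordinates: ",
         paste(ids[!in_ld & !has_coord], collapse = ", "))
  }
  ord <- order(assocs$pvalue, ids)
  alive <- rep(TRUE, nrow(assocs))
  accepted <- integer(0)
  for (i in ord) {
    if (!alive[i]) next
    accepted <- c(accepted, i)
    alive[i] <- FALSE
    for (j in ord) {
      if (!alive[j]) next
      pair_ld <- in_ld[i] && in_ld[j]
      if (pair_ld) {
        if (ld[ids[i], ids[j]] > r2_threshold) alive[j] <- FALSE
      } else if (has_coord[i] && has_coord[j] &&
                 assocs$chrom[i] == assocs$chrom[j] &&
                 abs(assocs$pos[i] - assocs$pos[j]) < window_kb * 1000) {
        alive[j] <- FALSE
      }
    }
  }
  out <- assocs[accepted, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Instrument-strength F statistics and variance explained
#'
#' Per-instrument F statistics `(beta/se)^2`, the variance in the exposure
#' explained by each instrument under the standardized-trait approximation
#' `r2_j = 2 eaf_j (1 - eaf_j) beta_j^2`, and the aggregate F
#' `(n - k - 1)/k * R2/(1 - R2)` over the `k` instruments jointly.
#'
#' @param assocs exposure-side associations (`gwas_assoc` columns `beta`,
#'   `se`, `eaf`) or an `mr_instrument_set` (its exposure side is used).
#' @param n exposure-GWAS sample size; must exceed the number of
#'   instruments plus one for the aggregate F.
#' @return An object of class `mr_strength`: list with `per_snp_f`,
#'   `mean_f`, `r2_total`, `aggregate_f`, `n`, `k` and a `note` recording
#'   the variance-explained approximation. When any eaf is missing,
#'   `r2_total` and `aggregate_f` are `NA` and the note says why.
#' @export
instrument_strength <- function(assocs, n) {
  if (inherits(assocs, "mr_instrument_set")) {
    inst <- assocs$instruments
    beta <- inst$beta_exposure; se <- inst$se_exposure; eaf <- inst$eaf_exposure
  } else {
    beta <- assocs$beta; se <- assocs$se; eaf <- assocs$eaf
  }
  k <- length(beta)
  stopifnot(k >= 1, all(se > 0))
  per_snp_f <- (beta / se)^2
  note <- "r2 per instrument approximated as 2*eaf*(1-eaf)*beta^2 (standardized trait)"
  if (any(is.na(eaf))) {
    r2_total <- NA_real_; aggregate_f <- NA_real_
    note <- paste0(note, "; unavailable: missing eaf")
  } else {
    r2_total <- sum(2 * eaf * (1 - eaf) * beta^2)
    if (missing(n) || is.na(n) || n <= k + 1) {
      aggregate_f <- NA_real_
      note <- paste0(note, "; aggregate F unavailable: need n > k + 1")
    } else {
      aggregate_f <- (n - k - 1) / k * r2_total / (1 - r2_total)
    }
  }
  structure(list(per_snp_f = per_snp_f, mean_f = mean(per_snp_f),
                 r2_total = r2_total, aggregate_f = aggregate_f,
                 n = if (missing(n)) NA_real_ else n, k = k, note = note),
            class = "mr_strength")
}

#' @export
print.mr_strength <- function(x, ...) {
  cat(sprintf("Instrument strength over %d instrument(s)\n", x$k))
  cat(sprintf("  mean per-SNP F: %.2f  (range %.2f-%.2f)\n",
              x$mean_f, min(x$per_snp_f), max(x$per_snp_f)))
  if (!is.na(x$r2_total))
    cat(sprintf("  total variance explained: %.4f; aggregate F: %.2f\n",
                x$r2_total, x$aggregate_f))
  invisible(x)
}
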