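#' Fit the full suite of two-sample MR estimators
#'
#' The central fitting function: given a harmonized instrument set it runs
#' the inverse-variance weighted model (multiplicative random effects — the
#' principal analysis — plus the fixed-effect version), the weighted
#' median, MR-Egger, MR-PRESSO outlier correction and the contamination
#' mixture model, together with Cochran's Q heterogeneity. Methods whose
#' preconditions the set cannot meet (e.g. MR-PRESSO below 4 instruments)
#' are skipped with a recorded note rather than an error.
#'
#' @param set an `mr_instrument_set` (see [harmonize()]).
#' @param methods subset of `c("ivw", "weighted_median", "egger",
#'   "presso", "conmix")`; IVW is always fitted.
#' @param n_boot bootstrap replicates for the weighted median.
#' @param seed RNG seed governing the weighted-median bootstrap and the
#'   MR-PRESSO simulations.
#' @param conmix_psi invalid-component scale for the contamination
#'   mixture, or `"auto"`.
#' @param presso_nsim,presso_alpha MR-PRESSO settings (see [mr_presso()]).
#' @param n_exposure exposure-GWAS sample size; when supplied (or
#'   recoverable from the set), instrument-strength F statistics are
#'   attached.
#' @return An object of class `mr_fit` with components `estimates` (one
#'   row per method: log-scale effect, SE, 95% CI, p-value, OR scale),
#'   `details` (the underlying method objects), `heterogeneity`,
#'   `strength`, `set`, `config` and `skipped`. Supports `print()`,
#'   `summary()`, `coef()`, `confint()`, `plot()` and `residuals()`.
#' @export
#' @examples
#' sim <- generate_two_sample(mr_scenario("mdd_to_gerd", seed = 7))
#' set <- harmonize(sim$exposure, sim$outcome,
#'                  exposure_name = "MDD", outcome_name = "GERD")
#' fit <- mr_fit(set)
#' fit
#' coef(fit)
mr_fit <- function(set,
                   methods = c("ivw", "weighted_median", "egger", "presso",
                               "conmix"),
                   n_boot = 1000, seed = 1, conmix_psi = "auto",
                   presso_nsim = 1000, presso_alpha = 0.05,
                   n_exposure = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  inst <- .set_instruments(set)
  J <- nrow(inst)
  if (J < 1) stop("empty instrument set")
  details <- list()
  skipped <- character(0)
  rows <- list()

  add_row <- function(est) rows[[length(rows) + 1L]] <<- est

  ivw_r <- mr_ivw(set, "random")
  details$ivw_random <- ivw_r
  add_row(ivw_r)

  if ("weighted_median" %in% methods) {
    if (J >= 3) {
      wm <- mr_weighted_median(set, n_boot = n_boot, seed = seed)
      details$weighted_median <- wm
      add_row(wm)
    } else skipped <- c(skipped, "weighted_median: needs >= 3 instruments")
  }
  if ("egger" %in% methods) {
    if (J >= 3) {
      eg <- mr_egger(set)
      details$egger <- eg
      add_row(eg$slope)
    } else skipped <- c(skipped, "egger: needs >= 3 instruments")
  }
  if ("presso" %in% methods) {
    if (J >= 4) {
      pr <- mr_presso(set, n_sim = presso_nsim, seed = seed,
                      outlier_alpha = presso_alpha)
      details$presso <- pr
      corrected <- pr$theta_corrected
      corrected$method <- "presso_corrected"
      add_row(corrected)
    } else skipped <- c(skipped, "presso: needs >= 4 instruments")
  }
  if ("conmix" %in% methods) {
    if (J >= 2) {
      cm <- mr_conmix(set, psi = conmix_psi)
      details$conmix <- cm
      add_row(cm$estimate)
    } else skipped <- c(skipped, "conmix: needs >= 2 instruments")
  }
  if (J >= 2) {
    ivw_f <- mr_ivw(set, "fixed")
    details$ivw_fixed <- ivw_f
    add_row(ivw_f)
  }

  estimates <- do.call(rbind, lapply(rows, function(e) {
    data.frame(method = e$method, theta = e$theta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, pvalue = e$pvalue,
               n_snps = e$n_snps, or = e$or, or_low = e$or_low,
               or_high = e$or_high, stringsAsFactors = FALSE)
  }))
  rownames(estimates) <- NULL

  heterogeneity <- if (J >= 2) cochran_q(set) else NULL

  if (is.null(n_exposure)) {
    # fall back to the per-variant n column carried through harmonization
    n_exposure <- set$selection_record$n_exposure
  }
  strength <- tryCatch({
    pseudo <- data.frame(beta = inst$beta_exposure, se = inst$se_exposure,
                         eaf = inst$eaf_exposure)
    if (is.null(n_exposure)) instrument_strength(pseudo)
    else instrument_strength(pseudo, n = n_exposure)
  }, error = function(e) NULL)

  structure(list(
    set = set, estimates = estimates, details = details,
    heterogeneity = heterogeneity, strength = strength,
    config = list(methods = methods, n_boot = n_boot, seed = seed,
                  conmix_psi = conmix_psi, presso_nsim = presso_nsim,
                  presso_alpha = presso_alpha, n_exposure = n_exposure),
    skipped = skipped
  ), class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-sample MR: %s -> %s (%d instruments)\n",
              x$set$exposure_name, x$set$outcome_name,
              nrow(x$set$instruments)))
  tab <- x$estimates
  out <- data.frame(method = tab$method,
                    theta = round(tab$theta, digits),
                    se = round(tab$se, digits),
                    OR = round(tab$or, 3),
                    `95% CI` = sprintf("%.3f-%.3f", tab$or_low, tab$or_high),
                    p = signif(tab$pvalue, 3),
                    check.names = FALSE)
  print(out, row.names = FALSE)
  if (!is.null(x$heterogeneity))
    cat(sprintf("Cochran's Q = %.2f on %d df (p = %.3g)\n",
                x$heterogeneity$q, x$heterogeneity$df,
                x$heterogeneity$pvalue))
  if (!is.null(x$details$egger))
    cat(sprintf("Egger intercept = %.4f (p = %.3g)\n",
                x$details$egger$intercept$estimate,
                x$details$egger$intercept$pvalue))
  if (length(x$skipped))
    cat("skipped:", paste(x$skipped, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  if (!is.null(f$strength) && !is.na(f$strength$mean_f)) {
    cat(sprintf("Mean instrument F = %.2f", f$strength$mean_f))
    if (!is.na(f$strength$r2_total))
      cat(sprintf("; total r2 = %.4f", f$strength$r2_total))
    if (!is.na(f$strength$aggregate_f))
      cat(sprintf("; aggregate F = %.2f", f$strength$aggregate_f))
    cat("\n")
  }
  if (!is.null(f$details$presso)) {
    pr <- f$details$presso
    cat(sprintf("MR-PRESSO global p = %.3g; %d outlier(s)%s\n",
                pr$global_pvalue, length(pr$outlier_indices),
                if (length(pr$outlier_indices))
                  sprintf(" (%s), distortion p = %.3g",
                          paste(pr$outlier_variants, collapse = ", "),
                          pr$distortion_pvalue) else ""))
  }
  if (!is.null(f$details$conmix)) {
    cm <- f$details$conmix
    cat(sprintf("Contamination mixture: psi = %.3f, %d/%d valid\n",
                cm$psi, sum(cm$valid), length(cm$valid)))
  }
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$estimates$theta, object$estimates$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  tab <- object$estimates
  if (level != 0.95)
    warning("intervals are computed at fit time for level 0.95; returning those")
  m <- cbind(tab$ci_low, tab$ci_high)
  dimnames(m) <- list(tab$method, c("2.5 %", "97.5 %"))
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' @export
residuals.mr_fit <- function(object, ...) {
  inst <- object$set$instruments
  theta <- object$estimates$theta[object$estimates$method == "ivw_random"][1]
  stats::setNames((inst$wald_ratio - theta) / inst$wald_se, inst$variant_id)
}

#' Scatter plot of a fitted MR model
#'
#' Outcome effects against exposure effects (oriented to positive exposure
#' effects) with one-standard-error bars and the fitted IVW, MR-Egger and
#' weighted-median lines.
#'
#' @param x an `mr_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mr_fit <- function(x, ...) {
  inst <- x$set$instruments
  flip <- sign(inst$beta_exposure)
  bx <- inst$beta_exposure * flip
  by <- inst$beta_outcome * flip
  graphics::plot(bx, by,
                 xlab = sprintf("effect on %s (log OR)", x$set$exposure_name),
                 ylab = sprintf("effect on %s (log OR)", x$set$outcome_name),
                 pch = 19, ...)
  graphics::segments(bx, by - inst$se_outcome, bx, by + inst$se_outcome,
                     col = "grey60")
  graphics::segments(bx - inst$se_exposure, by, bx + inst$se_exposure, by,
                     col = "grey60")
  tab <- x$estimates
  theta_of <- function(m) tab$theta[tab$method == m][1]
  graphics::abline(0, theta_of("ivw_random"), col = "black", lwd = 2)
  leg <- "IVW (random)"; cols <- "black"; ltys <- 1
  if (!is.null(x$details$egger)) {
    graphics::abline(x$details$egger$intercept$estimate,
                     x$details$egger$slope$theta, col = "blue", lty = 2)
    leg <- c(leg, "MR-Egger"); cols <- c(cols, "blue"); ltys <- c(ltys, 2)
  }
  if ("weighted_median" %in% tab$method) {
    graphics::abline(0, theta_of("weighted_median"), col = "darkgreen", lty = 3)
    leg <- c(leg, "weighted median"); cols <- c(cols, "darkgreen")
    ltys <- c(ltys, 3)
  }
  graphics::legend("topleft", legend = leg, col = cols, lty = ltys, bty = "n")
  invisible(x)
}
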