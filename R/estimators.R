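# Five causal estimators for two-sample MR on harmonized instrument sets.
# All work on the log-odds scale of both traits; every estimate is also
# reported on the odds-ratio scale (exp of the log-scale numbers).

.set_instruments <- function(set) {
  if (inherits(set, "mr_instrument_set")) set$instruments
  else stop("expected an mr_instrument_set; got ", class(set)[1])
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

mr_estimate <- function(method, theta, se, ci_low, ci_high, pvalue, n_snps) {
  structure(list(method = method, theta = theta, se = se,
                 ci_low = ci_low, ci_high = ci_high, pvalue = pvalue,
                 n_snps = n_snps,
                 or = exp(theta), or_low = exp(ci_low), or_high = exp(ci_high)),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: theta = %.4f (95%% CI %.4f to %.4f), OR = %.3f (%.3f-%.3f), p = %.3g, %d SNP(s)\n",
              x$method, x$theta, x$ci_low, x$ci_high,
              x$or, x$or_low, x$or_high, x$pvalue, x$n_snps))
  invisible(x)
}

#' Inverse-variance weighted causal estimate
#'
#' Combines per-variant Wald ratios with first-order inverse-variance
#' weights `w_j = (beta_exposure_j / se_outcome_j)^2`, equivalent to a
#' weighted regression of outcome effects on exposure effects through the
#' origin. The fixed-effect standard error is `(sum w_j)^{-1/2}`; the
#' multiplicative random-effects model (the principal analysis) inflates it
#' by `max(1, sqrt(Q / (J - 1)))` with Q Cochran's heterogeneity statistic
#' at the estimate, so the random-effects SE is never smaller than the
#' fixed-effect one. P-values and CIs use the standard normal reference.
#'
#' A single instrument degenerates to its Wald ratio with a warning.
#'
#' @param set an `mr_instrument_set` with at least one instrument.
#' @param model `"random"` (default) or `"fixed"`.
#' @return An `mr_estimate` (`method` `"ivw_random"`, `"ivw_fixed"` or
#'   `"wald"` in the degenerate case) with attribute `"Q"` carrying the
#'   heterogeneity statistic used for the inflation factor.
#' @export
mr_ivw <- function(set, model = c("random", "fixed")) {
  model <- match.arg(model)
  inst <- .set_instruments(set)
  J <- nrow(inst)
  if (J < 1) stop("IVW requires at least one instrument")
  if (J == 1) {
    warning("single instrument: IVW degenerates to the Wald ratio")
    theta <- inst$wald_ratio; se <- inst$wald_se
    z <- qnorm(0.975)
    est <- mr_estimate("wald", theta, se, theta - z * se, theta + z * se,
                       2 * pnorm(-abs(theta / se)), 1L)
    attr(est, "Q") <- 0
    return(est)
  }
  w <- (inst$beta_exposure / inst$se_outcome)^2
  if (all(w == 0)) stop("all IVW weights are zero")
  ratio <- inst$wald_ratio
  theta <- sum(w * ratio) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  Q <- sum(w * (ratio - theta)^2)
  se <- if (model == "random") se_fixed * max(1, sqrt(Q / (J - 1))) else se_fixed
  z <- qnorm(0.975)
  est <- mr_estimate(paste0("ivw_", model), theta, se,
                     theta - z * se, theta + z * se,
                     2 * pnorm(-abs(theta / se)), J)
  attr(est, "Q") <- Q
  est
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with
#' an unconstrained intercept, weights `1 / se_outcome^2`, after orienting
#' every instrument so its exposure effect is positive. The slope is the
#' pleiotropy-corrected causal estimate; the intercept estimates the
#' average directional pleiotropic effect, and its two-sided test is the
#' standard directional-pleiotropy diagnostic. Standard errors carry a
#' multiplicative overdispersion factor `max(1, sqrt(Q_egger / (J - 2)))`
#' and inference uses the t distribution with `J - 2` degrees of freedom.
#'
#' @param set an `mr_instrument_set` with at least 3 instruments.
#' @return Object of class `mr_egger`: list with `slope` (an
#'   `mr_estimate`, method `"egger"`), `intercept` (estimate, se, ci,
#'   pvalue), `Q` (residual heterogeneity, df `J - 2`) and `df`.
#' @export
mr_egger <- function(set) {
  inst <- .set_instruments(set)
  J <- nrow(inst)
  if (J < 3) stop("MR-Egger requires at least 3 instruments (got ", J, ")")
  flip <- sign(inst$beta_exposure)
  bx <- inst$beta_exposure * flip
  by <- inst$beta_outcome * flip
  w <- 1 / inst$se_outcome^2
  # weighted normal equations for [intercept, slope]
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  swxx <- sum(w * bx^2); swxy <- sum(w * bx * by)
  det <- sw * swxx - swx^2
  if (det <= 0) stop("degenerate design: exposure effects carry no spread")
  b0 <- (swxx * swy - swx * swxy) / det
  b1 <- (sw * swxy - swx * swy) / det
  resid <- by - b0 - b1 * bx
  Q <- sum(w * resid^2)
  phi <- max(1, sqrt(Q / (J - 2)))
  var0 <- swxx / det * phi^2
  var1 <- sw / det * phi^2
  se0 <- sqrt(var0); se1 <- sqrt(var1)
  tq <- qt(0.975, df = J - 2)
  p1 <- 2 * pt(-abs(b1 / se1), df = J - 2)
  p0 <- 2 * pt(-abs(b0 / se0), df = J - 2)
  slope <- mr_estimate("egger", b1, se1, b1 - tq * se1, b1 + tq * se1, p1, J)
  structure(list(
    slope = slope,
    intercept = list(estimate = b0, se = se0,
                     ci_low = b0 - tq * se0, ci_high = b0 + tq * se0,
                     pvalue = p0),
    Q = Q, df = J - 2, overdispersion = phi
  ), class = "mr_egger")
}

#' @export
print.mr_egger <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept = %.4f (SE %.4f), p = %.3g; residual Q = %.2f on %d df\n",
              x$intercept$estimate, x$intercept$se, x$intercept$pvalue,
              x$Q, x$df))
  invisible(x)
}

# Weighted median of ratio estimates by midpoint-cumulative-weight
# interpolation; weights must sum to 1.
.weighted_median_point <- function(ratio, weight) {
  o <- order(ratio)
  r <- ratio[o]
  w <- weight[o] / sum(weight)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(s)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted median causal estimate
#'
#' Consistent when instruments contributing at least half the total
#' inverse-variance weight are valid. Ratio estimates are sorted and the
#' estimate is the linear interpolation of the sorted ratios at cumulative
#' weight one half, using midpoint cumulative weights
#' `s_j = sum_{i<=j} w'_i - w'_j / 2` with normalized weights
#' `w_j = 1 / wald_se_j^2`. The standard error is the standard deviation of
#' the estimate over `n_boot` parametric-bootstrap replicates in which each
#' ratio is redrawn from `N(wald_ratio_j, wald_se_j^2)`; the bootstrap is
#' seeded and leaves the caller's RNG state untouched.
#'
#' @param set an `mr_instrument_set` with at least 3 instruments.
#' @param n_boot bootstrap replicates (default 1000, minimum 100).
#' @param seed RNG seed for the bootstrap (default 1).
#' @return An `mr_estimate` with method `"weighted_median"` (normal
#'   reference for CI and p-value).
#' @export
mr_weighted_median <- function(set, n_boot = 1000, seed = 1) {
  inst <- .set_instruments(set)
  J <- nrow(inst)
  if (J < 3) stop("weighted median requires at least 3 instruments (got ", J, ")")
  if (n_boot < 100) stop("n_boot must be at least 100")
  w <- 1 / inst$wald_se^2
  theta <- .weighted_median_point(inst$wald_ratio, w)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      r <- rnorm(J, mean = inst$wald_ratio, sd = inst$wald_se)
      .weighted_median_point(r, w)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  z <- qnorm(0.975)
  mr_estimate("weighted_median", theta, se, theta - z * se, theta + z * se,
              2 * pnorm(-abs(theta / se)), J)
}

#' Contamination mixture causal estimate
#'
#' Models each Wald ratio as drawn either from a valid component centred on
#' the causal effect (variance `wald_se_j^2`) or from an invalid component
#' centred on zero with inflated variance `wald_se_j^2 + psi^2`. For each
#' candidate effect on a grid, the profile log-likelihood takes the better
#' component per instrument and sums; the estimate maximizes the profile,
#' and the 95% confidence set collects grid values whose profile deviance
#' from the maximum is at most 3.84 (the chi-squared 1-df critical value) —
#' it may be a union of disjoint intervals when the instruments support
#' several effect values.
#'
#' @param set an `mr_instrument_set` with at least 2 instruments.
#' @param psi scale of the invalid component; `"auto"` (default) uses
#'   1.5 times the standard deviation of the ratio estimates, falling back
#'   to the median ratio SE when that spread is zero.
#' @param grid numeric vector of candidate effects; default spans the IVW
#'   random-effects estimate plus/minus 10 of its standard errors in 2001
#'   steps. A grid that excludes the IVW estimate triggers a warning.
#' @return Object of class `mr_conmix`: list with `estimate` (an
#'   `mr_estimate`, method `"contamination_mixture"`, `se` absent; its
#'   `ci_low`/`ci_high` are the extremes of the confidence set; the p-value
#'   is a 1-df likelihood-ratio test of zero effect), `theta_hat`, `ci_set`
#'   (data frame of interval bounds), `psi`, `valid` (logical per-SNP
#'   classification at the estimate), and the grid resolution.
#' @export
mr_conmix <- function(set, psi = "auto", grid = NULL) {
  inst <- .set_instruments(set)
  J <- nrow(inst)
  if (J < 2) stop("contamination mixture requires at least 2 instruments")
  r <- inst$wald_ratio
  s <- inst$wald_se
  if (identical(psi, "auto")) {
    psi <- 1.5 * stats::sd(r)
    # degenerate sets (identical ratios) would give psi = 0; fall back to
    # the median ratio SE so the invalid component stays proper
    if (!is.finite(psi) || psi <= 0) psi <- stats::median(s)
  }
  if (!is.numeric(psi) || psi <= 0) stop("psi must be positive or \"auto\"")
  ivw <- mr_ivw(set, "random")
  if (is.null(grid)) {
    grid <- seq(ivw$theta - 10 * ivw$se, ivw$theta + 10 * ivw$se,
                length.out = 2001)
  }
  grid <- sort(grid)
  if (ivw$theta < min(grid) || ivw$theta > max(grid)) {
    warning("grid excludes the IVW estimate; consider a wider grid")
  }
  s_inv <- sqrt(s^2 + psi^2)
  ll_invalid <- dnorm(r, 0, s_inv, log = TRUE)        # J
  # J x G matrix of valid-component log-likelihoods
  ll_valid <- dnorm(outer(r, grid, "-") / s, log = TRUE) - log(s)
  ll_prof <- colSums(pmax(ll_valid, ll_invalid))
  i_hat <- which.max(ll_prof)
  theta_hat <- grid[i_hat]
  inside <- 2 * (ll_prof[i_hat] - ll_prof) <= qchisq(0.95, 1)
  runs <- rle(inside)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  ci_set <- data.frame(low = grid[starts[keep]], high = grid[ends[keep]])
  valid <- dnorm(r, theta_hat, s, log = TRUE) >= ll_invalid
  # likelihood-ratio test of theta = 0 against the profile maximum
  ll0 <- sum(pmax(dnorm(r, 0, s, log = TRUE), ll_invalid))
  pvalue <- pchisq(2 * (ll_prof[i_hat] - ll0), df = 1, lower.tail = FALSE)
  est <- mr_estimate("contamination_mixture", theta_hat, NA_real_,
                     min(ci_set$low), max(ci_set$high), pvalue, J)
  structure(list(estimate = est, theta_hat = theta_hat, ci_set = ci_set,
                 psi = psi, valid = valid,
                 grid_range = range(grid), grid_steps = length(grid)),
            class = "mr_conmix")
}

#' @export
print.mr_conmix <- function(x, ...) {
  print(x$estimate)
  cat(sprintf("  psi = %.4f; %d/%d instrument(s) classified valid; confidence set of %d interval(s)\n",
              x$psi, sum(x$valid), length(x$valid), nrow(x$ci_set)))
  invisible(x)
}
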