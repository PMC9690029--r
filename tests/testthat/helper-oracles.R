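# Independent straight-line oracles. Each re-derives a quantity by a
# different route than the package (lm/QR instead of closed-form sums,
# explicit scans instead of vectorized interpolation) so agreement is a
# genuine cross-check.

# Weighted least squares through the origin via lm's QR decomposition;
# returns the estimate and the fixed-effect SE (residual scale forced to 1).
oracle_ivw_fixed <- function(bx, by, sy) {
  fit <- lm(by ~ 0 + bx, weights = 1 / sy^2)
  s <- summary(fit)
  theta <- unname(coef(fit)[1])
  se_fixed <- unname(s$coefficients[1, 2] / s$sigma)
  list(theta = theta, se = se_fixed)
}

# Weighted regression with intercept via lm, multiplicative overdispersion
# floored at 1, t reference with J - 2 df.
oracle_egger <- function(bx, by, sy) {
  flip <- sign(bx)
  bx <- bx * flip; by <- by * flip
  fit <- lm(by ~ bx, weights = 1 / sy^2)
  s <- summary(fit)
  J <- length(bx)
  phi <- max(1, s$sigma)
  se <- s$coefficients[, 2] / s$sigma * phi
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       se_intercept = unname(se[1]), se_slope = unname(se[2]),
       p_slope = 2 * pt(-abs(coef(fit)[2] / se[2]), J - 2))
}

# Brute-force weighted median: explicit scan of the midpoint cumulative
# weight function with manual interpolation.
oracle_weighted_median <- function(ratio, weight) {
  o <- order(ratio)
  r <- ratio[o]
  w <- weight[o] / sum(weight)
  s <- numeric(length(w))
  acc <- 0
  for (j in seq_along(w)) {
    s[j] <- acc + w[j] / 2
    acc <- acc + w[j]
  }
  if (s[1] >= 0.5) return(r[1])
  for (j in seq_len(length(s) - 1)) {
    if (s[j] < 0.5 && s[j + 1] >= 0.5) {
      return(r[j] + (r[j + 1] - r[j]) * (0.5 - s[j]) / (s[j + 1] - s[j]))
    }
  }
  r[length(r)]
}

# Greedy clumping re-executed as explicit set bookkeeping over id vectors.
oracle_clump <- function(assocs, ld, r2_threshold) {
  remaining <- assocs$variant_id
  accepted <- character(0)
  while (length(remaining)) {
    p <- assocs$pvalue[match(remaining, assocs$variant_id)]
    best <- remaining[order(p, remaining)][1]
    accepted <- c(accepted, best)
    remaining <- setdiff(remaining, best)
    drop <- remaining[ld[best, remaining] > r2_threshold]
    remaining <- setdiff(remaining, drop)
  }
  accepted
}

# Random positive-definite-ish r2 matrix with unit diagonal.
random_ld_matrix <- function(ids) {
  k <- length(ids)
  a <- matrix(rnorm((k + 5) * k), k + 5, k)
  r2 <- cov2cor(crossprod(a))^2
  diag(r2) <- 1
  dimnames(r2) <- list(ids, ids)
  r2
}
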