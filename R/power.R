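#' Analytic power for two-sample MR with a binary outcome
#'
#' Standard normal-approximation power for detecting a hypothesized odds
#' ratio per unit of exposure with a two-sided Wald test at level `alpha`:
#' `power = Phi(|ln OR| * sqrt(n * r2 * K * (1 - K)) - z_{1 - alpha/2})`,
#' where `n` is the outcome-GWAS sample size, `K` its case fraction, and
#' `r2` the fraction of exposure variance explained by the instruments.
#' Power is symmetric in `OR` and `1/OR` and monotone in `n`, `r2`,
#' `|ln OR|` and `K(1 - K)`; at `OR = 1` it equals `alpha / 2` (one tail
#' of the two-sided test).
#'
#' @param n outcome-GWAS sample size (> 0).
#' @param k_ratio proportion of cases K, in (0, 1).
#' @param odds_ratio hypothesized effect (> 0).
#' @param r2 exposure variance explained by the instruments, in (0, 1).
#' @param alpha two-sided significance level (default 0.05).
#' @return Power in \[0, 1\]. Vectorized over all arguments.
#' @export
#' @examples
#' mr_power_binary(n = 385276, k_ratio = 80265 / 385276,
#'                 odds_ratio = 1.31, r2 = 0.01)
mr_power_binary <- function(n, k_ratio, odds_ratio, r2, alpha = 0.05) {
  stopifnot(all(n > 0), all(k_ratio > 0 & k_ratio < 1),
            all(odds_ratio > 0), all(r2 > 0 & r2 < 1),
            all(alpha > 0 & alpha < 1))
  b <- log(odds_ratio)
  pnorm(abs(b) * sqrt(n * r2 * k_ratio * (1 - k_ratio)) - qnorm(1 - alpha / 2))
}
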