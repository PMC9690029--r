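# Synthetic two-sample GWAS summary statistics with known generating truth.
# Every stage of the analysis (selection, clumping, harmonization,
# estimation, diagnostics) can be exercised against these tables without
# any external data.

#' Generating parameters for a synthetic two-sample dataset
#'
#' Bundles the full generating truth of a simulated pair of case-control
#' GWAS: the causal effect `theta` (log-OR of outcome per log-OR of
#' exposure), the exposure-effect distribution, the pleiotropy structure,
#' and the two study designs. Per-variant standard errors follow the
#' allele-count approximation for a logistic-scale effect in a case-control
#' study, `se = 1 / sqrt(2 maf (1 - maf) n K (1 - K))`, which makes the
#' sample sizes interpretable as real case/non-case counts.
#'
#' @param theta true causal effect on the log-OR-per-log-OR scale.
#' @param n_snps number of instrument-candidate variants.
#' @param gamma_dist list `(mean, sd)` of the normal distribution of true
#'   exposure effects (log-odds per allele). The default (0.15, 0.03)
#'   yields per-variant F statistics of a few hundred at biobank-scale
#'   sample sizes, matching strongly instrumented analyses.
#' @param pleiotropy_mode `"none"`, `"balanced"` (mean-zero direct
#'   effects), `"directional"` (nonzero-mean direct effects), or
#'   `"inside_violating"` (direct effects correlated with the exposure
#'   effects, breaking the InSIDE assumption).
#' @param alpha_dist list `(mean, sd)` of pleiotropic direct effects for
#'   the contaminated variants.
#' @param invalid_fraction proportion of variants receiving a pleiotropic
#'   effect, in \[0, 1\].
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param case_fraction_exposure,case_fraction_outcome case proportions.
#' @param maf_dist list `(min, max)` of the uniform minor-allele-frequency
#'   distribution.
#' @param palindromic_fraction proportion of variants assigned an A/T or
#'   C/G allele pair (default 0.1), to exercise harmonization.
#' @param ld_blocks number of leading variant pairs given squared
#'   correlation `ld_block_r2` (default 0: identity LD).
#' @param ld_block_r2 within-block squared correlation.
#' @param seed RNG seed; the generator is fully deterministic given the
#'   truth, and a fixed seed yields bit-identical output.
#' @return An object of class `mr_truth` (validated list of the above).
#' @export
mr_truth <- function(theta = 0, n_snps = 31,
                     gamma_dist = list(mean = 0.15, sd = 0.03),
                     pleiotropy_mode = c("none", "balanced", "directional",
                                         "inside_violating"),
                     alpha_dist = list(mean = 0, sd = 0),
                     invalid_fraction = 0,
                     n_exposure = 173005, n_outcome = 385276,
                     case_fraction_exposure = 59851 / 173005,
                     case_fraction_outcome = 80265 / 385276,
                     maf_dist = list(min = 0.10, max = 0.35),
                     palindromic_fraction = 0.1,
                     ld_blocks = 0, ld_block_r2 = 0.5,
                     seed = 1) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(n_snps >= 1, invalid_fraction >= 0, invalid_fraction <= 1,
            n_exposure > 0, n_outcome > 0,
            case_fraction_exposure > 0, case_fraction_exposure < 1,
            case_fraction_outcome > 0, case_fraction_outcome < 1,
            maf_dist$min > 0, maf_dist$max < 0.5, maf_dist$min <= maf_dist$max,
            palindromic_fraction >= 0, palindromic_fraction <= 1,
            ld_blocks >= 0)
  structure(list(theta = theta, n_snps = as.integer(n_snps),
                 gamma_dist = gamma_dist, pleiotropy_mode = pleiotropy_mode,
                 alpha_dist = alpha_dist, invalid_fraction = invalid_fraction,
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 case_fraction_exposure = case_fraction_exposure,
                 case_fraction_outcome = case_fraction_outcome,
                 maf_dist = maf_dist,
                 palindromic_fraction = palindromic_fraction,
                 ld_blocks = as.integer(ld_blocks), ld_block_r2 = ld_block_r2,
                 seed = as.integer(seed)),
            class = "mr_truth")
}

.nonpal_pairs <- matrix(c("A", "C", "A", "G", "T", "C", "T", "G"),
                        ncol = 2, byrow = TRUE)
.pal_pairs <- matrix(c("A", "T", "C", "G"), ncol = 2, byrow = TRUE)

#' Generate a synthetic two-sample summary-statistics dataset
#'
#' Draws per-variant minor-allele frequencies and true exposure effects,
#' adds pleiotropic direct effects to the contaminated fraction according
#' to the pleiotropy mode, sets true outcome effects to
#' `theta * gamma_j + alpha_j`, and reports noisy estimates with the
#' case-control standard errors implied by each study's size and case
#' fraction. Effect-allele orientation is randomized independently per
#' study (and non-palindromic variants may additionally be reported on the
#' opposite strand in the outcome study), so the tables exercise the full
#' harmonization logic. Reported effect-allele frequencies are the true
#' frequencies on each study's orientation.
#'
#' @param truth an [mr_truth()] object.
#' @return A list with `exposure` and `outcome` (`gwas_assoc` data
#'   frames in the canonical dialect), `ld` (squared-correlation matrix:
#'   identity, plus any requested correlated blocks), and `truth` (the
#'   input, augmented with the per-variant `gamma`, `alpha` and
#'   `invalid` vectors actually drawn).
#' @export
generate_two_sample <- function(truth) {
  stopifnot(inherits(truth, "mr_truth"))
  J <- truth$n_snps
  with_seed(truth$seed, {
    maf <- runif(J, truth$maf_dist$min, truth$maf_dist$max)
    gamma <- rnorm(J, truth$gamma_dist$mean, truth$gamma_dist$sd)
    n_invalid <- round(truth$invalid_fraction * J)
    invalid <- rep(FALSE, J)
    if (n_invalid > 0) invalid[sample.int(J, n_invalid)] <- TRUE
    alpha <- numeric(J)
    if (any(invalid)) {
      m <- truth$alpha_dist$mean; s <- truth$alpha_dist$sd
      alpha[invalid] <- switch(truth$pleiotropy_mode,
        none = 0,
        balanced = rnorm(sum(invalid), 0, s),
        directional = rnorm(sum(invalid), m, s),
        inside_violating = m * gamma[invalid] / mean(gamma) +
          rnorm(sum(invalid), 0, s))
    }
    kx <- truth$case_fraction_exposure
    ky <- truth$case_fraction_outcome
    se_x <- 1 / sqrt(2 * maf * (1 - maf) * truth$n_exposure * kx * (1 - kx))
    se_y <- 1 / sqrt(2 * maf * (1 - maf) * truth$n_outcome * ky * (1 - ky))
    gamma_hat <- gamma + rnorm(J, 0, se_x)
    Gamma <- truth$theta * gamma + alpha
    Gamma_hat <- Gamma + rnorm(J, 0, se_y)

    pal <- runif(J) < truth$palindromic_fraction
    pair_idx_np <- sample.int(nrow(.nonpal_pairs), J, replace = TRUE)
    pair_idx_p <- sample.int(nrow(.pal_pairs), J, replace = TRUE)
    a_eff <- ifelse(pal, .pal_pairs[pair_idx_p, 1], .nonpal_pairs[pair_idx_np, 1])
    a_oth <- ifelse(pal, .pal_pairs[pair_idx_p, 2], .nonpal_pairs[pair_idx_np, 2])

    ids <- sprintf("rs%06d", seq_len(J))
    chrom <- as.character(rep_len(1:22, J))
    pos <- 1e6 + (seq_len(J) - 1) * 2e7
    if (truth$ld_blocks > 0) {
      # paired variants share a locus so window pruning also applies
      for (b in seq_len(min(truth$ld_blocks, J %/% 2))) {
        j <- 2 * b
        chrom[j] <- chrom[j - 1]
        pos[j] <- pos[j - 1] + 5e4
      }
    }

    study_table <- function(beta, se, n, flip_orient, flip_strand) {
      ea <- a_eff; oa <- a_oth; b <- beta; f <- maf
      sw <- flip_orient
      ea[sw] <- a_oth[sw]; oa[sw] <- a_eff[sw]
      b[sw] <- -b[sw]; f[sw] <- 1 - f[sw]
      st <- flip_strand & !pal
      ea[st] <- .complement[ea[st]]; oa[st] <- .complement[oa[st]]
      structure(data.frame(
        variant_id = ids, effect_allele = ea, other_allele = oa,
        eaf = f, beta = b, se = se,
        pvalue = pmax(2 * pnorm(-abs(beta / se)), 1e-300),
        n = n, chrom = chrom, pos = pos,
        stringsAsFactors = FALSE
      ), class = c("gwas_assoc", "data.frame"))
    }
    orient_x <- runif(J) < 0.5
    orient_y <- runif(J) < 0.5
    strand_y <- runif(J) < 0.25
    exposure <- study_table(gamma_hat, se_x, truth$n_exposure, orient_x, FALSE)
    outcome <- study_table(Gamma_hat, se_y, truth$n_outcome, orient_y, strand_y)

    ld <- diag(J)
    dimnames(ld) <- list(ids, ids)
    if (truth$ld_blocks > 0) {
      for (b in seq_len(min(truth$ld_blocks, J %/% 2))) {
        j <- 2 * b
        ld[j - 1, j] <- ld[j, j - 1] <- truth$ld_block_r2
      }
    }
    truth$gamma <- gamma; truth$alpha <- alpha; truth$invalid <- invalid
    truth$maf <- maf
    list(exposure = exposure, outcome = outcome, ld = ld, truth = truth)
  })
}

#' Study-scale synthetic scenarios
#'
#' Pre-configured generating truths mirroring the two directions of a
#' bidirectional depression/reflux-disease analysis: `"mdd_to_gerd"`
#' (31 instruments; exposure GWAS of 173,005 with 59,851 cases; outcome
#' GWAS of 385,276 with 80,265 cases; true effect ln 1.31) and
#' `"gerd_to_mdd"` (24 instruments; the study designs reversed; true
#' effect ln 1.28).
#'
#' @param name scenario name.
#' @param theta override the scenario's true causal effect.
#' @param seed RNG seed.
#' @param ... further overrides passed to [mr_truth()].
#' @return An `mr_truth`.
#' @export
mr_scenario <- function(name = c("mdd_to_gerd", "gerd_to_mdd"),
                        theta = NULL, seed = 1, ...) {
  name <- match.arg(name)
  base <- switch(name,
    mdd_to_gerd = list(theta = log(1.31), n_snps = 31,
                       n_exposure = 173005,
                       case_fraction_exposure = 59851 / 173005,
                       n_outcome = 385276,
                       case_fraction_outcome = 80265 / 385276),
    gerd_to_mdd = list(theta = log(1.28), n_snps = 24,
                       n_exposure = 385276,
                       case_fraction_exposure = 80265 / 385276,
                       n_outcome = 173005,
                       case_fraction_outcome = 59851 / 173005))
  if (!is.null(theta)) base$theta <- theta
  args <- utils::modifyList(c(base, list(seed = seed)), list(...))
  do.call(mr_truth, args)
}

#' Write a synthetic dataset to disk
#'
#' Writes the exposure and outcome tables in the canonical tab-separated
#' dialect, the LD matrix as a square TSV, and the truth as a JSON sidecar,
#' into `dir`.
#'
#' @param sim output of [generate_two_sample()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_two_sample <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(exposure = file.path(dir, "exposure.tsv"),
             outcome = file.path(dir, "outcome.tsv"),
             ld = file.path(dir, "ld.tsv"),
             truth = file.path(dir, "truth.json"))
  write_gwas_table(sim$exposure, paths[["exposure"]])
  write_gwas_table(sim$outcome, paths[["outcome"]])
  ld <- as.data.frame(sim$ld)
  ld[] <- lapply(ld, function(x) sprintf("%.17g", x))
  utils::write.table(ld, paths[["ld"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(unclass(sim$truth), paths[["truth"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
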