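# Fixture builders used across test files.

# Instrument set straight from aligned effect vectors (bypasses allele
# bookkeeping; uses the package-internal constructor).
make_set <- function(bx, sx, by, sy, ...) {
  bimr:::instrument_set(beta_exposure = bx, se_exposure = sx,
                        beta_outcome = by, se_outcome = sy, ...)
}

# Random instrument set with roughly realistic scales.
random_set <- function(J = 10, theta = 0.3) {
  bx <- rnorm(J, 0.15, 0.05)
  bx[abs(bx) < 0.01] <- 0.05
  sx <- runif(J, 0.005, 0.02)
  sy <- runif(J, 0.005, 0.03)
  by <- theta * bx + rnorm(J, 0, sy)
  make_set(bx, sx, by, sy)
}

# A gwas_assoc data frame written by hand (canonical dialect).
make_assoc <- function(variant_id, effect_allele = "A", other_allele = "G",
                       eaf = 0.3, beta = 0.1, se = 0.01,
                       pvalue = 2 * pnorm(-abs(beta / se)),
                       n = 10000, chrom = NA_character_, pos = NA_real_) {
  structure(data.frame(variant_id = variant_id,
                       effect_allele = effect_allele,
                       other_allele = other_allele,
                       eaf = eaf, beta = beta, se = se, pvalue = pvalue,
                       n = n, chrom = chrom, pos = pos,
                       stringsAsFactors = FALSE),
            class = c("gwas_assoc", "data.frame"))
}

write_tsv_fixture <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
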