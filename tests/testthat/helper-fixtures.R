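# Fixture builders shared across the suite. Everything is generated in
# code under fixed seeds; no binary data.

make_freqs <- function(n_snps, populations, seed = 1) {
  withr::with_seed(seed, {
    out <- tibble::tibble(rsid = sprintf("rs%03d", seq_len(n_snps)))
    for (pop in populations) out[[pop]] <- round(stats::runif(n_snps, 0.05, 0.95), 4)
    out
  })
}

make_panel <- function(populations, values, kind = "quantitative",
                       super = NULL) {
  super <- super %||% rep(c("AFR", "AMR", "EAS", "EUR", "SAS"),
                          length.out = length(populations))
  tibble::tibble(population = populations, super_population = super,
                 phenotype_value = values, phenotype_kind = kind,
                 sex_stratum = "combined")
}

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")  # session tempdir, reaped on exit
  writeLines(lines, path)
  path
}

# Independent two-sided Fisher oracle: enumerates margin-fixed tables
# with binomial-coefficient arithmetic (no dhyper), point-probability rule.
oracle_fisher <- function(m) {
  a <- m[1, 1]; row1 <- sum(m[1, ]); col1 <- sum(m[, 1]); n <- sum(m)
  support <- max(0, row1 + col1 - n):min(row1, col1)
  probs <- choose(col1, support) * choose(n - col1, row1 - support) / choose(n, row1)
  p_obs <- choose(col1, a) * choose(n - col1, row1 - a) / choose(n, row1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Closed-form simple-OLS oracle: slope, intercept, r2 from sums of squares.
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       r2 = sxy^2 / (sxx * syy))
}
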