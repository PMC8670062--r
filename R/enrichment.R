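#' Cross-tabulate GWAS significance against SNP-set filtering
#'
#' Builds the 2x2 table comparing the unfiltered SNP set with a pruned
#' (filtered) subset with respect to genome-wide significance of the
#' discovery p-value: rows are significant (`discovery_p <= threshold`)
#' vs not, columns are the full set vs the retained set. Note the
#' columns are full-vs-filtered (the filtered set is a subset of the
#' full set), not full-vs-removed.
#'
#' @param annotations Annotation tibble (see [read_association_table()]).
#' @param retained Character vector of retained rsids; must be a subset
#'   of `annotations$rsid`.
#' @param threshold Significance threshold on the discovery p-value
#'   (default `5e-8`, genome-wide significance).
#' @return A 2x2 integer matrix with dimnames
#'   `significant`/`not_significant` by `unfiltered`/`filtered`.
#' @export
significance_table <- function(annotations, retained, threshold = 5e-8) {
  stray <- setdiff(retained, annotations$rsid)
  if (length(stray) > 0) {
    abort(sprintf("retained rsid(s) missing from annotations: %s",
                  paste(stray, collapse = ", ")),
          class = "popprs_snp_error")
  }
  sig <- annotations$discovery_p <= threshold
  in_retained <- annotations$rsid %in% retained
  matrix(c(sum(sig), sum(!sig), sum(sig & in_retained), sum(!sig & in_retained)),
         nrow = 2,
         dimnames = list(c("significant", "not_significant"),
                         c("unfiltered", "filtered")))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Computes the two-sided Fisher exact p-value by direct hypergeometric
#' enumeration with fixed margins, using the point-probability rule: the
#' p-value is the sum of the probabilities of all tables whose point
#' probability does not exceed that of the observed table (up to a
#' relative tolerance of 1e-7 to absorb floating-point ties), the
#' convention of mainstream statistical software. Probabilities come
#' from `dhyper()`, which is numerically stable, so very small p-values
#' (down to the 1e-14 scale arising in large SNP-set enrichment tables)
#' are exact to working precision.
#'
#' @param table A 2x2 matrix of non-negative counts (e.g. from
#'   [significance_table()]).
#' @return The two-sided p-value in (0, 1].
#' @export
#' @examples
#' fisher_2x2(matrix(c(2, 0, 0, 2), nrow = 2)) # 1/3
fisher_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) || any(table != round(table))) {
    abort("expected a 2x2 matrix of non-negative integer counts",
          class = "popprs_type_error")
  }
  if (sum(table) == 0) {
    abort("all-zero table: Fisher test undefined", class = "popprs_type_error")
  }
  a <- table[1, 1]
  row1 <- sum(table[1, ])
  col1 <- sum(table[, 1])
  n <- sum(table)
  support <- max(0, row1 + col1 - n):min(row1, col1)
  probs <- dhyper(support, col1, n - col1, row1)
  p_obs <- dhyper(a, col1, n - col1, row1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Compare mean allele frequencies of two SNP sets
#'
#' For each SNP the mean risk-allele frequency across all populations is
#' computed first; the two sets of per-SNP means are then compared with
#' a two-sided Welch (unequal-variance) two-sample t-test. Used to ask
#' whether pruning preferentially retains more (or less) common alleles
#' than the full set.
#'
#' @param freqs Frequency tibble (`rsid` + population columns).
#' @param set_a,set_b Character vectors of rsids, non-empty and complete
#'   in `freqs`.
#' @return A one-row tibble: `mean_a`, `mean_b`, `statistic` (Welch t),
#'   `df`, `p_value`. With a singleton set the means are returned and
#'   the test columns are `NA` (variance undefined).
#' @export
compare_freq_means <- function(freqs, set_a, set_b) {
  validate_frequency_matrix(freqs)
  snp_means <- function(set, label) {
    if (length(set) == 0) abort(sprintf("%s is empty", label))
    missing <- setdiff(set, freqs$rsid)
    if (length(missing) > 0) {
      abort(sprintf("%s rsid(s) absent from frequency matrix: %s", label,
                    paste(missing, collapse = ", ")),
            class = "popprs_snp_error")
    }
    incomplete <- intersect(set, incomplete_snps(freqs))
    if (length(incomplete) > 0) {
      abort(sprintf("%s rsid(s) with missing frequencies: %s", label,
                    paste(incomplete, collapse = ", ")),
            class = "popprs_snp_error")
    }
    rowMeans(as.matrix(freqs[match(set, freqs$rsid), -1, drop = FALSE]))
  }
  ma <- snp_means(unique(set_a), "set_a")
  mb <- snp_means(unique(set_b), "set_b")
  if (length(ma) < 2 || length(mb) < 2) {
    inform("singleton SNP set: t-test undefined, p reported as NA")
    return(tibble(mean_a = mean(ma), mean_b = mean(mb),
                  statistic = NA_real_, df = NA_real_, p_value = NA_real_))
  }
  tt <- t.test(ma, mb, var.equal = FALSE)
  tibble(mean_a = mean(ma), mean_b = mean(mb),
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value)
}

#' Percentage of SNPs discovered in European-ancestry studies
#'
#' Most GWAS discovery cohorts are of European descent; this summarises
#' that bias for a trait's annotation set as the percentage of SNPs
#' whose discovery ancestry is European, rounded to 2 decimals.
#'
#' @param annotations Annotation tibble with a logical
#'   `discovery_ancestry_european` column.
#' @return A single number in \[0, 100\].
#' @export
percent_discovery_ancestry <- function(annotations) {
  if (nrow(annotations) == 0) abort("annotation list is empty")
  round(100 * mean(annotations$discovery_ancestry_european), 2)
}
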