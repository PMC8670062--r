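#' Physical spacing summary of a SNP set
#'
#' Summarises how a SNP set is spread along the genome: within each
#' chromosome the SNPs are sorted by position and the mean gap between
#' position-adjacent SNPs is computed; the overall mean pools the
#' adjacent gaps across chromosomes. As a proxy for likely linkage
#' disequilibrium, same-chromosome SNP pairs at distance at most
#' `threshold` base pairs (inclusive) are counted, along with the number
#' of SNPs belonging to at least one such pair. Chromosomes carrying a
#' single SNP contribute no gaps; distances are never computed across
#' chromosomes.
#'
#' @param annotations Annotation tibble with `rsid`, `chromosome`,
#'   `position`.
#' @param snp_set Character vector of rsids to summarise; defaults to
#'   all annotated SNPs.
#' @param threshold Proximity threshold in base pairs (default 30800,
#'   i.e. 30.8 kb).
#' @return An object of class `spacing_summary`: `per_chromosome`
#'   (tibble `chromosome`, `n_snps`, `mean_gap`), `overall_mean` (`NA`
#'   when no chromosome has 2+ SNPs), `n_pairs_within`,
#'   `n_snps_within`, `n_snps`, `threshold`. Supports [tidy()] and
#'   [glance()].
#' @export
spacing_summary <- function(annotations, snp_set = annotations$rsid,
                            threshold = 30800) {
  snp_set <- unique(as.character(snp_set))
  ann <- annotations[match(snp_set, annotations$rsid), , drop = FALSE]
  bad <- snp_set[is.na(ann$chromosome) | is.na(ann$position) | is.na(ann$rsid)]
  if (length(bad) > 0) {
    abort(sprintf("rsid(s) lacking coordinates: %s", paste(bad, collapse = ", ")),
          class = "popprs_snp_error")
  }
  per_chrom <- list()
  gaps_pooled <- double()
  n_pairs <- 0L
  snps_within <- character()
  for (chrom in unique(ann$chromosome)) {
    sub <- ann[ann$chromosome == chrom, ]
    sub <- sub[order(sub$position), ]
    gaps <- if (nrow(sub) >= 2) diff(sub$position) else double()
    gaps_pooled <- c(gaps_pooled, gaps)
    per_chrom[[chrom]] <- tibble(chromosome = chrom, n_snps = nrow(sub),
                                 mean_gap = if (length(gaps) > 0) mean(gaps) else NA_real_)
    if (nrow(sub) >= 2) {
      d <- abs(outer(sub$position, sub$position, "-"))
      close <- d <= threshold & upper.tri(d)
      n_pairs <- n_pairs + sum(close)
      hit <- unique(c(row(d)[close], col(d)[close]))
      snps_within <- c(snps_within, sub$rsid[hit])
    }
  }
  structure(
    list(per_chromosome = dplyr::bind_rows(per_chrom),
         overall_mean = if (length(gaps_pooled) > 0) mean(gaps_pooled) else NA_real_,
         n_pairs_within = n_pairs,
         n_snps_within = length(unique(snps_within)),
         n_snps = nrow(ann),
         threshold = threshold),
    class = "spacing_summary"
  )
}

#' Compare the spacing of a full SNP set with its pruned subset
#'
#' Reports how pruning changed the mean adjacent-SNP distance and the
#' proportion of SNPs with a near neighbour (within the shared
#' proximity threshold). Pruning that preferentially removes clustered
#' SNPs — the ones most likely in linkage disequilibrium — shows up as
#' a drop in that proportion.
#'
#' @param full,pruned `spacing_summary` objects computed at the same
#'   threshold.
#' @return A one-row tibble: `threshold`, `full_mean`, `pruned_mean`,
#'   `mean_change`, `full_n_within`, `pruned_n_within`,
#'   `full_prop_within`, `pruned_prop_within`, `prop_change`.
#' @export
compare_spacing <- function(full, pruned) {
  stopifnot(inherits(full, "spacing_summary"), inherits(pruned, "spacing_summary"))
  if (full$threshold != pruned$threshold) {
    abort(sprintf("threshold mismatch: %g vs %g bp", full$threshold, pruned$threshold),
          class = "popprs_type_error")
  }
  fp <- full$n_snps_within / full$n_snps
  pp <- pruned$n_snps_within / pruned$n_snps
  tibble(threshold = full$threshold,
         full_mean = full$overall_mean, pruned_mean = pruned$overall_mean,
         mean_change = pruned$overall_mean - full$overall_mean,
         full_n_within = full$n_snps_within, pruned_n_within = pruned$n_snps_within,
         full_prop_within = fp, pruned_prop_within = pp,
         prop_change = pp - fp)
}

#' @export
print.spacing_summary <- function(x, ...) {
  cat(sprintf("SNP spacing: %d SNPs on %d chromosome(s)\n",
              x$n_snps, nrow(x$per_chromosome)))
  cat(sprintf("  mean adjacent gap %s bp; %d pair(s) and %d SNP(s) within %g bp\n",
              ifelse(is.na(x$overall_mean), "NA", format(round(x$overall_mean))),
              x$n_pairs_within, x$n_snps_within, x$threshold))
  invisible(x)
}

#' @rdname spacing_summary
#' @param x A `spacing_summary` object.
#' @param ... Unused.
#' @export
tidy.spacing_summary <- function(x, ...) x$per_chromosome

#' @rdname spacing_summary
#' @export
glance.spacing_summary <- function(x, ...) {
  tibble(n_snps = x$n_snps, overall_mean = x$overall_mean,
         n_pairs_within = x$n_pairs_within, n_snps_within = x$n_snps_within,
         threshold = x$threshold)
}
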