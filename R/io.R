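#' Read a GWAS-Catalog-style association table
#'
#' Reads a tab-separated table of trait-associated SNPs (one row per
#' variant) and returns a validated annotation tibble. Rows whose
#' discovery p-value fails the inclusion threshold are dropped (with a
#' message), and duplicated rsids are collapsed to the record with the
#' smallest discovery p-value, mirroring how association tables pulled
#' from the GWAS Catalog are curated before score building.
#'
#' Required columns (tab-separated, header mandatory): `rsid`,
#' `chromosome`, `position`, `risk_allele`, `p_value`,
#' `discovery_ancestry`. The ancestry label is reduced to a European /
#' non-European flag (case-insensitive match on `"european"`), the
#' classification used when summarising discovery bias.
#'
#' @param path Path to a TSV file.
#' @param trait_id Character scalar identifying the trait; stored in the
#'   `trait_id` column.
#' @param p_threshold Inclusion threshold on the discovery p-value
#'   (default `1e-5`, the conventional suggestive-association cut-off).
#'   Rows with `p_value >= p_threshold` are dropped.
#'
#' @return A tibble with columns `rsid`, `chromosome`, `position`,
#'   `risk_allele`, `discovery_p`, `discovery_ancestry_european`,
#'   `trait_id`.
#' @export
read_association_table <- function(path, trait_id, p_threshold = 1e-5) {
  stopifnot(is.character(trait_id), length(trait_id) == 1L)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "."), progress = FALSE)
  required <- c("rsid", "chromosome", "position", "risk_allele", "p_value",
                "discovery_ancestry")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("association table %s is missing required column(s): %s",
                  path, paste(missing_cols, collapse = ", ")),
          class = "popprs_format_error")
  }
  p <- suppressWarnings(as.numeric(raw$p_value))
  bad_p <- which(is.na(p) & !is.na(raw$p_value))
  if (length(bad_p) > 0) {
    abort(sprintf("unparsable p-value '%s' at line %d of %s",
                  raw$p_value[bad_p[1]], bad_p[1] + 1L, path),
          class = "popprs_format_error")
  }
  pos <- suppressWarnings(as.integer(raw$position))
  bad_pos <- which((is.na(pos) | pos < 1L) & !is.na(raw$position))
  if (length(bad_pos) > 0) {
    abort(sprintf("invalid position '%s' at line %d of %s",
                  raw$position[bad_pos[1]], bad_pos[1] + 1L, path),
          class = "popprs_format_error")
  }
  ann <- tibble(
    rsid = raw$rsid,
    chromosome = sub("^chr", "", raw$chromosome, ignore.case = TRUE),
    position = pos,
    risk_allele = toupper(raw$risk_allele),
    discovery_p = p,
    discovery_ancestry_european = grepl("european", raw$discovery_ancestry,
                                        ignore.case = TRUE),
    trait_id = trait_id
  )
  bad_allele <- ann$rsid[!ann$risk_allele %in% c("A", "C", "G", "T")]
  if (length(bad_allele) > 0) {
    abort(sprintf("risk allele must be one of A/C/G/T; offending rsid(s): %s",
                  paste(bad_allele, collapse = ", ")),
          class = "popprs_format_error")
  }
  if (any(ann$discovery_p <= 0 | ann$discovery_p > 1)) {
    abort("discovery p-values must lie in (0, 1]", class = "popprs_format_error")
  }
  n_before <- nrow(ann)
  ann <- dplyr::filter(ann, .data$discovery_p < p_threshold)
  n_dropped <- n_before - nrow(ann)
  if (n_dropped > 0) {
    inform(sprintf("dropped %d row(s) with discovery p >= %g", n_dropped, p_threshold))
  }
  # duplicate rsids keep the strongest (smallest p) record
  ann <- ann |>
    dplyr::arrange(.data$discovery_p) |>
    dplyr::distinct(.data$rsid, .keep_all = TRUE) |>
    dplyr::arrange(match(.data$rsid, raw$rsid))
  ann
}

#' Read a SNP-by-population risk-allele frequency matrix
#'
#' Reads a wide TSV whose first column is `rsid` and whose remaining
#' columns are population codes holding risk-allele frequencies in
#' \[0, 1\]. Empty cells or `"."` denote missing frequencies; SNPs with
#' any missing population are kept in the table but flagged (see
#' [incomplete_snps()]) and are refused by [compute_psprs()] so that
#' scores stay comparable across populations.
#'
#' @param path Path to a TSV file.
#' @return A tibble: column `rsid` plus one numeric column per population.
#' @export
read_frequency_matrix <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  if (names(raw)[1] != "rsid") {
    abort(sprintf("frequency matrix %s must have 'rsid' as its first column", path),
          class = "popprs_format_error")
  }
  if (ncol(raw) < 2) {
    abort("frequency matrix has no population columns", class = "popprs_format_error")
  }
  dup <- raw$rsid[duplicated(raw$rsid)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate rsid row(s): %s", paste(unique(dup), collapse = ", ")),
          class = "popprs_format_error")
  }
  out <- raw["rsid"]
  for (pop in names(raw)[-1]) {
    cell <- raw[[pop]]
    is_missing <- is.na(cell) | cell == "" | cell == "."
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(!is_missing & is.na(val))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric cell '%s' at rsid %s, column %s",
                    cell[bad[1]], raw$rsid[bad[1]], pop),
            class = "popprs_format_error")
    }
    oob <- which(!is_missing & (val < 0 | val > 1))
    if (length(oob) > 0) {
      abort(sprintf("frequency %s out of [0, 1] at rsid %s, column %s",
                    cell[oob[1]], raw$rsid[oob[1]], pop),
            class = "popprs_format_error")
    }
    val[is_missing] <- NA_real_
    out[[pop]] <- val
  }
  as_tibble(out)
}

#' Write a frequency matrix to TSV
#'
#' Inverse of [read_frequency_matrix()]: missing frequencies are written
#' as empty cells, so reading the file back reproduces values and
#' missingness exactly.
#'
#' @param freqs Frequency tibble (`rsid` + population columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequency_matrix <- function(freqs, path) {
  validate_frequency_matrix(freqs)
  readr::write_tsv(freqs, path, na = "")
  invisible(path)
}

#' rsids with at least one missing population frequency
#'
#' @param freqs Frequency tibble (`rsid` + population columns).
#' @return Character vector of flagged rsids (possibly empty).
#' @export
incomplete_snps <- function(freqs) {
  validate_frequency_matrix(freqs)
  any_na <- rowSums(is.na(as.matrix(freqs[-1]))) > 0
  freqs$rsid[any_na]
}

validate_frequency_matrix <- function(freqs) {
  if (!is.data.frame(freqs) || ncol(freqs) < 2 || names(freqs)[1] != "rsid") {
    abort("expected a frequency tibble: 'rsid' column followed by population columns",
          class = "popprs_type_error")
  }
  vals <- as.matrix(freqs[-1])
  if (!is.numeric(vals)) {
    abort("population frequency columns must be numeric", class = "popprs_type_error")
  }
  if (any(vals < 0 | vals > 1, na.rm = TRUE)) {
    abort("frequencies must lie in [0, 1]", class = "popprs_type_error")
  }
  if (anyDuplicated(freqs$rsid)) {
    abort("duplicate rsids in frequency matrix", class = "popprs_type_error")
  }
  invisible(freqs)
}

#' Read a population phenotype panel
#'
#' Reads a TSV describing the study populations: one row per population
#' with its continental super-population, the phenotype value (a
#' prevalence proportion or a mean trait value such as height in cm),
#' the kind of phenotype, and the sex stratum the value refers to.
#'
#' Required columns: `population` (or `code`), `super_population` (one
#' of AFR/AMR/EAS/EUR/SAS), `phenotype_value`, `phenotype_kind`
#' (`prevalence` or `quantitative`), `sex_stratum` (`male`, `female` or
#' `combined`). Scientific-notation prevalences (e.g. `1.04e-3`) parse
#' exactly.
#'
#' @param path Path to a TSV file.
#' @return A validated tibble with the columns above (first column named
#'   `population`).
#' @export
read_population_panel <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "."), progress = FALSE)
  if ("code" %in% names(raw) && !"population" %in% names(raw)) {
    names(raw)[names(raw) == "code"] <- "population"
  }
  required <- c("population", "super_population", "phenotype_value",
                "phenotype_kind", "sex_stratum")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("population panel %s is missing required column(s): %s",
                  path, paste(missing_cols, collapse = ", ")),
          class = "popprs_format_error")
  }
  panel <- tibble(
    population = raw$population,
    super_population = raw$super_population,
    phenotype_value = suppressWarnings(as.numeric(raw$phenotype_value)),
    phenotype_kind = raw$phenotype_kind,
    sex_stratum = raw$sex_stratum
  )
  validate_population_panel(panel)
}

validate_population_panel <- function(panel) {
  if (anyDuplicated(panel$population)) {
    abort("population codes must be unique", class = "popprs_type_error")
  }
  bad_super <- setdiff(unique(panel$super_population), SUPER_POPULATIONS)
  if (length(bad_super) > 0) {
    abort(sprintf("unknown super-population label(s): %s",
                  paste(bad_super, collapse = ", ")),
          class = "popprs_type_error")
  }
  if (!all(panel$phenotype_kind %in% c("prevalence", "quantitative"))) {
    abort("phenotype_kind must be 'prevalence' or 'quantitative'",
          class = "popprs_type_error")
  }
  if (!all(panel$sex_stratum %in% c("male", "female", "combined"))) {
    abort("sex_stratum must be 'male', 'female' or 'combined'",
          class = "popprs_type_error")
  }
  prev <- panel$phenotype_kind == "prevalence" & !is.na(panel$phenotype_value)
  if (any(panel$phenotype_value[prev] > 1 | panel$phenotype_value[prev] < 0)) {
    offender <- panel$population[prev][panel$phenotype_value[prev] > 1 |
                                         panel$phenotype_value[prev] < 0][1]
    abort(sprintf("prevalence for %s is outside [0, 1]", offender),
          class = "popprs_type_error")
  }
  quant <- panel$phenotype_kind == "quantitative" & !is.na(panel$phenotype_value)
  if (any(panel$phenotype_value[quant] <= 0)) {
    abort("quantitative phenotype values must be positive",
          class = "popprs_type_error")
  }
  as_tibble(panel)
}

#' Bundled 1000 Genomes trait phenotype panel
#'
#' Returns the bundled table of per-population trait values for the 26
#' populations of the 1000 Genomes Project: lactase-persistence,
#' melanoma and multiple-sclerosis prevalence proportions, and male /
#' female mean height in cm, each with its continental super-population.
#' Populations with no published value for a trait are absent from that
#' trait's panel (e.g. lactase persistence is available for 24 of the
#' 26 populations).
#'
#' @param trait One of `"lactase_persistence"`, `"melanoma"`,
#'   `"multiple_sclerosis"`, `"height"`.
#' @param sex Sex stratum: `"combined"` (default; the disease
#'   prevalences) or `"male"` / `"female"` (height).
#' @return A population panel tibble (see [read_population_panel()]).
#' @export
phenotype_panel_1kg <- function(trait = c("lactase_persistence", "melanoma",
                                          "multiple_sclerosis", "height"),
                                sex = NULL) {
  trait <- match.arg(trait)
  sex <- sex %||% if (trait == "height") "male" else "combined"
  path <- system.file("extdata", "trait_phenotypes_1kg.tsv", package = "popprs",
                      mustWork = TRUE)
  tab <- readr::read_tsv(path, col_types = "cccccd", progress = FALSE,
                         na = character())
  tab <- dplyr::filter(tab, .data$trait == !!trait, .data$sex_stratum == !!sex)
  if (nrow(tab) == 0) {
    abort(sprintf("no bundled phenotype rows for trait '%s', sex '%s'", trait, sex))
  }
  validate_population_panel(dplyr::select(tab, "population", "super_population",
                                          "phenotype_value", "phenotype_kind",
                                          "sex_stratum"))
}

#' Compute population risk-allele frequencies from a multi-sample VCF
#'
#' For each annotated SNP, counts risk alleles among the called genotype
#' alleles of each population's samples. The risk allele is oriented
#' against REF/ALT: when it equals ALT the ALT-allele frequency is
#' reported, when it equals REF the complement (1 - ALT frequency) is
#' reported, and when it matches neither the SNP is flagged unresolvable
#' and left missing in every population. Multi-allelic records are
#' excluded, and SNPs absent from the VCF are missing for all
#' populations. Strand-ambiguous sites (A/T or C/G REF/ALT pairs) are
#' reported via a warning but not flipped, since the correct strand
#' cannot be inferred from the genotypes alone.
#'
#' @param vcf Path to a VCF file (v4.x; only GT is consumed).
#' @param sample_map Data frame with columns `sample` and `population`
#'   assigning each VCF sample to a population.
#' @param annotations Annotation tibble from [read_association_table()].
#' @return A frequency tibble (`rsid` + one column per population, in
#'   order of first appearance in `sample_map`), with attribute
#'   `"unresolved"` listing rsids whose risk allele matched neither REF
#'   nor ALT.
#' @export
frequencies_from_vcf <- function(vcf, sample_map, annotations) {
  stopifnot(all(c("sample", "population") %in% names(sample_map)))
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) {
    gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  }
  absent <- setdiff(sample_map$sample, colnames(gt))
  if (length(absent) > 0) {
    abort(sprintf("sample(s) missing from VCF: %s", paste(absent, collapse = ", ")))
  }
  fix$CHROM <- sub("^chr", "", fix$CHROM, ignore.case = TRUE)
  fix$POS <- as.integer(fix$POS)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    inform(sprintf("excluded %d multi-allelic record(s)", sum(multi)))
  }
  pops <- unique(sample_map$population)
  out <- tibble(rsid = annotations$rsid)
  for (pop in pops) out[[pop]] <- NA_real_
  unresolved <- character()
  ambiguous <- character()
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(nrow(annotations))) {
    hit <- which(!multi &
                   fix$CHROM == annotations$chromosome[i] &
                   fix$POS == annotations$position[i])
    if (length(hit) == 0) next
    hit <- hit[1]
    ref <- toupper(fix$REF[hit]); alt <- toupper(fix$ALT[hit])
    risk <- annotations$risk_allele[i]
    if (identical(alt, unname(comp[ref]))) {
      ambiguous <- c(ambiguous, annotations$rsid[i])
    }
    if (risk == alt) {
      count_allele <- "1"
    } else if (risk == ref) {
      count_allele <- "0"
    } else {
      unresolved <- c(unresolved, annotations$rsid[i])
      next
    }
    for (pop in pops) {
      samples <- sample_map$sample[sample_map$population == pop]
      alleles <- unlist(strsplit(gt[hit, samples], "[/|]"))
      alleles <- alleles[!is.na(alleles) & alleles != "."]
      if (length(alleles) == 0) next
      out[[pop]][i] <- sum(alleles == count_allele) / length(alleles)
    }
  }
  if (length(unresolved) > 0) {
    inform(sprintf("risk allele matched neither REF nor ALT for: %s (left missing)",
                   paste(unresolved, collapse = ", ")))
  }
  if (length(ambiguous) > 0) {
    warn(sprintf("strand-ambiguous REF/ALT pair(s) at: %s (frequencies reported as genotyped, not flipped)",
                 paste(ambiguous, collapse = ", ")))
  }
  attr(out, "unresolved") <- unresolved
  attr(out, "ambiguous_strand") <- ambiguous
  out
}
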