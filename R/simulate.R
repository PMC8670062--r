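#' Configuration for the synthetic study generator
#'
#' Bundles and validates the parameters of the synthetic
#' frequency-panel and phenotype generator. The defaults emulate a
#' 1000-Genomes-like panel: 26 populations in 5 continental
#' super-populations, 100 SNPs, moderate differentiation (Fst 0.1),
#' half the SNPs carrying a shared ("universal") phenotype effect, and
#' a linear prevalence link with mild noise. All randomness downstream
#' is a pure function of `seed`.
#'
#' @param seed Integer seed; every generated artifact is reproducible
#'   from it.
#' @param n_populations Number of populations (default 26).
#' @param n_super Number of super-populations (default 5, at most 5;
#'   labelled with the continental codes AFR/AMR/EAS/EUR/SAS).
#' @param n_snps Number of SNPs (default 100).
#' @param frac_universal Fraction of SNPs given a shared phenotype
#'   effect (default 0.5).
#' @param fst Differentiation parameter in (0, 1) of the hierarchical
#'   Balding-Nichols frequency model (default 0.1).
#' @param within_sd Standard deviation of the within-super-population
#'   perturbation of frequencies (default 0.02).
#' @param beta Phenotype effect per unit of summed universal-SNP
#'   frequency (default 0.01).
#' @param beta2 Second-order coefficient, used by the `poly2` link
#'   (default 0).
#' @param intercept Phenotype intercept (default 0.2; for the
#'   exponential link this is on the log scale).
#' @param noise_sd Standard deviation of the additive Gaussian
#'   phenotype noise (default 0.01).
#' @param link Phenotype link: `"linear"`, `"poly2"` or `"exponential"`.
#' @param decoy_beta Effect magnitude of non-universal (decoy) SNPs;
#'   0 (default) makes decoys pure noise, a positive value gives each
#'   decoy a per-super-population sign-flipped effect, the simplest
#'   mechanism for associations that do not transfer across populations.
#' @param phenotype_kind `"prevalence"` (values clipped to \[0, 1\],
#'   with a message when clipping occurs) or `"quantitative"`.
#' @return A validated list of class `psprs_sim_config`.
#' @export
sim_config <- function(seed, n_populations = 26, n_super = 5, n_snps = 100,
                       frac_universal = 0.5, fst = 0.1, within_sd = 0.02,
                       beta = 0.01, beta2 = 0, intercept = 0.2,
                       noise_sd = 0.01,
                       link = c("linear", "poly2", "exponential"),
                       decoy_beta = 0,
                       phenotype_kind = c("prevalence", "quantitative")) {
  link <- match.arg(link)
  phenotype_kind <- match.arg(phenotype_kind)
  stopifnot(length(seed) == 1, is.finite(seed))
  if (n_populations < 1 || n_snps < 1 || n_super < 1) {
    abort("n_populations, n_super and n_snps must be at least 1")
  }
  if (n_super > 5) abort("n_super is at most 5 (continental codes)")
  if (n_super > n_populations) abort("n_super cannot exceed n_populations")
  if (fst <= 0 || fst >= 1) abort("fst must lie in (0, 1)")
  if (frac_universal < 0 || frac_universal > 1) abort("frac_universal must lie in [0, 1]")
  if (noise_sd < 0 || within_sd < 0) abort("standard deviations must be non-negative")
  structure(
    list(seed = as.integer(seed), n_populations = as.integer(n_populations),
         n_super = as.integer(n_super), n_snps = as.integer(n_snps),
         frac_universal = frac_universal, fst = fst, within_sd = within_sd,
         beta = beta, beta2 = beta2, intercept = intercept, noise_sd = noise_sd,
         link = link, decoy_beta = decoy_beta, phenotype_kind = phenotype_kind),
    class = "psprs_sim_config"
  )
}

#' @export
print.psprs_sim_config <- function(x, ...) {
  cat(sprintf("synthetic study config: %d SNPs x %d populations (%d super), seed %d\n",
              x$n_snps, x$n_populations, x$n_super, x$seed))
  cat(sprintf("  fst %.3g, frac_universal %.2f, link %s, beta %.3g, noise_sd %.3g\n",
              x$fst, x$frac_universal, x$link, x$beta, x$noise_sd))
  invisible(x)
}

sim_population_codes <- function(config) {
  supers <- SUPER_POPULATIONS[seq_len(config$n_super)]
  assignment <- supers[((seq_len(config$n_populations) - 1L) %% config$n_super) + 1L]
  assignment <- sort(assignment)
  tibble(population = sprintf("POP%02d", seq_len(config$n_populations)),
         super_population = assignment)
}

#' Generate a hierarchical SNP-by-population frequency panel
#'
#' Draws risk-allele frequencies under a two-level Balding-Nichols
#' model: each SNP gets an ancestral frequency uniform on (0.05, 0.95);
#' each super-population draws its frequency from a Beta distribution
#' with mean equal to the ancestral frequency and variance
#' `fst * p * (1 - p)` (the standard Fst parameterisation,
#' `Beta(p(1-fst)/fst, (1-p)(1-fst)/fst)`); and each population inside
#' a super-population adds a small Gaussian perturbation (sd
#' `within_sd`), clamped to \[0, 1\]. The result has the structure the
#' psPRS analysis assumes: populations within a continental group
#' resemble each other far more than populations across groups.
#'
#' @param config A [sim_config()] object.
#' @return A frequency tibble (`rsid` + one column per population) with
#'   the population/super-population map in attribute `"populations"`.
#' @export
generate_frequencies <- function(config) {
  stopifnot(inherits(config, "psprs_sim_config"))
  pops <- sim_population_codes(config)
  withr::with_seed(config$seed, {
    p_anc <- runif(config$n_snps, 0.05, 0.95)
    shape_scale <- (1 - config$fst) / config$fst
    super_freq <- sapply(SUPER_POPULATIONS[seq_len(config$n_super)], function(sp) {
      rbeta(config$n_snps, p_anc * shape_scale, (1 - p_anc) * shape_scale)
    })
    out <- tibble(rsid = sprintf("rs%04d", seq_len(config$n_snps)))
    for (i in seq_len(nrow(pops))) {
      f <- super_freq[, pops$super_population[i]] +
        rnorm(config$n_snps, 0, config$within_sd)
      out[[pops$population[i]]] <- pmin(1, pmax(0, f))
    }
    attr(out, "populations") <- pops
    attr(out, "ancestral") <- p_anc
    out
  })
}

#' Generate population phenotypes from a frequency panel
#'
#' Designates a random subset of SNPs as "universal" (shared effect in
#' every population), sums their frequencies per population into the
#' true score `s`, and produces phenotypes under the configured link:
#' `intercept + beta * s` (linear), `intercept + beta * s + beta2 * s^2`
#' (poly2) or `exp(intercept + beta * s)` (exponential), plus additive
#' Gaussian noise with sd `noise_sd`. Non-universal SNPs contribute
#' nothing when `decoy_beta` is 0; otherwise each contributes
#' `decoy_beta` times its frequency with a random sign per
#' super-population, emulating associations whose direction does not
#' transfer across ancestries. For the `prevalence` phenotype kind,
#' values are clipped to \[0, 1\] (reported with a message).
#'
#' @param freqs A frequency tibble, typically from
#'   [generate_frequencies()] (any frequency tibble works if a
#'   population/super-population map is attached or derivable from
#'   `panel_map`).
#' @param config A [sim_config()] object; `frac_universal * n_snps`
#'   must be at least 1.
#' @param panel_map Optional tibble (`population`, `super_population`)
#'   overriding the map attached to `freqs`.
#' @return A list: `panel` (population panel tibble), `universal`
#'   (character vector of ground-truth universal rsids), `score` (the
#'   true per-population summed frequency).
#' @export
generate_phenotype <- function(freqs, config, panel_map = NULL) {
  stopifnot(inherits(config, "psprs_sim_config"))
  pops_map <- panel_map %||% attr(freqs, "populations")
  if (is.null(pops_map)) {
    abort("no population map: pass panel_map or use generate_frequencies() output")
  }
  pop_cols <- names(freqs)[-1]
  stopifnot(all(pop_cols %in% pops_map$population))
  n_universal <- round(config$frac_universal * nrow(freqs))
  if (n_universal < 1) {
    abort("frac_universal * n_snps must be at least 1")
  }
  withr::with_seed(config$seed + 1L, {
    universal <- sort(sample(freqs$rsid, n_universal))
    mat <- as.matrix(freqs[-1])
    rownames(mat) <- freqs$rsid
    s <- colSums(mat[universal, , drop = FALSE])
    eta <- config$intercept + config$beta * s +
      if (config$link == "poly2") config$beta2 * s^2 else 0
    decoys <- setdiff(freqs$rsid, universal)
    if (config$decoy_beta > 0 && length(decoys) > 0) {
      supers <- SUPER_POPULATIONS[seq_len(config$n_super)]
      signs <- matrix(sample(c(-1, 1), length(decoys) * length(supers), replace = TRUE),
                      nrow = length(decoys),
                      dimnames = list(decoys, supers))
      sp_of_pop <- pops_map$super_population[match(pop_cols, pops_map$population)]
      decoy_term <- colSums(mat[decoys, , drop = FALSE] *
                              signs[, sp_of_pop, drop = FALSE]) * config$decoy_beta
      eta <- eta + decoy_term
    }
    if (config$link == "exponential") {
      if (max(abs(eta)) > 700) {
        abort("exponential link overflows: |intercept + beta * s| too large")
      }
      y <- exp(eta)
    } else {
      y <- eta
    }
    y <- y + rnorm(length(y), 0, config$noise_sd)
    if (config$phenotype_kind == "prevalence") {
      clipped <- sum(y < 0 | y > 1)
      if (clipped > 0) {
        inform(sprintf("clipped %d phenotype value(s) to [0, 1]", clipped))
      }
      y <- pmin(1, pmax(0, y))
    }
    panel <- tibble(
      population = pop_cols,
      super_population = pops_map$super_population[match(pop_cols, pops_map$population)],
      phenotype_value = unname(y),
      phenotype_kind = config$phenotype_kind,
      sex_stratum = "combined"
    )
    list(panel = panel, universal = universal, score = setNames(s, pop_cols))
  })
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: [generate_frequencies()] followed by
#' [generate_phenotype()].
#'
#' @param config A [sim_config()] object.
#' @return A list: `freqs`, `panel`, `universal`, `score`.
#' @export
simulate_study <- function(config) {
  freqs <- generate_frequencies(config)
  pheno <- generate_phenotype(freqs, config)
  list(freqs = freqs, panel = pheno$panel, universal = pheno$universal,
       score = pheno$score)
}
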