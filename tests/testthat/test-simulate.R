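test_that("generated artifacts are pure functions of the seed", {
  cfg <- sim_config(seed = 5, n_snps = 30)
  f1 <- generate_frequencies(cfg)
  f2 <- generate_frequencies(cfg)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  p1 <- generate_phenotype(f1, cfg)
  p2 <- generate_phenotype(f2, cfg)
  expect_identical(p1$panel$phenotype_value, p2$panel$phenotype_value)
  expect_identical(p1$universal, p2$universal)
  # a different seed moves the draws
  f3 <- generate_frequencies(sim_config(seed = 6, n_snps = 30))
  expect_false(identical(f1$POP01, f3$POP01))
  # generation leaves the global RNG stream untouched
  withr::with_seed(1, {
    before <- stats::runif(1)
  })
  withr::with_seed(1, {
    invisible(simulate_study(cfg))
    expect_equal(stats::runif(1), before)
  })
})

test_that("frequency panel has 1000-Genomes-like shape and bounds", {
  cfg <- sim_config(seed = 2)
  freqs <- generate_frequencies(cfg)
  expect_equal(dim(freqs), c(100, 27))  # rsid + 26 populations
  vals <- as.matrix(freqs[-1])
  expect_true(all(vals >= 0 & vals <= 1))
  pops <- attr(freqs, "populations")
  expect_equal(nrow(pops), 26)
  expect_setequal(unique(pops$super_population),
                  c("AFR", "AMR", "EAS", "EUR", "SAS"))
})

test_that("vanishing Fst collapses populations onto the ancestral frequency", {
  cfg <- sim_config(seed = 8, fst = 1e-6, within_sd = 0.001, n_snps = 200)
  freqs <- generate_frequencies(cfg)
  anc <- attr(freqs, "ancestral")
  dev <- abs(as.matrix(freqs[-1]) - anc)
  expect_gte(mean(apply(dev, 1, max) < 0.01), 0.99)
})

test_that("across-population frequency variance matches the Fst parameterisation", {
  # one population per super-population, no within noise: the sample
  # variance across draws estimates fst * p * (1 - p)
  cfg <- sim_config(seed = 17, n_populations = 5, n_super = 5, n_snps = 2000,
                    fst = 0.1, within_sd = 0)
  freqs <- generate_frequencies(cfg)
  anc <- attr(freqs, "ancestral")
  v <- apply(as.matrix(freqs[-1]), 1, stats::var)
  ratio <- mean(v / (anc * (1 - anc)))
  expect_equal(ratio, 0.1, tolerance = 0.1)
})

test_that("noiseless links are recovered exactly by the downstream fits", {
  cfg <- sim_config(seed = 4, n_snps = 20, frac_universal = 1, beta = 0.4,
                    intercept = 0.3, noise_sd = 0, link = "linear",
                    phenotype_kind = "quantitative")
  st <- simulate_study(cfg)
  f <- fit_linear(compute_psprs(st$freqs, st$universal), st$panel)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_equal(f$slope, 0.4, tolerance = 1e-10)
  expect_equal(unname(f$coefficients[1]), 0.3, tolerance = 1e-9)

  cfge <- sim_config(seed = 4, n_snps = 20, frac_universal = 1, beta = 0.2,
                     intercept = -1, noise_sd = 0, link = "exponential",
                     phenotype_kind = "quantitative")
  ste <- simulate_study(cfge)
  fe <- fit_exponential(compute_psprs(ste$freqs, ste$universal), ste$panel)
  expect_equal(fe$r2, 1, tolerance = 1e-12)
  expect_equal(fe$slope, 0.2, tolerance = 1e-10)

  cfgp <- sim_config(seed = 4, n_snps = 20, frac_universal = 1, beta = 0.1,
                     beta2 = 0.05, intercept = 0, noise_sd = 0, link = "poly2",
                     phenotype_kind = "quantitative")
  stp <- simulate_study(cfgp)
  fp <- fit_poly2(compute_psprs(stp$freqs, stp$universal), stp$panel)
  expect_equal(fp$r2, 1, tolerance = 1e-12)
})

test_that("fitted slopes are unbiased for the generating effect size", {
  slopes <- vapply(1:200, function(seed) {
    cfg <- sim_config(seed = 1000 + seed, n_snps = 100, frac_universal = 0.5,
                      beta = 1, noise_sd = 0.1, intercept = 0,
                      phenotype_kind = "quantitative")
    st <- simulate_study(cfg)
    fit_linear(compute_psprs(st$freqs, st$universal), st$panel)$slope
  }, numeric(1))
  se <- stats::sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 1), 2 * se)
})

test_that("prevalence phenotypes stay in [0, 1], clipping is reported", {
  st <- simulate_study(sim_config(seed = 12))
  expect_true(all(st$panel$phenotype_value >= 0 & st$panel$phenotype_value <= 1))
  expect_equal(unique(st$panel$phenotype_kind), "prevalence")

  loud <- sim_config(seed = 12, noise_sd = 0.5)  # noise pushes values out
  expect_message(out <- simulate_study(loud), "clipped")
  expect_true(all(out$panel$phenotype_value >= 0 & out$panel$phenotype_value <= 1))
})

test_that("pruning improves the fit in nearly all decoy-laden replicates", {
  improved <- 0L; enriched <- 0L; n_rep <- 50L
  for (seed in seq_len(n_rep)) {
    cfg <- sim_config(seed = 400 + seed, n_populations = 26, n_snps = 20,
                      frac_universal = 0.5, beta = 1, decoy_beta = 0.2,
                      noise_sd = 0.1, intercept = 0,
                      phenotype_kind = "quantitative")
    st <- simulate_study(cfg)
    tr <- suppressMessages(prune_maximize_r2(st$freqs, st$panel, st$freqs$rsid))
    improved <- improved + (tr$final_r2 > tr$initial_r2 + 1e-9)
    enriched <- enriched +
      (mean(tr$retained %in% st$universal) > cfg$frac_universal)
  }
  expect_gte(improved / n_rep, 0.9)
  expect_gt(enriched / n_rep, 0.5)
})

test_that("configuration bounds are enforced", {
  expect_error(sim_config(seed = 1, fst = 0), "fst")
  expect_error(sim_config(seed = 1, fst = 1), "fst")
  expect_error(sim_config(seed = 1, frac_universal = 1.2), "frac_universal")
  expect_error(sim_config(seed = 1, n_super = 6), "at most 5")
  expect_error(sim_config(seed = 1, n_populations = 3, n_super = 5), "exceed")
  cfg <- sim_config(seed = 1, n_snps = 10, frac_universal = 0.01)
  expect_error(generate_phenotype(generate_frequencies(cfg), cfg), "at least 1")
  over <- sim_config(seed = 1, n_snps = 10, frac_universal = 1, beta = 1000,
                     link = "exponential", phenotype_kind = "quantitative")
  expect_error(simulate_study(over), "overflow")
})
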