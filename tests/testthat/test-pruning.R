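# Noiseless fixture: 4 SNPs whose summed frequency IS the phenotype,
# plus one decoy anti-correlated with it. Removing the decoy is the
# unique improving move.
decoy_fixture <- function(seed = 11, n_pops = 6) {
  withr::with_seed(seed, {
    pops <- paste0("P", seq_len(n_pops))
    freqs <- make_freqs(4, pops, seed = seed)
    y <- colSums(as.matrix(freqs[-1]))
    decoy <- 0.1 + 0.8 * (max(y) - y) / (max(y) - min(y))
    freqs <- dplyr::bind_rows(freqs, tibble::tibble(rsid = "rs_decoy", !!!setNames(
      as.list(round(decoy, 4)), pops)))
    list(freqs = freqs, panel = make_panel(pops, y))
  })
}

test_that("leave-one-out r2 equals a brute-force per-SNP refit", {
  pops <- paste0("P", 1:9)
  freqs <- make_freqs(5, pops, seed = 21)
  panel <- make_panel(pops, withr::with_seed(22, stats::runif(9)))
  loo <- leave_one_out_r2(freqs, panel, freqs$rsid)
  expect_equal(nrow(loo), 5)
  expect_equal(loo$rsid, freqs$rsid)
  for (i in 1:5) {
    refit <- fit_linear(compute_psprs(freqs, freqs$rsid[-i]), panel)
    expect_equal(loo$r2[i], refit$r2)
  }
})

test_that("removing a constant-frequency SNP reproduces the reduced model's r2", {
  pops <- paste0("P", 1:6)
  freqs <- tibble::tibble(rsid = c("rs_a", "rs_b"))
  freqs[pops] <- NA_real_
  freqs[1, pops] <- as.list(c(0.1, 0.3, 0.5, 0.7, 0.8, 0.2))
  freqs[2, pops] <- as.list(rep(0.4, 6))
  panel <- make_panel(pops, c(0.2, 0.5, 0.9, 1.3, 1.6, 0.4))
  loo <- suppressMessages(leave_one_out_r2(freqs, panel, c("rs_a", "rs_b")))
  solo_a <- fit_linear(compute_psprs(freqs, "rs_a"), panel)$r2
  expect_equal(loo$r2[loo$rsid == "rs_b"], solo_a)
  # removing rs_a leaves a constant score: fit undefined, reported NA
  expect_true(is.na(loo$r2[loo$rsid == "rs_a"]))
})

test_that("greedy pruning removes a single anti-correlated decoy and stops", {
  fx <- decoy_fixture()
  tr <- prune_maximize_r2(fx$freqs, fx$panel, fx$freqs$rsid)
  expect_equal(nrow(tr$steps), 1)
  expect_equal(tr$steps$rsid, "rs_decoy")
  expect_equal(tr$final_r2, 1, tolerance = 1e-10)
  expect_setequal(tr$retained, setdiff(fx$freqs$rsid, "rs_decoy"))
  # exhaustive search agrees this is the global optimum
  best <- exhaustive_best_subset(fx$freqs, fx$panel, fx$freqs$rsid)
  expect_equal(tr$final_r2, best$r2, tolerance = 1e-10)
  expect_setequal(best$subset, tr$retained)
})

test_that("pruning stops immediately when no removal helps", {
  pops <- paste0("P", 1:6)
  freqs <- make_freqs(2, pops, seed = 5)
  y <- colSums(as.matrix(freqs[-1]))  # the 2-SNP sum predicts perfectly
  panel <- make_panel(pops, y)
  tr <- prune_maximize_r2(freqs, panel, freqs$rsid)
  expect_equal(nrow(tr$steps), 0)
  expect_setequal(tr$retained, freqs$rsid)
  expect_equal(tr$final_r2, tr$initial_r2)
})

test_that("trace r2 is non-decreasing and final r2 matches a direct refit", {
  for (seed in 1:20) {
    cfg <- sim_config(seed = seed, n_populations = 12, n_snps = 10,
                      frac_universal = 0.5, beta = 1, decoy_beta = 0.5,
                      noise_sd = 0.1, intercept = 0,
                      phenotype_kind = "quantitative")
    st <- simulate_study(cfg)
    tr <- suppressMessages(prune_maximize_r2(st$freqs, st$panel, st$freqs$rsid))
    expect_true(all(diff(c(tr$initial_r2, tr$steps$r2)) >= -1e-12))
    refit <- fit_linear(compute_psprs(st$freqs, tr$retained), st$panel)
    expect_equal(tr$final_r2, refit$r2)
    expect_setequal(c(tr$retained, tr$steps$rsid), st$freqs$rsid)
  }
})

test_that("greedy never beats the exhaustive best subset", {
  for (seed in 1:8) {
    cfg <- sim_config(seed = 100 + seed, n_populations = 10, n_snps = 6,
                      frac_universal = 0.5, beta = 1, decoy_beta = 0.6,
                      noise_sd = 0.1, intercept = 0,
                      phenotype_kind = "quantitative")
    st <- simulate_study(cfg)
    tr <- suppressMessages(prune_maximize_r2(st$freqs, st$panel, st$freqs$rsid))
    best <- exhaustive_best_subset(st$freqs, st$panel, st$freqs$rsid)
    expect_lte(tr$final_r2, best$r2 + 1e-10)
  }
})

test_that("exhaustive search honours its tie and size rules", {
  pops <- paste0("P", 1:5)
  row <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  freqs <- tibble::tibble(rsid = c("rs1", "rs2", "rs3"))
  for (i in seq_along(pops)) freqs[pops[i]] <- row[i]
  panel <- make_panel(pops, c(0.15, 0.33, 0.52, 0.68, 0.88))
  best <- exhaustive_best_subset(freqs, panel, freqs$rsid)
  # identical SNPs: every subset ties, the largest wins
  expect_setequal(best$subset, freqs$rsid)

  one <- exhaustive_best_subset(freqs, panel, "rs2")
  expect_equal(one$subset, "rs2")
  expect_equal(one$r2, fit_linear(compute_psprs(freqs, "rs2"), panel)$r2)

  expect_error(exhaustive_best_subset(make_freqs(16, pops), panel,
                                      sprintf("rs%03d", 1:16)),
               "15")
})

test_that("exact ties are broken by earliest input position", {
  pops <- paste0("P", 1:5)
  row <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  freqs <- tibble::tibble(rsid = c("rs1", "rs2", "rs3"))
  for (i in seq_along(pops)) freqs[pops[i]] <- row[i]
  panel <- make_panel(pops, c(0.15, 0.33, 0.52, 0.68, 0.88))
  tr <- suppressMessages(prune_maximize_r2(freqs, panel, freqs$rsid))
  # plateau: equal-r2 removals proceed in input order down to one SNP
  expect_equal(tr$steps$rsid, c("rs1", "rs2"))
  expect_equal(tr$retained, "rs3")
})

test_that("final r2 is invariant to input SNP order away from ties", {
  cfg <- sim_config(seed = 9, n_populations = 12, n_snps = 8, beta = 1,
                    decoy_beta = 0.5, noise_sd = 0.1, intercept = 0,
                    phenotype_kind = "quantitative")
  st <- simulate_study(cfg)
  tr1 <- prune_maximize_r2(st$freqs, st$panel, st$freqs$rsid)
  shuffled <- withr::with_seed(1, sample(st$freqs$rsid))
  tr2 <- prune_maximize_r2(st$freqs, st$panel, shuffled)
  expect_equal(tr1$final_r2, tr2$final_r2)
  expect_setequal(tr1$retained, tr2$retained)
})

test_that("batch mode prunes multiple SNPs per iteration and stays consistent", {
  cfg <- sim_config(seed = 31, n_populations = 14, n_snps = 12, beta = 1,
                    decoy_beta = 0.8, noise_sd = 0.05, intercept = 0,
                    phenotype_kind = "quantitative")
  st <- simulate_study(cfg)
  tr <- prune_maximize_r2(st$freqs, st$panel, st$freqs$rsid, mode = "batch")
  expect_gt(length(tr$retained), 0)
  refit <- fit_linear(compute_psprs(st$freqs, tr$retained), st$panel)
  expect_equal(tr$final_r2, refit$r2)
  expect_gte(tr$final_r2, tr$initial_r2 - 1e-12)
})

test_that("degenerate pruning inputs are refused", {
  pops <- paste0("P", 1:5)
  freqs <- make_freqs(4, pops, seed = 2)
  expect_error(prune_maximize_r2(freqs, make_panel(pops, rep(1, 5)), freqs$rsid),
               "constant")
  expect_error(prune_maximize_r2(freqs, make_panel(pops, 1:5), "rs001"),
               "at least 2")
})

test_that("pruning enriches the retained set for universal SNPs", {
  # 20 replicates with population-specific decoys; aggregate a 2x2 of
  # universal/decoy by retained/removed and require one-sided enrichment
  tab <- matrix(0, 2, 2)
  for (seed in 1:20) {
    cfg <- sim_config(seed = 200 + seed, n_populations = 26, n_snps = 24,
                      frac_universal = 0.5, beta = 1, decoy_beta = 0.2,
                      noise_sd = 0.1, intercept = 0,
                      phenotype_kind = "quantitative")
    st <- simulate_study(cfg)
    tr <- suppressMessages(prune_maximize_r2(st$freqs, st$panel, st$freqs$rsid))
    is_universal <- st$freqs$rsid %in% st$universal
    is_retained <- st$freqs$rsid %in% tr$retained
    tab <- tab + matrix(c(sum(is_universal & is_retained),
                          sum(!is_universal & is_retained),
                          sum(is_universal & !is_retained),
                          sum(!is_universal & !is_retained)), 2)
  }
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  expect_lt(p, 0.05)
})
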