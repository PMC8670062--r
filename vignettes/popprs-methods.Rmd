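---
title: "Methods: population-level polygenic risk scores, prevalence regression and r²-maximization pruning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-level polygenic risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popprs)
```

## The model

`popprs` works at the level of populations, not individuals. For a SNP
set $S$ and a population with risk-allele frequencies $p_k$, the
population-specific polygenic risk score is the unweighted sum

$$\mathrm{psPRS} = \sum_{k \in S} p_k .$$

The working hypothesis is ecological: if a trait's genetic architecture
is additive and its risk alleles act similarly everywhere, then the
summed risk-allele frequency of a population should be proportional to
the trait's prevalence in that population. The score is deliberately
unweighted — per-allele effect sizes are estimated almost exclusively in
European-ancestry cohorts and transfer poorly, whereas the allele
frequency is measured in the scored population itself. A corollary is
that every conclusion drawn from these fits is about populations;
nothing here predicts an individual's risk, and reading the regressions
otherwise is the ecological fallacy.

Prevalence (a proportion) is regressed on the score across populations
under three links, all fit by ordinary least squares:

* **linear** — `phenotype ~ psprs`;
* **poly2** — `phenotype ~ psprs + psprs²`, capturing the convex
  relationships that appear when one continental group dominates the
  upper tail;
* **exponential** — `log(phenotype) ~ psprs`. We fit the exponential
  model by OLS on the log-transformed response rather than by iterative
  nonlinear least squares: the log-OLS solution is closed-form,
  deterministic, and has no starting-value or convergence behaviour to
  document. The reported r² is therefore the log-scale one, and
  coefficients are on the log scale (with `tidy()` also reporting the
  back-transformed per-unit growth factor `exp(slope)`). This choice
  matters when comparing exponential r² values across software.

The reported r² is always the plain (unadjusted) coefficient of
determination, and the reported p-value is the overall-model F-test —
identical to the slope t-test for the two single-predictor models. Fits
require at least 3 populations (4 for the polynomial), refuse a constant
score (undefined slope), and for the exponential link refuse nonpositive
phenotype values. Populations with missing phenotype values are dropped
from a fit silently, since published prevalence tables routinely lack a
handful of populations. Per-super-population fits (`fit_by_super_population()`)
apply the same rules within each continental group and skip, with a
message, groups too small to fit.

## r²-maximization pruning

The sensitivity analysis asks which SNPs actually carry
cross-population signal. Starting from the full set, each iteration
computes, for every remaining SNP, the linear-fit r² of the score with
that SNP removed (`leave_one_out_r2()`), then discards the removal with
the highest r², provided it is at least the current r²; it stops when no
removal qualifies or one SNP remains. SNPs whose presence lowers
cross-population predictiveness — population-specific effects, spurious
associations — are discarded; SNPs with universal effects survive.

Decisions made where the procedure's prose description is ambiguous:

* **Removal granularity.** The default removes one SNP per iteration
  (steepest ascent). Removing one at a time cannot overshoot the
  maximum, and makes the trace strictly interpretable: the recorded r²
  after each removal is non-decreasing by construction. A `batch` mode
  that removes every individually-improving SNP per iteration and then
  refits is provided for sensitivity; it is faster but the individual
  exclusions are not additive, so it can overshoot.
* **Acceptance rule.** Removals are accepted at `>=`, not `>`: a SNP
  whose removal leaves r² exactly unchanged contributes nothing to the
  fit and is dropped on the plateau.
* **Tie-breaking.** Exact ties are broken by earliest position in the
  input SNP order and reported with a message, so a run is reproducible
  from its inputs alone.
* **Floor.** The retained set never empties: a score over zero SNPs has
  no defined regression.

Two r² values within `1e-12` are treated as tied, and a candidate score
whose standard deviation across populations falls below
`1e-9 * (1 + |mean|)` is treated as constant (fit undefined, `NA`).
Both guards exist because the leave-one-out scores are computed by
subtraction from the full-set sum; exact zeros and exact ties are
destroyed by accumulated rounding otherwise.

`exhaustive_best_subset()` enumerates all non-empty subsets (capped at
15 SNPs) and is the ground-truth reference: the greedy final r² can
never exceed it, and on fixtures built with a single harmful SNP the
two coincide.

## Follow-up statistics

* **Significance enrichment.** `significance_table()` cross-tabulates
  genome-wide significance of the discovery p-value
  (`p <= 5e-8`) against membership in the full vs the retained set —
  the filtered column is a subset of the unfiltered one, matching how
  such tables are printed, not a disjoint full-vs-removed split.
  `fisher_2x2()` computes the two-sided Fisher exact p-value by direct
  hypergeometric enumeration at fixed margins under the
  point-probability rule (sum of the probabilities of all tables no
  more probable than the observed one, with a `1e-7` relative
  tolerance for floating-point ties) — the convention of mainstream
  statistical software. Probabilities come from `dhyper()`, so p-values
  at the 1e-14 scale arising from large SNP panels are exact to working
  precision.
* **Frequency means.** `compare_freq_means()` first averages each SNP's
  frequency across all populations, then compares the two sets of
  per-SNP means with a two-sided Welch (unequal-variance) t-test. The
  two sets are typically nested (full vs pruned), which the test
  tolerates; the Welch form was chosen because nothing guarantees equal
  variances between a full panel and its pruned subset.
* **Discovery ancestry.** `percent_discovery_ancestry()` reports the
  percentage of SNPs flagged as discovered in European-ancestry
  studies, rounded to two decimals as such tables are printed.
* **Spacing.** `spacing_summary()` interprets "average physical distance
  between SNPs" as the mean gap between position-adjacent SNPs within a
  chromosome (an all-pairs mean would be dominated by chromosome length
  and dwarf the magnitudes of interest); the overall mean pools
  adjacent gaps across chromosomes. Proximity uses an inclusive
  threshold, 30.8 kb by default, as a crude stand-in for linkage
  disequilibrium: no genotype-based r² is computed anywhere. The X
  chromosome participates when annotated; distances never cross
  chromosomes.

## Input handling

Frequency matrices are SNP × population tables with values in [0, 1];
empty cells or `"."` are missing. A SNP missing in *any* scored
population is excluded from scoring for *all* populations
(`compute_psprs()` refuses it): partial sums would make scores
incomparable across populations, and per-population imputation is an
uncontrolled guess. This mirrors the common situation where a few
catalogued SNPs are absent from a reference frequency panel.

When frequencies are computed from a VCF (`frequencies_from_vcf()`),
only GT fields are consumed. The GWAS risk allele is oriented against
REF/ALT: equal to ALT, the ALT-allele frequency is reported; equal to
REF, the complement; matching neither, the SNP is flagged unresolvable
and left missing. Multi-allelic records are excluded. Strand-ambiguous
sites (A/T and C/G REF/ALT pairs) are *flagged with a warning and left
as genotyped*: without strand metadata the correct orientation cannot
be inferred from genotypes, and silently flipping would be a guess.

Coordinates are 1-based (VCF convention) and `chr` prefixes are
stripped. Prevalences are proportions, parsed exactly from scientific
notation. The bundled panel `phenotype_panel_1kg()` carries the
published per-population values for lactase persistence, melanoma and
multiple-sclerosis prevalence and male/female mean height (cm) across
the 26 populations of the 1000 Genomes Project; populations lacking a
published value for a trait are simply absent from that trait's panel.

## The synthetic generator

`generate_frequencies()` draws a panel under a two-level
Balding–Nichols hierarchy, the standard model of allele-frequency
differentiation:

1. ancestral frequency $p \sim U(0.05, 0.95)$ per SNP;
2. super-population frequency $\sim \mathrm{Beta}$ with mean $p$ and
   variance $F_{st}\,p(1-p)$, i.e.
   $\mathrm{Beta}\!\big(p\tfrac{1-F_{st}}{F_{st}},\,(1-p)\tfrac{1-F_{st}}{F_{st}}\big)$;
3. population frequency = super-population frequency + Gaussian
   perturbation (sd `within_sd`), clamped to [0, 1].

Defaults (26 populations, 5 super-populations labelled with the
continental codes, `fst = 0.1`, `within_sd = 0.02`) emulate a
1000-Genomes-like panel: continental differentiation around
$F_{st} \approx 0.1$, with populations inside a continent far more
similar to each other than across continents. The within-continent
perturbation sd of 0.02 keeps within-group spread an order of magnitude
below between-group spread, which is the qualitative structure the
psPRS analysis relies on.

`generate_phenotype()` designates a random universal subset
(`frac_universal`, default 0.5), sums its frequencies into the true
score $s$, and emits phenotypes as `intercept + beta*s` (linear, with a
quadratic term for `poly2`, or `exp(...)` for the exponential link)
plus additive Gaussian noise. Defaults `beta = 0.01`,
`intercept = 0.2`, `noise_sd = 0.01` keep prevalence-kind phenotypes
inside [0, 1] for the default panel; values pushed outside are clipped
and the clipping reported. Non-universal SNPs contribute nothing by
default; with `decoy_beta > 0` each contributes its frequency times
`decoy_beta` with a random sign per super-population — the simplest
mechanism for an association whose direction does not transfer across
ancestries. Every artifact is a pure function of the configuration:
all draws run inside `withr::with_seed` (frequencies at `seed`,
phenotypes at `seed + 1`), leaving the caller's RNG untouched.

What the generator does *not* emulate, and what passing tests therefore
do not establish about real data: linkage disequilibrium between SNPs
(synthetic SNPs are independent), admixture (each population belongs
wholly to one super-population), sampling noise in published prevalence
estimates (which are themselves literature values of varying quality),
GWAS discovery bias, and any environmental structure correlated with
ancestry. Recovery results below are statements about the additive,
LD-free regime only.

## Behaviour worth knowing about

Characterisation on synthetic panels (26 populations, effect 1 per unit
summed frequency, noise sd 0.1, 20-replicate aggregates) shaped the
test suite and is worth restating:

* **Pruning enriches for universal SNPs only when decoy effects are
  weak.** With no-effect or weak population-specific decoys
  (`decoy_beta` ≤ ~0.2), the retained set is strongly enriched for the
  ground-truth universal SNPs. When population-specific effects rival
  the universal one, decoys carry genuine predictive signal and the
  greedy procedure rightly keeps many of them: maximizing r² selects
  for predictiveness, not for ground-truth universality. Retained sets
  should be read accordingly.
* **Few populations means overfitting.** The response has as many
  observations as populations (26 at best). With substantially fewer
  populations the greedy search can drive r² toward 1 by removing SNPs
  essentially at random, and the universal/decoy distinction dissolves.
  This is inherent to maximizing an in-sample r² over subset choices,
  not an implementation artifact — the same caution applies to real
  panels.
* **Individual runs vary.** Single seeds can produce pruned models with
  high r² and a sign-reversed slope. Aggregate statements in the tests
  are made over ≥ 20–200 seeded replicates for this reason.

## Test design and problem sizes

Expected values in the unit tests come from independent oracles frozen
into the suite: closed-form normal-equation solutions for every
regression check, explicit binomial-coefficient enumeration for Fisher
p-values, hand-counted allele tallies for the VCF reader, and
brute-force per-SNP refits and exhaustive subset enumeration for the
pruning routines. Property-style tests (score additivity, scale
equivariance, r² = squared correlation, trace monotonicity,
greedy ≤ exhaustive, order invariance, seed determinism) loop over
seeded generated cases. The suite's simulation sizes — panels of 6–26
populations, 2–100 SNPs, up to 200 replicates per property, exhaustive
Fisher validation over all 2×2 tables with total count ≤ 30 — were
chosen so the whole suite exercises every code path in a few minutes on
a single core while keeping Monte-Carlo margins comfortable.

## Limitations

Beyond the generator's idealisations listed above: the pruning trace is
specific to the input SNP order only at exact ties; the exponential fit
minimises log-scale, not natural-scale, squared error; the spacing
module's proximity counts are a physical-distance heuristic, not LD;
and the bundled phenotype panel inherits the heterogeneity of its
literature sources (country-level prevalence mapped onto sampled
populations). Published per-SNP frequency panels for the four studied
traits are not redistributed here; the reproduction tests that need
them document the expected file locations and fail informatively in
their absence.
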