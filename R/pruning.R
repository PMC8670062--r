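# Fast linear-fit r-squared machinery shared by the pruning routines.
# For a single-predictor OLS fit, r2 is the squared Pearson correlation
# between score and phenotype, so leave-one-out scans reduce to vector
# algebra instead of repeated lm() calls.

linear_r2_rows <- function(score_rows, y) {
  # score_rows: matrix, one candidate score vector per row; y: phenotype
  yc <- y - mean(y)
  ssy <- sum(yc^2)
  mu <- rowMeans(score_rows)
  cc <- score_rows - mu
  num <- as.vector(cc %*% yc)^2
  ssx <- rowSums(cc^2)
  r2 <- num / unname(ssx * ssy)
  # a score constant up to accumulated rounding has no defined slope
  sd_row <- sqrt(ssx / max(1, ncol(score_rows) - 1))
  r2[sd_row <= 1e-9 * (1 + abs(mu))] <- NA_real_
  unname(r2)
}

# two r2 values within this of each other are treated as tied; removals
# are accepted on the plateau so SNPs with zero contribution drop out
R2_TOL <- 1e-12

pruning_data <- function(freqs, panel, snp_set) {
  validate_frequency_matrix(freqs)
  snp_set <- as.character(snp_set)
  if (anyDuplicated(snp_set)) snp_set <- unique(snp_set)
  missing <- setdiff(snp_set, freqs$rsid)
  if (length(missing) > 0) {
    abort(sprintf("rsid(s) absent from frequency matrix: %s",
                  paste(missing, collapse = ", ")),
          class = "popprs_snp_error")
  }
  incomplete <- intersect(snp_set, incomplete_snps(freqs))
  if (length(incomplete) > 0) {
    abort(sprintf("rsid(s) with missing population frequencies: %s",
                  paste(incomplete, collapse = ", ")),
          class = "popprs_snp_error")
  }
  usable <- dplyr::filter(panel, !is.na(.data$phenotype_value))
  pops <- intersect(names(freqs)[-1], usable$population)
  if (length(pops) < 3) {
    abort("need at least 3 populations with phenotype data",
          class = "popprs_fit_error")
  }
  y <- usable$phenotype_value[match(pops, usable$population)]
  if (stats::var(y) == 0) {
    abort("phenotype is constant across populations; r2 undefined",
          class = "popprs_fit_error")
  }
  mat <- as.matrix(freqs[match(snp_set, freqs$rsid), pops, drop = FALSE])
  rownames(mat) <- snp_set
  list(mat = mat, y = y, snp_set = snp_set, populations = pops)
}

#' Leave-one-out r-squared over a SNP set
#'
#' For each SNP, computes the coefficient of determination of the linear
#' regression of phenotype on the psPRS built from the SNP set with that
#' one SNP removed. This per-SNP scan is the inner step of the
#' r-squared-maximization pruning procedure: SNPs whose removal raises
#' the r-squared are the ones degrading cross-population predictiveness.
#'
#' @inheritParams prune_maximize_r2
#' @return A tibble with columns `rsid` and `r2` (the r-squared of the
#'   fit without that rsid), one row per member of `snp_set`, in input
#'   order. `r2` is `NA` when the reduced fit is undefined (e.g. the
#'   remaining score is constant across populations); such cases are
#'   reported with a message.
#' @export
leave_one_out_r2 <- function(freqs, panel, snp_set) {
  if (length(snp_set) < 2) {
    abort("leave-one-out requires at least 2 SNPs", class = "popprs_fit_error")
  }
  pd <- pruning_data(freqs, panel, snp_set)
  total <- colSums(pd$mat)
  without <- matrix(rep(total, each = nrow(pd$mat)), nrow = nrow(pd$mat)) - pd$mat
  r2 <- linear_r2_rows(without, pd$y)
  if (anyNA(r2)) {
    inform(sprintf("reduced fit undefined after removing: %s",
                   paste(pd$snp_set[is.na(r2)], collapse = ", ")))
  }
  tibble(rsid = pd$snp_set, r2 = r2)
}

#' Prune SNPs by greedy maximization of r-squared
#'
#' Implements the sensitivity analysis that filters a psPRS down to the
#' SNPs that best predict trait prevalence across populations. Starting
#' from the full set, each iteration evaluates the linear-fit r-squared
#' of the score with each remaining SNP removed, discards the removal
#' that most improves (or, on a plateau, preserves) the r-squared, and
#' repeats until no removal helps or a single SNP remains. SNPs whose
#' presence lowers cross-population predictiveness — population-specific
#' or spurious associations — are thereby discarded while universally
#' acting SNPs are retained.
#'
#' Two removal granularities are available. The default `"single"` mode
#' removes one SNP per iteration (steepest ascent; the trace r-squared
#' is then non-decreasing by construction). `"batch"` mode removes every
#' SNP whose individual exclusion beats the current r-squared, then
#' refits; it is faster but can overshoot the maximum since the
#' individual exclusions are not additive.
#'
#' Ties are broken by earliest position in the input `snp_set` and
#' reported with a message. The acceptance rule is `>=`, so SNPs with
#' exactly zero contribution (e.g. a constant frequency column) are
#' removed on the plateau.
#'
#' @param freqs Frequency tibble (`rsid` + population columns).
#' @param panel Population panel; populations with missing phenotype
#'   values are ignored.
#' @param snp_set Character vector of rsids (at least 2), complete in
#'   `freqs`.
#' @param mode `"single"` (default) or `"batch"`.
#' @return An object of class `psprs_prune`: list with `steps` (tibble
#'   `step`, `rsid`, `r2` after the removal), `initial_r2`, `final_r2`,
#'   `retained` (rsids kept, in input order), `mode`, `populations`.
#'   Supports [tidy()], [glance()], [autoplot()].
#' @export
prune_maximize_r2 <- function(freqs, panel, snp_set, mode = c("single", "batch")) {
  mode <- match.arg(mode)
  if (length(snp_set) < 2) {
    abort("pruning requires at least 2 SNPs", class = "popprs_fit_error")
  }
  pd <- pruning_data(freqs, panel, snp_set)
  mat <- pd$mat; y <- pd$y
  current <- rownames(mat)
  current_r2 <- linear_r2_rows(matrix(colSums(mat), nrow = 1), y)[1]
  if (is.na(current_r2)) {
    abort("full-set linear fit is undefined (constant psPRS)",
          class = "popprs_fit_error")
  }
  initial_r2 <- current_r2
  steps <- list()
  step_i <- 0L
  repeat {
    if (length(current) <= 1) break
    sub <- mat[current, , drop = FALSE]
    total <- colSums(sub)
    without <- matrix(rep(total, each = nrow(sub)), nrow = nrow(sub)) - sub
    loo <- linear_r2_rows(without, y)
    if (mode == "single") {
      cand <- which(!is.na(loo) & loo >= current_r2 - R2_TOL)
      if (length(cand) == 0) break
      best_r2 <- max(loo[cand])
      best <- cand[loo[cand] >= best_r2 - R2_TOL]
      if (length(best) > 1) {
        inform(sprintf("tie at step %d between %s; removing earliest",
                       step_i + 1L, paste(current[best], collapse = ", ")))
      }
      pick <- best[1]
      step_i <- step_i + 1L
      steps[[step_i]] <- tibble(step = step_i, rsid = current[pick], r2 = loo[pick])
      current <- current[-pick]
      current_r2 <- loo[pick]
    } else {
      improving <- which(!is.na(loo) & loo > current_r2 + R2_TOL)
      if (length(improving) == 0) break
      if (length(improving) == length(current)) {
        # never empty the set: keep the single most predictive exclusion target
        improving <- improving[-which.max(loo[improving])]
        if (length(improving) == 0) break
      }
      removed <- current[improving]
      current <- current[-improving]
      current_r2 <- linear_r2_rows(
        matrix(colSums(mat[current, , drop = FALSE]), nrow = 1), y)[1]
      for (r in removed) {
        step_i <- step_i + 1L
        steps[[step_i]] <- tibble(step = step_i, rsid = r, r2 = current_r2)
      }
    }
  }
  steps_tbl <- if (step_i > 0) dplyr::bind_rows(steps) else
    tibble(step = integer(), rsid = character(), r2 = double())
  structure(
    list(steps = steps_tbl, initial_r2 = initial_r2, final_r2 = current_r2,
         retained = current, mode = mode, populations = pd$populations),
    class = "psprs_prune"
  )
}

#' Exhaustive best-subset search (small SNP sets)
#'
#' Enumerates every non-empty subset of `snp_set` (so at most 15 SNPs)
#' and returns the one whose psPRS linear fit has the highest
#' r-squared. Intended as a ground-truth reference for the greedy
#' procedure on small instances: the greedy final r-squared can never
#' exceed this value. Ties are broken in favour of the larger subset,
#' then by lexicographic order of the sorted rsid vectors.
#'
#' @inheritParams prune_maximize_r2
#' @return A list with `subset` (character vector, in input order) and
#'   `r2`.
#' @export
exhaustive_best_subset <- function(freqs, panel, snp_set) {
  n <- length(snp_set)
  if (n > 15) {
    abort(sprintf("exhaustive search limited to 15 SNPs (got %d)", n),
          class = "popprs_size_error")
  }
  if (n < 1) abort("snp_set must be non-empty")
  pd <- pruning_data(freqs, panel, snp_set)
  mat <- pd$mat; y <- pd$y
  ids <- rownames(mat)
  best <- NULL
  eps <- 1e-12
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    score <- colSums(mat[idx, , drop = FALSE])
    r2 <- linear_r2_rows(matrix(score, nrow = 1), y)[1]
    if (is.na(r2)) next
    if (is.null(best) || r2 > best$r2 + eps) {
      best <- list(subset = ids[idx], r2 = r2)
    } else if (abs(r2 - best$r2) <= eps) {
      cand <- ids[idx]
      take <- FALSE
      if (length(cand) > length(best$subset)) {
        take <- TRUE
      } else if (length(cand) == length(best$subset)) {
        a <- paste(sort(cand), collapse = "\r")
        b <- paste(sort(best$subset), collapse = "\r")
        take <- a < b
      }
      if (take) best <- list(subset = cand, r2 = max(r2, best$r2))
    }
  }
  if (is.null(best)) {
    abort("no subset yields a defined linear fit", class = "popprs_fit_error")
  }
  best
}

#' @export
print.psprs_prune <- function(x, ...) {
  cat(sprintf("psPRS pruning (%s mode): %d -> %d SNPs in %d removal(s)\n",
              x$mode, length(x$retained) + nrow(x$steps), length(x$retained),
              nrow(x$steps)))
  cat(sprintf("  r-squared %.4f -> %.4f\n", x$initial_r2, x$final_r2))
  invisible(x)
}

#' @rdname prune_maximize_r2
#' @param x A `psprs_prune` object.
#' @param ... Unused.
#' @export
tidy.psprs_prune <- function(x, ...) x$steps

#' @rdname prune_maximize_r2
#' @export
glance.psprs_prune <- function(x, ...) {
  tibble(mode = x$mode, n_input = length(x$retained) + nrow(x$steps),
         n_retained = length(x$retained), n_removed = nrow(x$steps),
         initial_r2 = x$initial_r2, final_r2 = x$final_r2)
}

#' @rdname prune_maximize_r2
#' @param object A `psprs_prune` object.
#' @export
autoplot.psprs_prune <- function(object, ...) {
  d <- dplyr::bind_rows(tibble(step = 0L, rsid = "(full set)", r2 = object$initial_r2),
                        object$steps)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$r2)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "SNPs removed", y = expression(r^2),
                  title = sprintf("r²-maximization pruning (%s mode)", object$mode)) +
    ggplot2::theme_minimal()
}
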