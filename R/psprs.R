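#' Population-specific polygenic risk scores
#'
#' The population-specific PRS (psPRS) for a population is the unweighted
#' sum of its risk-allele frequencies over a SNP set:
#' \deqn{\mathrm{psPRS} = \sum_k p_k}
#' where \eqn{p_k} is that population's frequency of the k-th risk
#' allele. No effect-size weighting is applied: at the population level,
#' effect sizes estimated in one ancestry need not transfer to another,
#' whereas the risk-allele frequency is measured in the scored
#' population itself.
#'
#' Every rsid in `snp_set` must be present in `freqs` and complete
#' (frequency observed in every population); incomplete SNPs would make
#' scores incomparable across populations, so they are refused rather
#' than partially summed.
#'
#' @param freqs Frequency tibble (`rsid` + population columns), e.g.
#'   from [read_frequency_matrix()].
#' @param snp_set Character vector of rsids to sum. May be empty, in
#'   which case every score is 0.
#' @return A tibble with columns `population` and `psprs`, carrying the
#'   summed rsids in attribute `"snp_set"`.
#' @export
#' @examples
#' freqs <- tibble::tibble(rsid = c("rs1", "rs2"), GBR = c(0.5, 0.2), YRI = c(0.1, 0.3))
#' compute_psprs(freqs, c("rs1", "rs2"))
compute_psprs <- function(freqs, snp_set) {
  validate_frequency_matrix(freqs)
  snp_set <- unique(as.character(snp_set))
  pops <- names(freqs)[-1]
  if (length(snp_set) == 0) {
    out <- tibble(population = pops, psprs = 0)
    attr(out, "snp_set") <- character()
    return(out)
  }
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
  mat <- as.matrix(freqs[match(snp_set, freqs$rsid), -1, drop = FALSE])
  out <- tibble(population = pops, psprs = unname(colSums(mat)))
  attr(out, "snp_set") <- snp_set
  out
}

join_scores_panel <- function(scores, panel) {
  stopifnot(all(c("population", "psprs") %in% names(scores)))
  merged <- dplyr::inner_join(
    dplyr::select(scores, "population", "psprs"),
    dplyr::filter(panel, !is.na(.data$phenotype_value)),
    by = "population"
  )
  merged
}

# noiseless inputs give exact fits; the "essentially perfect fit"
# caution is expected there, not a defect
quiet_summary <- function(fit) {
  withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

new_psprs_fit <- function(model, fit, data, response_label) {
  s <- quiet_summary(fit)
  fstat <- s$fstatistic
  p_value <- if (is.null(fstat)) NA_real_ else
    unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  structure(
    list(
      model = model,
      fit = fit,
      r2 = unname(s$r.squared),
      p_value = p_value,
      n = nrow(data),
      slope = unname(coef(fit)[2]),
      coefficients = coef(fit),
      data = data,
      response_label = response_label
    ),
    class = "psprs_fit"
  )
}

#' Regress population phenotype on psPRS
#'
#' Fits one of three models of the phenotype--psPRS relationship across
#' populations, by ordinary least squares:
#' \describe{
#'   \item{`linear`}{`phenotype ~ psprs`}
#'   \item{`poly2`}{`phenotype ~ psprs + psprs^2` (second-order polynomial)}
#'   \item{`exponential`}{`log(phenotype) ~ psprs`; coefficients are on
#'     the log-phenotype scale and the r-squared is the log-scale one.
#'     Fitting by log-OLS is deterministic and closed-form; the
#'     back-transformed per-unit growth factor `exp(slope)` is reported
#'     by [tidy()].}
#' }
#' The reported r-squared is the plain (unadjusted) coefficient of
#' determination and the p-value is the overall-model F-test (identical
#' to the slope t-test for the two single-predictor models).
#'
#' @param scores psPRS tibble from [compute_psprs()].
#' @param panel Population panel (see [read_population_panel()]);
#'   populations with missing phenotype values are excluded before
#'   fitting.
#' @param model `"linear"`, `"poly2"` or `"exponential"`.
#' @return An object of class `psprs_fit` with elements `model`, `r2`,
#'   `p_value`, `n`, `slope`, `coefficients`, the underlying `lm` fit
#'   and the fitting data; supports [tidy()], [glance()], [autoplot()].
#' @export
fit_psprs <- function(scores, panel, model = c("linear", "poly2", "exponential")) {
  model <- match.arg(model)
  data <- join_scores_panel(scores, panel)
  min_n <- if (model == "poly2") 4L else 3L
  if (nrow(data) < min_n) {
    abort(sprintf("%s fit needs at least %d populations with phenotype data, got %d",
                  model, min_n, nrow(data)),
          class = "popprs_fit_error")
  }
  if (stats::var(data$psprs) == 0) {
    abort("psPRS is constant across populations; slope undefined",
          class = "popprs_fit_error")
  }
  if (model == "exponential" && any(data$phenotype_value <= 0)) {
    abort(sprintf("exponential fit needs positive phenotype values; offending population(s): %s",
                  paste(data$population[data$phenotype_value <= 0], collapse = ", ")),
          class = "popprs_fit_error")
  }
  fit <- switch(model,
    linear = lm(phenotype_value ~ psprs, data = data),
    poly2 = lm(phenotype_value ~ psprs + I(psprs^2), data = data),
    exponential = lm(log(phenotype_value) ~ psprs, data = data)
  )
  new_psprs_fit(model, fit, data,
                if (model == "exponential") "log(phenotype)" else "phenotype")
}

#' @rdname fit_psprs
#' @export
fit_linear <- function(scores, panel) fit_psprs(scores, panel, "linear")

#' @rdname fit_psprs
#' @export
fit_poly2 <- function(scores, panel) fit_psprs(scores, panel, "poly2")

#' @rdname fit_psprs
#' @export
fit_exponential <- function(scores, panel) fit_psprs(scores, panel, "exponential")

#' Fit the phenotype--psPRS regression within each super-population
#'
#' Fits the chosen model independently inside each continental
#' super-population. Groups with fewer populations than the model needs
#' (3, or 4 for the polynomial) are skipped with a message, as are
#' groups with constant psPRS or (for the exponential model) nonpositive
#' phenotype values.
#'
#' @inheritParams fit_psprs
#' @return A tibble with one row per fitted super-population:
#'   `super_population`, `n`, `r2`, `p_value`, `slope`,
#'   `slope_sign` and a `fit` list-column of `psprs_fit` objects.
#'   Skipped groups are absent; their names are in attribute
#'   `"skipped"`.
#' @export
fit_by_super_population <- function(scores, panel,
                                    model = c("linear", "poly2", "exponential")) {
  model <- match.arg(model)
  data <- join_scores_panel(scores, panel)
  groups <- split(data$population, data$super_population)
  skipped <- character()
  rows <- list()
  for (sp in names(groups)) {
    sub_panel <- dplyr::filter(panel, .data$population %in% groups[[sp]])
    res <- tryCatch(fit_psprs(scores, sub_panel, model),
                    popprs_fit_error = function(e) e)
    if (inherits(res, "error")) {
      inform(sprintf("super-population %s skipped: %s", sp, conditionMessage(res)))
      skipped <- c(skipped, sp)
      next
    }
    rows[[sp]] <- tibble(super_population = sp, n = res$n, r2 = res$r2,
                         p_value = res$p_value, slope = res$slope,
                         slope_sign = sign(res$slope), fit = list(res))
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble(super_population = character(), n = integer(), r2 = double(),
           p_value = double(), slope = double(), slope_sign = double(),
           fit = list())
  attr(out, "skipped") <- skipped
  out
}

#' @export
print.psprs_fit <- function(x, ...) {
  cat(sprintf("psPRS %s fit: %d populations\n", x$model, x$n))
  cat(sprintf("  r-squared %.4f, slope %.4g, p-value %.3g\n", x$r2, x$slope, x$p_value))
  invisible(x)
}

#' @rdname fit_psprs
#' @param x A `psprs_fit` object.
#' @param ... Unused.
#' @export
tidy.psprs_fit <- function(x, ...) {
  s <- quiet_summary(x$fit)$coefficients
  out <- tibble(
    term = rownames(s),
    estimate = unname(s[, "Estimate"]),
    std.error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p.value = unname(s[, "Pr(>|t|)"])
  )
  if (x$model == "exponential") {
    out$growth_factor <- exp(out$estimate)
  }
  out
}

#' @rdname fit_psprs
#' @export
glance.psprs_fit <- function(x, ...) {
  tibble(model = x$model, r2 = x$r2, p_value = x$p_value, n = x$n, slope = x$slope)
}

#' @rdname fit_psprs
#' @param object A `psprs_fit` object.
#' @export
autoplot.psprs_fit <- function(object, ...) {
  d <- object$data
  d$.fitted_response <- if (object$model == "exponential")
    exp(stats::fitted(object$fit)) else stats::fitted(object$fit)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$psprs, y = .data$phenotype_value)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$super_population), size = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted_response),
                       linewidth = 0.4, colour = "grey30") +
    ggplot2::labs(x = "psPRS (sum of risk-allele frequencies)",
                  y = "phenotype value", colour = "super-population",
                  title = sprintf("%s fit: r² = %.2f, p = %.2g",
                                  object$model, object$r2, object$p_value)) +
    ggplot2::theme_minimal()
}
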