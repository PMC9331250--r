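#' Homeostasis model assessment of insulin resistance (HOMA-IR)
#'
#' `IR = insulin (ng/mL) x glucose (mM) / 22.5`. Vectorized; both inputs
#' must be non-negative.
#'
#' @param insulin fasting plasma insulin in ng/mL.
#' @param glucose fasting blood glucose in mM.
#' @return dimensionless HOMA-IR index.
#' @examples
#' homaIr(2.0, 6.7)   # lean control
#' homaIr(20.7, 6.9)  # insulin-resistant
#' @export
homaIr <- function(insulin, glucose) {
  if (any(insulin < 0) || any(glucose < 0))
    .err("negative_input", "insulin and glucose must be non-negative")
  insulin * glucose / 22.5
}

#' Two-group nonparametric comparison
#'
#' Two-sided Mann-Whitney U test (exact for small tie-free samples, normal
#' approximation with tie and continuity correction otherwise, the
#' standard [stats::wilcox.test()] behaviour), plus group means, SEMs and
#' the fold change of group means `b / a`.
#'
#' @param a,b numeric vectors, each of length >= 2 (convention: `a` =
#'   control/chow, `b` = treatment/HFD).
#' @return list with `mean_a`, `sem_a`, `mean_b`, `sem_b`, `fold_change`,
#'   `p_value`, `test`.
#' @export
compareGroups <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    .err("empty_group", "each group needs n >= 2")
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  p <- suppressWarnings(
    stats::wilcox.test(b, a, alternative = "two.sided"))$p.value
  list(mean_a = mean(a), sem_a = sem(a), mean_b = mean(b), sem_b = sem(b),
       fold_change = mean(b) / mean(a), p_value = p,
       test = "Mann-Whitney U")
}

#' Per-variable group comparisons with a Kruskal-Wallis gate
#'
#' For each phenotype variable and timepoint, compares HFD vs chow with
#' [compareGroups()]. When more than two (diet, time) groups are present
#' for a variable, a Kruskal-Wallis test across all groups is run first
#' and reported as a gate; with exactly two groups only the Mann-Whitney
#' test runs.
#'
#' @param pheno phenotype data.frame (see [readPhenotypeTable()]).
#' @param variables character, the measured columns to test (default: all
#'   numeric columns except `time_weeks`).
#' @return data.frame with one row per (variable, time_weeks): group
#'   means/SEMs, fold change HFD/chow, Mann-Whitney p, and the gate
#'   Kruskal-Wallis p for the variable (NA when only two groups exist).
#' @export
phenotypeStats <- function(pheno, variables = NULL) {
  if (is.null(variables)) {
    num <- vapply(pheno, is.numeric, logical(1))
    variables <- setdiff(colnames(pheno)[num], "time_weeks")
  }
  out <- list()
  for (v in variables) {
    grp <- interaction(pheno$diet, pheno$time_weeks, drop = TRUE)
    kw <- if (nlevels(grp) > 2)
      stats::kruskal.test(pheno[[v]], grp)$p.value else NA_real_
    for (tw in sort(unique(pheno$time_weeks))) {
      chow <- pheno[[v]][pheno$diet == "chow" & pheno$time_weeks == tw]
      hfd <- pheno[[v]][pheno$diet == "HFD" & pheno$time_weeks == tw]
      if (length(chow) < 2 || length(hfd) < 2) next
      cmp <- compareGroups(chow, hfd)
      out[[length(out) + 1L]] <- data.frame(
        variable = v, time_weeks = tw, mean_chow = cmp$mean_a,
        sem_chow = cmp$sem_a, mean_hfd = cmp$mean_b, sem_hfd = cmp$sem_b,
        fold_change = cmp$fold_change, p_mw = cmp$p_value,
        p_kruskal = kw, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Quadratic least-squares fit with R-squared
#'
#' Fits `y = b0 + b1 x + b2 x^2` by ordinary least squares and reports the
#' coefficients, `R^2 = 1 - SS_res / SS_tot`, and the p-value of the
#' 2-degree-of-freedom regression F-test.
#'
#' @param x,y numeric vectors, `length >= 4`, `x` not all identical.
#' @return list with `coefficients` (b0, b1, b2), `r_squared`, `p_value`.
#' @examples
#' quadraticFit(0:5, 1 + 2 * (0:5) - 0.3 * (0:5)^2)$r_squared  # 1
#' @export
quadraticFit <- function(x, y) {
  if (length(x) < 4 || length(x) != length(y))
    .err("bad_input", "need n >= 4 paired observations")
  if (stats::sd(x) == 0)
    .err("rank_deficient", "x values are all identical")
  if (stats::sd(y) == 0)  # SS_tot = 0: define R^2 = 0, nothing explained
    return(list(coefficients = c(b0 = y[1], b1 = 0, b2 = 0),
                r_squared = 0, p_value = 1))
  fit <- stats::lm(y ~ x + I(x^2))
  if (any(is.na(stats::coef(fit))))
    .err("rank_deficient", "quadratic design matrix is rank deficient")
  s <- summary(fit)
  pval <- if (s$sigma == 0) 0 else
    unname(stats::pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                     lower.tail = FALSE))
  list(coefficients = stats::setNames(unname(stats::coef(fit)),
                                      c("b0", "b1", "b2")),
       r_squared = s$r.squared, p_value = pval)
}
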